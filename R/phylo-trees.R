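#' Read a rooted, branch-length tree
#'
#' @param path tree file.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (default; NEXUS detected
#'   from a leading `#NEXUS`).
#' @return an `ape::phylo` tree, validated: rooted, unique tip labels,
#'   branch lengths present and non-negative.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tree <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("malformed ", format, " file ", path, ": ",
                             conditionMessage(e)))
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("not a parseable tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Write a tree
#'
#' @param tree `phylo` object.
#' @param path output path.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "nexus") ape::write.nexus(tree, file = path)
  else ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Resolve polytomies with zero-length branches
#'
#' Multifurcations are replaced by nested bifurcations joined by
#' zero-length branches, leaving total tree length and all tip-to-tip
#' patristic distances unchanged.  Resolution is deterministic
#' (children attached in input order) unless `random = TRUE`.
#'
#' @param tree `phylo`.
#' @param random resolve in random order (default `FALSE`).
#' @param seed seed used when `random = TRUE`.
#' @return a strictly binary `phylo`.
#' @export
resolve_polytomies <- function(tree, random = FALSE, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  if (random) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  out <- ape::multi2di(tree, random = random)
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}

#' Prune a tree to a set of taxa
#'
#' @param tree `phylo`.
#' @param names tip labels to retain.
#' @return the induced subtree (degree-2 nodes suppressed, stem lengths
#'   summed); patristic distances among retained tips are preserved.
#' @export
prune_to_taxa <- function(tree, names) {
  unknown <- setdiff(names, tree$tip.label)
  if (length(unknown))
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (setequal(names, tree$tip.label)) return(tree)
  ape::keep.tip(tree, names)
}

# tips below each edge: list over edge rows of tip index vectors
tips_below_edges <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  below <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) below[[i]] <- i
  # postorder guarantees children before parents
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2]]])
}

#' Paint evolutionary regimes onto a tree
#'
#' Either supply explicit clade assignments (`clades`, a named list mapping
#' state -> character vector of tips whose MRCA clade takes that state), or
#' only `tip_states` (named by tip), in which case every maximal clade whose
#' tips all share one state is painted with it and remaining branches take
#' the base state.  Clade painting includes the stem branch of the clade by
#' default; nested clades override their enclosing clade.
#'
#' @param tree binary rooted `phylo`.
#' @param base_state state of unpainted branches (default `"background"`;
#'   with `tip_states` only, defaults to the most frequent state).
#' @param clades named list: `list(state = c("tipA", "tipB", ...))`.
#' @param tip_states named character vector of states per tip.
#' @param include_stem paint the stem branch of each clade (default `TRUE`).
#' @return list of class `regime_painting`: `tree`, `edge_state` (state per
#'   edge row), `tip_states`, `states`.
#' @export
paint_regimes <- function(tree, base_state = NULL, clades = NULL,
                          tip_states = NULL, include_stem = TRUE) {
  n_tip <- length(tree$tip.label)
  edge_state <- NULL
  if (!is.null(clades)) {
    if (is.null(base_state)) base_state <- "background"
    edge_state <- rep(base_state, nrow(tree$edge))
    mrcas <- vapply(clades, function(tips) {
      unknown <- setdiff(tips, tree$tip.label)
      if (length(unknown))
        stop("unknown tip(s) in clade rule: ",
             paste(unknown, collapse = ", "))
      if (length(tips) == 1) match(tips, tree$tip.label)
      else ape::getMRCA(tree, tips)
    }, 0L)
    if (anyDuplicated(mrcas)) {
      d <- which(duplicated(mrcas) | duplicated(mrcas, fromLast = TRUE))
      stop("conflicting clade assignments: states ",
           paste(names(clades)[d], collapse = " and "),
           " name the same clade")
    }
    below <- tips_below_edges(tree)
    clade_sizes <- vapply(mrcas, function(nd)
      length(tips_under_node(tree, nd)), 0L)
    for (j in order(clade_sizes, decreasing = TRUE)) {
      nd <- mrcas[j]
      desc_tips <- tips_under_node(tree, nd)
      in_clade <- vapply(seq_len(nrow(tree$edge)), function(e)
        all(below[[e]] %in% desc_tips), TRUE)
      stem <- which(tree$edge[, 2] == nd)
      sel <- which(in_clade)
      if (!include_stem) sel <- setdiff(sel, stem)
      else sel <- union(sel, stem)
      edge_state[sel] <- names(clades)[j]
    }
    tip_states <- stats::setNames(
      edge_state[match(seq_len(n_tip), tree$edge[, 2])], tree$tip.label)
  } else if (!is.null(tip_states)) {
    tip_states <- tip_states[tree$tip.label]
    if (anyNA(tip_states))
      stop("every tip needs a state; missing: ",
           paste(tree$tip.label[is.na(tip_states)], collapse = ", "))
    if (is.null(base_state))
      base_state <- names(which.max(table(tip_states)))
    below <- tips_below_edges(tree)
    edge_state <- vapply(below, function(tp) {
      st <- unique(tip_states[tree$tip.label[tp]])
      if (length(st) == 1) st else base_state
    }, "")
  } else stop("supply either clades or tip_states")
  structure(list(tree = tree, edge_state = edge_state,
                 tip_states = tip_states,
                 states = sort(unique(c(edge_state, tip_states)))),
            class = "regime_painting")
}

# tip set under an internal node (breadth-first)
tips_under_node <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  todo <- node
  tips <- integer(0)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    ch <- children[[as.character(nd)]]
    tips <- c(tips, ch[ch <= n_tip])
    todo <- c(todo, ch[ch > n_tip])
  }
  sort(tips)
}

#' Per-branch segment table of a painting
#'
#' @param painting a [paint_regimes()] result.
#' @return data.frame `parent`, `child`, `length`, `state` (one segment per
#'   branch; segment lengths sum to branch lengths by construction).
#' @export
painting_segments <- function(painting) {
  data.frame(parent = painting$tree$edge[, 1],
             child = painting$tree$edge[, 2],
             length = painting$tree$edge.length,
             state = painting$edge_state)
}

#' Phylogenetic covariance matrix (optionally split by painted state)
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j
#' (diagonal = root-to-tip depth).  Under a painting, one component matrix
#' per state accumulates only the branch segments in that state; the
#' components sum to the total matrix.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param painting optional [paint_regimes()] result on the same tree.
#' @return the tip x tip covariance matrix, or (with a painting) a list
#'   with `total` and `components` (named by state).
#' @export
phylo_covariance <- function(tree, painting = NULL) {
  n_tip <- length(tree$tip.label)
  below <- tips_below_edges(tree)
  states <- if (is.null(painting)) rep("total", nrow(tree$edge))
            else painting$edge_state
  labs <- tree$tip.label
  comps <- lapply(unique(states), function(s) {
    C <- matrix(0, n_tip, n_tip, dimnames = list(labs, labs))
    for (e in which(states == s)) {
      idx <- below[[e]]
      C[idx, idx] <- C[idx, idx] + tree$edge.length[e]
    }
    C
  })
  names(comps) <- unique(states)
  if (is.null(painting)) return(comps[["total"]])
  list(total = Reduce(`+`, comps), components = comps)
}

# Cholesky with documented ridge fallback for (near-)singular covariances,
# e.g. duplicated rows from zero-length branches.
chol_with_ridge <- function(V, label = "covariance") {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  ridge_used <- 0
  if (is.null(ch)) {
    ridge_used <- 1e-8 * mean(diag(V))
    ch <- tryCatch(chol(V + diag(ridge_used, nrow(V))),
                   error = function(e) NULL)
    if (is.null(ch))
      stop(label, " singular even after ridge regularisation")
    warning(label, " singular; ridge of ", format(ridge_used, digits = 3),
            " added to the diagonal")
  }
  attr(ch, "ridge") <- ridge_used
  ch
}

# root-to-node depths (root depth 0)
node_depths <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n)
  for (e in rev(ape::postorder(tree)))  # preorder: parents before children
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + tree$edge.length[e]
  depth
}
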
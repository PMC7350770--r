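#' Simulate a rooted time tree
#'
#' Birth-death (conditioned on the tip count, ultrametric) or coalescent
#' trees; optionally a subset of tips is turned into "fossils" by shortening
#' their terminal branches, giving a non-ultrametric tree with extinct
#' samples like a fossil-calibrated phylogeny.
#'
#' @param n_tips number of tips (>= 2).
#' @param model `"birth-death"` (default) or `"coalescent"`.
#' @param birth,death birth-death rates per My (defaults 0.4, 0.2).
#' @param fossil_tips how many tips to truncate into fossils (default 0).
#' @param seed integer seed.
#' @return a rooted binary `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, model = c("birth-death", "coalescent"),
                          birth = 0.4, death = 0.2, fossil_tips = 0L,
                          seed = 1L) {
  model <- match.arg(model)
  if (n_tips < 2) stop("n_tips must be at least 2")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  tree <- if (model == "birth-death")
    ape::rphylo(n_tips, birth = birth, death = death)
  else ape::rcoal(n_tips)
  if (fossil_tips > 0) {
    term <- match(seq_len(n_tips), tree$edge[, 2])
    pick <- sample.int(n_tips, min(fossil_tips, n_tips))
    frac <- stats::runif(length(pick), 0.2, 0.9)
    tree$edge.length[term[pick]] <- tree$edge.length[term[pick]] * (1 - frac)
    tree$edge.length <- pmax(tree$edge.length, 1e-8)
  }
  validate_tree(tree)
}

#' Simulate a continuous trait on a tree
#'
#' Recursive root-to-tip simulation under Brownian motion or
#' Ornstein-Uhlenbeck dynamics.  Planted rate shifts multiply the Brownian
#' variance of an edge and all its descendants (nested override, as in the
#' rjMCMC model); planted jumps add an independent normal displacement on
#' the marked edges, inherited below.  Under OU with a painting, each edge
#' evolves towards the optimum of its painted state with the exact OU
#' transition.
#'
#' @param tree rooted binary `phylo`.
#' @param sigma2 Brownian rate (trait^2 per My).
#' @param root root state (default 0).
#' @param trend drift per My (BM only, default 0).
#' @param alpha OU attraction (default `NULL` = BM).
#' @param optima named optima per painted state (OU; a single unnamed value
#'   for an unpainted tree).
#' @param painting optional [paint_regimes()] result (OU regimes).
#' @param shift_edges named numeric vector: edge index -> rate multiplier.
#' @param jump_edges integer vector of edge indices receiving one jump each
#'   (repeat an index for multiple jumps).
#' @param jump_sd SD of each jump displacement (default 0).
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, sigma2 = 1, root = 0, trend = 0,
                           alpha = NULL, optima = NULL, painting = NULL,
                           shift_edges = NULL, jump_edges = integer(0),
                           jump_sd = 0, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n_edge <- nrow(tree$edge)
  scalar <- rep(0, n_edge)
  if (!is.null(shift_edges))
    scalar[as.integer(names(shift_edges))] <- as.numeric(shift_edges)
  pre <- rev(ape::postorder(tree))
  rates <- rbm_rel_rates_cpp(tree$edge[, 1], tree$edge[, 2], pre, scalar)
  jumps <- tabulate(jump_edges, n_edge)
  states <- if (!is.null(painting)) painting$edge_state else
    rep("s", n_edge)
  if (!is.null(alpha) && is.null(optima))
    stop("OU simulation needs optima")
  if (!is.null(optima) && is.null(names(optima)) && length(optima) == 1)
    names(optima) <- unique(states)[1]
  root_node <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  x <- numeric(max(tree$edge))
  x[root_node] <- root
  for (e in pre) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    v <- sigma2 * rates[e]
    if (is.null(alpha) || alpha < 1e-12) {
      x[ch] <- x[p] + trend * len + stats::rnorm(1, 0, sqrt(v * len))
    } else {
      th <- optima[[states[e]]]
      if (is.null(th)) stop("no optimum for state ", states[e])
      w <- exp(-alpha * len)
      sd_ou <- sqrt(v * (1 - exp(-2 * alpha * len)) / (2 * alpha))
      x[ch] <- x[p] * w + th * (1 - w) + stats::rnorm(1, 0, sd_ou)
    }
    if (jumps[e] > 0)
      x[ch] <- x[ch] + sum(stats::rnorm(jumps[e], 0, jump_sd))
  }
  stats::setNames(x[seq_along(tree$tip.label)], tree$tip.label)
}

#' Simulate a discrete character on a tree
#'
#' Continuous-time Markov simulation along each branch under a rate matrix
#' Q (exponential waiting times between transitions).
#'
#' @param tree rooted `phylo`.
#' @param model an [mk_model()] (or a bare rate matrix with dimnames).
#' @param root_state starting state (default: uniform draw).
#' @param seed integer seed.
#' @return named character vector of tip states.
#' @export
simulate_discrete <- function(tree, model, root_state = NULL, seed = 1L) {
  Q <- if (inherits(model, "mk_model")) model$Q else as.matrix(model)
  states <- rownames(Q)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  root_node <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  st <- character(max(tree$edge))
  st[root_node] <- root_state %||% sample(states, 1)
  for (e in rev(ape::postorder(tree))) {
    s <- st[tree$edge[e, 1]]
    t_left <- tree$edge.length[e]
    repeat {
      out_rate <- -Q[s, s]
      if (out_rate <= 0) break
      wait <- stats::rexp(1, out_rate)
      if (wait > t_left) break
      t_left <- t_left - wait
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample(states, 1, prob = probs)
    }
    st[tree$edge[e, 2]] <- s
  }
  stats::setNames(st[seq_along(tree$tip.label)], tree$tip.label)
}
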
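#' Build an Mk rate matrix
#'
#' Continuous-time Markov models of discrete character evolution with the
#' three classic transition structures: `ER` (all transitions share one
#' rate), `SYM` (rate i->j equals j->i), `ARD` (every ordered pair has its
#' own rate).  Off-diagonals are non-negative and rows sum to zero.
#'
#' @param states character vector of state labels (length s >= 2).
#' @param structure `"ER"`, `"SYM"`, or `"ARD"`.
#' @param rates free rate parameters: length 1 (ER), s(s-1)/2 (SYM, filling
#'   the upper triangle row-wise), or s(s-1) (ARD, off-diagonals row-wise).
#' @return list of class `mk_model`: `states`, `structure`, `rates`, `Q`.
#' @export
mk_model <- function(states, structure = c("ER", "SYM", "ARD"), rates) {
  structure <- match.arg(structure)
  s <- length(states)
  if (s < 2) stop("need at least 2 states")
  k <- mk_n_params(s, structure)
  if (length(rates) != k)
    stop(structure, " with ", s, " states needs ", k, " rate(s)")
  if (any(rates < 0)) stop("rates must be non-negative")
  Q <- matrix(0, s, s, dimnames = list(states, states))
  if (structure == "ER") {
    Q[] <- rates[1]
  } else if (structure == "SYM") {
    Q[upper.tri(Q)] <- 0
    idx <- 1
    for (i in seq_len(s - 1)) for (j in (i + 1):s) {
      Q[i, j] <- Q[j, i] <- rates[idx]; idx <- idx + 1
    }
  } else {
    idx <- 1
    for (i in seq_len(s)) for (j in seq_len(s)) if (i != j) {
      Q[i, j] <- rates[idx]; idx <- idx + 1
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  base::structure(list(states = states, structure = structure,
                       rates = rates, Q = Q),
                  class = "mk_model")
}

mk_n_params <- function(s, structure)
  switch(structure, ER = 1L, SYM = as.integer(s * (s - 1) / 2),
         ARD = as.integer(s * (s - 1)))

# matrix exponential via eigendecomposition, Pade/scaling-squaring fallback
mat_exp_factory <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  usable <- !is.null(eg) &&
    rcond(Re(eg$vectors)) > 1e-12 && all(abs(Im(eg$values)) < 1e-8)
  if (usable) {
    U <- Re(eg$vectors); Uinv <- solve(U); lam <- Re(eg$values)
    function(t) U %*% (exp(lam * t) * Uinv)
  } else {
    function(t) expm_ss(Q * t)
  }
}

# simple scaling-and-squaring Taylor matrix exponential (small matrices)
expm_ss <- function(A) {
  n <- nrow(A)
  j <- max(0, ceiling(log2(max(norm(A, "I"), 1e-300)))) + 1
  As <- A / 2^j
  E <- diag(n); term <- diag(n)
  for (k in 1:12) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(j)) E <- E %*% E
  E
}

#' Mk log-likelihood by the pruning algorithm
#'
#' Felsenstein pruning with a matrix exponential per branch; the root is
#' handled by a uniform prior over states (default) or the stationary
#' distribution of Q.
#'
#' @param tree rooted binary `phylo` with branch lengths.
#' @param tip_states named character vector (names = tip labels) of states.
#' @param model an [mk_model()].
#' @param root_prior `"uniform"` (default) or `"stationary"`.
#' @return the log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, tip_states, model,
                      root_prior = c("uniform", "stationary")) {
  root_prior <- match.arg(root_prior)
  s <- length(model$states)
  tip_states <- tip_states[tree$tip.label]
  if (anyNA(tip_states))
    stop("tip(s) without a state: ",
         paste(tree$tip.label[is.na(tip_states)], collapse = ", "))
  bad <- setdiff(unique(tip_states), model$states)
  if (length(bad))
    stop("state(s) not in the model vocabulary: ",
         paste(bad, collapse = ", "))
  n_tip <- length(tree$tip.label)
  po <- ape::postorder(tree)
  root_node <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  pi0 <- if (root_prior == "uniform") rep(1 / s, s)
         else as.numeric(stationary_dist(model$Q))
  # fast path: real, well-conditioned eigendecomposition handled in C++
  eg <- tryCatch(eigen(model$Q), error = function(e) NULL)
  if (!is.null(eg) && all(abs(Im(eg$values)) < 1e-8) &&
      rcond(Re(eg$vectors)) > 1e-12) {
    U <- Re(eg$vectors)
    return(mk_loglik_cpp(tree$edge[, 1], tree$edge[, 2],
                         tree$edge.length, po, n_tip, root_node,
                         match(tip_states, model$states), U, solve(U),
                         Re(eg$values), pi0))
  }
  pexp <- mat_exp_factory(model$Q)
  L <- matrix(1, n_tip + tree$Nnode, s)
  L[seq_len(n_tip), ] <- 0
  L[cbind(seq_len(n_tip), match(tip_states, model$states))] <- 1
  logscale <- 0
  # accumulate per-parent products of P(t) %*% L_child
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    msg <- pexp(tree$edge.length[e]) %*% L[ch, ]
    L[p, ] <- L[p, ] * msg
    m <- max(L[p, ])
    if (m > 0 && m < 1e-100) { L[p, ] <- L[p, ] / m; logscale <- logscale + log(m) }
  }
  val <- sum(pi0 * L[root_node, ])
  if (val <= 0) return(-Inf)
  log(val) + logscale
}

stationary_dist <- function(Q) {
  s <- nrow(Q)
  A <- rbind(t(Q), rep(1, s))
  b <- c(rep(0, s), 1)
  pi0 <- qr.solve(A, b)
  pi0 / sum(pi0)
}

#' Maximum-likelihood Mk fit
#'
#' Rates are maximised by bounded quasi-Newton search on the log scale
#' (bounds 1e-8 to 1e3 per My), from multiple deterministic starts.
#'
#' @inheritParams mk_loglik
#' @param structure transition structure (`"ER"`, `"SYM"`, `"ARD"`).
#' @param n_starts number of optimisation starts (default 5).
#' @return list of class `mk_fit`: `structure`, `rates`, `logLik`, `k`,
#'   `AIC`, `model`.
#' @export
fit_mk <- function(tree, tip_states, structure = c("ER", "SYM", "ARD"),
                   root_prior = "uniform", n_starts = 5L) {
  structure <- match.arg(structure)
  states <- sort(unique(tip_states))
  s <- length(states)
  k <- mk_n_params(s, structure)
  depth <- max(node_depths(tree))
  nll <- function(logr) {
    m <- mk_model(states, structure, exp(logr))
    -mk_loglik(tree, tip_states, m, root_prior)
  }
  # starts spread around the parsimony-informed scale 1/depth
  starts <- log(c(0.5, 2, 0.1, 10, 1)[seq_len(n_starts)] / depth)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(rep(st, k), nll, method = "L-BFGS-B",
                   lower = log(1e-8), upper = log(1e3),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("Mk optimisation failed for structure ", structure)
  rates <- exp(best$par)
  ll <- -best$value
  base::structure(
    list(structure = structure, rates = rates, logLik = ll, k = k,
         AIC = 2 * k - 2 * ll,
         model = mk_model(states, structure, rates)),
    class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$structure, "): logLik ", format(x$logLik, digits = 6),
      ", k = ", x$k, ", AIC = ", format(x$AIC, digits = 6), "\n", sep = "")
  invisible(x)
}
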
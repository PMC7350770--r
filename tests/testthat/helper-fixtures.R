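# Shared fixtures for the suite.  Everything is generated in code; nothing
# is read from disk except files the tests themselves write to tempdirs.

# tiny scheme: 2 bilateral pairs + 3 midline points (n_total = 7)
tiny_scheme <- function() {
  landmark_scheme(pairs = rbind(c(1, 3), c(2, 4)), midline = 5:7,
                  regions = c("nasal", "jugal", "nasal", "jugal",
                              "rostrum", "rostrum", "posterior"))
}

# a small configuration in general position for the tiny scheme
tiny_config <- function(id = "t1") {
  coords <- rbind(c(0.0, 1.0, 0.2),   # left nasal
                  c(1.0, 0.8, 0.1),   # left jugal
                  c(0.0, -1.0, 0.2),  # right nasal (mirror of 1)
                  c(1.0, -0.8, 0.1),  # right jugal (mirror of 2)
                  c(-0.5, 0, 0.0),    # midline
                  c(0.5, 0, 0.6),
                  c(1.5, 0, 0.1))
  landmark_config(id, coords)
}

# random rigid motion (proper rotation + translation), seeded
random_rigid <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, b = rnorm(3, 0, 5))
}

# matrix exponential via eigen (independent of package internals)
oracle_expm <- function(Q, t) {
  eg <- eigen(Q)
  Re(eg$vectors %*% diag(exp(eg$values * t), nrow(Q)) %*%
       solve(eg$vectors))
}

# brute-force Mk likelihood: sum over all internal-node state assignments
oracle_mk_lik <- function(tree, tip_states, Q, root_prior = NULL) {
  s <- nrow(Q)
  states <- rownames(Q)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  if (is.null(root_prior)) root_prior <- rep(1 / s, s)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  tip_idx <- match(tip_states[tree$tip.label], states)
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), n_int)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    state_of <- function(node)
      if (node <= n_tip) tip_idx[node] else assign_int[node - n_tip]
    term <- root_prior[state_of(root)]
    for (e in seq_len(nrow(tree$edge)))
      term <- term * P[[e]][state_of(tree$edge[e, 1]),
                            state_of(tree$edge[e, 2])]
    tot <- tot + as.numeric(term)
  }
  tot
}

# GLS closed-form BM estimates (independent linear-algebra route)
oracle_bm_fit <- function(tree, y) {
  C <- ape::vcv(tree)
  y <- y[rownames(C)]
  Ci <- solve(C)
  X <- matrix(1, length(y), 1)
  b <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  r <- y - as.numeric(b)
  s2 <- as.numeric(t(r) %*% Ci %*% r) / length(y)
  n <- length(y)
  ll <- -n / 2 * log(2 * pi * s2) -
    0.5 * determinant(C)$modulus[1] - n / 2
  list(root = as.numeric(b), sigma2 = s2, logLik = as.numeric(ll))
}

# cumulative distribution of a Half-Cauchy(scale)
phalfcauchy <- function(q, scale) 2 * (stats::pcauchy(q / scale) - 0.5)

# tips of some internal clade with size in [lo, hi] (never the whole tree)
clade_tips <- function(tree, lo, hi) {
  n_tip <- ape::Ntip(tree)
  for (nd in (n_tip + 2):(n_tip + tree$Nnode)) {
    tps <- ape::extract.clade(tree, nd)$tip.label
    if (length(tps) >= lo && length(tps) <= hi) return(tps)
  }
  stop("no clade of size ", lo, "-", hi, " in this tree")
}
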
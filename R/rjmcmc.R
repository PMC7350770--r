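#' Prior configuration for the relaxed-BM reversible-jump sampler
#'
#' Defaults follow the weakly informative choices standard for this model
#' class: a Poisson prior with mean log(2) on the number of rate shifts
#' (placing 50% prior probability on zero shifts), Half-Cauchy(scale 25)
#' priors on rate scalars and the measurement-error variance, and, for the
#' jump model, a Poisson prior on the tree-wide jump count and a
#' Half-Cauchy prior on the jump variance.
#'
#' @param shift_mean Poisson mean of the shift count (default `log(2)`).
#' @param scalar_scale Half-Cauchy scale of rate scalars (default 25).
#' @param error_scale Half-Cauchy scale of the measurement-error variance
#'   (default 25).
#' @param jump_mean Poisson mean of the tree-wide jump count (default
#'   `log(2)`).
#' @param jump_scale Half-Cauchy scale of the jump variance (default 25).
#' @return list of class `prior_config`.
#' @export
prior_config <- function(shift_mean = log(2), scalar_scale = 25,
                         error_scale = 25, jump_mean = log(2),
                         jump_scale = 25) {
  vals <- c(shift_mean, scalar_scale, error_scale, jump_mean, jump_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid prior: all Poisson means and Half-Cauchy scales must be ",
         "positive")
  structure(list(shift_mean = shift_mean, scalar_scale = scalar_scale,
                 error_scale = error_scale, jump_mean = jump_mean,
                 jump_scale = jump_scale),
            class = "prior_config")
}

# Half-Cauchy(scale) log density on [0, Inf)
dhalfcauchy_log <- function(x, scale)
  ifelse(x < 0, -Inf, log(2 / (pi * scale * (1 + (x / scale)^2))))

rhalfcauchy <- function(n, scale) abs(stats::rcauchy(n, scale = scale))

#' Run the reversible-jump MCMC over relaxed Brownian motion
#'
#' Samples branch rate-shift configurations (and, with `model =
#' "jump-rbm"`, per-branch trait jumps) for a continuous trait on a binary
#' tree.  A shift rescales the Brownian rate of its branch and all
#' descendants until overridden deeper; a jump adds an independent normal
#' displacement (variance = jump variance) inherited by the branch's
#' descendants, entering the likelihood as extra branch variance.  The
#' likelihood is the Brownian pruning likelihood with per-branch variances
#' `sigma2 * rate * length + jump_var * n_jumps` and measurement error on
#' the tip diagonal.
#'
#' @param tree binary rooted `phylo`.
#' @param trait named numeric vector of tip values (ignored when
#'   `likelihood = FALSE`).
#' @param prior a [prior_config()].
#' @param n_gen number of generations.
#' @param thin sampling interval (`n_gen >= thin`).
#' @param model `"rbm"` (shifts only) or `"jump-rbm"` (shifts + jumps).
#' @param seed integer seed; identical inputs and seed give an identical
#'   trace.
#' @param likelihood set `FALSE` for prior-predictive runs (likelihood
#'   ratio fixed at 1).
#' @param jump_cap maximum jumps per branch (default 5).
#' @return list of class `posterior_trace`: `samples` (one list per
#'   retained generation: `gen`, `shifts` data.frame, `jump_counts`,
#'   `sigma2`, `jump_var`, `me`, `z0`, `loglik`), `scalars` (data.frame of
#'   scalar traces), `tree`, `model`, `seed`, `thin`, `n_gen`,
#'   `acceptance` (rates per move type).
#' @export
run_rjmcmc <- function(tree, trait, prior = prior_config(),
                       n_gen = 1e6, thin = 1e4,
                       model = c("rbm", "jump-rbm"), seed = 1L,
                       likelihood = TRUE, jump_cap = 5L) {
  model <- match.arg(model)
  if (!inherits(prior, "prior_config")) stop("invalid prior")
  if (n_gen < thin) stop("n_gen must be at least thin")
  if (!ape::is.binary(tree)) stop("tree must be binary; ",
                                  "run resolve_polytomies first")
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  po <- ape::postorder(tree)
  pre <- rev(po)
  n_edge <- nrow(tree$edge)
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  y <- if (likelihood) prep_trait(tree, trait) else
    stats::setNames(rep(0, n_tip), tree$tip.label)
  sdy <- max(stats::sd(y), 1e-6)

  ll_fun <- function(st) {
    if (!likelihood) return(0)
    rbm_loglik_cpp(tree$edge[, 1], tree$edge[, 2], tree$edge.length,
                   pre, po, n_tip, root, as.numeric(y), st$scalar,
                   st$jumps, st$sigma2, st$jump_var, st$me, st$z0)
  }

  depth <- max(node_depths(tree))
  init_state <- function(attempt) {
    jit <- if (attempt == 1) 1 else exp(stats::rnorm(1, 0, 1))
    list(scalar = rep(0, n_edge),         # 0 = no shift on this edge
         jumps = rep(0L, n_edge),
         sigma2 = jit * max(stats::var(y), 1e-8) / max(depth, 1e-8),
         jump_var = if (model == "jump-rbm") 0.1 * max(stats::var(y), 1e-8)
                    else 0,
         me = 1e-4 * max(stats::var(y), 1e-8),
         z0 = mean(y))
  }
  st <- NULL
  for (attempt in 1:10) {
    cand <- init_state(attempt)
    if (is.finite(ll_fun(cand))) { st <- cand; break }
  }
  if (is.null(st)) stop("non-finite likelihood at initial state after ",
                        "10 re-initialisations")
  ll <- ll_fun(st)

  moves <- c(base_rate = 0.20, scalar = 0.20, birth = 0.10, death = 0.10,
             reloc = 0.10, root = 0.05, me = 0.05,
             jbirth = 0.07, jdeath = 0.07, jreloc = 0.03, jvar = 0.03)
  if (model == "rbm") moves <- moves[1:7]
  moves <- moves / sum(moves)
  acc <- att <- stats::setNames(numeric(length(moves)), names(moves))

  lam_s <- prior$shift_mean
  lam_j <- prior$jump_mean
  n_samp <- floor(n_gen / thin)
  samples <- vector("list", n_samp)
  scalars <- matrix(NA_real_, n_samp, 8,
                    dimnames = list(NULL, c("gen", "n_shifts", "n_jumps",
                                            "sigma2", "jump_var", "me",
                                            "z0", "loglik")))
  si <- 0L
  move_names <- names(moves)
  move_draws <- sample(length(moves), n_gen, replace = TRUE, prob = moves)

  for (gen in seq_len(n_gen)) {
    mv <- move_names[move_draws[gen]]
    att[mv] <- att[mv] + 1
    prop <- st
    log_alpha <- NULL
    if (mv == "base_rate") {
      f <- exp(stats::rnorm(1, 0, 0.5))
      prop$sigma2 <- st$sigma2 * f
      log_alpha <- dhalfcauchy_log(prop$sigma2, prior$scalar_scale) -
        dhalfcauchy_log(st$sigma2, prior$scalar_scale) + log(f)
    } else if (mv == "scalar") {
      has <- which(st$scalar > 0)
      if (!length(has)) {           # fall back to a base-rate update
        f <- exp(stats::rnorm(1, 0, 0.5))
        prop$sigma2 <- st$sigma2 * f
        log_alpha <- dhalfcauchy_log(prop$sigma2, prior$scalar_scale) -
          dhalfcauchy_log(st$sigma2, prior$scalar_scale) + log(f)
      } else {
        e <- has[sample.int(length(has), 1)]
        f <- exp(stats::rnorm(1, 0, 0.5))
        prop$scalar[e] <- st$scalar[e] * f
        log_alpha <- dhalfcauchy_log(prop$scalar[e], prior$scalar_scale) -
          dhalfcauchy_log(st$scalar[e], prior$scalar_scale) + log(f)
      }
    } else if (mv == "birth") {
      free <- which(st$scalar <= 0)
      k <- n_edge - length(free)
      if (length(free)) {
        e <- free[sample.int(length(free), 1)]
        prop$scalar[e] <- rhalfcauchy(1, prior$scalar_scale)
        # scalar prior cancels against its proposal; uniform placement and
        # binomial configuration terms cancel against birth/death choice
        log_alpha <- log(lam_s) - log(k + 1)
      }
    } else if (mv == "death") {
      has <- which(st$scalar > 0)
      k <- length(has)
      if (k) {
        e <- has[sample.int(k, 1)]
        prop$scalar[e] <- 0
        log_alpha <- log(k) - log(lam_s)
      }
    } else if (mv == "reloc") {
      has <- which(st$scalar > 0)
      free <- which(st$scalar <= 0)
      if (length(has) && length(free)) {
        e <- has[sample.int(length(has), 1)]
        to <- free[sample.int(length(free), 1)]
        prop$scalar[to] <- st$scalar[e]
        prop$scalar[e] <- 0
        log_alpha <- 0
      }
    } else if (mv == "root") {
      prop$z0 <- st$z0 + stats::rnorm(1, 0, sdy / 4)
      log_alpha <- 0
    } else if (mv == "me") {
      f <- exp(stats::rnorm(1, 0, 0.5))
      prop$me <- st$me * f
      log_alpha <- dhalfcauchy_log(prop$me, prior$error_scale) -
        dhalfcauchy_log(st$me, prior$error_scale) + log(f)
    } else if (mv == "jbirth") {
      e <- sample.int(n_edge, 1)
      if (st$jumps[e] < jump_cap) {
        prop$jumps[e] <- st$jumps[e] + 1L
        J <- sum(st$jumps)
        log_alpha <- log(lam_j) - log(J + 1)
      }
    } else if (mv == "jdeath") {
      J <- sum(st$jumps)
      if (J > 0) {
        e <- sample.int(n_edge, 1, prob = st$jumps)
        prop$jumps[e] <- st$jumps[e] - 1L
        log_alpha <- log(J) - log(lam_j)
      }
    } else if (mv == "jreloc") {
      J <- sum(st$jumps)
      if (J > 0) {
        e <- sample.int(n_edge, 1, prob = st$jumps)
        to <- sample.int(n_edge, 1)
        if (to != e && st$jumps[to] < jump_cap) {
          prop$jumps[e] <- st$jumps[e] - 1L
          prop$jumps[to] <- st$jumps[to] + 1L
          log_alpha <- 0
        }
      }
    } else if (mv == "jvar") {
      f <- exp(stats::rnorm(1, 0, 0.5))
      prop$jump_var <- st$jump_var * f
      log_alpha <- dhalfcauchy_log(prop$jump_var, prior$jump_scale) -
        dhalfcauchy_log(st$jump_var, prior$jump_scale) + log(f)
    }
    if (!is.null(log_alpha)) {
      ll_prop <- ll_fun(prop)
      log_alpha <- log_alpha + ll_prop - ll
      if (is.finite(ll_prop) && log(stats::runif(1)) < log_alpha) {
        st <- prop
        ll <- ll_prop
        acc[mv] <- acc[mv] + 1
      }
    }
    if (gen %% thin == 0) {
      si <- si + 1L
      has <- which(st$scalar > 0)
      samples[[si]] <- list(
        gen = gen,
        shifts = data.frame(edge = has, scalar = st$scalar[has]),
        jump_counts = st$jumps,
        sigma2 = st$sigma2, jump_var = st$jump_var, me = st$me,
        z0 = st$z0, loglik = ll)
      scalars[si, ] <- c(gen, length(has), sum(st$jumps), st$sigma2,
                         st$jump_var, st$me, st$z0, ll)
    }
  }
  structure(list(samples = samples, scalars = as.data.frame(scalars),
                 tree = tree, model = model, seed = seed, thin = thin,
                 n_gen = n_gen,
                 acceptance = ifelse(att > 0, acc / att, NA_real_)),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("rjMCMC trace (", x$model, "): ", length(x$samples), " samples (thin ",
      x$thin, ", ", x$n_gen, " generations)\n", sep = "")
  invisible(x)
}

retained_samples <- function(trace, burnin_fraction) {
  gens <- vapply(trace$samples, `[[`, 0, "gen")
  keep <- trace$samples[gens > burnin_fraction * trace$n_gen]
  if (!length(keep)) stop("burn-in leaves no samples")
  keep
}

#' Summarise posterior shift probabilities per branch
#'
#' @param trace a [run_rjmcmc()] result.
#' @param burnin_fraction fraction of generations discarded (default 0.25).
#' @return list of class `shift_summary`: `table` (data.frame `edge`,
#'   `parent`, `child`, `prob`, `direction` ("forward"/"backward"/`NA`),
#'   `mean_rel_rate`), `n_retained`.
#' @export
summarize_shifts <- function(trace, burnin_fraction = 0.25) {
  keep <- retained_samples(trace, burnin_fraction)
  tree <- trace$tree
  po <- ape::postorder(tree)
  pre <- rev(po)
  n_edge <- nrow(tree$edge)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(n_edge)
  present <- matrix(0, length(keep), n_edge)
  direction <- matrix(NA_real_, length(keep), n_edge)
  rel <- matrix(0, length(keep), n_edge)
  for (i in seq_along(keep)) {
    sc <- rep(0, n_edge)
    sh <- keep[[i]]$shifts
    if (nrow(sh)) sc[sh$edge] <- sh$scalar
    rates <- rbm_rel_rates_cpp(tree$edge[, 1], tree$edge[, 2], pre, sc)
    rel[i, ] <- rates
    if (nrow(sh)) {
      present[i, sh$edge] <- 1
      for (e in sh$edge) {
        pe <- parent_edge[tree$edge[e, 1]]
        parent_rate <- if (pe > 0) rates[pe] else 1
        direction[i, e] <- sign(log(sc[e] / parent_rate))
      }
    }
  }
  prob <- colMeans(present)
  dir_mean <- suppressWarnings(colMeans(direction, na.rm = TRUE))
  dir_lab <- ifelse(prob == 0, NA_character_,
                    ifelse(dir_mean >= 0, "forward", "backward"))
  structure(list(
    table = data.frame(edge = seq_len(n_edge),
                       parent = tree$edge[, 1], child = tree$edge[, 2],
                       prob = prob, direction = dir_lab,
                       mean_rel_rate = colMeans(rel)),
    n_retained = length(keep)),
    class = "shift_summary")
}

#' Summarise posterior jump probabilities and counts per branch
#'
#' @inheritParams summarize_shifts
#' @return list of class `jump_summary`: `table` (`edge`, `parent`,
#'   `child`, `prob`, `mean_count`) or `NULL` with an explanatory `status`
#'   for a shifts-only trace; `n_retained`.
#' @export
summarize_jumps <- function(trace, burnin_fraction = 0.25) {
  if (trace$model != "jump-rbm")
    return(structure(list(table = NULL,
                          status = "trace is from the 'rbm' model: no jumps",
                          n_retained = 0L),
                     class = "jump_summary"))
  keep <- retained_samples(trace, burnin_fraction)
  counts <- t(vapply(keep, `[[`, numeric(nrow(trace$tree$edge)),
                     "jump_counts"))
  structure(list(
    table = data.frame(edge = seq_len(ncol(counts)),
                       parent = trace$tree$edge[, 1],
                       child = trace$tree$edge[, 2],
                       prob = colMeans(counts > 0),
                       mean_count = colMeans(counts)),
    status = "ok", n_retained = length(keep)),
    class = "jump_summary")
}

# effective sample size by Geyer's initial monotone positive sequence
ess_single <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(NA_real_)
  rho <- as.numeric(stats::acf(x, lag.max = n - 2, plot = FALSE,
                               demean = TRUE)$acf)
  m_max <- floor((length(rho) - 1) / 2)
  gam <- rho[2 * seq_len(m_max) - 1] + rho[2 * seq_len(m_max)]
  # Gamma_0 uses rho_0 + rho_1; keep the initial monotone positive run
  gam0 <- rho[1] + rho[2]
  run <- numeric(0)
  prev <- gam0
  for (g in gam[-1]) {
    if (g <= 0 || g > prev) break
    run <- c(run, g)
    prev <- g
  }
  tau <- -1 + 2 * (gam0 + sum(run))
  max(1, min(n, n / max(tau, 1e-12)))
}

#' MCMC convergence diagnostics
#'
#' Effective sample size per scalar parameter (autocorrelation-time
#' estimate, initial monotone sequence) and, for two or more chains of
#' equal length, Gelman-Rubin potential scale reduction factors.
#'
#' @param traces a single [run_rjmcmc()] trace or a list of traces.
#' @param params scalar columns to assess (default sigma2, z0, me, loglik).
#' @param psrf compute PSRF (requires >= 2 chains; default automatic).
#' @param ess_threshold,psrf_threshold reporting flags (defaults 200 and
#'   1.1); these flag, they never fail.
#' @return list of class `mcmc_diagnostics`: `ess` (matrix chains x
#'   params), `psrf` (named vector or NULL), `flags`.
#' @export
mcmc_diagnostics <- function(traces,
                             params = c("sigma2", "z0", "me", "loglik"),
                             psrf = NULL, ess_threshold = 200,
                             psrf_threshold = 1.1) {
  if (inherits(traces, "posterior_trace")) traces <- list(traces)
  if (is.null(psrf)) psrf <- length(traces) >= 2
  if (psrf && length(traces) < 2)
    stop("PSRF requires at least 2 chains")
  mats <- lapply(traces, function(tr)
    as.matrix(tr$scalars[, params, drop = FALSE]))
  ess <- t(vapply(mats, function(m) apply(m, 2, ess_single),
                  numeric(length(params))))
  colnames(ess) <- params
  rhat <- NULL
  if (psrf) {
    lens <- vapply(mats, nrow, 0L)
    if (length(unique(lens)) != 1)
      stop("PSRF requires chains of equal length")
    rhat <- vapply(params, function(p) {
      chains <- lapply(mats, function(m) m[, p])
      psrf_stat(chains)
    }, 0)
  }
  flags <- list(low_ess = colSums(ess, na.rm = TRUE) < ess_threshold,
                high_psrf = if (!is.null(rhat))
                  rhat > psrf_threshold else NULL)
  structure(list(ess = ess, psrf = rhat, flags = flags),
            class = "mcmc_diagnostics")
}

psrf_stat <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W <= 0) return(1)
  vhat <- (n - 1) / n * W + B_over_n * (1 + 1 / m)
  max(1, sqrt(vhat / W))
}
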
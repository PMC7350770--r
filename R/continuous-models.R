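#' @name continuous-models
#' @title Multi-regime BM/OU model family for a continuous trait
#'
#' @description Maximum-likelihood machinery for the model family used to
#' describe the evolution of a scalar trait (here, per-specimen total
#' asymmetry) on a time-calibrated tree: Brownian motion (`BM`), BM with a
#' linear trend in time (`BMtr`), BM with separate per-state phylogenetic
#' means (`BMsm`), their multi-regime rate versions on a painted tree
#' (`BMM`, `BMMtr`, `BMMsm`), and Ornstein-Uhlenbeck with a single optimum
#' (`OU`) or per-regime optima (`OUM`).  Mean and scale parameters are
#' profiled analytically by GLS; the attraction `alpha` and relative regime
#' rates are optimised numerically.
NULL

CONT_CLASSES <- c("BM", "BMtr", "BMsm", "BMM", "BMMtr", "BMMsm",
                  "OU", "OUM")

needs_painting <- function(class)
  class %in% c("BMM", "BMMtr", "BMMsm", "OUM", "BMsm")

# per-tip root-to-tip path segments: list per tip of data.frame(t0, t1, state)
tip_path_segments <- function(tree, painting = NULL) {
  depth <- node_depths(tree)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  states <- if (is.null(painting)) rep("s", nrow(tree$edge))
            else painting$edge_state
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  lapply(seq_along(tree$tip.label), function(tip) {
    nd <- tip
    t0 <- numeric(0); t1 <- numeric(0); st <- character(0)
    while (nd != root) {
      e <- parent_edge[nd]
      p <- tree$edge[e, 1]
      t0 <- c(t0, depth[p]); t1 <- c(t1, depth[nd]); st <- c(st, states[e])
      nd <- p
    }
    list(t0 = t0, t1 = t1, state = st)   # plain lists: built once per fit
  })
}

# OU covariance for fixed (non-stationary) root: entries
# exp(-a(di+dj-2tij)) (1-exp(-2a tij)) / (2a), tij = shared depth.
ou_v0 <- function(C, alpha) {
  d <- diag(C)
  if (alpha < 1e-12) return(C)
  S <- outer(d, d, "+") - 2 * C
  exp(-alpha * S) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
}

# mean design matrix for a model class at given alpha
cont_design <- function(class, C, depths, tip_states = NULL,
                        segments = NULL, alpha = NULL) {
  n <- length(depths)
  ultra <- diff(range(depths)) < 1e-8 * max(depths, 1)
  if (class %in% c("BM", "BMM")) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "root"))
  } else if (class %in% c("BMtr", "BMMtr")) {
    if (ultra) {
      warning("trend unidentifiable on an ultrametric tree; fixing mu = 0")
      X <- matrix(1, n, 1, dimnames = list(NULL, "root"))
    } else
      X <- cbind(root = 1, trend = depths)
  } else if (class %in% c("BMsm", "BMMsm")) {
    sts <- sort(unique(tip_states))
    X <- sapply(sts, function(s) as.numeric(tip_states == s))
    colnames(X) <- paste0("mean_", sts)
  } else if (class == "OU") {
    w0 <- exp(-alpha * depths)
    if (ultra) {
      # z0 and theta are aliased: only the stationary mean is identifiable
      X <- matrix(1, n, 1, dimnames = list(NULL, "optim"))
      attr(X, "aliased") <- "root"
      return(X)
    }
    X <- cbind(root = w0, optim = 1 - w0)
  } else if (class == "OUM") {
    w0 <- exp(-alpha * depths)
    sts <- sort(unique(unlist(lapply(segments, function(sg) sg$state))))
    W <- matrix(0, n, length(sts), dimnames = list(NULL, sts))
    for (i in seq_len(n)) {
      sg <- segments[[i]]
      di <- depths[i]
      w <- exp(-alpha * (di - sg$t1)) - exp(-alpha * (di - sg$t0))
      for (k in seq_along(sts))
        W[i, k] <- sum(w[sg$state == sts[k]])
    }
    if (ultra) {
      # root state unidentifiable on ultrametric trees: adopt the
      # convention that the root sits at its own state's optimum
      root_state <- segments[[1]]$state[length(segments[[1]]$state)]
      W[, root_state] <- W[, root_state] + w0
      X <- W
      colnames(X) <- paste0("theta_", sts)
      attr(X, "aliased") <- "root"
      return(X)
    }
    X <- cbind(root = w0, W)
    colnames(X) <- c("root", paste0("theta_", sts))
  } else stop("unknown model class: ", class)
  # drop aliased columns (e.g. root weight constant on ultrametric trees)
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "aliased") <- aliased
  X
}

# GLS profile log-likelihood of y ~ N(X beta, sigma2 * V0)
gls_profile <- function(y, X, V0, sigma2 = NULL, beta = NULL) {
  n <- length(y)
  ch <- chol_with_ridge(V0, "model covariance")
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  logdet <- 2 * sum(log(diag(ch)))
  if (is.null(beta)) {
    fit <- stats::lm.fit(wX, wy)
    beta <- stats::setNames(fit$coefficients, colnames(X))
    rss <- sum(fit$residuals^2)
  } else {
    rss <- sum((wy - wX %*% beta)^2)
  }
  if (is.null(sigma2)) sigma2 <- rss / n
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - rss / (2 * sigma2)
  list(logLik = ll, beta = beta, sigma2 = sigma2, rss = rss)
}

prep_trait <- function(tree, trait) {
  if (is.null(names(trait)))
    stop("trait must be named by tip label")
  trait <- trait[tree$tip.label]
  if (anyNA(trait)) stop("trait missing for tip(s): ",
                         paste(tree$tip.label[is.na(trait)], collapse = ", "))
  if (any(!is.finite(trait))) stop("non-finite trait values")
  trait
}

#' Log-likelihood of a continuous model at given parameters
#'
#' Evaluates the multivariate-normal log-likelihood of a trait under one of
#' the model classes, with mean and scale parameters profiled by GLS unless
#' supplied.
#'
#' @param class one of `BM`, `BMtr`, `BMsm`, `BMM`, `BMMtr`, `BMMsm`, `OU`,
#'   `OUM`.
#' @param tree rooted binary `phylo` (branch lengths in My).
#' @param trait named numeric vector of tip values.
#' @param painting a [paint_regimes()] result (required by multi-regime and
#'   state-mean classes).
#' @param alpha OU attraction (required for `OU`/`OUM`).
#' @param rel_rates named relative rates per state (first state fixed at 1
#'   when omitted) for `BMM*` classes.
#' @param sigma2,beta optionally fix the scale and mean parameters instead
#'   of profiling.
#' @param error_variance per-tip measurement-error variance added to the
#'   diagonal (scalar or named vector; default 0).
#' @param cache optional precomputed pieces (`cov`, `segments`) reused
#'   across evaluations by [fit_model()].
#' @return list: `logLik`, `beta`, `sigma2`, `aliased`.
#' @export
model_loglik <- function(class, tree, trait, painting = NULL, alpha = NULL,
                         rel_rates = NULL, sigma2 = NULL, beta = NULL,
                         error_variance = 0, cache = NULL) {
  class <- match.arg(class, CONT_CLASSES)
  trait <- prep_trait(tree, trait)
  if (needs_painting(class) && is.null(painting))
    stop(class, " requires a regime painting")
  cov <- cache$cov %||% phylo_covariance(tree, painting)
  C <- if (is.null(painting)) cov else cov$total
  depths <- diag(C)
  multi_rate <- class %in% c("BMM", "BMMtr", "BMMsm")
  V0 <- if (multi_rate) {
    sts <- names(cov$components)
    if (is.null(rel_rates)) rel_rates <- stats::setNames(rep(1, length(sts)),
                                                         sts)
    if (!all(sts %in% names(rel_rates)))
      stop("rel_rates must name every painted state")
    Reduce(`+`, lapply(sts, function(s)
      rel_rates[[s]] * cov$components[[s]]))
  } else if (class %in% c("OU", "OUM")) {
    if (is.null(alpha)) stop(class, " requires alpha")
    ou_v0(C, alpha)
  } else C
  segments <- if (class == "OUM")
    cache$segments %||% tip_path_segments(tree, painting) else NULL
  tip_states <- if (!is.null(painting)) painting$tip_states else NULL
  X <- cont_design(class, C, depths, tip_states, segments, alpha)
  ev <- if (length(error_variance) == 1) rep(error_variance, length(trait))
        else error_variance[tree$tip.label]
  # error variance enters in trait units; fold into V0 only when profiling
  # sigma2 is off (otherwise it would be rescaled); standard usage is ev = 0.
  V <- V0 + diag(ev / max(sigma2 %||% 1, 1e-300), length(trait))
  out <- gls_profile(trait, X, V, sigma2 = sigma2, beta = beta)
  out$aliased <- attr(X, "aliased")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a continuous model by maximum likelihood
#'
#' Mean parameters (root state, trend, optima, state means) and the overall
#' rate sigma2 are profiled analytically; the OU attraction `alpha` and the
#' relative regime rates of `BMM*` classes are optimised by bounded
#' quasi-Newton search from multiple log-spaced starts.
#'
#' @inheritParams model_loglik
#' @param scenario optional label (e.g. `"regime"`, `"echo-freq"`) recorded
#'   in the fit and used by [rank_models()].
#' @param n_starts optimisation starts for numeric parameters (default 5).
#' @return list of class `cont_fit`: `class`, `scenario`, `name`, `params`
#'   (`sigma2`, `alpha`, `rel_rates`, mean coefficients), `logLik`, `k`,
#'   `AIC`, `aliased`.
#' @export
fit_model <- function(class, tree, trait, painting = NULL, scenario = NULL,
                      n_starts = 5L) {
  class <- match.arg(class, CONT_CLASSES)
  trait <- prep_trait(tree, trait)
  depth <- max(node_depths(tree))
  sts <- if (!is.null(painting)) sort(unique(painting$edge_state)) else NULL

  has_alpha <- class %in% c("OU", "OUM")
  multi_rate <- class %in% c("BMM", "BMMtr", "BMMsm")
  n_rate_par <- if (multi_rate) length(sts) - 1L else 0L
  cache <- list(cov = phylo_covariance(tree, painting),
                segments = if (class == "OUM")
                  tip_path_segments(tree, painting) else NULL)

  eval_at <- function(par, quiet = TRUE) {
    alpha <- if (has_alpha) exp(par[1]) else NULL
    rr <- NULL
    if (multi_rate) {
      rr <- stats::setNames(c(1, exp(par[has_alpha + seq_len(n_rate_par)])),
                            sts)
    }
    eval_once <- function() model_loglik(class, tree, trait, painting,
                                         alpha = alpha, rel_rates = rr,
                                         cache = cache)
    ll <- tryCatch(
      if (quiet) suppressWarnings(eval_once()) else eval_once(),
      error = function(e) NULL)
    if (is.null(ll) || !is.finite(ll$logLik))
      return(list(obj = 1e10, ll = NULL, alpha = alpha, rr = rr))
    list(obj = -ll$logLik, ll = ll, alpha = alpha, rr = rr)
  }

  n_par <- (has_alpha) + n_rate_par
  if (n_par == 0) {
    at <- eval_at(numeric(0), quiet = FALSE)
    if (is.null(at$ll)) stop("likelihood evaluation failed for ", class)
    best_par <- numeric(0)
  } else {
    alpha_starts <- log(exp(seq(log(0.1), log(20), length.out = n_starts)) /
                          depth)
    best <- NULL
    for (i in seq_len(n_starts)) {
      p0 <- c(if (has_alpha) alpha_starts[i],
              rep(0, n_rate_par))
      fit <- tryCatch(
        stats::optim(p0, function(p) eval_at(p)$obj, method = "L-BFGS-B",
                     lower = rep(log(1e-9), n_par),
                     upper = rep(log(1e6), n_par),
                     control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best))
      stop("optimisation failed for ", class,
           " after ", n_starts, " starts")
    best_par <- best$par
    at <- eval_at(best_par)
    if (is.null(at$ll)) stop("likelihood evaluation failed at the optimum")
  }
  ll <- at$ll
  # parameter count: overall sigma2 + mean coefficients + extra regime rates
  # + alpha; aliased mean columns are not counted.
  k <- 1L + length(ll$beta) + n_rate_par + as.integer(has_alpha)
  name <- if (is.null(scenario)) class else paste0(class, "-", scenario)
  base::structure(
    list(class = class, scenario = scenario, name = name,
         params = list(sigma2 = ll$sigma2, alpha = at$alpha,
                       rel_rates = at$rr, coefficients = ll$beta),
         logLik = ll$logLik, k = k, AIC = 2 * k - 2 * ll$logLik,
         aliased = ll$aliased),
    class = "cont_fit")
}

#' @export
print.cont_fit <- function(x, ...) {
  cat("Model ", x$name, ": logLik ", format(x$logLik, digits = 6),
      ", k = ", x$k, ", AIC = ", format(x$AIC, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits list of [fit_model()] (or [fit_mk()]) results.
#' @return data.frame `model`, `class`, `scenario`, `logLik`, `k`, `AIC`,
#'   `dAIC`, ascending in AIC with deterministic tie-break by model name.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fits to rank")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$name %||% f$structure %||% NA_character_,
               class = f$class %||% f$structure %||% NA_character_,
               scenario = f$scenario %||% NA_character_,
               logLik = f$logLik, k = f$k, AIC = f$AIC)))
  tab <- tab[order(tab$AIC, tab$model), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}
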
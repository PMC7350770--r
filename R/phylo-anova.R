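#' Phylogenetic GLS with a Pagel's lambda correlation structure
#'
#' Fits `trait ~ factor` by generalized least squares under the covariance
#' `V(lambda)`: the phylogenetic covariance with its off-diagonal entries
#' multiplied by lambda, lambda constrained to \[0, 1\].  Lambda is profiled
#' by a 21-point grid followed by golden-section refinement; coefficients
#' and the residual variance are then the GLS/ML solutions at lambda-hat.
#'
#' @param trait named numeric vector of tip values.
#' @param factor named factor/character of tip group labels (a constant,
#'   e.g. `"1"`, gives the intercept-only null model).
#' @param tree rooted `phylo` whose tips match the trait names.
#' @param lambda fix lambda instead of profiling (optional).
#' @param tol golden-section tolerance (default 1e-6).
#' @return list of class `gls_lambda_fit`: `coefficients`, `lambda`,
#'   `boundary` (`TRUE` at 0/1), `logLik`, `sigma2`, `rss` (whitened
#'   residual sum of squares), `df_model`, `n`, `levels`, `V0`, `trait`,
#'   `design`.
#' @export
fit_gls_lambda <- function(trait, factor, tree, lambda = NULL, tol = 1e-6) {
  trait <- prep_trait(tree, trait)
  n <- length(trait)
  if (length(factor) == 1) factor <- rep(factor, n)
  if (is.null(names(factor))) names(factor) <- names(trait)
  factor <- factor[tree$tip.label]
  if (anyNA(factor)) stop("factor missing for tip(s): ",
                          paste(tree$tip.label[is.na(factor)],
                                collapse = ", "))
  f <- base::factor(factor)
  X <- if (nlevels(f) < 2)
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~f)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased level(s): ",
         paste(aliased, collapse = ", "))
  }
  C <- phylo_covariance(tree)
  V_of <- function(lam) {
    V <- lam * C
    diag(V) <- diag(C)
    V
  }
  ll_of <- function(lam) gls_profile(trait, X, V_of(lam))$logLik
  if (is.null(lambda)) {
    grid <- seq(0, 1, length.out = 21)
    lls <- vapply(grid, ll_of, 0)
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(21, i + 1)]
    lambda <- golden_section(ll_of, lo, hi, tol)
    if (ll_of(0) >= ll_of(lambda)) lambda <- 0
    if (ll_of(1) >= ll_of(lambda)) lambda <- 1
  } else if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  fit <- gls_profile(trait, X, V_of(lambda))
  structure(list(coefficients = fit$beta, lambda = lambda,
                 boundary = lambda %in% c(0, 1), logLik = fit$logLik,
                 sigma2 = fit$sigma2, rss = fit$rss,
                 df_model = ncol(X), n = n, levels = levels(f),
                 V0 = V_of(lambda), trait = trait, design = X),
            class = "gls_lambda_fit")
}

golden_section <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

#' @export
print.gls_lambda_fit <- function(x, ...) {
  cat("GLS (Pagel's lambda =", format(x$lambda, digits = 4),
      if (x$boundary) "[boundary]", "): logLik",
      format(x$logLik, digits = 6), "\n")
  invisible(x)
}

#' Phylogenetic ANOVA F test
#'
#' Compares a factor model against its intercept-only null by the GLS
#' (whitened) residual sums of squares, both evaluated at the alternative
#' model's fitted lambda (the correlation structure is fitted once per
#' scenario, not refitted under the null).
#'
#' @param fit the alternative-model [fit_gls_lambda()].
#' @param null the intercept-only fit on the same tips; when omitted it is
#'   computed at `fit$lambda`.
#' @param tree the tree (needed only when `null` is omitted).
#' @param scenario optional label.
#' @return list of class `anova_result`: `scenario`, `F`, `df1`, `df2`,
#'   `p`, `lambda`.
#' @export
anova_f <- function(fit, null = NULL, tree = NULL, scenario = NULL) {
  if (is.null(null)) {
    if (is.null(tree)) stop("supply either a null fit or the tree")
    null <- fit_gls_lambda(fit$trait, "1", tree, lambda = fit$lambda)
  }
  if (null$n != fit$n) stop("null and alternative use different tips")
  if (null$df_model > fit$df_model)
    stop("models are not nested: null has more parameters")
  df1 <- fit$df_model - null$df_model
  df2 <- fit$n - fit$df_model
  if (df1 == 0)
    return(structure(list(scenario = scenario, F = 0, df1 = 0, df2 = df2,
                          p = 1, lambda = fit$lambda),
                     class = "anova_result"))
  Fstat <- ((null$rss - fit$rss) / df1) / (fit$rss / df2)
  Fstat <- max(Fstat, 0)
  structure(list(scenario = scenario, F = Fstat, df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 lambda = fit$lambda),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Phylogenetic ANOVA", if (!is.null(x$scenario)) paste0("(",
      x$scenario, ")"), ": F =", format(x$F, digits = 4),
      ", df =", x$df1, "/", x$df2, ", p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values `p_(i) * m / i` with a running minimum from
#' the largest rank; ties keep their input order.
#'
#' @param pvalues numeric vector in \[0, 1\] (optionally named by scenario).
#' @return data.frame `scenario`, `p`, `p_BH`, in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    stop("p values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, pvalues[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  data.frame(scenario = names(pvalues) %||% paste0("test", seq_len(m)),
             p = as.numeric(pvalues), p_BH = adj)
}

#' Phylogenetic ANOVA across a family of scenarios with FDR control
#'
#' Runs [fit_gls_lambda()] + [anova_f()] for each scenario factor and
#' adjusts the family of p values by Benjamini-Hochberg.
#'
#' @param trait named numeric vector of tip values.
#' @param scenarios named list of per-tip factors (each named by tip).
#' @param tree rooted `phylo`.
#' @return data.frame `scenario`, `F`, `df1`, `df2`, `lambda`, `p`, `p_BH`.
#' @export
run_phylo_anova <- function(trait, scenarios, tree) {
  res <- lapply(names(scenarios), function(sc) {
    fit <- fit_gls_lambda(trait, scenarios[[sc]], tree)
    anova_f(fit, tree = tree, scenario = sc)
  })
  p <- stats::setNames(vapply(res, `[[`, 0, "p"), names(scenarios))
  adj <- bh_adjust(p)
  data.frame(scenario = names(scenarios),
             F = vapply(res, `[[`, 0, "F"),
             df1 = vapply(res, `[[`, 0, "df1"),
             df2 = vapply(res, `[[`, 0, "df2"),
             lambda = vapply(res, `[[`, 0, "lambda"),
             p = adj$p, p_BH = adj$p_BH)
}
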
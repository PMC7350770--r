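test_that("prior configuration is validated", {
  expect_s3_class(prior_config(), "prior_config")
  expect_error(prior_config(shift_mean = 0), "invalid prior")
  expect_error(prior_config(scalar_scale = -2), "invalid prior")
  tr <- simulate_tree(10, seed = 1)
  y <- simulate_trait(tr, seed = 2)
  expect_error(run_rjmcmc(tr, y, prior = list(a = 1), n_gen = 100,
                          thin = 10), "invalid prior")
  expect_error(run_rjmcmc(tr, y, n_gen = 5, thin = 10), "at least thin")
})

test_that("identical seeds give identical traces", {
  tr <- simulate_tree(20, seed = 3)
  y <- simulate_trait(tr, sigma2 = 0.05, seed = 4)
  t1 <- run_rjmcmc(tr, y, n_gen = 3000, thin = 50, model = "jump-rbm",
                   seed = 11)
  t2 <- run_rjmcmc(tr, y, n_gen = 3000, thin = 50, model = "jump-rbm",
                   seed = 11)
  expect_identical(t1$scalars, t2$scalars)
  expect_identical(t1$samples, t2$samples)
  t3 <- run_rjmcmc(tr, y, n_gen = 3000, thin = 50, model = "jump-rbm",
                   seed = 12)
  expect_false(identical(t1$scalars, t3$scalars))
})

test_that("the sampled likelihood agrees with the BMM covariance route", {
  # a fixed shift configuration is a two-regime Brownian model: the pruning
  # likelihood must equal the multivariate-normal BMM likelihood
  tr <- simulate_tree(30, seed = 5)
  below <- cetasym:::tips_below_edges(tr)
  e <- which(lengths(below) >= 6 & lengths(below) <= 12)[1]
  clade_tips <- tr$tip.label[below[[e]]]
  y <- simulate_trait(tr, sigma2 = 0.04, seed = 6)
  r <- 5.3; s2 <- 0.04; z0 <- 0.12

  po <- ape::postorder(tr)
  scalar <- rep(0, nrow(tr$edge)); scalar[e] <- r
  ll_prune <- cetasym:::rbm_loglik_cpp(
    tr$edge[, 1], tr$edge[, 2], tr$edge.length, rev(po), po,
    ape::Ntip(tr), ape::Ntip(tr) + 1, as.numeric(y[tr$tip.label]),
    scalar, rep(0L, nrow(tr$edge)), s2, 0, 0, z0)

  pk <- paint_regimes(tr, base_state = "bg",
                      clades = list(fast = clade_tips))
  ll_mvn <- model_loglik("BMM", tr, y, painting = pk,
                         rel_rates = c(bg = 1, fast = r),
                         sigma2 = s2, beta = z0)$logLik
  expect_equal(ll_prune, ll_mvn, tolerance = 1e-8)
})

test_that("summaries expose probabilities, directions and counts", {
  tr <- simulate_tree(15, seed = 7)
  y <- simulate_trait(tr, sigma2 = 0.05, seed = 8)
  tra <- run_rjmcmc(tr, y, n_gen = 4000, thin = 40, model = "jump-rbm",
                    seed = 21)
  ss <- summarize_shifts(tra)
  expect_true(all(ss$table$prob >= 0 & ss$table$prob <= 1))
  expect_equal(nrow(ss$table), nrow(tr$edge))
  expect_gt(ss$n_retained, 0)
  js <- summarize_jumps(tra)
  expect_true(all(js$table$mean_count >= 0))
  expect_true(all(js$table$mean_count[js$table$prob == 0] == 0))

  # an rbm trace yields an empty jump summary with explanatory status
  tra_rbm <- run_rjmcmc(tr, y, n_gen = 1000, thin = 100, model = "rbm",
                        seed = 22)
  js2 <- summarize_jumps(tra_rbm)
  expect_null(js2$table)
  expect_match(js2$status, "no jumps")

  # a trace in which no sample has a shift gives all-zero probabilities
  tra0 <- tra
  tra0$samples <- lapply(tra0$samples, function(s) {
    s$shifts <- s$shifts[0, ]; s
  })
  ss0 <- summarize_shifts(tra0)
  expect_true(all(ss0$table$prob == 0))
  expect_true(all(is.na(ss0$table$direction)))
  expect_true(all(ss0$table$mean_rel_rate == 1))

  # probabilities invariant to integer thinning of retained samples
  tra_thin <- tra
  keep <- seq(1, length(tra$samples), by = 2)
  tra_thin$samples <- tra$samples[keep]
  tra_thin$scalars <- tra$scalars[keep, ]
  p_full <- summarize_shifts(tra, burnin_fraction = 0)$table$prob
  p_thin <- summarize_shifts(tra_thin, burnin_fraction = 0)$table$prob
  sub <- summarize_shifts(tra, burnin_fraction = 0)
  # thinned probabilities are the sample mean over the thinned subset
  pres <- sapply(tra$samples[keep], function(s)
    seq_len(nrow(tr$edge)) %in% s$shifts$edge)
  expect_equal(p_thin, rowMeans(pres))

  expect_error(summarize_shifts(tra, burnin_fraction = 1), "no samples")
})

test_that("no spurious shift inflation under single-rate BM", {
  tr <- simulate_tree(100, seed = 9)
  y <- simulate_trait(tr, sigma2 = 0.02, seed = 10)
  tra <- run_rjmcmc(tr, y, n_gen = 3e4, thin = 100, model = "rbm",
                    seed = 31)
  post <- tra$scalars$n_shifts[tra$scalars$gen > 0.25 * 3e4]
  expect_lte(mean(post), log(2) + 0.5)
})

test_that("a large planted jump is localised (scaled-down recovery)", {
  # scaled from the stated 20-replicate design: 10 replicates, 1.2e5
  # generations, 60 tips; the planted branch must carry the top jump
  # probability in >= 70% of replicates
  tr <- simulate_tree(60, seed = 13)
  below <- cetasym:::tips_below_edges(tr)
  e <- which(lengths(below) >= 10 & lengths(below) <= 20)[1]
  hits <- 0L
  for (r in 1:10) {
    y <- simulate_trait(tr, sigma2 = 0.01, jump_edges = e,
                        jump_sd = 5 * sqrt(0.01 * max(diag(
                          phylo_covariance(tr)))), seed = 800 + r)
    tra <- run_rjmcmc(tr, y, n_gen = 1.2e5, thin = 300, model = "jump-rbm",
                      seed = 900 + r)
    js <- summarize_jumps(tra)
    top <- js$table$edge[which.max(js$table$prob)]
    # accept the planted edge or an adjacent edge of the same clade path
    adj <- c(e, which(tr$edge[, 1] == tr$edge[e, 2]),
             which(tr$edge[, 2] == tr$edge[e, 1]))
    if (top %in% adj) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.7)
})

test_that("convergence diagnostics behave on analytic chains", {
  fake_trace <- function(x, seed) {
    structure(list(samples = list(), tree = NULL, model = "rbm",
                   seed = seed, thin = 1, n_gen = length(x),
                   scalars = data.frame(gen = seq_along(x), sigma2 = x,
                                        z0 = x, me = x, loglik = x)),
              class = "posterior_trace")
  }
  set.seed(17)
  x <- rnorm(5000)
  d1 <- mcmc_diagnostics(fake_trace(x, 1), params = "sigma2")
  expect_lte(d1$ess[1, 1], 5000)
  expect_gt(d1$ess[1, 1], 0.9 * 5000)      # iid: ESS within 10% of n

  ar <- as.numeric(stats::arima.sim(list(ar = 0.5), 5000))
  d2 <- mcmc_diagnostics(fake_trace(ar, 1), params = "sigma2")
  target <- 5000 * (1 - 0.5) / (1 + 0.5)
  expect_lt(abs(d2$ess[1, 1] - target) / target, 0.15)

  # two identical chains: PSRF exactly 1
  d3 <- mcmc_diagnostics(list(fake_trace(x, 1), fake_trace(x, 1)),
                         params = c("sigma2", "z0"))
  expect_equal(unname(d3$psrf), c(1, 1), tolerance = 1e-6)

  expect_error(mcmc_diagnostics(fake_trace(x, 1), psrf = TRUE),
               "at least 2 chains")
})
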
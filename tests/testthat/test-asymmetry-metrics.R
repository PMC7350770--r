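test_that("radii decompose displacements in spherical coordinates", {
  fn <- matrix(0, 4, 3)
  rn <- fn
  expect_true(all(radii(fn, rn)$rho == 0))
  expect_true(all(is.na(radii(fn, rn)$phi)))

  fn2 <- rn
  fn2[2, ] <- c(0.03, 0, 0)
  r <- radii(fn2, rn)
  expect_equal(r$rho[2], 0.03)
  expect_equal(r$phi[2], 0)
  expect_equal(r$theta[2], pi / 2)
  expect_equal(nrow(r), 4)

  expect_error(radii(fn, rn[1:3, ]), "frame mismatch")
})

test_that("specimen sums are exact and invariant to relabelling", {
  rec <- data.frame(specimen_id = rep(c("a", "b"), each = 2),
                    landmark = c(1, 2, 1, 2),
                    rho = c(0.1, 0.2, 0, 0))
  s <- specimen_sum(rec)
  expect_equal(s$sum_rho[s$specimen_id == "a"], 0.3)
  expect_equal(s$sum_rho[s$specimen_id == "b"], 0)

  # permutation of rows and landmark order leaves sums unchanged
  perm <- rec[sample(nrow(rec)), ]
  s2 <- specimen_sum(perm)
  expect_equal(sort(s2$sum_rho), sort(s$sum_rho))

  # sensitivity mode drops TPS-estimated landmarks
  rec$estimated <- c(FALSE, TRUE, FALSE, FALSE)
  s3 <- specimen_sum(rec, include_estimated = FALSE)
  expect_equal(s3$sum_rho[s3$specimen_id == "a"], 0.1)
})

test_that("group summaries match brute-force means and rank deterministically", {
  rec <- expand.grid(specimen_id = c("s1", "s2", "s3"), landmark = 1:2)
  rec$rho <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  md <- data.frame(specimen_id = c("s1", "s2", "s3"),
                   group = c("g1", "g1", "g2"))
  gs <- group_summary(rec, md)
  # brute force: s1 sum 0.5, s2 sum 0.7, s3 sum 0.9
  expect_equal(gs$group_means$mean_sum_rho[gs$group_means$group == "g1"],
               mean(c(0.5, 0.7)))
  expect_equal(gs$group_means$mean_sum_rho[gs$group_means$group == "g2"],
               0.9)
  lm11 <- gs$landmark_means
  expect_equal(lm11$mean_rho[lm11$group == "g1" & lm11$landmark == 1],
               mean(c(0.1, 0.2)))
  expect_equal(gs$ranking$specimen_id, c("s3", "s2", "s1"))

  # ties break lexicographically by specimen id
  rec2 <- data.frame(specimen_id = c("zz", "aa"), landmark = 1,
                     rho = c(0.5, 0.5))
  gs2 <- group_summary(rec2, data.frame(specimen_id = c("zz", "aa"),
                                        group = "g"))
  expect_equal(gs2$ranking$specimen_id, c("aa", "zz"))

  # singleton group mean equals the specimen's own sum
  expect_equal(gs$group_means$mean_sum_rho[gs$group_means$group == "g2"],
               gs$ranking$sum_rho[gs$ranking$specimen_id == "s3"])

  # empty group warns
  md3 <- data.frame(specimen_id = c("s1", "s2", "s3"),
                    group = c("g1", "g1", "g1"), other = "x")
  expect_warning(group_summary(rec,
                               rbind(md3, data.frame(specimen_id = "ghost",
                                                     group = "g9",
                                                     other = "x"))),
                 "empty group")
})

test_that("region fractions follow the closed-form ratio", {
  sch <- make_template()$scheme
  n_rost <- sum(sch$regions == "rostrum")
  rec <- data.frame(specimen_id = "u", landmark = seq_len(sch$n_total),
                    rho = 1)
  rf <- region_fraction(rec, sch, "rostrum")
  expect_equal(rf$percent, 100 * n_rost / sch$n_total)

  # all displacement confined to the region -> 100%
  rec2 <- rec
  rec2$rho <- ifelse(sch$regions == "rostrum", 0.4, 0)
  expect_equal(region_fraction(rec2, sch, "rostrum")$percent, 100)

  # zero total -> NA, unknown region -> error
  rec3 <- rec; rec3$rho <- 0
  expect_true(is.na(region_fraction(rec3, sch, "rostrum")$percent))
  expect_error(region_fraction(rec, sch, "wing"), "unknown region")
})

test_that("drop_region removes whole bilateral blocks and re-indexes", {
  tm <- make_template()
  ds <- landmark_dataset(tm$scheme, list(tm$config))
  p <- sum(tm$scheme$regions[tm$scheme$pairs[, 1]] == "rostrum")
  m <- sum(tm$scheme$regions[tm$scheme$midline] == "rostrum")
  red <- drop_region(ds, "rostrum")
  expect_equal(red$scheme$n_total, tm$scheme$n_total - 2 * p - m)
  expect_false("rostrum" %in% red$scheme$regions)
  expect_equal(nrow(red$configurations$template$coords),
               red$scheme$n_total)
  # the reduced scheme still satisfies its invariants (constructor ran)
  expect_s3_class(red$scheme, "landmark_scheme")

  # a region with only one side of a pair is rejected
  bad <- landmark_scheme(pairs = rbind(c(1, 3), c(2, 4)), midline = 5,
                         regions = c("a", "b", "b", "b", "b"))
  cfg <- landmark_config("x", matrix(rnorm(15), 5, 3))
  expect_error(drop_region(landmark_dataset(bad, list(cfg)), "a"),
               "bilaterality")
})

test_that("drop_region then quantify reduces the specimen sum sensibly", {
  tm <- make_template()
  cf <- apply_asymmetry(tm$config, tm$scheme, c("rostrum", "nasal"),
                        3, side = "right")
  cf$specimen_id <- "planted"
  ds <- landmark_dataset(tm$scheme, list(tm$config, cf))
  full <- quantify_asymmetry(ds)$sums
  red <- quantify_asymmetry(drop_region(ds, "rostrum"))$sums
  s_full <- full$sum_rho[full$specimen_id == "planted"]
  s_red <- red$sum_rho[red$specimen_id == "planted"]
  expect_lt(s_red, s_full)     # rostral contribution removed
  expect_gt(s_red, 0.25 * s_full)  # nasal contribution remains
})

test_that("PCA satisfies its spectral invariants and matches the oracle", {
  tm <- make_template()
  set.seed(5)
  cfs <- lapply(1:5, function(i) {
    cf <- tm$config
    cf$specimen_id <- paste0("s", i)
    cf$coords <- cf$coords + matrix(rnorm(length(cf$coords), 0, 2),
                                    ncol = 3)
    cf
  })
  al <- gpa(cfs)
  pc <- asym_pca(al)
  expect_equal(sum(pc$proportion), 1, tolerance = 1e-12)
  expect_true(all(pc$proportion >= 0))
  expect_equal(crossprod(pc$loadings)[1:4, 1:4], diag(4),
               tolerance = 1e-10)

  # eigen oracle on the flattened coordinates, up to sign
  X <- t(sapply(al$aligned, as.numeric))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  oracle_scores <- Xc %*% ev$vectors[, 1:4]
  for (j in 1:4)
    expect_equal(abs(pc$scores[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)

  # duplicating the specimen set leaves variance proportions unchanged
  al2 <- gpa(c(cfs, lapply(cfs, function(cf) {
    cf$specimen_id <- paste0(cf$specimen_id, "_dup"); cf
  })))
  pc2 <- asym_pca(al2)
  expect_equal(pc2$proportion[1:4], pc$proportion[1:4], tolerance = 1e-8)
})

test_that("planted displacements scale linearly and preserve ordering", {
  tm <- make_template()
  cs <- sqrt(sum(sweep(tm$config$coords, 2,
                       colMeans(tm$config$coords))^2))
  deltas <- c(1, 2, 4)
  cfs <- c(list(tm$config), lapply(seq_along(deltas), function(i) {
    cf <- apply_asymmetry(tm$config, tm$scheme, "nasal", deltas[i],
                          side = "right")
    cf$specimen_id <- paste0("d", deltas[i])
    cf
  }))
  res <- quantify_asymmetry(landmark_dataset(tm$scheme, cfs))
  s <- res$sums$sum_rho[match(paste0("d", deltas), res$sums$specimen_id)]
  expect_true(all(diff(s) > 0))                       # monotone in delta
  expect_equal(s[2] / s[1], 2, tolerance = 0.02)      # ~linear scaling
  expect_equal(s[3] / s[1], 4, tolerance = 0.02 * 4)

  # Spearman ordering over 20 specimens with graded nasofacial asymmetry
  # under digitising noise (the generator's odontocete construction)
  grades <- seq(1.5, 8.5, length.out = 20)
  cfs2 <- lapply(seq_along(grades), function(i) {
    cf <- apply_asymmetry(tm$config, tm$scheme,
                          c("nasal", "premaxilla", "maxilla"), grades[i],
                          side = "right")
    cf$specimen_id <- sprintf("g%02d", i)
    cf
  })
  ds2 <- degrade(landmark_dataset(tm$scheme, cfs2),
                 specimen_missing_fraction = 0, landmark_missing_rate = 0,
                 noise_sd = 0.5, seed = 8)
  res2 <- quantify_asymmetry(ds2)
  rho_s <- stats::cor(res2$sums$sum_rho,
                      grades[match(res2$sums$specimen_id,
                                   sprintf("g%02d", 1:20))],
                      method = "spearman")
  expect_gte(rho_s, 0.95)

  # with noise-free planted nasal asymmetry, the nasal region's share
  # exceeds every other region's share
  planted <- res$sums$specimen_id[res$sums$specimen_id != "template"]
  rf_nasal <- region_fraction(res, region = "nasal")
  rf_nasal <- rf_nasal$percent[match(planted, rf_nasal$specimen_id)]
  for (reg in setdiff(unique(tm$scheme$regions), "nasal")) {
    rf_other <- region_fraction(res, region = reg)
    rf_other <- rf_other$percent[match(planted, rf_other$specimen_id)]
    expect_true(all(rf_nasal > rf_other))
  }
})
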
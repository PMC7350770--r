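test_that("the template realises the digitising scheme exactly", {
  tm <- make_template()
  expect_equal(nrow(tm$config$coords), 123)
  expect_equal(nrow(tm$scheme$pairs), 57)
  expect_length(tm$scheme$midline, 9)
  expect_length(tm$scheme$reference_set, 66)
  # exact bilateral symmetry
  m <- mirror_fill(tm$config, tm$scheme)
  expect_lt(max(abs(m$coords - tm$config$coords)), 1e-12)
  # deterministic in the seed
  expect_equal(make_template(seed = 5)$config$coords,
               make_template(seed = 5)$config$coords)
  expect_false(isTRUE(all.equal(make_template(seed = 5)$config$coords,
                                make_template(seed = 6)$config$coords)))
  # custom sizes
  small <- make_template(n_pairs = 4, n_midline = 3)
  expect_equal(small$scheme$n_total, 11)
  # requested centroid size honoured
  cs <- sqrt(sum(sweep(tm$config$coords, 2,
                       colMeans(tm$config$coords))^2))
  expect_equal(cs, 500, tolerance = 1e-9)
})

test_that("apply_asymmetry displaces exactly the requested landmarks", {
  tm <- make_template()
  same <- apply_asymmetry(tm$config, tm$scheme, "nasal", 0)
  expect_equal(same$coords, tm$config$coords)

  shifted <- apply_asymmetry(tm$config, tm$scheme, "nasal", 3,
                             direction = c(0, 0, 1), side = "right")
  moved <- which(rowSums(abs(shifted$coords - tm$config$coords)) > 0)
  expected <- intersect(which(tm$scheme$regions == "nasal"),
                        tm$scheme$pairs[, "right"])
  expect_equal(moved, expected)
  expect_equal(shifted$coords[moved[1], 3] - tm$config$coords[moved[1], 3],
               3)
  # jugal has no midline landmarks: empty affected set
  expect_error(apply_asymmetry(tm$config, tm$scheme, "jugal", 1,
                               side = "midline"),
               "no landmarks")
})

test_that("degrade is a pure function with calibrated missingness", {
  tm <- make_template()
  cfs <- lapply(1:164, function(i) {
    cf <- tm$config; cf$specimen_id <- sprintf("s%03d", i); cf
  })
  ds <- landmark_dataset(tm$scheme, cfs)

  # all rates zero: identity
  same <- degrade(ds, 0, 0, 0, seed = 1)
  expect_equal(same$configurations$s001$coords, tm$config$coords)
  expect_false(any(sapply(same$configurations, function(cf)
    any(cf$missing))))

  # the museum rate: ~39% of 164 specimens acquire missing landmarks
  deg <- degrade(ds, 0.39, 0.02, 0, seed = 2)
  vr <- validate_dataset(deg)
  n_deg <- sum(vr$per_specimen$n_missing > 0)
  expect_gt(n_deg, 64 - 3.5 * sqrt(164 * 0.39 * 0.61))  # binomial band
  expect_lt(n_deg, 64 + 3.5 * sqrt(164 * 0.39 * 0.61))

  # missingness is concentrated in the fragile regions
  miss_idx <- unlist(lapply(deg$configurations, function(cf)
    which(cf$missing)))
  fragile <- tm$scheme$regions[miss_idx] %in%
    c("jugal", "squamosal", "rostrum")
  expect_gt(mean(fragile), 0.5)

  # reproducible
  expect_identical(degrade(ds, 0.3, 0.05, 0.2, seed = 9),
                   degrade(ds, 0.3, 0.05, 0.2, seed = 9))
  expect_error(degrade(ds, 1.2, 0, 0), "\\[0, 1\\]")
})

test_that("simulated trees satisfy their contracts", {
  expect_equal(ape::Ntip(simulate_tree(2, seed = 1)), 2)
  tr <- simulate_tree(40, seed = 2)
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_identical(simulate_tree(15, seed = 3),
                   simulate_tree(15, seed = 3))
  fossil <- simulate_tree(40, seed = 2, fossil_tips = 10)
  expect_false(ape::is.ultrametric(fossil, tol = 1e-6))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("trait simulation follows the BM variance law and OU stationarity", {
  # 2000 independent replicate tips at depth t: sample variance ~ sigma2*t
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(2.5, 2000)
  y <- simulate_trait(star, sigma2 = 0.4, root = 1, seed = 11)
  expect_lt(abs(stats::var(y) - 0.4 * 2.5) / (0.4 * 2.5), 0.05)
  expect_equal(mean(y), 1, tolerance = 0.05)

  # strong attraction: tips sit at the optimum
  y_ou <- simulate_trait(star, sigma2 = 0.4, root = 0, alpha = 5,
                         optima = 2, seed = 12)
  se <- stats::sd(y_ou) / sqrt(2000)
  expect_lt(abs(mean(y_ou) - 2), 3 * se)

  # trend shifts the mean by mu * t
  y_tr <- simulate_trait(star, sigma2 = 0.01, root = 0, trend = 0.8,
                         seed = 13)
  expect_equal(mean(y_tr), 0.8 * 2.5, tolerance = 0.05)

  expect_identical(simulate_trait(star, seed = 5),
                   simulate_trait(star, seed = 5))
})

test_that("planted rate shifts multiply subtree contrast variance", {
  tr <- simulate_tree(80, seed = 21)
  below <- cetasym:::tips_below_edges(tr)
  e <- which(lengths(below) >= 20 & lengths(below) <= 35)[1]
  clade_tips <- tr$tip.label[below[[e]]]
  clade_node <- tr$edge[e, 2]
  inside <- numeric(0); outside <- numeric(0)
  for (r in 1:100) {
    y <- simulate_trait(tr, sigma2 = 0.01,
                        shift_edges = stats::setNames(8, e),
                        seed = 3000 + r)
    pic <- ape::pic(y[tr$tip.label], tr)
    desc <- cetasym:::tips_under_node(tr, clade_node)
    # nodes wholly inside the shifted clade vs wholly outside
    in_nodes <- vapply(as.integer(names(pic)), function(nd)
      all(cetasym:::tips_under_node(tr, nd) %in% desc), TRUE)
    out_nodes <- vapply(as.integer(names(pic)), function(nd)
      !any(cetasym:::tips_under_node(tr, nd) %in% desc), TRUE)
    inside <- c(inside, pic[in_nodes]^2)
    outside <- c(outside, pic[out_nodes]^2)
  }
  ratio <- mean(inside) / mean(outside)
  expect_lt(abs(ratio - 8) / 8, 0.25)
})

test_that("discrete simulation respects rates and seeds", {
  tr <- simulate_tree(25, seed = 31)
  m0 <- mk_model(c("a", "b"), "ER", 0)
  st0 <- simulate_discrete(tr, m0, root_state = "b", seed = 32)
  expect_true(all(st0 == "b"))

  # long-branch limit: states near-independent with frequency ~ 1/2
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(100, 2000)
  st <- simulate_discrete(star, mk_model(c("a", "b"), "ER", 1),
                          root_state = "a", seed = 33)
  expect_lt(abs(mean(st == "a") - 0.5), 3.5 * sqrt(0.25 / 2000))

  expect_identical(simulate_discrete(tr, mk_model(c("a", "b"), "ER", 0.5),
                                     seed = 34),
                   simulate_discrete(tr, mk_model(c("a", "b"), "ER", 0.5),
                                     seed = 34))
})

test_that("the assembled synthetic dataset tells the intended story", {
  ds <- make_synthetic_dataset(n_odontocete = 30, n_mysticete = 8,
                               n_archaeocete = 4, n_terrestrial = 3,
                               missing_fraction = 0.39, seed = 2)
  md <- ds$metadata
  expect_equal(nrow(md), 45)
  expect_setequal(unique(md$group),
                  c("odontocete", "mysticete", "archaeocete",
                    "terrestrial"))
  expect_true(all(md$regime[md$family %in%
    c("Monodontidae", "Physeteridae", "Platanistidae")] == "regime4"))
  expect_setequal(unique(md$regime_split[md$regime == "regime4"]),
                  c("regime4a", "regime4b", "regime4c"))

  res <- quantify_asymmetry(ds)
  gm <- group_summary(res)$group_means
  m <- stats::setNames(gm$mean_sum_rho, gm$group)
  # odontocetes most asymmetric; baseline groups lowest
  expect_gt(m["odontocete"], m["archaeocete"])
  expect_gt(m["archaeocete"], m["terrestrial"])
  expect_lt(max(abs(m[c("mysticete", "terrestrial")] - 0.16)), 0.08)
  # specimen sums span the intended range
  expect_gt(min(res$sums$sum_rho), 0.1)
  expect_lt(max(res$sums$sum_rho), 0.65)
  expect_gt(max(res$sums$sum_rho), 0.4)

  # regime4 families carry the top sums
  top <- group_summary(res)$ranking$specimen_id[1:3]
  expect_true(all(md$regime[match(top, md$specimen_id)] == "regime4"))
})
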
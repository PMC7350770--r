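test_that("symmetry plane matches the eigen oracle and rejects degeneracy", {
  # random anchor cloud fed in as midline landmarks of a degenerate scheme
  set.seed(42)
  for (rep in 1:5) {
    anchors <- matrix(rnorm(30), 10, 3)
    sch <- landmark_scheme(pairs = rbind(c(11, 12)),
                           midline = 1:10, regions = rep("m", 12))
    coords <- rbind(anchors, c(0, 1, 0), c(0, -1, 0))
    cf <- landmark_config("x", coords)
    pl <- fit_symmetry_plane(cf, sch, use_pair_midpoints = FALSE)
    ctr <- colMeans(anchors)
    eg <- eigen(crossprod(sweep(anchors, 2, ctr)), symmetric = TRUE)
    oracle_n <- eg$vectors[, 3]
    expect_equal(abs(sum(pl$normal * oracle_n)), 1, tolerance = 1e-10)
    expect_equal(pl$point, ctr)
  }

  # exactly coplanar anchors: zero residual
  plane_pts <- cbind(rnorm(6), rnorm(6), 0.5)
  sch2 <- landmark_scheme(pairs = rbind(c(7, 8)), midline = 1:6,
                          regions = rep("m", 8))
  cf2 <- landmark_config("p", rbind(plane_pts, c(0, 0, 1), c(0, 0, 0)))
  pl2 <- fit_symmetry_plane(cf2, sch2, use_pair_midpoints = FALSE)
  resid <- sweep(plane_pts, 2, pl2$point) %*% pl2$normal
  expect_lt(sum(resid^2), 1e-20)

  # collinear anchors and too-few anchors
  line_pts <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  cf3 <- landmark_config("l", rbind(line_pts, c(0, 1, 0), c(0, -1, 0)))
  expect_error(fit_symmetry_plane(cf3, sch2, use_pair_midpoints = FALSE),
               "collinear")
  cf4 <- cf2
  cf4$missing[1:4] <- TRUE
  expect_error(fit_symmetry_plane(cf4, sch2, use_pair_midpoints = FALSE),
               "fewer than 3")
})

test_that("reflection is an involution", {
  set.seed(7)
  for (rep in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    pl <- structure(list(point = rnorm(3), normal = n),
                    class = "symmetry_plane")
    pts <- matrix(rnorm(30), 10, 3)
    expect_equal(reflect_points(reflect_points(pts, pl), pl), pts,
                 tolerance = 1e-12)
  }
})

test_that("mirror_fill reproduces symmetry and propagates missingness", {
  tm <- make_template()
  m <- mirror_fill(tm$config, tm$scheme)
  expect_lt(max(abs(m$coords - tm$config$coords)), 1e-9)
  expect_equal(m$source, "template")

  # planted 2 mm lateral displacement of one right landmark
  sch <- tm$scheme
  r_jugal <- intersect(which(sch$regions == "jugal"), sch$pairs[, "right"])
  cf <- tm$config
  cf$coords[r_jugal[1], ] <- cf$coords[r_jugal[1], ] + c(0, 2, 0)
  m2 <- mirror_fill(cf, sch)
  gap <- sqrt(sum((cf$coords[r_jugal[1], ] - m2$coords[r_jugal[1], ])^2))
  expect_equal(gap, 2, tolerance = 1e-6)

  # missing left jugal -> mirrored right jugal missing
  l_jugal <- sch$pairs[match(r_jugal[1], sch$pairs[, "right"]), "left"]
  cf3 <- tm$config
  cf3$missing[l_jugal] <- TRUE
  cf3$coords[l_jugal, ] <- NA
  m3 <- mirror_fill(cf3, sch)
  expect_true(m3$missing[r_jugal[1]])
  expect_false(m3$missing[setdiff(sch$pairs[, "right"], r_jugal[1])[1]])
})

test_that("TPS interpolates controls exactly and reproduces affine maps", {
  set.seed(11)
  from <- matrix(rnorm(45), 15, 3)
  to <- from + 0.3 * matrix(rnorm(45), 15, 3)
  model <- tps_fit(from, to)
  expect_lt(max(abs(tps_predict(model, from) - to)), 1e-8)
  expect_gt(model$bending_energy, 0)

  A <- matrix(c(1.2, 0.1, 0, -0.1, 0.8, 0.05, 0, 0.1, 1.1), 3, 3)
  b <- c(2, -1, 0.5)
  aff <- from %*% A + rep(b, each = 15)
  m_aff <- tps_fit(from, aff)
  expect_lt(m_aff$bending_energy, 1e-8)
  new_pts <- matrix(rnorm(15), 5, 3)
  expect_equal(tps_predict(m_aff, new_pts),
               new_pts %*% A + rep(b, each = 5), tolerance = 1e-8)

  expect_error(tps_fit(from[1:3, ], to[1:3, ]), "at least 4")
  flat <- cbind(rnorm(8), rnorm(8), 1)
  expect_error(tps_fit(flat, flat + 1), "degenerate")
})

test_that("estimate_missing restores landmarks (identity and affine cases)", {
  tm <- make_template()
  ref <- tm$config

  # no missing landmarks: unchanged
  out0 <- estimate_missing(ref, ref)
  expect_equal(out0$coords, ref$coords)
  expect_length(attr(out0, "estimated"), 0)

  # config equal to reference with one landmark deleted: exact restore
  cf <- ref
  cf$specimen_id <- "del"
  cf$missing[40] <- TRUE
  cf$coords[40, ] <- NA
  out <- estimate_missing(cf, ref)
  expect_equal(out$coords[40, ], ref$coords[40, ], tolerance = 1e-10)
  expect_equal(attr(out, "estimated"), 40L)
  expect_false(any(out$missing))

  # affinely deformed copy: restored at the affine image
  A <- matrix(c(1.1, 0.05, 0, -0.02, 0.95, 0.04, 0.01, 0, 1.02), 3, 3)
  b <- c(4, 1, -2)
  warped <- ref$coords %*% A + rep(b, each = nrow(ref$coords))
  cf2 <- landmark_config("aff", warped)
  cf2$missing[c(10, 77)] <- TRUE
  cf2$coords[c(10, 77), ] <- NA
  out2 <- estimate_missing(cf2, ref)
  expect_equal(out2$coords[c(10, 77), ], warped[c(10, 77), ],
               tolerance = 1e-8)
})

test_that("GPA superimposes rigid copies exactly and normalises size", {
  tm <- make_template()
  base <- tm$config
  rig <- random_rigid(3)
  cf2 <- landmark_config("moved", 2.5 * base$coords %*% rig$R +
                           rep(rig$b, each = nrow(base$coords)))
  al <- gpa(list(base, cf2))
  expect_lt(sqrt(sum((al$aligned$template - al$aligned$moved)^2)), 1e-10)
  for (A in al$aligned) {
    expect_equal(sqrt(sum(A^2)), 1, tolerance = 1e-12)
    expect_equal(colMeans(A), c(0, 0, 0), tolerance = 1e-12)
  }
  for (tr in al$transforms)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
  # objective is non-increasing over iterations
  expect_true(all(diff(al$objective) <= 1e-9))
})

test_that("GPA never absorbs reflections, unlike an improper oracle", {
  tm <- make_template(jitter_sd = 0.03, seed = 9)
  base <- tm$config
  mirror_coords <- base$coords
  mirror_coords[, 2] <- -mirror_coords[, 2]     # improper image
  cfm <- landmark_config("mirror", mirror_coords)
  al <- gpa(list(base, cfm))
  d_proper <- sqrt(sum((al$aligned$template - al$aligned$mirror)^2))
  expect_gt(d_proper, 1e-4)

  # oracle allowing improper rotations: distance collapses to ~0
  center_scale <- function(X) {
    X <- sweep(X, 2, colMeans(X)); X / sqrt(sum(X^2))
  }
  A <- center_scale(base$coords)
  B <- center_scale(mirror_coords)
  sv <- svd(t(B) %*% A)
  R_improper <- sv$u %*% t(sv$v)                # no det constraint
  expect_lt(sqrt(sum((B %*% R_improper - A)^2)), 1e-10)
})

test_that("single configurations and degenerate input are handled", {
  tm <- make_template()
  al1 <- gpa(list(tm$config))
  expect_equal(sqrt(sum(al1$aligned$template^2)), 1, tolerance = 1e-12)
  zero <- landmark_config("z", matrix(1, 7, 3))
  expect_error(gpa(list(zero)), "zero centroid size")
  miss <- tiny_config("m")
  miss$missing[1] <- TRUE
  expect_error(gpa(list(miss)), "missing landmarks")
})

test_that("align_mirrored shares the focal Procrustes frame", {
  tm <- make_template()
  m <- mirror_fill(tm$config, tm$scheme)
  al <- gpa(list(tm$config))
  rn <- align_mirrored(al, m)
  expect_lt(max(abs(rn - al$aligned$template)), 1e-9)

  # planted 2 mm displacement scales by 1/centroid-size
  sch <- tm$scheme
  r_idx <- sch$pairs[1, "right"]
  cf <- tm$config
  cf$coords[r_idx, ] <- cf$coords[r_idx, ] + c(0, 2, 0)
  s <- sqrt(sum(sweep(cf$coords, 2, colMeans(cf$coords))^2))
  m2 <- mirror_fill(cf, sch)
  al2 <- gpa(list(cf))
  rn2 <- align_mirrored(al2, m2)
  gap <- sqrt(sum((al2$aligned$template[r_idx, ] - rn2[r_idx, ])^2))
  expect_equal(gap, 2 / s, tolerance = 1e-4)

  # applying the transform twice is not the identity
  m2_again <- m2
  m2_again$coords <- rn2
  twice <- align_mirrored(al2, m2_again)
  expect_gt(max(abs(twice - rn2)), 1e-6)

  m2$source <- "nobody"
  expect_error(align_mirrored(al2, m2), "unknown source")
})
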
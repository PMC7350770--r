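#' Fit the midsagittal symmetry plane of a configuration
#'
#' Anchors are the non-missing midline landmarks plus the midpoints of fully
#' observed bilateral pairs; the plane is the total-least-squares plane
#' through the anchors (normal = eigenvector of the anchor scatter with the
#' smallest eigenvalue).
#'
#' @param config a [landmark_config()].
#' @param scheme its [landmark_scheme()].
#' @param use_pair_midpoints include midpoints of observed pairs as
#'   anchors.  Default `NULL` ("auto"): midline landmarks only whenever at
#'   least 3 non-collinear ones are observed, pair midpoints otherwise.
#'   Midpoints of genuinely asymmetric pairs drag the plane towards the
#'   asymmetry, biasing the mirror, so they are only a fallback.
#' @return list of class `symmetry_plane` with `point` (3-vector on the
#'   plane) and unit `normal`.
#' @export
fit_symmetry_plane <- function(config, scheme, use_pair_midpoints = NULL) {
  anchors <- config$coords[intersect(scheme$midline, which(!config$missing)),
                           , drop = FALSE]
  if (is.null(use_pair_midpoints))
    use_pair_midpoints <- nrow(anchors) < 3 ||
      !midline_spans_plane(anchors)
  if (use_pair_midpoints) {
    ok <- !config$missing[scheme$pairs[, 1]] &
      !config$missing[scheme$pairs[, 2]]
    if (any(ok)) {
      mids <- (config$coords[scheme$pairs[ok, 1], , drop = FALSE] +
               config$coords[scheme$pairs[ok, 2], , drop = FALSE]) / 2
      anchors <- rbind(anchors, mids)
    }
  }
  if (nrow(anchors) < 3)
    stop("cannot fit plane: fewer than 3 anchor points")
  ctr <- colMeans(anchors)
  A <- sweep(anchors, 2, ctr)
  eg <- eigen(crossprod(A), symmetric = TRUE)
  # collinear anchors: two near-zero eigenvalues relative to the largest
  if (eg$values[2] <= 1e-12 * max(eg$values[1], .Machine$double.eps))
    stop("cannot fit plane: anchors are collinear")
  normal <- eg$vectors[, 3]
  nz <- which(abs(normal) > 1e-12)[1]
  if (normal[nz] < 0) normal <- -normal     # canonical sign
  structure(list(point = ctr, normal = normal), class = "symmetry_plane")
}

#' Reflect points through a symmetry plane
#'
#' @param points n x 3 matrix.
#' @param plane a `symmetry_plane`.
#' @return the reflected n x 3 matrix.  Reflection is an involution.
#' @export
reflect_points <- function(points, plane) {
  points <- rbind(points)  # tolerate a bare 3-vector
  d <- sweep(points, 2, plane$point) %*% plane$normal
  points - 2 * (d %*% t(plane$normal))
}

#' Build the mirrored (symmetric reference) configuration
#'
#' Constructs the computer-mirrored counterpart of a focal configuration:
#' left-side and midline landmarks are copied verbatim, each right-side
#' landmark is replaced by the reflection of its left partner through the
#' specimen's fitted symmetry plane.  A right landmark is missing in the
#' mirror iff its left partner is missing in the focal configuration.
#'
#' @inheritParams fit_symmetry_plane
#' @return a [landmark_config()] with extra fields `source` (focal specimen
#'   id) and `plane`, class `c("mirrored_config", "landmark_config")`.
#' @export
mirror_fill <- function(config, scheme, use_pair_midpoints = NULL) {
  plane <- fit_symmetry_plane(config, scheme, use_pair_midpoints)
  coords <- config$coords
  miss <- config$missing
  l <- scheme$pairs[, 1]; r <- scheme$pairs[, 2]
  lobs <- !config$missing[l]
  coords[r[lobs], ] <- reflect_points(
    config$coords[l[lobs], , drop = FALSE], plane)
  miss[r] <- config$missing[l]
  coords[miss, ] <- NA_real_
  out <- landmark_config(paste0(config$specimen_id, "_mirror"), coords, miss)
  out$source <- config$specimen_id
  out$plane <- plane
  class(out) <- c("mirrored_config", class(out))
  out
}

# TRUE when midline anchors alone pin down a plane (not collinear)
midline_spans_plane <- function(anchors) {
  A <- sweep(anchors, 2, colMeans(anchors))
  ev <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
  ev[2] > 1e-12 * max(ev[1], .Machine$double.eps)
}

# ---- thin-plate spline (3D, kernel U(r) = r) --------------------------------

#' Fit a 3D thin-plate spline between two point sets
#'
#' Interpolating volumetric spline with kernel U(r) = r; maps each control
#' point of `from` exactly onto the matching point of `to`, with zero
#' bending energy iff the map is affine.
#'
#' @param from,to k x 3 matrices of corresponding control points (k >= 4,
#'   not coplanar).
#' @return list of class `tps_model` with `control_points`, `weights`,
#'   `affine` (4 x 3: intercept row + linear map) and `bending_energy`.
#' @export
tps_fit <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  k <- nrow(from)
  if (k < 4) stop("TPS needs at least 4 control points")
  ctr <- colMeans(from)
  fc <- sweep(from, 2, ctr)
  if (qr(fc)$rank < 3)
    stop("degenerate TPS control points: coplanar or collinear")
  scl <- sqrt(mean(rowSums(fc^2)))      # normalise for conditioning
  fn <- fc / scl
  K <- as.matrix(stats::dist(fn))
  P <- cbind(1, fn)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(to, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  sol <- sol + solve(L, rhs - L %*% sol)   # one refinement step
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:4, , drop = FALSE]
  be <- sum(abs(colSums(W * (K %*% W))))   # magnitude of bending functional
  structure(list(control_points = from, norm_center = ctr,
                 norm_scale = scl, control_norm = fn, weights = W,
                 affine = A, bending_energy = be),
            class = "tps_model")
}

#' Evaluate a fitted thin-plate spline at new points
#'
#' @param model a [tps_fit()] result.
#' @param points m x 3 matrix.
#' @return m x 3 matrix of warped points.
#' @export
tps_predict <- function(model, points) {
  points <- rbind(points)
  pn <- sweep(points, 2, model$norm_center) / model$norm_scale
  cp <- model$control_norm
  # pairwise distances points x control; explicit differences avoid the
  # cancellation that would blunt the sqrt kernel at the control points
  D <- sqrt(outer(pn[, 1], cp[, 1], "-")^2 +
              outer(pn[, 2], cp[, 2], "-")^2 +
              outer(pn[, 3], cp[, 3], "-")^2)
  cbind(1, pn) %*% model$affine + D %*% model$weights
}

#' Estimate missing landmarks by thin-plate spline warping
#'
#' Builds a TPS from the reference's observed-landmark positions onto the
#' focal configuration's observed landmarks, then places each missing
#' landmark at the warped image of its reference position (the
#' minimum-bending-energy completion).
#'
#' @param config a [landmark_config()] possibly with missing landmarks.
#' @param reference a complete [landmark_config()] (or bare n x 3 matrix)
#'   with the same landmark count.
#' @return `config` with all landmarks observed; the indices that were
#'   estimated are recorded in `attr(, "estimated")`.
#' @export
estimate_missing <- function(config, reference) {
  ref <- if (inherits(reference, "landmark_config")) {
    if (any(reference$missing)) stop("reference must be complete")
    reference$coords
  } else as.matrix(reference)
  if (nrow(ref) != nrow(config$coords))
    stop("reference and configuration landmark counts differ")
  miss <- which(config$missing)
  if (!length(miss)) {
    attr(config, "estimated") <- integer(0)
    return(config)
  }
  obs <- which(!config$missing)
  model <- tps_fit(ref[obs, , drop = FALSE],
                   config$coords[obs, , drop = FALSE])
  config$coords[miss, ] <- tps_predict(model, ref[miss, , drop = FALSE])
  config$missing[] <- FALSE
  attr(config, "estimated") <- miss
  config
}

#' Complete every configuration of a dataset
#'
#' The TPS reference is the Procrustes mean shape of all complete
#' specimens, rescaled to their median centroid size (so the warp operates
#' at data scale); the choice is recorded in the returned run log.
#'
#' @param dataset a [landmark_dataset()].
#' @return the completed dataset, with `attr(, "completion_log")` recording
#'   the reference and the estimated landmark indices per specimen.
#' @export
estimate_missing_dataset <- function(dataset) {
  complete <- Filter(function(cf) !any(cf$missing), dataset$configurations)
  if (!length(complete))
    stop("no complete specimen available to build a TPS reference")
  if (length(complete) >= 2) {
    al <- gpa(complete)
    ref <- al$consensus
  } else ref <- {
    cf <- complete[[1]]
    sweep(cf$coords, 2, colMeans(cf$coords)) / centroid_size_of(cf$coords)
  }
  med_cs <- stats::median(vapply(complete, function(cf)
    centroid_size_of(cf$coords), 0))
  ref <- ref * (med_cs / centroid_size_of(ref))
  log <- list(reference = "Procrustes mean of complete specimens",
              n_complete = length(complete), reference_size = med_cs,
              estimated = list())
  dataset$configurations <- lapply(dataset$configurations, function(cf) {
    out <- estimate_missing(cf, ref)
    log$estimated[[cf$specimen_id]] <<- attr(out, "estimated")
    out
  })
  attr(dataset, "completion_log") <- log
  dataset
}

# ---- generalized Procrustes analysis ---------------------------------------

# proper orthogonal Procrustes rotation of A onto C (det = +1)
proper_rotation <- function(A, C) {
  sv <- svd(t(A) %*% C)
  s <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Superimposes complete configurations by removing translation (centering),
#' size (scaling to unit centroid size) and orientation (proper rotations
#' only -- reflections are never absorbed, so bilateral asymmetry survives
#' superimposition).  The consensus is the running mean shape; iteration
#' stops when the consensus changes by less than `tol` (Frobenius norm) or
#' after `max_iter` sweeps.
#'
#' @param configs list of complete [landmark_config()]s (>= 1), all with the
#'   same landmark count.
#' @param tol convergence tolerance on consensus change (default 1e-10).
#' @param max_iter maximum sweeps (default 100).
#' @return list of class `aligned_dataset`: `aligned` (named list of n x 3
#'   matrices in Procrustes units), `transforms` (per specimen: `center`,
#'   `scale`, `rotation`), `consensus`, `iterations`, `final_change`,
#'   `objective` (per-sweep sum of squared distances to the consensus).
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  ids <- vapply(configs, function(cf) cf$specimen_id, "")
  for (cf in configs)
    if (any(cf$missing))
      stop("specimen ", cf$specimen_id,
           " has missing landmarks; run estimate_missing first")
  k <- length(configs)
  centered <- lapply(configs, function(cf) {
    ctr <- colMeans(cf$coords)
    X <- sweep(cf$coords, 2, ctr)
    cs <- sqrt(sum(X^2))
    if (cs == 0) stop("specimen ", cf$specimen_id, " has zero centroid size")
    list(X = X / cs, center = ctr, scale = cs)
  })
  aligned <- lapply(centered, `[[`, "X")
  rotations <- rep(list(diag(3)), k)
  if (k == 1) {
    out <- list(aligned = stats::setNames(aligned, ids),
                transforms = stats::setNames(lapply(centered, function(cc)
                  list(center = cc$center, scale = cc$scale,
                       rotation = diag(3))), ids),
                consensus = aligned[[1]], iterations = 0L,
                final_change = 0, objective = numeric(0))
    class(out) <- "aligned_dataset"
    return(out)
  }
  consensus <- aligned[[1]]
  objective <- numeric(0)
  change <- Inf
  iter <- 0L
  while (iter < max_iter && change > tol) {
    iter <- iter + 1L
    for (i in seq_len(k)) {
      R <- proper_rotation(centered[[i]]$X, consensus)
      rotations[[i]] <- R
      aligned[[i]] <- centered[[i]]$X %*% R
    }
    new_consensus <- Reduce(`+`, aligned) / k
    objective <- c(objective, sum(vapply(aligned, function(A)
      sum((A - new_consensus)^2), 0)))
    change <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  out <- list(
    aligned = stats::setNames(aligned, ids),
    transforms = stats::setNames(lapply(seq_len(k), function(i)
      list(center = centered[[i]]$center, scale = centered[[i]]$scale,
           rotation = rotations[[i]])), ids),
    consensus = consensus, iterations = iter, final_change = change,
    objective = objective)
  class(out) <- "aligned_dataset"
  out
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("GPA alignment:", length(x$aligned), "configurations,",
      x$iterations, "iterations, final consensus change",
      format(x$final_change, digits = 3), "\n")
  invisible(x)
}

#' Carry a mirrored configuration into its focal specimen's Procrustes frame
#'
#' Applies the focal specimen's fitted translation, scale and rotation
#' verbatim to the mirrored configuration, so focal and mirror live in one
#' frame before radii are measured.
#'
#' @param aligned an [gpa()] result containing the mirror's source specimen.
#' @param mirrored a [mirror_fill()] result.
#' @return n x 3 matrix of aligned mirrored coordinates (Procrustes units).
#' @export
align_mirrored <- function(aligned, mirrored) {
  tr <- aligned$transforms[[mirrored$source]]
  if (is.null(tr))
    stop("unknown source specimen: ", mirrored$source)
  sweep(mirrored$coords, 2, tr$center) %*% tr$rotation / tr$scale
}
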
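#' Per-landmark displacement radii between focal and mirrored configurations
#'
#' For each landmark, decomposes the displacement from the mirrored
#' (symmetric reference) position to the focal position in spherical
#' coordinates: `rho` (Euclidean distance, Procrustes units), `phi` (azimuth
#' of the projection on the equatorial plane) and `theta` (polar angle).
#' Angles are measured in the frame of the first two principal axes of the
#' consensus mean shape (the equatorial plane) and are `NA` where rho = 0.
#'
#' @param aligned_fn,aligned_rn n x 3 matrices in one Procrustes frame
#'   (focal and mirrored).
#' @param axes optional 3 x 3 orthonormal axis matrix (columns = equatorial
#'   x, equatorial y, polar z); default the identity frame.
#' @return data.frame with columns `landmark`, `rho`, `phi`, `theta`.
#' @export
radii <- function(aligned_fn, aligned_rn, axes = NULL) {
  if (!all(dim(aligned_fn) == dim(aligned_rn)))
    stop("frame mismatch: configurations have different landmark counts")
  d <- aligned_fn - aligned_rn
  if (!is.null(axes)) d <- d %*% axes
  rho <- sqrt(rowSums(d^2))
  phi <- ifelse(rho > 0, atan2(d[, 2], d[, 1]), NA_real_)
  theta <- ifelse(rho > 0, acos(pmin(pmax(d[, 3] / pmax(rho, 1e-300),
                                          -1), 1)), NA_real_)
  data.frame(landmark = seq_len(nrow(d)), rho = rho, phi = phi,
             theta = theta)
}

# principal axes of a point set (columns ordered by decreasing variance)
principal_axes <- function(points) {
  eigen(stats::cov(points), symmetric = TRUE)$vectors
}

#' Quantify cranial asymmetry for a whole dataset
#'
#' Runs the full quantification pipeline: (1) thin-plate-spline completion
#' of missing landmarks against the Procrustes mean of complete specimens,
#' (2) mirroring of each focal configuration across its fitted midsagittal
#' plane, (3) generalized Procrustes superimposition of the focal
#' configurations only, (4) transfer of each mirror into its focal frame,
#' and (5) per-landmark displacement radii.  Specimens whose symmetry plane
#' cannot be fitted are excluded with a logged reason.
#'
#' @param dataset a [landmark_dataset()].
#' @param use_pair_midpoints passed to [fit_symmetry_plane()].
#' @param include_estimated include TPS-estimated landmarks in the specimen
#'   sums (default `TRUE`; set `FALSE` for a sensitivity run).
#' @return list of class `asymmetry_result`: `radii` (long data.frame:
#'   `specimen_id`, `landmark`, `rho`, `phi`, `theta`, `estimated`),
#'   `sums` (data.frame `specimen_id`, `sum_rho`), `aligned` (the [gpa()]
#'   result), `scheme`, `metadata`, `excluded` (named reasons),
#'   `include_estimated`.
#' @export
quantify_asymmetry <- function(dataset, use_pair_midpoints = NULL,
                               include_estimated = TRUE) {
  any_missing <- any(vapply(dataset$configurations,
                            function(cf) any(cf$missing), TRUE))
  estimated <- list()
  if (any_missing) {
    dataset <- estimate_missing_dataset(dataset)
    estimated <- attr(dataset, "completion_log")$estimated
  }
  excluded <- character(0)
  mirrors <- list()
  for (cf in dataset$configurations) {
    m <- tryCatch(mirror_fill(cf, dataset$scheme, use_pair_midpoints),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) excluded[cf$specimen_id] <- m
    else mirrors[[cf$specimen_id]] <- m
  }
  keep <- setdiff(names(dataset$configurations), names(excluded))
  if (length(keep) == 0) stop("no specimens usable: all plane fits failed")
  al <- gpa(dataset$configurations[keep])
  axes <- principal_axes(al$consensus)
  rad <- do.call(rbind, lapply(keep, function(id) {
    rn <- align_mirrored(al, mirrors[[id]])
    r <- radii(al$aligned[[id]], rn, axes)
    r$specimen_id <- id
    est <- estimated[[id]]
    r$estimated <- r$landmark %in% est
    r[, c("specimen_id", "landmark", "rho", "phi", "theta", "estimated")]
  }))
  rownames(rad) <- NULL
  res <- structure(
    list(radii = rad, aligned = al, scheme = dataset$scheme,
         metadata = dataset$metadata, excluded = excluded,
         include_estimated = include_estimated),
    class = "asymmetry_result")
  res$sums <- specimen_sum(rad, include_estimated = include_estimated)
  res
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat("Asymmetry quantification:", nrow(x$sums), "specimens,",
      nrow(x$radii), "radii values\n")
  if (length(x$excluded))
    cat("Excluded:", paste(names(x$excluded), collapse = ", "), "\n")
  invisible(x)
}

#' Per-specimen total asymmetry (sum of radii)
#'
#' @param records radii data.frame (as in [quantify_asymmetry()]`$radii`),
#'   or an `asymmetry_result`.
#' @param include_estimated when `FALSE`, TPS-estimated landmarks are left
#'   out of the sums (sensitivity mode).
#' @return data.frame with `specimen_id` and `sum_rho`, in first-appearance
#'   order.
#' @export
specimen_sum <- function(records, include_estimated = TRUE) {
  if (inherits(records, "asymmetry_result")) records <- records$radii
  records$specimen_id <- as.character(records$specimen_id)
  if (!include_estimated && "estimated" %in% names(records))
    records <- records[!records$estimated, , drop = FALSE]
  sums <- tapply(records$rho, records$specimen_id, sum)
  ids <- unique(records$specimen_id)
  data.frame(specimen_id = ids, sum_rho = as.numeric(sums[ids]))
}

#' Group summaries of asymmetry
#'
#' Computes, per group: the mean of per-specimen total asymmetry (the group
#' mean sum-of-radii), the per-landmark mean radius across the group's
#' specimens, and a descending ranking of specimens by total asymmetry
#' (ties broken by specimen id for determinism).
#'
#' @param result an `asymmetry_result` (or its `radii` data.frame, in which
#'   case `metadata` must be supplied).
#' @param metadata data.frame with `specimen_id` and the grouping column.
#' @param grouping name of the metadata column to group by (default
#'   `"group"`).
#' @param top_k length of the returned ranking (default all).
#' @return list with `group_means` (`group`, `n`, `mean_sum_rho`),
#'   `landmark_means` (`group`, `landmark`, `mean_rho`), `ranking`
#'   (`rank`, `specimen_id`, group, `sum_rho`).
#' @export
group_summary <- function(result, metadata = NULL, grouping = "group",
                          top_k = Inf) {
  if (inherits(result, "asymmetry_result")) {
    records <- result$radii
    if (is.null(metadata)) metadata <- result$metadata
    include_estimated <- result$include_estimated
  } else {
    records <- result
    include_estimated <- TRUE
  }
  if (is.null(metadata) || !grouping %in% names(metadata))
    stop("metadata with a '", grouping, "' column is required")
  sums <- specimen_sum(records, include_estimated)
  grp <- metadata[[grouping]][match(sums$specimen_id,
                                    metadata$specimen_id)]
  if (anyNA(grp))
    stop("specimen(s) without a '", grouping, "' label: ",
         paste(sums$specimen_id[is.na(grp)], collapse = ", "))
  empty <- setdiff(unique(metadata[[grouping]]), grp)
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  gm <- do.call(rbind, lapply(split(sums$sum_rho, grp), function(v)
    data.frame(n = length(v), mean_sum_rho = mean(v))))
  gm <- data.frame(group = rownames(gm), gm, row.names = NULL)
  rg <- records
  rg$group <- grp[match(rg$specimen_id, sums$specimen_id)]
  lm_mean <- stats::aggregate(rho ~ group + landmark, rg, mean)
  names(lm_mean)[3] <- "mean_rho"
  lm_mean <- lm_mean[order(lm_mean$group, lm_mean$landmark), ]
  rownames(lm_mean) <- NULL
  ord <- order(-sums$sum_rho, sums$specimen_id)
  ranking <- data.frame(rank = seq_along(ord),
                        specimen_id = sums$specimen_id[ord],
                        group = grp[ord], sum_rho = sums$sum_rho[ord])
  if (is.finite(top_k)) ranking <- ranking[seq_len(min(top_k,
                                                       nrow(ranking))), ]
  list(group_means = gm, landmark_means = lm_mean, ranking = ranking)
}

#' Fraction of a specimen's asymmetry located in one region
#'
#' @param records radii data.frame or `asymmetry_result`.
#' @param scheme the [landmark_scheme()] (taken from the result when
#'   omitted).
#' @param region a region label present in the scheme.
#' @return data.frame `specimen_id`, `percent` -- 100 x (sum of rho over the
#'   region's landmarks) / (total sum of rho); `NA` when the total is 0.
#' @export
region_fraction <- function(records, scheme = NULL, region) {
  if (inherits(records, "asymmetry_result")) {
    if (is.null(scheme)) scheme <- records$scheme
    records <- records$radii
  }
  if (!region %in% scheme$regions)
    stop("unknown region: ", region)
  in_region <- which(scheme$regions == region)
  tot <- specimen_sum(records)
  reg <- records[records$landmark %in% in_region, , drop = FALSE]
  reg_sum <- tapply(reg$rho, reg$specimen_id, sum)
  pct <- 100 * as.numeric(reg_sum[tot$specimen_id]) / tot$sum_rho
  pct[!is.finite(pct)] <- NA_real_
  data.frame(specimen_id = tot$specimen_id, percent = pct)
}

#' Remove a region's landmarks from a dataset
#'
#' Drops every landmark of the region from the scheme and from all
#' configurations, re-indexing pairs and midline.  Regions must respect
#' bilaterality: a region containing only one member of a pair is an error.
#'
#' @param dataset a [landmark_dataset()].
#' @param region region label to remove.
#' @return the reduced [landmark_dataset()].
#' @export
drop_region <- function(dataset, region) {
  scheme <- dataset$scheme
  if (!region %in% scheme$regions) stop("unknown region: ", region)
  drop <- which(scheme$regions == region)
  if (!length(drop)) return(dataset)
  lin <- scheme$pairs[, 1] %in% drop
  rin <- scheme$pairs[, 2] %in% drop
  if (any(lin != rin))
    stop("region '", region, "' breaks bilaterality: pairs with only one ",
         "side in the region")
  keep <- setdiff(seq_len(scheme$n_total), drop)
  remap <- integer(scheme$n_total)
  remap[keep] <- seq_along(keep)
  keep_pairs <- scheme$pairs[!lin, , drop = FALSE]
  new_scheme <- landmark_scheme(
    pairs = cbind(remap[keep_pairs[, 1]], remap[keep_pairs[, 2]]),
    midline = remap[setdiff(scheme$midline, drop)],
    regions = scheme$regions[keep])
  dataset$scheme <- new_scheme
  dataset$configurations <- lapply(dataset$configurations, function(cf)
    landmark_config(cf$specimen_id, cf$coords[keep, , drop = FALSE],
                    cf$missing[keep]))
  names(dataset$configurations) <-
    vapply(dataset$configurations, `[[`, "", "specimen_id")
  dataset
}

#' Principal component analysis of aligned configurations
#'
#' Eigen-decomposition of the covariance of the flattened Procrustes
#' coordinates; scores are centred.  Zero-variance data yield zero variance
#' proportions without division-by-zero.
#'
#' @param aligned an [gpa()] result or `asymmetry_result`.
#' @return list of class `asym_pca`: `scores` (specimens x components),
#'   `proportion` (variance proportions), `loadings`.
#' @export
asym_pca <- function(aligned) {
  if (inherits(aligned, "asymmetry_result")) aligned <- aligned$aligned
  mats <- aligned$aligned
  if (length(mats) < 2) stop("PCA needs at least 2 specimens")
  X <- t(vapply(mats, function(m) as.numeric(m),
                numeric(length(mats[[1]]))))
  rownames(X) <- names(mats)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  ev <- sv$d^2
  prop <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  scores <- Xc %*% sv$v
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, proportion = prop, loadings = sv$v),
            class = "asym_pca")
}
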
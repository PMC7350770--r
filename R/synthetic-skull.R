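#' Default region layout for the stylised skull template
#'
#' Allocates bilateral pairs and midline landmarks to anatomical regions.
#' The default mimics a cetacean-like cranium: an elongated rostrum, a
#' nasofacial block (nasal, premaxilla, maxilla), lateral arcs (orbit,
#' jugal, squamosal) and a posterior braincase, with 57 pairs and 9 midline
#' points (123 landmarks).  The layout is reconstructed from anatomical
#' descriptions and is illustrative, not an authoritative digitising
#' protocol.
#'
#' @return list with integer vectors `pairs` and `midline` of per-region
#'   counts (named by region).
#' @export
default_region_layout <- function() {
  list(pairs = c(rostrum = 12L, premaxilla = 7L, maxilla = 9L, nasal = 7L,
                 orbit = 6L, jugal = 4L, squamosal = 6L, posterior = 6L),
       midline = c(rostrum = 2L, nasal = 2L, posterior = 3L, other = 2L))
}

# deterministic anterior-posterior position in [0, 1] for each region
region_axis_pos <- c(rostrum = 0.15, premaxilla = 0.38, maxilla = 0.50,
                     nasal = 0.62, orbit = 0.58, jugal = 0.66,
                     squamosal = 0.78, posterior = 0.92, other = 0.85)

#' Generate a symmetric skull landmark template and its scheme
#'
#' Builds a stylised, exactly bilaterally symmetric skull: left-side
#' landmarks are laid out on smooth arcs per region (with small seeded
#' jitter so configurations are in general position), right-side landmarks
#' are their exact reflections through the y = 0 midsagittal plane, and
#' midline landmarks lie exactly in that plane.  The long axis is x
#' (rostrum towards +x is *anterior*... here the rostrum sits at low x and
#' the braincase at high x), the lateral axis is y (left = +y), dorsoventral
#' is z.
#'
#' @param n_pairs number of bilateral landmark pairs (default 57).
#' @param n_midline number of midline landmarks (default 9).
#' @param centroid_size target centroid size in mm (default 500).
#' @param layout region layout as from [default_region_layout()]; ignored
#'   when `n_pairs`/`n_midline` differ from the layout totals, in which case
#'   regions are recycled proportionally.
#' @param jitter_sd relative jitter (fraction of skull length) applied
#'   symmetrically, default 0.01.
#' @param seed integer seed; the template is a pure function of its
#'   arguments.
#' @return list with elements `config` (a [landmark_config()]) and `scheme`
#'   (a [landmark_scheme()]).
#' @export
make_template <- function(n_pairs = 57L, n_midline = 9L, centroid_size = 500,
                          layout = default_region_layout(),
                          jitter_sd = 0.01, seed = 1L) {
  stopifnot(n_pairs >= 1, n_midline >= 1)
  pair_regions <- rep(names(layout$pairs), layout$pairs)
  mid_regions <- rep(names(layout$midline), layout$midline)
  pair_regions <- rep_len(pair_regions, n_pairs)
  mid_regions <- rep_len(mid_regions, n_midline)

  old <- local_seed(seed)
  on.exit(restore_seed(old))

  # left-side landmarks: per-region arcs in (x, y>0, z)
  left <- matrix(0, n_pairs, 3)
  for (r in unique(pair_regions)) {
    idx <- which(pair_regions == r)
    k <- length(idx)
    t <- seq(0.15, 0.85, length.out = k)
    x0 <- region_axis_pos[[r]]
    left[idx, 1] <- x0 + 0.12 * (t - 0.5)
    left[idx, 2] <- 0.10 + 0.18 * sin(pi * t) *
      (1 - 0.5 * abs(x0 - 0.6))            # widest near the orbit region
    left[idx, 3] <- 0.15 * cos(pi * t) + 0.25 * x0
  }
  left <- left + matrix(stats::rnorm(3 * n_pairs, 0, jitter_sd), n_pairs, 3)
  left[, 2] <- pmax(left[, 2], 0.02)       # stay strictly on the left side

  # midline profile arcs from the rostrum tip over the cranial vertex, so
  # the midline points alone span the sagittal plane well (a thin profile
  # makes the fitted plane unstable under digitising noise)
  tm <- seq(0.02, 0.98, length.out = n_midline)
  mid <- cbind(tm, 0, 0.08 + 0.35 * sin(pi * tm))
  jm <- matrix(stats::rnorm(2 * n_midline, 0, jitter_sd), n_midline, 2)
  mid[, 1] <- mid[, 1] + jm[, 1]           # jitter within the plane only
  mid[, 3] <- mid[, 3] + jm[, 2]

  right <- left
  right[, 2] <- -left[, 2]                 # exact reflection through y = 0

  coords <- rbind(left, right, mid)
  pairs <- cbind(seq_len(n_pairs), n_pairs + seq_len(n_pairs))
  midline <- 2L * n_pairs + seq_len(n_midline)
  regions <- c(pair_regions, pair_regions, mid_regions)

  cs <- centroid_size_of(coords)
  ctr <- colMeans(coords)
  coords <- sweep(coords, 2, ctr)
  coords <- coords * (centroid_size / cs)
  coords[, 2] <- coords[, 2] - mean(coords[midline, 2])  # keep plane exact
  coords[midline, 2] <- 0
  coords[pairs[, 2], 2] <- -coords[pairs[, 1], 2]

  list(config = landmark_config("template", coords),
       scheme = landmark_scheme(pairs, midline, regions))
}

centroid_size_of <- function(coords) {
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, ctr)^2))
}

#' Plant directional asymmetry into a configuration
#'
#' Translates every landmark of the target region(s), on the affected side,
#' by `magnitude * direction`.  Displacing one side of a bilateral region
#' makes the configuration depart from its mirrored reference, emulating
#' e.g. the directional (posterior and sinistral) nasofacial displacement of
#' echolocating odontocetes.
#'
#' @param config a [landmark_config()].
#' @param scheme its [landmark_scheme()].
#' @param region character vector of region labels to displace.
#' @param magnitude displacement in mm (>= 0).
#' @param direction length-3 direction (normalised internally); default
#'   posterior-sinistral `(+x, +y)` in template axes.
#' @param side which landmarks move: `"right"` (default), `"left"`,
#'   `"midline"`, or `"all"`.
#' @return the displaced [landmark_config()].
#' @export
apply_asymmetry <- function(config, scheme, region, magnitude,
                            direction = c(1, 1, 0), side = "right") {
  stopifnot(magnitude >= 0)
  direction <- direction / sqrt(sum(direction^2))
  in_region <- which(scheme$regions %in% region)
  side_idx <- switch(side,
    left = scheme$pairs[, "left"],
    right = scheme$pairs[, "right"],
    midline = scheme$midline,
    all = seq_len(scheme$n_total),
    stop("unknown side: ", side))
  affected <- intersect(in_region, side_idx)
  if (!length(affected))
    stop("no landmarks of region ", paste(region, collapse = "/"),
         " on side ", side)
  config$coords[affected, ] <- config$coords[affected, , drop = FALSE] +
    rep(magnitude * direction, each = length(affected))
  config
}

#' Degrade a dataset with missing landmarks and digitising noise
#'
#' A fraction of specimens receives missing landmarks, preferentially in
#' fragile regions (broken jugals, squamosals and rostrum tips dominate
#' missing data in museum skulls); isotropic Gaussian noise is added to all
#' observed landmarks.  Pure function of `(dataset, rates, seed)`.
#'
#' @param dataset a [landmark_dataset()].
#' @param specimen_missing_fraction fraction of specimens degraded with
#'   missing landmarks, in \[0,1\].
#' @param landmark_missing_rate per-landmark missingness rate within a
#'   degraded specimen, in \[0,1\] (applied with 4x weight in fragile
#'   regions).
#' @param noise_sd isotropic noise SD in mm.
#' @param fragile_regions regions attracting missingness.
#' @param seed integer seed.
#' @return the degraded [landmark_dataset()].
#' @export
degrade <- function(dataset, specimen_missing_fraction = 0.39,
                    landmark_missing_rate = 0.05, noise_sd = 0,
                    fragile_regions = c("jugal", "squamosal", "rostrum"),
                    seed = 1L) {
  if (specimen_missing_fraction < 0 || specimen_missing_fraction > 1)
    stop("specimen_missing_fraction must be in [0, 1]")
  if (landmark_missing_rate < 0 || landmark_missing_rate > 1)
    stop("landmark_missing_rate must be in [0, 1]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  scheme <- dataset$scheme
  fragile <- scheme$regions %in% fragile_regions
  p_land <- ifelse(fragile, pmin(4 * landmark_missing_rate, 1),
                   landmark_missing_rate)
  n <- length(dataset$configurations)
  degraded_specs <- stats::runif(n) < specimen_missing_fraction
  dataset$configurations <- lapply(
    seq_len(n), function(i) {
      cf <- dataset$configurations[[i]]
      if (noise_sd > 0) {
        obs <- !cf$missing
        cf$coords[obs, ] <- cf$coords[obs, , drop = FALSE] +
          matrix(stats::rnorm(3 * sum(obs), 0, noise_sd), sum(obs), 3)
      }
      if (degraded_specs[i]) {
        miss <- stats::runif(scheme$n_total) < p_land
        if (!any(miss)) miss[sample(which(fragile), 1)] <- TRUE
        cf$missing <- cf$missing | miss
        cf$coords[cf$missing, ] <- NA_real_
      }
      cf
    })
  names(dataset$configurations) <-
    vapply(dataset$configurations, `[[`, "", "specimen_id")
  dataset
}

# Seed hygiene: run under a given seed, then restore the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
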
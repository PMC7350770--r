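#' Construct a landmark scheme
#'
#' A landmark scheme describes the fixed landmark template shared by every
#' specimen in a dataset: which landmarks form bilateral (left, right) pairs,
#' which lie on the midline, and which anatomical region each belongs to.
#' The mirroring reference set (left-side plus midline landmarks) is derived,
#' never supplied.
#'
#' Indices are 1-based throughout, matching the convention of landmark files
#' ("landmark 15", "landmark 79").
#'
#' @param pairs integer matrix with columns `left` and `right`, one row per
#'   bilateral landmark pair.
#' @param midline integer vector of midline landmark indices.
#' @param regions character vector of region labels, one per landmark
#'   (length `n_total`), or a named vector indexed by landmark.
#' @return An object of class `landmark_scheme` with elements `n_total`,
#'   `pairs`, `midline`, `regions`, `reference_set`.
#' @export
landmark_scheme <- function(pairs, midline, regions) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  midline <- as.integer(midline)
  n_total <- 2L * nrow(pairs) + length(midline)
  left <- pairs[, 1]
  right <- pairs[, 2]
  all_idx <- c(left, right, midline)
  if (anyDuplicated(all_idx))
    stop("scheme invariant violated: landmark index ",
         all_idx[duplicated(all_idx)][1],
         " assigned to more than one side")
  if (!setequal(all_idx, seq_len(n_total)))
    stop("scheme invariant violated: left/right/midline sets must ",
         "partition 1..", n_total)
  regions <- as.character(regions)
  if (length(regions) != n_total)
    stop("regions must have one label per landmark (", n_total, ")")
  structure(
    list(n_total = n_total,
         pairs = pairs,
         midline = midline,
         regions = regions,
         reference_set = sort(c(left, midline))),
    class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_total, "landmarks (",
      nrow(x$pairs), "bilateral pairs +", length(x$midline),
      "midline );", length(x$reference_set), "mirroring reference landmarks\n")
  cat("Regions:", paste(sort(unique(x$regions)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a landmark scheme file
#'
#' The scheme file is a delimited table with columns
#' `landmark,side,partner,region`; `side` is one of `left`, `right`,
#' `midline`, and `partner` gives the paired landmark for sided landmarks
#' (empty/NA for midline).
#'
#' @param path path to a CSV scheme file.
#' @return A [landmark_scheme()].
#' @export
read_scheme <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark", "side", "region")
  if (!all(need %in% names(tab)))
    stop("scheme file must have columns landmark, side, partner, region")
  tab$side <- tolower(tab$side)
  bad <- setdiff(unique(tab$side), c("left", "right", "midline"))
  if (length(bad))
    stop("unknown side value(s): ", paste(bad, collapse = ", "))
  lefts <- tab[tab$side == "left", ]
  rights <- tab[tab$side == "right", ]
  if (nrow(lefts) != nrow(rights))
    stop("left/right landmark counts differ (", nrow(lefts), " vs ",
         nrow(rights), ")")
  partner <- suppressWarnings(as.integer(tab$partner))
  names(partner) <- tab$landmark
  pl <- partner[as.character(lefts$landmark)]
  if (anyNA(pl))
    stop("left landmark ", lefts$landmark[which(is.na(pl))[1]],
         " has no right partner")
  if (!setequal(pl, rights$landmark))
    stop("pair partners do not match the set of right landmarks")
  regions <- character(max(tab$landmark))
  regions[tab$landmark] <- tab$region
  landmark_scheme(pairs = cbind(lefts$landmark, pl),
                  midline = tab$landmark[tab$side == "midline"],
                  regions = regions)
}

#' Write a landmark scheme file
#'
#' @param scheme a [landmark_scheme()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  n <- scheme$n_total
  side <- rep("right", n)
  side[scheme$pairs[, "left"]] <- "left"
  side[scheme$midline] <- "midline"
  partner <- rep(NA_integer_, n)
  partner[scheme$pairs[, "left"]] <- scheme$pairs[, "right"]
  partner[scheme$pairs[, "right"]] <- scheme$pairs[, "left"]
  utils::write.csv(
    data.frame(landmark = seq_len(n), side = side, partner = partner,
               region = scheme$regions),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a single landmark configuration
#'
#' @param specimen_id specimen identifier.
#' @param coords numeric n x 3 matrix of landmark coordinates (mm).
#' @param missing logical mask, `TRUE` where a landmark is missing.  Rows of
#'   `coords` at missing landmarks are set to `NA`.
#' @return Object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords, missing = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (is.null(missing)) missing <- rep(FALSE, nrow(coords))
  missing <- as.logical(missing)
  if (length(missing) != nrow(coords))
    stop("missing mask length must equal the landmark count")
  coords[missing, ] <- NA_real_
  structure(list(specimen_id = as.character(specimen_id),
                 coords = coords, missing = missing),
            class = "landmark_config")
}

#' Assemble a landmark dataset
#'
#' @param scheme a [landmark_scheme()].
#' @param configurations list of [landmark_config()] objects.
#' @param metadata optional data.frame of specimen metadata with a
#'   `specimen_id` column; when supplied its id set must match the
#'   configurations exactly.
#' @return Object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(scheme, configurations, metadata = NULL) {
  ids <- vapply(configurations, function(cf) cf$specimen_id, "")
  if (anyDuplicated(ids))
    stop("duplicate specimen_id: ", ids[duplicated(ids)][1])
  for (cf in configurations)
    if (nrow(cf$coords) != scheme$n_total)
      stop("specimen ", cf$specimen_id, " has ", nrow(cf$coords),
           " landmarks; scheme expects ", scheme$n_total)
  names(configurations) <- ids
  if (!is.null(metadata)) {
    if (!"specimen_id" %in% names(metadata))
      stop("metadata must have a specimen_id column")
    if (anyDuplicated(metadata$specimen_id))
      stop("duplicate metadata row for specimen ",
           metadata$specimen_id[duplicated(metadata$specimen_id)][1])
    if (!setequal(metadata$specimen_id, ids))
      stop("metadata and configuration specimen_id sets differ")
    metadata <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(scheme = scheme, configurations = configurations,
                 metadata = metadata),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", length(x$configurations), "specimens x",
      x$scheme$n_total, "landmarks\n")
  nmiss <- sum(vapply(x$configurations, function(cf) any(cf$missing), TRUE))
  cat(nmiss, "specimen(s) with missing landmarks\n")
  invisible(x)
}

# Sentinel used by landmark digitising software for missing landmarks.
MISSING_SENTINEL <- -9999

#' Read a landmark coordinate table
#'
#' Accepts the long form (`specimen_id,landmark,x,y,z`, one row per
#' specimen-landmark) or, auto-detected from the header, the wide form
#' (`specimen_id,x1,y1,z1,...`).  Any coordinate equal to the missing
#' sentinel (-9999) marks the whole landmark as missing; a landmark with
#' only some sentinel coordinates is treated as wholly missing, with a
#' warning.
#'
#' @param path path to a delimited text file.
#' @param scheme a [landmark_scheme()] the data must conform to.
#' @param metadata optional metadata data.frame (see [landmark_dataset()]).
#' @return A [landmark_dataset()].
#' @export
read_landmark_table <- function(path, scheme, metadata = NULL) {
  header <- gsub('"', "", strsplit(readLines(path, n = 1), ",")[[1]])
  long <- all(c("landmark", "x", "y", "z") %in% header)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no specimens in ", path)
  if (!long) tab <- wide_to_long(tab, scheme$n_total)
  check_numeric_cols(tab, path)
  configs <- lapply(split(tab, tab$specimen_id), function(rows) {
    id <- rows$specimen_id[1]
    if (anyDuplicated(rows$landmark))
      stop("duplicate row for (", id, ", landmark ",
           rows$landmark[duplicated(rows$landmark)][1], ")")
    if (nrow(rows) != scheme$n_total)
      stop("specimen ", id, " has ", nrow(rows),
           " landmark rows; expected ", scheme$n_total)
    rows <- rows[order(rows$landmark), ]
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    sent <- xyz == MISSING_SENTINEL
    miss <- apply(sent, 1, any)
    if (any(miss & !apply(sent, 1, all)))
      warning("specimen ", id, ": landmark(s) with a partial -9999 ",
              "sentinel treated as wholly missing")
    landmark_config(id, xyz, miss)
  })
  # preserve file order of first appearance
  configs <- configs[unique(tab$specimen_id)]
  landmark_dataset(scheme, configs, metadata)
}

wide_to_long <- function(tab, n_total) {
  if (!"specimen_id" %in% names(tab))
    stop("landmark table must have a specimen_id column")
  coord_cols <- paste0(rep(c("x", "y", "z"), n_total),
                       rep(seq_len(n_total), each = 3))
  if (!all(coord_cols %in% names(tab)))
    stop("wide-form table lacks coordinate columns up to landmark ", n_total)
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(specimen_id = tab$specimen_id[i],
               landmark = seq_len(n_total),
               x = as.numeric(tab[i, paste0("x", seq_len(n_total))]),
               y = as.numeric(tab[i, paste0("y", seq_len(n_total))]),
               z = as.numeric(tab[i, paste0("z", seq_len(n_total))]))
  }))
}

check_numeric_cols <- function(tab, path) {
  for (cc in c("x", "y", "z")) {
    v <- tab[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("unreadable numeric in column ", cc, " of ", path,
           " at data line ", bad)
    }
  }
}

#' Write a landmark dataset as a long coordinate table
#'
#' Missing landmarks are written with the -9999 sentinel, so
#' write-then-read is the identity for coordinates and masks.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(dataset, path) {
  rows <- lapply(dataset$configurations, function(cf) {
    xyz <- cf$coords
    xyz[cf$missing, ] <- MISSING_SENTINEL
    data.frame(specimen_id = cf$specimen_id,
               landmark = seq_len(nrow(xyz)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Expected columns: `specimen_id`, `species`, `family`, `group` (one of
#' archaeocete/odontocete/mysticete/terrestrial) and, optionally,
#' `geologic_age`, `echo_presence`, `echo_frequency`, `regime`,
#' `regime_split`, `fossil`.
#'
#' @param path CSV path.
#' @return data.frame of metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "family", "group")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  groups <- c("archaeocete", "odontocete", "mysticete", "terrestrial")
  bad <- setdiff(unique(md$group), groups)
  if (length(bad))
    stop("unknown group value(s): ", paste(bad, collapse = ", "))
  md
}

#' Validate a landmark dataset and summarise missingness
#'
#' Reports, per specimen, the number and fraction of missing landmarks, and
#' dataset-wide the fraction of specimens with at least one missing
#' landmark.  Specimens whose missing fraction exceeds `flag_threshold` are
#' flagged (never dropped).
#'
#' @param dataset a [landmark_dataset()].
#' @param flag_threshold missing-landmark fraction above which a specimen is
#'   flagged (default 0.2).
#' @return A list of class `validation_report`: `per_specimen` data.frame
#'   (`specimen_id`, `n_missing`, `missing_fraction`, `flagged`),
#'   `fraction_with_missing`, `n_specimens`, `flag_threshold`.
#' @export
validate_dataset <- function(dataset, flag_threshold = 0.2) {
  n <- dataset$scheme$n_total
  per <- do.call(rbind, lapply(dataset$configurations, function(cf) {
    k <- sum(cf$missing)
    data.frame(specimen_id = cf$specimen_id, n_missing = k,
               missing_fraction = k / n)
  }))
  rownames(per) <- NULL
  per$flagged <- per$missing_fraction > flag_threshold
  structure(list(per_specimen = per,
                 fraction_with_missing = mean(per$n_missing > 0),
                 n_specimens = nrow(per),
                 flag_threshold = flag_threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation:", x$n_specimens, "specimens;",
      sprintf("%.1f%%", 100 * x$fraction_with_missing),
      "with >=1 missing landmark;",
      sum(x$per_specimen$flagged), "flagged (threshold",
      x$flag_threshold, ")\n")
  invisible(x)
}
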
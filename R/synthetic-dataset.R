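#' Generate a complete synthetic skull dataset with metadata
#'
#' Emulates the structure of a museum-scan cranial dataset: one specimen
#' per species, each a copy of the symmetric skull template with
#' group-dependent planted asymmetry, digitising noise, and (optionally)
#' missing landmarks concentrated in fragile regions.
#'
#' Groups and their planted asymmetry (chosen once to emulate the stated
#' world: baseline specimen sums around 0.15-0.2, the most asymmetric
#' odontocetes above 0.4):
#' \itemize{
#' \item odontocetes: posterior-sinistral displacement of the right nasal,
#'   premaxilla and maxilla landmarks, magnitude graded 1.5-4.5 mm; the
#'   three most asymmetric families (monodontids, physeteroids,
#'   platanistids) take 5.5-8.5 mm and form "regime4";
#' \item archaeocetes: rostral displacement 1.5-3 mm;
#' \item mysticetes and terrestrial artiodactyls: no planted displacement
#'   (noise only).
#' }
#'
#' @param n_odontocete,n_mysticete,n_archaeocete,n_terrestrial group sizes
#'   (defaults 120, 32, 10, 10, i.e. 172 specimens).
#' @param centroid_size template centroid size in mm (default 500).
#' @param noise_sd digitising noise SD in mm (default 0.1% of centroid
#'   size).
#' @param missing_fraction fraction of specimens degraded with missing
#'   landmarks (default 0 = complete; the museum value is ~0.39).
#' @param seed integer seed.
#' @return a [landmark_dataset()] with full metadata columns (`species`,
#'   `family`, `group`, `geologic_age`, `fossil`, `echo_presence`,
#'   `echo_frequency`, `regime`, `regime_split`) and
#'   `attr(, "planted_delta")` recording each specimen's displacement (mm).
#' @export
make_synthetic_dataset <- function(n_odontocete = 120L, n_mysticete = 32L,
                                   n_archaeocete = 10L, n_terrestrial = 10L,
                                   centroid_size = 500, noise_sd = 0.5,
                                   missing_fraction = 0, seed = 1L) {
  tmpl <- make_template(centroid_size = centroid_size, seed = seed)
  old <- local_seed(seed + 1L)
  on.exit(restore_seed(old))
  groups <- rep(c("odontocete", "mysticete", "archaeocete", "terrestrial"),
                c(n_odontocete, n_mysticete, n_archaeocete, n_terrestrial))
  n <- length(groups)
  ids <- sprintf("spec%03d", seq_len(n))
  species <- sprintf("%s_sp%03d", substr(groups, 1, 4), seq_len(n))

  # odontocete families: first 12 specimens go to the highly asymmetric
  # clades (regime4), the rest to ordinary delphinoid-like families
  fam <- character(n)
  od <- which(groups == "odontocete")
  special <- rep(c("Monodontidae", "Physeteridae", "Platanistidae"),
                 length.out = min(12L, length(od)))
  fam[od] <- c(special, sample(c("Delphinidae", "Phocoenidae", "Ziphiidae",
                                 "Iniidae", "Kentriodontidae"),
                               max(0L, length(od) - length(special)),
                               replace = TRUE))
  fam[groups == "mysticete"] <-
    sample(c("Balaenopteridae", "Balaenidae", "Aetiocetidae"),
           n_mysticete, replace = TRUE)
  fam[groups == "archaeocete"] <-
    sample(c("Basilosauridae", "Protocetidae", "Pakicetidae"),
           n_archaeocete, replace = TRUE)
  fam[groups == "terrestrial"] <- "Bovidae"

  # magnitudes chosen so specimen sums span ~0.14-0.55 Procrustes units at
  # the default noise level (23 nasofacial landmarks move per odontocete,
  # 12 rostral pairs per archaeocete, centroid size 500 mm)
  delta <- numeric(n)
  delta[od] <- stats::runif(length(od), 1.5, 4.5)
  delta[od[seq_along(special)]] <- stats::runif(length(special), 5.5, 8.5)
  ar <- which(groups == "archaeocete")
  delta[ar] <- stats::runif(length(ar), 1.5, 3)

  fossil <- groups == "archaeocete" |
    (groups != "terrestrial" & stats::runif(n) < 0.4)
  age <- ifelse(groups == "archaeocete", "Eocene",
                ifelse(fossil, sample(c("Oligocene", "Miocene"), n, TRUE),
                       "extant"))
  echo_presence <- ifelse(groups == "odontocete", "Band3",
                          ifelse(groups == "archaeocete", "Band1", "Band0"))
  echo_frequency <- ifelse(groups != "odontocete", "low-frequency",
    ifelse(fam == "Monodontidae", "NBS",
    ifelse(fam == "Physeteridae", "sperm-whale",
    ifelse(fam == "Platanistidae", "BBLF",
    ifelse(fam == "Ziphiidae", "FM-buzz",
    ifelse(fam == "Phocoenidae", "NBHF", "BBLF"))))))
  regime <- ifelse(groups == "archaeocete", "regime1",
            ifelse(groups == "mysticete", "regime2",
            ifelse(groups == "terrestrial", "outgroup",
            ifelse(fam %in% c("Monodontidae", "Physeteridae",
                              "Platanistidae"), "regime4", "regime3"))))
  regime_split <- regime
  regime_split[fam == "Monodontidae"] <- "regime4a"
  regime_split[fam == "Physeteridae"] <- "regime4b"
  regime_split[fam == "Platanistidae"] <- "regime4c"

  configs <- lapply(seq_len(n), function(i) {
    cf <- tmpl$config
    cf$specimen_id <- ids[i]
    if (delta[i] > 0) {
      region <- if (groups[i] == "archaeocete") "rostrum"
                else c("nasal", "premaxilla", "maxilla")
      cf <- apply_asymmetry(cf, tmpl$scheme, region, delta[i],
                            direction = c(1, 1, 0), side = "right")
    }
    cf
  })
  md <- data.frame(specimen_id = ids, species = species, family = fam,
                   group = groups, geologic_age = age, fossil = fossil,
                   echo_presence = echo_presence,
                   echo_frequency = echo_frequency,
                   regime = regime, regime_split = regime_split)
  ds <- landmark_dataset(tmpl$scheme, configs, md)
  ds <- degrade(ds, specimen_missing_fraction = missing_fraction,
                landmark_missing_rate = 0.02, noise_sd = noise_sd,
                seed = seed + 2L)
  attr(ds, "planted_delta") <- stats::setNames(delta, ids)
  ds
}
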
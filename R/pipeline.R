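#' Read a flat pipeline configuration file
#'
#' Minimal `key: value` format (one pair per line, `#` comments); values
#' are parsed as logical, numeric, or comma-separated character lists.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parsed <- if (val %in% c("true", "TRUE", "yes")) TRUE
      else if (val %in% c("false", "FALSE", "no")) FALSE
      else if (grepl(",", val)) trimws(strsplit(val, ",")[[1]])
      else if (!is.na(suppressWarnings(as.numeric(val)))) as.numeric(val)
      else val
    out[[key]] <- parsed
  }
  out
}

# map scenario labels onto metadata columns
SCENARIO_COLUMNS <- c(ancestral = "group", regime = "regime",
                      "regime-split" = "regime_split",
                      echo = "echo_presence", "echo-freq" = "echo_frequency",
                      age = "geologic_age", suborder = "group")

pipeline_defaults <- function() {
  list(seed = 1, outdir = "pipeline_out",
       scenarios = c("regime", "regime-split", "echo-freq", "age",
                     "suborder", "echo"),
       fit_scenarios = c("regime", "regime-split"),
       model_classes = c("BM", "OU", "BMM", "OUM"),
       mcmc_model = "jump-rbm", mcmc_ngen = 2e4, mcmc_thin = 200,
       mcmc_chains = 1, drop_outgroup = TRUE)
}

#' Run the full asymmetry pipeline
#'
#' Stages: `quantify` (missing-landmark completion, mirroring, GPA, radii,
#' summaries, PCA), `fit` (multi-regime BM/OU model ranking per scenario),
#' `mcmc` (relaxed-BM rjMCMC with shifts/jumps and diagnostics), `anova`
#' (lambda-GLS phylogenetic ANOVA with Benjamini-Hochberg control).  Each
#' stage reads only prior-stage outputs; identical config and seed give an
#' identical output bundle.  A run manifest (config snapshot, timings,
#' warnings, file checksums) is written even on partial failure.
#'
#' @param config named list (or path to a [read_config()] file).  Either
#'   `synthetic: true` (with optional `n_specimens`, `missing_fraction`)
#'   or the input paths `landmarks`, `scheme`, `metadata`, `tree`.  See
#'   `pipeline_defaults()` in the source for tunables and their defaults;
#'   `mcmc_ngen`/`mcmc_thin` default to a desk-scale 2e4/200 (the
#'   full-scale analysis uses 1e6/1e4).
#' @param stages which stages to run (default all, in order).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("quantify", "fit", "mcmc", "anova")) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(pipeline_defaults(), config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config,
                   version = as.character(utils::packageVersion("cetasym")),
                   stages = list(), warnings = character(0),
                   failure = NULL)
  results <- list()
  warn_collect <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  finish <- function() {
    files <- list.files(outdir, full.names = TRUE)
    files <- files[!grepl("manifest[.]json$", files)]
    manifest$files <<- data.frame(
      file = basename(files),
      md5 = as.character(tools::md5sum(files)), row.names = NULL)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ warn_collect(fun()); TRUE },
                   error = function(e) {
                     manifest$failure <<- list(stage = name,
                                               message = conditionMessage(e))
                     FALSE
                   })
    manifest$stages[[name]] <<-
      list(seconds = round(proc.time()[["elapsed"]] - t0, 3), ok = ok)
    if (!ok) { finish(); stop("stage '", name, "' failed: ",
                              manifest$failure$message, call. = FALSE) }
  }

  # ---- inputs ----
  synthetic <- isTRUE(config$synthetic)
  if (!synthetic) {
    for (key in c("landmarks", "scheme", "metadata", "tree"))
      if (is.null(config[[key]]))
        stop("config missing '", key, "'")
    for (key in c("landmarks", "scheme", "metadata", "tree"))
      if (!file.exists(config[[key]]))
        stop("config input '", key, "' not found: ", config[[key]])
  }
  seed <- as.integer(config$seed)

  if (synthetic) {
    nspec <- config$n_specimens %||% 60
    per <- c(odo = round(0.7 * nspec), mys = round(0.18 * nspec),
             arch = round(0.06 * nspec))
    dataset <- make_synthetic_dataset(
      n_odontocete = per[["odo"]], n_mysticete = per[["mys"]],
      n_archaeocete = per[["arch"]],
      n_terrestrial = nspec - sum(per),
      missing_fraction = config$missing_fraction %||% 0.2, seed = seed)
  } else {
    scheme <- read_scheme(config$scheme)
    dataset <- read_landmark_table(config$landmarks, scheme,
                                   read_metadata(config$metadata))
  }
  if (!is.null(config$drop_specimens))
    dataset <- subset_dataset(dataset,
                              setdiff(names(dataset$configurations),
                                      config$drop_specimens))
  if (isTRUE(config$no_rostrum)) dataset <- drop_region(dataset, "rostrum")
  if (isTRUE(config$no_fossils) && !is.null(dataset$metadata$fossil))
    dataset <- subset_dataset(
      dataset, dataset$metadata$specimen_id[!dataset$metadata$fossil])

  # ---- quantify ----
  if ("quantify" %in% stages) run_stage("quantify", function() {
    res <- quantify_asymmetry(dataset)
    results$asymmetry <<- res
    utils::write.csv(res$radii, file.path(outdir, "radii.csv"),
                     row.names = FALSE)
    summ <- merge(res$sums, dataset$metadata, by = "specimen_id",
                  sort = FALSE)
    utils::write.csv(summ, file.path(outdir, "asymmetry_summary.csv"),
                     row.names = FALSE)
    gs <- group_summary(res)
    utils::write.csv(gs$group_means, file.path(outdir, "group_summary.csv"),
                     row.names = FALSE)
    pc <- asym_pca(res)
    utils::write.csv(data.frame(specimen_id = rownames(pc$scores),
                                pc$scores[, 1:min(5, ncol(pc$scores))]),
                     file.path(outdir, "pca_scores.csv"), row.names = FALSE)
  })

  # ---- species-level trait + tree ----
  need_tree <- any(c("fit", "mcmc", "anova") %in% stages)
  tree <- NULL; trait <- NULL; md_sp <- NULL
  if (need_tree) run_stage("prepare_tree", function() {
    res <- results$asymmetry %||% quantify_asymmetry(dataset)
    results$asymmetry <<- res
    md <- dataset$metadata
    keep <- if (isTRUE(config$drop_outgroup))
      md$specimen_id[md$group != "terrestrial"] else md$specimen_id
    sums <- res$sums[res$sums$specimen_id %in% keep, ]
    sp <- md$species[match(sums$specimen_id, md$specimen_id)]
    trait <<- tapply(sums$sum_rho, sp, mean)
    md_sp <<- md[match(names(trait), md$species), ]
    tr <- if (synthetic)
      simulate_tree(length(trait), seed = seed + 10L,
                    fossil_tips = round(0.3 * length(trait)))
    else read_tree(config$tree)
    if (synthetic) tr$tip.label <- names(trait)
    common <- intersect(tr$tip.label, names(trait))
    if (length(common) < 3) stop("fewer than 3 taxa shared by tree and data")
    tr <- prune_to_taxa(tr, common)
    if (length(config$matrix_taxa))
      tr <- prune_to_taxa(tr, intersect(common, config$matrix_taxa))
    tree <<- resolve_polytomies(tr)
    trait <<- trait[tree$tip.label]
    md_sp <<- md_sp[match(tree$tip.label, md_sp$species), ]
  })

  scenario_factor <- function(sc) {
    col <- SCENARIO_COLUMNS[[sc]]
    if (is.null(col) || !col %in% names(md_sp))
      stop("unknown scenario or missing metadata column for: ", sc)
    stats::setNames(as.character(md_sp[[col]]), md_sp$species)
  }

  # ---- fit ----
  if ("fit" %in% stages) run_stage("fit", function() {
    fits <- list()
    for (cl in intersect(config$model_classes, c("BM", "BMtr", "OU")))
      fits[[cl]] <- fit_model(cl, tree, trait, scenario = "ancestral")
    for (sc in config$fit_scenarios) {
      pk <- paint_regimes(tree, tip_states = scenario_factor(sc))
      for (cl in intersect(config$model_classes,
                           c("BMM", "BMMtr", "BMMsm", "OUM")))
        fits[[paste0(cl, "-", sc)]] <-
          fit_model(cl, tree, trait, painting = pk, scenario = sc)
    }
    ranking <- rank_models(fits)
    results$ranking <<- ranking
    utils::write.csv(ranking, file.path(outdir, "model_ranking.csv"),
                     row.names = FALSE)
  })

  # ---- mcmc ----
  if ("mcmc" %in% stages) run_stage("mcmc", function() {
    chains <- lapply(seq_len(config$mcmc_chains), function(i)
      run_rjmcmc(tree, trait, n_gen = config$mcmc_ngen,
                 thin = config$mcmc_thin, model = config$mcmc_model,
                 seed = seed + 100L + i))
    results$mcmc <<- chains
    sh <- summarize_shifts(chains[[1]])
    utils::write.csv(sh$table, file.path(outdir, "shifts.csv"),
                     row.names = FALSE)
    jm <- summarize_jumps(chains[[1]])
    if (!is.null(jm$table))
      utils::write.csv(jm$table, file.path(outdir, "jumps.csv"),
                       row.names = FALSE)
    dg <- mcmc_diagnostics(chains, psrf = length(chains) >= 2)
    jsonlite::write_json(
      list(ess = as.data.frame(dg$ess), psrf = as.list(dg$psrf),
           retained = sh$n_retained),
      file.path(outdir, "diagnostics.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  })

  # ---- anova ----
  if ("anova" %in% stages) run_stage("anova", function() {
    usable <- Filter(function(sc) {
      f <- scenario_factor(sc)
      length(unique(f)) >= 2
    }, config$scenarios)
    tab <- run_phylo_anova(trait, stats::setNames(
      lapply(usable, scenario_factor), usable), tree)
    results$anova <<- tab
    utils::write.csv(tab, file.path(outdir, "anova.csv"), row.names = FALSE)
  })

  finish()
  invisible(list(results = results, manifest = manifest))
}

# keep a subset of specimens (configurations + metadata rows)
subset_dataset <- function(dataset, ids) {
  landmark_dataset(dataset$scheme, dataset$configurations[ids],
                   dataset$metadata[dataset$metadata$specimen_id %in% ids, ,
                                    drop = FALSE])
}

#' Sensitivity re-run of the model ranking
#'
#' Re-runs the pipeline under one modification -- `no-rostrum` (rostral
#' landmarks removed), `no-fossils` (fossil specimens removed), or
#' `matrix-tree` (tree pruned to `config$matrix_taxa`) -- and compares the
#' AIC ordering of the fitted models against the base run.
#'
#' @param config pipeline config (list or path).
#' @param mode one of `"no-rostrum"`, `"no-fossils"`, `"matrix-tree"`.
#' @return list: `base`, `modified` (ranking data.frames),
#'   `ordering_preserved` (logical).
#' @export
sensitivity <- function(config,
                        mode = c("no-rostrum", "no-fossils",
                                 "matrix-tree")) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(pipeline_defaults(), config)
  base_cfg <- config
  base_cfg$outdir <- file.path(config$outdir, "base")
  alt_cfg <- config
  alt_cfg$outdir <- file.path(config$outdir, mode)
  if (mode == "no-rostrum") alt_cfg$no_rostrum <- TRUE
  if (mode == "no-fossils") alt_cfg$no_fossils <- TRUE
  if (mode == "matrix-tree" && is.null(alt_cfg$matrix_taxa))
    alt_cfg$matrix_taxa <- character(0)   # empty -> all taxa, identity run
  stages <- c("quantify", "fit")
  base <- run_pipeline(base_cfg, stages = stages)$results$ranking
  alt <- run_pipeline(alt_cfg, stages = stages)$results$ranking
  common <- intersect(base$model, alt$model)
  list(base = base, modified = alt,
       ordering_preserved = identical(base$model[base$model %in% common],
                                      alt$model[alt$model %in% common]))
}
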
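# Config-driven orchestration of the full analysis chain on a synthetic
# landscape: simulate -> screen -> fit -> evaluate -> project -> overlap ->
# risk -> disperse -> demography -> report. Every stage reads and writes
# only plain-text formats (ASCII grids, delimited text), so stages are
# independently re-runnable; a manifest of content hashes makes runs
# comparable.

#' Default pipeline configuration
#'
#' A complete, validated configuration for the synthetic study: a 60x60
#' landscape with 6 predictors (two driving the invader, one extra driving
#' the crop, one redundant pair exercising the collinearity screen), 150
#' invader and 200 crop occurrences, a forest land-cover map, a 4-period
#' drifting future series, and 16 demography sites.
#'
#' @param seed Global seed; per-stage sub-seeds are derived by stable
#'   hashing of stage names, so stage randomness is order-independent.
#' @param out_dir Output directory for all artifacts.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, out_dir = "pipeline_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      nrows = 60L, ncols = 60L, n_vars = 6L, smoothing_radius = 3L,
      redundant_source = "env5", redundant_copy = "env6",
      n_snail = 150L, n_crop = 200L, forest_fraction = 0.6,
      drift_layer = "env1", drift = 0.15, periods = 4L,
      n_sites = 16L, demog_effect = 10, demog_noise_sd = 2,
      snail_linear = c(env1 = 4, env2 = -3),
      snail_intercept = -7,
      crop_linear = c(env1 = 2, env3 = 1.5),
      crop_intercept = -0.5),
    screen = list(threshold = 0.7, sample_n = 10000L),
    fit = list(reg_beta = 1.0, n_background = 2000L,
               feature_types = c("linear", "quadratic", "product")),
    evaluate = list(n_replicates = 5L, test_fraction = 0.3),
    overlap = list(),
    risk = list(high_threshold = 0.5, band_width = 1),
    disperse = list(rcThreshold = 600, encChgSteps = 4L, dispSteps = 20L,
                    iniMatAge = 1L, propagule_prod = 1.0, lddFreq = 0.05,
                    lddMinDist = 2L, lddMaxDist = 0L, replicates = 5L),
    demography = list(group_a = c(2, 3), group_b = c(0, 1)),
    report = list()),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @param seed,out_dir Defaults used where the file does not set them.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path, seed = 1L, out_dir = "pipeline_out") {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config(seed, out_dir))
  merge_into <- function(base, over, prefix = "") {
    for (k in names(over)) {
      full <- paste0(prefix, k)
      if (!k %in% names(base))
        stop("unknown config key: ", full, call. = FALSE)
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_into(base[[k]], over[[k]], paste0(full, "."))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  structure(merge_into(cfg, user), class = "pipeline_config")
}

# Stable per-stage sub-seed: polynomial hash of the stage name folded with
# the global seed, kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1009001
  as.integer((as.numeric(seed) * 7919 + h * 31 + 17) %% 2147483629)
}

pipe_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_artifacts <- function(cfg, files, producer) {
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L)
    stop("missing artifact(s) ", paste(basename(missing), collapse = ", "),
         ": run stage '", producer, "' first", call. = FALSE)
  invisible(TRUE)
}

read_stack_dir <- function(dir, layer_names) {
  layers <- lapply(layer_names, function(nm)
    read_ascii_grid(file.path(dir, paste0(nm, ".asc"))))
  names(layers) <- layer_names
  egridstack(layers)
}

# ---- individual stages -----------------------------------------------------

stage_simulate <- function(cfg) {
  sc <- cfg$simulate
  dir.create(pipe_path(cfg, "simulate", "future"), recursive = TRUE,
             showWarnings = FALSE)
  mix <- diag(sc$n_vars)
  vars <- paste0("env", seq_len(sc$n_vars))
  i <- match(sc$redundant_copy, vars)
  j <- match(sc$redundant_source, vars)
  mix[i, ] <- 0; mix[i, j] <- 1; mix[i, i] <- 0.2  # near-duplicate layer
  spec <- landscape_spec(sc$nrows, sc$ncols, sc$n_vars,
                         sc$smoothing_radius, mixing = mix,
                         seed = stage_seed(cfg$seed, "simulate"))
  stack <- gen_env_stack(spec, names = vars)
  for (nm in vars)
    write_ascii_grid(stack$layers[[nm]],
                     pipe_path(cfg, "simulate", paste0(nm, ".asc")))

  truth_sn <- truth_model(sc$snail_linear, intercept = sc$snail_intercept)
  truth_cr <- truth_model(sc$crop_linear, intercept = sc$crop_intercept)
  surf_sn <- true_suitability(stack, truth_sn)
  surf_cr <- true_suitability(stack, truth_cr)
  write_ascii_grid(surf_sn, pipe_path(cfg, "simulate", "truth_snail.asc"))
  write_ascii_grid(surf_cr, pipe_path(cfg, "simulate", "truth_crop.asc"))

  occ_sn <- sample_occurrences(surf_sn, sc$n_snail,
                               seed = stage_seed(cfg$seed, "occ_snail"),
                               species = "snail")
  occ_cr <- sample_occurrences(surf_cr, sc$n_crop,
                               seed = stage_seed(cfg$seed, "occ_crop"),
                               species = "crop")
  write_occurrences(occ_sn, pipe_path(cfg, "simulate", "occ_snail.csv"))
  write_occurrences(occ_cr, pipe_path(cfg, "simulate", "occ_crop.csv"))

  lc <- gen_landcover(spec, sc$forest_fraction)
  write_ascii_grid(lc, pipe_path(cfg, "simulate", "landcover.asc"))

  trends <- stats::setNames(sc$drift, sc$drift_layer)
  future <- gen_future_series(stack, trends, sc$periods)
  for (k in seq_along(future))
    for (nm in vars)
      write_ascii_grid(future[[k]]$layers[[nm]],
                       pipe_path(cfg, "simulate", "future",
                                 sprintf("%s_p%d.asc", nm, k)))

  # site design stratified across the suitability range, as field surveys
  # place demography plots in every habitat class
  ref <- stack_ref(stack)
  ok <- which(!is.na(ref$values))
  strata <- seq(0.125, 0.875, length.out = 4)
  per <- ceiling(sc$n_sites / 4)
  cells <- integer(0)
  for (s in strata) {
    cand <- setdiff(ok[order(abs(surf_sn$values[ok] - s))], cells)
    cells <- c(cells, cand[seq_len(per)])
  }
  cells <- cells[seq_len(sc$n_sites)]
  nr <- nrow(ref$values)
  sites <- data.frame(
    site_id = paste0("site", seq_len(sc$n_sites)),
    lon = ref$xmin + (((cells - 1L) %/% nr)) * ref$cell_size +
      0.5 * ref$cell_size,
    lat = ref$ymax - (((cells - 1L) %% nr)) * ref$cell_size -
      0.5 * ref$cell_size)
  demog <- gen_demography(sites, surf_sn, effect = sc$demog_effect,
                          noise_sd = sc$demog_noise_sd,
                          seed = stage_seed(cfg$seed, "demography_data"))
  utils::write.csv(demog, pipe_path(cfg, "simulate", "sites.csv"),
                   row.names = FALSE)
  writeLines(vars, pipe_path(cfg, "simulate", "layers.txt"))
  invisible(NULL)
}

stage_screen <- function(cfg) {
  sim <- pipe_path(cfg, "simulate")
  require_artifacts(cfg, file.path(sim, "layers.txt"), "simulate")
  dir.create(pipe_path(cfg, "screen"), recursive = TRUE, showWarnings = FALSE)
  vars <- readLines(file.path(sim, "layers.txt"))
  stack <- read_stack_dir(sim, vars)
  corr <- corr_matrix(stack, cfg$screen$sample_n,
                      seed = stage_seed(cfg$seed, "screen"))
  res <- prune_correlated(corr, cfg$screen$threshold, priority = vars)
  write_screen_report(res, pipe_path(cfg, "screen", "corr.csv"),
                      pipe_path(cfg, "screen", "screen_report.csv"))
  writeLines(res$retained, pipe_path(cfg, "screen", "retained.txt"))
  invisible(NULL)
}

fit_one_species <- function(cfg, species, stack) {
  occ <- read_occurrences(pipe_path(cfg, "simulate",
                                    paste0("occ_", species, ".csv")))
  bg <- sample_background(stack,
                          min(cfg$fit$n_background,
                              sum(!is.na(stack_ref(stack)$values))),
                          seed = stage_seed(cfg$seed, paste0("bg_", species)))
  model <- fit_maxent(occ, bg, stack,
                      feature_spec(cfg$fit$feature_types),
                      reg_beta = cfg$fit$reg_beta)
  list(model = model, occ = occ)
}

stage_fit <- function(cfg) {
  require_artifacts(cfg, pipe_path(cfg, "screen", "retained.txt"), "screen")
  dir.create(pipe_path(cfg, "fit"), recursive = TRUE, showWarnings = FALSE)
  retained <- readLines(pipe_path(cfg, "screen", "retained.txt"))
  stack <- read_stack_dir(pipe_path(cfg, "simulate"), retained)
  for (sp in c("snail", "crop")) {
    f <- fit_one_species(cfg, sp, stack)
    write_lambdas(f$model, pipe_path(cfg, "fit", paste0("lambdas_", sp, ".txt")))
    pred <- predict(f$model, stack, output = "logistic")
    write_ascii_grid(pred, pipe_path(cfg, "fit",
                                     paste0("suitability_", sp, ".asc")))
    utils::write.csv(percent_contribution(f$model),
                     pipe_path(cfg, "fit", paste0("contribution_", sp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(
      permutation_importance(f$model, stack,
                             seed = stage_seed(cfg$seed, paste0("perm_", sp))),
      pipe_path(cfg, "fit", paste0("importance_", sp, ".csv")),
      row.names = FALSE)
  }
  invisible(NULL)
}

stage_evaluate <- function(cfg) {
  require_artifacts(cfg, pipe_path(cfg, "screen", "retained.txt"), "screen")
  dir.create(pipe_path(cfg, "evaluate"), recursive = TRUE,
             showWarnings = FALSE)
  retained <- readLines(pipe_path(cfg, "screen", "retained.txt"))
  stack <- read_stack_dir(pipe_path(cfg, "simulate"), retained)
  mtss <- numeric(0)
  for (sp in c("snail", "crop")) {
    occ <- read_occurrences(pipe_path(cfg, "simulate",
                                      paste0("occ_", sp, ".csv")))
    ev <- replicate_evaluate(
      occ, stack, feature_spec(cfg$fit$feature_types),
      reg_beta = cfg$fit$reg_beta,
      n_replicates = cfg$evaluate$n_replicates,
      test_fraction = cfg$evaluate$test_fraction,
      n_background = cfg$fit$n_background,
      seed = stage_seed(cfg$seed, paste0("eval_", sp)))
    utils::write.csv(ev$replicates,
                     pipe_path(cfg, "evaluate", paste0("replicates_", sp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ev$summary,
                     pipe_path(cfg, "evaluate", paste0("summary_", sp, ".csv")),
                     row.names = FALSE)
    mtss[sp] <- ev$summary$mean[ev$summary$statistic == "mtss_threshold"]
  }
  utils::write.csv(data.frame(species = names(mtss), mtss = unname(mtss)),
                   pipe_path(cfg, "evaluate", "mtss.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_project <- function(cfg) {
  require_artifacts(cfg, pipe_path(cfg, "fit", "lambdas_snail.txt"), "fit")
  dir.create(pipe_path(cfg, "project"), recursive = TRUE,
             showWarnings = FALSE)
  retained <- readLines(pipe_path(cfg, "screen", "retained.txt"))
  stack <- read_stack_dir(pipe_path(cfg, "simulate"), retained)
  periods <- cfg$simulate$periods
  for (sp in c("snail", "crop")) {
    f <- fit_one_species(cfg, sp, stack)  # deterministic refit from artifacts
    for (k in seq_len(periods)) {
      layers <- lapply(retained, function(nm)
        read_ascii_grid(pipe_path(cfg, "simulate", "future",
                                  sprintf("%s_p%d.asc", nm, k))))
      names(layers) <- retained
      fut <- egridstack(layers)
      pred <- predict(f$model, fut, output = "logistic")
      write_ascii_grid(pred, pipe_path(cfg, "project",
                                       sprintf("suitability_%s_p%d.asc", sp, k)))
    }
  }
  invisible(NULL)
}

stage_overlap <- function(cfg) {
  require_artifacts(cfg, c(pipe_path(cfg, "fit", "suitability_snail.asc"),
                           pipe_path(cfg, "evaluate", "mtss.csv")),
                    "fit/evaluate")
  dir.create(pipe_path(cfg, "overlap"), recursive = TRUE,
             showWarnings = FALSE)
  mtss <- utils::read.csv(pipe_path(cfg, "evaluate", "mtss.csv"))
  thr <- stats::setNames(mtss$mtss, mtss$species)
  bin <- list()
  for (sp in c("snail", "crop")) {
    suit <- read_ascii_grid(pipe_path(cfg, "fit",
                                      paste0("suitability_", sp, ".asc")))
    bin[[sp]] <- binarize(suit, thr[[sp]])
    write_ascii_grid(bin[[sp]], pipe_path(cfg, "overlap",
                                          paste0("binary_", sp, ".asc")))
  }
  om <- overlap_map(bin$snail, bin$crop)
  write_ascii_grid(om, pipe_path(cfg, "overlap", "overlap.asc"))
  po <- proportional_overlap(bin$snail, bin$crop)
  utils::write.csv(data.frame(statistic = "proportional_overlap",
                              value = po),
                   pipe_path(cfg, "overlap", "proportional_overlap.csv"),
                   row.names = FALSE)
  utils::write.csv(latitude_band_counts(om, cfg$risk$band_width),
                   pipe_path(cfg, "overlap", "overlap_bands.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

stage_risk <- function(cfg) {
  require_artifacts(cfg, c(pipe_path(cfg, "overlap", "binary_crop.asc"),
                           pipe_path(cfg, "evaluate", "mtss.csv")),
                    "overlap")
  dir.create(pipe_path(cfg, "risk"), recursive = TRUE, showWarnings = FALSE)
  mtss <- utils::read.csv(pipe_path(cfg, "evaluate", "mtss.csv"))
  thr <- stats::setNames(mtss$mtss, mtss$species)
  crop_bin <- read_ascii_grid(pipe_path(cfg, "overlap", "binary_crop.asc"))
  suit_sn <- read_ascii_grid(pipe_path(cfg, "fit", "suitability_snail.asc"))
  occ_sn <- read_occurrences(pipe_path(cfg, "simulate", "occ_snail.csv"))
  lc <- read_ascii_grid(pipe_path(cfg, "simulate", "landcover.asc"))

  # invader categorical suitability restricted to crop-suitable cells
  cat_sn <- categorize(suit_sn, thr[["snail"]])
  cat_sn$values[is.na(crop_bin$values) | crop_bin$values != 1] <- NA_real_
  lcc <- landcover_component(lc, forest_classes = 1)
  lcc$values[is.na(cat_sn$values)] <- NA_real_
  dist_c <- proximity_component(crop_bin, occ_sn)
  risk <- invasion_risk(cat_sn, lcc, dist_c)
  write_ascii_grid(risk, pipe_path(cfg, "risk", "risk.asc"))
  utils::write.csv(risk_by_latitude(risk, cfg$risk$high_threshold,
                                    cfg$risk$band_width),
                   pipe_path(cfg, "risk", "risk_bands.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

stage_disperse <- function(cfg) {
  periods <- cfg$simulate$periods
  need <- c(pipe_path(cfg, "project",
                      sprintf("suitability_snail_p%d.asc", seq_len(periods))),
            pipe_path(cfg, "simulate", "landcover.asc"))
  require_artifacts(cfg, need, "project")
  dir.create(pipe_path(cfg, "disperse"), recursive = TRUE,
             showWarnings = FALSE)
  dc <- cfg$disperse
  params <- dispersal_params(
    rcThreshold = dc$rcThreshold, encChgSteps = dc$encChgSteps,
    dispSteps = dc$dispSteps, iniMatAge = dc$iniMatAge,
    propagule_prod = dc$propagule_prod, lddFreq = dc$lddFreq,
    lddMinDist = dc$lddMinDist, lddMaxDist = dc$lddMaxDist,
    replicates = dc$replicates, seed = stage_seed(cfg$seed, "disperse"))
  lc <- read_ascii_grid(pipe_path(cfg, "simulate", "landcover.asc"))
  barrier <- grid_like(lc, 1 - lc$values)  # forest (1) passable, rest barrier
  occ_sn <- read_occurrences(pipe_path(cfg, "simulate", "occ_snail.csv"))
  init_v <- matrix(0, nrow(lc$values), ncol(lc$values))
  init_v[cell_index_of_points(lc, occ_sn$lon, occ_sn$lat)] <- 1
  initial <- grid_like(lc, init_v)
  series <- lapply(seq_len(periods), function(k) {
    g <- read_ascii_grid(pipe_path(cfg, "project",
                                   sprintf("suitability_snail_p%d.asc", k)))
    grid_like(g, round(1000 * g$values))
  })
  mtss <- utils::read.csv(pipe_path(cfg, "evaluate", "mtss.csv"))
  thr_crop <- mtss$mtss[mtss$species == "crop"]
  crop_fut <- lapply(seq_len(periods), function(k)
    binarize(read_ascii_grid(pipe_path(cfg, "project",
                                       sprintf("suitability_crop_p%d.asc", k))),
             thr_crop))
  for (scen in c("unlimited", "none", "constrained")) {
    run <- run_dispersal(initial, barrier, series, params, scenario = scen)
    for (k in seq_len(periods))
      write_ascii_grid(run$occupancy[[k]],
                       pipe_path(cfg, "disperse",
                                 sprintf("occupancy_%s_p%d.asc", scen, k)))
    if (!is.null(run$history))
      utils::write.csv(run$history,
                       pipe_path(cfg, "disperse",
                                 sprintf("history_%s.csv", scen)),
                       row.names = FALSE)
    if (scen == "constrained") {
      fr <- future_risk_series(
        lapply(seq_len(periods), function(k)
          lapply(run$replicate_occupancy, function(rep) rep[[k]])),
        crop_fut)
      for (k in seq_len(periods))
        write_ascii_grid(fr[[k]],
                         pipe_path(cfg, "disperse",
                                   sprintf("future_risk_p%d.asc", k)))
    }
  }
  invisible(NULL)
}

stage_demography <- function(cfg) {
  require_artifacts(cfg, c(pipe_path(cfg, "simulate", "sites.csv"),
                           pipe_path(cfg, "fit", "suitability_snail.asc"),
                           pipe_path(cfg, "evaluate", "mtss.csv")),
                    "fit/evaluate")
  dir.create(pipe_path(cfg, "demography"), recursive = TRUE,
             showWarnings = FALSE)
  sites <- utils::read.csv(pipe_path(cfg, "simulate", "sites.csv"))
  suit <- read_ascii_grid(pipe_path(cfg, "fit", "suitability_snail.asc"))
  mtss <- utils::read.csv(pipe_path(cfg, "evaluate", "mtss.csv"))
  thr <- mtss$mtss[mtss$species == "snail"]
  rec <- assign_sites(sites, suit, thr)
  utils::write.csv(rec, pipe_path(cfg, "demography", "records.csv"),
                   row.names = FALSE)
  rows <- list()
  for (par in c("adults", "juveniles", "juv_per_adult")) {
    cmp <- tryCatch(
      compare_groups(rec, cfg$demography$group_a, cfg$demography$group_b,
                     par),
      error = function(e) NULL)
    if (!is.null(cmp))
      rows[[par]] <- data.frame(parameter = par, mean_high = cmp$mean_a,
                                mean_low = cmp$mean_b, t = cmp$t,
                                df = cmp$df, p = cmp$p,
                                n_excluded = cmp$n_excluded)
  }
  utils::write.csv(do.call(rbind, rows),
                   pipe_path(cfg, "demography", "comparisons.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

stage_report <- function(cfg) {
  dir.create(pipe_path(cfg, "report"), recursive = TRUE,
             showWarnings = FALSE)
  pick <- function(path) if (file.exists(path)) utils::read.csv(path) else NULL
  summ <- pick(pipe_path(cfg, "evaluate", "summary_snail.csv"))
  po <- pick(pipe_path(cfg, "overlap", "proportional_overlap.csv"))
  contrib <- pick(pipe_path(cfg, "fit", "contribution_snail.csv"))
  lines <- c("statistic,value")
  if (!is.null(summ))
    lines <- c(lines, sprintf("%s,%.6g", paste0("snail_", summ$statistic),
                              summ$mean))
  if (!is.null(po)) lines <- c(lines, sprintf("proportional_overlap,%.6g",
                                              po$value))
  writeLines(lines, pipe_path(cfg, "report", "summary.csv"))
  if (!is.null(contrib))
    utils::write.csv(contrib, pipe_path(cfg, "report", "contributions.csv"),
                     row.names = FALSE)
  invisible(NULL)
}

#' Run the pipeline
#'
#' Runs the requested stages in dependency order, snapshots the resolved
#' configuration next to the outputs, and returns a manifest of every
#' artifact with its MD5 content hash. Rerunning with an identical
#' configuration and seed reproduces identical hashes.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [read_config()]).
#' @param stages Character subset of
#'   `c("simulate","screen","fit","evaluate","project","overlap","risk",
#'   "disperse","demography","report")`; defaults to all, run in canonical
#'   order.
#' @return Invisibly, a data frame manifest (`artifact`, `md5`).
#' @export
run_pipeline <- function(config, stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "screen", "fit", "evaluate", "project",
                  "overlap", "risk", "disperse", "demography", "report")
  if (is.null(stages)) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  snapshot <- unclass(config)
  snapshot$out_dir <- NULL  # run location is metadata, not configuration
  yaml::write_yaml(snapshot,
                   file.path(config$out_dir, "resolved_config.yaml"))
  runners <- list(simulate = stage_simulate, screen = stage_screen,
                  fit = stage_fit, evaluate = stage_evaluate,
                  project = stage_project, overlap = stage_overlap,
                  risk = stage_risk, disperse = stage_disperse,
                  demography = stage_demography, report = stage_report)
  warnings_log <- character(0)
  for (st in stages) {
    t0 <- Sys.time()
    withCallingHandlers(
      runners[[st]](config),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    message(sprintf("[invasim] stage %-10s done in %.1fs", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  if (length(warnings_log) > 0L)
    writeLines(warnings_log, file.path(config$out_dir, "warnings.txt"))
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.csv$", files)]
  manifest <- data.frame(
    artifact = sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                    config$out_dir), "/?"), "", files),
    md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$artifact), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
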
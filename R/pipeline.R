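#' Assemble a pipeline run configuration
#'
#' Collects every knob of the pipeline in one place; all of the standard
#' numeric thresholds (35 GPS observations, 30 labeled days, 1 km/h
#' stationary speed, 20-cluster cap) are named keys with those defaults. A
#' configuration can also be loaded from a single YAML document with
#' [read_run_config()].
#'
#' @param simulate list of [cohort_config()] arguments (for the simulate
#'   stage), or `NULL` when ingesting real files.
#' @param min_days,min_gps_obs participant-inclusion filters.
#' @param speed_threshold_kmh stationary speed threshold.
#' @param max_K cluster cap for both clusterings.
#' @param tz study timezone.
#' @param tasks character subset of `c("binary", "regression")`.
#' @param families named list: for each task, the model families to fit.
#' @param hyper_mode,inner_folds passed to [model_spec()].
#' @param scopes character subset of `c("personal", "population")`; the
#'   population scope adds population-model errors but is not needed for the
#'   lift test.
#' @param n_permutations,exact_cap permutation-test settings.
#' @param seed master seed for the run.
#' @return List of class `ul_run_config`.
#' @export
run_config <- function(simulate = list(), min_days = 30, min_gps_obs = 35,
                       speed_threshold_kmh = 1, max_K = 20, tz = "UTC",
                       tasks = c("binary", "regression"),
                       families = list(binary = "logistic_l2",
                                       regression = "lasso"),
                       hyper_mode = "nested", inner_folds = 10,
                       scopes = "personal",
                       n_permutations = 10000, exact_cap = 20, seed = 1) {
  structure(list(simulate = simulate, min_days = min_days,
                 min_gps_obs = min_gps_obs,
                 speed_threshold_kmh = speed_threshold_kmh, max_K = max_K,
                 tz = tz, tasks = match.arg(tasks, several.ok = TRUE),
                 families = families, hyper_mode = hyper_mode,
                 inner_folds = inner_folds, scopes = scopes,
                 n_permutations = n_permutations, exact_cap = exact_cap,
                 seed = check_count(seed, "seed", 0L)),
            class = "ul_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path path to a YAML document whose keys mirror the arguments of
#'   [run_config()].
#' @return `ul_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ul_abort(paste("no such file:", path), "userlift_io_error")
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

write_manifest <- function(dir, stage, config, inputs = character()) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("userlift")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    inputs = inputs,
    seed = config$seed %||% NA
  )
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Pipeline stage: simulate a cohort to disk
#'
#' @param config `ul_run_config` whose `simulate` entry holds
#'   [cohort_config()] arguments.
#' @param out_dir output directory.
#' @return Paths written (locations/responses/scales/truth + manifest).
#' @export
run_simulate <- function(config, out_dir) {
  sim_args <- config$simulate %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  cohort <- generate_cohort(do.call(cohort_config, sim_args))
  paths <- write_cohort(cohort, out_dir)
  c(paths, manifest = write_manifest(out_dir, "simulate", config))
}

#' Pipeline stage: ingest + mobility features
#'
#' Reads the raw tables, applies the inclusion filters, fits the per-user
#' clusterings and writes `day_records.csv` (the labels) and `features.csv`
#' (the daily feature vectors), plus per-user cluster summaries as JSON.
#'
#' @param config `ul_run_config`.
#' @param locations_path,responses_path,scales_path input CSV/YAML paths.
#' @param scale_id which scale in `scales.yaml` to analyze (default: the
#'   first).
#' @param out_dir output directory.
#' @return Paths written.
#' @export
run_features <- function(config, locations_path, responses_path, scales_path,
                         scale_id = NULL, out_dir) {
  for (p in c(locations_path, responses_path, scales_path)) {
    if (!file.exists(p)) {
      ul_abort(paste("missing pipeline input:", p), "userlift_io_error")
    }
  }
  scales <- read_scales(scales_path)
  scale <- if (is.null(scale_id)) scales[[1L]] else scales[[scale_id]]
  if (is.null(scale)) ul_abort(paste("unknown scale_id:", scale_id), "userlift_config_error")
  locations <- read_locations(locations_path)
  responses <- read_responses(responses_path, scale)
  days <- build_day_records(responses, locations, scale, tz = config$tz)
  days <- filter_participants(days, min_days = config$min_days,
                              min_gps_obs = config$min_gps_obs)
  feats <- extract_mobility_features(
    locations[locations$user_id %in% unique(days$user_id), , drop = FALSE],
    days, max_K = config$max_K, tz = config$tz, seed = config$seed,
    speed_threshold_kmh = config$speed_threshold_kmh)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  day_path <- file.path(out_dir, "day_records.csv")
  feat_path <- file.path(out_dir, "features.csv")
  readr::write_csv(days, day_path, progress = FALSE)
  readr::write_csv(feats$features, feat_path, progress = FALSE)
  model_path <- file.path(out_dir, "cluster_models.json")
  jsonlite::write_json(
    lapply(feats$models, function(m) list(
      user_id = m$user_id, K_full = m$full$K, K_stationary = m$stationary$K,
      weights = m$full$weights, means = m$full$means, vars = m$full$vars,
      stationary_centers = m$stationary$centers,
      home_id = m$semantic$home_id, work_id = m$semantic$work_id,
      night_id = m$semantic$night_id, origin = m$origin)),
    model_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  c(day_records = day_path, features = feat_path, cluster_models = model_path,
    manifest = write_manifest(out_dir, "features", config,
                              inputs = c(locations_path, responses_path,
                                         scales_path)))
}

#' Pipeline stage: baselines, models and the user-lift test
#'
#' Joins the labels and features, computes personal (and population)
#' baselines, fits the configured model families under LOOCV, and writes
#' `lift_report.csv` (one row per task/family: average personal baseline
#' error, average model error, average user lift, p-value) plus a JSON
#' variant carrying the per-user lifts.
#'
#' @param config `ul_run_config`.
#' @param features_path,day_records_path outputs of [run_features()].
#' @param out_dir output directory.
#' @return Paths written.
#' @export
run_evaluate <- function(config, features_path, day_records_path, out_dir) {
  for (p in c(features_path, day_records_path)) {
    if (!file.exists(p)) {
      ul_abort(paste("missing pipeline input (run the features stage first?):", p),
               "userlift_io_error")
    }
  }
  feats <- readr::read_csv(features_path, show_col_types = FALSE, progress = FALSE)
  days <- readr::read_csv(day_records_path, show_col_types = FALSE, progress = FALSE)
  data <- dplyr::inner_join(days, feats, by = c("user_id", "date"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summaries <- list(); per_users <- list()
  for (task in config$tasks) {
    pb <- personal_baseline(data, task)
    popb <- population_baseline(data, task)
    fams <- config$families[[task]] %||% UL_FAMILIES[[task]][1L]
    model_rows <- dplyr::bind_rows(lapply(fams, function(fam) {
      spec <- model_spec(task, fam, hyper_mode = config$hyper_mode,
                         inner_folds = config$inner_folds, seed = config$seed)
      rows <- loocv_personal(data, spec)
      if ("population" %in% config$scopes) {
        rows <- dplyr::bind_rows(rows, loocv_population(data, spec))
      }
      rows
    }))
    ev <- evaluate_cohort(pb, model_rows, population_baselines = popb,
                          n_permutations = config$n_permutations,
                          seed = config$seed, exact_cap = config$exact_cap)
    summaries[[task]] <- ev$summary
    per_users[[task]] <- ev$per_user
  }
  report <- dplyr::bind_rows(summaries)
  report_path <- file.path(out_dir, "lift_report.csv")
  readr::write_csv(report, report_path, progress = FALSE)
  json_path <- file.path(out_dir, "lift_report.json")
  jsonlite::write_json(list(summary = report,
                            per_user = dplyr::bind_rows(per_users)),
                       json_path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  c(lift_report = report_path, lift_report_json = json_path,
    manifest = write_manifest(out_dir, "evaluate", config,
                              inputs = c(features_path, day_records_path)))
}

#' Pipeline stage: human-readable report
#'
#' Writes a plain-text summary of the lift table and, optionally, a
#' box-style plot of the per-user error distributions (means, quartiles and
#' 5th/95th percentile whiskers) to PDF.
#'
#' @param eval_dir directory holding `lift_report.csv` / `.json`.
#' @param out_dir output directory.
#' @param plot logical; write `error_distributions.pdf`.
#' @return Paths written.
#' @export
run_report <- function(eval_dir, out_dir = eval_dir, plot = TRUE) {
  report_path <- file.path(eval_dir, "lift_report.csv")
  json_path <- file.path(eval_dir, "lift_report.json")
  if (!file.exists(report_path)) {
    ul_abort(paste("missing pipeline input (run the evaluate stage first?):",
                   report_path), "userlift_io_error")
  }
  report <- readr::read_csv(report_path, show_col_types = FALSE, progress = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  txt <- c("user-lift evaluation summary", "",
           utils::capture.output(print(as.data.frame(report), row.names = FALSE)))
  txt_path <- file.path(out_dir, "summary.txt")
  writeLines(txt, txt_path)
  paths <- c(summary = txt_path)
  if (plot && file.exists(json_path)) {
    per_user <- as_tibble(jsonlite::read_json(json_path, simplifyVector = TRUE)$per_user)
    p <- plot_error_distributions(per_user)
    plot_path <- file.path(out_dir, "error_distributions.pdf")
    ggplot2::ggsave(plot_path, p, width = 7, height = 4)
    paths <- c(paths, plot = plot_path)
  }
  paths
}

#' Per-user error distributions, box-style
#'
#' Summary display of personal baseline vs personal model error across
#' users: boxes for the quartiles, whiskers for the 5th/95th percentiles,
#' a line at the mean.
#'
#' @param per_user the `per_user` table of an [evaluate_cohort()] result.
#' @return A ggplot object.
#' @export
plot_error_distributions <- function(per_user) {
  long <- tidyr::pivot_longer(
    per_user,
    cols = dplyr::any_of(c("personal_baseline_error", "personal_model_error",
                           "population_baseline_error",
                           "population_model_error")),
    names_to = "source", values_to = "error")
  long <- long[!is.na(long$error), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source, y = .data$error)) +
    ggplot2::stat_summary(
      fun.min = function(z) stats::quantile(z, 0.05),
      fun.max = function(z) stats::quantile(z, 0.95),
      geom = "errorbar", width = 0.2) +
    ggplot2::stat_summary(
      fun.min = function(z) stats::quantile(z, 0.25),
      fun.max = function(z) stats::quantile(z, 0.75),
      fun = stats::median, geom = "crossbar", width = 0.45, fill = "grey90") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3) +
    ggplot2::facet_wrap(~task, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-user error") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 25, hjust = 1))
}

#' Simulate one cohort and evaluate it in memory
#'
#' End-to-end convenience for simulation studies: generates a cohort, builds
#' and filters day records, extracts the mobility features, fits the personal
#' models under LOOCV, computes the personal (and optionally population)
#' baselines and returns the user-lift evaluation. No files are written.
#'
#' @param config an `ul_cohort_config`.
#' @param task `"binary"` or `"regression"`.
#' @param family model family (default `"logistic_l2"` / `"lasso"`).
#' @param max_K cluster cap for the feature stage.
#' @param hyper_mode hyperparameter mode for [model_spec()].
#' @param population also compute the population baseline and model.
#' @param seed analysis seed (clustering restarts, folds, permutation test);
#'   defaults to the cohort's seed.
#' @param n_permutations permutation-test draws (Monte Carlo mode).
#' @return An `ul_eval` (see [evaluate_cohort()]); attribute `cohort` holds
#'   the generated cohort.
#' @export
simulate_and_evaluate <- function(config, task = "binary", family = NULL,
                                  max_K = 20, hyper_mode = "nested",
                                  population = FALSE, seed = NULL,
                                  n_permutations = 10000) {
  seed <- seed %||% config$seed
  cohort <- generate_cohort(config)
  days <- filter_participants(build_day_records(cohort$responses,
                                                cohort$locations,
                                                cohort$scale))
  feats <- suppressMessages(extract_mobility_features(
    cohort$locations, days, max_K = max_K, seed = seed))
  data <- dplyr::inner_join(days, feats$features, by = c("user_id", "date"))
  spec <- model_spec(task, family, hyper_mode = hyper_mode, seed = seed)
  model_rows <- suppressMessages(loocv_personal(data, spec))
  pop_base <- NULL
  if (population) {
    model_rows <- dplyr::bind_rows(model_rows,
                                   suppressMessages(loocv_population(data, spec)))
    pop_base <- population_baseline(data, task)
  }
  ev <- evaluate_cohort(personal_baseline(data, task), model_rows,
                        population_baselines = pop_base,
                        n_permutations = n_permutations, seed = seed)
  attr(ev, "cohort") <- cohort
  ev
}

#' Run the whole pipeline
#'
#' simulate -> features -> evaluate -> report, under one configuration and
#' one output directory; each stage writes a manifest (inputs, config hash,
#' seed, package version) so a rerun with the same configuration reproduces
#' identical artifacts.
#'
#' @param config `ul_run_config` (with a `simulate` entry).
#' @param out_dir output directory; stages write into subdirectories.
#' @param report logical; also run the report stage.
#' @return Named vector of all paths written.
#' @export
run_pipeline <- function(config, out_dir, report = TRUE) {
  sim_dir <- file.path(out_dir, "sim")
  feat_dir <- file.path(out_dir, "features")
  eval_dir <- file.path(out_dir, "eval")
  p1 <- run_simulate(config, sim_dir)
  p2 <- run_features(config, p1[["locations"]], p1[["responses"]],
                     p1[["scales"]], out_dir = feat_dir)
  p3 <- run_evaluate(config, p2[["features"]], p2[["day_records"]], eval_dir)
  out <- c(p1, p2, p3)
  if (report) out <- c(out, run_report(eval_dir, plot = FALSE))
  out
}
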
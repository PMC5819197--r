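#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML (or already-parsed list) with the keys
#' below; unknown keys are rejected so typos fail loudly before any
#' compute.
#'
#' \describe{
#'   \item{model}{`"packaged"` (the shipped reference surrogate) or a path
#'     to a model YAML.}
#'   \item{n_simulations}{Cohort size, >= 1.}
#'   \item{master_seed}{Integer seed; every stochastic stage derives its
#'     stream from it.}
#'   \item{sampling}{`"uniform"` (default) or `"log_uniform"`.}
#'   \item{thresholds}{`normal_max`, `mild_lo`, `mild_hi` (defaults 1, 5,
#'     10).}
#'   \item{screen_days}{Days for the overlap screen (default 7, 14, 21,
#'     40).}
#'   \item{evaluation_days}{Days for the regression panels (default 14,
#'     21).}
#'   \item{markers}{Marker states for the panels (default the model's
#'     IL-10/TIMP-1/fibronectin analogs).}
#'   \item{n_bins}{Histogram bins (default 50).}
#'   \item{cv_folds}{Cross-validation folds (default 10).}
#'   \item{write_trajectories}{Write the (large) tidy trajectory CSV
#'     (default FALSE).}
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated configuration list of class `pipeline_config`, with
#'   defaults filled in and a `config_hash` field.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("model", "n_simulations", "master_seed", "sampling",
             "thresholds", "screen_days", "evaluation_days", "markers",
             "n_bins", "cv_folds", "write_trajectories")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    model = config$model %||% "packaged",
    n_simulations = config$n_simulations %||% 5000,
    master_seed = config$master_seed %||% 1,
    sampling = config$sampling %||% "uniform",
    thresholds = utils::modifyList(
      list(normal_max = 1, mild_lo = 5, mild_hi = 10),
      config$thresholds %||% list()),
    screen_days = unlist(config$screen_days %||% c(7, 14, 21, 40)),
    evaluation_days = unlist(config$evaluation_days %||% c(14, 21)),
    markers = config$markers,
    n_bins = config$n_bins %||% 50,
    cv_folds = config$cv_folds %||% 10,
    write_trajectories = isTRUE(config$write_trajectories))
  if (!is.numeric(cfg$n_simulations) || cfg$n_simulations < 1) {
    stop("n_simulations must be >= 1")
  }
  if (!cfg$sampling %in% c("uniform", "log_uniform")) {
    stop("sampling must be 'uniform' or 'log_uniform'")
  }
  th <- cfg$thresholds
  if (!(th$normal_max < th$mild_lo && th$mild_lo <= th$mild_hi)) {
    stop("thresholds must satisfy normal_max < mild_lo <= mild_hi")
  }
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes the four stages in order — cohort simulation, outcome
#' classification, overlap screening, and panel evaluation — from one
#' configuration, persisting every intermediate artifact under `out_dir`.
#' Rerunning with the same configuration and seed reproduces all outputs.
#'
#' @param config A [pipeline_config()], a list, or a YAML path.
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param quiet Suppress per-stage progress messages.
#'
#' @return A run report (list of class `run_report`): `class_counts`,
#'   `rankings`, `auc_table`, `comparisons`, `cv`, `overlaps`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  say <- function(...) if (!quiet) message(...)
  model <- if (identical(cfg$model, "packaged")) reference_model() else
    reference_model(cfg$model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  say("stage 1/4: simulating cohort of ", cfg$n_simulations, " draws")
  draws <- sample_parameters(model$default_params, cfg$n_simulations,
                             seed = cfg$master_seed,
                             log_uniform = cfg$sampling == "log_uniform")
  cohort <- run_cohort(model, draws)
  say("  ", nrow(cohort$trajectories), " trajectories, ",
      nrow(cohort$failures), " failures")
  if (!is.null(out_dir)) {
    utils::write.csv(
      data.frame(draw_id = seq_len(nrow(draws)), draws, row.names = NULL),
      file.path(out_dir, "draws.csv"), row.names = FALSE)
    if (cfg$write_trajectories) {
      tr <- lapply(seq_len(nrow(cohort$trajectories)), function(i) {
        structure(cohort$trajectories[i, , ],
                  dimnames = dimnames(cohort$trajectories)[2:3])
      })
      names(tr) <- rownames(cohort$trajectories)
      utils::write.csv(tidy_trajectories(tr),
                       file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(model = model$name, n_simulations = cfg$n_simulations,
           master_seed = cfg$master_seed, config_hash = cfg$config_hash,
           n_failures = nrow(cohort$failures),
           failures = cohort$failures),
      file.path(out_dir, "cohort_metadata.json"), auto_unbox = TRUE)
  }

  say("stage 2/4: classifying scarring outcomes")
  labels <- label_cohort(cohort, cfg$thresholds)
  class_counts <- table(labels$class4)
  say("  ", paste(names(class_counts), as.integer(class_counts),
                  sep = "=", collapse = ", "))
  if (!is.null(out_dir)) {
    utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
  }

  say("stage 3/4: screening protein concentration distributions")
  screen <- screen_overlap(cohort, labels, days = cfg$screen_days,
                           n_bins = cfg$n_bins)
  if (!is.null(out_dir)) {
    utils::write.csv(screen$overlaps, file.path(out_dir, "overlap.csv"),
                     row.names = FALSE)
    jsonlite::write_json(screen$ranking,
                         file.path(out_dir, "ranking.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  say("stage 4/4: evaluating biomarker panels")
  evaluation <- evaluate_panels(cohort, labels,
                                days = cfg$evaluation_days,
                                markers = cfg$markers,
                                cv_folds = cfg$cv_folds,
                                seed = cfg$master_seed + 1)
  auc_table <- panel_auc_table(evaluation)
  comparisons <- do.call(rbind, lapply(evaluation, function(d) {
    cbind(day = d$day, d$comparisons)
  }))
  rownames(comparisons) <- NULL
  cv <- lapply(evaluation, function(d) d$cv)
  if (!is.null(out_dir)) {
    utils::write.csv(auc_table, file.path(out_dir, "panel_auc.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "delong_tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(evaluation, function(d) {
        list(day = d$day,
             panels = lapply(d$panels, function(p) {
               p$fitted <- NULL; p$roc <- NULL; p
             }),
             cv = d$cv)
      }),
      file.path(out_dir, "panels.json"), auto_unbox = TRUE, digits = NA)
  }

  report <- structure(
    list(class_counts = class_counts,
         rankings = screen$ranking,
         auc_table = auc_table,
         comparisons = comparisons,
         cv = cv,
         overlaps = screen$overlaps,
         n_failures = nrow(cohort$failures),
         provenance = list(
           model = model$name, config_hash = cfg$config_hash,
           master_seed = cfg$master_seed,
           package_version = as.character(utils::packageVersion(
             "scarscreen")))),
    class = "run_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      report_json(report), file.path(out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

report_json <- function(report) {
  list(class_counts = as.list(report$class_counts),
       n_failures = report$n_failures,
       rankings = report$rankings,
       auc_table = report$auc_table,
       delong_comparisons = report$comparisons,
       cv = report$cv,
       provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> model=", x$provenance$model, " seed=",
      x$provenance$master_seed, "\n", sep = "")
  cat("class counts: ",
      paste(names(x$class_counts), as.integer(x$class_counts), sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("top-ranked prognostic candidates per day:\n")
  top <- x$rankings[x$rankings$rank <= 3, c("day", "role", "rank",
                                            "protein", "mean_bc")]
  print(top, row.names = FALSE)
  cat("panel AUCs:\n")
  print(x$auc_table, row.names = FALSE)
  for (d in names(x$cv)) {
    cat(sprintf("%s CV (%s): AUC %.3f [%.3f, %.3f]\n", d, x$cv[[d]]$panel,
                x$cv[[d]]$auc, x$cv[[d]]$ci[1], x$cv[[d]]$ci[2]))
  }
  invisible(x)
}
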
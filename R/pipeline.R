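#' Configuration of a full adherence-prediction experiment
#'
#' Bundles every knob of the end-to-end pipeline: the cohort source, the
#' adherence labelling rule, the window-estimation bounds, the grids of
#' model families and augmentation techniques to compare, the training
#' hyperparameters and the output location.  One model is trained per
#' participant per (family, technique) cell; all cell seeds are derived
#' deterministically from `seed`.
#'
#' @param cohort A [cohort_config()] to simulate from, a cohort tibble, or
#'   the path of a cohort CSV.
#' @param rule A [label_rule()].
#' @param families Character vector of model families to compare.
#' @param techniques Character vector of augmentation techniques to compare.
#' @param w_max,fallback Window-estimation bounds (see
#'   [estimate_window_size()]).
#' @param train_days Last day of the training phase.
#' @param sigma_jitter,sigma_scaling,sigma_warp,n_knots,folds Augmentation
#'   parameters (see [augmentation_config()]).
#' @param training A [training_config()]; its `seed` is ignored in favour of
#'   per-cell derived seeds.
#' @param output_dir Directory for report files, or `NULL` to keep results
#'   in memory only.
#' @param seed Global experiment seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              rule = label_rule(),
                              families = model_families,
                              techniques = augmentation_techniques,
                              w_max = 10, fallback = 3, train_days = 30,
                              sigma_jitter = 0.01, sigma_scaling = 0.1,
                              sigma_warp = 0.2, n_knots = 4, folds = 5,
                              training = training_config(),
                              output_dir = NULL,
                              seed = 1L) {
  if (length(families) == 0 || !all(families %in% model_families)) {
    abort(sprintf("`families` must be a non-empty subset of {%s}",
                  paste(model_families, collapse = ", ")))
  }
  if (length(techniques) == 0 ||
      !all(techniques %in% augmentation_techniques)) {
    abort(sprintf("`techniques` must be a non-empty subset of {%s}",
                  paste(augmentation_techniques, collapse = ", ")))
  }
  structure(
    list(cohort = cohort, rule = rule, families = families,
         techniques = techniques, w_max = w_max, fallback = fallback,
         train_days = as.integer(train_days),
         sigma_jitter = sigma_jitter, sigma_scaling = sigma_scaling,
         sigma_warp = sigma_warp, n_knots = as.integer(n_knots),
         folds = as.integer(folds), training = training,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "cohort_config")) return(simulate_cohort(cohort))
  if (is.character(cohort)) return(read_cohort(cohort))
  validate_cohort(cohort)
  cohort
}

# Train and evaluate one (participant, family, technique) cell.
run_cell <- function(split, family, technique, config) {
  aug_cfg <- augmentation_config(
    technique = technique,
    sigma_jitter = config$sigma_jitter,
    sigma_scaling = config$sigma_scaling,
    sigma_warp = config$sigma_warp,
    n_knots = config$n_knots,
    folds = config$folds,
    seed = derive_seed(config$seed, split$participant_id, family, technique,
                       "augment")
  )
  train_set <- augment_samples(split$train, aug_cfg)
  spec <- architecture_spec(family, window_size = split$window_size)
  fit_cfg <- config$training
  fit_cfg$seed <- derive_seed(config$seed, split$participant_id, family,
                              technique, "fit")
  model <- fit_adherence_model(train_set, spec, fit_cfg)
  metrics <- evaluate_model(model, split$test,
                            threshold = config$training$decision_threshold)
  mutate(metrics,
         participant_id = split$participant_id,
         family = family,
         technique = technique,
         window_size = split$window_size,
         n_train = nrow(train_set),
         final_loss = model$history[length(model$history)],
         .before = 1)
}

#' Run the full per-participant modeling experiment
#'
#' For every participant: estimate the lookback window from the
#' training-phase play-time series, build the sliding-window train/test
#' split, and then, for every (model family, augmentation technique) cell,
#' augment the training set, train a personalized classifier and score its
#' day-by-day predictions over the test phase.  Finally macro-average the
#' five metrics across participants within each cell.
#'
#' A failure for one participant-cell is caught, reported as a warning, and
#' surfaced in the `failures` element; remaining cells still run.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_result` with elements
#'   `per_participant` (one row per participant x family x technique),
#'   `grid` (macro-averaged metrics per cell), `windows` (per-participant
#'   window estimates), `failures` and `config`.  If
#'   `config$output_dir` is set, the tables are also written there (CSV +
#'   a JSON summary of the grid).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  windows <- estimate_window_sizes(cohort, train_days = config$train_days,
                                   w_max = config$w_max,
                                   fallback = config$fallback)
  ids <- unique(cohort$participant_id)
  rows <- list()
  failures <- list()
  for (pid in ids) {
    log <- filter(cohort, .data$participant_id == pid)
    w <- windows$window_size[windows$participant_id == pid]
    split <- make_supervised(log, window_size = w, rule = config$rule,
                             train_days = config$train_days)
    for (family in config$families) {
      for (technique in config$techniques) {
        res <- tryCatch(
          run_cell(split, family, technique, config),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          warn(sprintf("cell (%s, %s, %s) failed: %s",
                       pid, family, technique, conditionMessage(res)))
          failures[[length(failures) + 1]] <- tibble(
            participant_id = pid, family = family, technique = technique,
            message = conditionMessage(res))
        } else {
          rows[[length(rows) + 1]] <- res
        }
      }
    }
  }
  per_participant <- bind_rows(rows)
  if (nrow(per_participant) == 0) abort("every experiment cell failed")
  grid <- summarise_grid(per_participant)
  out <- structure(
    list(per_participant = per_participant, grid = grid, windows = windows,
         failures = bind_rows(failures), config = config),
    class = "experiment_result"
  )
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

# Macro-average the per-participant table within each (family, technique)
# cell, dropping undefined metrics and counting the exclusions.
summarise_grid <- function(per_participant) {
  per_participant |>
    group_by(.data$family, .data$technique) |>
    summarise(
      n_participants = n(),
      precision = mean(.data$precision, na.rm = TRUE),
      recall = mean(.data$recall, na.rm = TRUE),
      f1 = mean(.data$f1, na.rm = TRUE),
      auc = mean(.data$auc, na.rm = TRUE),
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      n_f1_excluded = sum(is.na(.data$f1)),
      n_auc_excluded = sum(is.na(.data$auc)),
      .groups = "drop"
    )
}

#' Write / re-render experiment reports
#'
#' `write_experiment()` writes the per-participant table, the window-size
#' table and the macro grid (CSV), plus a JSON summary of the grid.
#' `render_report()` rebuilds the macro grid from a stored per-participant
#' table, so a finished run can be re-aggregated without retraining.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if missing).
#' @return `write_experiment()` returns `dir` invisibly; `render_report()`
#'   returns the grid tibble.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$per_participant,
                   file.path(dir, "per_participant.csv"))
  readr::write_csv(result$windows, file.path(dir, "window_sizes.csv"))
  readr::write_csv(result$grid, file.path(dir, "grid.csv"))
  jsonlite::write_json(
    list(seed = result$config$seed,
         n_participants = length(unique(result$per_participant$participant_id)),
         grid = result$grid),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_experiment
#' @export
render_report <- function(dir) {
  path <- file.path(dir, "per_participant.csv")
  if (!file.exists(path)) {
    abort(sprintf("no per-participant table found at %s", path))
  }
  per_participant <- readr::read_csv(path, show_col_types = FALSE,
                                     progress = FALSE)
  summarise_grid(per_participant)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d participants x {%s} x {%s}\n",
              length(unique(x$per_participant$participant_id)),
              paste(x$config$families, collapse = ", "),
              paste(x$config$techniques, collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' @rdname tidy.adherence_model
#' @export
tidy.experiment_result <- function(x, ...) x$per_participant

#' @rdname tidy.adherence_model
#' @export
glance.experiment_result <- function(x, ...) x$grid

#' Read an experiment configuration from a YAML file
#'
#' The file mirrors the blocks of [experiment_config()]: `cohort:` (either a
#' `source:` path or generator fields), `label:`, `window:`,
#' `augmentation:`, `model:`, `training:`, `output:` and a top-level
#' `seed:`.  Every field has a default, so a minimal file can be empty.
#'
#' @param path YAML file path.
#' @param overrides Named list of top-level overrides (e.g. from CLI flags):
#'   `cohort`, `output_dir`, `seed`.
#' @return An [experiment_config()].
#' @export
#' @examples
#' example <- system.file("extdata", "example-experiment.yaml",
#'                        package = "dailyadhere")
#' read_experiment_config(example)$techniques
read_experiment_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- raw %||% list()
  get_block <- function(name) raw[[name]] %||% list()
  co <- get_block("cohort")
  cohort <- overrides$cohort %||% (
    if (!is.null(co$source)) {
      co$source
    } else {
      do.call(cohort_config, c(
        co[intersect(names(co), names(formals(cohort_config)))],
        if (is.null(co$seed)) list(seed = raw$seed %||% 1L)
      ))
    }
  )
  lb <- get_block("label")
  wd <- get_block("window")
  au <- get_block("augmentation")
  md <- get_block("model")
  tr <- get_block("training")
  ou <- get_block("output")
  experiment_config(
    cohort = cohort,
    rule = label_rule(threshold_seconds = lb$threshold_seconds %||% 600),
    families = md$families %||% model_families,
    techniques = au$techniques %||% augmentation_techniques,
    w_max = wd$w_max %||% 10,
    fallback = wd$fallback %||% 3,
    train_days = wd$train_days %||% 30,
    sigma_jitter = au$sigma_jitter %||% 0.01,
    sigma_scaling = au$sigma_scaling %||% 0.1,
    sigma_warp = au$sigma_warp %||% 0.2,
    n_knots = au$n_knots %||% 4,
    folds = au$folds %||% 5,
    training = training_config(
      learning_rate = tr$learning_rate %||% 1e-3,
      epochs = tr$epochs %||% 100,
      batch_size = tr$batch_size %||% 16,
      decision_threshold = tr$decision_threshold %||% 0.5
    ),
    output_dir = overrides$output_dir %||% ou$dir,
    seed = overrides$seed %||% raw$seed %||% 1L
  )
}
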
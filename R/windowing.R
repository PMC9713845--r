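#' Adherence labelling rule
#'
#' A day counts as adherent when the participant played for at least
#' `threshold_seconds` (default 600 s = 10 minutes).  The threshold guards
#' against counting days where the app was opened accidentally and closed
#' immediately.
#'
#' @param threshold_seconds Positive threshold, in seconds.  The boundary is
#'   inclusive: exactly `threshold_seconds` of play is adherent.
#' @return A list of class `label_rule`.
#' @export
label_rule <- function(threshold_seconds = 600) {
  assert_positive_scalar(threshold_seconds, "threshold_seconds")
  structure(list(threshold_seconds = as.numeric(threshold_seconds)),
            class = "label_rule")
}

#' Binarize daily play time into adherent / non-adherent
#'
#' @param play_seconds Non-negative numeric vector of daily play times.
#' @param rule A [label_rule()].
#' @return Integer vector of 0/1 labels, 1 = adherent (played at least the
#'   threshold).
#' @export
#' @examples
#' binarize_adherence(c(0, 599.9, 600, 2700))
binarize_adherence <- function(play_seconds, rule = label_rule()) {
  stopifnot(inherits(rule, "label_rule"))
  if (any(!is.finite(play_seconds)) || any(play_seconds < 0)) {
    abort("`play_seconds` must be non-negative and finite")
  }
  as.integer(play_seconds >= rule$threshold_seconds)
}

#' Estimate a participant's lookback window from the dominant play-time cycle
#'
#' Detects the most prominent cycle in a training-phase play-time series and
#' uses its period as the length of the sliding window for that participant.
#' The procedure: (1) subtract the series mean, so a constant offset can
#' never win; (2) take the discrete Fourier transform; (3) pick the frequency
#' bin `k` in `1..floor(T/2)` with the largest amplitude (ties broken toward
#' the smallest bin, i.e. the longest period); (4) convert the winning bin
#' back to a time interval, `period = round(T / k)`; (5) clamp the period to
#' `[2, w_max]`.  A series that is constant after de-meaning has no cycle;
#' the estimate then falls back to `fallback` and is flagged.
#'
#' @param train_play_series Numeric vector of daily play times from the
#'   training phase only (length at least 4).
#' @param w_max Upper clamp for the window size.
#' @param fallback Window size used when the spectrum is flat.
#' @return A one-row tibble with columns `window_size`, `dominant_bin`
#'   (`NA` for the fallback case) and `is_fallback`.
#' @export
#' @examples
#' # a 6-cycles-in-30-days series has period 5
#' estimate_window_size(cos(2 * pi * 6 * (0:29) / 30))
estimate_window_size <- function(train_play_series, w_max = 10, fallback = 3) {
  x <- as.numeric(train_play_series)
  n <- length(x)
  if (n < 4) abort("need at least 4 training days to estimate a window size")
  if (any(!is.finite(x))) abort("`train_play_series` must be finite")
  if (w_max < 2) abort("`w_max` must be at least 2")
  centred <- x - mean(x)
  if (all(abs(centred) < 1e-12)) {
    return(tibble(window_size = as.integer(fallback),
                  dominant_bin = NA_integer_,
                  is_fallback = TRUE))
  }
  spec <- Mod(fft(centred))
  ks <- seq_len(floor(n / 2))       # non-constant bins up to Nyquist
  amp <- spec[ks + 1L]              # spec[1] is the (zeroed) DC component
  k_star <- ks[which.max(amp)]      # which.max takes the first maximum: ties
                                    # resolve to the smallest bin
  period <- round(n / k_star)
  tibble(window_size = as.integer(min(max(period, 2), w_max)),
         dominant_bin = as.integer(k_star),
         is_fallback = FALSE)
}

#' Per-participant window sizes for a whole cohort
#'
#' Applies [estimate_window_size()] to each participant's training-phase
#' play-time series (days `1..train_days` only, so nothing from the test
#' phase can influence the estimate).
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param train_days Last day of the training phase.
#' @inheritParams estimate_window_size
#' @return A tibble with one row per participant: `participant_id`,
#'   `window_size`, `dominant_bin`, `is_fallback`.
#' @export
estimate_window_sizes <- function(cohort, train_days = 30, w_max = 10,
                                  fallback = 3) {
  validate_cohort(cohort)
  cohort |>
    filter(.data$day <= train_days) |>
    arrange(.data$participant_id, .data$day) |>
    group_by(.data$participant_id) |>
    summarise(estimate_window_size(.data$play_seconds, w_max = w_max,
                                   fallback = fallback),
              .groups = "drop")
}

#' Min-max feature scaler fitted on training days only
#'
#' `fit_scaler()` learns per-feature minima and maxima from a training-phase
#' feature matrix; `apply_scaler()` maps features affinely so the training
#' range becomes `[0, 1]`.  A feature that is constant over the training
#' phase maps to 0 everywhere.  Test-phase values outside the training range
#' map outside `[0, 1]`; the map stays affine and monotone.
#'
#' @param train_days Numeric matrix (days x features) from the training
#'   phase.
#' @return `fit_scaler()` returns a tibble with columns `feature`, `min`,
#'   `max`; `apply_scaler()` returns a matrix of the same shape as its input.
#' @export
fit_scaler <- function(train_days) {
  stopifnot(is.matrix(train_days), nrow(train_days) > 0)
  tibble(feature = colnames(train_days) %||% paste0("V", seq_len(ncol(train_days))),
         min = apply(train_days, 2, min),
         max = apply(train_days, 2, max))
}

#' @rdname fit_scaler
#' @param x Matrix to transform (same feature order as the fit).
#' @param scaler_stats Result of `fit_scaler()`.
#' @export
apply_scaler <- function(x, scaler_stats) {
  stopifnot(is.matrix(x), ncol(x) == nrow(scaler_stats))
  rng <- scaler_stats$max - scaler_stats$min
  out <- sweep(x, 2, scaler_stats$min, "-")
  nonconst <- rng > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2, rng[nonconst], "/")
  out[, !nonconst] <- 0
  out
}

predictor_features <- c("play_seconds", "n_sessions", "max_level", "n_tasks")

#' Sliding-window supervised framing of one participant's log
#'
#' Converts a complete daily log into supervised samples: each sample's
#' features are the previous `window_size` days of the four predictors
#' (play seconds, sessions, max level, tasks; min-max normalized on
#' training-phase statistics), and its label is the adherence of the next
#' day.  The window advances one day at a time.  Training samples predict
#' days `window_size + 1 .. train_days`; test samples predict every day of
#' the test phase (`train_days + 1 .. n_days`), with the earliest test
#' windows reaching back into the last training days so that the test phase
#' always contributes one prediction per day.
#'
#' @param log One participant's rows of a cohort tibble (all days present,
#'   consecutive).
#' @param window_size Lookback length in days (2..`train_days`), typically
#'   from [estimate_window_size()].
#' @param rule A [label_rule()].
#' @param train_days Last day of the training phase.
#' @return A list of class `supervised_split` with elements `train` and
#'   `test` (tibbles with columns `target_day`, `label` and a list-column
#'   `features` of `window_size x 4` matrices), `scaler` (the fitted
#'   min-max statistics), `window_size` and `participant_id`.
#' @export
make_supervised <- function(log, window_size, rule = label_rule(),
                            train_days = 30) {
  validate_cohort(log, call_site = "participant log")
  if (length(unique(log$participant_id)) != 1) {
    abort("`log` must contain exactly one participant")
  }
  n_days <- nrow(log)
  w <- as.integer(window_size)
  if (w < 2) abort("`window_size` must be at least 2")
  if (w > train_days) {
    abort(sprintf("`window_size` (%d) exceeds the training phase (%d days)",
                  w, train_days))
  }
  if (n_days <= train_days) {
    abort("`log` must extend beyond the training phase")
  }
  log <- arrange(log, .data$day)
  feat <- as.matrix(log[predictor_features])
  scaler <- fit_scaler(feat[seq_len(train_days), , drop = FALSE])
  scaled <- apply_scaler(feat, scaler)
  labels <- binarize_adherence(log$play_seconds, rule)

  window_sample <- function(target) {
    rows <- (target - w):(target - 1L)
    tibble(target_day = as.integer(target),
           label = labels[target],
           features = list(scaled[rows, , drop = FALSE]))
  }
  train_targets <- seq.int(w + 1L, train_days)
  test_targets <- seq.int(train_days + 1L, n_days)
  structure(
    list(
      participant_id = log$participant_id[1],
      window_size = w,
      scaler = scaler,
      train = bind_rows(lapply(train_targets, window_sample)),
      test = bind_rows(lapply(test_targets, window_sample))
    ),
    class = "supervised_split"
  )
}

#' @export
print.supervised_split <- function(x, ...) {
  cat(sprintf("<supervised_split> participant %s, window %d: %d train / %d test samples\n",
              x$participant_id, x$window_size, nrow(x$train), nrow(x$test)))
  invisible(x)
}
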
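#' Configuration for the synthetic gameplay cohort generator
#'
#' Builds the parameter set from which [simulate_cohort()] draws a cohort of
#' daily gameplay logs.  The generator emulates the structure of a prescribed
#' cognitive-training schedule: participants are asked to play on a fixed
#' number of preferred days per week for a target number of minutes, adhere to
#' that schedule with heterogeneous per-participant propensities, and drift
#' toward non-adherence in the second half of the study.
#'
#' Per participant, an adherence propensity is drawn from a
#' `Beta(adherence_base_rate_params[1], adherence_base_rate_params[2])`
#' distribution and a random set of `preferred_days_per_week` weekdays is
#' chosen.  On day `d` the probability of an adherent play day is
#' `propensity * m(d) * decay_rate^max(0, d - 30)`, where `m(d)` is 1 on
#' preferred weekdays and `off_day_multiplier` otherwise.  Play time on
#' adherent days is Normal around `target_play_minutes * 60` seconds (rounded
#' to whole seconds, floored at 0); session, task and level counts are drawn
#' positively associated with play time.  Non-play days are explicit zero
#' rows, so downstream sliding windows never contain gaps.  A small
#' probability of an "accidental open" (a short sub-threshold play burst on an
#' otherwise non-adherent day) exercises the ten-minute adherence threshold.
#'
#' @param n_participants Number of participants (the study emulated here
#'   enrolled 118).
#' @param n_days Length of each log in days; the first half is the training
#'   phase, the second half the test phase.
#' @param adherence_base_rate_params Length-2 positive vector: shape
#'   parameters of the Beta distribution of per-participant adherence
#'   propensities.
#' @param weekly_period Length of the weekly cycle in days.
#' @param preferred_days_per_week Number of prescribed play days per cycle
#'   (between 0 and `weekly_period`).
#' @param target_play_minutes Prescribed daily play time, in minutes.
#' @param play_noise_sd_minutes Standard deviation of daily play time around
#'   the target, in minutes.
#' @param decay_rate Per-day multiplicative decline of the adherence
#'   propensity after day 30, in `[0, 1]`; 1 means no decline.
#' @param off_day_multiplier Multiplier applied to the propensity on
#'   non-preferred weekdays, in `[0, 1]`.
#' @param accidental_open_prob Probability that a would-be non-play day turns
#'   into a short accidental open (played, but under the adherence
#'   threshold).
#' @param level_cap_range Length-2 integer vector: each participant's
#'   maximum attainable level is drawn uniformly from this range (game
#'   tasks have finite level ladders, typically a few dozen levels).
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()], [simulate_participant()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 5, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' dplyr::count(cohort, participant_id)
cohort_config <- function(n_participants = 118,
                          n_days = 60,
                          adherence_base_rate_params = c(3.5, 1.5),
                          weekly_period = 7,
                          preferred_days_per_week = 5,
                          target_play_minutes = 45,
                          play_noise_sd_minutes = 5,
                          decay_rate = 0.97,
                          off_day_multiplier = 0.1,
                          accidental_open_prob = 0.03,
                          level_cap_range = c(16L, 58L),
                          seed = 1L) {
  assert_positive_scalar(n_participants, "n_participants")
  if (n_days < 2) abort("`n_days` must be at least 2")
  if (length(adherence_base_rate_params) != 2 ||
      any(!is.finite(adherence_base_rate_params)) ||
      any(adherence_base_rate_params <= 0)) {
    abort("`adherence_base_rate_params` must be two strictly positive shape parameters")
  }
  assert_positive_scalar(weekly_period, "weekly_period")
  if (preferred_days_per_week < 0 || preferred_days_per_week > weekly_period) {
    abort("`preferred_days_per_week` must lie in [0, weekly_period]")
  }
  assert_positive_scalar(target_play_minutes, "target_play_minutes")
  assert_positive_scalar(play_noise_sd_minutes, "play_noise_sd_minutes", strict = FALSE)
  if (!is.numeric(decay_rate) || decay_rate < 0 || decay_rate > 1) {
    abort("`decay_rate` must lie in [0, 1]")
  }
  if (off_day_multiplier < 0 || off_day_multiplier > 1) {
    abort("`off_day_multiplier` must lie in [0, 1]")
  }
  if (accidental_open_prob < 0 || accidental_open_prob > 1) {
    abort("`accidental_open_prob` must lie in [0, 1]")
  }
  if (length(level_cap_range) != 2 || level_cap_range[1] < 1 ||
      level_cap_range[2] < level_cap_range[1]) {
    abort("`level_cap_range` must be an increasing pair of positive integers")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_days = as.integer(n_days),
      adherence_base_rate_params = as.numeric(adherence_base_rate_params),
      weekly_period = as.integer(weekly_period),
      preferred_days_per_week = as.integer(preferred_days_per_week),
      target_play_minutes = as.numeric(target_play_minutes),
      play_noise_sd_minutes = as.numeric(play_noise_sd_minutes),
      decay_rate = as.numeric(decay_rate),
      off_day_multiplier = as.numeric(off_day_multiplier),
      accidental_open_prob = as.numeric(accidental_open_prob),
      level_cap_range = as.integer(level_cap_range),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Preferred play days form a contiguous block at a random offset of the
# weekly cycle (a work-week-like schedule with a weekend-like break), the
# arrangement a prescribed n-of-m-days schedule induces in practice.
draw_preferred_days <- function(config) {
  start <- sample.int(config$weekly_period, 1) - 1L
  ((start + seq_len(config$preferred_days_per_week) - 1L) %%
      config$weekly_period) + 1L
}

# Draws one participant's daily records.  All randomness comes from the
# caller's RNG stream; the exported wrappers seed it.
sim_participant_records <- function(config, propensity, preferred_days) {
  n_days <- config$n_days
  target_seconds <- config$target_play_minutes * 60
  noise_sd <- config$play_noise_sd_minutes * 60
  weekday <- ((seq_len(n_days) - 1L) %% config$weekly_period) + 1L
  mult <- ifelse(weekday %in% preferred_days, 1, config$off_day_multiplier)
  decay <- config$decay_rate ^ pmax(0L, seq_len(n_days) - 30L)
  p_day <- pmin(1, pmax(0, propensity * mult * decay))

  adherent <- rbinom(n_days, 1L, p_day) == 1L
  play <- numeric(n_days)
  play[adherent] <- pmax(0, round(rnorm(sum(adherent), target_seconds, noise_sd)))
  # accidental opens: short sub-threshold bursts on otherwise idle days
  idle <- !adherent & p_day > 0
  opened <- idle & runif(n_days) < config$accidental_open_prob
  play[opened] <- round(runif(sum(opened), 30, 570))

  played <- play > 0
  n_sessions <- integer(n_days)
  n_tasks <- integer(n_days)
  n_sessions[played] <- 1L + rpois(sum(played), play[played] / 1800)
  n_tasks[played] <- rpois(sum(played), play[played] / 300)

  # noisy non-decreasing level ramp, advancing only on adherent play days
  # and saturating at the participant's finite level ladder
  cap <- sample(seq(config$level_cap_range[1], config$level_cap_range[2]), 1)
  inc <- integer(n_days)
  ramp_days <- adherent & played
  inc[ramp_days] <- rbinom(sum(ramp_days), 1L, 0.5)
  max_level <- pmin(1L + cumsum(inc), cap)

  tibble(
    day = seq_len(n_days),
    play_seconds = play,
    n_sessions = n_sessions,
    max_level = as.integer(max_level),
    n_tasks = n_tasks
  )
}

#' Simulate a single participant's gameplay log
#'
#' Low-level entry point used by [simulate_cohort()]; exposed so degenerate
#' and single-participant scenarios can be constructed directly.
#'
#' @param config A [cohort_config()].
#' @param propensity Adherence propensity in `[0, 1]`; if `NULL`, drawn from
#'   the configured Beta distribution.
#' @param preferred_days Integer vector of preferred weekday indices in
#'   `[1, weekly_period]`; if `NULL`, drawn uniformly without replacement.
#' @param participant_id Identifier stored in the log.
#' @param seed Integer seed for this participant's stream.
#'
#' @return A tibble with one row per day and columns `participant_id`, `day`,
#'   `play_seconds`, `n_sessions`, `max_level`, `n_tasks`.
#' @export
simulate_participant <- function(config, propensity = NULL,
                                 preferred_days = NULL,
                                 participant_id = "P001",
                                 seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    if (is.null(propensity)) {
      propensity <- rbeta(1, config$adherence_base_rate_params[1],
                          config$adherence_base_rate_params[2])
    }
    if (is.null(preferred_days)) {
      preferred_days <- draw_preferred_days(config)
    }
    rec <- sim_participant_records(config, propensity, preferred_days)
    mutate(rec, participant_id = participant_id, .before = 1)
  })
}

#' Simulate a synthetic cohort of gameplay logs
#'
#' Draws `config$n_participants` independent participant logs.  Each
#' participant receives their own propensity and preferred-day set; each log
#' is generated from a seed derived deterministically from `config$seed` and
#' the participant id, so the cohort is reproducible and order-independent.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `adherence_cohort` in long format, one row per
#'   participant-day, with the generating config in the `"config"` attribute.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  draws <- with_seed(config$seed, {
    purrr::map(ids, function(id) {
      list(
        propensity = rbeta(1, config$adherence_base_rate_params[1],
                           config$adherence_base_rate_params[2]),
        preferred_days = draw_preferred_days(config)
      )
    })
  })
  logs <- purrr::map2(ids, draws, function(id, d) {
    simulate_participant(config,
                         propensity = d$propensity,
                         preferred_days = d$preferred_days,
                         participant_id = id,
                         seed = derive_seed(config$seed, "participant", id))
  })
  out <- bind_rows(logs)
  attr(out, "config") <- config
  class(out) <- c("adherence_cohort", class(out))
  out
}

cohort_columns <- c("participant_id", "day", "play_seconds",
                    "n_sessions", "max_level", "n_tasks")

# Structural validation shared by the generator's tests and read_cohort().
validate_cohort <- function(df, call_site = "cohort") {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required columns: %s",
                  call_site, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) abort(sprintf("%s contains no rows", call_site))
  num_cols <- setdiff(cohort_columns, "participant_id")
  for (col in num_cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("%s: negative or non-finite `%s` at row %d",
                    call_site, col, bad[1]))
    }
  }
  zero_bad <- which(df$play_seconds == 0 & (df$n_sessions > 0 | df$n_tasks > 0))
  if (length(zero_bad) > 0) {
    abort(sprintf("%s: sessions/tasks recorded with zero play time at row %d",
                  call_site, zero_bad[1]))
  }
  split_rows <- split(seq_len(nrow(df)), df$participant_id)
  for (rows in split_rows) {
    days <- df$day[rows]
    expected <- seq_along(days)
    off <- which(days != expected)
    if (length(off) > 0) {
      abort(sprintf("%s: non-consecutive day index for participant %s at row %d (day %s, expected %d)",
                    call_site, df$participant_id[rows[off[1]]],
                    rows[off[1]], format(days[off[1]]), expected[off[1]]))
    }
    lvl <- df$max_level[rows]
    dec <- which(diff(lvl) < 0)
    if (length(dec) > 0) {
      abort(sprintf("%s: decreasing max_level for participant %s at row %d",
                    call_site, df$participant_id[rows[dec[1] + 1]],
                    rows[dec[1] + 1]))
    }
  }
  invisible(df)
}

#' Write / read a cohort as CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `participant_id, day, play_seconds, n_sessions, max_level, n_tasks`, one
#' row per participant-day with 1-based consecutive days and explicit zero
#' rows for non-play days.  `read_cohort()` validates the structural
#' invariants and fails with a message naming the first offending row.
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[cohort_columns], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      participant_id = readr::col_character(),
                      .default = readr::col_double()
                    )),
    error = function(e) abort(sprintf("failed to parse cohort file %s: %s",
                                      path, conditionMessage(e)))
  )
  if (nrow(df) == 0) abort(sprintf("cohort file %s is empty", path))
  validate_cohort(df, call_site = path)
  df <- mutate(df,
               day = as.integer(.data$day),
               n_sessions = as.integer(.data$n_sessions),
               max_level = as.integer(.data$max_level),
               n_tasks = as.integer(.data$n_tasks))
  class(df) <- c("adherence_cohort", class(df))
  df
}
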
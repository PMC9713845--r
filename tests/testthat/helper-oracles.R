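# Independent oracles and shared fixtures.  The oracles deliberately avoid
# the package's own code paths: period recovery is cross-checked against a
# brute-force autocovariance maximum, and the rank-based AUC against direct
# trapezoidal integration of the ROC curve.

# Brute-force period estimate: the lag in [2, w_max] maximizing the
# unnormalized autocovariance of the de-meaned series.
acf_period_oracle <- function(x, w_max = 10) {
  xc <- x - mean(x)
  n <- length(xc)
  lags <- 2:w_max
  ac <- vapply(lags, function(lag) {
    sum(xc[seq_len(n - lag)] * xc[(lag + 1):n])
  }, numeric(1))
  lags[which.max(ac)]
}

# Trapezoidal integration of the ROC curve over all score thresholds.
trapezoid_auc_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                     numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Periodic series: period p cycles over T days, with Gaussian noise scaled
# to the REALIZED power of the sampled signal so the series' actual
# signal-to-noise ratio equals `snr` (a cosine of period 2 sampled at
# integers has amplitude |cos(phase)|, so scaling to the nominal amplitude
# would silently break the SNR premise).
periodic_series <- function(p, T_len = 30, amplitude = 1, phase = 0,
                            snr = Inf) {
  t <- seq_len(T_len) - 1
  s <- amplitude * cos(2 * pi * t / p + phase)
  if (!is.finite(snr)) return(s)
  power <- mean((s - mean(s))^2)
  s + rnorm(T_len, 0, sqrt(power / snr))
}

# Cohort with strong, nearly deterministic periodic structure: almost-unit
# adherence propensity on 3 preferred days of a 5-day cycle, little
# play-time noise, no late-phase decay.  A 5-day cycle keeps the training
# phase (30 days) an exact multiple of the period, so the dominant
# spectral bin coincides with the true frequency; a 7-day cycle over 30
# days sits between bins and its leakage-split fundamental can lose to a
# square-wave harmonic.
periodic_cohort_config <- function(n_participants = 10, seed = 1) {
  cohort_config(
    n_participants = n_participants,
    # tight propensity distribution (mean 0.984, sd 0.005): every
    # participant, not just most, has near-deterministic structure
    adherence_base_rate_params = c(600, 10),
    weekly_period = 5,
    preferred_days_per_week = 3,
    play_noise_sd_minutes = 2,
    decay_rate = 1,
    off_day_multiplier = 0.02,
    accidental_open_prob = 0,
    seed = seed
  )
}

# Noisy small-data cohort: the generator's standard study structure
# (heterogeneous propensities, 5-of-7 preferred days) with heavy noise on
# the play-time magnitude — a 20-minute daily SD around the 45-minute
# target (44% coefficient of variation) drops ~8% of adherent days below
# the 10-minute threshold, so labels are noisy exactly where the
# adherence criterion binarizes them.  No late-phase decay: this fixture
# isolates measurement noise, not drift.
noisy_cohort_config <- function(n_participants = 20, seed = 1) {
  cohort_config(
    n_participants = n_participants,
    play_noise_sd_minutes = 20,
    decay_rate = 1,
    seed = seed
  )
}

# Separable toy task: the label is 1 iff the last day's first feature
# exceeds 0.5.  Expressible by every architecture (it only needs the final
# time step), so training should drive the loss toward zero.  A positive
# `margin` keeps a guard band around the threshold, making the classes
# separable with a margin so held-out errors reflect the learned boundary,
# not irreducible boundary noise.
separable_toy_samples <- function(n, w = 5, n_features = 4, seed = 1,
                                  margin = 0) {
  withr::with_seed(seed, {
    feats <- lapply(seq_len(n), function(i) {
      repeat {
        m <- matrix(runif(w * n_features), w, n_features)
        if (abs(m[w, 1] - 0.5) > margin) return(m)
      }
    })
    tibble::tibble(
      target_day = seq_len(n),
      label = vapply(feats, function(m) as.integer(m[w, 1] > 0.5),
                     integer(1)),
      features = feats
    )
  })
}

# A deterministic 60-day log with period-p adherence, for windowing tests.
deterministic_log <- function(p = 5, n_days = 60, play_on = 2700,
                              id = "P001") {
  playing <- (seq_len(n_days) - 1) %% p < (p - 2)
  play <- ifelse(playing, play_on, 0)
  tibble::tibble(
    participant_id = id,
    day = seq_len(n_days),
    play_seconds = play,
    n_sessions = as.integer(playing) * 2L,
    max_level = cumsum(as.integer(playing)) + 1L,
    n_tasks = as.integer(playing) * 5L
  )
}
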
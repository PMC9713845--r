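make_train_samples <- function(n = 27, w = 3, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      target_day = seq_len(n) + w,
      label = rep_len(c(1L, 0L, 1L), n),
      features = lapply(seq_len(n), function(i) matrix(runif(w * 4), w, 4))
    )
  })
}

test_that("all operators reduce to the identity as sigma goes to zero", {
  m <- matrix(runif(20), 5, 4)
  withr::with_seed(1, {
    expect_equal(jitter_window(m, sigma = 0), m, tolerance = 1e-6)
    expect_equal(scale_window(m, sigma = 0), m, tolerance = 1e-6)
    # unit knot heights: the warp path is the identity map
    expect_equal(time_warp_window(m, sigma = 0), m, tolerance = 1e-3,
                 ignore_attr = TRUE)
  })
})

test_that("jitter noise has the configured first two moments", {
  m <- matrix(0, 50, 4)  # 200 entries per draw
  withr::with_seed(2, {
    draws <- replicate(50, jitter_window(m, sigma = 0.01))
  })
  eps <- as.numeric(draws)
  n <- length(eps)
  expect_lt(abs(mean(eps)), 3 * 0.01 / sqrt(n))
  expect_lt(abs(sd(eps) - 0.01), 3 * 0.01 / sqrt(2 * n))
})

test_that("scaling draws one factor per feature with mean 1, sd sigma", {
  m <- matrix(1, 3, 4)  # constant columns expose alpha directly
  withr::with_seed(3, {
    alphas <- replicate(2500, {
      out <- scale_window(m, sigma = 0.1)
      # constancy within a column is preserved
      expect_true(all(apply(out, 2, function(col) diff(range(col)) == 0)))
      out[1, ]
    })
  })
  a <- as.numeric(alphas)
  n <- length(a)
  expect_lt(abs(mean(a) - 1), 3 * 0.1 / sqrt(n))
  expect_lt(abs(sd(a) - 0.1), 3 * 0.1 / sqrt(2 * n))
})

test_that("time warping preserves shape, endpoints and monotone structure", {
  withr::with_seed(4, {
    for (i in 1:100) {
      w <- sample(4:10, 1)
      ramp <- matrix(rep(seq_len(w), 4), w, 4)
      out <- time_warp_window(ramp, sigma = 0.2)
      expect_equal(dim(out), dim(ramp))
      # warping a monotone ramp through a monotone path stays monotone
      expect_true(all(apply(out, 2, function(col) all(diff(col) >= 0))))
      # endpoints of the warp path are fixed
      expect_equal(out[1, ], ramp[1, ], ignore_attr = TRUE)
      expect_equal(out[w, ], ramp[w, ], ignore_attr = TRUE)
    }
  })
})

test_that("the warp path is strictly increasing with fixed endpoints", {
  withr::with_seed(5, {
    for (i in 1:50) {
      w <- sample(2:10, 1)
      tau <- dailyadhere:::warp_path(
        w, seq(1, w, length.out = 6), rnorm(6, 1, 0.2))
      expect_equal(tau[1], 1)
      expect_equal(tau[w], w)
      if (w > 1) expect_true(all(diff(tau) > 0))
    }
  })
})

test_that("augmentation grows the training set by exactly folds copies", {
  train <- make_train_samples(27)
  for (tech in setdiff(dailyadhere:::augmentation_techniques, "none")) {
    cfg <- augmentation_config(tech, folds = 5, seed = 10)
    out <- augment_samples(train, cfg)
    expect_equal(nrow(out), 162L)  # 6x the original 27
    expect_identical(out$is_synthetic, rep(c(FALSE, TRUE), c(27, 135)))
    # label multiset: folds + 1 copies of the original labels
    expect_identical(sort(out$label), sort(rep(train$label, 6)))
    # originals precede synthetics and are untouched
    expect_identical(out$features[1:27], train$features)
    # every original is deformed exactly once per fold
    expect_identical(as.integer(table(out$target_day)), rep(6L, 27))
  }
})

test_that("none and zero folds are no-ops", {
  train <- make_train_samples(9)
  none <- augment_samples(train, augmentation_config("none"))
  expect_equal(nrow(none), 9L)
  expect_identical(none$features, train$features)
  zero <- augment_samples(train, augmentation_config("jitter", folds = 0))
  expect_equal(nrow(zero), 9L)
})

test_that("stacked techniques with zero sigmas reproduce their originals", {
  train <- make_train_samples(6)
  cfg <- augmentation_config("jitter_time_warp", sigma_jitter = 0,
                             sigma_warp = 0, folds = 2, seed = 8)
  out <- augment_samples(train, cfg)
  synth <- out[out$is_synthetic, ]
  for (i in seq_len(nrow(synth))) {
    original <- train$features[[((i - 1) %% 6) + 1]]
    expect_equal(synth$features[[i]], original, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("augmentation is deterministic given its seed", {
  train <- make_train_samples(12)
  cfg <- augmentation_config("scaling_time_warp", seed = 99)
  expect_identical(augment_samples(train, cfg), augment_samples(train, cfg))
  cfg2 <- augmentation_config("scaling_time_warp", seed = 100)
  expect_false(identical(augment_samples(train, cfg),
                         augment_samples(train, cfg2)))
})

test_that("configuration errors are caught", {
  expect_error(augmentation_config("rotate"), "unknown augmentation technique")
  expect_error(augmentation_config("jitter", sigma_jitter = -1), "sigma_jitter")
  expect_error(augmentation_config("jitter", folds = -1), "folds")
  expect_error(time_warp_window(matrix(1, 1, 4)), "at least 2")
})
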
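test_that("layer-size arithmetic matches the architecture contract", {
  # cnn with w = 6: conv (L - k + 1) then pool floor: 5 -> 2 -> 1 -> 1
  spec <- architecture_spec("cnn", window_size = 6)
  expect_equal(spec$dims$L1, 5L)
  expect_equal(spec$dims$L1p, 2L)
  expect_equal(spec$dims$L2, 1L)
  expect_equal(spec$dims$L2p, 1L)  # pooling a length-1 sequence is a no-op
  expect_equal(spec$dims$flat, 64L)

  # cnn_lstm splits into 2 subsequences from w = 4 up, 1 below
  expect_equal(architecture_spec("cnn_lstm", 7)$dims$n_sub, 2L)
  expect_equal(architecture_spec("cnn_lstm", 7)$dims$sub_len, 4L)
  expect_equal(architecture_spec("cnn_lstm", 3)$dims$n_sub, 1L)

  expect_equal(architecture_spec("cnn", 6)$conv_filters, 64L)
  expect_equal(architecture_spec("cnn_lstm", 6)$conv_filters, 32L)
  expect_error(architecture_spec("gru", 5), "unknown model family")
  expect_error(architecture_spec("cnn", 1), "at least 2")
})

test_that("every family maps any clamp-range window to one probability", {
  withr::with_seed(6, {
    for (w in 2:10) {
      x <- matrix(runif(w * 4), w, 4)
      for (fam in c("cnn", "lstm", "cnn_lstm")) {
        model <- build_model(architecture_spec(fam, w), seed = 1)
        p <- predict(model, x)
        expect_length(p, 1)
        expect_true(p > 0 && p < 1)
      }
    }
  })
})

test_that("initialization and training are seed-deterministic", {
  spec <- architecture_spec("lstm", 5)
  expect_identical(build_model(spec, seed = 4)$weights,
                   build_model(spec, seed = 4)$weights)
  expect_false(identical(build_model(spec, seed = 4)$weights,
                         build_model(spec, seed = 5)$weights))

  train <- separable_toy_samples(40, w = 5, seed = 2)
  cfg <- training_config(epochs = 5, seed = 9)
  m1 <- fit_adherence_model(train, spec, cfg)
  m2 <- fit_adherence_model(train, spec, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, train), predict(m2, train))
})

test_that("all families learn a separable last-day rule", {
  train <- separable_toy_samples(200, w = 5, seed = 31)
  cfg <- training_config(epochs = 100, seed = 1)

  # the cnn reproduces the literal rule on its training data
  cnn <- fit_adherence_model(train, architecture_spec("cnn", 5), cfg)
  expect_equal(predict(cnn, train, type = "label"), train$label)
  expect_length(cnn$history, 100)
  expect_lt(cnn$history[100], cnn$history[1])

  # all three families generalize to i.i.d. samples from the same
  # margin-separated rule, each at a sample size where its estimator is
  # consistent: the recurrent families from 200 samples, the heavily
  # over-parameterized double-conv cnn from 1000 (at a few hundred samples
  # it interpolates the training set but still generalizes imperfectly —
  # the small-data overfitting regime that motivates augmentation)
  held_out <- separable_toy_samples(100, w = 5, seed = 32, margin = 0.1)
  for (fam in c("cnn", "lstm", "cnn_lstm")) {
    n_train <- if (fam == "cnn") 1000 else 200
    train_m <- separable_toy_samples(n_train, w = 5, seed = 31, margin = 0.1)
    accs <- vapply(1:3, function(s) {
      m <- fit_adherence_model(train_m, architecture_spec(fam, 5),
                               training_config(epochs = 100, seed = s))
      mean(predict(m, held_out, type = "label") == held_out$label)
    }, numeric(1))
    expect_true(all(accs >= 0.95))
  }
})

test_that("analytic gradients match finite differences for every family", {
  withr::with_seed(55, {
    for (fam in c("cnn", "lstm", "cnn_lstm")) {
      for (w in c(2, 5, 10)) {
        spec <- architecture_spec(fam, w)
        model <- build_model(spec, seed = 3)
        X <- array(runif(w * 4 * 4), dim = c(w, 4, 4))
        y <- c(0, 1, 1, 0)
        arch <- dailyadhere:::arch_for_cpp(spec)
        fc <- dailyadhere:::family_code(fam)
        ag <- dailyadhere:::cpp_loss_grad(fc, X, y, model$weights, arch)
        for (i in seq_along(model$weights)) {
          for (j in sample(length(model$weights[[i]]),
                           min(3, length(model$weights[[i]])))) {
            h <- 1e-5
            wp <- model$weights
            wp[[i]][j] <- wp[[i]][j] + h
            wm <- model$weights
            wm[[i]][j] <- wm[[i]][j] - h
            num <- (dailyadhere:::cpp_loss_grad(fc, X, y, wp, arch)$loss -
                    dailyadhere:::cpp_loss_grad(fc, X, y, wm, arch)$loss) /
                   (2 * h)
            ana <- ag$grad[[i]][j]
            expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
          }
        }
      }
    }
  })
})

test_that("single-class training warns and collapses predictions", {
  train <- separable_toy_samples(30, w = 4, seed = 3)
  train$label <- 1L
  expect_warning(
    m <- fit_adherence_model(train, architecture_spec("cnn", 4),
                             training_config(epochs = 50)),
    "all 30 training labels are 1"
  )
  expect_true(all(predict(m, train) > 0.9))
})

test_that("hard calls respect the threshold with an inclusive boundary", {
  model <- build_model(architecture_spec("cnn", 4), seed = 2)
  x <- matrix(0.3, 4, 4)
  p <- predict(model, x)
  expect_identical(predict_label(model, x, threshold = p), 1L)
  expect_identical(predict_label(model, x, threshold = p + 1e-9), 0L)
  # labels are a monotone function of the probability for any threshold
  for (thr in c(0.1, 0.5, 0.9)) {
    expect_identical(predict(model, x, type = "label", threshold = thr),
                     as.integer(p >= thr))
  }
})

test_that("shape mismatches and bad configs are rejected", {
  model <- build_model(architecture_spec("cnn", 5), seed = 1)
  expect_error(predict(model, matrix(0, 4, 4)), "expected 5 x 4")
  expect_error(predict(model, matrix(0, 5, 3)), "expected 5 x 4")
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(training_config(decision_threshold = 1), "strictly between")
  expect_error(fit_adherence_model(separable_toy_samples(0, seed = 1),
                                   architecture_spec("cnn", 5)),
               "non-empty|no samples")
})
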
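model_families <- c("cnn", "lstm", "cnn_lstm")

conv_len <- function(L, k) L - min(k, L) + 1L
# a pool stage that would empty the sequence degrades to the identity
pool_len <- function(L, p) if (L %/% p >= 1L) L %/% p else L

#' Architecture of a per-participant sequence classifier
#'
#' Describes one of the three small architectures used for next-day
#' adherence prediction.  All map a `window_size x 4` feature window to a
#' single sigmoid probability:
#'
#' * `cnn` — two blocks of 1-D convolution (64 filters of width 2, valid
#'   mode, stride 1) followed by max pooling (pool 2), then flatten, a
#'   32-unit dense layer and the sigmoid output.
#' * `lstm` — a single 32-unit LSTM layer (standard forget/input/output
#'   gates); the final hidden state feeds a 32-unit dense layer and the
#'   sigmoid output.
#' * `cnn_lstm` — the window is cut into two contiguous subsequences
#'   (one for windows shorter than 4 days), each encoded by a shared
#'   1-D convolution block (32 filters of width 2, max pool 2, flatten);
#'   the subsequence encodings are consumed in order by a 32-unit LSTM
#'   whose final state feeds the sigmoid output.
#'
#' Short windows degrade gracefully: a convolution whose input is shorter
#' than the kernel shrinks its kernel to the input length, and a pool stage
#' that would empty the sequence becomes a no-op, so every family accepts
#' any window size in the estimation clamp range.
#'
#' @param family One of `"cnn"`, `"lstm"`, `"cnn_lstm"`.
#' @param window_size Lookback length in days.
#' @param n_features Number of predictors per day.
#' @param conv_filters Number of convolution filters (default 64 for `cnn`,
#'   32 for `cnn_lstm`).
#' @param kernel_size Convolution kernel width.
#' @param pool_size Max-pooling width.
#' @param dense_units Width of the dense layer.
#' @param lstm_units Number of LSTM units.
#' @return A list of class `architecture_spec` including the derived layer
#'   dimensions.
#' @export
architecture_spec <- function(family, window_size, n_features = 4,
                              conv_filters = if (family == "cnn") 64 else 32,
                              kernel_size = 2, pool_size = 2,
                              dense_units = 32, lstm_units = 32) {
  if (!family %in% model_families) {
    abort(sprintf("unknown model family %s; must be one of %s",
                  paste(deparse(family), collapse = ""),
                  paste(model_families, collapse = ", ")))
  }
  w <- as.integer(window_size)
  if (w < 2) abort("`window_size` must be at least 2")
  if (family == "cnn" && w < kernel_size) {
    abort("`window_size` must be at least `kernel_size` for the cnn family")
  }
  dims <- list()
  if (family == "cnn") {
    k1 <- min(kernel_size, w)
    L1 <- conv_len(w, k1)
    L1p <- pool_len(L1, pool_size)
    k2 <- min(kernel_size, L1p)
    L2 <- conv_len(L1p, k2)
    L2p <- pool_len(L2, pool_size)
    dims <- list(k1 = k1, L1 = L1, L1p = L1p, k2 = k2, L2 = L2, L2p = L2p,
                 flat = L2p * conv_filters)
  } else if (family == "cnn_lstm") {
    n_sub <- if (w >= 4) 2L else 1L
    sub_len <- as.integer(ceiling(w / n_sub))
    k1 <- min(kernel_size, sub_len)
    L <- conv_len(sub_len, k1)
    Lp <- pool_len(L, pool_size)
    dims <- list(n_sub = n_sub, sub_len = sub_len, k1 = k1, L = L, Lp = Lp,
                 flat = Lp * conv_filters)
  }
  structure(
    list(family = family, window_size = w, n_features = as.integer(n_features),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         dense_units = as.integer(dense_units),
         lstm_units = as.integer(lstm_units),
         dims = dims),
    class = "architecture_spec"
  )
}

#' Training hyperparameters
#'
#' Training always minimizes binary cross-entropy (forced by the sigmoid
#' output) with the Adam optimizer.
#'
#' @param learning_rate Adam step size.
#' @param epochs Number of full passes over the training set.
#' @param batch_size Mini-batch size.
#' @param weight_decay Decoupled (AdamW-style) weight-decay coefficient,
#'   applied to weight matrices but not biases; 0 (the default) disables
#'   it.  If used, note the effective strength depends on the number of
#'   optimizer steps: the cumulative shrink factor is roughly
#'   `(1 - learning_rate * weight_decay)^steps`.
#' @param decision_threshold Probability cutoff for [predict_label()]; the
#'   boundary counts as the positive (adherent) class.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, epochs = 100,
                            batch_size = 16, weight_decay = 0,
                            decision_threshold = 0.5,
                            seed = 1L) {
  assert_positive_scalar(learning_rate, "learning_rate")
  if (epochs < 1) abort("`epochs` must be at least 1")
  if (batch_size < 1) abort("`batch_size` must be at least 1")
  assert_positive_scalar(weight_decay, "weight_decay", strict = FALSE)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    abort("`decision_threshold` must lie strictly between 0 and 1")
  }
  structure(
    list(learning_rate = as.numeric(learning_rate),
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         weight_decay = as.numeric(weight_decay),
         decision_threshold = as.numeric(decision_threshold),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

zeros <- function(n) matrix(0, n, 1)

lstm_block_weights <- function(d_in, H) {
  gates <- lapply(1:4, function(i) glorot(H + d_in, H))
  biases <- c(list(matrix(1, H, 1)),          # forget-gate bias starts open
              lapply(1:3, function(i) zeros(H)))
  c(gates, biases)
}

init_weights <- function(spec) {
  f <- spec$n_features
  F_ <- spec$conv_filters
  D <- spec$dense_units
  H <- spec$lstm_units
  d <- spec$dims
  switch(spec$family,
    cnn = list(
      glorot(d$k1 * f, F_), zeros(F_),
      glorot(d$k2 * F_, F_), zeros(F_),
      glorot(d$flat, D), zeros(D),
      glorot(D, 1), zeros(1)
    ),
    lstm = c(
      lstm_block_weights(f, H),
      list(glorot(H, D), zeros(D), glorot(D, 1), zeros(1))
    ),
    cnn_lstm = c(
      list(glorot(d$k1 * f, F_), zeros(F_)),
      lstm_block_weights(d$flat, H),
      list(glorot(H, 1), zeros(1))
    )
  )
}

# which parameter tensors weight decay applies to (never biases)
decay_mask <- function(spec) {
  switch(spec$family,
    cnn = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    lstm = c(rep(TRUE, 4), rep(FALSE, 4), TRUE, FALSE, TRUE, FALSE),
    cnn_lstm = c(TRUE, FALSE, rep(TRUE, 4), rep(FALSE, 4), TRUE, FALSE)
  )
}

arch_for_cpp <- function(spec) {
  d <- spec$dims
  list(pool = spec$pool_size,
       k1 = d$k1 %||% 0L,
       k2 = d$k2 %||% 0L,
       lstm_units = spec$lstm_units,
       n_sub = d$n_sub %||% 1L,
       sub_len = d$sub_len %||% spec$window_size)
}

family_code <- function(family) match(family, model_families)

#' Build an untrained per-participant classifier
#'
#' Initializes the architecture's parameters (Glorot-uniform weight
#' matrices, zero biases, forget-gate biases at 1) under the given seed.
#' The result can be used with [predict()] immediately — the sigmoid output
#' is a valid probability before training — or passed to
#' [fit_adherence_model()].
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `adherence_model` with `trained = FALSE`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  weights <- with_seed(seed, init_weights(spec))
  structure(
    list(spec = spec, weights = weights, trained = FALSE, history = numeric(),
         config = NULL, n_train = 0L),
    class = "adherence_model"
  )
}

samples_to_cube <- function(samples, spec) {
  feats <- if (is.data.frame(samples)) samples$features else samples
  if (is.matrix(feats)) feats <- list(feats)
  n <- length(feats)
  if (n == 0) abort("no samples supplied")
  cube <- array(0, dim = c(spec$window_size, spec$n_features, n))
  for (i in seq_len(n)) {
    m <- feats[[i]]
    if (!is.matrix(m) || nrow(m) != spec$window_size ||
        ncol(m) != spec$n_features) {
      abort(sprintf(
        "sample %d has shape %s, expected %d x %d",
        i, paste(dim(m), collapse = " x "),
        spec$window_size, spec$n_features))
    }
    if (any(!is.finite(m))) {
      abort(sprintf("sample %d contains non-finite feature values", i))
    }
    cube[, , i] <- m
  }
  cube
}

#' Train a per-participant adherence classifier
#'
#' Minimizes binary cross-entropy with Adam over the (possibly augmented)
#' training samples of one participant.  Training is deterministic given
#' `config$seed`, which drives both the parameter initialization and the
#' per-epoch shuffling.
#'
#' @param samples Training samples: a tibble with a `features` list-column
#'   of `window_size x 4` matrices and a binary `label` column (the `train`
#'   element of a [supervised_split][make_supervised], optionally passed
#'   through [augment_samples()]).
#' @param spec An [architecture_spec()] matching the sample shape.
#' @param config A [training_config()].
#' @return An `adherence_model` with learned weights and a per-epoch
#'   training-loss `history`.
#' @export
fit_adherence_model <- function(samples, spec, config = training_config()) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(config, "training_config"))
  if (nrow(samples) == 0) abort("`samples` must be non-empty")
  y <- as.numeric(samples$label)
  if (!all(y %in% c(0, 1))) abort("labels must be 0/1")
  if (length(unique(y)) == 1) {
    warn(sprintf(
      "all %d training labels are %d: predictions will collapse toward that class",
      length(y), unique(y)))
  }
  cube <- samples_to_cube(samples, spec)
  n <- dim(cube)[3]
  fitted <- with_seed(config$seed, {
    weights <- init_weights(spec)
    perms <- t(vapply(seq_len(config$epochs), function(e) sample.int(n),
                      integer(n)))
    cpp_fit(family_code(spec$family), cube, y, weights, arch_for_cpp(spec),
            config$epochs, config$batch_size, config$learning_rate,
            config$weight_decay, decay_mask(spec), perms)
  })
  structure(
    list(spec = spec, weights = fitted$weights, trained = TRUE,
         history = as.numeric(fitted$history), config = config,
         n_train = n, label_mean = mean(y)),
    class = "adherence_model"
  )
}

#' Predict next-day adherence probabilities or labels
#'
#' @param object An `adherence_model`.
#' @param new_data A tibble with a `features` list-column, a list of
#'   matrices, or a single `window_size x 4` matrix.
#' @param type `"prob"` for probabilities, `"label"` for hard 0/1 calls.
#' @param threshold Probability cutoff used for `type = "label"`; a
#'   probability exactly at the threshold is called adherent.
#' @param ... Unused.
#' @return A numeric vector of probabilities in (0, 1), or an integer
#'   vector of 0/1 labels.
#' @export
predict.adherence_model <- function(object, new_data,
                                    type = c("prob", "label"),
                                    threshold = NULL, ...) {
  type <- match.arg(type)
  cube <- samples_to_cube(new_data, object$spec)
  probs <- as.numeric(cpp_predict(family_code(object$spec$family), cube,
                                  object$weights, arch_for_cpp(object$spec)))
  if (type == "prob") return(probs)
  thr <- threshold %||% object$config$decision_threshold %||% 0.5
  as.integer(probs >= thr)
}

#' @rdname predict.adherence_model
#' @param model An `adherence_model`.
#' @export
predict_proba <- function(model, new_data) {
  predict(model, new_data, type = "prob")
}

#' @rdname predict.adherence_model
#' @export
predict_label <- function(model, new_data, threshold = 0.5) {
  predict(model, new_data, type = "label", threshold = threshold)
}

#' @export
print.adherence_model <- function(x, ...) {
  cat(sprintf("<adherence_model> %s, window %d x %d features%s\n",
              x$spec$family, x$spec$window_size, x$spec$n_features,
              if (x$trained) {
                sprintf(", trained on %d samples (%d epochs, final loss %.4f)",
                        x$n_train, length(x$history),
                        x$history[length(x$history)])
              } else " (untrained)"))
  invisible(x)
}

#' Tidy summaries of a fitted adherence model
#'
#' `tidy()` returns one row per parameter tensor (its role and size);
#' `glance()` returns a one-row model summary.
#'
#' @param x,... An `adherence_model`; further arguments are ignored.
#' @return A tibble.
#' @export
tidy.adherence_model <- function(x, ...) {
  names_by_family <- list(
    cnn = c("conv1_kernel", "conv1_bias", "conv2_kernel", "conv2_bias",
            "dense_kernel", "dense_bias", "output_kernel", "output_bias"),
    lstm = c("lstm_w_forget", "lstm_w_input", "lstm_w_output", "lstm_w_cell",
             "lstm_b_forget", "lstm_b_input", "lstm_b_output", "lstm_b_cell",
             "dense_kernel", "dense_bias", "output_kernel", "output_bias"),
    cnn_lstm = c("conv_kernel", "conv_bias",
                 "lstm_w_forget", "lstm_w_input", "lstm_w_output",
                 "lstm_w_cell", "lstm_b_forget", "lstm_b_input",
                 "lstm_b_output", "lstm_b_cell",
                 "output_kernel", "output_bias")
  )
  nm <- names_by_family[[x$spec$family]]
  tibble(
    term = nm,
    rows = vapply(x$weights, nrow, integer(1)),
    cols = vapply(x$weights, ncol, integer(1)),
    n_parameters = vapply(x$weights, length, integer(1))
  )
}

#' @rdname tidy.adherence_model
#' @export
glance.adherence_model <- function(x, ...) {
  tibble(
    family = x$spec$family,
    window_size = x$spec$window_size,
    n_features = x$spec$n_features,
    n_parameters = sum(vapply(x$weights, length, integer(1))),
    trained = x$trained,
    n_train = x$n_train,
    epochs = length(x$history),
    initial_loss = if (x$trained) x$history[1] else NA_real_,
    final_loss = if (x$trained) x$history[length(x$history)] else NA_real_
  )
}
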
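augmentation_techniques <- c("none", "jitter", "scaling", "time_warp",
                             "jitter_time_warp", "scaling_time_warp")

#' Configuration of the time-series augmentation operators
#'
#' Parameters for the three transform-based augmentation operators and their
#' stacked combinations.  The noise scales follow the convention of the
#' transform-based augmentation literature for unit-scaled features: jitter
#' adds per-timestep Gaussian noise with standard deviation `sigma_jitter`;
#' scaling multiplies each feature column by one draw of
#' `N(1, sigma_scaling^2)`; time warping resamples each window along a
#' smooth monotone warp path built from a cubic spline through knots with
#' heights drawn from `N(1, sigma_warp^2)`.
#'
#' @param technique One of `"none"`, `"jitter"`, `"scaling"`, `"time_warp"`,
#'   `"jitter_time_warp"`, `"scaling_time_warp"`.  The stacked variants apply
#'   jitter (or scaling) first, then time warping.
#' @param sigma_jitter Jitter noise standard deviation.
#' @param sigma_scaling Scaling-factor standard deviation.
#' @param sigma_warp Warp-knot-height standard deviation.
#' @param n_knots Number of interior knots of the warping spline.
#' @param folds Number of synthetic copies of the training set to generate;
#'   5 folds make the augmented set 6 times the original size.
#' @param seed Integer seed.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(technique = "none",
                                sigma_jitter = 0.01,
                                sigma_scaling = 0.1,
                                sigma_warp = 0.2,
                                n_knots = 4,
                                folds = 5,
                                seed = 1L) {
  if (!is.character(technique) || length(technique) != 1 ||
      !technique %in% augmentation_techniques) {
    abort(sprintf("unknown augmentation technique %s; must be one of %s",
                  paste(deparse(technique), collapse = ""),
                  paste(augmentation_techniques, collapse = ", ")))
  }
  for (s in c("sigma_jitter", "sigma_scaling", "sigma_warp")) {
    assert_positive_scalar(get(s), s, strict = FALSE)
  }
  if (n_knots < 1) abort("`n_knots` must be at least 1")
  if (folds < 0) abort("`folds` must be non-negative")
  structure(
    list(technique = technique,
         sigma_jitter = as.numeric(sigma_jitter),
         sigma_scaling = as.numeric(sigma_scaling),
         sigma_warp = as.numeric(sigma_warp),
         n_knots = as.integer(n_knots),
         folds = as.integer(folds),
         seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

#' Augmentation operators on a single window
#'
#' Each operator takes a `window x features` matrix and returns a deformed
#' matrix of the same shape; the adherence label of a sample is never
#' touched.  `jitter_window()` adds independent `N(0, sigma^2)` noise to
#' every entry.  `scale_window()` draws one factor `alpha ~ N(1, sigma^2)`
#' per feature column and multiplies the whole column.  `time_warp_window()`
#' deforms the window in time: knot heights `~ N(1, sigma^2)` at evenly
#' spaced positions (endpoints included) define, through a natural cubic
#' spline, a smooth positive speed curve; its cumulative sum, rescaled to
#' fix both endpoints, is a strictly increasing warp path `tau` mapping
#' `[1, w]` onto itself, and every feature is linearly resampled at
#' `tau(t)`.  The same path warps all features of the window so their
#' temporal alignment is preserved.
#'
#' @param features Numeric matrix, time steps in rows, features in columns.
#' @param sigma Noise scale; 0 gives the identity transform (for the warp,
#'   up to interpolation round-off).
#' @param n_knots Number of interior spline knots.
#' @return A matrix of the same shape as `features`.
#' @export
jitter_window <- function(features, sigma = 0.01) {
  stopifnot(is.matrix(features), sigma >= 0)
  features + matrix(rnorm(length(features), 0, sigma),
                    nrow(features), ncol(features))
}

#' @rdname jitter_window
#' @export
scale_window <- function(features, sigma = 0.1) {
  stopifnot(is.matrix(features), sigma >= 0)
  alpha <- rnorm(ncol(features), 1, sigma)
  sweep(features, 2, alpha, "*")
}

#' @rdname jitter_window
#' @export
time_warp_window <- function(features, sigma = 0.2, n_knots = 4) {
  stopifnot(is.matrix(features), sigma >= 0, n_knots >= 1)
  w <- nrow(features)
  if (w < 2) abort("time warping needs a window of at least 2 time steps")
  knot_pos <- seq(1, w, length.out = n_knots + 2)
  knot_height <- rnorm(n_knots + 2, 1, sigma)
  tau <- warp_path(w, knot_pos, knot_height)
  apply(features, 2, function(col) approx(seq_len(w), col, xout = tau)$y)
}

# Strictly increasing warp path over 1..w from spline-interpolated knot
# heights; the speed curve is floored at a small positive value so a large
# negative spline excursion can never fold time back on itself.
warp_path <- function(w, knot_pos, knot_height, floor_speed = 1e-3) {
  speed <- splinefun(knot_pos, knot_height, method = "natural")(seq_len(w))
  speed <- pmax(speed, floor_speed)
  cum <- cumsum(speed)
  tau <- 1 + (w - 1) * (cum - cum[1]) / (cum[w] - cum[1])
  # pin the endpoints against floating-point drift so resampling never
  # reads outside [1, w]
  tau <- pmin(pmax(tau, 1), w)
  tau[1] <- 1
  tau[w] <- w
  tau
}

apply_technique <- function(features, config) {
  switch(config$technique,
    jitter = jitter_window(features, config$sigma_jitter),
    scaling = scale_window(features, config$sigma_scaling),
    time_warp = time_warp_window(features, config$sigma_warp, config$n_knots),
    jitter_time_warp = time_warp_window(
      jitter_window(features, config$sigma_jitter),
      config$sigma_warp, config$n_knots),
    scaling_time_warp = time_warp_window(
      scale_window(features, config$sigma_scaling),
      config$sigma_warp, config$n_knots),
    abort(sprintf("unknown augmentation technique: %s", config$technique))
  )
}

#' Expand a training set with augmented copies
#'
#' Appends `folds` synthetic copies of the training samples, each produced by
#' applying the configured technique to an original sample (originals are
#' cycled uniformly, so every fold deforms every original exactly once).
#' Labels are carried over unchanged: the deformations are label-preserving
#' by construction.  With `technique = "none"` or `folds = 0` the input is
#' returned untouched.
#'
#' @param samples A tibble of window samples (columns `target_day`, `label`,
#'   `features`), normally the `train` element of a
#'   [supervised_split][make_supervised].
#' @param config An [augmentation_config()].
#' @return A tibble with `(folds + 1) * nrow(samples)` rows (originals first,
#'   flagged by the logical column `is_synthetic`).
#' @export
#' @examples
#' \dontrun{
#' augmented <- augment_samples(split$train,
#'                              augmentation_config("jitter_time_warp"))
#' }
augment_samples <- function(samples, config) {
  stopifnot(inherits(config, "augmentation_config"))
  originals <- mutate(samples, is_synthetic = FALSE)
  if (config$technique == "none" || config$folds == 0 || nrow(samples) == 0) {
    return(originals)
  }
  n <- nrow(samples)
  synth_idx <- rep(seq_len(n), times = config$folds)
  synth <- with_seed(config$seed, {
    samples[synth_idx, ] |>
      mutate(features = purrr::map(.data$features, apply_technique,
                                   config = config),
             is_synthetic = TRUE)
  })
  bind_rows(originals, synth)
}
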
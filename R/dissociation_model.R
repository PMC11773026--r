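#' Piecewise-linear dissociation-rate model
#'
#' The formin dissociation rate is constant at a basal value while fewer
#' than two-thirds of polymerized subunits arrive via FH1-mediated delivery,
#' and rises linearly in the FH1-delivered fraction above that threshold:
#' `k_off(f) = k_basal` for `f <= threshold`, and
#' `k_basal + slope * (f - threshold)` above it (continuous at the
#' threshold by construction).
#'
#' Defaults are the published model parameters: basal rate 0.0039 s^-1,
#' slope 0.02 s^-1 per unit fraction, threshold 2/3. The threshold is stored
#' as the exact rational 2/3; pass `threshold = 0.67` to replay arithmetic
#' done with the rounded printed value.
#'
#' @param k_basal Basal dissociation rate (s^-1, > 0).
#' @param slope Rate increase per unit FH1 fraction above threshold
#'   (s^-1, >= 0).
#' @param threshold FH1-fraction threshold, in (0, 1).
#' @return An object of class `dissociation_model`.
#' @examples
#' m <- dissociation_model()
#' predict_koff(c(0.5, 0.77), m)
#' @export
dissociation_model <- function(k_basal = 0.0039, slope = 0.02,
                               threshold = 2 / 3) {
  stopifnot(is.numeric(k_basal), is.numeric(slope), is.numeric(threshold))
  if (k_basal <= 0) stop("k_basal must be > 0")
  if (slope < 0) stop("slope must be >= 0")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(k_basal = k_basal, slope = slope, threshold = threshold),
            class = "dissociation_model")
}

#' @export
print.dissociation_model <- function(x, ...) {
  cat(sprintf(
    "Piecewise dissociation model: k_off = %g s^-1 below f = %.4g, then %g + %g * (f - %.4g) s^-1\n",
    x$k_basal, x$threshold, x$k_basal, x$slope, x$threshold))
  invisible(x)
}

#' Predicted dissociation rate at an FH1-delivered fraction
#'
#' @param f_fh1 FH1-delivered fraction(s) in `[0, 1]`.
#' @param model A [dissociation_model()].
#' @return Dissociation rate(s), s^-1.
#' @export
predict_koff <- function(f_fh1, model = dissociation_model()) {
  stopifnot(inherits(model, "dissociation_model"), is.numeric(f_fh1))
  if (any(f_fh1 < 0 | f_fh1 > 1))
    stop("f_fh1 must be in [0, 1]")
  model$k_basal + model$slope * pmax(f_fh1 - model$threshold, 0)
}

#' Fit the piecewise dissociation model at a fixed threshold
#'
#' The slope comes from ordinary least squares on the points with FH1
#' fraction above the threshold (unconstrained straight line, as in the
#' published analysis); the basal rate is the mean dissociation rate of the
#' points at or below it. The threshold itself is held fixed, not estimated.
#'
#' @param f_fh1 FH1-delivered fractions.
#' @param k_off Dissociation rates (s^-1), same length.
#' @param threshold Fixed threshold (default 2/3).
#' @return A [dissociation_model()] carrying the fitted `k_basal` and
#'   `slope`, with attributes `n_below`, `n_above`, `se_slope` and
#'   `intercept_above` (intercept of the unconstrained upper-line fit).
#' @export
fit_piecewise <- function(f_fh1, k_off, threshold = 2 / 3) {
  stopifnot(is.numeric(f_fh1), is.numeric(k_off),
            length(f_fh1) == length(k_off))
  if (any(f_fh1 < 0 | f_fh1 > 1)) stop("f_fh1 must be in [0, 1]")
  above <- f_fh1 > threshold
  if (sum(above) < 2)
    stop("fit_piecewise needs at least 2 points above the threshold (got ",
         sum(above), ")")
  if (sum(!above) < 1)
    stop("fit_piecewise needs at least 1 point at or below the threshold")
  upper <- stats::lm(k_off[above] ~ f_fh1[above])
  slope <- unname(stats::coef(upper)[2])
  # suppress summary.lm's note on exactly collinear (noiseless) points
  se_slope <- if (sum(above) > 2)
    unname(suppressWarnings(sqrt(diag(stats::vcov(upper))))[2]) else NA_real_
  model <- dissociation_model(k_basal = mean(k_off[!above]),
                              slope = max(slope, 0), threshold = threshold)
  attr(model, "n_below") <- sum(!above)
  attr(model, "n_above") <- sum(above)
  attr(model, "se_slope") <- se_slope
  attr(model, "slope_raw") <- slope
  attr(model, "intercept_above") <- unname(stats::coef(upper)[1])
  model
}

#' Relative increase in dissociation rate over an FH1-fraction interval
#'
#' Percentage change of the predicted dissociation rate when the
#' FH1-delivered fraction rises from `f0` to `f0 + delta_f`. With the
#' default model, a 10-percentage-point rise starting at the threshold
#' increases the rate by about 50%.
#'
#' @param model A [dissociation_model()].
#' @param f0 Starting fraction.
#' @param delta_f Increase in fraction (may be 0).
#' @return Percent change, `100 * (k(f0 + delta_f) - k(f0)) / k(f0)`.
#' @examples
#' relative_rate_increase(dissociation_model(), 2 / 3, 0.10)
#' @export
relative_rate_increase <- function(model, f0, delta_f) {
  k0 <- predict_koff(f0, model)
  k1 <- predict_koff(f0 + delta_f, model)
  100 * (k1 - k0) / k0
}

#' Probability of consecutive FH1-mediated deliveries
#'
#' If each incoming subunit is FH1-delivered independently with probability
#' `f_fh1`, the chance that `runs` consecutive additions are all
#' FH1-delivered is `f_fh1 ^ runs`. At the two-thirds threshold the chance
#' of two consecutive deliveries is just under one half, the proposed
#' mechanistic reading of the threshold: destabilization sets in when
#' back-to-back deliveries become the dominant addition pattern.
#'
#' @param f_fh1 FH1-delivered fraction(s) in `[0, 1]`.
#' @param runs Number of consecutive deliveries (default 2).
#' @return Probability in `[0, 1]`.
#' @examples
#' consecutive_delivery_probability(0.67)
#' @export
consecutive_delivery_probability <- function(f_fh1, runs = 2) {
  stopifnot(is.numeric(f_fh1), runs >= 1)
  if (any(f_fh1 < 0 | f_fh1 > 1)) stop("f_fh1 must be in [0, 1]")
  f_fh1^runs
}

#' Serialize or restore a dissociation model as JSON
#'
#' @param model A [dissociation_model()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json A JSON string or file path to read from.
#' @return `dissociation_model_to_json()` returns the JSON string (or writes
#'   the file); `dissociation_model_from_json()` returns the model.
#' @export
dissociation_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "dissociation_model"))
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname dissociation_model_to_json
#' @export
dissociation_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  dissociation_model(k_basal = x$k_basal, slope = x$slope,
                     threshold = x$threshold)
}
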
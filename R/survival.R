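#' Convert a formin run length to a run time
#'
#' A formin that polymerized `subunits` actin subunits at a constant
#' elongation rate stayed bound for `subunits / elongation_rate` seconds.
#'
#' @param subunits Run length in subunits (>= 0). Vectorized.
#' @param elongation_rate Elongation rate in subunits/s (> 0).
#' @return Run time in seconds.
#' @examples
#' run_time_from_length(5300, 18.55)
#' @export
run_time_from_length <- function(subunits, elongation_rate) {
  stopifnot(is.numeric(subunits), is.numeric(elongation_rate))
  if (any(subunits < 0)) stop("subunits must be >= 0")
  if (any(elongation_rate <= 0)) stop("elongation_rate must be > 0")
  subunits / elongation_rate
}

#' Convert a filament length in micrometers to subunits
#'
#' Uses the standard conversion of 370 actin subunits per micrometer of
#' filament. Returns a real value; rounding is left to the caller.
#'
#' @param length_um Filament length (um, >= 0). Vectorized.
#' @param subunits_per_um Conversion factor (default 370 subunits/um).
#' @return Length in subunits.
#' @export
subunits_from_um <- function(length_um, subunits_per_um = 370) {
  stopifnot(is.numeric(length_um))
  if (any(length_um < 0)) stop("length_um must be >= 0")
  length_um * subunits_per_um
}

#' Validate and complete a filament records table
#'
#' Canonicalizes a per-filament observation table. Required columns:
#' `condition_id`, `elongation_rate` (subunits/s), and at least one of
#' `run_length_subunits` or `run_length_um` (converted at 370 subunits/um).
#' `run_time` is derived from length and rate when absent; `censored`
#' defaults to `FALSE`. Optional fluorescence columns `formin_intensity`
#' and `control_intensity` are preserved.
#'
#' @param df A data.frame, one row per filament.
#' @return A validated data.frame with columns `condition_id`,
#'   `run_length_subunits`, `run_length_um`, `elongation_rate`, `run_time`,
#'   `censored`, plus any fluorescence columns present.
#' @export
as_filament_records <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"condition_id" %in% names(df)) df$condition_id <- "unspecified"
  if (!"elongation_rate" %in% names(df)) {
    if ("elongation_rate_sub_s" %in% names(df)) {
      df$elongation_rate <- df$elongation_rate_sub_s
      df$elongation_rate_sub_s <- NULL
    } else stop("records need an elongation_rate column (subunits/s)")
  }
  if (!"run_length_subunits" %in% names(df)) {
    if (!"run_length_um" %in% names(df))
      stop("records need run_length_subunits or run_length_um")
    df$run_length_subunits <- subunits_from_um(df$run_length_um)
  }
  if (!"run_length_um" %in% names(df))
    df$run_length_um <- df$run_length_subunits / 370
  if (!"censored" %in% names(df)) df$censored <- FALSE
  df$censored <- as.logical(df$censored)
  if (!"run_time" %in% names(df))
    df$run_time <- run_time_from_length(df$run_length_subunits,
                                        df$elongation_rate)
  if (any(df$run_length_subunits < 0)) stop("run lengths must be >= 0")
  if (any(df$elongation_rate <= 0)) stop("elongation rates must be > 0")
  rel_err <- abs(df$run_time - df$run_length_subunits / df$elongation_rate) /
    pmax(df$run_time, .Machine$double.eps)
  if (any(rel_err > 1e-6))
    warning("run_time inconsistent with run_length/elongation_rate for ",
            sum(rel_err > 1e-6), " record(s)")
  df
}

#' Read or write a filament records CSV
#'
#' Plain-CSV serialization of a per-filament table; `read_filament_csv()`
#' canonicalizes through [as_filament_records()].
#'
#' @param path File path.
#' @param records A filament records data.frame.
#' @return `read_filament_csv()` returns the records data.frame;
#'   `write_filament_csv()` returns `path` invisibly.
#' @export
read_filament_csv <- function(path) {
  as_filament_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_filament_csv
#' @export
write_filament_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Build an empirical survival curve of run lengths or run times
#'
#' The survival curve gives, for each observed value, the fraction of
#' formin-filament interactions lasting at least that long (in subunits for
#' the length domain, seconds for the time domain). Under a constant
#' dissociation hazard it is a single exponential.
#'
#' Two estimators are available. `method = "exclude"` drops censored records
#' (filaments still formin-bound at the end of observation) and computes the
#' plain empirical survivor function of the complete runs; this mirrors the
#' experimental practice of only measuring filaments with a visible
#' dim-to-bright transition, but is biased when censoring is heavy.
#' `method = "km"` uses the Kaplan-Meier estimator over all records,
#' treating censored runs as right-censored observations; it is the correct
#' choice for simulator output, where late-nucleated filaments have short
#' observation windows.
#'
#' @param records A filament records data.frame (see
#'   [as_filament_records()]) or a bare numeric vector of uncensored values.
#' @param domain `"length"` (run length, subunits) or `"time"` (run time, s).
#' @param method `"exclude"` (default) or `"km"`.
#' @return An object of class `survival_curve`: list with `domain`, `values`
#'   (strictly increasing), `surv` (non-increasing fractions, first = 1),
#'   `n_observations`, `n_censored`, `method`.
#' @export
build_survival_curve <- function(records, domain = c("length", "time"),
                                 method = c("exclude", "km")) {
  domain <- match.arg(domain)
  method <- match.arg(method)
  if (is.numeric(records)) {
    values <- records
    censored <- rep(FALSE, length(values))
  } else {
    records <- as_filament_records(records)
    values <- if (domain == "length") records$run_length_subunits
              else records$run_time
    censored <- records$censored
  }
  n_cens <- sum(censored)
  if (sum(!censored) < 2)
    stop("survival curve needs at least 2 uncensored records (got ",
         sum(!censored), ")")

  if (method == "exclude") {
    if (n_cens > 0)
      message(n_cens, " censored record(s) excluded from survival curve")
    x <- values[!censored]
    n <- length(x)
    tab <- table(x)
    v <- as.numeric(names(tab))
    # fraction of runs with value >= v_i
    surv <- rev(cumsum(rev(as.numeric(tab)))) / n
  } else {
    km <- survival::survfit(survival::Surv(values, !censored) ~ 1)
    ev <- km$n.event > 0
    v <- km$time[ev]
    # fraction surviving >= v_i is the KM estimate just before v_i
    surv <- c(1, utils::head(km$surv[ev], -1))
    n <- sum(!censored)
  }
  structure(list(domain = domain, values = v, surv = surv,
                 n_observations = n, n_censored = n_cens, method = method),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "Survival curve (%s domain, %s estimator): %d points, %d observations, %d censored\n",
    x$domain, x$method, length(x$values), x$n_observations, x$n_censored))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ..., log_y = TRUE) {
  xlab <- if (x$domain == "length") "Run length (subunits)" else
    "Run time (s)"
  plot(x$values, x$surv, log = if (log_y) "y" else "", xlab = xlab,
       ylab = "Fraction surviving", pch = 16, cex = 0.4, ...)
  invisible(x)
}

#' Fit a single exponential to a survival curve
#'
#' Unweighted nonlinear least squares of `A * exp(-rate * x)` to the points
#' of a survival curve, with the amplitude free. A free amplitude absorbs
#' the under-representation of short runs in experimental data, which pushes
#' the y-intercept above 1; for the same reason the first point is omitted
#' by default in the length domain. Starting values come from a log-linear
#' regression. The 95% CI is the Gaussian approximation from the fit
#' covariance; because survival points are cumulative and therefore highly
#' correlated, this interval understates sampling error (use
#' [fit_exponential_mle()] for a calibrated interval).
#'
#' @param curve A `survival_curve` from [build_survival_curve()].
#' @param omit_first Drop the first point before fitting. Default `TRUE` in
#'   the length domain, `FALSE` in the time domain.
#' @return An object of class `survival_fit`: `rate` (per subunit or per
#'   second), `mean` (= 1/rate), `amplitude`, `se_rate`, `ci95_rate`,
#'   `n_used`, `omitted_first_point`, `domain`, `method`.
#' @export
fit_survival_exponential <- function(curve, omit_first = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  if (is.null(omit_first)) omit_first <- curve$domain == "length"
  v <- curve$values
  s <- curve$surv
  if (omit_first && length(v) > 1) {
    v <- v[-1]; s <- s[-1]
  }
  if (length(v) < 4)
    stop("exponential fit needs at least 4 survival points after omission (",
         length(v), " available)")
  if (all(s == s[1]))
    stop("degenerate survival curve: all fractions identical")

  pos <- s > 0
  start_fit <- stats::lm(log(s[pos]) ~ v[pos])
  r0 <- max(-unname(stats::coef(start_fit)[2]), 1e-12)
  a0 <- exp(unname(stats::coef(start_fit)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ A * exp(-r * v),
                      start = list(A = a0, r = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("exponential fit failed for ", curve$domain,
           "-domain survival curve: ", conditionMessage(e)))
  co <- stats::coef(fit)
  if (co["r"] <= 0)
    stop("exponential fit returned a non-positive rate for the ",
         curve$domain, "-domain curve")
  se <- sqrt(diag(stats::vcov(fit)))["r"]
  structure(list(
    rate = unname(co["r"]), mean = unname(1 / co["r"]),
    amplitude = unname(co["A"]), se_rate = unname(se),
    ci95_rate = unname(co["r"] + c(-1, 1) * 1.96 * se),
    n_used = length(v), omitted_first_point = omit_first,
    domain = curve$domain, method = "nls-survival"),
    class = "survival_fit")
}

#' Censoring-aware exponential maximum-likelihood fit
#'
#' MLE of a constant hazard from possibly right-censored durations:
#' `rate = events / total observed duration`. Its 95% CI uses the exact
#' asymptotics of the exponential likelihood on the log scale,
#' `rate * exp(+/- 1.96 / sqrt(events))`, and is well calibrated (unlike
#' the covariance interval of the survival-curve fit).
#'
#' @param values Durations (run times, or run lengths for a per-subunit
#'   rate).
#' @param censored Logical vector; `TRUE` marks right-censored durations.
#' @return A `survival_fit` with `amplitude = NA`.
#' @export
fit_exponential_mle <- function(values, censored = NULL) {
  stopifnot(is.numeric(values))
  if (is.null(censored)) censored <- rep(FALSE, length(values))
  stopifnot(length(censored) == length(values))
  d <- sum(!censored)
  if (d < 2) stop("exponential MLE needs at least 2 events")
  total <- sum(values)
  if (total <= 0) stop("total observed duration must be > 0")
  rate <- d / total
  ci <- rate * exp(c(-1, 1) * 1.96 / sqrt(d))
  structure(list(rate = rate, mean = 1 / rate, amplitude = NA_real_,
                 se_rate = rate / sqrt(d), ci95_rate = ci, n_used = d,
                 omitted_first_point = FALSE, domain = "time",
                 method = "mle"),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  unit <- if (x$domain == "length") "subunit" else "s"
  cat(sprintf(
    "Single-exponential %s fit (%s domain):\n  rate %.6g per %s (95%% CI %.6g-%.6g)\n  mean %.6g %s%s; amplitude %.4g; n = %d%s\n",
    x$method, x$domain, x$rate, unit, x$ci95_rate[1], x$ci95_rate[2],
    x$mean, unit, if (x$domain == "length") "s" else "",
    x$amplitude, x$n_used,
    if (x$omitted_first_point) "; first point omitted" else ""))
  invisible(x)
}

#' Convert dissociation rates to per-increment probabilities
#'
#' A constant hazard `k` implies a dissociation probability over one
#' increment of `1 - exp(-k * increment)`: one FH2 step for the per-step
#' probability, `dt` seconds for the per-time probability.
#' `rate_from_p_off()` is the exact inverse, `-log(1 - p) / increment`.
#'
#' @param k_off_step Dissociation rate per FH2 step (>= 0).
#' @param k_off_time Dissociation rate per second (>= 0).
#' @param dt Time increment in seconds (> 0; simulations use 0.01 s).
#' @param p_off Per-increment dissociation probability in `[0, 1)`.
#' @param increment Increment size the probability refers to (1 step, or
#'   `dt` seconds).
#' @return A probability in `[0, 1)`, or a rate for `rate_from_p_off()`.
#' @examples
#' p_off_step_from_rate(1 / 5300)
#' p_off_time_from_rate(0.0035, dt = 0.01)
#' @export
p_off_step_from_rate <- function(k_off_step) {
  stopifnot(is.numeric(k_off_step))
  if (any(k_off_step < 0)) stop("k_off_step must be >= 0")
  -expm1(-k_off_step)
}

#' @rdname p_off_step_from_rate
#' @export
p_off_time_from_rate <- function(k_off_time, dt = 0.01) {
  stopifnot(is.numeric(k_off_time), is.numeric(dt))
  if (any(k_off_time < 0)) stop("k_off_time must be >= 0")
  if (any(dt <= 0)) stop("dt must be > 0")
  -expm1(-k_off_time * dt)
}

#' @rdname p_off_step_from_rate
#' @export
rate_from_p_off <- function(p_off, increment = 1) {
  stopifnot(is.numeric(p_off))
  if (any(p_off < 0 | p_off >= 1)) stop("p_off must be in [0, 1)")
  if (any(increment <= 0)) stop("increment must be > 0")
  -log1p(-p_off) / increment
}

#' Per-step dissociation rate from a per-time rate
#'
#' The FH2 domain takes one step per added subunit, so a temporal
#' dissociation rate divides by the elongation rate to give the rate per
#' FH2 step.
#'
#' @param k_off_time Dissociation rate (s^-1, >= 0).
#' @param elongation_rate Elongation rate (subunits/s, > 0).
#' @return Dissociation rate per FH2 step.
#' @examples
#' k_step_from_k_time(0.0035, 17.5)
#' @export
k_step_from_k_time <- function(k_off_time, elongation_rate) {
  stopifnot(is.numeric(k_off_time), is.numeric(elongation_rate))
  if (any(k_off_time < 0)) stop("k_off_time must be >= 0")
  if (any(elongation_rate <= 0)) stop("elongation_rate must be > 0")
  k_off_time / elongation_rate
}
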
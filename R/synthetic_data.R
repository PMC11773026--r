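#' Specify a synthetic observation scenario
#'
#' A scenario bundles the true (generating) parameters for one experimental
#' condition: the dissociation hazard, the elongation-rate distribution, the
#' FH1-delivered fraction encoded in the fluorescence, and the observation
#' window. [generate_observations()] turns it into a per-filament table with
#' the statistical structure the analysis assumes: exponential lifetimes,
#' Gaussian per-filament elongation rates, run lengths tied to lifetimes
#' through the elongation rate, and fluorescence ratios whose inversion
#' recovers the FH1 fraction.
#'
#' @param condition A [reaction_condition()].
#' @param true_k_off Generating dissociation rate (s^-1, > 0).
#' @param elongation_rate_mean Mean elongation rate (subunits/s, > 0).
#' @param elongation_rate_sd SD of per-filament elongation rates
#'   (subunits/s, >= 0).
#' @param true_fh1_fraction Generating FH1-delivered fraction, `[0, 1]`.
#' @param fluorescence_noise_sd Relative SD of multiplicative fluorescence
#'   noise (>= 0).
#' @param n_filaments Number of filaments (>= 1).
#' @param censor_time Observation window (s); lifetimes beyond it are
#'   right-censored. Default `Inf` (no censoring).
#' @param detection_filter Drop runs shorter than `detection_min_subunits`,
#'   emulating the difficulty of quantifying short dim stretches (default
#'   `FALSE`).
#' @param detection_min_subunits Detection threshold in subunits (default
#'   500).
#' @param seed Integer seed for reproducible generation.
#' @param label Condition identifier stamped on the records.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(condition, true_k_off, elongation_rate_mean,
                          elongation_rate_sd = 0, true_fh1_fraction = 0,
                          fluorescence_noise_sd = 0, n_filaments = 1000,
                          censor_time = Inf, detection_filter = FALSE,
                          detection_min_subunits = 500, seed = NULL,
                          label = NULL) {
  stopifnot(inherits(condition, "reaction_condition"))
  if (true_k_off <= 0) stop("true_k_off must be > 0")
  if (elongation_rate_mean <= 0) stop("elongation_rate_mean must be > 0")
  if (elongation_rate_sd < 0) stop("elongation_rate_sd must be >= 0")
  if (true_fh1_fraction < 0 || true_fh1_fraction > 1)
    stop("true_fh1_fraction must be in [0, 1]")
  if (fluorescence_noise_sd < 0) stop("fluorescence_noise_sd must be >= 0")
  if (n_filaments < 1) stop("n_filaments must be >= 1")
  if (censor_time <= 0) stop("censor_time must be > 0")
  if (is.null(label))
    label <- sprintf("%s_%s_p%g_a%g", condition$profilin_isoform,
                     condition$formin_construct, condition$profilin_total,
                     condition$actin_unlabeled + condition$actin_labeled)
  structure(list(
    condition = condition, true_k_off = true_k_off,
    elongation_rate_mean = elongation_rate_mean,
    elongation_rate_sd = elongation_rate_sd,
    true_fh1_fraction = true_fh1_fraction,
    fluorescence_noise_sd = fluorescence_noise_sd,
    n_filaments = as.integer(n_filaments), censor_time = censor_time,
    detection_filter = detection_filter,
    detection_min_subunits = detection_min_subunits, seed = seed,
    label = label),
    class = "scenario_spec")
}

# truncated-normal elongation rates (> 0), by rejection
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

#' Generate a synthetic per-filament observation table
#'
#' Lifetimes are drawn from an exponential distribution with the scenario's
#' dissociation rate and right-censored at the observation window;
#' per-filament elongation rates are Gaussian truncated at zero; run lengths
#' are elongation rate times bound lifetime. Fluorescence intensities are
#' generated so the dimming inversion returns the scenario's FH1-delivered
#' fraction: the unlabeled fraction is `f / (1 + g)` with `g` the
#' labeled/unlabeled profilin-actin ratio of the condition (shared-pool
#' equilibrium), the normalized intensity is one minus that, and
#' multiplicative Gaussian noise is applied to both segment intensities.
#' Deterministic for a fixed seed.
#'
#' @param spec A [scenario_spec()].
#' @return A filament records data.frame (see [as_filament_records()]) with
#'   fluorescence columns `formin_intensity` and `control_intensity`.
#' @export
generate_observations <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_filaments

  lifetime <- stats::rexp(n, spec$true_k_off)
  censored <- lifetime > spec$censor_time
  obs_time <- pmin(lifetime, spec$censor_time)
  rate <- rtnorm_pos(n, spec$elongation_rate_mean, spec$elongation_rate_sd)
  len <- rate * obs_time

  g <- pa_label_ratio(solve_shared_profilin(spec$condition))
  black_true <- spec$true_fh1_fraction / (1 + g)
  norm_true <- 1 - black_true
  base <- 100
  control <- base * pmax(1 + stats::rnorm(n, 0, spec$fluorescence_noise_sd),
                         1e-3)
  formin <- base * norm_true *
    pmax(1 + stats::rnorm(n, 0, spec$fluorescence_noise_sd), 1e-3)

  records <- data.frame(
    condition_id = spec$label, run_length_subunits = len,
    run_length_um = len / 370, elongation_rate = rate, run_time = obs_time,
    censored = censored, formin_intensity = formin,
    control_intensity = control)
  if (isTRUE(spec$detection_filter)) {
    kept <- records$run_length_subunits >= spec$detection_min_subunits
    message(sum(!kept), " run(s) below the ", spec$detection_min_subunits,
            "-subunit detection threshold dropped")
    records <- records[kept, ]
  }
  as_filament_records(records)
}

#' Preset scenarios for the standard condition grid
#'
#' Builds scenario specs spanning the experimental condition grid: Sc
#' profilin (Kd 2.9/29 uM) at 0.5-20 uM with 0.75 and 1 uM actin, human
#' profilin-1 (Kd 0.1/1.0 uM) at 0.25-5 uM with 0.75 uM actin, and the
#' FH1FH2, PCPD-FH2 and FH1FH2-C constructs. Each preset's generating
#' dissociation rate comes from the piecewise model evaluated at the
#' preset's FH1-delivered fraction, so a piecewise fit across presets can
#' recover the model parameters end-to-end.
#'
#' True per-condition elongation rates and FH1 fractions are not tabulated
#' anywhere; the presets use representative placeholder maps (elongation
#' rate proportional to the profilin-actin concentration, anchored at
#' 18.55 subunits/s for 5 uM Sc profilin with 0.75 uM actin; FH1 fraction a
#' saturating function of profilin-actin) and should be treated as
#' plausible, not authoritative.
#'
#' @param model Generating [dissociation_model()].
#' @param n_filaments Filaments per preset (default 12000).
#' @param seed Base seed; preset `i` gets `seed + i`.
#' @return A list of [scenario_spec()] objects.
#' @export
condition_presets <- function(model = dissociation_model(),
                              n_filaments = 12000, seed = 100) {
  conditions <- list()
  for (actin in c(0.75, 1)) {
    for (p in c(0.5, 1, 2.5, 5, 10, 20))
      conditions[[length(conditions) + 1L]] <- sc_condition(p, actin)
  }
  for (p in c(0.25, 0.5, 1, 2.5, 5))
    conditions[[length(conditions) + 1L]] <- hs_condition(p, 0.75)
  for (p in c(1, 5, 10)) {
    conditions[[length(conditions) + 1L]] <-
      sc_condition(p, 0.75, formin_construct = "PCPD-FH2")
    conditions[[length(conditions) + 1L]] <-
      sc_condition(p, 0.75, formin_construct = "FH1FH2-C")
  }

  anchor_pa <- solve_shared_profilin(sc_condition(5, 0.75))$pa_total
  lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    pa <- solve_shared_profilin(cond)$pa_total
    # PCPD-FH2 delivers profilin-actin less efficiently: lower FH1 share
    # and slower elongation than the intact FH1 at the same concentrations
    eff <- if (cond$formin_construct == "PCPD-FH2") 0.5 else 1
    f <- eff * pa / (pa + 0.08)
    rate <- max(18.55 * eff * pa / anchor_pa, 1)
    scenario_spec(
      condition = cond, true_k_off = predict_koff(f, model),
      elongation_rate_mean = rate, elongation_rate_sd = 0.1 * rate,
      true_fh1_fraction = f, fluorescence_noise_sd = 0.02,
      n_filaments = n_filaments, seed = seed + i)
  })
}
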
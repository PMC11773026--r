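#' Configuration for a stochastic filament-population simulation
#'
#' Parameterizes a population of independently elongating formin-bound
#' filaments. In `per_time` mode each increment lasts `dt` seconds and adds
#' `elongation_rate * dt` subunits; in `per_step` mode each increment is one
#' FH2 step adding one subunit (lasting `1 / elongation_rate` seconds). At
#' every increment the formin dissociates with probability `p_off`
#' (dissociation is tested before elongating, so a formin that dissociates
#' on its first increment leaves a run length of 0 in `per_step` mode).
#'
#' Defaults follow the published simulation protocol: 12,000 filaments over
#' a 1200 s reaction with dt = 0.01 s, an initial pool of 20% of the
#' filaments present at t = 0, and the remainder nucleating at a constant
#' 8 filaments/s (2400 + 8 x 1200 = 12,000). A pool/nucleation combination
#' that does not add up to `n_filaments` is allowed but warned about.
#'
#' @param n_filaments Total filaments to nucleate (default 12000).
#' @param duration Reaction duration in seconds (default 1200).
#' @param dt Time increment in seconds for `per_time` mode (default 0.01).
#' @param mode `"per_time"` or `"per_step"`.
#' @param elongation_rate Elongation rate (subunits/s).
#' @param p_off Dissociation probability per increment, in `[0, 1)`.
#' @param nucleation_rate Filaments nucleated per second after t = 0
#'   (default 8).
#' @param initial_pool_fraction Fraction of filaments present at t = 0
#'   (default 0.20).
#' @param nucleation_schedule `"uniform"` (evenly spaced arrivals, default)
#'   or `"poisson"` (exponential inter-arrival times).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param record_censored Keep filaments still formin-bound at the end of
#'   the reaction in the output records (flagged `censored = TRUE`)? Default
#'   `FALSE`: they are counted but not listed.
#' @param fast_path Sample each filament's increment count directly from the
#'   geometric distribution (default) instead of drawing one uniform number
#'   per increment. The two are distributionally identical; the literal loop
#'   is retained for validation.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_filaments = 12000, duration = 1200,
                              dt = 0.01, mode = c("per_time", "per_step"),
                              elongation_rate, p_off, nucleation_rate = 8,
                              initial_pool_fraction = 0.20,
                              nucleation_schedule = c("uniform", "poisson"),
                              seed = NULL, record_censored = FALSE,
                              fast_path = TRUE) {
  mode <- match.arg(mode)
  nucleation_schedule <- match.arg(nucleation_schedule)
  if (n_filaments < 1) stop("n_filaments must be >= 1")
  if (duration <= 0) stop("duration must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (elongation_rate <= 0) stop("elongation_rate must be > 0")
  if (p_off < 0 || p_off >= 1) stop("p_off must be in [0, 1)")
  if (nucleation_rate < 0) stop("nucleation_rate must be >= 0")
  if (initial_pool_fraction < 0 || initial_pool_fraction > 1)
    stop("initial_pool_fraction must be in [0, 1]")
  expected <- initial_pool_fraction * n_filaments +
    nucleation_rate * duration
  if (abs(expected - n_filaments) > 0.5)
    warning(sprintf(
      "initial pool (%g) + nucleation (%g/s x %g s) = %g filaments, not n_filaments = %d",
      initial_pool_fraction * n_filaments, nucleation_rate, duration,
      expected, n_filaments), call. = FALSE)
  structure(list(
    n_filaments = as.integer(n_filaments), duration = duration, dt = dt,
    mode = mode, elongation_rate = elongation_rate, p_off = p_off,
    nucleation_rate = nucleation_rate,
    initial_pool_fraction = initial_pool_fraction,
    nucleation_schedule = nucleation_schedule, seed = seed,
    record_censored = record_censored, fast_path = fast_path),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d filaments, %g s, %s mode (dt %g s), elongation %g sub/s, p_off %.4g\n  nucleation: %g%% initial pool + %g filaments/s (%s schedule)%s\n",
    x$n_filaments, x$duration, x$mode, x$dt, x$elongation_rate, x$p_off,
    100 * x$initial_pool_fraction, x$nucleation_rate, x$nucleation_schedule,
    if (is.null(x$seed)) "" else sprintf("; seed %d", x$seed)))
  invisible(x)
}

# Number of completed increments before dissociation, drawn one uniform per
# increment (the literal algorithm): test u < p_off, dissociate on success,
# elongate on failure. Chunked draws keep the sequential semantics.
literal_increment_count <- function(p_off, max_incr, chunk = 4096L) {
  if (p_off <= 0) return(list(n_incr = max_incr, censored = TRUE))
  done <- 0
  while (done < max_incr) {
    m <- min(chunk, max_incr - done)
    u <- stats::runif(m)
    hit <- which(u < p_off)
    if (length(hit) > 0)
      return(list(n_incr = done + hit[1] - 1, censored = FALSE))
    done <- done + m
  }
  list(n_incr = max_incr, censored = TRUE)
}

#' Simulate a single formin-bound filament
#'
#' Runs the per-increment dissociation/elongation scheme for one filament
#' with a time budget of `t_available` seconds. Returns the resulting
#' filament record as a one-row data.frame.
#'
#' @param p_off Dissociation probability per increment, `[0, 1)`.
#' @param mode `"per_time"` or `"per_step"`.
#' @param elongation_rate Elongation rate (subunits/s).
#' @param dt Time increment (s), used in `per_time` mode.
#' @param t_available Time budget (s, > 0).
#' @param fast_path Sample the increment count from the geometric
#'   distribution instead of looping over uniform draws.
#' @return One-row data.frame with `run_length_subunits`, `elongation_rate`,
#'   `run_time`, `censored`.
#' @export
simulate_filament <- function(p_off, mode = c("per_time", "per_step"),
                              elongation_rate, dt = 0.01, t_available,
                              fast_path = TRUE) {
  mode <- match.arg(mode)
  if (p_off < 0 || p_off >= 1) stop("p_off must be in [0, 1)")
  if (t_available <= 0) stop("t_available must be > 0")
  if (elongation_rate <= 0) stop("elongation_rate must be > 0")
  max_incr <- if (mode == "per_time") floor(t_available / dt)
              else floor(t_available * elongation_rate)
  if (fast_path) {
    if (p_off == 0) {
      n_incr <- max_incr; censored <- TRUE
    } else {
      m <- stats::rgeom(1, p_off)
      censored <- m >= max_incr
      n_incr <- min(m, max_incr)
    }
  } else {
    res <- literal_increment_count(p_off, max_incr)
    n_incr <- res$n_incr; censored <- res$censored
  }
  if (mode == "per_time") {
    run_time <- n_incr * dt
    len <- n_incr * elongation_rate * dt
  } else {
    len <- n_incr
    run_time <- n_incr / elongation_rate
  }
  data.frame(run_length_subunits = len, elongation_rate = elongation_rate,
             run_time = run_time, censored = censored)
}

nucleation_times <- function(config) {
  n_init <- round(config$initial_pool_fraction * config$n_filaments)
  n_rest <- config$n_filaments - n_init
  if (n_rest == 0) return(rep(0, n_init))
  if (config$nucleation_rate <= 0) {
    warning("nucleation_rate is 0 with filaments left to nucleate; ",
            "starting them at t = 0", call. = FALSE)
    return(rep(0, config$n_filaments))
  }
  later <- if (config$nucleation_schedule == "poisson") {
    cumsum(stats::rexp(n_rest, config$nucleation_rate))
  } else {
    # evenly spaced arrivals at the midpoints of the 1/rate intervals, so a
    # schedule that exactly fills the reaction keeps every filament inside it
    ((1:n_rest) - 0.5) / config$nucleation_rate
  }
  c(rep(0, n_init), later)
}

#' Simulate a population of formin-bound filaments
#'
#' Nucleates `n_filaments` filaments (an initial pool at t = 0, the rest on
#' the configured schedule), simulates each independently with its remaining
#' time budget `duration - t_nucleated`, and records run lengths and run
#' times. Filaments still formin-bound when the reaction ends are censored;
#' they are counted always and listed in the records only when
#' `record_censored = TRUE`. Output is deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param condition_id Label stamped on the output records.
#' @return An object of class `sim_result`: list with `records` (filament
#'   records data.frame), `n_dissociated`, `n_censored`, `n_nucleated`, and
#'   `config`.
#' @examples
#' cfg <- simulation_config(n_filaments = 200, duration = 300,
#'                          elongation_rate = 18.55,
#'                          p_off = p_off_time_from_rate(0.0035),
#'                          nucleation_rate = 0.5,
#'                          initial_pool_fraction = 0.25, seed = 7)
#' simulate_population(cfg)
#' @export
simulate_population <- function(config, condition_id = "simulated") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  t0 <- nucleation_times(config)
  keep <- t0 < config$duration
  if (any(!keep)) {
    warning(sum(!keep), " filament(s) scheduled at or after the end of the",
            " reaction were not nucleated", call. = FALSE)
    t0 <- t0[keep]
  }
  n <- length(t0)
  t_avail <- config$duration - t0
  max_incr <- if (config$mode == "per_time") floor(t_avail / config$dt)
              else floor(t_avail * config$elongation_rate)

  if (config$p_off == 0) {
    m <- rep(Inf, n)
  } else if (config$fast_path) {
    m <- stats::rgeom(n, config$p_off)
  } else {
    m <- vapply(max_incr, function(mx)
      literal_increment_count(config$p_off, mx)$n_incr + 0, numeric(1))
    # literal path already caps at max_incr; mark censored via equality below
  }
  censored <- m >= max_incr
  n_incr <- pmin(m, max_incr)

  if (config$mode == "per_time") {
    run_time <- n_incr * config$dt
    len <- n_incr * config$elongation_rate * config$dt
  } else {
    len <- n_incr
    run_time <- n_incr / config$elongation_rate
  }
  records <- data.frame(
    filament_id = seq_len(n), condition_id = condition_id,
    t_nucleated = t0, run_length_subunits = len,
    run_length_um = len / 370,
    elongation_rate = config$elongation_rate, run_time = run_time,
    censored = censored)
  if (!config$record_censored) records <- records[!records$censored, ]

  structure(list(records = records, n_dissociated = sum(!censored),
                 n_censored = sum(censored), n_nucleated = n,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Simulated population: %d nucleated, %d dissociated, %d still bound at %g s\n",
    x$n_nucleated, x$n_dissociated, x$n_censored, x$config$duration))
  invisible(x)
}

#' Simulate replicate populations
#'
#' Runs `n_replicates` independent populations; replicate `i` uses seed
#' `config$seed + i` so the set is reproducible and replicates are
#' independent.
#'
#' @param config A [simulation_config()] with a non-`NULL` seed.
#' @param n_replicates Number of replicates (default 10).
#' @return List of `sim_result`.
#' @export
simulate_replicates <- function(config, n_replicates = 10) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  if (is.null(config$seed))
    stop("simulate_replicates needs a seeded config")
  lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    simulate_population(cfg)
  })
}

# Survival-fit summaries of a filament record table. Uses the Kaplan-Meier
# curve when censored records are present so truncated observation windows
# do not bias the fitted rates.
fit_records <- function(recs, omit_first_length = TRUE) {
  if (sum(!recs$censored) < 4)
    stop("too few dissociation events to fit (", sum(!recs$censored), ")")
  method <- if (any(recs$censored)) "km" else "exclude"
  fr <- as_filament_records(recs)
  time_fit <- fit_survival_exponential(
    build_survival_curve(fr, "time", method = method), omit_first = FALSE)
  len_fit <- fit_survival_exponential(
    build_survival_curve(fr, "length", method = method),
    omit_first = omit_first_length)
  list(time = time_fit, length = len_fit, method = method)
}

fit_simulated_population <- function(result, omit_first_length = TRUE) {
  fit_records(result$records, omit_first_length)
}

#' Summarize one or more simulated populations
#'
#' Fits single exponentials to the run-length and lifetime survival curves
#' of each replicate (Kaplan-Meier curves when censored filaments are in
#' the records) and reports the fitted dissociation rate and mean run
#' length, with mean and SD across replicates when there are several.
#'
#' @param results A `sim_result` or a list of them (e.g. from
#'   [simulate_replicates()]).
#' @param omit_first_length Omit the first point of the length-domain
#'   survival curve before fitting (default `TRUE`).
#' @return A list with `per_replicate` (data.frame: `fitted_k_off`,
#'   `mean_run_length`, `n_dissociated`, `n_censored`) and `summary`
#'   (means and SDs across replicates; SDs are `NA` for a single
#'   replicate).
#' @export
summarize_population <- function(results, omit_first_length = TRUE) {
  if (inherits(results, "sim_result")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "sim_result")))
  rows <- lapply(seq_along(results), function(i) {
    fits <- fit_simulated_population(results[[i]], omit_first_length)
    data.frame(replicate = i, fitted_k_off = fits$time$rate,
               mean_run_length = fits$length$mean,
               n_dissociated = results[[i]]$n_dissociated,
               n_censored = results[[i]]$n_censored)
  })
  per_replicate <- do.call(rbind, rows)
  n_rep <- nrow(per_replicate)
  summary <- list(
    mean_k_off = mean(per_replicate$fitted_k_off),
    sd_k_off = if (n_rep > 1) stats::sd(per_replicate$fitted_k_off)
               else NA_real_,
    mean_run_length = mean(per_replicate$mean_run_length),
    sd_run_length = if (n_rep > 1) stats::sd(per_replicate$mean_run_length)
                    else NA_real_,
    n_replicates = n_rep)
  list(per_replicate = per_replicate, summary = summary)
}

#' Sweep simulated run lengths over FH1 fraction and elongation rate
#'
#' For each combination of elongation rate and FH1-delivered fraction, the
#' piecewise dissociation model sets the hazard, which is converted to a
#' per-time dissociation probability (`1 - exp(-k * dt)`), a population is
#' simulated, and the mean run length and dissociation rate are recovered
#' from survival fits. Below the threshold the hazard is flat, so mean run
#' lengths depend only on the elongation rate; above it they fall as
#' FH1-mediated delivery dominates.
#'
#' @param elongation_rates Elongation rates to sweep (subunits/s).
#' @param f_grid FH1-delivered fractions to sweep, in `[0, 1]`.
#' @param model A [dissociation_model()].
#' @param config A [simulation_config()] template; its `mode`, `p_off` and
#'   `elongation_rate` are overridden per cell, and cell seeds are derived
#'   from `config$seed`.
#' @return data.frame with one row per (rate, fraction) cell:
#'   `elongation_rate`, `f_fh1`, `k_model`, `p_off_time`,
#'   `mean_run_length`, `fitted_k_off`, `n_dissociated`.
#' @export
simulate_fh1_sweep <- function(elongation_rates, f_grid,
                               model = dissociation_model(), config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(elongation_rates <= 0)) stop("elongation rates must be > 0")
  if (any(f_grid < 0 | f_grid > 1)) stop("f_grid must be in [0, 1]")
  grid <- expand.grid(f_fh1 = f_grid, elongation_rate = elongation_rates)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$f_fh1[i]; r <- grid$elongation_rate[i]
    k <- predict_koff(f, model)
    cfg <- config
    cfg$mode <- "per_time"
    cfg$elongation_rate <- r
    cfg$p_off <- p_off_time_from_rate(k, cfg$dt)
    cfg$record_censored <- TRUE
    if (!is.null(config$seed)) cfg$seed <- config$seed + i
    res <- simulate_population(cfg)
    fits <- fit_simulated_population(res)
    data.frame(elongation_rate = r, f_fh1 = f, k_model = k,
               p_off_time = cfg$p_off, mean_run_length = fits$length$mean,
               fitted_k_off = fits$time$rate,
               n_dissociated = res$n_dissociated)
  })
  do.call(rbind, rows)
}
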
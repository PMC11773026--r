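#' Run the full processivity analysis pipeline
#'
#' Executes the stage sequence on a set of scenarios (or an existing
#' filament table): generate observations, solve per-condition equilibria,
#' compute FH1-delivered fractions, fit run-length and lifetime survival
#' curves, convert dissociation rates to per-step and per-time
#' probabilities, and fit the piecewise dissociation model across
#' conditions. Each stage writes a plain-text artifact (CSV or JSON) into
#' `out_dir`, and a `manifest.json` records the package version, seed,
#' stage outputs and their MD5 checksums, so a rerun with the same seed is
#' byte-identical. A stage failure halts the run with the failing stage
#' named; artifacts of completed stages are retained and listed in the
#' manifest.
#'
#' @param scenarios A list of [scenario_spec()] (default: a reduced
#'   [condition_presets()] grid). Ignored when `input_csv` is given.
#' @param input_csv Optional path to an existing filament records CSV; the
#'   generate stage then reads instead of simulating. Conditions in the file
#'   must match the scenario labels for the equilibria stage.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the manifest and used to re-seed
#'   the scenario generators (scenario `i` gets `seed + i`).
#' @param omit_first_length Omit the first survival point in length-domain
#'   fits (default `TRUE`).
#' @param threshold Piecewise-model threshold (default 2/3).
#' @param dt Time increment for per-time probabilities (default 0.01 s).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(scenarios = NULL, input_csv = NULL,
                         out_dir = "forminsim_run", seed = 1,
                         omit_first_length = TRUE, threshold = 2 / 3,
                         dt = 0.01) {
  if (is.null(scenarios))
    scenarios <- condition_presets(n_filaments = 2000, seed = seed)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- list(package = "forminsim",
                   version = as.character(utils::packageVersion("forminsim")),
                   seed = seed, stages = list())
  finish_stage <- function(name, files, info = NULL) {
    manifest$stages[[name]] <<- list(
      outputs = basename(files),
      md5 = unname(tools::md5sum(files)), info = info)
  }
  fail <- function(name, e) {
    manifest$stages[[name]] <<- list(error = conditionMessage(e))
    write_manifest(manifest, out_dir)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  out <- function(f) file.path(out_dir, f)

  ## stage 1: generate / ingest
  records <- tryCatch({
    if (!is.null(input_csv)) {
      read_filament_csv(input_csv)
    } else {
      do.call(rbind, lapply(seq_along(scenarios), function(i) {
        sp <- scenarios[[i]]
        sp$seed <- seed + i
        generate_observations(sp)
      }))
    }
  }, error = function(e) fail("generate", e))
  write_filament_csv(records, out("observations.csv"))
  finish_stage("generate", out("observations.csv"),
               info = list(n_filaments = nrow(records),
                           n_censored = sum(records$censored)))

  by_label <- stats::setNames(scenarios,
                              vapply(scenarios, `[[`, "", "label"))

  ## stage 2: equilibria per condition
  eq_tab <- tryCatch({
    do.call(rbind, lapply(names(by_label), function(lab) {
      cond <- by_label[[lab]]$condition
      st <- solve_shared_profilin(cond)
      data.frame(condition_id = lab,
                 profilin_isoform = cond$profilin_isoform,
                 formin_construct = cond$formin_construct,
                 actin_unlabeled = cond$actin_unlabeled,
                 actin_labeled = cond$actin_labeled,
                 profilin_total = cond$profilin_total,
                 pa_unlabeled = st$pa_unlabeled,
                 pa_labeled = st$pa_labeled, pa_total = st$pa_total,
                 profilin_free = st$profilin_free,
                 pa_label_ratio = pa_label_ratio(st))
    }))
  }, error = function(e) fail("equilibria", e))
  utils::write.csv(eq_tab, out("equilibria.csv"), row.names = FALSE)
  finish_stage("equilibria", out("equilibria.csv"))

  ## stage 3: FH1-delivered fractions
  fh1 <- tryCatch({
    ratios <- stats::setNames(eq_tab$pa_label_ratio, eq_tab$condition_id)
    fh1_condition_summary(records, ratios)
  }, error = function(e) fail("fh1_fractions", e))
  utils::write.csv(fh1$per_filament, out("fh1_per_filament.csv"),
                   row.names = FALSE)
  utils::write.csv(fh1$per_condition, out("fh1_by_condition.csv"),
                   row.names = FALSE)
  finish_stage("fh1_fractions",
               c(out("fh1_per_filament.csv"), out("fh1_by_condition.csv")))

  ## stage 4: survival fits per condition
  fits <- tryCatch({
    do.call(rbind, lapply(split(records, records$condition_id),
      function(recs) {
        f <- fit_records(recs, omit_first_length = omit_first_length)
        data.frame(condition_id = recs$condition_id[1],
                   k_off_time = f$time$rate,
                   k_off_ci_lo = f$time$ci95_rate[1],
                   k_off_ci_hi = f$time$ci95_rate[2],
                   mean_run_length = f$length$mean,
                   amplitude_length = f$length$amplitude,
                   elongation_rate = mean(recs$elongation_rate),
                   n_uncensored = sum(!recs$censored),
                   curve_method = f$method)
      }))
  }, error = function(e) fail("survival_fits", e))
  utils::write.csv(fits, out("survival_fits.csv"), row.names = FALSE)
  finish_stage("survival_fits", out("survival_fits.csv"))

  ## stage 5: dissociation probabilities
  probs <- tryCatch({
    k_step <- k_step_from_k_time(fits$k_off_time, fits$elongation_rate)
    data.frame(condition_id = fits$condition_id,
               k_off_time = fits$k_off_time, k_off_step = k_step,
               dt = dt, p_off_time = p_off_time_from_rate(fits$k_off_time, dt),
               p_off_step = p_off_step_from_rate(k_step))
  }, error = function(e) fail("probabilities", e))
  utils::write.csv(probs, out("probabilities.csv"), row.names = FALSE)
  finish_stage("probabilities", out("probabilities.csv"))

  ## stage 6: piecewise dissociation model across conditions
  model <- tryCatch({
    merged <- merge(fh1$per_condition, fits, by = "condition_id")
    fit_piecewise(merged$mean_fh1_total, merged$k_off_time,
                  threshold = threshold)
  }, error = function(e) fail("model_fit", e))
  dissociation_model_to_json(model, out("model.json"))
  finish_stage("model_fit", out("model.json"),
               info = list(k_basal = model$k_basal, slope = model$slope,
                           threshold = model$threshold))

  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Parameter-recovery experiment on synthetic data
#'
#' Generates `replicates` independent synthetic datasets from a scenario,
#' runs the survival analysis on each, and reports per-replicate recovered
#' parameters with bias and confidence-interval coverage against the
#' scenario's generating values. Coverage uses the calibrated event-count
#' interval of the censoring-aware exponential MLE (the covariance interval
#' of the curve fit is optimistic; see [fit_exponential_mle()]).
#'
#' @param spec A [scenario_spec()] with a non-`NULL` seed; replicate `i`
#'   uses `spec$seed + i`.
#' @param replicates Number of replicates (>= 1).
#' @return A list with `per_replicate` (data.frame: fitted and MLE rates,
#'   CI bounds, coverage flag, mean run length, recovered FH1 fraction) and
#'   `summary` (true values, mean estimates, relative bias, CI coverage;
#'   SDs absent for a single replicate).
#' @export
recover_experiment <- function(spec, replicates = 10) {
  stopifnot(inherits(spec, "scenario_spec"), replicates >= 1)
  if (is.null(spec$seed)) stop("recover_experiment needs a seeded scenario")
  g <- pa_label_ratio(solve_shared_profilin(spec$condition))

  rows <- lapply(seq_len(replicates), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i
    recs <- generate_observations(sp)
    fits <- fit_records(recs)
    mle <- fit_exponential_mle(recs$run_time, recs$censored)
    norm <- normalized_fluorescence(recs$formin_intensity,
                                    recs$control_intensity)
    fh1 <- suppressWarnings(fh1_fraction_total(norm, g))
    data.frame(replicate = i, k_off_fit = fits$time$rate,
               k_off_mle = mle$rate, ci_lo = mle$ci95_rate[1],
               ci_hi = mle$ci95_rate[2],
               covered = mle$ci95_rate[1] <= spec$true_k_off &
                 spec$true_k_off <= mle$ci95_rate[2],
               mean_run_length = fits$length$mean,
               fh1_total = mean(fh1$fh1_total))
  })
  per_replicate <- do.call(rbind, rows)
  n <- nrow(per_replicate)
  summary <- list(
    true_k_off = spec$true_k_off,
    true_fh1_fraction = spec$true_fh1_fraction,
    mean_k_off = mean(per_replicate$k_off_fit),
    sd_k_off = if (n > 1) stats::sd(per_replicate$k_off_fit) else NA_real_,
    bias_k_off = mean(per_replicate$k_off_fit) / spec$true_k_off - 1,
    ci_coverage = mean(per_replicate$covered),
    mean_fh1_total = mean(per_replicate$fh1_total),
    bias_fh1 = mean(per_replicate$fh1_total) - spec$true_fh1_fraction,
    n_replicates = n)
  list(per_replicate = per_replicate, summary = summary)
}
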
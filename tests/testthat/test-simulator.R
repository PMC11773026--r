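test_that("config validates and checks the nucleation bookkeeping", {
  expect_error(simulation_config(elongation_rate = 10, p_off = 1), "p_off")
  expect_error(simulation_config(elongation_rate = 0, p_off = 0.1), "> 0")
  expect_warning(
    simulation_config(n_filaments = 1000, duration = 1200,
                      elongation_rate = 10, p_off = 0.1),
    "not n_filaments")
  # paper defaults balance exactly: 2400 + 8/s x 1200 s = 12,000
  expect_silent(cfg <- simulation_config(elongation_rate = 10, p_off = 0.1))
  expect_equal(cfg$initial_pool_fraction * cfg$n_filaments +
                 cfg$nucleation_rate * cfg$duration, 12000)
})

test_that("single-filament simulation hits its degenerate limits", {
  set.seed(41)
  rec <- simulate_filament(0.999999, "per_step", elongation_rate = 10,
                           t_available = 100)
  expect_lte(rec$run_length_subunits, 1)
  expect_false(rec$censored)
  rec0 <- simulate_filament(0, "per_time", elongation_rate = 10, dt = 0.01,
                            t_available = 50)
  expect_true(rec0$censored)
  expect_equal(rec0$run_length_subunits, 10 * 50)
  expect_error(simulate_filament(1, "per_step", 10, t_available = 1),
               "p_off")
})

test_that("per-step run lengths match the geometric-distribution mean", {
  p <- 1.8866e-4
  cfg <- simulation_config(n_filaments = 12000, duration = 1e7,
                           mode = "per_step", elongation_rate = 1,
                           p_off = p, nucleation_rate = 0,
                           initial_pool_fraction = 1, seed = 42)
  res <- suppressWarnings(simulate_population(cfg))
  expect_equal(res$n_censored, 0)
  mean_true <- (1 - p) / p            # closed form, ~ 1/p ~ 5300
  se <- sqrt(1 - p) / p / sqrt(12000)
  expect_lt(abs(mean(res$records$run_length_subunits) - mean_true), 3 * se)
})

test_that("population runs are deterministic for a fixed seed", {
  cfg <- simulation_config(n_filaments = 500, duration = 600,
                           elongation_rate = 15, p_off = 1e-4,
                           nucleation_rate = 0.5,
                           initial_pool_fraction = 0.4, seed = 7,
                           record_censored = TRUE)
  a <- suppressWarnings(simulate_population(cfg))
  b <- suppressWarnings(simulate_population(cfg))
  expect_identical(a$records, b$records)
  cfg$seed <- 8
  c2 <- suppressWarnings(simulate_population(cfg))
  expect_false(identical(a$records, c2$records))
})

test_that("every nucleated filament is either dissociated or censored", {
  for (sched in c("uniform", "poisson")) {
    cfg <- simulation_config(n_filaments = 2000, duration = 1000,
                             elongation_rate = 12, p_off = 5e-4,
                             nucleation_rate = 1.6,
                             initial_pool_fraction = 0.2, seed = 11,
                             nucleation_schedule = sched,
                             record_censored = TRUE)
    res <- suppressWarnings(simulate_population(cfg))
    expect_equal(res$n_dissociated + res$n_censored, res$n_nucleated)
    expect_equal(nrow(res$records), res$n_nucleated)
    expect_true(all(res$records$run_length_subunits >= 0))
    expect_true(all(res$records$run_time <=
                      cfg$duration - res$records$t_nucleated + 1e-9))
  }
})

test_that("paper-default schedule nucleates exactly 12,000 filaments", {
  cfg <- simulation_config(elongation_rate = 18.55,
                           p_off = p_off_time_from_rate(0.0035), seed = 1)
  res <- simulate_population(cfg)
  expect_equal(res$n_nucleated, 12000)
})

test_that("fast path and literal loop draw the same distribution", {
  p <- 1e-3
  n <- 2000
  ks_p <- means_fast <- means_lit <- se2 <- numeric(20)
  for (s in 1:20) {
    cfg <- simulation_config(n_filaments = n, duration = 1e5,
                             mode = "per_step", elongation_rate = 1,
                             p_off = p, nucleation_rate = 0,
                             initial_pool_fraction = 1, seed = 1000 + s)
    fast <- suppressWarnings(simulate_population(cfg))
    cfg$fast_path <- FALSE
    cfg$seed <- 2000 + s
    lit <- suppressWarnings(simulate_population(cfg))
    x <- fast$records$run_length_subunits
    y <- lit$records$run_length_subunits
    ks_p[s] <- suppressWarnings(ks.test(x, y))$p.value
    means_fast[s] <- mean(x); means_lit[s] <- mean(y)
    se2[s] <- var(x) / length(x) + var(y) / length(y)
  }
  expect_lte(sum(ks_p <= 0.01), 2)
  within3se <- abs(means_fast - means_lit) <= 3 * sqrt(se2)
  expect_gte(sum(within3se), 18)
})

test_that("per-time lifetimes are exponential with the generating hazard", {
  for (k in c(0.0035, 0.0039, 0.0105)) {
    cfg <- simulation_config(elongation_rate = 15,
                             p_off = p_off_time_from_rate(k, 0.01),
                             seed = round(k * 1e6), record_censored = TRUE)
    res <- simulate_population(cfg)
    fit <- fit_survival_exponential(
      build_survival_curve(res$records, "time", method = "km"),
      omit_first = FALSE)
    mle <- fit_exponential_mle(res$records$run_time, res$records$censored)
    expect_true(mle$ci95_rate[1] <= k && k <= mle$ci95_rate[2])
    expect_equal(fit$rate, k, tolerance = 0.05)
  }
})

test_that("replicate summaries are deterministic and recover the hazard", {
  k <- 0.0035
  cfg <- simulation_config(n_filaments = 3000, duration = 1200,
                           elongation_rate = 18.55,
                           p_off = p_off_time_from_rate(k),
                           nucleation_rate = 2,
                           initial_pool_fraction = 0.2, seed = 50,
                           record_censored = TRUE)
  reps <- suppressWarnings(simulate_replicates(cfg, 10))
  s1 <- summarize_population(reps)
  reps2 <- suppressWarnings(simulate_replicates(cfg, 10))
  expect_identical(s1, summarize_population(reps2))
  expect_lt(abs(s1$summary$mean_k_off - k), 2 * s1$summary$sd_k_off)
  one <- summarize_population(reps[[1]])
  expect_true(is.na(one$summary$sd_k_off))
  tiny <- suppressWarnings(simulate_population(
    simulation_config(n_filaments = 3, duration = 1, dt = 0.5,
                      elongation_rate = 1, p_off = 0, nucleation_rate = 0,
                      initial_pool_fraction = 1, record_censored = TRUE)))
  expect_error(summarize_population(tiny), "too few")
})

test_that("sweep is flat below threshold and falls above it", {
  m <- dissociation_model()
  cfg <- simulation_config(n_filaments = 4000, duration = 1200,
                           elongation_rate = 15, p_off = 0.001,
                           nucleation_rate = 0, initial_pool_fraction = 1,
                           seed = 60)
  sw <- suppressWarnings(
    simulate_fh1_sweep(15, c(0, 0.3, 0.6, 0.5, 1.0), m, cfg))
  flat <- sw[sw$f_fh1 %in% c(0, 0.3, 0.6), ]
  se <- flat$mean_run_length / sqrt(flat$n_dissociated)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(flat$mean_run_length[i] - flat$mean_run_length[j]),
              3 * sqrt(se[i]^2 + se[j]^2))
  len_05 <- sw$mean_run_length[sw$f_fh1 == 0.5]
  len_10 <- sw$mean_run_length[sw$f_fh1 == 1.0]
  expect_lt(len_10, len_05)
  # hazards 0.0039 vs 0.010567: run length ratio is the inverse hazard ratio
  expect_equal(len_10 / len_05, 0.0039 / predict_koff(1, m),
               tolerance = 0.1)
})

test_that("run length scales with elongation rate at fixed hazard", {
  m <- dissociation_model()
  cfg <- simulation_config(n_filaments = 6000, duration = 1200,
                           elongation_rate = 15, p_off = 0.001,
                           nucleation_rate = 0, initial_pool_fraction = 1,
                           seed = 61)
  sw <- suppressWarnings(simulate_fh1_sweep(c(5, 35), 0.5, m, cfg))
  ratio <- sw$mean_run_length[sw$elongation_rate == 35] /
    sw$mean_run_length[sw$elongation_rate == 5]
  expect_equal(ratio, 7, tolerance = 0.05)
})
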
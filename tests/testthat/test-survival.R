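test_that("run time and length conversions follow the printed constants", {
  expect_equal(run_time_from_length(1000, 10), 100)
  expect_equal(run_time_from_length(0, 10), 0)
  # 5300 subunits at 18.55 sub/s is ~286 s, i.e. 1/0.0035 s^-1
  expect_equal(run_time_from_length(5300, 18.55), 285.7143,
               tolerance = 1e-6)
  expect_equal(run_time_from_length(5300, 18.55), 1 / 0.0035,
               tolerance = 0.001)
  expect_error(run_time_from_length(10, 0), "> 0")
  expect_equal(subunits_from_um(1), 370)
  expect_equal(subunits_from_um(0), 0)
  expect_equal(subunits_from_um(14.324), 5299.88)
  expect_error(subunits_from_um(-1), ">= 0")
})

test_that("empirical survival curve is the fraction at or beyond each value", {
  cv <- build_survival_curve(c(1, 2, 3), "time")
  expect_equal(cv$values, c(1, 2, 3))
  expect_equal(cv$surv, c(1, 2 / 3, 1 / 3))
  tied <- build_survival_curve(c(5, 5, 5), "time")
  expect_equal(tied$values, 5)
  expect_equal(tied$surv, 1)
  expect_error(build_survival_curve(3, "time"), "at least 2")
})

test_that("survival curve invariants hold and censored records are excluded", {
  recs <- make_records(c(1, 4, 2, 8, 3), censored = c(FALSE, FALSE, TRUE,
                                                      FALSE, FALSE))
  expect_message(cv <- build_survival_curve(recs, "time"), "1 censored")
  expect_equal(cv$n_observations, 4)
  expect_equal(cv$surv[1], 1)
  expect_true(all(diff(cv$surv) <= 0))
  expect_true(all(diff(cv$values) > 0))
  all_cens <- make_records(c(1, 2, 3), censored = TRUE)
  expect_error(build_survival_curve(all_cens, "time"), "at least 2")
})

test_that("log survival of an exponential sample is linear with slope -k", {
  set.seed(7)
  x <- rexp(5000, 1 / 286)
  cv <- build_survival_curve(x, "time")
  keep <- cv$surv > 0.01
  slope <- unname(coef(lm(log(cv$surv[keep]) ~ cv$values[keep]))[2])
  expect_equal(slope, -1 / 286, tolerance = 0.05)
})

test_that("exponential fit recovers noiseless curves exactly", {
  x <- seq(0, 30000, by = 250)
  cv <- structure(list(domain = "length", values = x,
                       surv = exp(-x / 5300), n_observations = length(x),
                       n_censored = 0, method = "exclude"),
                  class = "survival_curve")
  fit <- fit_survival_exponential(cv, omit_first = FALSE)
  expect_equal(fit$rate, 1 / 5300, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$mean * fit$rate, 1)
  cv$surv <- 1.3 * exp(-x / 5300)
  fit13 <- fit_survival_exponential(cv, omit_first = FALSE)
  expect_equal(fit13$amplitude, 1.3, tolerance = 1e-6)
  expect_equal(fit13$rate, 1 / 5300, tolerance = 1e-6)
})

test_that("first-point omission defaults on for length, off for time", {
  set.seed(8)
  recs <- make_records(rexp(50, 0.01))
  fit_len <- fit_survival_exponential(build_survival_curve(recs, "length"))
  fit_time <- fit_survival_exponential(build_survival_curve(recs, "time"))
  expect_true(fit_len$omitted_first_point)
  expect_false(fit_time$omitted_first_point)
})

test_that("fit recovers the rate of a large simulated lifetime sample", {
  set.seed(9)
  x <- rexp(12000, 0.0035)
  fit <- fit_survival_exponential(build_survival_curve(x, "time"))
  mle <- fit_exponential_mle(x)  # oracle: ML mean of an exponential sample
  expect_true(mle$ci95_rate[1] <= 0.0035 && 0.0035 <= mle$ci95_rate[2])
  expect_equal(fit$rate, mle$rate, tolerance = 0.02)
  expect_equal(fit$rate, 0.0035, tolerance = 0.05)
})

test_that("MLE interval is calibrated at the experimental minimum n", {
  # n = 70 filaments, 200 replicates: the event-count CI of the exponential
  # MLE covers the true rate in at least 90% of replicates
  set.seed(10)
  covered <- vapply(1:200, function(i) {
    m <- fit_exponential_mle(rexp(70, 0.0035))
    m$ci95_rate[1] <= 0.0035 && 0.0035 <= m$ci95_rate[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("length- and time-domain fits agree at constant elongation rate", {
  set.seed(11)
  rate <- 15
  recs <- make_records(rexp(4000, 0.004), elongation_rate = rate)
  k_time <- fit_survival_exponential(
    build_survival_curve(recs, "time"), omit_first = FALSE)$rate
  k_len <- fit_survival_exponential(
    build_survival_curve(recs, "length"), omit_first = FALSE)$rate
  expect_equal(k_len * rate, k_time, tolerance = 1e-6)
})

test_that("degenerate curves are refused", {
  cv <- build_survival_curve(c(1, 2, 3), "time")
  expect_error(fit_survival_exponential(cv), "at least 4")
})

test_that("probability conversions match frozen high-precision values", {
  expect_equal(p_off_step_from_rate(0), 0)
  expect_equal(p_off_step_from_rate(1 / 5300), 1.886614465e-4,
               tolerance = 1e-8)
  expect_equal(p_off_time_from_rate(0.0035, 0.01), 3.499938751e-5,
               tolerance = 1e-8)
  expect_equal(p_off_time_from_rate(0, 3), 0)
  expect_equal(p_off_time_from_rate(log(2) / 0.01, 0.01), 0.5)
  expect_error(p_off_step_from_rate(-1), ">= 0")
  expect_error(p_off_time_from_rate(1, 0), "> 0")
})

test_that("probability and rate conversions are exact inverses", {
  k <- 10^seq(-8, log10(5), length.out = 400)
  expect_equal(rate_from_p_off(p_off_step_from_rate(k)), k,
               tolerance = 1e-9)
  dt <- 0.01
  expect_equal(rate_from_p_off(p_off_time_from_rate(k, dt), dt), k,
               tolerance = 1e-9)
  expect_error(rate_from_p_off(1), "\\[0, 1\\)")
})

test_that("per-step rate is the per-time rate over the elongation rate", {
  expect_equal(k_step_from_k_time(0.0035, 17.5), 2e-4)
  expect_equal(k_step_from_k_time(0, 17.5), 0)
  expect_equal(k_step_from_k_time(0.0039, 15), 2.6e-4)
  expect_error(k_step_from_k_time(1, 0), "> 0")
})

test_that("records tables canonicalize and round-trip through CSV", {
  df <- data.frame(condition_id = "x", run_length_um = c(1, 2),
                   elongation_rate_sub_s = 10)
  recs <- as_filament_records(df)
  expect_equal(recs$run_length_subunits, c(370, 740))
  expect_equal(recs$run_time, c(37, 74))
  expect_false(any(recs$censored))
  path <- tempfile(fileext = ".csv")
  write_filament_csv(recs, path)
  back <- read_filament_csv(path)
  expect_equal(back$run_length_subunits, recs$run_length_subunits)
  expect_equal(back$run_time, recs$run_time)
  expect_error(as_filament_records(data.frame(elongation_rate = 1)),
               "run_length")
})
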
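# shared fixtures, built in code

make_records <- function(run_time, elongation_rate = 10,
                         condition_id = "cond", censored = FALSE) {
  data.frame(condition_id = condition_id,
             run_length_subunits = run_time * elongation_rate,
             elongation_rate = elongation_rate, run_time = run_time,
             censored = censored)
}

# independent oracle for the shared-profilin-pool equilibrium: damped
# two-variable fixed point on the mass-action relations, no root finding
shared_pool_oracle <- function(au, al, pt, ku, kl, tol = 1e-14) {
  pu <- 0; pl <- 0
  for (i in 1:20000) {
    pf <- pt - pu - pl
    pu_new <- au * pf / (ku + pf)
    pl_new <- al * pf / (kl + pf)
    if (max(abs(pu_new - pu), abs(pl_new - pl)) < tol) break
    pu <- (pu + pu_new) / 2
    pl <- (pl + pl_new) / 2
  }
  list(pa_unlabeled = pu, pa_labeled = pl, profilin_free = pt - pu - pl)
}

# bisection root of the single-species mass-action equation
# (A - PA)(P - PA) / PA = kd
pa_bisection <- function(actin, profilin, kd) {
  if (actin == 0 || profilin == 0) return(0)
  f <- function(pa) (actin - pa) * (profilin - pa) / pa - kd
  stats::uniroot(f, c(1e-15, min(actin, profilin) * (1 - 1e-12)),
                 tol = 1e-14)$root
}
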
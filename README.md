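# forminsim

Quantitative analysis of **formin processivity** — how long a formin such as
budding-yeast Bni1p stays attached to the barbed end of a growing actin
filament, and how that lifetime depends on the route by which subunits
arrive (direct barbed-end binding versus FH1-mediated delivery of
profilin–actin).

The package is for single-molecule biophysicists working with TIRF
measurements of formin-assembled filaments, and for anyone who wants to
simulate or re-analyze processive polymerization data. It covers the whole
chain:

* **Binding equilibria** — labeled and unlabeled actin monomers competing
  for one profilin pool. Each complex obeys mass action,
  `[PA_i] = [A_i][P_free]/(K_d,i + [P_free])`, with the free pool fixed by
  conservation `P_free + PA_u + PA_l = P_total` (exact shared-pool solve;
  per-species approximations available). Tight binders use the binding
  quadratic `PA = ((A+P+K_d) − sqrt((A+P+K_d)² − 4AP))/2`.
* **Survival analysis** — run lengths (370 subunits/µm) and run times
  (length / elongation rate), empirical or Kaplan–Meier survival curves,
  and free-amplitude single-exponential fits `A·exp(−k·x)` giving the
  dissociation rate `k_off` and mean run length. Censoring-aware
  exponential MLE with a calibrated 95% interval.
* **FH1-delivery fractions** — from the dimming of formin-assembled
  segments: `FH1_black = 1 − F_norm`, `FH1_green = FH1_black · (PA_l/PA_u)`,
  total = sum.
* **Piecewise dissociation model** —
  `k_off(f) = k_basal + slope · max(f − 2/3, 0)` with defaults
  0.0039 s⁻¹ and 0.02 s⁻¹ per unit FH1 fraction; fixed-threshold fitting
  (OLS slope above, mean basal rate below).
* **Stochastic simulator** — populations of filaments with per-step or
  per-time dissociation probability `p = 1 − exp(−k·Δ)`, a nucleation
  schedule (20% initial pool + 8 filaments/s over 1200 s = 12,000
  filaments by default), a geometric fast path with a literal
  per-increment validation loop, and the FH1-fraction × elongation-rate
  sweep.
* **Synthetic data + recovery** — a generator that emulates the per-filament
  observation tables (exponential lifetimes, Gaussian elongation-rate
  noise, fluorescence encoding a known FH1 fraction) so the entire pipeline
  is validated by parameter recovery.

## Worked example

```r
library(forminsim)

## 0.75 uM actin (33% labeled), 5 uM Sc profilin: shared-pool equilibrium
cond <- sc_condition(profilin_total = 5)
eq <- solve_shared_profilin(cond)
eq
#> Profilin-actin equilibrium (uM):
#>   PA unlabeled 0.308132, PA labeled 0.0345934, PA total 0.342725
#>   free profilin 4.65727

## FH1-delivered fraction of a filament whose formin-built segment is
## 42% as bright as its control segment
fh1_fraction_total(normalized_fluorescence(42, 100), pa_label_ratio(eq))
#>   fh1_black fh1_green fh1_total normalized_raw
#> 1      0.58    0.0651    0.6451           0.42

## the piecewise dissociation model
m <- dissociation_model()        # basal 0.0039 s^-1, slope 0.02, threshold 2/3
predict_koff(0.77, m)            #> 0.005966667 s^-1
relative_rate_increase(m, m$threshold, 0.10)  #> 51.3 (%)

## simulate a 12,000-filament population at the 5 uM-profilin anchor
## (k_off = 0.0035 s^-1, elongation 18.55 subunits/s) and recover the rate
cfg <- simulation_config(elongation_rate = 18.55,
                         p_off = p_off_time_from_rate(0.0035, 0.01),
                         seed = 1, record_censored = TRUE)
res <- simulate_population(cfg)
res
#> Simulated population: 12000 nucleated, 9787 dissociated, 2213 still bound at 1200 s
fit_survival_exponential(
  build_survival_curve(res$records, "time", method = "km"),
  omit_first = FALSE)
#> Single-exponential nls-survival fit (time domain):
#>   rate 0.00353879 per s (95% CI 0.0035382-0.00353938)
#>   mean 282.583 s; amplitude 0.9982; n = 8813
```

The recovered rate (0.00354 s⁻¹, mean lifetime ≈ 283 s) matches the input
hazard to ~1%; the Kaplan–Meier curve is what makes that work, since ~18%
of filaments are still formin-bound when the 1200 s reaction ends and
dropping them would bias the fit upward. A filament that ran ~5300 subunits
before its formin dissociated corresponds to the same anchor in the length
domain (`run_time_from_length(5300, 18.55)` ≈ 286 s ≈ 1/0.0035 s⁻¹).

`run_pipeline()` chains the stages (generate → equilibria → FH1 fractions →
survival fits → probabilities → piecewise-model fit) and writes per-stage
CSV/JSON artifacts plus a checksummed manifest;
`recover_experiment()` reports bias and CI coverage over replicates. A thin
CLI over these functions lives at `inst/cli/forminsim.R`
(`Rscript inst/cli/forminsim.R simulate --config sim.yaml --seed 1 --out out.csv`).

See `vignettes/formin-processivity.Rmd` for the modeling assumptions,
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

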
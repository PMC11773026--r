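---
title: "Modeling formin processivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling formin processivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forminsim)
```

## The biological question

Formins such as budding-yeast Bni1p nucleate actin filaments and then track
the growing barbed end, stepping with their dimeric FH2 domain onto each
newly added subunit while their FH1 domains capture profilin–actin
complexes and deliver them to the end. The persistence of this association
— processivity — is quantified by the *run length* (subunits polymerized
before the formin falls off) and the *lifetime* of the attachment. Both are
exponentially distributed across a filament population when the
dissociation hazard is constant, so a single dissociation rate
$k_{\mathrm{off}}$ summarizes each reaction condition.

`forminsim` implements the full quantitative chain from raw per-filament
measurements (or simulations) to the central mechanistic result: the
dissociation rate is flat at a basal value while direct barbed-end binding
contributes substantially to elongation, and rises linearly once more than
two-thirds of subunits arrive via FH1-mediated delivery.

## Binding equilibria

Reactions mix unlabeled and fluorescently labeled actin monomers (labeling
weakens profilin binding roughly 10-fold) competing for one profilin pool.
Each complex obeys mass action with the shared free profilin concentration,

$$[PA_i] = \frac{[A_i]\,[P_{\mathrm{free}}]}{K_{d,i} + [P_{\mathrm{free}}]},
\qquad
[P_{\mathrm{free}}] + [PA_u] + [PA_l] = [P_{\mathrm{total}}].$$

`solve_shared_profilin()` solves the conservation equation exactly. The
residual is strictly increasing in $[P_{\mathrm{free}}]$ on
$[0, P_{\mathrm{total}}]$, so the bracketed root is unique; we locate it
with `uniroot()` at an absolute tolerance of $10^{-12}$ µM (tighter than
any concentration resolved experimentally). Two alternative modes exist
because the literature often treats the species independently:
`profilin_free = "total"` evaluates the isotherm at
$P_{\mathrm{free}} = P_{\mathrm{total}}$ (adequate for weak binders like Sc
profilin, $K_d$ 2.9/29 µM, where bound complexes deplete the pool by only a
few percent), and `solve_independent_species()` gives each species the full
pool, using the exact binding quadratic per species for tight binders like
human profilin-1 ($K_d$ 0.1/1.0 µM). The shared-pool solve is the package
default because it is the only mode that conserves profilin exactly; the
others are provided for comparison with per-species calculations. Note that
at 5 µM Sc profilin the free pool (≈ 4.66 µM) is *not* small relative to
$K_d = 2.9$ µM, so the labeled/unlabeled complex ratio (≈ 0.112) is more
than twice the weak-binding-limit value $(A_l/K_l)/(A_u/K_u) = 0.05$; the
weak limit is only reached well below ~0.5 µM profilin.

The binding quadratic is evaluated in the stable form
$2AP/(b + \sqrt{b^2 - 4AP})$ with $b = A + P + K_d$, which avoids
cancellation when the smaller root is tiny.

## Survival analysis

Run lengths in µm convert to subunits at 370 subunits/µm, and run time is
run length over the condition's elongation rate. The survival curve — the
fraction of attachments lasting at least a given length or time — is fitted
with a free-amplitude single exponential $A e^{-kx}$ by unweighted
nonlinear least squares (`minpack.lm::nlsLM`, started from a log-linear
regression). Two conventions follow experimental practice:

* **First-point omission** defaults on in the length domain and off in the
  time domain. Short dim stretches (≲ 500 subunits) are hard to score in
  micrographs, so the first survival point under-represents short runs;
  dropping it and letting the amplitude float (y-intercept > 1) mirrors how
  the experimental curves are fitted. The synthetic generator reproduces
  this with an optional detection filter (`detection_filter`, threshold 500
  subunits).
* **Censoring.** Filaments still formin-bound when observation ends carry
  only a lower bound on their run. The default curve (`method = "exclude"`)
  drops them, as experiments do when no dim-to-bright transition is seen.
  For simulator output this is *not* innocuous: with the default nucleation
  schedule, filaments born late in a 1200 s reaction have observation
  windows much shorter than the ~286 s mean lifetime, and fitting only the
  completed runs inflates the rate by roughly a quarter. We therefore
  provide `method = "km"`, a Kaplan–Meier curve over all records, and use
  it whenever censored records are present in simulation summaries. With it
  the generating hazard is recovered to within sampling error.

The 95% interval reported by `fit_survival_exponential()` comes from the
fit covariance, matching how experimental survival fits are usually quoted.
Survival points are cumulative and hence strongly correlated, so this
interval is optimistic — at $n = 70$ filaments its empirical coverage is
near 20%, not 95%. `fit_exponential_mle()` supplies the calibrated
alternative: the censoring-aware exponential MLE
$\hat k = d / \sum t_i$ with interval
$\hat k\,e^{\pm 1.96/\sqrt d}$, which covers at the nominal level. All
coverage claims in the test suite use the MLE interval; the curve-fit
interval is retained for comparability with published fits.

## Rates and probabilities

A hazard converts to a per-increment dissociation probability by
$p = 1 - e^{-k\,\Delta}$ with $\Delta$ one FH2 step (per-step) or
$\Delta t = 0.01$ s (per-time), and back by $k = -\log(1-p)/\Delta$
(`expm1`/`log1p` keep these exact inverses to < 1e-9 relative error down to
$k\Delta = 10^{-8}$). Temporal rates divide by the elongation rate to give
per-step rates.

## The piecewise dissociation model

`dissociation_model()` encodes
$k_{\mathrm{off}}(f) = k_{\mathrm{basal}} + s\,\max(f - \tau, 0)$ with
defaults $k_{\mathrm{basal}} = 0.0039\ \mathrm{s^{-1}}$,
$s = 0.02\ \mathrm{s^{-1}}$ per unit fraction, and $\tau = 2/3$ stored as
the exact rational (a threshold of 0.67 reproduces arithmetic done with the
rounded printed value; the difference is third-digit). Fitting
(`fit_piecewise()`) holds $\tau$ fixed: the slope is unconstrained OLS on
the points above threshold — we do not force the upper line through the
basal level, since the published fit is described as a plain linear fit —
and the basal rate is the mean of the points at or below it. Estimating
$\tau$ itself (changepoint detection) is out of scope.

A mechanistic aside motivates the threshold: if subunits are FH1-delivered
independently with probability $f$, two consecutive deliveries occur with
probability $f^2$, which crosses one half just above $f = 0.7$;
`consecutive_delivery_probability()` exposes this arithmetic.

## The population simulator

Each filament is an independent Bernoulli process: at every increment the
formin dissociates with probability `p_off`, *tested before elongating*, so
a first-increment dissociation leaves a zero-length run in per-step mode
(this matches the if/else order of the published algorithm; the boundary
`u == p_off` has measure zero, and we use strict `<`). Increment count to
dissociation is therefore geometric, and the default *fast path* samples it
directly with `rgeom()`; the literal one-uniform-per-increment loop is
retained (`fast_path = FALSE`) and the test suite verifies the two are
distributionally indistinguishable (two-sample KS across 20 seeds at
n = 2000). The literal loop at full scale would need ~1.4 × 10⁹ uniform
draws per run, which is why it is the validation path rather than the
default.

Populations follow the standard protocol: 12,000 filaments over 1200 s
with Δt = 0.01 s, 20% present at t = 0 and the rest nucleating at
8 filaments/s. The uniform schedule places arrivals at interval midpoints
$(i - \tfrac12)/\mathrm{rate}$ so that a schedule which exactly fills the
reaction nucleates every filament strictly inside it; a Poisson-arrival
option exists. A pool/rate/duration combination that does not add up to
`n_filaments` warns rather than errors. Filaments still bound at the end
are always counted as censored; `record_censored` controls whether they
appear in the output table (default off, mirroring experimental tables of
completed runs — turn it on for unbiased Kaplan–Meier fitting, as
`simulate_fh1_sweep()` and the summary helpers do).

Randomness comes from one seeded base-R generator per population; all
increment counts are drawn in a single vectorized call, so output is
deterministic per seed and independent of filament iteration order. We did
not implement per-filament counter-based substreams: base R lacks a cheap
substream API and the single vectorized draw achieves the same
order-independence.

The FH1 sweep couples the pieces: for each elongation rate and FH1
fraction, the piecewise model sets the hazard, the hazard sets the per-time
probability, and survival fits of the simulated population return the mean
run length. Below threshold the curves are flat in $f$; above it run
lengths fall toward the all-FH1 minimum, and the spread across elongation
rates narrows.

## Synthetic data generator

`generate_observations()` emulates what the microscopy measurements look
like *after* image analysis: exponential lifetimes (the primitive variable;
run lengths inherit per-filament Gaussian elongation-rate noise through
run length = rate × lifetime, which ties the length- and time-domain fits
together exactly as the conversion equation assumes), right-censoring at
the observation window, and segment fluorescence built so that the dimming
inversion returns the scenario's FH1 fraction: the unlabeled delivered
fraction is $f/(1+g)$ with $g$ the condition's labeled/unlabeled
profilin–actin ratio, the normalized intensity is one minus that, and both
segment intensities get multiplicative Gaussian noise.

It does **not** emulate: photobleaching, stage drift or tracing errors,
filament crossing/bundling, diffraction-limited length quantization, or
intensity correlations along a filament. Passing recovery tests therefore
demonstrates the *analysis chain* is unbiased for data satisfying its
stated assumptions, not that those assumptions hold in any particular
microscope.

`condition_presets()` spans the experimental grid (Sc profilin 0.5–20 µM at
0.75 and 1 µM actin; human profilin-1 0.25–5 µM; FH1FH2, PCPD-FH2 and
FH1FH2-C constructs). True per-condition elongation rates and FH1 fractions
are nowhere tabulated, so the presets use representative maps — elongation
rate proportional to profilin–actin concentration anchored at
18.55 subunits/s for 5 µM Sc profilin (the value implied by the
5300-subunit run length and 0.0035 s⁻¹ rate at that anchor), an FH1
fraction saturating in profilin–actin, and a PCPD construct with halved
delivery efficiency. Their generating dissociation rates come from the
piecewise model evaluated at the preset's fraction, which is what makes
end-to-end recovery of $(k_{\mathrm{basal}}, s)$ a meaningful closed-loop
test. These placeholder maps are deliberately simple and flagged
non-authoritative.

## Problem sizes and tolerances in the test suite

Stochastic checks use the full 12,000-filament population where the claim
is about that population (hazard recovery, run-length anchors, end-to-end
model recovery over the 23-preset grid × 10 seeds) and reduced sizes where
the claim is distributional (fast-path vs literal-loop equivalence at
n = 2000 × 20 seeds, CI calibration at the experimental minimum of 70
filaments × 200 replicates). Stochastic tolerances are stated in sampling
units (multiples of the relevant SE, or the calibrated 95% interval) rather
than raw percentages wherever possible; fixed-seed determinism keeps every
run reproducible.

## Known limitations

* Single-exponential hazards only; mixtures or aging hazards (e.g. formin
  photodamage) are out of scope, as are Kaplan–Meier curves with staggered
  *entry* (left truncation).
* The equilibria module fixes µM units and ignores nucleotide state,
  temperature and ionic-strength dependence of the affinities.
* The FH1-fraction algebra treats the black and green fractions as shares
  of all polymerized subunits, so their sum is the total delivered
  fraction; values pushed outside [0, 1] by noise are clamped with a
  warning and the raw ratio kept for audit.
* The simulator is non-spatial and single-filament-independent: no monomer
  depletion, capping-protein competition, or force dependence.
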
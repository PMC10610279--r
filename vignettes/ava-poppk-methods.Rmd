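---
title: "Population pharmacokinetics of apovincaminic acid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of apovincaminic acid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avapk)
```

## The problem

Vinpocetine, a semi-synthetic vinca alkaloid sold both as a prescription
drug and (controversially) as a nootropic supplement, is metabolized very
rapidly; its active de-esterified metabolite, apovincaminic acid (AVA), is
the analyte usually measured and the accepted exposure surrogate. `avapk`
implements a population pharmacokinetic (PopPK) model for AVA after oral
vinpocetine, estimated from a single-dose, three-formulation crossover study
in twelve healthy men, together with everything needed to work with such a
model end to end: simulation of the study, estimation by SAEM, diagnostics,
and clinical-trial simulation of dosing regimens.

Because no raw data accompany the model, the package treats the study as a
*generative* object: the synthetic-data module reproduces the study design
so that every stage — estimation, diagnostics, simulation — can be exercised
and tested without any download.

## Structural model

AVA kinetics follow a two-compartment disposition model with linear
elimination, fed by a zero-order (constant-rate) input of duration
$T_{k0}$ that begins after a lag $T_{lag}$. With micro constants
$k_{10}=CL/V_1$, $k_{12}=Q/V_1$, $k_{21}=Q/V_2$ and biexponential rates
$\alpha\beta = k_{10}k_{21}$, $\alpha+\beta = k_{10}+k_{12}+k_{21}$, the
central concentration after a dose $D$ is the familiar piecewise form: zero
until $T_{lag}$, the constant-rate-infusion solution during input, and
biexponential washout afterwards. The implementation expresses the whole
curve as the difference of two cumulative infusion responses, which makes
continuity at both breakpoints exact by construction rather than a property
to be checked numerically. When the two rates collapse
(discriminant below $10^{-10}$ relative), the critically damped closed form
$(D/V_1)\,e^{-\lambda t}\{1+(\lambda-k_{10}-k_{12})\,t\}$ takes over.

All parameters are *apparent* (CL/F, V/F, ...): oral bioavailability and the
vinpocetine-to-AVA conversion fraction are not separable from single-dose
oral data and are folded into $F$. Doses are entered in mg of vinpocetine
and converted internally to µg, so that with volumes in litres
concentrations come out in µg/L, the scale of the original assay
(quantification limit 5 µg/L).

The published fixed effects are available as `ava_model()` and as the
packaged config `inst/extdata/ava_final_model.json`:

```{r}
print(ava_model())
```

Two derived quantities summarize disposition at the immediate-release
tablet covariate level:

```{r}
derived_metrics(typical_params(ava_model(), "#2"))
```

A note on attribution: the source publication attributes the ~4.7 h
terminal half-life to the sustained-release formulation, but recomputation
from its own estimates places that value (and the ~135 L steady-state
volume, which the same text assigns to the immediate-release tablet) with
the immediate-release-adjusted central volume; the reference-category
convention of the estimates table admits no other reading. The package
follows the estimates table.

## Population layer

Individual log-parameters are normal around the covariate-adjusted typical
values:
$$\log \theta_{ik} = \log \theta_{\mathrm{pop},k} + \beta_k[\mathrm{form}_i] + \eta_{ik},
\qquad \eta_i \sim \mathcal N(0, \Omega).$$

* Formulation is the only covariate: coefficients exist for $T_{k0}$ and
  $V_1$ of the immediate-release tablet (#2) and the oral solution (#3),
  with the sustained-release tablet (#1) as reference. The multiplicative
  `exp(β)` convention is forced by the published ~135 L steady-state volume:
  $208.34\,e^{-1.26}+76.15 \approx 135$ L only under that reading.
* All six parameters carry lognormal random effects; the single correlated
  pair is (V1, CL), $\rho = 0.72$. Sampling uses the Cholesky factor of the
  structured covariance; parameters with $\omega=0$ are held fixed exactly.
* Residual error is proportional, $y = C(1 + b\,\varepsilon)$,
  $\varepsilon\sim\mathcal N(0,1)$, $b = 0.14$. Negative simulated
  observations (possible when $b\varepsilon< -1$, about 0.1% of draws at
  the fitted $b$) are retained, mirroring the uncensored handling of
  below-quantification values in the source analysis.

## The synthetic study

`default_design()` encodes the crossover layout: 12 subjects, three
periods, one 20 mg vinpocetine dose per period, each subject receiving all
three formulations in a balanced Latin-square sequence, 7-day washout,
sampling from 0.25 to 10 h, LLOQ 5 µg/L. Choices the design source does not
pin down, fixed here once for reproducibility:

* the 13-point sampling grid (0.25–10 h) typical of single-dose
  bioavailability studies over that window;
* Latin-square sequence assignment — inert, because the model has no
  carry-over (the washout exceeds 35 terminal half-lives; the generator
  verifies carry-over < 0.1% of Cmax and warns otherwise);
* one random-effect vector per subject shared across periods (the model has
  no inter-occasion variability), so period contrasts are purely
  formulation effects.

Each subject consumes an independent child random stream derived from the
root seed, making per-subject results invariant to subject ordering and
cohort size. What the generator deliberately does *not* emulate: assay
drift, dropout, sampling-time deviations, inter-occasion variability, or
any demographic covariate effect (none survived screening in the source
analysis). Green tests therefore certify the machinery under the model's
own assumptions, not robustness to real-data pathologies.

## SAEM estimation

`saem_fit()` maximizes the marginal likelihood by stochastic approximation
EM. Internals, all recorded in `fit_settings()`:

* **Latents.** The sampled quantity per subject is the reference-scale
  log-parameter vector $\psi_i = \mu + \eta_i$; covariate shifts enter the
  observation model, so the Gaussian layer has closed-form sufficient
  statistics.
* **Kernel.** One chain; two sweeps per iteration of a component-wise
  random-walk Metropolis step, vectorized across subjects; proposal scales
  adapt by Robbins–Monro towards ~30% acceptance during burn-in and the
  exploratory phase and are frozen for smoothing.
* **Schedule.** 20 burn-in iterations (no parameter updates), 300
  exploratory iterations with step size 1, 200 smoothing iterations with
  step $1/k^{0.7}$.
* **M-step.** $\mu$ and the structured $\Omega$ come from stochastically
  averaged first and second moments; the covariance structure (diagonal
  plus the (V1, CL) block) is imposed by blockwise projection, which for a
  block-diagonal structure is the exact constrained MLE. Covariate
  coefficients are updated by a short warm-started BFGS step on the
  complete-data likelihood, relaxed by the same step size. $b$ comes from
  stochastically averaged squared proportional residuals.
* **Numerical floors.** The observation SD is
  $\sqrt{(bf)^2 + \sigma_0^2}$ with $\sigma_0 = 0.01$ µg/L, which
  regularizes the pre-lag region where predictions are exactly zero.
  Residuals for the $b$ update divide by $\max(f, 1)$ µg/L. The projected
  covariance diagonal keeps a floor of $0.02^2$ on the log scale so the
  sampler retains mobility when a variance estimate collapses — an order of
  magnitude below any plausible between-subject SD in this domain, so
  multi-subject estimates are unaffected, while near-degenerate fits (one
  subject, near-noiseless data) still converge.
* **Initialization.** Naive-pooled log-scale least squares for the fixed
  effects (`init_pooled()`), $\omega = 0.3$, correlation 0, $b = 0.2$.
* **Convergence flag.** Relative SD of each fixed effect over the last 50
  smoothing iterations below 1%.

Standard errors come from a linearized (first-order conditional) Fisher
information: the Jacobian of each subject's predictions with respect to the
random effects, evaluated at the empirical Bayes modes, yields both the
fixed-effect gradient (by the chain rule through the log) and the marginal
covariance; variance parameters use the standard Gaussian trace identity.
These are curvature-based approximations of the same kind pharmacometric
tools report, not bootstrap intervals.

The likelihood itself (`ofv_importance_sampling()`) is estimated per
subject by importance sampling from a normal proposal centred at the EBE
mode with covariance $1.3\times$ the inverse local Hessian (prior
covariance as fallback). `bicc()` applies the hybrid penalty: parameters
tied to subject-level random effects pay $\log N$, the rest $\log n_{obs}$.
Because the original software's exact SAEM settings and BICc variant are
not published, reproduced OFV/BICc values are comparable in *ordering*, not
absolutely — which is how the tests use them (the two-compartment
zero-order model beats a one-compartment first-order comparator on data it
generated).

Empirical Bayes estimation (`ebe_estimate()`) maximizes
$p(y_i\mid\eta)\,p(\eta)$ by BFGS from $\eta=0$, falling back to zero with
a warning on optimizer failure. Covariate screening (`covariate_screen()`)
is the usual EBE screen: Pearson correlation tests for continuous
covariates, Kruskal–Wallis across groups for categorical ones; the Wald
test on a coefficient is two-sided normal (a $t$ reference would be
anti-conservative folklore at $N=12$ either way — the small-$N$ caveat
applies to both).

## Diagnostics

`gof()` produces population predictions ($\eta = 0$), individual
predictions (at the EBEs) and individual weighted residuals
$(y - \hat y_i)/(b\,\hat y_i)$. With six free effects per subject the EBE
residual SD deflates by roughly $\sqrt{1 - P/n_i}$; the calibration tests
use ~33 observations per subject so the band $[0.85, 1.15]$ is meaningful.

`vpc()` simulates replicate datasets on the observed design, bins by
nominal sampling time (merging bins under three observations), and wraps
each requested percentile (default 10/50/90) in a 95% prediction-interval
envelope (level chosen here; 500 replicates by default). Self-consistency
coverage of the median curve on data simulated from the model itself runs
around 95% per bin in the package's own checks.

## Trial simulation

`simulate_trials()` reproduces the replicate-trial simulation study: per
replicate, one draw of the fixed effects under estimation uncertainty
(lognormal with log-SD = SE/estimate for positive parameters, normal for
coefficients; $\omega$ and $b$ held fixed), then a cohort of virtual
subjects with full inter-individual variability, evaluated on noise-free
concentration curves. Defaults are ten replicates of 50 subjects at the
immediate-release-tablet covariate level — the presentation the simulated
regimens (5 mg tablets and multiples) are built from, and the only level
whose derived half-lives and volumes match the published derived values.

Two post-processing conventions required decisions the simulation source
does not state, and both were fixed by consistency with its printed
summaries before the engine was frozen:

* **Summary statistic.** The headline "mean Cmax/Cmin" of a regimen is the
  maximum / end-of-interval trough of each replicate's *mean concentration
  curve*, averaged over replicates. Averaging individual maxima instead
  yields values ~10% higher (individual peaks do not align in time, so the
  mean curve's peak is smeared), incompatible with the published
  once-daily summary; the mean-curve reading also reproduces the published
  between-replicate ranges. Per-individual exact Cmax/trough distributions
  are nevertheless retained in the result for percentile queries.
* **Window.** Metrics are computed over one dosing interval at treatment
  onset. The alternative — the last interval of a week at steady state —
  is incompatible with the published every-8-hours trough: accumulation
  puts even the *typical subject's* steady-state trough (1.72 µg/L) far
  above the published mean (1.25 µg/L), whereas the first-interval trough
  matches it to ~2%.

One published value resists every reconstruction: the once-daily mean
trough (0.52 µg/L). Under the published parameters the model's mean
24-hour trough is ~0.36–0.42 µg/L under any window, and the pair of
published troughs jointly implies a terminal half-life near 7.7 h —
inconsistent with the 4.7 h the same parameters produce. The package
reports its honestly computed value and documents the gap rather than
adjusting anything towards the printed number.

`reference_band()` returns the effectiveness/safety band of the reference
maintenance regimen (5 mg every 8 h): the 5th percentile of individual
troughs to the 95th percentile of individual peaks, individuals pooled
across replicates. `regimen_comparison()` expresses each regimen's pooled
means relative to that reference; splitting a daily dose lowers the peak
and raises the trough, and the 60 mg once-daily "biohacker" dose exceeds
the reference peak more than tenfold — the simulation study's central
message.

## Problem sizes and budgets

The test-suite sizes are the package's own choices: 100 random parameter
sets for the ODE-oracle comparison ($10^{-6}$ relative), $10^5$ draws for
covariance recovery (correlation within 0.015), five replicate studies for
SAEM recovery at the study's own $N = 12$ (clearance within 15%, all fixed
effects within 25%, median bias under 10%), ten replicate model
comparisons for the BICc ordering, and 100×200 replicate trials in the
acceptance script, where the replicate count is raised purely to tighten
Monte-Carlo error while leaving each virtual trial's design untouched.

## Known limitations

* Parent-drug (vinpocetine) kinetics, nonlinear elimination,
  transit-compartment absorption, inter-occasion variability and
  continuous-covariate effects are out of scope.
* SEs are linearization-based; at $N = 12$ they are indicative, like the
  published relative standard errors they mirror (3–40%).
* BLQ observations enter the likelihood as ordinary continuous data
  (the uncensored convention of the source analysis); no M3-style
  likelihood adjustment is implemented.
* The simulation study's once-daily trough is reported as computed, not as
  published, for the reasons above.
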
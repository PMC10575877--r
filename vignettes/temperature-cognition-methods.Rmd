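---
title: "Methods: Bayesian spatiotemporal models of temperature and cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian spatiotemporal models of temperature and cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermocog)
```

# The model

`thermocog` estimates the association between monthly ambient temperature
and MMSE cognitive scores in older adults with a Gaussian spatiotemporal
hierarchical model.  Writing $y_{ict}$ for the score of subject $i$ in
county $c$ at study month $t$ (month of year $m(t)$),

$$
y_{ict} = \alpha_0 + \beta_0 t + f(\mathrm{temp}_{ct})
        + (\alpha_c + \beta_c t) + (\alpha_{m} + \beta_{m} t)
        + (\zeta_{cm} + \psi_{cm} t) + \nu_t
        + \beta_1\,\mathrm{precip}_{ct} + \beta_2\,\mathrm{PM_{2.5}}_{ct}
        + \varepsilon_{ict},
\qquad \varepsilon_{ict} \sim N(0, \sigma^2_\varepsilon).
$$

The random-effect priors follow the disease-mapping tradition:

* **County** intercepts and slopes are Besag–York–Mollié pairs: an
  intrinsic conditional autoregressive (ICAR) field on the county adjacency
  graph, with structure matrix $Q = D - W$ (degree minus adjacency), plus an
  iid Gaussian component.  We use the classic additive parameterization, not
  the rescaled variant, and no graph-based rescaling by default.
* **Month-of-year** intercepts and slopes follow a first-order random walk
  made cyclic, so December is adjacent to January.
* **County-by-month interactions** $\zeta_{cm}, \psi_{cm}$ are iid Gaussian
  pairs (the weakest structure consistent with level-and-trend interactions)
  with one sum-to-zero constraint per block.
* $\nu_t$ is a (linear) first-order random walk over the consecutive study
  months, capturing nonlinear variation along the entire time scale; the
  month-of-year block and $\nu$ coexist because one lives on the cyclic
  12-month clock and the other on the full study index.
* $\varepsilon$ is the record-level over-dispersion term.  With an identity
  link and a Gaussian likelihood a separate iid record effect is
  unidentifiable from observation noise, so $\sigma^2_\varepsilon$ *is* the
  observation variance; the `overdispersion` flag controls whether it is
  estimated or fixed.

The model is fit to subject-level records by default;
`aggregate_linked()` provides the county-month-mean alternative (unweighted,
so the subject-level fit is preferred whenever counts per cell vary).
Individual covariates (gender, age, residence, education, income,
ethnicity) do not enter the linear predictor; they define subgroups for the
heterogeneity analysis, mirroring the modelling tradition this package
implements.

Conventions that matter for interpretation:

* "time" is the consecutive study-month index centered at mid-study, so the
  intercept refers to the study midpoint and is decorrelated from the slope.
* Temperature, precipitation and PM2.5 columns are centered at their sample
  means (stored in the fit's provenance).  Centering moves only the
  intercept; slopes, contrasts and curves are unaffected.
* The county-by-month interaction cell for county $i$ (graph order) and
  month $m$ has flat index $12(i-1) + m$.

# Temperature response bases

Four candidate forms of $f$ are supported: raw polynomial (default cubic,
degree configurable), cubic B-spline, and natural cubic splines with 3 or 5
knots.  The intercept column is always excluded ($\alpha_0$ absorbs it).
Column counts: degree $d$ polynomial, $d$; natural spline with $k$ knots,
$k-1$; B-spline, interior knots + degree (the partition-of-unity basis minus
its intercept-carrying first column).  Whether the published analyses
centered or intercepted their B-spline is not stated; here all temperature
columns are mean-centered and the convention is recorded in provenance.

Knot placement, when not explicit, uses equally spaced empirical quantiles
with the 5th and 95th percentiles as boundaries (3 knots: 5/50/95; 5 knots:
5/27.5/50/72.5/95), with type-7 (linear-interpolation) quantiles.  B-spline
interior knots default to the quartiles.  The natural cubic spline is built
from the textbook truncated-power construction with linearity constraints
beyond the boundary knots; it spans the same space as `splines::ns` (the
test suite checks span equality) but keeps coordinates that are directly
comparable to hand calculations.

`select_basis()` fits all candidates and picks the minimal DIC
($\mathrm{DIC} = \bar{D} + p_D$, with $\bar{D}$ the posterior mean deviance
and $p_D = \bar{D} - D(\hat\theta)$).  Ties — which arise only for
numerically identical fits — go to the candidate with fewer columns, then to
declaration order.

# Priors and inference

**Hyperpriors.** Every random-effect precision and the observation
precision get a Gamma(`tau_shape`, `tau_rate`) prior; the default is
Gamma(0.01, 0.01), approximately flat on the log-precision scale.  The
disease-mapping tradition often uses Gamma(1, 5e-5); on a 0–30 score scale
that choice is far from innocuous: it puts almost all prior mass on
component standard deviations below 0.1 and its log-scale density increases
toward $\tau = 2\times10^4$, so weakly identified blocks (a seasonal effect
of sd 0.3 against record noise of sd 2, say) are pulled into a degenerate
$\tau\to\text{large}$ corner, which also narrows the intervals of the fixed
effects that those blocks partially confound.  In simulation-based
calibration checks the flat-on-log default restores nominal fixed-effect
coverage while the traditional values do not; they remain available through
`st_priors()` for comparability.  Fixed effects get independent
$N(0, 10^6)$ priors (precision `beta_precision = 1e-6`, configurable); the
model is therefore never singular, and degenerate designs behave like
heavily penalized ridge fits.

**Laplace engine (default).** Conditional on the precisions the model is
jointly Gaussian, so the coefficient posterior is available exactly through
one sparse Cholesky factorization of
$P(\theta) = M^\top M/\sigma^2 + D(\theta)$ (CHOLMOD, with the symbolic
factorization reused across hyperparameter evaluations).  The engine
maximizes the (hyperprior-weighted) marginal likelihood over
$\theta = \log$ precisions with Nelder–Mead, then integrates over
hyperparameter uncertainty by sampling `hyper_draws` (default 20) values of
$\theta$ from a Gaussian approximation at the mode and mixing the
conditional Gaussians; `hyper_draws = 1` gives plain empirical Bayes.
Posterior summaries of fixed effects use the mixture draws when
hyperparameters are uncertain and the exact conditional moments otherwise.
The whole procedure is deterministic given the seed.

**MCMC engine.** A conjugate block Gibbs sampler: the full coefficient
vector is drawn jointly from its conditional Gaussian, then each precision
from its conditional Gamma.  It serves as an independent cross-check of the
Laplace engine (the suite compares them) and as the option of choice when
full posterior propagation matters more than speed.  Basic split-chain
R-hat diagnostics are reported; non-convergence flags the fit without
discarding it.

**Constraints.**  ICAR and RW1 blocks are reparameterized onto the positive
eigenspace of their structure matrix, which drops one constant per
connected component and therefore enforces the per-component sum-to-zero
constraints exactly (islands get their own constraint; isolated counties
have no structured effect and are carried by the iid BYM component).  The
iid interaction blocks stay in sparse indicator coordinates and are
constrained by conditioning-by-kriging on means and draws.  Deviance and
DIC are computed at the hyperparameter mode; $p_D$ uses the exact trace
formula $\operatorname{tr}(\Sigma M^\top M)/\sigma^2$, so adding a
flat-prior covariate raises $p_D$ by exactly one.

# Effect products

**Response curve.**  `response_curve()` reports
$\mathrm{dev}(T) = g(T) - g(T_\text{ref})$ where $g$ is the posterior basis
contribution, with bands from draw-wise contrasts (never the delta method).
The deviation and its band are exactly zero at the reference, and pairwise
differences $\mathrm{dev}(T_1)-\mathrm{dev}(T_2)$ do not depend on the
reference choice.  The default grid runs over the observed range in 0.5
degC steps and always includes the reference.  The global score's default
reference is $-7$ degC; sub-domain references default to the fitted peak
(`find_peak_reference()`, grid argmax, ties to the lowest temperature).
Two published reference presets are shipped verbatim in
`reference_presets()`; they disagree with each other (and list five values
for six outcomes), so neither is silently imposed.

**Interval effects.**  The range is partitioned into five intervals (range
minimum to reference; reference to 5; 5–15; 15–25; 25 to range maximum),
half-open except the topmost.  Each interval is refit with a single linear
temperature term on the records whose *current-month* temperature falls
inside it, keeping the full random-effect structure.  The reported
`decline_per_degree` is the score drop per 1 degC *rise* on the hot side
($-\beta$) and per 1 degC *drop* on the cold side ($+\beta$), with CIs
transformed draw-wise under the same convention.  A minimum-record guard
(default 50) flags sparse intervals rather than silently fitting them.

**Displacement.**  `displacement_fit()` enters the current month and up to
`l_max = 3` preceding (lag) or following (lead) monthly temperatures
jointly — one model, not one offset at a time — restricted by the
current-month regime interval only.  Lag and lead are separate models.  The
overall effect is the draw-wise sum of the coefficients over a configurable
offset set; the default $\{0, 1\}$ reflects the finding that only the
current and previous month carry signal, and the full $\{0,1,2,3\}$ sum is
one argument away.  Summing draws (not intervals) makes the overall CI
honor the strong serial correlation between offset temperatures; the fit
warns when offsets correlate beyond $|r| > 0.99$.

**Heterogeneity.**  Subgroup overall effects come from per-level
displacement fits ($Q$ = posterior mean of the overall sum, $SE$ = its
posterior sd).  `heterogeneity_test()` implements the published interval
$(Q_1 - Q_2) \pm 1.96\sqrt{SE_1 + SE_2}$ with the $\ge 2$ indicator rule.
The unsquared $\sqrt{SE_1+SE_2}$ is dimensionally inconsistent (not
scale-invariant), which the function surfaces with a warning; the
conventional Wald form $\sqrt{SE_1^2+SE_2^2}$ is available as
`variance_rule = "squared"`, and both can be reported side by side with
`pairwise_heterogeneity()`.  No multiple-testing correction is applied
across pairs, matching the source procedure.  `sensitivity_grid()` refits
the overall cold/hot effects under user-chosen subsets of disabled
confounder blocks, always anchored by the full-model reference row.

# The synthetic generator

Because the survey microdata this analysis style is applied to are
restricted, `synth_config()`/`simulate_study()` generate studies with the
exact statistical structure the model assumes, with every generating
parameter known:

* a connected rook-adjacency lattice of counties (default 5×8 = 40);
* monthly temperature = county gradient (by lattice row, emulating a
  latitude gradient of 18 degC across counties) + a sinusoid peaking in
  July (amplitude 12 degC) + interannual noise (sd 1.5 degC), affinely
  rescaled so the realized range is exactly the configured −14..31 degC;
* precipitation and PM2.5 linear in temperature plus noise (4 mm/degC and
  −0.8 µg/m³/degC by default, so pollution is higher in cold months);
* subjects (default 2000 over 36 months) allocated to counties by a
  Dirichlet-weighted multinomial (uneven coverage), exam months uniform;
* the latent score from the full linear predictor: baseline 27, secular
  trend −0.02/month, a quadratic response peaked at −7 degC with curvature
  −0.01 (so the hot extreme loses ≈ 14.4 points), β_precip −0.005,
  β_pm25 −0.02, ICAR county field (sd 0.6) + iid (sd 0.4), cyclic month
  effect (sd 0.3), iid interactions (sd 0.2), study-month walk (sd 0.15),
  record noise sd 2 — values a field epidemiologist would recognise as a
  plausible effect hierarchy on the MMSE scale;
* domain scores as a fixed convex split of the latent global score plus
  small noise; optional subgroup multipliers scale the temperature response
  for heterogeneity experiments.

Structured fields are drawn through the same spectral factorization the
fitter uses, so generated ICAR/RW1 fields satisfy their sum-to-zero
constraints exactly.  Scores are left unclamped by default — rounding and
clamping to 0..30 breaks the Gaussian model and is offered only for realism
demonstrations, with the flag recorded in the output.

What the generator does **not** emulate: real county geography and
adjacency irregularity, survey nonresponse and wave structure, repeated
measurements on the same subject, non-Gaussian score discreteness, and
climate fields more textured than gradient + season + noise.  Passing
recovery tests therefore demonstrates the estimators are correct and
calibrated *under the model's own assumptions*, not that the model is
adequate for any particular real dataset.

# Problem sizes and numerical choices

The test suite validates parameter recovery at the generator's default
conditions (40 counties, 36 months, 2000 records; 50 replicates for
fixed-effect coverage, 30 for distributed-lag recovery, 10 for DIC basis
selection), sizes at which each replicate fits in about a second and the
full experiment remains comfortably reproducible on a laptop.  Replicate
experiments warm-start each fit from the previous replicate's
hyperparameter estimates, which only changes optimizer effort, not the
optimum.  Other defaults: optimizer budget `maxit = 1000` Nelder–Mead
evaluations (convergence is reported in `$diagnostics`); 1000 stored
posterior draws; eigenvalues below $10^{-9}\times$ the spectral maximum
treated as null space; the marginal-likelihood surface is explored from
moment-based initial values (half the response variance to noise, a tenth
to each component).

# Known limitations

* The Laplace engine's hyperparameter integration is a sampled Gaussian
  approximation at the mode; strongly multimodal hyperparameter posteriors
  are better served by the Gibbs engine.
* DIC is computed at the hyperparameter mode in the Laplace engine, so DIC
  comparisons across models assume the mode is representative.
* The Gibbs sampler uses the centered parameterization and can mix slowly
  for variance components near zero.
* Interval and displacement fits refit the full model on the regime subset
  (the reading taken of the source procedure); with few records in a regime
  the random-effect structure is weakly informed, which the record guards
  only partially mitigate.
* The per-item MMSE weights and item-to-domain partition shipped in
  `mmse_config()` are a declared stand-in (six 2-point items in the
  attention domain, 1-point items elsewhere, summing to 30), not the actual
  survey instrument.
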
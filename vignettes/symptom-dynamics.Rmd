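---
title: "Multi-scale dynamics of autism-spectrum symptom expression: models, engine and estimation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale dynamics of autism-spectrum symptom expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdyn)
```

`asdyn` implements a mechanistic, multi-timescale dynamical framework for the
core symptoms of autism spectrum disorder. Each symptom domain is a
closed-form submodel whose parameters carry neurobiological interpretations
(precision-weighting of prediction errors, environmental entropy,
excitation/inhibition balance, social reward salience); a hierarchical engine
couples the submodels across timescales; and synthetic
ecological-momentary-assessment (EMA) machinery plus nonlinear least-squares
tooling make every claim about parameter estimability testable in
simulation. This vignette is the package's account of the science: the
models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic data do and do not emulate, and the design
decisions taken where the framework itself left the choice open.

## 1. The submodels

### 1.1 Social reciprocity as resource depletion

Reciprocal social engagement within a single interaction is modelled as an
exponentially depleting resource,

$$R(t) = \alpha R_0 \, e^{-\beta_{\mathrm{eff}} t}, \qquad
\beta_{\mathrm{eff}} = \beta_{\mathrm{base}}
\frac{1 + k_E E + k_\Lambda \Lambda_s + k_P \Pi_{\mathrm{load}}}
     {1 + k_M M + k_{Pr} Pr + k_I I}.$$

The mechanistic reading: long-range connectivity differences make social
processing executively expensive, so engagement decays with a rate that
rises with executive load $E$, concurrent sensory load $\Lambda_s$ and
predictive-processing load $\Pi_{\mathrm{load}}$, and falls with social
motivation $M$, environmental predictability $Pr$ and interest alignment
$I$. $\beta_{\mathrm{base}}$ is measured per hour; the theoretically
plausible band is 0.1–0.5 h⁻¹ and the population sampler draws from exactly
that range. All six sensitivity coefficients are dimensionless and
nonnegative; $\alpha R_0 \in [0,1]$ so the trajectory starts inside the unit
interval.

The printed form assumes a constant $\beta_{\mathrm{eff}}$. Inside the
engine the loads vary, so `reciprocity_trajectory()` uses the
integrated-hazard generalisation
$R(t) = \alpha R_0 \exp(-\int_0^t \beta_{\mathrm{eff}}(\tau)\,d\tau)$ with
trapezoidal accumulation; constant loads reproduce the closed form to
machine precision, and the suite checks invariance under grid refinement.

### 1.2 Nonverbal communication as multi-channel integration

Effectiveness is a weighted sum $N = \sum_i w_{\mathrm{norm},i}\,\eta_i\,x_i$
over six default channels (gaze, facial expression, gesture, posture,
paralinguistics, proxemics). $w_{\mathrm{norm},i}$ is the channel's
normative importance, $\eta_i \in [0,1]$ the individual's processing
efficiency, and $x_i$ the cue score. The model is deliberately linear —
channel heterogeneity, not interaction, is the phenomenon it encodes — and
`N` is not clamped; arbitrary channel registries are allowed beyond the six
defaults.

### 1.3 Relationship development as reward-modulated sigmoid growth

Each relationship $j$ follows
$a_j / (1 + e^{-k_j (t - t_j)})$ on a timescale of months, with
$a_j = a_{\max} (M_{\mathrm{soc}}/M_{\mathrm{norm}})$ and
$k_j = k_{\mathrm{base}} (R_{\mathrm{sal}}/R_{\mathrm{norm}})(1 - P_{\mathrm{var}})$:
low social motivation lowers the attainable depth, low reward salience and
high prediction-error variance slow growth. Total integration $C(t)$ sums
over relationships. The degenerate case $k_j = 0$ (e.g. $P_{\mathrm{var}} = 1$)
returns the analytic limit $a_j/2$ rather than an error — the sigmoid's
value at any finite time when its slope vanishes.

### 1.4 Stereotypies as entropy-regulated oscillation

$$M(t) = M_0 + \Gamma_{\mathrm{eff}} \sin(\omega t + \varphi), \qquad
\Gamma_{\mathrm{eff}} = \Gamma_{\max}
\frac{H_{\mathrm{env}}}{H_{\mathrm{env}} + k_H}
\cdot \frac{1}{1 + k_E E + k_\Phi \Phi_{\mathrm{alt}}}.$$

Repetitive movement is read as a homeostatic entropy-reduction mechanism:
amplitude rises with environmental entropy $H_{\mathrm{env}}$ (bits),
saturating with half-maximum at $k_H$, and is divided down by absorbing
engagement $E$ and by the availability of alternative regulatory behaviours
$\Phi_{\mathrm{alt}}$. Note the notation collision resolved in code: the
engagement sensitivity here is `k_engage` and the alternatives sensitivity
`k_alt`, distinct from the reciprocity submodel's `k_E`;
`notation_table()` prints the full symbol-field concordance.

The sinusoid may dip below $M_0$; no clamp is applied by default because
the model itself never clamps, but `clamp = TRUE` (and the scenario flag
`clamp_M`) floors the observable intensity at zero for observation realism.

Many stereotypies are bursty rather than continuous, so `simulate_bouts()`
provides the hybrid extension: bout onsets follow a non-homogeneous Poisson
process simulated by thinning, and within bouts the sinusoid applies. The
framework specifies only that the onset rate depends on entropy; we reuse
the amplitude's saturating form
$\lambda(t) = \text{rate\_scale} \cdot H/(H + k_H)$ so the package has a
single entropy nonlinearity, and accept any user-supplied rate function
bounded by `rate_scale` as a hook. Bout durations default to log-normal
(configurable to exponential or fixed): durations are positive,
right-skewed, and occasionally long, which a log-normal captures with two
parameters. Durations are truncated at the next onset so bouts never
overlap.

### 1.5 Insistence on sameness as precision-weighted prediction error

Distress at a deviation from routine $k$'s expected state is

$$S_k = \frac{s_k}{1 + e^{-r_k(|x_k - \bar{x}_k| - \theta_k)}}, \qquad
r_k = r_{\mathrm{base},k}\,\pi_k.$$

Bayesian precision $\pi_k$ steepens the response — with high precision even
small deviations beyond the tolerance threshold $\theta_k$ produce
near-maximal distress, the formal core of the "minor changes feel
catastrophic" phenomenon. The sigmoid floor $s_k/(1 + e^{r_k \theta_k})$ at
zero deviation is retained rather than forced to zero: it is what the
functional form implies, it is tiny for steep responses, and zeroing it
would break the analytic midpoint identity $S_k(\theta_k) = s_k/2$ that the
tests rely on.

Equifinality is first-class: `equifinality_profiles()` constructs, for any
target distress at a reference deviation, three mechanistically distinct
configurations — high precision, low threshold, high ceiling — that agree at
the anchor (closed-form, via the logit identity
$\theta = d - \mathrm{logit}(S/s)/r$) and demonstrably differ away from it.
These regimes carry different intervention implications, which is why the
package treats distinguishing them as a diagnostic operation.

### 1.6 Restricted interests as sustained reward

$$I(t) = I_0 + \sum_l b_l e^{-\lambda_l \Delta t_l}, \qquad
b_l = b_{\mathrm{base},l} \frac{R_{\mathrm{int},l}}{R_{\mathrm{norm}}}, \quad
\lambda_l = \lambda_{\mathrm{base},l} (1 - P_{\mathrm{acc},l}).$$

Each interest decays from its own acquisition time ($\Delta t_l$ is time
since acquisition, months); an interest not yet acquired contributes
nothing. High relative reward raises initial intensity; high within-domain
prediction accuracy suppresses decay, with $P_{\mathrm{acc}} = 1$ freezing
the term — the formal statement of interests that never fade.

### 1.7 Sensory sensitivity as cumulative load under habituation failure

Cumulative impact of stimulus $s$ over an exposure of length $T$ is
$P(s) = \int_0^T \sigma_s e^{-\delta_s t}\,dt$ with the net habituation rate
$\delta_s = \delta_{\mathrm{base},s}\,(\mathrm{GABA}_{\mathrm{func}}/\mathrm{GABA}_{\mathrm{norm}}) - k_{\mathrm{sens}}\,\Xi(t)$.
The three analytic branches — bounded saturation ($\delta > 0$), linear
accumulation ($\delta = 0$, habituation failure), exponential escalation
($\delta < 0$, sensitisation) — are evaluated in closed form.
Reduced GABAergic inhibition lowers $\delta$; arousal $\Xi$ can push it
negative, which is how anxiety converts a tolerable stimulus into an
escalating one. Unbounded accumulation past a regulatory threshold is the
model's account of delayed meltdown/shutdown.

One unit ambiguity is inherited from the framework: $\sigma_s$ is described
as a dimensionless sensitivity index *per hour*. We store it as a rate
(index per time unit) whose numerator is dimensionless, and
`dimensional_check()` treats $\sigma_s T$ products accordingly.

## 2. The composite index

The seven components are normalised to $[0,1]$ via
$z_i = (x_i - x_{i,\min})/(x_{i,\max} - x_{i,\min})$ and combined as
$A(t) = \sum_i w_i z_i$ with nonnegative weights summing to one (the
two-domain coefficients $\alpha_{1..3}, \beta_{1..4}$ map onto $w_{1..7}$ in
order; `domain_weights()` exposes that naming). Three points deserve
emphasis:

- **Orientation.** The framework calls $A$ a severity measure but never
  states the direction of the social-communication components, for which
  *higher* raw values mean *better* functioning. We therefore reflect
  $z \leftarrow 1 - z$ for `R`, `N`, `C` by default, controlled by a
  per-component orientation flag, so that larger $A$ always means greater
  symptom expression. This is a package decision, recorded in run metadata
  and fully configurable.
- **Bounds.** Defaults are theoretical where forced ($R \in [0,1]$, sums of
  ceilings elsewhere); the `P_total` ceiling uses the habituation-failure
  linear reference $\sum_s \sigma_s T_s$, widened to the realised trajectory
  when sensitisation exceeds it, so clipping (always warned and logged)
  marks genuinely out-of-band values. Bounds used are always recorded in the
  bundle metadata.
- **Redundancy.** $P_{\mathrm{total}}$ enters $A$ directly and also drives
  depletion through $\Lambda_s$; this partial double-counting is retained as
  acknowledged, and the metadata labels $A$ a descriptive summary. $A$ is
  never fed back into any mechanism.

## 3. The coupling engine

The submodels live on different timescales — seconds-to-minutes for sensory
load, minutes-to-hours for reciprocity and stereotypies, months-to-years for
relationships and interests — and are hierarchically coupled rather than
simultaneously solved. Within one fast step the engine updates, in
dependency order: cumulative sensory load (using the *previous* step's
arousal in the habituation rate — the one-step lag that keeps the graph
acyclic, asserted by topological sort at startup); the coupling
$\Lambda_s = P_{\mathrm{total}}/(P_{\mathrm{total}} + \text{capacity})$;
the depletion rate and reciprocity via integrated hazard; stereotypy
amplitude and intensity; sameness distress over active deviation events; and
the next-step arousal. Slow submodels are quasi-static within a fast
scenario and evaluated at the scenario age. The composite is computed last.

Three quantities the framework leaves unspecified are closed by explicit,
configurable package decisions:

- **The coupling map.** Only "$\Lambda_s$ increases with $P_{\mathrm{total}}$"
  is given; we use the saturating form above with a person-specific
  `capacity` (the load at which coupling is half-maximal) so that
  $\Lambda_s$ stays a bounded, dimensionless load.
- **Arousal dynamics.** No equation for $\Xi(t)$ is given; we use the
  minimal linear recursion
  $\Xi_{n+1} = \max(0,\, a\,\Xi_n + b\,\Lambda_{s,n} + c\,S_n)$ with
  per-person coefficients defaulting to $(0.8, 0.5, 0.5)$ — persistence plus
  drive from sensory load and acute distress, the smallest structure that
  produces lagged arousal feedback.
- **Recovery.** Removal of a stimulus stops accumulation; an optional
  first-order clearance of $P_{\mathrm{total}}$ (off by default, matching
  the monotone accumulation of the packaged scenario) models post-exposure
  decay, since recovery is asserted by the framework but given no rate.

**Units.** Profile rates are canonical — $\beta_{\mathrm{base}}$ and
$\omega$ per hour, relationship and interest rates per month — and the
engine converts them to the scenario time unit (minutes or hours).
Stimulus $\sigma$ and $\delta$ are interpreted in scenario time units.
This split exists to reproduce the framework's worked scenario literally:
its arithmetic computes $P_{\mathrm{total}} = 0.8 \times 90 = 72$ at
$t = 90$ minutes, i.e. a per-minute $\sigma$ with $\delta = 0$, even though
it also narrates $\delta_s \approx 0.02$ ("near-absent habituation") — an
internal inconsistency we resolve in favour of the printed arithmetic, with
$\delta$ exactly zero in the packaged scenario.

**The packaged restaurant scenario.** `restaurant_vignette()` encodes the
two-hour event: $\sigma = 0.8$, $\delta = 0$, $R_0 = 0.85$, executive load
0.4, predictive load 0.5, motivation 0.6, interest alignment 0.3 (raised to
0.9 at t = 75 when conversation turns to a restricted interest), entropy
rising linearly 3.0 → 5.5 bits, a seating-routine deviation of 0.6 at
t = 70 against $(\pi = 4.0,\ \theta = 0.3,\ s = 0.9)$, threshold 70, and a
15-minute reporting grid. The steepness $r_{\mathrm{base}}$ needed for the
narrated distress of 0.85 is not stated anywhere; it is a derived
calibration, $r_{\mathrm{base}} = \mathrm{logit}(0.85/0.9)/(0.3 \times 4) =
\log(17)/1.2 \approx 2.361$, and is treated as such (the tests verify it
against an independent bisection oracle, never as ground truth). Withdrawal
fires at the first *reporting-grid* time with
$P_{\mathrm{total}}$ strictly above threshold — 90 minutes, since
$P(75) = 60 \le 70 < 72 = P(90)$ — matching the narration cadence. Two
narrated magnitudes ($R(60) \approx 0.45$, $\Gamma_{\mathrm{eff}}$ rising
0.4 → 0.7) depend on parameters the framework never prints
(the $\Lambda_s$ path, $\Gamma_{\max}$); the packaged scenario matches them
qualitatively (monotone reciprocity decline, rising amplitude) and the suite
deliberately asserts only the qualitative shape.

```{r vignette-run}
b <- run_scenario(restaurant_vignette(), seed = 1)
b$series[b$series$time %in% c(0, 45, 70, 90, 120),
         c("time", "R", "beta_eff", "Gamma_eff", "S", "P_total", "A")]
b$events
```

## 4. Synthetic EMA data

`sample_profile()` draws a full person from independent uniform ranges (the
depletion rate from its stated 0.1–0.5 h⁻¹ band; the remaining ranges chosen
once as plausible regimes: moderate loads, sub-unit distress ceilings,
entropy half-saturations of 1–4 bits — see `default_population_spec()`).
`generate_environment()` produces piecewise-linear entropy, exposure
windows, and deviation events as a Poisson stream. `observe()` samples the
latent trajectory at EMA prompts — by default six per day with ±30 minutes
of uniform jitter, mirroring common EMA practice — adds independent Gaussian
noise and clips to each variable's valid range. Additive-Gaussian-with-clip
was chosen over a logit-normal model for simplicity; at the default noise
levels clipping is rare enough that the estimation module can ignore
censoring. Each observation carries its variable's identifiability tier
(1 = EMA-identifiable, 2 = structured observation, 3 = neuroimaging-informed)
so fitting runs can be restricted to realistic channels. The pipeline is
byte-reproducible from its seed triple (profile, environment/trajectory,
observation).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: no missing-not-at-random mechanisms (real EMA
compliance correlates with state), no actigraphy waveforms (bout sequences
stand in for movement counts), a single generic channel per variable where
real designs mix self-report and observer coding, and no clinical-instrument
scoring. Recovery results here are statements about the models' structural
identifiability under clean sampling, not about clinical feasibility.

## 5. Estimation and identifiability

`fit_submodel()` minimises the sum of squared residuals with
Levenberg–Marquardt, over a seeded Latin-hypercube multi-start (default 8)
inside box bounds; parameters are optimised on a logit-rescaled unbounded
scale so every iterate respects its bounds, and the best start by SSR wins.
Asymptotic standard errors come from the Jacobian at the optimum
($\hat\sigma^2 (J^\top J)^{-1}$); a near-singular information matrix is
reported as an identifiability note rather than an error, and
non-convergence is flagged in the result, not raised. The relationship
submodel's inflection bounds are filled from the observed time range — an
inflection is only locatable inside the design window.

**Canonical reparameterisation.** Several mechanistic products are not
separately identifiable from trajectories alone: $\alpha$ and $R_0$ enter
only through $\alpha R_0$; $r_{\mathrm{base}}$ and $\pi$ only through their
product; the interest coefficients only through $b_l$ and $\lambda_l$. The
registry therefore estimates the products (`R_amp`, `r`, `b`, `lambda`),
and the mechanistic factors are reported individually only when one member
is fixed by configuration. `identifiability_audit()` makes this concrete:
it ranks the Fisher-information spectrum of the *full* parameterisation on
the log scale, where an exact multiplicative confound appears as a
$(+1,-1)/\sqrt{2}$ null direction, and confirms that fixing one factor
removes it.

```{r audit}
identifiability_audit("reciprocity")
```

A caveat inherited from the framework's own tier analysis: $\delta_s$ and
$\beta_{\mathrm{base}}$ are classed as neuroimaging-informed (tier 3), yet
this package can only demonstrate their recovery from synthetic
trajectories, which overstates real-world identifiability; the tier tags on
EMA datasets exist precisely so that experiments can honour the realistic
restriction.

`recovery_experiment()` wraps the replicate loop
(draw truth → simulate → perturb → refit) and reports per-parameter bias,
RMSE, and the fraction of replicates with every parameter inside three
asymptotic standard errors.

## 6. Numerical choices

- **Series branch for $\delta \approx 0$:** the closed forms
  $(\sigma/\delta)(1 - e^{-\delta T})$ cancel catastrophically near zero, so
  for $|\delta| \le 10^{-8}$ h⁻¹ the second-order series
  $\sigma T (1 - \delta T/2 + (\delta T)^2/6)$ is used; continuity across
  the branch boundary is tested to $10^{-6}\sigma T$ and agreement with
  adaptive quadrature to $10^{-8}$ relative.
- **Hazard integration:** trapezoid on the scenario grid; exact for
  constant and linear-in-time rates, with step-halving stability asserted on
  the packaged scenario (< $10^{-3}$ relative at the endpoints).
- **Weight normalisation:** composite weights are renormalised on
  construction and on file load (with a message), then validated to
  $\Sigma w = 1$ within $10^{-12}$.
- **Degenerate inputs:** sigmoid growth at $k = 0$ returns the analytic
  limit $a/2$; empty stimulus lists give zero load; empty grids, negative
  loads, nonpositive capacities and dangling event references are errors
  with named causes.
- **Thinning:** bout onsets use the dominating homogeneous rate
  `rate_scale` (the saturating form is bounded by it), so acceptance
  probabilities are exact and no rate envelope needs tuning.
- **Determinism:** every stochastic operation takes an explicit seed;
  same-seed runs are byte-identical, and trajectory CSVs round-trip within
  float precision.

**Problem sizes.** The test suite and acceptance script use sizes chosen to
make Monte-Carlo checks sharp but quick on a single CPU: 1000-draw property
sweeps, 200-replicate bout calibration (3-standard-error band around the
Poisson mean of 100), 50-replicate noisy recovery at 200 observations per
fit, and 120-point noiseless round-trips; the full suite runs in about half
a minute.

## 7. Known limitations

The framework is theory-derived and the package inherits that status: no
empirical dataset exists, parameter ranges are plausibility bands, and the
packaged scenario is an illustration, not data. Cross-domain couplings
beyond those specified (sensory load into depletion; entropy into
amplitude; arousal into habituation) are absent by design, as are
developmental parameter drift ($\beta_{\mathrm{base}}$ as a function of
age is an extension point, not a feature), mixture/subtype structure,
hierarchical-Bayesian and state-space estimators (interface stubs only),
and clinical-instrument integration. The composite index is a descriptive
summary with acknowledged redundancy; a structural-equation decomposition
of shared variance is explicitly out of scope.
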
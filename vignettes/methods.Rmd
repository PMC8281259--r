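---
title: "Methods: circulation modelling, assimilation and identifiability in cardiolpn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulation modelling, assimilation and identifiability in cardiolpn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The circulation model

`cardiolpn` represents the adult circulation as a closed-loop electrical
analogue with seven compartments: four heart chambers, an aortic
capacitor, a systemic RCR block and a pulmonary RC block. Pressure plays
the role of voltage, flow of current; resistances model viscous losses,
capacitors vessel compliance, and inductors blood inertia at the valves.

Each chamber's pressure is the sum of a passive exponential curve and an
activation-scaled linear active curve,

$$P_i = K_{pas1,i}\left(e^{K_{pas2,i}(V_i - V_{0,i})} - 1\right)
      + A_i(t)\,E_{act,i}(V_i - V_{0,i}),$$

with half-cosine activation windows. The cycle starts at the onset of
ventricular systole; the ventricular window spans $[0, t_c t_{svs})$ and
the atrial window is positioned by the delay $t_{pw} = t_c / t_{pws}$. The
delay enters as a *divisor* of the cycle length; a product convention
would be equally plausible a priori, but the divisor form is what the
chamber-timing interface exposes, and `t_pws` is an ordinary free
parameter so the data can move the atrial kick within its admissible
window.

Valves are perfect and one-way. A valve is open if and only if its
upstream pressure strictly exceeds its downstream pressure; the
measure-zero equality case is treated as closed. While open, the flow
follows $\dot Q = (P_{up} - P_{dn} - RQ)/L$; on closure the flow state is
reset to zero rather than frozen, because a frozen state would re-inject
stale momentum when the valve reopens. Chamber volumes therefore never
receive retrograde flow, and the sum of chamber volumes and capacitor
charges ($\sum V + C_{ao}P_{ao} + C_{sys}P_{sys} + C_{pa}P_{pa}$) is an
exact invariant of the continuous dynamics — a property the test suite
verifies to integrator precision.

## Numerical integration

The right-hand side switches discontinuously at valve events, which makes
high-order adaptive stiff solvers unattractive: their step-size control
chatters at the switching surfaces and run-to-run reproducibility suffers.
We integrate with a fixed-step classical Runge-Kutta (RK4) scheme at 1000
steps per cardiac cycle ($\Delta t = t_c/1000 \approx 0.75$ ms), applying
the valve reset after each full step. Halving the step changes every
reported waveform extremum by well under 0.5%, so the scheme is in its
convergence regime. Integration proceeds cycle by cycle from the initial
conditions (which are themselves model parameters) until the relative
change of every state's cycle mean drops below $10^{-4}$, with a cap of 50
cycles; unconverged runs are flagged and score $-\infty$ in the
likelihood. The integrator core is compiled C++ (Rcpp); a pure-R reference
implementation of the same right-hand side is exported and cross-checked
against the compiled one in the tests.

Because a valve closes the instant its pressure gradient reverses (not
when flow reaches zero), late ejection can show brief close/reopen
chatter: the flow state is cut to zero mid-deceleration, the upstream
pressure rebuilds, and the valve reopens. This is the literal behaviour
of the gradient-switched valve law. It leaves volumes and pressures
well-behaved (the conservation checks pass to integrator precision), but
it makes *sampled* valve-flow averages overestimate the effective
transvalvular flow by O(jump × dt); cycle-averaged flow balances are
therefore always assessed through the continuous fluxes (the resistive
branches) or through volume excursions, never through sampled valve-flow
means.

Internally everything runs in CGS units (Barye, mL, s; 1 mmHg = 1333.22
Barye); all user-facing inputs and outputs are clinical (mmHg, L/min, bpm,
ms, dynes·s·cm⁻⁵).

## Parameters, anchors and the prior box

The model has 45 parameters: 4 timing, 16 chamber, 8 valve (R, L), 6
circuit, and 11 initial conditions. Valve resistances and inertances are
frozen by default — valvular stenosis is assumed to have been excluded as
a cause of hypertension — leaving 37 free parameters; the mask is
configurable because the left-heart valve resistances are physiologically
interesting in their own right.

Default parameter values are the package's own *anchors*: a healthy and a
severe diastolic-dysfunction parameter set calibrated once, with the
package's own MCMC-plus-Nelder-Mead machinery and a fixed seed, against
the healthy and severe columns of the shipped validation table, then
stored as plain-text fixtures. The moderate anchor is the parameter-space
midpoint. The independent uniform prior box was chosen to span adult
physiology from health to severe failure with generous margins (roughly a
factor 3-10 around the anchors in each coordinate); it is deliberately
wide, which makes the non-identifiability findings below meaningful.

# Clinical target extraction

`extract_targets()` maps one converged cycle to 26 EHR-style quantities
plus auxiliary validation quantities. Most maps are direct (systolic
pressure = waveform maximum, cardiac output = heart rate times stroke
volume, and so on). Conventions worth stating:

* **Wedge pressure.** The pulmonary RC block has no capillary node, so the
  time-averaged left-atrial pressure serves as the wedge surrogate.
* **Mean PAP.** Model side: time mean of $P_{pa}$. Data side, when only
  systolic/diastolic values are recorded: the standard clinical estimate
  $(s + 2d)/3$.
* **End-diastolic pressures.** Chamber pressure at inflow-valve closure
  (the closure instant with the largest chamber volume if several exist).
  Because filling flow is non-negative, this instant coincides with the
  volume maximum.
* **Mitral E/A and deceleration time.** The atrial activation onset
  splits diastole into the E and A windows; the E peak is the maximum
  mitral flow before it, the A peak after it. The deceleration time
  extrapolates a line fitted to the descending E limb between 90% and 30%
  of the peak down to zero flow.
* **Valve gradients.** Instantaneous model pressure differences over the
  ejection window — a modelling convention, not the clinical Bernoulli
  $4v^2$ estimate.
* **`lvot_max_flow`** is reported (peak aortic-valve flow) but excluded
  from likelihoods by default since it carries no assigned uncertainty.

Landmark failures (e.g. no A wave when atrial activation is absent) mark
the token unavailable instead of raising an error; the likelihood treats a
requested-but-unavailable token as a rejection.

# Inference

With $m$ available targets, independent Gaussian errors give
$$\log L = -\tfrac{m}{2}\log 2\pi - \sum_i \log\sigma_i
 - \tfrac12 \sum_i \frac{(d_i - G_i(y))^2}{\sigma_i^2},$$
combined with the uniform box prior. Two training routes are provided and
usually composed: DREAM MCMC for exploration, then repeated Nelder-Mead
for MAP refinement from the best draw (`refine_map()`).

* **Nelder-Mead protocol.** Default 20 restarts drawn uniformly from the
  prior box, each capped at 2000 evaluations with relative tolerance
  1e-6, in box-normalised coordinates; out-of-box excursions are
  penalised. Warm-start points can be supplied.
* **DREAM defaults.** 10 chains; differential-evolution jumps with
  $\delta \in \{1,2,3\}$ pairs, $\gamma = 2.38/\sqrt{2\delta d'}$ on a
  crossover-selected subspace with 3 adaptive crossover levels, 10% unit
  jumps for mode hopping, $10^{-6}$ proposal noise; outlier chains
  replaced by an IQR rule on second-half mean log-posterior during
  burn-in (first half); Gelman-Rubin threshold 1.1 on the kept half.
  Out-of-box proposals are rejected through the prior; reflection is
  available as an option.
* **Seeds.** Every stochastic entry point takes an explicit integer seed;
  cohort analyses derive per-patient seeds as base + patient index.

For *structural identifiability* self-fits — where the data are exact
model outputs rather than noisy measurements — the assumed measurement
model is an artifice. The sampler keeps the clinical standard deviations
(so learning factors remain comparable with the practical setting), while
the final Nelder-Mead refinement tightens the assumed noise by a factor of
ten: with noiseless on-manifold data the optimum is exact recovery, and
without the tightening the optimizer has essentially no gradient once
residuals fall below a tenth of the clinical uncertainty. Chains are
initialised away from the generating parameters (other severity anchors
plus prior draws) so recovery is non-trivial.

# Sensitivity, identifiability, admissibility

Local sensitivities are one-sided (forward) relative differences at a 1%
step, as is conventional for reporting; the Fisher-information Jacobian
instead uses central differences at the same relative step for symmetry —
an intentional, documented asymmetry. The FIM is $J B J^T$ with
$B = \mathrm{diag}(1/\sigma_i^2)$; near-zero eigenvalues flag
non-identifiable parameter combinations, with a default cut-off of
$10^{-13}$ and a sweepable range $[10^{-16}, 10^{-12}]$ over which flag
counts are insensitive. The learning factor
$\theta_j = 1 - \mathrm{Var}_{post}/\mathrm{Var}_{prior}$ (uniform prior
variance $(b-a)^2/12$) and the coefficient of variation summarise marginal
shrinkage.

Admissibility compares the assumed target Gaussian against a Gaussian
kernel density estimate (Scott's bandwidth) of posterior-predictive
samples via $KL(\mathrm{target}\,\|\,\mathrm{predicted})$ — the direction
that measures information lost by using the prediction in place of the
assumption — integrated by trapezoid on a $\mu \pm 6\sigma$ grid with the
predicted density clipped at $10^{-12}$. The integrator is validated
against the closed-form Gaussian KL before any KDE use.

# Synthetic cohorts

`generate_cohort()` emulates the structure of a sparse clinical EHR table:
ground-truth parameters are drawn by interpolating healthy-to-severe
anchors with a severity blend (±0.15 jitter) and ±5% per-parameter
multiplicative jitter, clipped to the prior box; targets are extracted
from a converged simulation; zero-mean Gaussian noise with the dictionary
standard deviations is added (resampling non-physical draws); and a
missingness pattern with modes at 4, 8 and 17 available targets is
applied, heart rate and systemic pressures always present, missing
completely at random within a mode. Ground-truth PH labels come from the
noiseless pulmonary values.

What the generator does *not* emulate: correlated measurement errors,
protocol-driven (informative) missingness, inter-patient covariance
beyond the one-dimensional severity blend, measurement-type mixtures
(echo vs catheter), or comorbidity structure. Passing tests on these
cohorts therefore demonstrates internal consistency of the pipeline —
recovery of quantities the model itself generated — not clinical validity
on real EHR data.

# Problem sizes and design choices in the shipped analyses

The test-suite and acceptance analyses run at desk scale, chosen so the
full suite completes in tens of minutes on one CPU: severity fits use a
short DREAM warm start (9 chains × 300 generations across the severity
anchors) followed by repeated Nelder-Mead refinement (roughly 2 × 10^4
evaluations); admissibility posteriors use 10 chains × ~2000 generations
with 8 crossover levels and ~300 propagated draws; the self-fit posterior
uses 10 × 2500 generations from anchors-plus-prior starts;
pulmonary-blind prediction uses 6 × 500 generations and 250 draws per
patient on a 10-patient cohort; the ranking demo fits with 1 restart ×
150 evaluations per candidate. These sizes are scaled-down versions of
the reference protocol (10 chains, 5000 generations, 5000 propagated
draws) and the documented defaults remain the reference values.

Other deliberate choices:

* **Greedy ranking budgets.** The forward-selection sweep is quadratic in
  the number of candidates, so per-candidate fits use reduced Nelder-Mead
  budgets (5 restarts × 500 evaluations by default); ties in the argmin
  are broken by dictionary order of the tokens for reproducibility.
* **Classifier.** Gaussian naive Bayes (features are continuous), with a
  variance floor of $10^{-9}$ times the largest feature variance so that
  constant imputed columns stay well-defined. Imputation statistics are
  learned on the training fold only — whole-matrix imputation would leak
  test information through the fill values — and balancing touches the
  training fold only.
* **Threshold rule.** PH if mean PAP > 25 mmHg or systolic PAP > 35 mmHg,
  strictly; patients with neither quantity determinable are excluded as
  unlabelled.

# Known limitations

* The elastance chamber has no relaxation-rate (tau) parameter, so it
  cannot reproduce the *impaired-relaxation* (E/A < 1) Doppler pattern of
  early diastolic dysfunction: raising passive stiffness increases filling
  pressures and drives the simulated mitral inflow toward the restrictive,
  E-dominant pattern instead. The E/A ratio is therefore a monotone marker
  of stiffness here, not a stage-resolved one.

* The wedge and mean-PAP surrogates are conventions; other choices shift
  absolute pulmonary errors.
* End-diastolic pressure sampled at inflow-valve closure inherits the
  atrial-kick pressure elevation, which makes very low LVEDP targets
  (healthy physiology) hard to match exactly — visible as the largest
  residual in the healthy validation fit.
* The model is structurally non-identifiable (by design of the analysis):
  MAP parameter values, in particular unstressed volumes and the
  systemic arterial/venous resistance split, should be interpreted only
  through model outputs or posterior summaries.
* Valve regurgitation/prolapse, baroreflex regulation, and 1D/3D
  hemodynamics are out of scope.
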
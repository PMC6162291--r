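---
title: "Models and calibration methods in tumorcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and calibration methods in tumorcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorcal)
```

`tumorcal` calibrates the parameters of an avascular tumor growth model —
apoptosis, proliferation, necrosis and cell mobility — against in vitro
viability time courses and time-resolved microscopy fields, one mechanism
at a time. This vignette describes the models, the likelihoods and error
metrics, the sampler, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The model hierarchy

The fullest model in the package is a two-field phase-field description of
a monolayer tumor culture on a 2D domain with zero-flux boundaries. The
state is the total tumor volume fraction $\phi_T(x,t) \in [0,1]$ and the
necrotic fraction $\phi_N(x,t) \le \phi_T$; the viable fraction is
$\phi_V = \phi_T - \phi_N$. Adhesion among tumor cells is encoded by the
free energy

$$E[\phi_T] = \int_\Omega \Psi(\phi_T)
  + \tfrac{\varepsilon_T^2}{2}\,|\nabla \phi_T|^2 \, dx, \qquad
  \Psi(\phi) = \bar{E}_T\, \phi^2 (1-\phi)^2,$$

whose quartic double well drives segregation into the pure phases
$\phi_T = 0$ and $\phi_T = 1$; the interaction length $\varepsilon_T$
(micrometers) sets the interface thickness. Mass moves down gradients of
the chemical potential $\mu = \Psi'(\phi_T) - \varepsilon_T^2 \Delta
\phi_T$ with a mobility degraded by the (immobile) necrotic fraction,
$\bar{M}_T = M_T (1 - \phi_N/\phi_T)$. Growth, apoptosis and
nutrient-gated necrosis enter as local source terms:

$$\partial_t \phi_T = \nabla \cdot \bar{M}_T \nabla \mu
  + \lambda_{prol}\, \phi_\sigma\, \phi_V \left(1 - \tfrac{\phi_T}{K}\right)
  - \lambda_{apop}\, \phi_V, \qquad
\partial_t \phi_N = \lambda_{VN}\, \mathcal{H}(\sigma_{VN} - \phi_\sigma)\,
  \phi_V.$$

$\phi_\sigma \in [0,1]$ is the prescribed nutrient fraction (the
experiment's FBS percentage divided by 10), $K \in (0,1]$ the carrying
capacity, and $\sigma_{VN}$ the nutrient threshold below which viable
cells transfer to the necrotic compartment. We fix $\sigma_{VN} = 1$
(the 10% FBS vendor-optimal level): every reduced-nutrient condition then
has the gate open, and the fully fed condition has it shut. The gate is
evaluated with a strict inequality, $\phi_\sigma < \sigma_{VN}$, so that
optimally fed cultures undergo no necrosis; because $\phi_\sigma$ is a
per-scenario constant, the gate never switches during a run.

Each calibration experiment isolates a mechanism, which reduces the full
model to something far smaller:

* **Apoptosis** (Mitomycin-C–treated, fully fed): proliferation is
  chemically inhibited and nutrient is ample, so
  $d\phi_V/dt = -\lambda_{apop}\phi_V$ — pure exponential death.
* **Proliferation** (untreated, fully fed): logistic growth minus
  apoptosis, $d\phi_V/dt = \lambda_{prol}\phi_\sigma \phi_V (1 -
  \phi_V/K) - \lambda_{apop}\phi_V$, with $\phi_\sigma = 1$.
* **Necrosis** (reduced FBS): the two-compartment system in
  $(\phi_T, \phi_N)$ above without the transport term, with the gate open.
* **Mobility** (12-hour imaging window): proliferation and death are
  negligible on that time scale, leaving the mobility-only
  Cahn–Hilliard equation $\partial_t \phi_T = \nabla\cdot \bar M_T
  \nabla\mu$.

Each reduced model has a closed-form or semi-closed-form solution in some
limit (pure exponential; shifted logistic with rate
$r = \lambda_{prol}\phi_\sigma - \lambda_{apop}$ and effective capacity
$K_{eff} = K(1 - \lambda_{apop}/\lambda_{prol}\phi_\sigma)$; starvation
decay at rate $\lambda_{apop} + \lambda_{VN}$ when $\phi_\sigma = 0$).
These closed forms are exported (`*_closed_form()`) purely as independent
oracles; the calibration pipeline always integrates numerically.

## Numerics

**ODEs.** All reduced models are integrated by classical fixed-step
fourth-order Runge–Kutta (`rk4_integrate()`), default step 0.01 day. The
integrator accepts matrix states, which the posterior-predictive machinery
uses to advance an entire parameter ensemble at once
(`ensemble_trajectories()`). Inside MCMC the step is 0.05 day: with daily
observations and rates below 1/day the fourth-order local error is many
orders below measurement noise. The test suite pins the solver against the
closed forms at 1e-6 relative (1e-8 for the pure exponential) and against
an independent adaptive solver.

**The phase-field solver.** Space is discretized by second-order finite
differences on a uniform grid (fields are `ny x nx` matrices; origin
top-left, x rightward, y downward, pixel centers at $(i+\frac12)h$).
Zero-flux conditions are imposed by mirror ghosts; a periodic variant
exists for analysis harnesses. Time stepping uses the convex
(contractive–expansive) splitting of the double well,
$\Psi = \Psi_c - \Psi_e$ with $\Psi_c = \tfrac32 \bar E_T \phi^2$: the
linear contractive term and the $-\varepsilon_T^2\Delta$ term are
implicit, the expansive derivative is explicit, and the degraded mobility
is lagged one step. Each step is then a single sparse linear solve,
performed by a sparse direct factorization (reused across steps whenever
the mobility field cannot change, e.g. whenever $\phi_N \equiv 0$); the
relative residual is checked against 1e-10 and a convergence error names
the step and residual on failure. Direct solves were chosen over an
iterative method because the grids in scope (up to 64×64 at the imaging
resolution used here) factor in milliseconds and remove a tolerance knob.

Two discrete invariants follow from this construction and are enforced by
tests rather than by fixes at run time: the face-flux form conserves total
mass to solver precision, and the scheme dissipates the discrete energy
$\sum \Psi(\phi) h^2 + \tfrac{\varepsilon^2}{2}\sum_{faces}(\Delta\phi)^2$
at every step. During development the energy test and a linear-stability
oracle (decay rate of a small cosine mode, $M k^2(\Psi''+\varepsilon^2
k^2)$ with the discrete Laplacian symbol) caught a sign error in the
explicit splitting term — which is precisely why both are kept in the
suite.

**Bounds.** The quartic-potential Cahn–Hilliard equation obeys no maximum
principle: marginally resolved interfaces produce Gibbs-type under- and
overshoots of order a few percent. The solvers therefore never clamp the
evolving state; they raise an invariant-violation error if $\phi_T$
leaves $[-\delta_b, 1+\delta_b]$ with `bound_tol` $\delta_b = 0.05$ by
default, which flags genuine blow-up while tolerating ordinary
discretization overshoot. The ordering $0 \le \phi_N \le \phi_T$ is
checked at the much tighter $10^{-6}$. Observation-side clamping to
$[0,1]$ happens only where the data contract requires it (TIFF export,
synthetic observed frames).

**Operator splitting.** The full model advances by Lie splitting: one
semi-implicit Cahn–Hilliard step, then the local reaction terms pointwise
by RK4 over the same step. For spatially uniform states the transport
term vanishes identically and the trajectory collapses to the reduced
ODE system; the suite checks this homogeneous limit at 1e-8.

## Calibration

**Likelihoods.** Measurement noise and model inadequacy are collapsed
into a single zero-mean Gaussian with a calibrated standard deviation
$\sigma$. For viability time courses the log likelihood sums over
$N_t$ days and $N_r$ replicates of
$-\tfrac12\log(2\pi\sigma^2) - (y^{ij} - d_j(\theta))^2/2\sigma^2$. For
spatial data the model-data residual per frame is $1 - \mathrm{PCC}$,
the Pearson correlation between the observed and simulated fields paired
pixel by pixel, inserted into the same Gaussian form. The first frame
seeds the simulation and is skipped by default (its correlation is
trivially 1). $\sigma$ priors are $U(10^{-5}, 20)$ for time-course
stages and $U(10^{-5}, 0.2)$ for mobility.

**Sampler.** `run_mcmc()` is an adaptive random-walk Metropolis sampler
with a diagonal Gaussian proposal. During burn-in a global scale is tuned
toward 20–40% acceptance and the per-parameter scales are periodically
reset from the trailing window's standard deviations (scaled
$2.38/\sqrt{p}$); the proposal is frozen after burn-in so retained draws
target the exact posterior. Chains start from the best of 200 prior
draws — with the wide uniform priors used at stage one, most prior mass
lies where the likelihood is flat, and a purely random start can
otherwise spend the whole burn-in wandering. Acceptance rate and a crude
autocorrelation-based effective sample size are reported. The sampler is
validated against the conjugate-Gaussian posterior (mean and sd within
2% at $10^5$ draws) and is bit-reproducible given a seed.

**Sequential prior propagation.** The study design calibrates stages in
order: apoptosis → proliferation → necrosis (per FBS level and density),
with mobility independent. Each stage's posterior marginals are fitted
with a moment-matched Normal and (for positive draws) a LogNormal; the
family whose CDF is closer to the empirical one in the L1 sense is kept,
truncated to the parameter's original support, and becomes the
downstream prior (`posterior_to_prior()`). Parametric fits were chosen
over raw-sample kernel densities for cheap downstream density
evaluation; a kernel-density option (`method = "empirical"`) is
retained. Every replaced entry records its source stage, so provenance
is auditable, and a missing upstream stage raises a dependency error.

**Predictions and error.** Posterior-predictive bands resample parameter
vectors, simulate each, and report the pointwise mean and equal-tail 95%
band. The calibration error at each measurement day is the L1 distance
between the empirical CDFs of the predictive draws and of the day's
replicates, normalized by the day's data mean; the integrand is piecewise
constant between merged sample points, so the integral is evaluated
exactly. Errors average arithmetically across days and are reported as
percentages. The same metric with parameter samples measures the
prior-to-posterior `distribution_shift()`, normalized by the prior mean.
Whether the model-side CDF should come from predictive draws or from the
deterministic mean trajectory is genuinely open; predictive draws are the
default because they propagate parameter uncertainty, and a
mean-trajectory comparison can be had by passing that trajectory as the
sample.

**Cross-validation.** `cross_validate()` holds out one replicate at a
time: it calibrates on the rest, simulates the predictive ensemble with
the held-out replicate's first measurement as the initial condition, and
scores the prediction against the held-out series with the same metric.

## The synthetic study

`synthetic_study_spec()` fixes the ground truth and design of a synthetic
study shaped like the in vitro one: five seeding densities
(5×10³–1×10⁵ cells/ml) under Mitomycin-C for 7 days; the same five
untreated at 10% FBS for 21 days; three densities at each of four
reduced-FBS levels (0–7.5%, mapped to $\phi_\sigma$ = 0–0.75) for 7 days;
and five FBS levels of 2D field series imaged every 30 minutes for 12
hours. Four replicates per time-course scenario; additive Gaussian noise
on the volume-fraction scale with scenario-level sd equal to 5% of the
day-0 signal; negative draws floored at zero and flagged per observation.
Initial volume fractions come from the anchored linear conversion
(`seeding_density_to_volume_fraction()`), which is proportional through
the origin — the five printed day-0 fractions are exact multiples of one
another, so an intercept would be unidentifiable and is fixed at zero.

Default truths sit centrally in the ranges calibrated for this cell line
($\lambda_{apop} = 0.09$, $\lambda_{prol} = 0.5$, $K = 0.14$ per day
resp. dimensionless; $\lambda_{VN}$ from $e^{-5.5}$ at 7.5% FBS to
$e^{-2.2}$ at 0%; $M_T = 200$ μm/day, $\varepsilon_T = 30$ μm,
$\bar E_T = 0.65$). They are fixture choices for recovery experiments,
chosen once, not measured claims. Mobility fields start from clusters of
viable cells (sums of tanh-profile bumps) because that is the
configuration such experiments start from; with that initial condition
the double-well energy scale is barely informed by 12 hours of dynamics,
so the scaled-down mobility recovery fixes $\bar E_T$ and
$\varepsilon_T$ at truth and calibrates $M_T$ and $\sigma$.

What the generator does **not** emulate: fluorescence units and
background (observations are generated directly on the volume-fraction
scale, so unit-conversion error is exercised only through the anchored
linear map); spatial segmentation error beyond i.i.d. pixel noise;
replicate-level systematic effects (plate position, pipetting bias);
non-Gaussian or multiplicative noise (a multiplicative option exists but
is off by default); and any 3D or microenvironmental structure. Passing
recovery tests therefore demonstrates the *inferential machinery* is
correct and calibrated under the stated noise model — not that the model
is adequate for any particular real dataset.

## Problem sizes and defaults

The package's documented defaults are study-scale (200,000 predictive
draws); tests and the bundled acceptance analysis use deliberately
smaller, seed-pinned configurations chosen to keep full recovery
experiments comfortable on a single core: 4,000 retained draws after
2,000 burn-in for time-course stages, 800/400 for the mobility stage,
2,000-draw predictive ensembles, a 64×64 grid for solver-invariant checks
and 32×32 for mobility recovery (1160 μm domain — the microscope montage
size — at 36 μm pixels), and a 1/96-day solver step against 1/192-day
generation so the inference grid never reuses the generator's exact
trajectory. At these sizes the apoptosis-rate 95% credible interval
covers the truth in 20/20 seeded repetitions with posterior-mean relative
errors around 10%, and the chained stages recover
$(\lambda_{prol}, K, \lambda_{VN})$ within their 95% intervals while
moving the upstream $\lambda_{apop}$ prior by under 3% in the L1-CDF
sense — the quantities `scripts/acceptance.R` recomputes from scratch.

## Known limitations

* The sampler is single-chain random-walk Metropolis; multimodal
  posteriors (not observed in these stages) would need tempering or an
  ensemble sampler.
* Degenerate noise ($\sigma \to 0$) pushes $\sigma$ against its prior
  bound and slows mixing; the noise-free cross-validation oracle needs
  the longer chain configuration used in its test.
* The mobility stage's identifiability is limited by design: 12 hours of
  near-equilibrium cluster dynamics inform $M_T$ through frame
  correlations only, so its posterior is wide and skewed; the package
  reports the full interval rather than a point estimate.
* `M_T` carries the nominal unit μm/day; its dimensional role inside a
  fourth-order operator is treated as a label, not reinterpreted.
* Volume fractions are treated as exact transforms of the assay signal;
  anchor uncertainty on day 0 is not propagated.
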
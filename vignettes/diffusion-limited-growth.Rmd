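---
title: "Diffusion-limited tumor growth: model, estimation and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-limited tumor growth: model, estimation and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlgrowth)
```

## The model

Preclinical tumor growth is usually described by a rate equation
$\dot V = g(V) - \ell(c)\,V$ for the measured volume, with $g$ an empirical
growth function and $\ell(c)$ an exponential-kill treatment term driven by
the plasma drug concentration $c(t)$. dlgrowth implements a mechanistic
alternative in that same mathematical shape. A spherical tumor of radius
$R$ consumes nutrient that diffuses in from the surface; when $R$ exceeds a
critical radius $R_c$, the center falls below the viability threshold and a
necrotic core of radius $R_n$ forms. At the quasi-steady state of the
spherical diffusion problem (uniform consumption in the live shell, no flux
into the core) the core radius satisfies

$$R^2 - 3R_n^2 + \frac{2R_n^3}{R} = R_c^2 ,$$

and the growing (proliferating) volume fraction is $G = 1 - (R_n/R)^3$.
The volume then evolves as

$$\dot V = \lambda\,G\,V \;-\; \lambda_n\,(1-G)\,V \;-\; k\,c(t)\,G\,V ,$$

with $\lambda$ the net proliferation rate in the growing fraction,
$\lambda_n$ the rate of breakdown and removal in the necrotic core, and $k$
the drug potency; the drug kills only living (proliferating) cells. Below
the critical volume $V_c = \tfrac{4\pi}{3}R_c^3$ the tumor is fully
proliferating ($G = 1$) and grows exponentially. The five parameters —
$\lambda$ (day$^{-1}$), $\lambda_n$ (day$^{-1}$), $k$ (kg mg$^{-1}$
day$^{-1}$), $R_c$ (cm), $V_0$ (cm$^3$) — are all observable quantities,
and the model additionally *predicts* the growth fraction over time, which
can be checked against endpoint Ki-67 histology through the central
cross-section relation: the necrotic area fraction of an equatorial section
is $(R_n/R)^2 = (1-G)^{2/3}$ (`necrotic_area_fraction()`).

Pharmacokinetics are single-exponential: bolus doses (mg/kg) raise the
concentration instantaneously and decay at `k_elim`; the default
corresponds to the 12-hour plasma half-life of irinotecan (CPT-11),
$k_e = \ln 2 / 0.5\ \mathrm{day}^{-1}$. Concentration is the superposition
of all past doses, right-continuous at dose times.

## Numerical treatment of the constraint

The constraint is scale-invariant: with $x = R_n/R$ and $s = (R_c/R)^2$ it
becomes $2x^3 - 3x^2 + (1 - s) = 0$, whose physical branch has the exact
trigonometric root

$$x(s) = \tfrac12 + \cos\!\Big(\tfrac{2\pi - \arccos(2s-1)}{3}\Big).$$

`solve_necrotic_radius()` evaluates this closed form by default (a
bracketed Brent solve is retained as `method = "brent"`; the test suite
checks both against a dense sign-scan of the constraint). $G(V)$ is
continuous and continuously differentiable through the onset $V = V_c$ (its
derivative vanishes there), so the right-hand side of the volume equation
is $C^1$ and integrators do not need to treat the onset as a hard event.

Two integration routes are provided and cross-validated:

* **algebraic** (default): integrate $V$ alone, re-solving the constraint
  exactly at every right-hand-side evaluation;
* **ode**: the differentiated-constraint route, integrating
  $(V, z = R_n^2)$. The squared radius is used because
  $\dot z = 2 R'(R_n^2 + R_n R + R^2)/(3R)$ is finite at onset while
  $\dot R_n \propto 1/R_n$ is singular; crossings of $V_c$ in either
  direction (growth into necrosis, drug-induced shrinkage back to full
  proliferation) are located by the integrator's root finder and the
  integration restarts at each.

Both routes split the time axis at dose events and use the exact
within-segment exponential concentration, so the solver never steps across
a discontinuity. A compiled fixed-step RK4 core (step 0.02–0.05 day)
implements the algebraic route for the estimation machinery, where millions
of model evaluations are needed; it agrees with the `deSolve` reference to
better than $10^{-6}$ relative error in the tests.

## Spatially limited drug penetration

For large-molecule drugs the assumption of a uniform intratumoral
concentration fails. In the spatial extension the drug obeys the same
quasi-steady spherical diffusion balance as the nutrient, with uptake
proportional to concentration: on the live shell $R_n \le r \le R$,
$c(R) = c_b(t)$ (the applied plasma concentration), zero flux at $R_n$, and
dimensionless penetration parameter $\rho$ (collecting decay, uptake
efficiency and diffusivity). The profile is
$c(r) = (A\sinh(\rho r/R) + B\cosh(\rho r/R))/r$ with the constants fixed
by the boundary conditions; `shell_profile()` evaluates it in a
shifted-exponential form stable for arbitrarily large $\rho$. The kill term
becomes the shell integral
$k\,\frac{3}{R^3}\int_{R_n}^{R} c(r)\,r^2\,dr$ (`effective_kill()`,
adaptive quadrature at relative tolerance $10^{-8}$), which reduces
*exactly* to $k\,c_b\,G$ for $\rho = 0$. At $\rho = 0$ the whole spatial
trajectory coincides with the non-spatial one; as $\rho$ grows the drug is
confined to the surface and the treatment effect weakens monotonically.
$\rho$ is held fixed over a simulation by default, matching how penetration
sweeps are usually presented; a `"physical"` mode rescales it with $R$
instead, since the underlying decay length, not $\rho$ itself, is the
material constant. The quasi-steady assumption reflects that drug diffusion
equilibrates in minutes–hours while the geometry changes over days.

## Comparator growth laws

`growth_law()` provides the standard empirical laws (linear, exponential,
logistic, Gompertz, exponential-linear, surface growth, proliferative rim)
under the same dosing interface, with the kill acting on total volume since
these laws carry no growth fraction. The exponential-linear (EL) model uses
the smooth transition
$g(V) = \lambda_0 V / (1 + (\lambda_0 V/\lambda_1)^{\psi})^{1/\psi}$ with
$\psi = 20$ fixed, making it effectively three-parameter plus potency; the
power is evaluated in log space so large volumes cannot overflow. The
surface-growth law is $a V^{2/3}$ and the proliferative-rim law multiplies
the rate by the volume of an outer shell of fixed thickness; these are the
conventional forms of those models.

## Population estimation (SAEM)

Xenograft cohorts show strong inter-subject heterogeneity, so the package
fits a nonlinear mixed-effects model: individual log-parameters
$\phi_i = \log\theta_i$ are Gaussian around $\mu = \log\theta_{pop}$ with
diagonal covariance $\Omega$ (log-normal random effects, the standard
choice for strictly positive parameters), and volumes carry proportional
residual error by default. For comparability with how variability is
tabulated, iiv is reported as the SD of the parameter on the natural
scale; `iiv_to_omega()` maps it to the log-scale SD via
$\mathrm{SD}/\mathrm{median} = e^{\omega^2/2}\sqrt{e^{\omega^2}-1}$.

`fit_population()` implements stochastic approximation EM:

* **E-step**: per subject, a Metropolis-Hastings sweep — one independent
  proposal from the current population distribution, then componentwise
  adaptive random-walk updates. Componentwise proposals were chosen because
  the likelihood has strongly correlated, nearly flat directions (see
  below) along which joint jumps mix poorly.
* **SA step**: sufficient statistics (first and second moments of $\phi_i$,
  residual sum of squares) are averaged with step size 1 during burn-in and
  $1/(k - K_{burn})$ during smoothing.
* **M-step**: closed-form updates of $\mu$, $\Omega$ and $\sigma$.

Several numerical choices matter and were made deliberately:

* **Residual-variance initialization.** $\sigma$ starts at the SD of
  residuals from pilot individual fits rather than at a conventional
  inflated value. Against a deliberately weakened likelihood, weakly
  identified parameters drift down their flat directions during burn-in
  and the fit settles in a spurious basin; starting the likelihood at its
  real strength prevents this.
* **Variance freezing and bounding.** $\Omega$ is frozen at a moderate
  initial value during burn-in and bounded above ($\omega \le 1.5$ by
  default). The loss rate $\lambda_n$ has a one-sided flat direction
  ($\lambda_n \to 0$ is unbounded below on the log scale); letting its
  variance inflate early destroys shrinkage and drags the population
  median down the ridge.
* **Initialization.** Medians of per-subject Levenberg-Marquardt fits,
  refined by a naive pooled fit (all subjects sharing one parameter
  vector), which is robust exactly where individual fits scatter.
* **Determinism.** All randomness flows from the single `seed`; identical
  seed, data and control give bit-identical traces.

The marginal log-likelihood for AIC ($-2\ln L + 2p$, $p$ counting fixed
effects, iiv variances and the residual variance) is computed by
importance sampling with a Gaussian proposal built from the posterior
samples retained during smoothing; the tests check it against dense
one-dimensional quadrature in a single-random-effect case.

### Identifiability under the emulated study design

A Fisher-information analysis of the mean model at the default population
values (10% proportional error, three-protocol design, ~14 observations
per subject over 30 days) gives per-parameter sampling SDs of roughly
1–12% for $\lambda$, $k$, $R_c$ and $V_0$ at $n = 40$–95 subjects — but
~37% for $\lambda_n$ even at $n = 95$ and with no inter-individual
variability at all. The necrotic loss rate only acts through the slow late
deceleration of growth and is intrinsically poorly identified by volume
data on this horizon; its estimates scatter accordingly, and recovery
experiments judge it against its sampling SE rather than the tight
tolerance appropriate for the other parameters. This is a property of the
design, not of the estimator; histological growth-fraction data would be
the natural way to pin it down.

## Synthetic cohorts

`generate_cohort()` emulates a three-protocol CDX efficacy study: weekly
50 mg/kg doses on days 1/8/15, 1/8/15/22 or 4/11/18/25, arm sizes in
proportion 68:18:9 (95 subjects total in the full design), caliper
measurements every 2–3 days to day 30, log-normal inter-individual
variability at the package's default population values, and 10%
proportional measurement noise emulating caliper error on the volume. A
caliper length–width observation layer ($V = \pi/6\,L W^2$) would be the
next level of realism but volume-level noise is what the fitting machinery
assumes and suffices for testing. Per-subject random streams are derived
from (seed, arm, position), so resizing one arm leaves the other subjects'
data untouched. What the generator does *not* emulate: dropout and
humane-endpoint censoring, non-spherical tumors, measurement-day jitter,
and the tumor-type mix of PDX panels — so green recovery tests demonstrate
estimator correctness under the stated generative model, not robustness to
those real-data features.

## Visual predictive checks

`simulate_replicates()` draws full replicate cohorts (fresh random effects
and noise); `vpc_bands()` computes, per time bin, the 5th/50th/95th
percentiles within each replicate and their 95% confidence bands across
replicates, with observed per-bin percentiles (optionally smoothed by a
centered rolling mean across bins — the window is configurable since
rolling-average summaries of observed percentiles have no canonical width)
overlaid. Under the true model, observed percentiles fall inside their
bands at about the nominal rate, which the acceptance suite checks with a
binomial tolerance.

## Scales used by the shipped experiments

The test suite and `scripts/acceptance.R` run the recovery experiment at
the full 95-subject design (two-start SAEM: 120 burn-in + 60 smoothing
iterations, 2 chains, likelihood-selected), the EL recovery at 40 subjects
under protocol 1, model
discrimination on twenty 20-subject replicates (120 + 60 iterations, one
chain, importance sampling with 400 draws per subject), and VPCs with
300 replicates. These sizes keep each experiment's Monte-Carlo error
comfortably below the effects being measured.

## Known limitations

* The growth-fraction constraint assumes a spherical tumor with a single
  diffusion-limited nutrient; vascularized or irregular geometries are out
  of scope.
* $\Omega$ is diagonal: parameter correlations across subjects are not
  estimated.
* SAEM is a stochastic optimizer on a multi-modal surface. On some
  realizations of the emulated CDX design the joint (mean, variance)
  surface has a spurious local optimum — growth rate and potency low,
  critical radius high, the loss rate compensating — whose marginal
  likelihood is decisively worse (tens of log-units) than the principal
  optimum, yet purely data-driven starts settle there a substantial
  fraction of the time. `fit_population_runs()` therefore diversifies
  starts (one run from the data-driven initialization, one from the
  bundled published population values, as a modeller would) and selects by
  the importance-sampling marginal likelihood; a start is kept only when
  the data prefer where it leads. The CLI exposes this as `--n-runs`.
* The EL comparator's transit-compartment treated variant is not
  implemented; its kill term is the same exponential-loss form used by all
  comparator laws here.
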
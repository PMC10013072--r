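---
title: "Methods: mean-field reduction and slow-fast analysis of resource-coupled excitable rotators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-field reduction and slow-fast analysis of resource-coupled excitable rotators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`oaburst` studies a two-layer multiscale system. The fast layer is a
population of $N$ globally coupled *active rotators*

$$\dot\phi_k \;=\; I_k - \sin\phi_k \;+\; \frac{\sigma}{N}\sum_{j=1}^N
\sin(\phi_j - \phi_k), \qquad I_k = r_1 + r_2\,\nu_k,$$

with frozen heterogeneity $\nu_k \sim \mathcal N(0,1)$. A single rotator
with input $I$ is excitable for $|I| < 1$ (a stable rest angle
$\arcsin I$ coexisting with a saddle) and oscillates for $|I| > 1$; the
transition is a SNIPER (saddle-node infinite-period) bifurcation, so
oscillations are born with finite amplitude but diverging period. The
population coherence is measured by the Kuramoto order parameter
$Z = N^{-1}\sum_j e^{i\phi_j} = R\,e^{i\Theta}$ and the collective
activity by the mean phase velocity $A = N^{-1}\sum_j \dot\phi_j$,
which satisfies the exact identity $A = r_1 + r_2\bar\nu -
\operatorname{Im} Z$ (the coupling term averages out).

The slow layer is a resource pool: a Stuart–Landau (Hopf normal form)
oscillator for the complex resource $r = r_1 + i r_2$ around a base
level $s = s_1 + i s_2$, driven by an activity variable $\lambda$,

$$\dot r = \epsilon\, (r-s)\bigl(\lambda + i\omega - |r-s|^2\bigr),
\qquad
\dot\lambda = -\epsilon'\bigl(\lambda - \lambda_0 - \gamma A(t)\bigr),$$

with $\epsilon, \epsilon' \ll 1$ (the package keeps them as separate
fields but defaults to $\epsilon' = \epsilon$). For fixed $\lambda$ the
resource subsystem has a supercritical Hopf bifurcation exactly at
$\lambda = 0$: inactive (stable focus at $s$) for $\lambda < 0$, active
(limit cycle of radius $\sqrt\lambda$ around $s$) for $\lambda > 0$.
The loop closes because the resource components $(r_1, r_2)$ are the
mean and spread of the population's inputs, while the population's
activity drives $\lambda$.

Default parameters (`model_params()`): $\sigma = 5$,
$\epsilon = \epsilon' = 0.05$, $s = 0.97 + 1.2i$, $\omega = 0.2$,
$\lambda_0 = -0.05$, $\gamma = 0.5$, $N = 5000$. All are
dimensionless; $\omega$ is an angular frequency per *slow* time unit,
so one resource rotation takes $2\pi/(\epsilon\omega) \approx 628$ fast
time units.

## Ott–Antonsen reduction of the layer problem

On time scales short compared with $1/\epsilon$ the resource variables
are frozen parameters — the *layer problem*. In the thermodynamic limit
the phase density restricted to the Ott–Antonsen manifold is fully
described by a local order parameter $z(I,t)$ per input value, obeying

$$\dot z = \tfrac12\,(1 - z^2) + i I z + \tfrac{\sigma}{2} Z
  - \tfrac{\sigma}{2}\bar Z z^2, \qquad
  Z(t) = \int g(I)\, z(I,t)\, dI,$$

with $g = \mathcal N(r_1, r_2^2)$. The package never represents the
full phase density; `oa_field()` stores $z$ at fixed quadrature nodes
in $\nu$-space so that time-varying $(r_1, r_2)$ only remap the inputs
$I_m = r_1 + r_2\nu_m$, never the grid. Two rules are provided
(`make_quadrature()`): probabilists' Gauss–Hermite for smooth
integrands, and a Gaussian-weighted trapezoid on $[-8, 8]$ — the
default for trajectories, because stationary $z$-profiles have a
square-root kink at $|I| = B$ that defeats spectral convergence. All
quadratures truncate the Gaussian at $8$ standard deviations (mass
below $10^{-15}$, far under the integration tolerances).

$|z_m| \le 1$ is an invariant of the exact flow. The integrators
monitor it and raise an error beyond $1 + 10^{-6}$ rather than clip;
a breach indicates a misconfigured step size, not a state to repair.

## Stationary states and the self-consistency equation

A stationary mean field rotates the effective drive into
$B e^{i\beta} = 1 + \sigma Z$; each rotator then feels
$\dot\phi = I - B\sin(\phi - \beta)$, so $B$ acts as a collective
excitability threshold splitting the population into a locked group
($|I| < B$, $|z| = 1$) and a drifting group ($|I| > B$,
$|z| = (|I| - \sqrt{I^2 - B^2})/B$). Inserting these profiles into the
order-parameter integral gives two real integrals $p_1(B), p_2(B)$
(`p_integrals()`; the square-root endpoints are removed by $I = B\sin
t$ and $I = \pm B\cosh u$ substitutions before adaptive quadrature) and
the scalar self-consistency function

$$p(B) = B^2 - 2\sigma p_2(B) +
\frac{\sigma^2}{B^2}\bigl(p_1^2 + p_2^2\bigr) - 1,$$

whose positive roots are the stationary states
(`find_stationary_states()`). Depending on $(r_1, r_2)$ there are one
or three roots, labelled $B_1 > B_2 > B_3$; a larger root locks a
larger population fraction. Root search scans 2000 log-spaced points
with sign-change bracketing and `uniroot` polishing; the scan is
doubled automatically when two resolutions disagree on the count, and
roots closer than $10^{-4}$ are flagged fold-proximal instead of being
merged. The macroscopic reconstruction uses
$R = \sqrt{p_1^2+p_2^2}/B$ and the two-argument arctangent
$\Theta = \operatorname{atan2}(p_1,\, p_2 - \sigma R^2)$ — the scalar
arctangent form is quadrant-ambiguous. For the population profile the
stable rest branch $\Phi^* = \arcsin(I/B)$ is used; the saddle
companion ($\pi - \arcsin$) carries no stationary density.

## Linear stability: continuous and discrete spectra

Linearizing the OA equation in real coordinates around a branch gives a
multiplication operator (local Jacobians $P(I)$, from the closed-form
entries in `oa_jacobians()`, validated against finite differences) plus
a rank-style global coupling through $Q(I)$ and the integral constraint.
The spectrum splits into:

* a **continuous part** — eigenvalues of $P(I)$ over the input support
  (`continuous_spectrum()`). It is stable or marginally stable: locked
  inputs give real negative pairs, drifting inputs purely imaginary
  pairs (neutral rotation along the drift cycle).
* a **discrete part** — roots of $\det C(\mu) = 0$ with
  $C(\mu) = \mathbb 1 + \int g(I)\,(P(I) - \mu)^{-1} Q(I)\,dI$
  (`characteristic_det()`, composite Gauss–Legendre panels with edges
  at $\pm B$; `discrete_spectrum()` runs Newton iteration seeded both
  from a rectangular grid and from isolated eigenvalues of a
  $2M \times 2M$ block discretization of the linearized operator,
  which also serves as an independent sign cross-check in the tests).

Two numerical facts shape the implementation, both visible in the
diagnostics the functions return. First, the resolvent integrand has
poles where an eigenvalue of $P(I)$ equals $\mu$, so quadrature error
concentrates along the continuous-spectrum curves and produces spurious
near-curve zeros; every root is therefore annotated with its distance
to the sampled continuous spectrum. Second, for the most coherent
branch the real continuous spectrum densely covers an interval of the
negative axis and the (robustly negative) real discrete roots sit
numerically close to it, so their *positions* converge slowly in the
panel count even though their *signs* do not. `classify_stability()`
therefore ignores roots that are simultaneously within $0.05$ of the
sampled continuum and within $0.05$ of the imaginary axis — candidates
that cannot be distinguished from marginal-continuum contamination —
and classifies stable/unstable (node/focus) from the leading surviving
eigenvalue(s). With these rules the three coexisting branches at the
reference point $(r_1, r_2, \sigma) = (0.9, 2, 5)$ classify as stable
node, unstable node and unstable focus, in agreement with direct
perturb-and-integrate experiments on the layer dynamics.

## Two-parameter structure: folds, cusp, critical line

Folds of stationary states satisfy the double-root condition
$\{p = 0, \partial_B p = 0\}$; `fold_point()` brackets the root-count
transition in $r_1$ by bisection and polishes $(B, r_1)$ with a damped
Newton iteration on finite-difference derivatives. `fold_branches()`
sections the plane at fixed $r_2$ values (plain predictor from the
scan, not pseudo-arclength — adequate because each section is solved
independently), labelling each fold by which pair it annihilates
(lower: $B_1$–$B_2$; upper: $B_2$–$B_3$) and estimating the cusp where
the two branches cease to coexist.

The *critical line* — the boundary between stationary and oscillating
mean-phase dynamics — is defined operationally (`critical_line()`): at
each $r_2$, bisect $r_1$ on `classify_theta_dynamics()` applied to an
OA layer run of 200 time units from the incoherent state ($z = 0$),
classifying over the last 100. The fold-based prediction is reported
alongside; the two coincide where a single stable state exists. A
trajectory is called oscillating when the unwrapped $\Theta$ drifts
by more than $2\pi$ over the window or the peak-to-peak amplitude of
$\operatorname{Im} Z$ exceeds a floor of $0.05$. The floor is a
deliberate choice: a finite heterogeneity grid leaves a residual
ripple around stable stationary states (peak-to-peak $\approx
0.007$–$0.02$ for $M = 801$–$201$, shrinking with grid refinement),
while genuine collective oscillations are born macroscopic (peak-to-peak
$\gtrsim 0.5$) at the infinite-period threshold — the floor sits an
order of magnitude from both.

## Slow dynamics, bursting, and the experiment protocols

Averaging over the fast layer closes the slow subsystem to three
dimensions: $\dot r = f(r - s, \lambda)$,
$\dot\lambda = -(\lambda - \lambda_0 - \gamma\langle A\rangle(r_1,
r_2))$ in rescaled slow time, with $\langle A\rangle$ tabulated on a
resource grid (`average_activity_map()`, bilinear interpolation). This
averaged system (`reduced_rhs()`, `integrate_reduced_avg()`) is exposed
for mechanism illustration; quantitative experiments use either the
full network (`simulate_network()`) or the *coupled reduced system*
(`simulate_reduced_oa()`): the OA field integrated simultaneously with
the slow resource equations, no averaging — averaging fails inside a
burst's fast oscillatory episodes.

**Collective activity bursting.** With the base level $s$ placed just
on the oscillating side of the critical line, neither regime is
self-sustaining: an active population drives $\lambda$ positive, the
resource orbit swings $(r_1, r_2)$ across the critical line, activity
collapses, $\lambda$ relaxes toward $\lambda_0 < 0$, and the inward
spiral toward $s$ re-enters the active region — a recurrent alternation
of quiescent and oscillatory episodes visible as sign alternation of
$\lambda(t)$. The package adopts this as the regime criterion
(`summarize_timeseries()`): *steady* iff $\max\lambda < 0$ over the
window; *bursting* additionally requires at least two zero crossings
of $\lambda$, a distinction the steady/active dichotomy alone leaves
informal.

**Heterogeneity sampling and finite-size behavior.** `init_population()`
offers iid Gaussian draws (the model's definition) and a stratified
mode ($\nu_k = \Phi^{-1}((k - \tfrac12)/N)$, a variance-reduction
device). Stratified samples reproduce the continuum distribution
faithfully at small $N$, which makes them the right surrogate for
mean-field comparisons: the package's cross-engine checks (network vs
OA layer) and the scaled-down bursting runs use stratified populations.
The choice matters near criticality: with an iid draw the *effective*
homogeneous input is $r_1 + r_2\bar\nu$, so a draw's empirical mean
shifts the sample's criticality by $O(r_2/\sqrt N)$ — about $\pm 0.02$
at $N = 1000$ — and the extreme $\nu_k$ decide whether a fully locked
(exactly steady) finite population state exists slightly *beyond* the
mean-field fold. The coexistence of a steady state with bursting near
criticality, probed by the sweep and switching experiments, lives in
exactly that window; those experiments therefore use iid draws with a
fixed, recorded seed, as their reference protocol did, and report the
draw used. A stratified population, reproducing the continuum tails
at every $N$, never supports the locked state beyond the mean-field
fold — a useful illustration that this bistability is a finite-sample
phenomenon whose extent depends on the realized heterogeneity.

**Adiabatic sweeps** (`adiabatic_sweep()`) chain simulations over a
monotone sequence of base levels $s_1$, each warm-started from the
predecessor's final state; up-sweeps start from the locked equilibrium
(`locked_state()`, a damped fixed-point iteration on $Z$), down-sweeps
from a burned-in oscillatory state. The reference protocol (step
$\Delta s_1 = 0.002$, 7000 time units per step, averages over the last
5000) is the package default; the test suite runs a 10×-shortened
variant (700/500) with $\Delta s_1 = 0.02$ and $N = 1000$, which
preserves the hysteresis loop: near criticality the two sweep
directions terminate in different regimes.

**Switching** (`apply_perturbation()`) implements the two protocols:
an instantaneous reset of $\lambda$ at $t_p$, and a clamp holding
$\lambda$ fixed for a duration (its equation suspended, then
released). The verdict compares regime labels over matched windows
before and after; because escaping a bursting state depends on the
burst phase at which the perturbation lands, the pre-perturbation
$\lambda$ is reported with the verdict.

## Numerical choices

* **Integrators.** The default is a compiled fixed-step classical RK4
  with $dt = 0.01$ fast time units — chosen over adaptive stepping for
  bit-reproducibility of the long slow-fast experiments and for speed;
  the fastest phase velocities at the default parameters are
  $O(10)$, so the step resolves them by two orders of magnitude. An
  adaptive alternative (deSolve `ode45`, rtol $10^{-8}$ / atol
  $10^{-10}$) is available everywhere via `method = "adaptive"` and the
  two are cross-checked in the tests; halving the fixed step or
  doubling the output sampling changes trajectories only at the
  integration-error level.
* **Quadratures.** OA trajectories: trapezoid $M = 201$ on $[-8, 8]$
  (robust to profile kinks); self-consistency and profile
  reconstruction: adaptive quadrature at rel. tol. $10^{-11}$ after
  kink-removing substitutions; resolvent integrals: 40 Gauss–Legendre
  panels of degree 10 per segment, segment edges at $\pm B$.
* **Root finding.** Branch roots: `uniroot` at tol $10^{-12}$ after
  log-grid bracketing; folds: damped 2-variable Newton to residuals
  $|p| < 10^{-8}$, $|\partial_B p| < 10^{-8}$; discrete eigenvalues:
  complex Newton (central-difference derivative, tol $10^{-10}$),
  deduplication distance $10^{-6}$, conjugate completion.
* **Problem sizes in the shipped tests.** Scaled to single-CPU runtime
  as the package's own protocol: bursting surrogates at $N = 1000$
  (network) and $M = 201$ (reduced OA) over 2500 time units; sweeps at
  $N = 1000$ with 700/500 windows; cross-engine agreement at
  $N = 4000$ stratified over a 3×3 resource grid; spectra at the
  reference three-root point. The reference protocol values (7000/5000
  windows, $\Delta s_1 = 0.002$, $N = 5000$) remain the defaults of
  `experiment_config()`.

## Known limitations

* Gaussian heterogeneity only; no closed Lorentzian shortcut is
  provided (the Gaussian requires quadrature by design), and no other
  input distributions.
* All-to-all coupling only; no noise, delays, or network topology.
* The discrete-spectrum solver reports eigenvalue *positions* only up
  to the quadrature caveats above when they lie near the continuous
  spectrum; classifications are robust but near-continuum positions
  carry $O(10^{-2})$ uncertainty.
* The Hopf-like stability change of $B_3$ is located operationally
  (leading-pair real part through zero); no normal-form analysis is
  attempted — near that curve the pair merges with the marginal
  continuum and center-manifold arguments do not directly apply.
* Finite-size effects near criticality are draw-dependent (see above);
  results at $N \lesssim 1000$ within $\approx 0.01$ of the critical
  line should be read with the sampling mode and seed in mind.
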
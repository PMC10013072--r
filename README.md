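# oaburst

Collective activity bursting in a heterogeneous population of excitable
units coupled to a slowly varying pool of resources — simulation,
mean-field reduction, and bifurcation analysis.

## The problem

Populations of excitable elements (the motivating picture is spiking
neurons constrained by slowly replenishing metabolic resources) can
display *collective activity bursting*: the whole population alternates
between episodes of quiescence and episodes of macroscopic oscillation,
even though no single element bursts on its own. `oaburst` implements a
minimal, analytically tractable model of this phenomenon and the full
analysis pipeline around it, for anyone studying collective dynamics of
coupled excitable systems: the microscopic model, its exact mean-field
reduction, the stationary-state and stability theory of the fast
subsystem, two-parameter bifurcation maps, and the slow-fast experiments
(bursting, hysteresis, induced switching) that the theory explains.

## The model

N active rotators with Kuramoto coupling and Gaussian-distributed
inputs, bidirectionally coupled to a Stuart–Landau resource pool:

    phi_k' = r1 + r2*nu_k - sin(phi_k) + (sigma/N) sum_j sin(phi_j - phi_k)
    r'     = eps  * (r - s)(lambda + i*omega - |r - s|^2),   r = r1 + i*r2
    lambda' = -eps' * (lambda - lambda0 - gamma * A(t))

with `nu_k ~ N(0,1)` frozen, `A = mean(phi_k')` the population
activity, and `eps, eps' << 1` the slow-fast separation. The resource
components set the mean (`r1`) and spread (`r2`) of the population's
inputs; the population's activity in turn activates (`lambda > 0`,
limit cycle) or deactivates (`lambda < 0`, stable focus) the resource
pool. On the fast time scale the layer dynamics is analysed through
the Ott–Antonsen reduction: a local order parameter `z(I, t)` per
input obeying

    z' = (1 - z^2)/2 + i*I*z + (sigma/2) Z - (sigma/2) conj(Z) z^2,
    Z  = integral g(I) z(I, t) dI,   g = N(r1, r2^2),

whose stationary states are roots of a scalar self-consistency function
`p(B)` in the effective excitability parameter `B = |1 + sigma*Z|`, with
stability decided by the discrete spectrum of the linearized mean-field
operator (`det C(mu) = 0`). Folds of `p` organise the `(r1, r2)` plane
around a cusp; the resource feedback slowly drags the population across
that critical structure, producing bursting, bistability and
switchable regimes.

See the methods vignette (`vignettes/oaburst-methods.Rmd`) for the
derivations, numerical choices and protocol definitions.

## Worked example

Stationary states of the layer dynamics at `(r1, r2, sigma) =
(0.9, 2, 5)`, their stability, and the critical boundary:

```r
library(oaburst)

branches <- find_stationary_states(0.9, 2, 5)
for (b in branches) print(b)
#> Stationary branch B1 at (r1, r2, sigma) = (0.9, 2, 5)
#>   B = 4.882522, R = 0.893156, Theta = 1.240604, beta = 1.045623
#> Stationary branch B2 at (r1, r2, sigma) = (0.9, 2, 5)
#>   B = 3.659729, R = 0.801894, Theta = 2.047880, beta = 1.802698
#> Stationary branch B3 at (r1, r2, sigma) = (0.9, 2, 5)
#>   B = 1.924798, R = 0.525246, Theta = 2.495011, beta = 2.176661

classify_stability(branches[[1]])   # "stable node"
classify_stability(branches[[2]])   # "unstable node"
classify_stability(branches[[3]])   # "unstable focus"

# fold of the stable state at r2 = 1.2: the critical resource level
fold_point(sigma = 5, r2 = 1.2, r1_bracket = c(0.9, 1.0))$r1
#> [1] 0.9677686
```

Three coexisting mean-field states: `B1` locks almost the whole
population (`R = 0.89`, stable), while `B2`, `B3` mix locked and
drifting units and are unstable — so for these resource levels the
population settles into coherent quiescence. Past the fold at
`r1 ≈ 0.968` no stable stationary state survives and the mean phase
rotates collectively. Placing the resource base level just past this
boundary and switching the feedback on produces bursting:

```r
ts <- simulate_reduced_oa(model_params(), t_end = 2500)
sm <- summarize_timeseries(ts, transient = 500)
sm$label                  # "active/bursting"
sm$n_lambda_crossings     # 41: lambda alternates sign recurrently
```

The full microscopic system (`simulate_network()`), adiabatic sweeps in
the base level (`adiabatic_sweep()`, showing steady/bursting
hysteresis), and the lambda-reset / lambda-clamp switching protocols
(`apply_perturbation()`) follow the same interface; `run_experiment()`
drives any of them from a YAML config, and
`inst/scripts/run_experiment.R` wraps that for the shell.

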
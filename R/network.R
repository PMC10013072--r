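#' Initialize a rotator population
#'
#' Draws the frozen heterogeneity parameters \eqn{\nu_k} and the initial
#' phases of a population of `N` active rotators.  In mode `"iid"` the
#' \eqn{\nu_k} are independent standard normal draws; in mode
#' `"stratified"` they are the equiprobable Gaussian quantiles
#' \eqn{\nu_k = \Phi^{-1}((k - 1/2)/N)} in fixed order, a
#' variance-reduction option that tightens finite-size agreement with the
#' mean-field limit.
#'
#' @param N population size.
#' @param seed integer seed; the draw is deterministic given
#'   `(N, seed, sampling_mode, phase_init)`.
#' @param sampling_mode `"iid"` or `"stratified"`.
#' @param phase_init `"random_uniform"` (i.i.d. uniform on \[0, 2*pi)) or
#'   `"all_zero"`.
#' @return Object of class `"population"`: list with `phases`, `nu`, `N`
#'   and the generating settings.
#' @export
#' @examples
#' pop <- init_population(50, seed = 1)
init_population <- function(N, seed = 1L,
                            sampling_mode = c("iid", "stratified"),
                            phase_init = c("random_uniform", "all_zero")) {
  sampling_mode <- match.arg(sampling_mode)
  phase_init <- match.arg(phase_init)
  if (N < 1) stop("'N' must be >= 1")
  nu <- withr::with_seed(seed, {
    if (sampling_mode == "iid") stats::rnorm(N)
    else stats::qnorm((seq_len(N) - 0.5) / N)
  })
  phases <- withr::with_seed(seed + 1L, {
    if (phase_init == "random_uniform") stats::runif(N, 0, 2 * pi)
    else rep(0, N)
  })
  structure(list(phases = phases, nu = nu, N = as.integer(N), seed = seed,
                 sampling_mode = sampling_mode, phase_init = phase_init),
            class = "population")
}

#' Right-hand side of the full microscopic system
#'
#' Evaluates the coupled derivatives of phases, resource variable and
#' resource activity, using the order-parameter form of the mean-field
#' coupling: \eqn{\dot\phi_k = I_k - \sin\phi_k + \sigma\,
#' \mathrm{Im}(Z e^{-i\phi_k})} (algebraically identical to the
#' all-to-all double sum, at O(N) cost), \eqn{\dot r = \epsilon f(r - s,
#' \lambda)} and \eqn{\dot\lambda = -\epsilon'(\lambda - \lambda_0 -
#' \gamma A)}.  The instantaneous activity `A` is the exact mean of the
#' analytic phase derivatives; since the coupling term averages to zero
#' it satisfies \eqn{A = r_1 + r_2 \bar\nu - \mathrm{Im}(Z)} identically.
#'
#' @param pop a [init_population()] object.
#' @param res a [resource_state()].
#' @param params a [model_params()].
#' @return List with `dphases`, `dr` (complex), `dlam`, and `A`.
#' @export
full_rhs <- function(pop, res, params) {
  stopifnot(inherits(pop, "population"), inherits(res, "resource_state"))
  if (!all(is.finite(pop$phases))) stop("non-finite phases")
  r1 <- Re(res$r); r2 <- Im(res$r)
  Z <- mean(exp(1i * pop$phases))
  dphases <- r1 + r2 * pop$nu - sin(pop$phases) +
    params$sigma * (Im(Z) * cos(pop$phases) - Re(Z) * sin(pop$phases))
  A <- mean(dphases)
  intr <- resource_rhs(res, params)
  list(dphases = dphases, dr = intr$dr,
       dlam = intr$dlam + params$eps_prime * params$gamma * A, A = A)
}

#' Simulate the full rotator-resource system
#'
#' Integrates the coupled microscopic system from the given population and
#' resource state.  The default integrator is a fixed-step classical RK4
#' (compiled, bit-reproducible); `method = "adaptive"` uses `deSolve`'s
#' adaptive Runge-Kutta with tolerances `1e-8`/`1e-10` instead.
#'
#' @param pop a [init_population()] object.
#' @param res initial [resource_state()]; default is the base level
#'   `(s1, s2)` with `lam = lambda0`.
#' @param params a [model_params()]; `params$N` is ignored in favor of
#'   `pop$N`.
#' @param t_end integration time in fast time units.
#' @param dt_out output sampling interval.
#' @param method `"rk4"` (fixed step `dt`) or `"adaptive"`.
#' @param dt fixed RK4 step.
#' @param freeze_r if `TRUE`, hold the resource variable r fixed
#'   (layer-type run with frozen `(r1, r2)`).
#' @param freeze_lambda if `TRUE`, hold the activity variable fixed
#'   (clamp protocol).
#' @param t0 time offset for the recorded time axis (used when chaining
#'   simulation segments).
#' @return Object of class `"oaburst_ts"`: a data frame with columns
#'   `t, A, R, Theta, r1, r2, lambda` and attributes `params`, `meta`
#'   (seeds and integrator settings) and `state` (final population and
#'   resource state for chaining).
#' @export
simulate_network <- function(pop, res = NULL, params = model_params(),
                             t_end, dt_out = 0.5,
                             method = c("rk4", "adaptive"), dt = 0.01,
                             freeze_r = FALSE, freeze_lambda = FALSE,
                             t0 = 0) {
  method <- match.arg(method)
  if (t_end <= 0) stop("'t_end' must be > 0")
  if (is.null(res))
    res <- resource_state(params$s1, params$s2, params$lambda0)

  if (method == "rk4") {
    record_every <- max(1L, round(dt_out / dt))
    nsteps <- ceiling(t_end / dt)
    # make nsteps a multiple of record_every so the final state is recorded
    nsteps <- as.integer(ceiling(nsteps / record_every) * record_every)
    out <- rk4_network_cpp(pop$phases, pop$nu, Re(res$r), Im(res$r), res$lam,
                           params$sigma, params$eps, params$eps_prime,
                           params$s1, params$s2, params$omega,
                           params$lambda0, params$gamma,
                           dt, nsteps, record_every,
                           freeze_r, freeze_lambda, t0)
    ts <- data.frame(t = out$t, A = out$A, R = out$R, Theta = out$Theta,
                     r1 = out$r1, r2 = out$r2, lambda = out$lambda)
    final_pop <- pop
    final_pop$phases <- out$phases_final
    final_res <- resource_state(out$r1_final, out$r2_final, out$lambda_final)
  } else {
    times <- seq(0, t_end, by = dt_out)
    y0 <- c(pop$phases, Re(res$r), Im(res$r), res$lam)
    n <- pop$N
    dfun <- function(t, y, parms) {
      p <- pop; p$phases <- y[seq_len(n)]
      rs <- resource_state(y[n + 1], y[n + 2], y[n + 3])
      d <- full_rhs(p, rs, params)
      if (freeze_r) d$dr <- 0 + 0i
      if (freeze_lambda) d$dlam <- 0
      list(c(d$dphases, Re(d$dr), Im(d$dr), d$dlam))
    }
    sol <- deSolve::ode(y0, times, dfun, NULL, method = "ode45",
                        rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop("adaptive integration failed; see deSolve diagnostics")
    ts <- do.call(rbind, lapply(seq_len(nrow(sol)), function(i) {
      y <- sol[i, -1]
      p <- pop; p$phases <- y[seq_len(n)]
      rs <- resource_state(y[n + 1], y[n + 2], y[n + 3])
      d <- full_rhs(p, rs, params)
      op <- order_parameter(p$phases)
      data.frame(t = t0 + sol[i, 1], A = d$A, R = op$R, Theta = op$Theta,
                 r1 = Re(rs$r), r2 = Im(rs$r), lambda = rs$lam)
    }))
    yF <- sol[nrow(sol), -1]
    final_pop <- pop; final_pop$phases <- yF[seq_len(n)]
    final_res <- resource_state(yF[n + 1], yF[n + 2], yF[n + 3])
  }

  structure(ts, class = c("oaburst_ts", "data.frame"),
            params = params,
            meta = list(seed = pop$seed, sampling_mode = pop$sampling_mode,
                        phase_init = pop$phase_init, method = method, dt = dt,
                        dt_out = dt_out, freeze_r = freeze_r,
                        freeze_lambda = freeze_lambda),
            state = list(pop = final_pop, res = final_res))
}

#' Summarize a simulated trajectory into a regime record
#'
#' Time averages over the final `window` of the series (after discarding
#' `transient`), plus the regime label: a state counts as `"steady"` if
#' and only if the maximum of \eqn{\lambda(t)} over the window is
#' negative, otherwise `"active/bursting"`.  The number of zero crossings
#' of \eqn{\lambda} is also reported; recurrent alternation (at least two
#' crossings) distinguishes genuine bursting from merely active states.
#'
#' @param ts an `"oaburst_ts"` data frame (or any data frame with columns
#'   `t, A, R, lambda`).
#' @param transient initial duration to discard.
#' @param window averaging window (defaults to everything after
#'   `transient`).
#' @return List with `A_mean`, `R_mean`, `R_range` (max R - min R),
#'   `lambda_max`, `n_lambda_crossings`, `label` and `bursting`.
#' @export
summarize_timeseries <- function(ts, transient = 0, window = NULL) {
  dur <- max(ts$t) - min(ts$t)
  if (is.null(window)) window <- dur - transient
  if (window > dur - transient + 1e-9) stop("window exceeds series duration")
  sel <- ts$t > max(ts$t) - window
  lam <- ts$lambda[sel]
  ncross <- sum(diff(sign(lam)) != 0)
  lambda_max <- max(lam)
  list(A_mean = mean(ts$A[sel]), R_mean = mean(ts$R[sel]),
       R_range = diff(range(ts$R[sel])), lambda_max = lambda_max,
       n_lambda_crossings = ncross,
       label = if (lambda_max < 0) "steady" else "active/bursting",
       bursting = lambda_max >= 0 && ncross >= 2)
}

#' Fully phase-locked network equilibrium
#'
#' Searches for the frozen equilibrium of the finite population at fixed
#' resource levels, in which every rotator sits at its stable rest angle
#' \eqn{\phi_k = \beta + \arcsin(I_k / B)} with
#' \eqn{B e^{i\beta} = 1 + \sigma Z}, via damped fixed-point iteration on
#' \eqn{Z}.  Such an equilibrium requires \eqn{|I_k| < B} for every unit
#' and may exist for a finite sample of \eqn{\nu_k} even where the
#' continuum limit has no stable stationary state (the Gaussian tail is
#' truncated at the sample extremes).  Used to prepare steady initial
#' conditions for sweeps and switching experiments.
#'
#' @param pop a [init_population()] object (only `nu` is used).
#' @param r1,r2 frozen resource levels.
#' @param sigma coupling strength.
#' @param max_iter,tol iteration controls.
#' @return The population with phases at the locked equilibrium, or
#'   `NULL` if the iteration fails or some unit has `|I| >= B`.
#' @export
locked_state <- function(pop, r1, r2, sigma, max_iter = 20000, tol = 1e-12) {
  I <- r1 + r2 * pop$nu
  Z <- exp(0i)  # start from full synchrony at phase 0
  for (it in seq_len(max_iter)) {
    H <- 1 + sigma * Z
    B <- Mod(H); beta <- Arg(H)
    if (any(abs(I) >= B)) return(NULL)
    phi <- beta + asin(I / B)
    Znew <- mean(exp(1i * phi))
    if (Mod(Znew - Z) < tol) {
      pop$phases <- phi
      return(pop)
    }
    Z <- 0.5 * Z + 0.5 * Znew
  }
  NULL
}
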
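#' Average-activity table over resource levels
#'
#' Tabulates the time-averaged population activity \eqn{\langle A\rangle
#' = \langle r_1 - \mathrm{Im}\,Z\rangle} and coherence
#' \eqn{\langle R\rangle} of the layer dynamics over a grid of frozen
#' resource levels, using the fixed-resource protocol (`t_end` time
#' units, averages over the final `t_end - transient`).  The table is
#' the closed slow-system input: the averaged resource dynamics reads
#' the population only through \eqn{\langle A\rangle(r_1, r_2)}.
#'
#' @param r1_values,r2_values monotone grid axes.
#' @param sigma coupling strength.
#' @param t_end,transient protocol windows.
#' @param M OA quadrature resolution.
#' @return Object of class `"activity_table"`: list with the axes and
#'   matrices `A`, `R` (rows = r1, cols = r2), plus the protocol record.
#' @export
average_activity_map <- function(r1_values, r2_values, sigma = 5,
                                 t_end = 200, transient = 100, M = 101) {
  if (is.unsorted(r1_values) || is.unsorted(r2_values))
    stop("grid axes must be increasing")
  A <- R <- matrix(NA_real_, length(r1_values), length(r2_values))
  for (j in seq_along(r2_values)) for (i in seq_along(r1_values)) {
    run <- integrate_layer(oa_field(r1_values[i], r2_values[j], M = M),
                           sigma, t_end = t_end)
    sel <- run$ts$t > transient
    A[i, j] <- mean(r1_values[i] - run$ts$ImZ[sel])
    R[i, j] <- mean(run$ts$R[sel])
  }
  structure(list(r1 = r1_values, r2 = r2_values, A = A, R = R,
                 sigma = sigma,
                 protocol = list(t_end = t_end, transient = transient,
                                 M = M, engine = "oa")),
            class = "activity_table")
}

#' Bilinear interpolation in an activity table
#'
#' @param table an [average_activity_map()] result.
#' @param r1,r2 query point; must lie inside the table hull.
#' @param what `"A"` or `"R"`.
#' @return Interpolated value (bounded by the four surrounding nodes).
#' @export
interp_activity <- function(table, r1, r2, what = "A") {
  g1 <- table$r1; g2 <- table$r2
  if (r1 < g1[1] || r1 > g1[length(g1)] ||
      r2 < g2[1] || r2 > g2[length(g2)])
    stop(sprintf("query (%g, %g) outside table hull", r1, r2))
  i <- max(1, min(findInterval(r1, g1), length(g1) - 1))
  j <- max(1, min(findInterval(r2, g2), length(g2) - 1))
  tx <- (r1 - g1[i]) / (g1[i + 1] - g1[i])
  ty <- (r2 - g2[j]) / (g2[j + 1] - g2[j])
  m <- table[[what]]
  (1 - tx) * (1 - ty) * m[i, j] + tx * (1 - ty) * m[i + 1, j] +
    (1 - tx) * ty * m[i, j + 1] + tx * ty * m[i + 1, j + 1]
}

#' Averaged slow resource dynamics
#'
#' Right-hand side of the averaged slow subsystem in rescaled slow time
#' (\eqn{t_{new} = \epsilon t_{old}}, with \eqn{\epsilon' = \epsilon}):
#' \deqn{\dot r = f(r - s, \lambda), \qquad
#'   \dot\lambda = -(\lambda - \lambda_0 - \gamma \langle A\rangle(r_1, r_2)),}
#' where \eqn{\langle A\rangle} is read from the activity table.
#' Averaging is valid while the layer relaxes quickly compared to the
#' resource motion; within a burst's fast oscillatory episodes it is
#' only qualitative.
#'
#' @param res a [resource_state()].
#' @param table an [average_activity_map()] result.
#' @param params a [model_params()].
#' @return List with `dr` (complex) and `dlam` (slow-time derivatives).
#' @export
reduced_rhs <- function(res, table, params) {
  u <- res$r - complex(real = params$s1, imaginary = params$s2)
  dr <- u * (res$lam + 1i * params$omega - Mod(u)^2)
  Aavg <- interp_activity(table, Re(res$r), Im(res$r), "A")
  dlam <- -(res$lam - params$lambda0 - params$gamma * Aavg)
  list(dr = dr, dlam = dlam)
}

#' Integrate the averaged slow system
#'
#' Integrates [reduced_rhs()] in rescaled slow time with an adaptive
#' solver.  Useful for mechanism illustration: the orbit shows the slow
#' resource loop crossing the critical line of the layer dynamics.
#'
#' @param res0 initial [resource_state()].
#' @param table an [average_activity_map()] result.
#' @param params a [model_params()].
#' @param t_end duration in slow time units.
#' @param dt_out output sampling interval.
#' @return Data frame with columns `t, r1, r2, lambda`.
#' @export
integrate_reduced_avg <- function(res0, table, params, t_end, dt_out = 0.1) {
  dfun <- function(t, y, parms) {
    d <- reduced_rhs(resource_state(y[1], y[2], y[3]), table, params)
    list(c(Re(d$dr), Im(d$dr), d$dlam))
  }
  sol <- deSolve::ode(c(Re(res0$r), Im(res0$r), res0$lam),
                      seq(0, t_end, by = dt_out), dfun, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  data.frame(t = sol[, 1], r1 = sol[, 2], r2 = sol[, 3], lambda = sol[, 4])
}

#' Simulate the coupled reduced system (OA field + slow resources)
#'
#' Integrates, without averaging, the mean-field reduction of the full
#' two-layer model: the OA field on its heterogeneity grid coupled to
#' the slow resource equations, with activity \eqn{A = r_1 -
#' \mathrm{Im}\,Z}:
#' \deqn{\dot z = \tfrac12(1 - z^2) + iIz + \tfrac\sigma2 Z -
#'   \tfrac\sigma2\bar Z z^2,\quad \dot r = \epsilon f(r - s, \lambda),
#'   \quad \dot\lambda = -\epsilon'(\lambda - \lambda_0 - \gamma A).}
#'
#' @param params a [model_params()].
#' @param field0 initial [oa_field()]; default incoherent at the base
#'   level `(s1, s2)`.
#' @param res0 initial [resource_state()]; default `(s, lambda0)`.
#' @param t_end duration (fast time units).
#' @param dt_out output sampling interval.
#' @param dt RK4 step.
#' @param M quadrature resolution when `field0` is not supplied.
#' @param freeze_lambda hold the activity variable fixed (clamp runs).
#' @param t0 time offset.
#' @return Object of class `"oaburst_ts"`: data frame `t, A, R, Theta,
#'   r1, r2, lambda` with the final field and resource state attached as
#'   attribute `state`.
#' @export
simulate_reduced_oa <- function(params = model_params(), field0 = NULL,
                                res0 = NULL, t_end, dt_out = 0.5,
                                dt = 0.01, M = 201,
                                freeze_lambda = FALSE, t0 = 0) {
  if (is.null(res0))
    res0 <- resource_state(params$s1, params$s2, params$lambda0)
  if (is.null(field0)) field0 <- oa_field(Re(res0$r), Im(res0$r), M = M)
  record_every <- max(1L, round(dt_out / dt))
  nsteps <- ceiling(t_end / dt)
  nsteps <- as.integer(ceiling(nsteps / record_every) * record_every)
  out <- rk4_oa_cpp(field0$z, field0$nodes, field0$weights,
                    Re(res0$r), Im(res0$r), res0$lam,
                    params$sigma, params$eps, params$eps_prime,
                    params$s1, params$s2, params$omega,
                    params$lambda0, params$gamma,
                    dt, nsteps, record_every,
                    FALSE, freeze_lambda, t0)
  if (out$max_abs_z > 1 + 1e-6)
    stop(sprintf("OA unit-disk invariant breached: max |z| = %.8f",
                 out$max_abs_z))
  ts <- data.frame(t = out$t, A = out$r1 - out$ImZ,
                   R = sqrt(out$ReZ^2 + out$ImZ^2),
                   Theta = atan2(out$ImZ, out$ReZ),
                   r1 = out$r1, r2 = out$r2, lambda = out$lambda)
  fieldF <- field0
  fieldF$z <- as.complex(out$z_final)
  fieldF$r1 <- out$r1_final; fieldF$r2 <- out$r2_final
  structure(ts, class = c("oaburst_ts", "data.frame"), params = params,
            meta = list(engine = "reduced_oa", dt = dt, dt_out = dt_out,
                        M = length(field0$z)),
            state = list(field = fieldF,
                         res = resource_state(out$r1_final, out$r2_final,
                                              out$lambda_final)))
}

#' Adiabatic continuation in the resource base level s1
#'
#' Chains full-system simulations over a sequence of `s1` values, each
#' step warm-started from the predecessor's final state, and summarizes
#' each step over its final `window`.  Sweeping up from a stable
#' stationary state and down from a developed oscillatory state exposes
#' hysteresis: near criticality the two directions terminate in
#' different regimes.
#'
#' For the `"network"` engine the up-sweep initial state is the fully
#' phase-locked equilibrium at the first `s1` (via [locked_state()],
#' falling back to relaxation from coherent phases), and the down-sweep
#' initial state is a random-phase population burned in at the first
#' `s1` for `burnin` time units.  For the `"oa"` engine the equivalents
#' are the B1 stationary profile and the incoherent state.
#'
#' @param s1_values sequence of base levels (increasing for a sweep up,
#'   decreasing for a sweep down).
#' @param params a [model_params()]; `s1` is overridden per step.
#' @param engine `"network"` or `"oa"`.
#' @param t_per_step simulated duration per step (fast time units).
#' @param window averaging window per step.
#' @param pop population for the network engine; default
#'   `init_population(params$N, seed = 1, sampling_mode = "stratified")`.
#' @param burnin burn-in duration for the oscillatory-side start.
#' @param dt RK4 step.
#' @param M OA quadrature resolution.
#' @param state optional starting state (`list(pop =, res =)` or
#'   `list(field =, res =)`), e.g. the `final_state` of a previous
#'   sweep segment; overrides the automatic preparation.
#' @return Object of class `"sweep_result"`: data frame with one row per
#'   step (`s1`, `A_mean`, `R_mean`, `lambda_max`, `n_lambda_crossings`,
#'   `label`, `bursting`) with attributes `direction` and `final_state`
#'   (for chaining segments).
#' @export
adiabatic_sweep <- function(s1_values, params = model_params(),
                            engine = c("network", "oa"),
                            t_per_step = 700, window = 500,
                            pop = NULL, burnin = 1000, dt = 0.01,
                            M = 201, state = NULL) {
  engine <- match.arg(engine)
  if (length(s1_values) < 1 || any(abs(diff(s1_values)) < .Machine$double.eps))
    stop("'s1_values' must move monotonically")
  direction <- if (length(s1_values) == 1 ||
                   s1_values[2] > s1_values[1]) "up" else "down"
  s1_first <- s1_values[1]
  p0 <- params; p0$s1 <- s1_first

  if (!is.null(state)) {
    # warm start handed over from a previous segment
  } else if (engine == "network") {
    if (is.null(pop))
      pop <- init_population(params$N, seed = 1, sampling_mode = "stratified")
    if (direction == "up") {
      locked <- locked_state(pop, s1_first, params$s2, params$sigma)
      if (!is.null(locked)) pop <- locked else pop$phases <- rep(0, pop$N)
      res <- resource_state(s1_first, params$s2, params$lambda0)
    } else {
      pop$phases <- withr::with_seed(pop$seed + 2L,
                                     stats::runif(pop$N, 0, 2 * pi))
      res <- resource_state(s1_first, params$s2, params$lambda0)
      warm <- simulate_network(pop, res, p0, t_end = burnin, dt = dt)
      st <- attr(warm, "state")
      pop <- st$pop; res <- st$res
    }
    state <- list(pop = pop, res = res)
  } else {
    res <- resource_state(s1_first, params$s2, params$lambda0)
    if (direction == "up") {
      brs <- find_stationary_states(s1_first, params$s2, params$sigma)
      field <- oa_field(s1_first, params$s2, M = M, z = brs[[1]])
    } else {
      field <- oa_field(s1_first, params$s2, M = M)
      warm <- simulate_reduced_oa(p0, field, res, t_end = burnin, dt = dt)
      st <- attr(warm, "state")
      field <- st$field; res <- st$res
    }
    state <- list(field = field, res = res)
  }

  rows <- list()
  for (s1 in s1_values) {
    p <- params; p$s1 <- s1
    if (engine == "network") {
      ts <- simulate_network(state$pop, state$res, p, t_end = t_per_step,
                             dt = dt)
      st <- attr(ts, "state")
      state <- list(pop = st$pop, res = st$res)
    } else {
      ts <- simulate_reduced_oa(p, state$field, state$res,
                                t_end = t_per_step, dt = dt)
      st <- attr(ts, "state")
      state <- list(field = st$field, res = st$res)
    }
    sm <- summarize_timeseries(ts, transient = t_per_step - window)
    rows[[length(rows) + 1]] <- data.frame(
      s1 = s1, A_mean = sm$A_mean, R_mean = sm$R_mean,
      R_range = sm$R_range, lambda_max = sm$lambda_max,
      n_lambda_crossings = sm$n_lambda_crossings, label = sm$label,
      bursting = sm$bursting)
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"),
            direction = direction, engine = engine, final_state = state,
            protocol = list(t_per_step = t_per_step, window = window,
                            delta_s1 = if (length(s1_values) > 1)
                              s1_values[2] - s1_values[1] else NA_real_))
}

#' Perturb the resource activity and record the regime switch
#'
#' Applies one of two perturbation protocols to a running full-system
#' (or reduced OA) simulation: `"reset"` instantaneously sets the
#' resource activity \eqn{\lambda} to a new value at time `t_p`;
#' `"clamp"` holds \eqn{\lambda} at a value for a duration `duration`
#' starting at `t_p` (its equation is suspended, then released).  The
#' verdict compares the regime labels over matched windows before `t_p`
#' and at the end of the run.  Because switching out of a bursting state
#' can depend on the burst phase at which the perturbation lands, the
#' \eqn{\lambda} value immediately before application is reported.
#'
#' @param init initial state: `list(pop = , res = )` for the network
#'   engine or `list(field = , res = )` for the reduced OA engine.
#' @param params a [model_params()].
#' @param protocol list with `type` (`"reset"` or `"clamp"`), `lambda`,
#'   `t_p`, and for clamps `duration` (> 0).
#' @param t_end total duration (fast time units), `> t_p` (plus
#'   `duration` for clamps).
#' @param window label window used both before `t_p` and at the end.
#' @param dt RK4 step.
#' @param dt_out output sampling.
#' @return List with `ts` (chained trajectory), `verdict` (list with
#'   `pre`, `post`, `switched`), `lambda_before` and the protocol.
#' @export
apply_perturbation <- function(init, params, protocol, t_end,
                               window = 1000, dt = 0.01, dt_out = 0.5) {
  stopifnot(is.list(protocol), protocol$type %in% c("reset", "clamp"))
  t_p <- protocol$t_p
  if (t_p <= 0 || t_p >= t_end) stop("'t_p' must lie within the run")
  if (protocol$type == "clamp") {
    if (is.null(protocol$duration) || protocol$duration <= 0)
      stop("clamp duration must be > 0")
    if (t_p + protocol$duration >= t_end)
      stop("clamp must end before 't_end'")
  }
  if (is.null(init$pop) && is.null(init$field))
    stop("'init' must carry a population ('pop') or an OA field ('field')")
  network <- !is.null(init$pop)

  run <- function(state, t_len, freeze_lambda, t0) {
    if (network) {
      ts <- simulate_network(state$pop, state$res, params, t_end = t_len,
                             dt = dt, dt_out = dt_out,
                             freeze_lambda = freeze_lambda, t0 = t0)
      list(ts = ts, state = attr(ts, "state"))
    } else {
      ts <- simulate_reduced_oa(params, state$field, state$res,
                                t_end = t_len, dt = dt, dt_out = dt_out,
                                freeze_lambda = freeze_lambda, t0 = t0)
      list(ts = ts, state = attr(ts, "state"))
    }
  }
  seg1 <- run(init, t_p, FALSE, 0)
  lambda_before <- seg1$state$res$lam
  st <- seg1$state
  st$res <- resource_state(st$res$r, lam = protocol$lambda)
  segs <- list(seg1$ts)
  t_cur <- t_p
  if (protocol$type == "clamp") {
    seg2 <- run(st, protocol$duration, TRUE, t_cur)
    segs <- c(segs, list(seg2$ts))
    st <- seg2$state
    t_cur <- t_cur + protocol$duration
  }
  seg3 <- run(st, t_end - t_cur, FALSE, t_cur)
  segs <- c(segs, list(seg3$ts))
  ts <- do.call(rbind, lapply(segs, as.data.frame))
  ts <- ts[!duplicated(ts$t), ]

  pre <- summarize_timeseries(ts[ts$t <= t_p, ],
                              transient = max(0, t_p - window))
  post <- summarize_timeseries(ts[ts$t > t_end - window, ])
  list(ts = ts,
       verdict = list(pre = pre$label, post = post$label,
                      switched = pre$label != post$label),
       lambda_before = lambda_before, protocol = protocol)
}
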
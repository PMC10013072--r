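test_that("population initialization is deterministic and correctly stratified", {
  pop <- init_population(5, seed = 7, sampling_mode = "stratified",
                         phase_init = "all_zero")
  expect_equal(pop$nu, qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9)), tolerance = 1e-15)
  expect_identical(pop$nu[3], 0)
  expect_identical(pop$phases, rep(0, 5))

  a <- init_population(200, seed = 42)
  b <- init_population(200, seed = 42)
  expect_identical(a, b)
  c <- init_population(200, seed = 43)
  expect_false(identical(a$nu, c$nu))
  expect_error(init_population(100, 1, sampling_mode = "nope"))
})

test_that("iid heterogeneity draws obey the CLT bound on the sample mean", {
  for (seed in 1:3) {
    pop <- init_population(1e5, seed = seed)
    expect_lt(abs(mean(pop$nu)), 3 / sqrt(1e5))
    expect_lt(abs(sd(pop$nu) - 1), 0.02)
  }
})

test_that("full rhs reduces correctly at synchrony and satisfies the activity identity", {
  p <- model_params(sigma = 3, N = 64)
  pop <- init_population(64, seed = 1)
  res <- resource_state(0.7, 1.1, -0.02)

  # coupling vanishes when all phases coincide
  pop_sync <- pop
  pop_sync$phases <- rep(0.8, 64)
  d <- full_rhs(pop_sync, res, p)
  expect_equal(d$A, 0.7 + 1.1 * mean(pop$nu) - sin(0.8), tolerance = 1e-13)

  # A = r1 + r2 mean(nu) - Im(Z) exactly, for random states
  for (seed in 1:5) {
    pop$phases <- withr::with_seed(seed, runif(64, 0, 2 * pi))
    d <- full_rhs(pop, res, p)
    Z <- mean(exp(1i * pop$phases))
    expect_equal(d$A, 0.7 + 1.1 * mean(pop$nu) - Im(Z), tolerance = 1e-12)
  }
})

test_that("a single uncoupled rotator has rest states at arcsin(I)", {
  p <- model_params(sigma = 0, N = 1)
  pop <- init_population(1, seed = 1, phase_init = "all_zero")
  pop$nu <- 0
  res <- resource_state(0.5, 0, 0)
  for (phi in c(asin(0.5), pi - asin(0.5))) {
    pop$phases <- phi
    expect_equal(full_rhs(pop, res, p)$dphases, 0, tolerance = 1e-14)
  }
  # and the rest state at arcsin is the stable one
  pop$phases <- asin(0.5) + 1e-3
  expect_lt(full_rhs(pop, res, p)$dphases, 0)
})

test_that("with feedback off the resource relaxes to its rest configuration", {
  p <- model_params(gamma = 0, N = 100)
  pop <- init_population(100, seed = 3)
  res <- resource_state(0.5, 0.8, 1)   # far from (s1, s2, lambda0)
  ts <- simulate_network(pop, res, p, t_end = 2000, dt_out = 10)
  n <- nrow(ts)
  expect_equal(ts$lambda[n], p$lambda0, tolerance = 1e-6)
  # r spirals in at the slow rate eps*|lambda0| = 2.5e-3 per time unit,
  # so after 2000 units the offset has shrunk by ~e^-5
  expect_lt(abs(ts$r1[n] - p$s1), 5e-3)
  expect_lt(abs(ts$r2[n] - p$s2), 5e-3)
  offset <- sqrt((ts$r1 - p$s1)^2 + (ts$r2 - p$s2)^2)
  expect_lt(offset[n], 0.01 * offset[1])
})

test_that("output sampling does not alter the dynamics", {
  p <- model_params(N = 50)
  pop <- init_population(50, seed = 5)
  coarse <- simulate_network(pop, NULL, p, t_end = 50, dt_out = 1)
  fine <- simulate_network(pop, NULL, p, t_end = 50, dt_out = 0.5)
  shared <- fine$t %in% coarse$t
  expect_equal(fine$A[shared], coarse$A, tolerance = 1e-13)
  expect_equal(fine$lambda[shared], coarse$lambda, tolerance = 1e-13)
})

test_that("uncoupled homogeneous rotators reproduce the infinite-period scaling", {
  # phase velocity I - sin(phi): oscillation period 2*pi/sqrt(I^2 - 1)
  measure_period <- function(r1) {
    p <- model_params(sigma = 0, N = 1)
    pop <- init_population(1, seed = 1, phase_init = "all_zero")
    pop$nu <- 0
    res <- resource_state(r1, 0, -1)
    ts <- simulate_network(pop, res, p, t_end = 400, dt_out = 0.1,
                           freeze_r = TRUE, freeze_lambda = TRUE,
                           dt = 0.002)
    # period from interpolated full-rotation crossing times (robust to
    # the partial cycle at the window edges)
    sel <- ts$t > 100
    th <- oaburst:::unwrap_angles(ts$Theta[sel])
    tt <- ts$t[sel]
    th <- th * sign(th[length(th)] - th[1])
    marks <- seq(ceiling(min(th) / (2 * pi)) * 2 * pi, max(th),
                 by = 2 * pi)
    cross <- approx(th, tt, xout = marks)$y
    mean(diff(cross))
  }
  for (r1 in c(1.05, 1.2)) {
    expect_equal(measure_period(r1), 2 * pi / sqrt(r1^2 - 1),
                 tolerance = 5e-3)
  }
  # divergence toward the threshold
  expect_gt(measure_period(1.02), measure_period(1.05))
})

test_that("trajectory summaries label steady and active states correctly", {
  flat <- data.frame(t = 0:100, A = 0.3, R = 0.9, lambda = -0.05)
  sm <- summarize_timeseries(flat, transient = 10)
  expect_equal(sm$A_mean, 0.3)
  expect_equal(sm$R_range, 0)
  expect_identical(sm$label, "steady")
  expect_false(sm$bursting)

  burst <- data.frame(t = 0:100, A = 0.3,
                      R = 0.5, lambda = 0.1 * sin((0:100) / 5))
  smb <- summarize_timeseries(burst, transient = 10)
  expect_identical(smb$label, "active/bursting")
  expect_true(smb$bursting)
  expect_error(summarize_timeseries(flat, transient = 10, window = 200),
               "window")
})

test_that("rk4 and adaptive integrators agree on a short trajectory", {
  p <- model_params(N = 30)
  pop <- init_population(30, seed = 9)
  a <- simulate_network(pop, NULL, p, t_end = 20, dt_out = 1,
                        method = "rk4", dt = 0.005)
  b <- simulate_network(pop, NULL, p, t_end = 20, dt_out = 1,
                        method = "adaptive")
  expect_equal(a$A, b$A, tolerance = 1e-6)
  expect_equal(a$R, b$R, tolerance = 1e-6)
})
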
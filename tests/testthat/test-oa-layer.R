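test_that("quadrature rules integrate standard-normal moments", {
  for (scheme in c("gauss_hermite", "trapezoid")) {
    q <- make_quadrature(if (scheme == "gauss_hermite") 40 else 201, scheme)
    expect_equal(sum(q$weights), 1, tolerance = 1e-12)
    expect_equal(sum(q$weights * q$nodes^2), 1, tolerance = 1e-10)
    # characteristic function: E[e^{i nu}] = e^{-1/2}
    expect_equal(sum(q$weights * exp(1i * q$nodes)),
                 complex(real = exp(-0.5)), tolerance = 1e-8)
  }
  expect_error(make_quadrature(2), "M")
  expect_error(make_quadrature(10, "simpson"))
})

test_that("layer equation preserves the unit circle and matches a direct evaluation", {
  # all z on the unit circle with sigma = 0: modulus derivative vanishes
  f <- oa_field(0.7, 1.5, M = 31, z = 1 + 0i)
  dz <- oa_rhs(f, sigma = 0)
  I <- f$r1 + f$r2 * f$nodes
  expect_equal(Re(Conj(f$z) * dz), rep(0, 31), tolerance = 1e-14)

  # independent re-implementation: assemble Z by an explicit weighted sum
  zr <- withr::with_seed(11, complex(real = runif(31, -0.5, 0.5),
                                     imaginary = runif(31, -0.5, 0.5)))
  f$z <- zr
  sigma <- 4.2
  Z <- sum(f$weights * zr)
  direct <- vapply(seq_len(31), function(m) {
    0.5 * (1 - zr[m]^2) + 1i * I[m] * zr[m] +
      sigma / 2 * Z - sigma / 2 * Conj(Z) * zr[m]^2
  }, complex(1))
  expect_equal(oa_rhs(f, sigma), direct, tolerance = 1e-14)
})

test_that("uncoupled nodes reproduce the single-input stationary solutions", {
  # sigma = 0 decouples the nodes; the closed-form solutions with
  # B = 1, beta = 0 are per-node fixed points of the layer equation
  b0 <- find_stationary_states(0.3, 1, 0)[[1]]
  expect_equal(b0$B, 1)
  f <- oa_field(0.3, 1, M = 41, z = 0)
  I <- f$r1 + f$r2 * f$nodes
  f$z <- local_profile(b0, I)
  expect_lt(max(Mod(oa_rhs(f, sigma = 0))), 1e-12)

  # excitable nodes attract onto the rest profile (drifting nodes are
  # neutrally stable centers of the uncoupled equation and merely orbit)
  f0 <- oa_field(0.3, 1, M = 41, z = 0)
  run <- integrate_layer(f0, sigma = 0, t_end = 300)
  zs <- run$field$z
  excitable <- abs(I) < 0.85
  expect_close(zs[excitable], local_profile(b0, I[excitable]), 1e-3)
  drift <- abs(I) > 1.05
  expect_lte(max(Mod(zs[drift])), 1 + 1e-6)
})

test_that("layer trajectories converge to the regimes of the reference points", {
  run_s <- integrate_layer(oa_field(0.9, 1), sigma = 5, t_end = 200)
  expect_identical(classify_theta_dynamics(run_s$ts), "stationary")
  tailR <- run_s$ts$R[run_s$ts$t > 190]
  expect_lt(diff(range(tailR)), 1e-4)

  run_o <- integrate_layer(oa_field(1.1, 2), sigma = 5, t_end = 200)
  expect_identical(classify_theta_dynamics(run_o$ts), "oscillating")
  # tonic oscillation: activity r1 - Im Z swings by order one
  A <- 1.1 - run_o$ts$ImZ[run_o$ts$t > 100]
  expect_gt(diff(range(A)), 0.5)
  expect_lte(run_o$max_abs_z, 1 + 1e-6)
})

test_that("a stationary profile is a resident state of the layer dynamics", {
  # pointwise 1e-6 residence is unattainable under any finite
  # quadrature: nodes near |I| = B are neutrally stable and integrate
  # the O(quadrature error) offset in Z into slow local orbits.  The
  # collective state, however, must stay put.
  b1 <- ref_branches()[[1]]
  f <- oa_field(0.9, 2, M = 201, z = b1)
  run <- integrate_layer(f, sigma = 5, t_end = 100)
  Zt <- complex(real = run$ts$ReZ, imaginary = run$ts$ImZ)
  expect_lt(max(Mod(Zt - b1$Z)), 5e-3)
  expect_identical(classify_theta_dynamics(run$ts, transient = 50),
                   "stationary")
})

test_that("homogeneous populations stay homogeneous", {
  f <- oa_field(0.8, 0, M = 21, z = 0.3 + 0.1i)
  run <- integrate_layer(f, sigma = 5, t_end = 50)
  expect_lt(max(Mod(run$field$z - run$field$z[1])), 1e-12)
})

test_that("classification separates drifting, rippling and constant trajectories", {
  tt <- seq(0, 200, by = 0.5)
  const <- data.frame(t = tt, ReZ = 0.5, ImZ = 0.2)
  expect_identical(classify_theta_dynamics(const), "stationary")
  rot <- data.frame(t = tt, ReZ = 0.5 * cos(tt / 5), ImZ = 0.5 * sin(tt / 5))
  expect_identical(classify_theta_dynamics(rot), "oscillating")
  # sub-floor ripple counts as stationary, macroscopic wobble does not
  ripple <- data.frame(t = tt, ReZ = 0.9, ImZ = 0.2 + 0.005 * sin(tt))
  expect_identical(classify_theta_dynamics(ripple), "stationary")
  wobble <- data.frame(t = tt, ReZ = 0.9, ImZ = 0.2 + 0.1 * sin(tt))
  expect_identical(classify_theta_dynamics(wobble), "oscillating")
  expect_error(classify_theta_dynamics(const, transient = 300), "transient")
})

test_that("rk4 and adaptive layer integrators agree", {
  f <- oa_field(0.9, 2, M = 61)
  a <- integrate_layer(f, 5, t_end = 30, dt_out = 1, method = "rk4",
                       dt = 0.005)
  b <- integrate_layer(f, 5, t_end = 30, dt_out = 1, method = "adaptive")
  expect_close(a$ts$ReZ, b$ts$ReZ, 1e-6)
  expect_close(a$ts$ImZ, b$ts$ImZ, 1e-6)
})

test_that("a resource driver remaps inputs without re-gridding", {
  f <- oa_field(0.9, 1, M = 41)
  drv <- function(t) c(0.9 + 0.1 * sin(0.01 * t), 1)
  run <- integrate_layer(f, 5, t_end = 20, dt_out = 5,
                         resource_driver = drv)
  expect_equal(run$ts$r1, 0.9 + 0.1 * sin(0.01 * run$ts$t),
               tolerance = 1e-12)
  expect_identical(run$field$nodes, f$nodes)
})
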
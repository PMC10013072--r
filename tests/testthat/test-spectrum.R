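test_that("closed-form Jacobians match finite differences of the vector field", {
  b <- ref_branches()[[2]]
  h <- 1e-6
  X0 <- Re(b$Z); Y0 <- Im(b$Z)
  for (I in c(-3.1, 0.4, 1.9, 4.9, 7.3)) {
    z <- local_profile(b, I)
    x0 <- Re(z); y0 <- Im(z)
    pq <- oa_jacobians(I, b)
    fd <- function(f) f / (2 * h)
    Pfd <- cbind(
      fd(oaburst:::oa_fg(x0 + h, y0, X0, Y0, I, 5) -
           oaburst:::oa_fg(x0 - h, y0, X0, Y0, I, 5)),
      fd(oaburst:::oa_fg(x0, y0 + h, X0, Y0, I, 5) -
           oaburst:::oa_fg(x0, y0 - h, X0, Y0, I, 5)))
    Qfd <- cbind(
      fd(oaburst:::oa_fg(x0, y0, X0 + h, Y0, I, 5) -
           oaburst:::oa_fg(x0, y0, X0 - h, Y0, I, 5)),
      fd(oaburst:::oa_fg(x0, y0, X0, Y0 + h, I, 5) -
           oaburst:::oa_fg(x0, y0, X0, Y0 - h, I, 5)))
    expect_close(pq$P, Pfd, 1e-6)
    expect_close(pq$Q, Qfd, 1e-6)
    # trace cross-check against the same oracle
    expect_equal(sum(diag(pq$P)), sum(diag(Pfd)), tolerance = 1e-6)
  }
})

test_that("global feedback vanishes without coupling", {
  b0 <- find_stationary_states(0.4, 1, 0)[[1]]
  for (I in c(-1, 0.2, 2)) {
    expect_identical(oa_jacobians(I, b0)$Q, matrix(0, 2, 2))
  }
})

test_that("continuous spectrum is (marginally) stable with the expected structure", {
  for (b in ref_branches()) {
    cs <- continuous_spectrum(b, 400)
    expect_lte(max(cs$Re), 1e-8)
    # excitable inputs give real pairs, oscillating inputs complex pairs
    exc <- abs(cs$I) < b$B - 0.1
    osc <- abs(cs$I) > b$B + 0.1
    expect_true(all(abs(cs$Im[exc]) < 1e-10))
    expect_true(all(abs(cs$Im[osc]) > 1e-10))
  }
  expect_error(continuous_spectrum(ref_branches()[[1]], 50), "n_samples")
})

test_that("uncoupled oscillating input has a marginal rotational mode", {
  # single drifting rotator: neutral phase shift along its cycle
  b0 <- find_stationary_states(1.5, 1e-2, 0)[[1]]
  ev <- eigen(oa_jacobians(1.5, b0)$P, only.values = TRUE)$values
  expect_lt(abs(max(Re(ev))), 1e-10)
})

test_that("characteristic determinant has the right asymptotics and symmetry", {
  b <- ref_branches()[[1]]
  quad <- oaburst:::resolvent_quad(b)
  # resolvent decays ~ 1/mu: det -> 1 for large |mu|, with the leading
  # correction of order integral(g tr Q)/|mu| ~ sigma/|mu|
  d1 <- Mod(oaburst:::det_c_quad(60 + 40i, quad) - 1)
  d2 <- Mod(oaburst:::det_c_quad(300 + 200i, quad) - 1)
  expect_lt(d1, 10 / Mod(60 + 40i))
  expect_lt(d2, 10 / Mod(300 + 200i))
  expect_lt(d2, d1 / 3)
  # real system: det C(conj mu) = conj det C(mu)
  for (mu in c(1 + 2i, -0.5 + 0.8i, 0.3 + 4i)) {
    expect_lt(Mod(oaburst:::det_c_quad(Conj(mu), quad) -
                    Conj(oaburst:::det_c_quad(mu, quad))), 1e-10)
  }
  # holomorphy off the continuous spectrum: Cauchy-Riemann residual
  h <- 1e-5
  for (mu in c(1 + 1i, 0.8 + 2.5i)) {
    dre <- (oaburst:::det_c_quad(mu + h, quad) -
              oaburst:::det_c_quad(mu - h, quad)) / (2 * h)
    dim_ <- (oaburst:::det_c_quad(mu + 1i * h, quad) -
               oaburst:::det_c_quad(mu - 1i * h, quad)) / (2i * h)
    expect_lt(Mod(dre - dim_), 1e-5)
  }
  # singularity guard
  cs <- continuous_spectrum(b, 1000)
  on_curve <- complex(real = cs$Re[5], imaginary = cs$Im[5])
  expect_error(characteristic_det(on_curve, b, quad = quad,
                                  continuous = cs), "singular")
})

test_that("discrete spectra reproduce the reference stability types", {
  sps <- ref_spectra()
  brs <- ref_branches()

  # eigenvalues come in conjugate pairs and satisfy det C ~ 0
  for (sp in sps) {
    expect_true(all(sp$det_mod < 1e-8))
    cplx <- sp[sp$Im > 1e-9, ]
    for (k in seq_len(nrow(cplx))) {
      expect_true(any(abs(sp$Re - cplx$Re[k]) < 1e-8 &
                        abs(sp$Im + cplx$Im[k]) < 1e-8))
    }
    expect_true(all(sp$dist_continuum > 1e-6))
  }

  expect_identical(classify_stability(brs[[1]], spectrum = sps[[1]]),
                   "stable node")
  expect_identical(classify_stability(brs[[2]], spectrum = sps[[2]]),
                   "unstable node")
  expect_identical(classify_stability(brs[[3]], spectrum = sps[[3]]),
                   "unstable focus")
})

test_that("B3's unstable pair agrees in sign with the discretized operator", {
  b3 <- ref_branches()[[3]]
  sp3 <- ref_spectra()[[3]]
  lead <- sp3[which.max(sp3$Re), ]
  L <- oaburst:::discretized_operator(b3, M = 400)
  evL <- eigen(L, only.values = TRUE)$values
  # leading isolated operator eigenvalue: same sign, nearby location
  cs <- continuous_spectrum(b3, 2000)
  cpts <- complex(real = cs$Re, imaginary = cs$Im)
  iso <- evL[vapply(evL, function(m) min(Mod(cpts - m)), 0) > 0.05]
  lead_op <- iso[which.max(Re(iso))]
  expect_identical(sign(lead$Re), sign(Re(lead_op)))
  expect_lt(Mod(complex(real = lead$Re, imaginary = lead$Im) - lead_op),
            0.05)
})

test_that("classification rules map synthetic spectra correctly", {
  fake <- function(re, im) data.frame(Re = re, Im = im,
                                      det_mod = 0, dist_continuum = 1,
                                      near_continuum = FALSE)
  b <- ref_branches()[[1]]
  expect_identical(classify_stability(b, spectrum = fake(c(-1, -2), c(0, 0))),
                   "stable node")
  expect_identical(
    classify_stability(b, spectrum = fake(c(0.1, 0.1), c(2, -2))),
    "unstable focus")
  expect_identical(
    classify_stability(b, spectrum = fake(c(-0.4, -0.4), c(1, -1))),
    "stable focus")
  expect_identical(classify_stability(b, spectrum = fake(0, 0)), "marginal")
})
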
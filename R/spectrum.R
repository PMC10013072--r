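#' Local and global Jacobians of the linearized layer dynamics
#'
#' Writing the OA equation in real coordinates \eqn{z = x + iy},
#' \eqn{Z = X + iY} gives a vector field \eqn{(F, G)} whose
#' linearization around a stationary state decomposes into a local part
#' \eqn{P(I) = \partial(F,G)/\partial(x,y)} and a global-feedback part
#' \eqn{Q(I) = \partial(F,G)/\partial(X,Y)}, both evaluated on the
#' branch profile \eqn{(x_0, y_0)(I)} and the reconstructed
#' \eqn{(X_0, Y_0)}.  Entries are closed-form in
#' \eqn{(x_0, y_0, X_0, Y_0, I, \sigma)}:
#' \deqn{P = \begin{pmatrix} -x(1+\sigma X) - \sigma y Y &
#'   y - I + \sigma X y - \sigma x Y \\
#'   -y + I - \sigma y X + \sigma Y x & -x - \sigma x X - \sigma Y y
#'   \end{pmatrix}, \quad
#'   Q = \frac{\sigma}{2}\begin{pmatrix} 1 - x^2 + y^2 & -2xy \\
#'   -2xy & 1 + x^2 - y^2 \end{pmatrix}.}
#' For \eqn{\sigma = 0}, `Q` vanishes (no global feedback).
#'
#' @param I input value.
#' @param branch a `"stationary_branch"`.
#' @return List with 2x2 real matrices `P` and `Q`.
#' @export
oa_jacobians <- function(I, branch) {
  sigma <- branch$params$sigma
  z <- local_profile(branch, I)
  x <- Re(z); y <- Im(z)
  X <- Re(branch$Z); Y <- Im(branch$Z)
  P <- matrix(c(-x * (1 + sigma * X) - sigma * y * Y,
                y - I + sigma * X * y - sigma * x * Y,
                -y + I - sigma * y * X + sigma * Y * x,
                -x - sigma * x * X - sigma * Y * y),
              2, 2, byrow = TRUE)
  Q <- sigma / 2 * matrix(c(1 - (x^2 - y^2), -2 * x * y,
                            -2 * x * y, 1 + (x^2 - y^2)),
                          2, 2, byrow = TRUE)
  list(P = P, Q = Q)
}

# Real vector field (F, G) of the OA equation; reference for
# finite-difference validation of the Jacobians.
oa_fg <- function(x, y, X, Y, I, sigma) {
  c(F = 0.5 * (1 - x^2 + y^2) - I * y + sigma / 2 * X -
      sigma / 2 * X * (x^2 - y^2) - sigma * x * y * Y,
    G = -x * y + I * x + sigma / 2 * Y - sigma * x * y * X +
      sigma / 2 * Y * (x^2 - y^2))
}

#' Continuous spectrum of a stationary branch
#'
#' Eigenvalues of the local Jacobian \eqn{P(I)} sampled over the
#' truncated input support \eqn{[r_1 - 8 r_2, r_1 + 8 r_2]}.  Excitable
#' inputs (\eqn{|I| < B}) contribute real pairs, oscillating inputs
#' complex-conjugate pairs; the whole set is stable or marginally
#' stable.
#'
#' @param branch a `"stationary_branch"`.
#' @param n_samples number of I-grid points (>= 100).
#' @return Data frame with columns `I`, `Re`, `Im` (two rows per sample).
#' @export
continuous_spectrum <- function(branch, n_samples = 400) {
  if (n_samples < 100) stop("'n_samples' must be >= 100")
  r1 <- branch$params$r1; r2 <- branch$params$r2
  I <- seq(r1 - 8 * r2, r1 + 8 * r2, length.out = n_samples)
  ev <- lapply(I, function(ii) {
    eigen(oa_jacobians(ii, branch)$P, only.values = TRUE)$values
  })
  data.frame(I = rep(I, each = 2),
             Re = unlist(lapply(ev, Re)),
             Im = unlist(lapply(ev, Im)))
}

# Precompute the resolvent-integral quadrature for a branch: composite
# Gauss-Legendre panels over the truncated support, with panel edges at
# +-B where the stationary profile has a kink.  Returns vectors of P, Q
# entries and Gaussian-weighted quadrature weights.
resolvent_quad <- function(branch, npanel = 40, deg = 10) {
  r1 <- branch$params$r1; r2 <- branch$params$r2
  lo <- r1 - 8 * r2; hi <- r1 + 8 * r2
  edges <- sort(unique(pmin(pmax(c(lo, -branch$B, branch$B, hi), lo), hi)))
  gl <- pracma::gaussLegendre(deg, 0, 1)
  xs <- ws <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    sub <- seq(edges[i], edges[i + 1], length.out = npanel + 1)
    for (j in seq_len(npanel)) {
      a <- sub[j]; b <- sub[j + 1]
      xs <- c(xs, a + (b - a) * gl$x)
      ws <- c(ws, (b - a) * gl$w)
    }
  }
  pq <- lapply(xs, oa_jacobians, branch = branch)
  list(I = xs, w = ws * stats::dnorm(xs, r1, r2),
       p11 = vapply(pq, function(e) e$P[1, 1], 0),
       p12 = vapply(pq, function(e) e$P[1, 2], 0),
       p21 = vapply(pq, function(e) e$P[2, 1], 0),
       p22 = vapply(pq, function(e) e$P[2, 2], 0),
       q11 = vapply(pq, function(e) e$Q[1, 1], 0),
       q12 = vapply(pq, function(e) e$Q[1, 2], 0),
       q21 = vapply(pq, function(e) e$Q[2, 1], 0),
       q22 = vapply(pq, function(e) e$Q[2, 2], 0))
}

det_c_quad <- function(mu, q) {
  a <- q$p11 - mu; b <- q$p12; cc <- q$p21; d <- q$p22 - mu
  dt <- a * d - b * cc
  m11 <- sum(q$w * (d * q$q11 - b * q$q21) / dt)
  m12 <- sum(q$w * (d * q$q12 - b * q$q22) / dt)
  m21 <- sum(q$w * (-cc * q$q11 + a * q$q21) / dt)
  m22 <- sum(q$w * (-cc * q$q12 + a * q$q22) / dt)
  (1 + m11) * (1 + m22) - m12 * m21
}

#' Characteristic determinant of the discrete spectrum
#'
#' Evaluates \eqn{\det C(\mu)} with
#' \eqn{C(\mu) = \mathbb{1} + \int g(I)\,(P(I) - \mu)^{-1} Q(I)\, dI},
#' whose zeros off the continuous spectrum are the discrete eigenvalues
#' of the linearized mean-field operator.  The integral uses composite
#' Gauss-Legendre panels on the truncated support with edges at
#' \eqn{\pm B}.  Trial values closer than `1e-6` to the sampled
#' continuous spectrum are rejected (resolvent singular there).
#'
#' @param mu complex trial eigenvalue (vectorized).
#' @param branch a `"stationary_branch"`.
#' @param npanel,deg quadrature resolution (panels per segment, nodes
#'   per panel).
#' @param quad optional precomputed quadrature (internal reuse).
#' @param continuous optional precomputed [continuous_spectrum()] sample
#'   used for the singularity guard.
#' @return Complex determinant value(s).
#' @export
characteristic_det <- function(mu, branch, npanel = 40, deg = 10,
                               quad = NULL, continuous = NULL) {
  if (is.null(quad)) quad <- resolvent_quad(branch, npanel, deg)
  if (is.null(continuous)) continuous <- continuous_spectrum(branch, 1000)
  cpts <- complex(real = continuous$Re, imaginary = continuous$Im)
  vapply(as.complex(mu), function(m) {
    if (min(Mod(cpts - m)) < 1e-6)
      stop("resolvent singular: mu lies on the sampled continuous spectrum")
    det_c_quad(m, quad)
  }, complex(1))
}

newton_det <- function(mu, quad, tol = 1e-10, maxit = 80) {
  for (i in seq_len(maxit)) {
    f <- det_c_quad(mu, quad)
    if (!is.finite(f)) return(NA_complex_)
    h <- 1e-6 * (1 + Mod(mu))
    fp <- (det_c_quad(mu + h, quad) - det_c_quad(mu - h, quad)) / (2 * h)
    step <- f / fp
    if (!is.finite(step)) return(NA_complex_)
    mu <- mu - step
    if (Mod(step) < tol) return(mu)
  }
  NA_complex_
}

# Discretized linearized operator: block matrix L with blocks
# L[m, n] = delta_mn P(I_m) + Q(I_m) w_n over a heterogeneity grid.
# Its isolated eigenvalues approximate the discrete spectrum and seed
# the Newton iteration on det C; it also serves as an independent
# cross-check of eigenvalue signs.
discretized_operator <- function(branch, M = 300) {
  q <- make_quadrature(M, "trapezoid")
  r1 <- branch$params$r1; r2 <- branch$params$r2
  I <- r1 + r2 * q$nodes
  L <- matrix(0, 2 * M, 2 * M)
  for (m in seq_len(M)) {
    pq <- oa_jacobians(I[m], branch)
    rows <- (2 * m - 1):(2 * m)
    for (n in seq_len(M)) {
      cols <- (2 * n - 1):(2 * n)
      L[rows, cols] <- pq$Q * q$weights[n]
    }
    L[rows, rows] <- L[rows, rows] + pq$P
  }
  L
}

#' Discrete spectrum of a stationary branch
#'
#' Solves the characteristic equation \eqn{\det C(\mu) = 0} by Newton
#' iteration seeded from (a) isolated eigenvalues of a finite
#' discretization of the linearized operator and (b) a rectangular grid
#' of starting points in `search_region`.  Converged roots are kept when
#' the determinant modulus is below `1e-8` and the root keeps a minimum
#' distance (`exclusion`) from the sampled continuous spectrum, then
#' deduplicated (distance `1e-6`) and completed with complex conjugates.
#' An empty result is legitimate: it means no isolated eigenvalue was
#' found in the region.
#'
#' Each root is annotated with its distance to the sampled continuous
#' spectrum; roots within `0.05` of it are flagged `near_continuum` and
#' treated with care by [classify_stability()], since quadrature error
#' concentrates along the continuous-spectrum curves.
#'
#' @param branch a `"stationary_branch"`.
#' @param search_region `c(re_min, re_max, im_min, im_max)`; conjugates
#'   are added by symmetry, so the imaginary range is the upper half
#'   plane by default.
#' @param n_seeds approximate number of grid seeds.
#' @param npanel,deg resolvent quadrature resolution.
#' @param exclusion minimum admissible distance from the sampled
#'   continuous spectrum.
#' @return Data frame with columns `Re`, `Im`, `det_mod`,
#'   `dist_continuum`, `near_continuum`, ordered by decreasing `Re`.
#' @export
discrete_spectrum <- function(branch, search_region = c(-2, 2, 0, 5),
                              n_seeds = 20, npanel = 40, deg = 10,
                              exclusion = 5e-3) {
  quad <- resolvent_quad(branch, npanel, deg)
  cont <- continuous_spectrum(branch, 2000)
  cpts <- complex(real = cont$Re, imaginary = cont$Im)

  L <- discretized_operator(branch)
  evL <- eigen(L, only.values = TRUE)$values
  distL <- vapply(evL, function(m) min(Mod(cpts - m)), 0)
  seeds <- evL[distL > 0.02 & Im(evL) > -1e-9]

  nre <- max(2L, round(sqrt(n_seeds)))
  nim <- max(2L, ceiling(n_seeds / nre))
  grid <- as.vector(outer(seq(search_region[1], search_region[2],
                              length.out = nre),
                          1i * seq(search_region[3], search_region[4],
                                   length.out = nim), `+`))
  seeds <- c(seeds, grid)

  found <- complex(0)
  for (s in seeds) {
    if (min(Mod(cpts - s)) < exclusion) next
    m <- newton_det(s, quad)
    if (is.na(m)) next
    if (Re(m) < search_region[1] - 0.5 || Re(m) > search_region[2] + 0.5)
      next
    if (abs(Im(m)) > search_region[4] + 0.5) next
    if (min(Mod(cpts - m)) < exclusion) next
    if (Mod(det_c_quad(m, quad)) > 1e-8) next
    if (Im(m) < 0) m <- Conj(m)
    if (length(found) == 0 || min(Mod(found - m)) > 1e-6)
      found <- c(found, m)
  }
  if (length(found) == 0) {
    warning("no discrete eigenvalues found in the search region")
    return(data.frame(Re = numeric(0), Im = numeric(0),
                      det_mod = numeric(0), dist_continuum = numeric(0),
                      near_continuum = logical(0)))
  }
  # complete conjugate pairs
  withc <- unique(c(found, Conj(found[abs(Im(found)) > 1e-9])))
  res <- data.frame(Re = Re(withc), Im = Im(withc),
                    det_mod = Mod(vapply(withc, det_c_quad, complex(1),
                                         q = quad)),
                    dist_continuum = vapply(withc, function(m)
                      min(Mod(cpts - m)), 0))
  res$near_continuum <- res$dist_continuum < 0.05
  res[order(-res$Re), , drop = FALSE]
}

#' Classify the linear stability of a stationary branch
#'
#' Classification from the leading discrete eigenvalue(s):
#' `"stable"`/`"unstable"` by the sign of the maximal real part
#' (`"marginal"` within `1e-7`), `"node"`/`"focus"` by whether the
#' leading eigenvalue is real or a complex pair.  Roots that are both
#' flagged `near_continuum` and have `|Re| < 0.05` are excluded from the
#' decision: within that marginal band, discrete candidates cannot be
#' distinguished numerically from contamination by the marginally stable
#' continuous spectrum.  If no discrete eigenvalue survives, the result
#' falls back to the continuous spectrum and is flagged
#' `"continuous-only"`.
#'
#' @param branch a `"stationary_branch"`.
#' @param spectrum optional precomputed [discrete_spectrum()] result.
#' @param ... passed to [discrete_spectrum()] when it must be computed.
#' @return Classification string, e.g. `"stable node"`; possibly with a
#'   `" (continuous-only)"` suffix.
#' @export
classify_stability <- function(branch, spectrum = NULL, ...) {
  if (is.null(spectrum)) spectrum <- discrete_spectrum(branch, ...)
  keep <- spectrum[!(spectrum$near_continuum & abs(spectrum$Re) < 0.05), ,
                   drop = FALSE]
  if (nrow(keep) == 0) {
    cont <- continuous_spectrum(branch, 1000)
    lead <- max(cont$Re)
    lab <- if (lead > 1e-7) "unstable" else "marginal"
    return(paste0(lab, " (continuous-only)"))
  }
  lead_re <- max(keep$Re)
  leading <- keep[abs(keep$Re - lead_re) < 1e-9, , drop = FALSE]
  shape <- if (any(abs(leading$Im) > 1e-9)) "focus" else "node"
  if (abs(lead_re) <= 1e-7) return("marginal")
  paste(if (lead_re > 0) "unstable" else "stable", shape)
}
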
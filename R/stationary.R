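#' Self-consistency integrals of the stationary layer state
#'
#' For a stationary mean field the population splits at the effective
#' excitability parameter \eqn{B = |1 + \sigma Z|} into an excitable
#' group (\eqn{|I| < B}, locked at rest with \eqn{|z| = 1}) and an
#' oscillating group (\eqn{|I| > B}, drifting with \eqn{|z| < 1}).
#' Inserting the stationary local profiles into the order-parameter
#' integral yields the two real integrals
#' \deqn{p_1(B) = r_1 - \int_{|I| > B} \mathrm{sign}(I)
#'   \sqrt{I^2 - B^2}\, g(I)\, dI, \qquad
#'   p_2(B) = \int_{|I| < B} \sqrt{B^2 - I^2}\, g(I)\, dI,}
#' with \eqn{g = \mathcal{N}(r_1, r_2^2)}.  The integrable square-root
#' behavior at \eqn{I = \pm B} is removed by the substitutions
#' \eqn{I = B\sin t} (excitable side) and \eqn{I = \pm B\cosh u}
#' (oscillating side); the support is truncated at \eqn{r_1 \pm 8 r_2}.
#'
#' @param B effective excitability parameter (> 0).
#' @param r1,r2 mean and standard deviation of the input distribution
#'   (`r2 > 0`).
#' @return Named vector `c(p1, p2)`.
#' @export
p_integrals <- function(B, r1, r2) {
  if (!is.numeric(B) || B <= 0) stop("'B' must be > 0")
  if (r2 <= 0) stop("'r2' must be > 0")
  lo <- r1 - 8 * r2
  hi <- r1 + 8 * r2

  p2 <- 0
  a <- max(lo, -B); b <- min(hi, B)
  if (b > a) {
    ta <- asin(a / B); tb <- asin(b / B)
    p2 <- stats::integrate(function(t) {
      ct <- cos(t)
      stats::dnorm(B * sin(t), r1, r2) * B^2 * ct^2
    }, ta, tb, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }

  osc <- 0
  if (hi > B) {
    umax <- acosh(hi / B)
    osc <- osc + stats::integrate(function(u) {
      sh <- sinh(u)
      stats::dnorm(B * cosh(u), r1, r2) * B^2 * sh^2
    }, 0, umax, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }
  if (lo < -B) {
    umax <- acosh(-lo / B)
    osc <- osc - stats::integrate(function(u) {
      sh <- sinh(u)
      stats::dnorm(-B * cosh(u), r1, r2) * B^2 * sh^2
    }, 0, umax, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }
  c(p1 = r1 - osc, p2 = p2)
}

#' Self-consistency function p(B)
#'
#' Stationary mean-field states are the positive roots of
#' \deqn{p(B) = B^2 - 2\sigma p_2(B) +
#'   \frac{\sigma^2}{B^2}\left(p_1(B)^2 + p_2(B)^2\right) - 1.}
#' In the uncoupled limit \eqn{\sigma = 0} this reduces to
#' \eqn{B^2 - 1} with the single positive root \eqn{B = 1}.
#'
#' @param B scalar or vector of positive values.
#' @inheritParams p_integrals
#' @param sigma coupling strength.
#' @return `p(B)`, vectorized over `B`.
#' @export
p_function <- function(B, r1, r2, sigma) {
  vapply(B, function(b) {
    pp <- p_integrals(b, r1, r2)
    b^2 - 2 * sigma * pp[["p2"]] +
      sigma^2 / b^2 * (pp[["p1"]]^2 + pp[["p2"]]^2) - 1
  }, numeric(1))
}

make_branch <- function(B, r1, r2, sigma, label = NA_character_,
                        fold_proximal = FALSE) {
  pp <- p_integrals(B, r1, r2)
  p1 <- pp[["p1"]]; p2 <- pp[["p2"]]
  R <- sqrt(p1^2 + p2^2) / B
  Theta <- atan2(p1, p2 - sigma * R^2)
  beta <- atan2(sigma * p1, B^2 - sigma * p2)
  Z <- complex(real = p2 - sigma * R^2, imaginary = p1)
  structure(list(B = B, p1 = p1, p2 = p2, R = R, Theta = Theta, beta = beta,
                 Z = Z, label = label, fold_proximal = fold_proximal,
                 params = list(r1 = r1, r2 = r2, sigma = sigma)),
            class = "stationary_branch")
}

#' @export
print.stationary_branch <- function(x, ...) {
  cat(sprintf(
    "Stationary branch %s at (r1, r2, sigma) = (%g, %g, %g)\n",
    ifelse(is.na(x$label), "?", x$label),
    x$params$r1, x$params$r2, x$params$sigma))
  cat(sprintf("  B = %.6f, R = %.6f, Theta = %.6f, beta = %.6f%s\n",
              x$B, x$R, x$Theta, x$beta,
              if (x$fold_proximal) "  [fold-proximal]" else ""))
  invisible(x)
}

#' Find all stationary mean-field states
#'
#' Locates every positive root of the self-consistency function
#' [p_function()] by sign-change bracketing on a logarithmic scan grid
#' followed by root polishing, and returns the corresponding branches in
#' decreasing order of `B`, labelled `"B1" > "B2" > "B3"`.  A larger `B`
#' means a larger excitable (locked) fraction of the population.  When
#' two consecutive scan resolutions disagree on the root count the
#' resolution is doubled (fold-proximity safeguard); roots closer than
#' `1e-4` in `B` are flagged `fold_proximal` rather than merged.
#'
#' @inheritParams p_function
#' @param B_range scan interval; default `c(1e-3, 1 + sigma + r1 + 8 r2)`.
#' @param n_scan number of log-spaced scan points.
#' @return List of `"stationary_branch"` objects, `B`-descending.
#' @export
#' @examples
#' length(find_stationary_states(0.9, 2, 5))  # three branches
find_stationary_states <- function(r1, r2, sigma, B_range = NULL,
                                   n_scan = 2000) {
  if (r2 <= 0) stop("'r2' must be > 0")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) {
    # B e^{i beta} = 1: single branch with B = 1
    return(list(make_branch(1, r1, r2, 0, label = "B1")))
  }
  if (is.null(B_range)) B_range <- c(1e-3, 1 + sigma + r1 + 8 * r2)

  scan_roots <- function(n) {
    Bs <- exp(seq(log(B_range[1]), log(B_range[2]), length.out = n))
    ps <- p_function(Bs, r1, r2, sigma)
    idx <- which(diff(sign(ps)) != 0)
    vapply(idx, function(i) {
      stats::uniroot(p_function, c(Bs[i], Bs[i + 1]), r1 = r1, r2 = r2,
                     sigma = sigma, tol = 1e-12)$root
    }, numeric(1))
  }

  roots <- scan_roots(n_scan)
  roots2 <- scan_roots(2L * n_scan)
  if (length(roots2) != length(roots)) roots <- scan_roots(4L * n_scan)

  roots <- sort(roots, decreasing = TRUE)
  prox <- rep(FALSE, length(roots))
  if (length(roots) > 1) {
    gap <- abs(diff(roots))
    close_pair <- which(gap < 1e-4)
    prox[close_pair] <- TRUE
    prox[close_pair + 1] <- TRUE
  }
  lapply(seq_along(roots), function(i) {
    make_branch(roots[i], r1, r2, sigma, label = paste0("B", i),
                fold_proximal = prox[i])
  })
}

#' Stationary local order parameter profile
#'
#' Evaluates the stationary local order parameter \eqn{z^*(I)} of a
#' branch: for the excitable group \eqn{|I| < B} the stable rest
#' solution \eqn{z^* = e^{i(\beta + \Phi^*)}} with
#' \eqn{\Phi^* = \arcsin(I/B)} (unit modulus); for the oscillating group
#' \eqn{|I| > B} the drifting solution with modulus
#' \eqn{\rho^* = (|I| - \sqrt{I^2 - B^2})/B} and
#' \eqn{\Phi^* = (\pi/2)\,\mathrm{sign}(I)}.  At \eqn{|I| = B} the two
#' expressions meet continuously at \eqn{\rho^* = 1}.
#'
#' @param branch a `"stationary_branch"`.
#' @param I input value(s).
#' @return Complex vector `z*(I)`.
#' @export
local_profile <- function(branch, I) {
  B <- branch$B; beta <- branch$beta
  rho <- ifelse(abs(I) < B, 1, (abs(I) - sqrt(pmax(I^2 - B^2, 0))) / B)
  Phi <- ifelse(abs(I) < B, asin(pmin(pmax(I / B, -1), 1)),
                pi / 2 * sign(I))
  rho * exp(1i * (beta + Phi))
}

#' Reconstruct the global order parameter of a branch
#'
#' Integrates the stationary local profile against the input density:
#' \eqn{Z = \int g(I) z^*(I) dI}.  With `field` supplied the quadrature
#' sum \eqn{\sum_m w_m z^*(I_m)} is used; otherwise adaptive integration
#' with the same square-root substitutions as [p_integrals()], which
#' resolves the kink at \eqn{|I| = B} to near machine precision.  At a
#' true root of `p(B)` the result closes the self-consistency loop:
#' \eqn{B e^{i\beta} = 1 + \sigma Z}.
#'
#' @param branch a `"stationary_branch"`.
#' @param field optional [oa_field()] providing quadrature nodes.
#' @return Complex `Z`.
#' @export
reconstruct_Z <- function(branch, field = NULL) {
  if (!is.null(field)) {
    I <- field$r1 + field$r2 * field$nodes
    return(sum(field$weights * local_profile(branch, I)))
  }
  r1 <- branch$params$r1; r2 <- branch$params$r2
  B <- branch$B
  lo <- r1 - 8 * r2; hi <- r1 + 8 * r2
  pieces <- 0 + 0i

  cint <- function(f, a, b) {
    re <- stats::integrate(function(x) Re(f(x)), a, b,
                           rel.tol = 1e-11, abs.tol = 1e-13)$value
    im <- stats::integrate(function(x) Im(f(x)), a, b,
                           rel.tol = 1e-11, abs.tol = 1e-13)$value
    complex(real = re, imaginary = im)
  }
  a <- max(lo, -B); b <- min(hi, B)
  if (b > a) {
    pieces <- pieces + cint(function(t) {
      I <- B * sin(t)
      local_profile(branch, I) * stats::dnorm(I, r1, r2) * B * cos(t)
    }, asin(a / B), asin(b / B))
  }
  if (hi > B) {
    pieces <- pieces + cint(function(u) {
      I <- B * cosh(u)
      local_profile(branch, I) * stats::dnorm(I, r1, r2) * B * sinh(u)
    }, 0, acosh(hi / B))
  }
  if (lo < -B) {
    pieces <- pieces + cint(function(u) {
      I <- -B * cosh(u)
      local_profile(branch, I) * stats::dnorm(I, r1, r2) * B * sinh(u)
    }, 0, acosh(-lo / B))
  }
  pieces
}

#' Excitable (locked) population fraction of a branch
#'
#' \eqn{\int_{|I| < B} g(I)\, dI}: the probability mass of inputs in the
#' excitable window.  Nested across branches at fixed parameters: a
#' larger `B` always contains a larger locked fraction.
#'
#' @param branch a `"stationary_branch"`.
#' @return Scalar in \[0, 1\].
#' @export
excitable_fraction <- function(branch) {
  with(branch$params,
       stats::pnorm(branch$B, r1, r2) - stats::pnorm(-branch$B, r1, r2))
}
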
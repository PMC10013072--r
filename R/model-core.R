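#' Model parameters for the rotator-resource system
#'
#' Container for the parameters of the two-layer model: a population of
#' `N` active rotators \eqn{\dot\phi_k = I_k - \sin\phi_k +
#' (\sigma/N)\sum_j \sin(\phi_j - \phi_k)} with inputs
#' \eqn{I_k = r_1 + r_2 \nu_k}, coupled to a slow resource pool
#' \eqn{\dot r = \epsilon f(r - s, \lambda)},
#' \eqn{\dot\lambda = -\epsilon'(\lambda - \lambda_0 - \gamma A)} where
#' \eqn{f(u, \lambda) = u(\lambda + i\omega - |u|^2)} is the Hopf normal
#' form and \eqn{A} is the population mean phase velocity.
#'
#' The defaults reproduce the reference parameter set
#' \eqn{\sigma = 5}, \eqn{\epsilon = \epsilon' = 0.05},
#' \eqn{s_1 = 0.97}, \eqn{s_2 = 1.2}, \eqn{\omega = 0.2},
#' \eqn{\lambda_0 = -0.05}, \eqn{\gamma = 0.5}, \eqn{N = 5000}.
#'
#' @param sigma coupling strength (>= 0).
#' @param eps fast/slow scale separation \eqn{\epsilon} (> 0, small).
#' @param eps_prime relaxation scale \eqn{\epsilon'} of the resource
#'   activity variable; defaults to `eps`.
#' @param s1,s2 components of the resource base level \eqn{s = s_1 + i s_2}.
#' @param omega angular frequency of the resource limit cycle (rad per
#'   slow time unit).
#' @param lambda0 rest level of the resource activity variable.
#' @param gamma adaptation strength coupling population activity into the
#'   resource pool (>= 0).
#' @param N population size (positive integer).
#'
#' @return An object of class `"oaburst_params"` (a named list).
#' @export
#' @examples
#' p <- model_params()
#' p$sigma
model_params <- function(sigma = 5, eps = 0.05, eps_prime = eps,
                         s1 = 0.97, s2 = 1.2, omega = 0.2,
                         lambda0 = -0.05, gamma = 0.5, N = 5000) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  if (!is.numeric(eps) || eps <= 0) stop("'eps' must be > 0")
  if (!is.numeric(eps_prime) || eps_prime <= 0) stop("'eps_prime' must be > 0")
  if (gamma < 0) stop("'gamma' must be >= 0")
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("'N' must be a positive integer")
  structure(list(sigma = sigma, eps = eps, eps_prime = eps_prime,
                 s1 = s1, s2 = s2, omega = omega, lambda0 = lambda0,
                 gamma = gamma, N = N),
            class = "oaburst_params")
}

#' @export
print.oaburst_params <- function(x, ...) {
  cat("Rotator-resource model parameters\n")
  cat(sprintf("  sigma = %g, eps = %g, eps' = %g\n", x$sigma, x$eps, x$eps_prime))
  cat(sprintf("  s = (%g, %g), omega = %g, lambda0 = %g, gamma = %g\n",
              x$s1, x$s2, x$omega, x$lambda0, x$gamma))
  cat(sprintf("  N = %d\n", x$N))
  invisible(x)
}

#' State of the resource pool
#'
#' The resource pool is described by the complex resource variable
#' \eqn{r = r_1 + i r_2} and the scalar activity variable \eqn{\lambda}.
#'
#' @param r1,r2 real and imaginary components of the resource variable,
#'   or `r1` may be a single complex number.
#' @param lam resource activity variable \eqn{\lambda}.
#' @return An object of class `"resource_state"` with fields `r` (complex)
#'   and `lam`.
#' @export
resource_state <- function(r1, r2 = NULL, lam) {
  r <- if (is.complex(r1)) r1 else complex(real = r1, imaginary = r2)
  if (!is.finite(Re(r)) || !is.finite(Im(r)) || !is.finite(lam))
    stop("resource state must be finite")
  structure(list(r = r, lam = lam), class = "resource_state")
}

#' Gaussian input density
#'
#' Density of the external inputs \eqn{I = r_1 + r_2 \nu} with standard
#' normal heterogeneity \eqn{\nu}: the normal density with mean `r1` and
#' standard deviation `r2`.  The homogeneous limit `r2 = 0` (a delta
#' distribution) is rejected here and must be treated separately by
#' callers.
#'
#' @param I input value(s).
#' @param r1 mean (homogeneous resource component).
#' @param r2 standard deviation (heterogeneous resource component, > 0).
#' @return Density values, same length as `I`.
#' @export
gaussian_density <- function(I, r1, r2) {
  if (!is.numeric(r2) || length(r2) != 1 || r2 <= 0)
    stop("'r2' must be a single positive number")
  stats::dnorm(I, mean = r1, sd = r2)
}

#' Kuramoto order parameter of a phase population
#'
#' Computes \eqn{Z = N^{-1}\sum_j e^{i\phi_j} = R e^{i\Theta}}.
#'
#' @param phases numeric vector of phases (radians, any branch).
#' @return A list of class `"macro_state"` with components `Z` (complex),
#'   `R` (modulus, in \[0, 1\]) and `Theta` (argument, in (-pi, pi\]).
#' @export
#' @examples
#' order_parameter(c(0, pi / 2))$R  # sqrt(2)/2
order_parameter <- function(phases) {
  if (length(phases) < 1) stop("need at least one phase")
  if (!all(is.finite(phases))) stop("phases must be finite")
  Z <- mean(exp(1i * phases))
  structure(list(Z = Z, R = Mod(Z), Theta = Arg(Z)), class = "macro_state")
}

#' Intrinsic resource derivatives (activity drive excluded)
#'
#' Evaluates the autonomous part of the slow resource equations:
#' \eqn{\dot r = \epsilon f(r - s, \lambda)} with
#' \eqn{f(u,\lambda) = u(\lambda + i\omega - |u|^2)}, and the relaxation
#' \eqn{\dot\lambda = -\epsilon'(\lambda - \lambda_0)}.  The activity
#' drive \eqn{\epsilon' \gamma A} is added by the callers that know the
#' population state.
#'
#' @param state a [resource_state()].
#' @param params a [model_params()].
#' @return List with components `dr` (complex) and `dlam`.
#' @export
resource_rhs <- function(state, params) {
  stopifnot(inherits(state, "resource_state"), inherits(params, "oaburst_params"))
  u <- state$r - complex(real = params$s1, imaginary = params$s2)
  dr <- params$eps * u * (state$lam + 1i * params$omega - Mod(u)^2)
  dlam <- -params$eps_prime * (state$lam - params$lambda0)
  list(dr = dr, dlam = dlam)
}

#' Hopf point of the resource subsystem
#'
#' Treating \eqn{\lambda} as a parameter, the linearization of
#' \eqn{f(r - s, \lambda)} at the base level \eqn{r = s} has eigenvalues
#' \eqn{\lambda \pm i\omega}.  This helper locates the zero crossing of
#' the eigenvalue real part numerically (by bisection on the computed
#' Jacobian spectrum), returning the critical \eqn{\lambda} of the
#' supercritical Hopf bifurcation separating the inactive (stable focus)
#' from the active (limit cycle) resource regime.
#'
#' @param params a [model_params()].
#' @param interval search interval for \eqn{\lambda}.
#' @param tol bisection tolerance.
#' @return The critical value of \eqn{\lambda}.
#' @export
resource_hopf_point <- function(params = model_params(),
                                interval = c(-1, 1), tol = 1e-12) {
  lead_re <- function(lam) {
    J <- resource_jacobian(lam, params)
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  stats::uniroot(lead_re, interval, tol = tol)$root
}

# Jacobian of f(r - s, lam) at r = s, real 2x2 form.
resource_jacobian <- function(lam, params) {
  # d/du [u (lam + i omega - |u|^2)] at u = 0 is multiplication by lam + i omega
  matrix(c(lam, -params$omega, params$omega, lam), 2, 2)
}

#' Wrap phases to \[0, 2*pi)
#'
#' Internal integration uses unwrapped phases; this helper maps them to
#' the fundamental interval for output.
#' @param phases numeric vector.
#' @return Wrapped phases.
#' @export
wrap_phases <- function(phases) phases %% (2 * pi)

# Unwrap a sampled angle series (inverse of atan2 branch cuts).
unwrap_angles <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  theta + c(0, cumsum(round(-d / (2 * pi)))) * 2 * pi
}
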
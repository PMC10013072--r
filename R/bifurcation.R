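#' Locate a fold of stationary states at fixed r2
#'
#' A fold (saddle-node) of the self-consistency equation satisfies the
#' double-root condition \eqn{p(B) = 0,\ \partial_B p(B) = 0}.  The
#' root-count transition is first bracketed by bisection in `r1`, then
#' the pair `(B, r1)` is polished by Newton iteration on the
#' two-equation system with finite-difference derivatives.
#'
#' @param sigma coupling strength.
#' @param r2 heterogeneous resource component.
#' @param r1_bracket interval of `r1` whose endpoints have different
#'   root counts.
#' @param tol Newton residual tolerance.
#' @return List with `r1`, `r2`, `B` (the double root), `branch_id`
#'   (`"lower"` for a B1-B2 fold, `"upper"` for B2-B3), and residuals
#'   `p`, `dp_dB`.
#' @export
fold_point <- function(sigma, r2, r1_bracket, tol = 1e-10) {
  count <- function(r1) length(find_stationary_states(r1, r2, sigma))
  c_lo <- count(r1_bracket[1]); c_hi <- count(r1_bracket[2])
  if (c_lo == c_hi)
    stop(sprintf("no root-count change in r1 bracket [%g, %g] (both %d)",
                 r1_bracket[1], r1_bracket[2], c_lo))
  lo <- r1_bracket[1]; hi <- r1_bracket[2]
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (count(mid) == c_lo) lo <- mid else hi <- mid
  }
  # merging pair on the 3-root side
  side3 <- if (c_lo == 3) lo else hi
  roots <- vapply(find_stationary_states(side3, r2, sigma), `[[`,
                  numeric(1), "B")
  gaps <- abs(diff(roots))
  i <- which.min(gaps)
  B0 <- mean(roots[i:(i + 1)])
  branch_id <- if (i == 1) "lower" else "upper"  # B descending: 1st gap = B1-B2
  r10 <- (lo + hi) / 2

  pB <- function(B, r1) p_function(B, r1, r2, sigma)
  x <- c(B0, r10)
  for (it in 1:60) {
    hB <- 1e-6 * (1 + x[1])
    f1 <- pB(x[1], x[2])
    f2 <- (pB(x[1] + hB, x[2]) - pB(x[1] - hB, x[2])) / (2 * hB)
    if (abs(f1) < tol && abs(f2) < 1e-8) break
    hr <- 1e-6
    j11 <- f2
    j12 <- (pB(x[1], x[2] + hr) - pB(x[1], x[2] - hr)) / (2 * hr)
    j21 <- (pB(x[1] + hB, x[2]) - 2 * f1 + pB(x[1] - hB, x[2])) / hB^2
    j22 <- ((pB(x[1] + hB, x[2] + hr) - pB(x[1] - hB, x[2] + hr)) -
              (pB(x[1] + hB, x[2] - hr) - pB(x[1] - hB, x[2] - hr))) /
      (4 * hB * hr)
    J <- matrix(c(j11, j12, j21, j22), 2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, c(f1, f2)), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # damp to stay in the admissible region
    while (x[1] - step[1] <= 0) step <- step / 2
    x <- x - step
    if (max(abs(step)) < 1e-12) break
  }
  hB <- 1e-6 * (1 + x[1])
  list(r1 = x[2], r2 = r2, B = x[1], branch_id = branch_id,
       p = pB(x[1], x[2]),
       dp_dB = (pB(x[1] + hB, x[2]) - pB(x[1] - hB, x[2])) / (2 * hB))
}

#' Trace the fold branches in the (r1, r2) plane
#'
#' For each value of `r2` the root count of the self-consistency
#' function is scanned over `r1` and every transition is polished with
#' [fold_point()].  The lower branch (annihilating the B1-B2 pair) and
#' the upper branch (B2-B3) are returned together; they meet at the
#' codimension-two cusp, estimated as the `r2` beyond which no
#' three-root interval survives.
#'
#' @param sigma coupling strength.
#' @param r2_values vector of r2 levels to section.
#' @param r1_range scan range in r1.
#' @param n_scan number of scan points per section.
#' @return Object of class `"fold_curves"`: data frame with columns
#'   `r1`, `r2`, `B`, `branch_id`; the cusp estimate (if bracketed) is
#'   attached as attribute `cusp`.
#' @export
fold_branches <- function(sigma, r2_values, r1_range = c(0.3, 1.3),
                          n_scan = 41) {
  rows <- list()
  for (r2 in r2_values) {
    r1s <- seq(r1_range[1], r1_range[2], length.out = n_scan)
    counts <- vapply(r1s, function(r1)
      length(find_stationary_states(r1, r2, sigma)), integer(1))
    trans <- which(diff(counts) != 0)
    for (i in trans) {
      fp <- tryCatch(
        fold_point(sigma, r2, c(r1s[i], r1s[i + 1])),
        error = function(e) NULL)
      if (!is.null(fp))
        rows[[length(rows) + 1]] <-
          data.frame(r1 = fp$r1, r2 = r2, B = fp$B,
                     branch_id = fp$branch_id)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r1 = numeric(0), r2 = numeric(0), B = numeric(0),
               branch_id = character(0))
  # cusp: last sectioned r2 that still carries two distinct folds
  cusp <- NULL
  if (nrow(out)) {
    both <- tapply(out$branch_id, out$r2, function(b)
      length(unique(b)) == 2)
    r2b <- as.numeric(names(both))[both]
    if (length(r2b) && max(r2b) < max(r2_values)) {
      sel <- out$r2 == max(r2b)
      cusp <- c(r1 = mean(out$r1[sel]), r2 = max(r2b))
    }
  }
  structure(out, class = c("fold_curves", "data.frame"), cusp = cusp,
            sigma = sigma)
}

#' Critical line between stationary and oscillating mean phase
#'
#' For each `r2`, bisects `r1` on the [classify_theta_dynamics()]
#' outcome of an Ott-Antonsen layer run started from the incoherent
#' state (protocol: 200 time units, classification over the final 100),
#' and also reports the fold-based prediction from the double-root
#' condition for comparison.  The two boundaries coincide where only
#' one stable state exists.
#'
#' @param sigma coupling strength.
#' @param r2_values vector of r2 levels.
#' @param r1_bracket bracket straddling the transition.
#' @param tol bisection tolerance in r1.
#' @param M quadrature resolution of the layer runs.
#' @param t_end,transient layer-run protocol.
#' @return Data frame with columns `r2`, `r1_sim`, `r1_fold`.
#' @export
critical_line <- function(sigma, r2_values, r1_bracket = c(0.85, 1.1),
                          tol = 2e-3, M = 201, t_end = 200,
                          transient = 100) {
  classify_at <- function(r1, r2) {
    run <- integrate_layer(oa_field(r1, r2, M = M), sigma, t_end = t_end)
    classify_theta_dynamics(run$ts, transient = transient)
  }
  rows <- lapply(r2_values, function(r2) {
    lo <- r1_bracket[1]; hi <- r1_bracket[2]
    c_lo <- classify_at(lo, r2); c_hi <- classify_at(hi, r2)
    if (c_lo == c_hi)
      stop(sprintf(
        "no stationary/oscillating change in bracket [%g, %g] at r2 = %g",
        lo, hi, r2))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (classify_at(mid, r2) == c_lo) lo <- mid else hi <- mid
    }
    fp <- tryCatch(fold_point(sigma, r2, r1_bracket),
                   error = function(e) list(r1 = NA_real_))
    data.frame(r2 = r2, r1_sim = (lo + hi) / 2, r1_fold = fp$r1)
  })
  do.call(rbind, rows)
}

#' Regime map over the (r1, r2) plane
#'
#' Per-cell summaries of the layer dynamics following the fixed-resource
#' protocol: simulate for `t_end` time units and average over the final
#' `t_end - transient`.  The `"oa"` engine integrates the mean-field
#' layer from the incoherent state; the `"network"` engine simulates a
#' finite population with frozen resources, reusing one heterogeneity
#' draw across all cells.
#'
#' @param sigma coupling strength.
#' @param r1_values,r2_values grid axes.
#' @param engine `"oa"` or `"network"`.
#' @param t_end,transient protocol windows.
#' @param M OA quadrature resolution.
#' @param pop population for the network engine (one draw reused across
#'   cells); default `init_population(1000, seed = 1)`.
#' @return Data frame (class `"regime_map"`) with columns `r1`, `r2`,
#'   `A_mean`, `R_mean`, `R_range`, `theta_class`.
#' @export
regime_map <- function(sigma, r1_values, r2_values,
                       engine = c("oa", "network"),
                       t_end = 200, transient = 100, M = 201, pop = NULL) {
  engine <- match.arg(engine)
  if (engine == "network" && is.null(pop))
    pop <- init_population(1000, seed = 1)
  rows <- list()
  for (r2 in r2_values) for (r1 in r1_values) {
    if (engine == "oa") {
      run <- integrate_layer(oa_field(r1, r2, M = M), sigma, t_end = t_end)
      ts <- run$ts
      sel <- ts$t > transient
      A <- r1 - ts$ImZ[sel]
      rows[[length(rows) + 1]] <- data.frame(
        r1 = r1, r2 = r2, A_mean = mean(A), R_mean = mean(ts$R[sel]),
        R_range = diff(range(ts$R[sel])),
        theta_class = classify_theta_dynamics(ts, transient = transient))
    } else {
      params <- model_params(sigma = sigma, N = pop$N)
      res <- resource_state(r1, r2, params$lambda0)
      ts <- simulate_network(pop, res, params, t_end = t_end,
                             dt_out = 0.1, freeze_r = TRUE,
                             freeze_lambda = TRUE)
      sel <- ts$t > transient
      ts$ReZ <- ts$R * cos(ts$Theta); ts$ImZ <- ts$R * sin(ts$Theta)
      rows[[length(rows) + 1]] <- data.frame(
        r1 = r1, r2 = r2, A_mean = mean(ts$A[sel]),
        R_mean = mean(ts$R[sel]), R_range = diff(range(ts$R[sel])),
        theta_class = classify_theta_dynamics(ts, transient = transient))
    }
  }
  structure(do.call(rbind, rows), class = c("regime_map", "data.frame"),
            engine = engine, sigma = sigma)
}

#' Locus of the Hopf-like stability change of branch B3
#'
#' Along this curve the leading complex-conjugate pair of the discrete
#' spectrum of the lowest stationary branch crosses the imaginary axis.
#' For each `r2`, `r1` is bisected on the sign of the leading pair's
#' real part; points where `|Re|` is already below `1e-6` are returned
#' immediately.  Near the locus the pair approaches the marginally
#' stable continuous spectrum, so the crossing is tracked with the
#' near-continuum filter disabled.
#'
#' @param sigma coupling strength.
#' @param r2_values r2 levels, inside the three-root wedge.
#' @param r1_bracket bisection bracket.
#' @param tol bisection tolerance in r1.
#' @param ... passed to [discrete_spectrum()].
#' @return Data frame with columns `r2`, `r1`, `re_lead`.
#' @export
hopf_like_locus <- function(sigma, r2_values, r1_bracket, tol = 1e-3, ...) {
  lead_pair_re <- function(r1, r2) {
    brs <- find_stationary_states(r1, r2, sigma)
    if (length(brs) < 3) stop(sprintf("branch B3 absent at (%g, %g)", r1, r2))
    sp <- discrete_spectrum(brs[[3]], ...)
    cplx <- sp[abs(sp$Im) > 1e-6, , drop = FALSE]
    if (nrow(cplx) == 0) return(NA_real_)
    max(cplx$Re)
  }
  rows <- lapply(r2_values, function(r2) {
    lo <- r1_bracket[1]; hi <- r1_bracket[2]
    f_lo <- lead_pair_re(lo, r2); f_hi <- lead_pair_re(hi, r2)
    if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi))
      return(data.frame(r2 = r2, r1 = NA_real_, re_lead = NA_real_))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- lead_pair_re(mid, r2)
      if (is.na(fm) || abs(fm) < 1e-6) {
        lo <- hi <- mid
        break
      }
      if (sign(fm) == sign(f_lo)) lo <- mid else hi <- mid
    }
    mid <- (lo + hi) / 2
    data.frame(r2 = r2, r1 = mid,
               re_lead = tryCatch(lead_pair_re(mid, r2),
                                  error = function(e) NA_real_))
  })
  do.call(rbind, rows)
}
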
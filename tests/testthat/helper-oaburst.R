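# Shared fixtures, computed once per test run.

# Stationary branches at the three-root reference point (r1, r2, sigma)
# = (0.9, 2, 5).
ref_branches <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- find_stationary_states(0.9, 2, 5)
    cache
  }
})

# Discrete spectra of the reference branches (computed lazily; the block
# matrix seed search dominates the cost).
ref_spectra <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(ref_branches(), discrete_spectrum)
    cache
  }
})

expect_close <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|%s - %s| = %g < %g",
                              deparse(substitute(object)),
                              deparse(substitute(expected)),
                              max(abs(object - expected)), tol))
}
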
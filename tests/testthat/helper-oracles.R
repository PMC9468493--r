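# Reference integrator: classical 4th-order Runge-Kutta at a fine step,
# built on the R-level derivative function, independent of the compiled
# Euler stepping used by the package.
rk4_integrate <- function(state, params, t_end, dt = 1e-3) {
  s <- as.numeric(state)
  for (i in seq_len(round(t_end / dt))) {
    k1 <- state_derivative(s, params)
    k2 <- state_derivative(s + dt / 2 * k1, params)
    k3 <- state_derivative(s + dt / 2 * k2, params)
    k4 <- state_derivative(s + dt * k3, params)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# The standard 20-trace synthetic cohort (1 group, 180 frames at 1 Hz,
# 2%-of-range observation noise) and its inversions, computed once and
# shared across test files.
standard_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(20, list(A = c()), seed = 42)
      res <- run_batch(coh)
      cache <<- list(cohort = coh, results = res, table = results_table(res))
    }
    cache
  }
})
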
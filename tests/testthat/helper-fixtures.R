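# Shared fixtures for the test suite. Everything is generated in code with
# fixed seeds; no data files.

# A small count table with planted structure, used by several suites.
small_synth_config <- function(...) {
  synth_config(n_soils = 3, ph_grid = seq(3, 9, length.out = 5),
               n_asv = 150, n_phyla = 12, ...)
}

# Independent ODE oracle: integrates the raw (unrescaled) consumer-resource
# system with deSolve directly, bypassing the package's model code.
integrate_raw_oracle <- function(raw, times) {
  rhs <- function(t, y, p) {
    A <- max(y[1], 0); C <- max(y[2], 0); x <- max(y[3], 0)
    mA <- A / (A + p["K_A"]); mC <- C / (C + p["K_C"])
    list(c(-p["r_A"] * x * mA,
           -p["r_C"] * x * mC,
           p["gamma"] * x * mA * mC))
  }
  grid <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(c(A = raw$A0, C = raw$C0, x = raw$x0), grid, rhs,
                      c(r_A = raw$r_A, r_C = raw$r_C, K_A = raw$K_A,
                        K_C = raw$K_C, gamma = raw$gamma),
                      method = "radau", rtol = 1e-10, atol = 1e-12)
  if (times[1] > 0) out <- out[-1, , drop = FALSE]
  out
}

# Reference integration of the rescaled system, independent of simulate_crm.
integrate_rescaled_oracle <- function(params, times, growth_on = TRUE) {
  rhs <- function(t, y, p) {
    A <- max(y[1], 0); C <- max(y[2], 0); x <- max(y[3], 0)
    mA <- A / (A + p["K_A"]); mC <- C / (C + p["K_C"])
    list(c(-x * mA, -x * mC, p["gamma"] * x * mA * mC))
  }
  a0 <- if (growth_on) params$A0 else params$A0c
  g <- if (growth_on) params$gamma else 0
  grid <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(c(A = a0, C = params$C0_tilde, x = params$x0_tilde),
                      grid, rhs,
                      c(K_A = params$K_A, K_C = params$K_C_tilde, gamma = g),
                      method = "radau", rtol = 1e-10, atol = 1e-12)
  if (times[1] > 0) out <- out[-1, , drop = FALSE]
  out
}

# Draw replicate x ASV count matrices from a known noise model around fixed
# expected abundances (the enrichment null / power fixture).
draw_replicate_counts <- function(expected, n_rep, model) {
  t(vapply(seq_len(n_rep), function(r) {
    pmax(round(stats::rnorm(length(expected), expected,
                            noise_sd(expected, model))), 0)
  }, numeric(length(expected))))
}
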
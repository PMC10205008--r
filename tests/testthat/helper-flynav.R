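# Shared fixtures: the study's fitted parameter set and a couple of small
# protocols used across test files.

table1_params <- function() turn_model_params()

small_grid <- function() {
  data.frame(frequency = c(0.2, 1.5, 3), duration = c(1, 0.1, 0.25))
}

# Square-wave signal trace with exact pulse times, outside the block
# structure (for kernel unit tests).
square_signal <- function(frequency, duration, t_end, dt = 1 / 60) {
  onsets <- seq(0, t_end - 1e-9, by = 1 / frequency)
  signal_trace(onsets, pmin(onsets + duration, t_end), t_end, dt)
}

# Explicit Euler integration of the two-timescale integrator at a fixed
# step; the independent oracle for the closed-form cycle average.
euler_two_timescale <- function(frequency, intermittency, tau_g, tau_d,
                                n_periods = 200, h = 1e-4) {
  T <- 1 / frequency
  D <- intermittency * T
  R <- 0
  t <- 0
  n <- round(n_periods * T / h)
  last_vals <- NULL
  keep_from <- round((n_periods - 1) * T / h)
  vals <- numeric(n - keep_from)
  for (i in seq_len(n)) {
    s <- (t %% T) < D
    dR <- if (s) (1 - R) / max(tau_g, h / 10) else -R / max(tau_d, h / 10)
    if (tau_g == 0 && s) R <- 1 else if (tau_d == 0 && !s) R <- 0 else
      R <- R + h * dR
    if (R > 1) R <- 1
    if (R < 0) R <- 0
    t <- t + h
    if (i > keep_from) vals[i - keep_from] <- R
  }
  mean(vals)
}
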
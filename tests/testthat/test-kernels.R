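test_that("novelty response spikes to 1 and follows the amplitude rule", {
  s <- square_signal(5, 0.05, 4)
  N <- novelty_response(s, tau_N = 2.04, tau_ND = 0.55)
  expect_equal(N$value[1], 1)            # first onset: maximal response
  expect_true(all(N$value >= 0 & N$value <= 1))
  # later spike amplitudes follow 1 - exp(-T / tau_N)
  amp <- 1 - exp(-0.2 / 2.04)
  on_idx <- which(s$t >= 2 & abs(s$t %% 0.2) < 1e-9)
  expect_equal(max(N$value[on_idx]), amp, tolerance = 1e-6)
  # widely spaced onsets recover the maximal response
  s2 <- signal_trace(c(0, 100), c(0.5, 100.5), 101)
  N2 <- novelty_response(s2, 2.04, 0.55)
  expect_gt(N2$value[which(s2$t >= 100)[1]], 0.999)
  # non-increasing strictly between onsets
  seg <- N$value[s$t > 0.2 + 1e-9 & s$t < 0.4 - 1e-9]
  expect_true(all(diff(seg) <= 0))
  # empty signal -> all-zero trace
  s0 <- signal_trace(numeric(0), numeric(0), 1)
  expect_true(all(novelty_response(s0, 2.04, 0.55)$value == 0))
})

test_that("offset response is the positive slow-minus-fast difference", {
  # constant-on signal: OFF settles to 0
  s1 <- signal_trace(0, 10, 10)
  off1 <- off_response(s1, 0.19, 0.22)
  expect_true(all(off1$value[s1$t > 3] < 1e-6))
  expect_true(all(off1$value >= 0))
  # no signal at all: identically 0
  s0 <- signal_trace(numeric(0), numeric(0), 2)
  expect_true(all(off_response(s0, 0.19, 0.22)$value == 0))
  # after a 1 s pulse the response peaks at the analytic maximum
  s2 <- signal_trace(0, 1, 4, dt = 1 / 600)
  off2 <- off_response(s2, 0.19, 0.22)
  tf <- 0.19; ts <- 0.22
  If0 <- 1 - exp(-1 / tf); Is0 <- 1 - exp(-1 / ts)
  f <- function(u) Is0 * exp(-u / ts) - If0 * exp(-u / tf)
  u_peak <- optimize(f, c(0, 2), maximum = TRUE)
  post <- s2$t > 1
  expect_equal(max(off2$value[post]), u_peak$objective, tolerance = 1e-3)
  expect_lt(abs(s2$t[post][which.max(off2$value[post])] - 1 - u_peak$maximum),
            0.01)
  # decays back to ~0
  expect_lt(off2$value[length(off2$value)], 1e-4)
  # constructor guard and degenerate formula check
  expect_error(off_response(s1, 0.22, 0.19), "tau_fast")
  i1 <- intermittency_filter(s2, 0.2)
  expect_equal(pmax(0, i1$value - i1$value), numeric(length(i1$value)))
})

test_that("intermittency filter converges to the signal intermittency", {
  s1 <- signal_trace(0, 20, 20)
  i1 <- intermittency_filter(s1, 0.04)
  expect_equal(i1$value[length(i1$value)], 1, tolerance = 1e-6)
  s0 <- signal_trace(numeric(0), numeric(0), 2)
  expect_true(all(intermittency_filter(s0, 0.04)$value == 0))
  # square wave f = 2, D = 0.25: cycle-averaged I after 10 s is Int = 0.5
  s2 <- square_signal(2, 0.25, 12)
  i2 <- intermittency_filter(s2, 0.04)
  cyc <- s2$t >= 10 & s2$t < 10.5
  expect_equal(mean(i2$value[cyc]), 0.5, tolerance = 0.02)
})

test_that("onset-frequency filter is a decaying onset counter", {
  s1 <- signal_trace(1, 1.2, 5)
  f1 <- onset_frequency_filter(s1, 0.5)
  post <- s1$t >= 1
  expect_equal(f1$value[post], exp(-(s1$t[post] - 1) / 0.5), tolerance = 1e-9)
  expect_true(all(f1$value[s1$t < 1] == 0))
  # periodic onsets reach the geometric-series steady state
  s2 <- square_signal(2, 0.05, 20)
  f2 <- onset_frequency_filter(s2, 0.5)
  at_onset <- which(abs(s2$t %% 0.5) < 1e-9 & s2$t >= 15)
  expect_equal(max(f2$value[at_onset]), 1 / (1 - exp(-0.5 / 0.5)),
               tolerance = 1e-3)
  s0 <- signal_trace(numeric(0), numeric(0), 2)
  expect_true(all(onset_frequency_filter(s0, 0.5)$value == 0))
})

test_that("dual response is the gain-weighted sum of I and F", {
  s <- square_signal(2, 0.1, 10)
  I <- intermittency_filter(s, 0.1)
  F <- onset_frequency_filter(s, 0.1)
  H0 <- dual_response(I, F, 0, 0)
  expect_true(all(H0$value == 0))
  H <- dual_response(I, F, 2.7, 3.2)
  expect_equal(H$value, 2.7 * I$value + 3.2 * F$value)
  # linearity in the I channel
  H2 <- dual_response(I, F, 5.4, 3.2)
  expect_equal(H2$value - H$value, 2.7 * I$value)
  I_bad <- intermittency_filter(square_signal(2, 0.1, 5), 0.1)
  expect_error(dual_response(I_bad, F, 1, 1), "time grid")
})

test_that("two-timescale response matches its closed forms", {
  s1 <- signal_trace(0, 10, 10)
  r1 <- two_timescale_response(s1, 0.5, 1)
  expect_equal(r1$value, 1 - exp(-s1$t / 0.5), tolerance = 1e-9)
  # equal timescales reduce to the single-timescale integrator
  s2 <- square_signal(1.5, 0.25, 8)
  r2 <- two_timescale_response(s2, 0.3, 0.3)
  i2 <- intermittency_filter(s2, 0.3)
  expect_equal(r2$value, i2$value, tolerance = 1e-9)
  expect_true(all(r2$value >= 0 & r2$value <= 1))
  # fitted timescales on the 2 Hz / 0.05 s protocol: cycle average matches
  # the asymptotic closed form to < 2%
  s3 <- square_signal(2, 0.05, 40)
  r3 <- two_timescale_response(s3, 0.01, 0.97)
  cyc <- s3$t >= 39 & s3$t < 39.5
  expect_equal(mean(r3$value[cyc]),
               asymptotic_mean_response(2, 0.1, 0.01, 0.97),
               tolerance = 0.02)
})

test_that("asymptotic mean response has the documented structure", {
  # equal timescales: exactly the intermittency
  for (int in c(0.05, 0.3, 0.7)) {
    expect_equal(asymptotic_mean_response(2, int, 0.4, 0.4), int)
  }
  # limit formulas agree with the full expression at the limits
  expect_equal(asymptotic_mean_response(2, 0.3, 0, 0.97),
               asymptotic_mean_response_limit(2, 0.3, 0.97, "fast_rise"))
  expect_equal(asymptotic_mean_response(2, 0.3, 0.5, 0),
               asymptotic_mean_response_limit(2, 0.3, 0.5, "fast_decay"))
  # instantaneous rise at very high frequency saturates toward 1
  expect_gt(asymptotic_mean_response(100, 0.2, 0, 0.97), 0.99)
  # monotone increasing in intermittency at fixed frequency
  ints <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(ints, asymptotic_mean_response, 0, frequency = 1.5,
                 tau_g = 0.01, tau_d = 0.97)
  expect_true(all(diff(vals) > 0))
  # fast rise: grows with frequency then levels off near 1/tau_d
  fr <- c(0.2, 0.5, 1, 2, 5)
  v1 <- vapply(fr, asymptotic_mean_response, 0, intermittency = 0.2,
               tau_g = 0.001, tau_d = 0.97)
  expect_true(all(diff(v1) > 0))
  expect_lt(v1[5] - v1[4], v1[2] - v1[1])
  # fast decay: decreases with frequency
  v2 <- vapply(fr, asymptotic_mean_response, 0, intermittency = 0.2,
               tau_g = 0.97, tau_d = 0.001)
  expect_true(all(diff(v2) < 0))
})

test_that("exact kernel evaluation is sampling-grid free and Euler-limited", {
  s_a <- square_signal(1.75, 0.1, 6, dt = 1 / 60)
  s_b <- square_signal(1.75, 0.1, 6, dt = 1 / 120)
  keep <- match(round(s_a$t, 9), round(s_b$t, 9))
  for (f in list(
    function(s) novelty_response(s, 2.04, 0.55)$value,
    function(s) off_response(s, 0.19, 0.22)$value,
    function(s) intermittency_filter(s, 0.04)$value,
    function(s) two_timescale_response(s, 0.01, 0.97)$value)) {
    expect_lt(max(abs(f(s_a) - f(s_b)[keep])), 1e-12)
  }
  # explicit Euler at a fine step converges to the exact trace
  h <- 1 / 600
  tt <- seq(0, 6 - h / 2, by = h)
  on <- (tt %% (1 / 1.75)) < 0.1 & tt < 6
  I_euler <- numeric(length(tt))
  for (i in seq_along(tt)[-1]) {
    I_euler[i] <- I_euler[i - 1] + h / 0.2 * (on[i - 1] - I_euler[i - 1])
  }
  I_exact <- intermittency_filter(square_signal(1.75, 0.1, 6, dt = h),
                                  0.2)$value
  expect_lt(max(abs(I_euler - I_exact)), 0.01)
})
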
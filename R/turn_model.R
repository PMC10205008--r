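#' Parameters of the generative turning model
#'
#' The full fitted parameter set: turn-rate coefficients (baseline `lambda0`,
#' novelty `lambda1`, offset `lambda2`, events/s), excess mean-turn-speed
#' coefficients (`mu0`, `mu1`, `mu2`, deg/s beyond the 25 deg/s floor), the
#' excess turn-duration timescale `tau_dur` (s beyond the 0.18 s floor), the
#' upwind-bias baseline shift `a0` and gain `g`, the bias kernel choice, and
#' the kernel timescales. Defaults are the study's fitted values, so that in
#' the absence of signal the mean total turn speed is 25 + 68.1 = 93.1 deg/s
#' and the mean total turn duration is 0.18 + 0.18 = 0.36 s.
#'
#' @param lambda0,lambda1,lambda2 turn-rate coefficients (events/s).
#' @param mu0,mu1,mu2 excess mean-turn-speed coefficients (deg/s).
#' @param tau_dur excess turn-duration timescale (s).
#' @param a0 baseline bias shift (dimensionless).
#' @param g bias gain for the chosen kernel.
#' @param bias_kernel one of "R", "I", "F", "H".
#' @param kernel_params a [kernel_params()] object.
#' @param speed_floor minimum turn speed (25 deg/s).
#' @param duration_floor minimum turn duration (0.18 s).
#' @param gamma_shape shape of the turn-speed Gamma distribution (fixed 2).
#' @return A list of class `turn_model_params`.
#' @export
turn_model_params <- function(lambda0 = 3.06, lambda1 = 2.80,
                              lambda2 = 45.14, mu0 = 68.1, mu1 = 47.1,
                              mu2 = 582.0, tau_dur = 0.18, a0 = -0.49,
                              g = 1.5, bias_kernel = c("R", "I", "F", "H"),
                              kernel_params = flynav::kernel_params(),
                              speed_floor = 25, duration_floor = 0.18,
                              gamma_shape = 2) {
  bias_kernel <- match.arg(bias_kernel)
  stopifnot(tau_dur > 0, speed_floor > 0, duration_floor > 0)
  if (gamma_shape != 2) stop("gamma_shape is fixed at 2 in this model")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2,
                 mu0 = mu0, mu1 = mu1, mu2 = mu2, tau_dur = tau_dur,
                 a0 = a0, g = g, bias_kernel = bias_kernel,
                 kernel_params = kernel_params, speed_floor = speed_floor,
                 duration_floor = duration_floor, gamma_shape = gamma_shape),
            class = "turn_model_params")
}

#' @export
print.turn_model_params <- function(x, ...) {
  cat("turn_model_params:\n")
  cat(sprintf("  rate: %g + %g N + %g OFF /s\n", x$lambda0, x$lambda1,
              x$lambda2))
  cat(sprintf("  speed: %g + %g N + %g OFF deg/s above the %g deg/s floor\n",
              x$mu0, x$mu1, x$mu2, x$speed_floor))
  cat(sprintf("  duration: %g s above the %g s floor\n", x$tau_dur,
              x$duration_floor))
  cat(sprintf("  bias: 1/(1+exp(-(%g + %g u) sin^2 theta)), u = %s(t)\n",
              x$a0, x$g, x$bias_kernel))
  invisible(x)
}

#' Instantaneous turn rate
#'
#' `lambda(t) = lambda0 + lambda1 N(t) + lambda2 OFF(t)`, events per second.
#' A negative result signals nonsensical parameters and raises an error.
#'
#' @param N novelty response value(s) in \[0, 1\].
#' @param OFF offset response value(s), >= 0.
#' @param params a [turn_model_params()].
#' @return Turn rate(s) in events/s.
#' @export
turn_rate <- function(N, OFF, params) {
  lam <- params$lambda0 + params$lambda1 * N + params$lambda2 * OFF
  if (any(lam < 0)) stop("negative turn rate; check model parameters")
  lam
}

#' Excess mean turn speed
#'
#' `mu(t) = mu0 + mu1 N(t) + mu2 OFF(t)`, the mean turn speed in excess of
#' the speed floor; the expected total turn speed is `speed_floor + mu(t)`.
#'
#' @inheritParams turn_rate
#' @return Excess mean turn speed(s) in deg/s.
#' @export
mean_turn_speed <- function(N, OFF, params) {
  mu <- params$mu0 + params$mu1 * N + params$mu2 * OFF
  if (any(mu <= 0)) stop("non-positive excess mean turn speed; check parameters")
  mu
}

#' Upwind-bias probability
#'
#' `B = 1 / (1 + exp(-(a0 + g u) sin^2 theta))`: the probability that an
#' initiated turn rotates the heading toward upwind (180 deg). The `sin^2`
#' factor makes the bias maximal for crosswind headings and exactly 0.5 at
#' 0 or 180 deg.
#'
#' @param u bias-kernel output value(s).
#' @param theta heading(s) in degrees, \[0, 360).
#' @param a0 baseline shift.
#' @param g kernel gain.
#' @return Probability the next turn is upwind.
#' @export
upwind_bias <- function(u, theta, a0, g) {
  s2 <- sin(theta * pi / 180)^2
  1 / (1 + exp(-(a0 + g * u) * s2))
}

#' Sample a single turn event
#'
#' Duration is the floor plus an exponential excess (`tau_dur`), total mean
#' speed is the floor plus a Gamma(shape 2) excess with mean from the speed
#' model, and the direction is Bernoulli with the supplied upwind bias.
#'
#' @param t_start turn start time (s).
#' @param N,OFF kernel values at initiation.
#' @param bias upwind probability at initiation.
#' @param params a [turn_model_params()].
#' @return A one-row data.frame (class `turn_event`): `t_start`, `duration`,
#'   `mean_speed` (total, deg/s), `upwind` (logical), `signed_angle` (deg,
#'   positive upwind).
#' @export
sample_turn <- function(t_start, N, OFF, bias, params) {
  mu <- mean_turn_speed(N, OFF, params)
  n <- max(length(t_start), length(N), length(OFF), length(bias))
  duration <- params$duration_floor + rexp(n, rate = 1 / params$tau_dur)
  speed <- params$speed_floor +
    rgamma(n, shape = params$gamma_shape, scale = mu / params$gamma_shape)
  upwind <- runif(n) < bias
  out <- data.frame(t_start = rep_len(t_start, n), duration = duration,
                    mean_speed = speed, upwind = upwind,
                    signed_angle = ifelse(upwind, 1, -1) * speed * duration)
  class(out) <- c("turn_event", class(out))
  out
}

#' Parabolic angular-speed profile of a turn
#'
#' `|omega|(t) = 6 mu / d^2 (t - t_start)(t_start + d - t)` inside the turn
#' and 0 outside; zero at both endpoints, maximum `1.5 mu` at the midpoint,
#' and time-average exactly `mu` (the event's total mean speed).
#'
#' @param event a one-row turn event (from [sample_turn()]) or a list with
#'   `t_start`, `duration`, `mean_speed`, `upwind`.
#' @param t evaluation time(s) in seconds.
#' @return Signed angular velocity (deg/s; positive = upwind rotation).
#' @export
turn_profile <- function(event, t) {
  d <- event$duration
  mu <- event$mean_speed
  tr <- t - event$t_start
  v <- ifelse(tr >= 0 & tr <= d, 6 * mu / d^2 * tr * (d - tr), 0)
  sgn <- if (isTRUE(event$upwind) || identical(event$upwind, 1L)) 1 else -1
  sgn * v
}

#' Reflect a full-circle heading onto [0, 180]
#'
#' Headings greater than 180 deg are reflected so orientations run from 0
#' (directly downwind) to 180 (directly upwind); a uniform spread of headings
#' has mean reflected orientation 90 deg.
#'
#' @param theta heading(s) in degrees (any real; reduced modulo 360).
#' @return Reflected orientation(s) in \[0, 180\].
#' @export
reflect_orientation <- function(theta) {
  theta <- theta %% 360
  pmin(theta, 360 - theta)
}

# Per-frame lambda / excess-mu / bias-kernel traces for a rendered protocol.
model_traces <- function(signal, params) {
  kp <- params$kernel_params
  N <- cpp_novelty(signal$t, signal$onsets, kp$tau_N, kp$tau_ND)
  islow <- cpp_exp_filter(signal$t, signal$onsets, signal$offsets, kp$tau_slow)
  ifast <- cpp_exp_filter(signal$t, signal$onsets, signal$offsets, kp$tau_fast)
  OFF <- pmax(0, islow - ifast)
  u <- switch(params$bias_kernel,
    R = cpp_two_timescale(signal$t, signal$onsets, signal$offsets, kp$tau_g,
                          kp$tau_d),
    I = cpp_exp_filter(signal$t, signal$onsets, signal$offsets, kp$tau_I),
    F = cpp_onset_filter(signal$t, signal$onsets, kp$tau_F),
    H = kp$g_I * cpp_exp_filter(signal$t, signal$onsets, signal$offsets,
                                kp$tau_H) +
        kp$g_F * cpp_onset_filter(signal$t, signal$onsets, kp$tau_H))
  # for H the sigmoid gain g is fixed to 1 by convention
  g <- if (params$bias_kernel == "H") 1 else params$g
  list(t = signal$t, N = N, OFF = OFF, u = u, g = g,
       lambda = turn_rate(N, OFF, params),
       mu = mean_turn_speed(N, OFF, params))
}

#' Simulate a population of turning agents under a stimulus protocol
#'
#' Agents initiate turns from the non-turning state as an inhomogeneous
#' Poisson process with rate `lambda(t)`; each turn's excess duration is
#' exponential, its excess mean speed Gamma(shape 2) with signal-dependent
#' mean, and its direction Bernoulli with the sigmoidal upwind bias evaluated
#' (together with N and OFF) at the initiation frame and frozen for the
#' turn. During a turn the heading evolves by Euler steps of the signed
#' parabolic angular-speed profile; outside turns the angular velocity is 0.
#' Agents all start in the non-turning state, so the first 0.1 s of the
#' simulated traces is flagged as burn-in.
#'
#' @param protocol a [stimulus_protocol()] (or a pre-rendered
#'   `signal_trace`).
#' @param params a [turn_model_params()].
#' @param n_agents number of agents.
#' @param init_headings initial headings in degrees; default uniform on
#'   \[0, 360).
#' @param seed optional RNG seed (set via [set.seed()]).
#' @param store_traces keep per-frame matrices (`theta`, `omega`,
#'   `turning`); turn events are always returned.
#' @return A list of class `population_sim`: `t`, `events` (data.frame with
#'   per-turn agent, start frame, duration, total mean speed, direction,
#'   heading at start), the per-frame trace matrices (frames x agents) when
#'   requested, the model traces, and `burnin` (logical per-frame flag).
#' @export
simulate_population <- function(protocol, params, n_agents,
                                init_headings = NULL, seed = NULL,
                                store_traces = TRUE) {
  signal <- if (inherits(protocol, "signal_trace")) protocol else
    render_signal(protocol)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_headings)) {
    init_headings <- runif(n_agents, 0, 360)
  } else {
    init_headings <- rep_len(init_headings, n_agents)
  }
  tr <- model_traces(signal, params)
  res <- cpp_simulate_population(
    tr$lambda, tr$mu, tr$u, params$a0, tr$g, signal$dt, n_agents,
    init_headings, params$tau_dur, params$duration_floor, params$speed_floor,
    store_traces, FALSE)
  ev <- res$events
  ev$t_start <- signal$t[ev$start_frame]
  out <- list(t = signal$t, dt = signal$dt, events = ev,
              traces = tr, signal = signal, n_agents = n_agents,
              burnin = signal$t < 0.1)
  if (store_traces) {
    out$theta <- res$theta
    out$omega <- res$omega
    out$turning <- res$turning
  }
  class(out) <- "population_sim"
  out
}

#' @export
print.population_sim <- function(x, ...) {
  cat(sprintf("population_sim: %d agents, %d frames (%.3g s), %d turn events\n",
              x$n_agents, length(x$t), length(x$t) * x$dt, nrow(x$events)))
  invisible(x)
}

# Mean reflected-orientation trace of a simulated population without storing
# per-agent matrices (used by the bias-kernel grid search).
simulate_mean_orientation <- function(signal, params, n_agents,
                                      init_headings, g = NULL, u = NULL,
                                      n_frames = NULL) {
  tr <- model_traces(signal, params)
  if (!is.null(u)) tr$u <- u
  if (!is.null(g)) tr$g <- g
  keep <- if (is.null(n_frames)) length(tr$t) else min(n_frames, length(tr$t))
  idx <- seq_len(keep)
  res <- cpp_simulate_population(
    tr$lambda[idx], tr$mu[idx], tr$u[idx], params$a0, tr$g, signal$dt,
    n_agents, rep_len(init_headings, n_agents), params$tau_dur,
    params$duration_floor, params$speed_floor, FALSE, TRUE)
  res$mean_orientation
}
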
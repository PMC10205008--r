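#' Gaussian-packet plume configuration
#'
#' World description for the agent-based navigation experiments: odor packets
#' released from the source at a Poisson rate, advected downwind at `v_d`,
#' dispersed crosswind by a telegraph velocity (switching between +/- `v_c`
#' at rate `lambda_c`), and spreading as isotropic Gaussians whose variance
#' grows linearly with age while total mass is conserved (peak concentration
#' scales inversely with the squared width). Packet size/amplitude
#' parameters default to values calibrated (see [calibrate_plume_packets()])
#' so the low-frequency plume (release 0.75/s) has a sector-average
#' encounter frequency of about 0.2 Hz at detection threshold 1 a.u.
#'
#' x is the downwind coordinate (the source sits upwind at small x; agents
#' start far downwind and must travel toward 180 deg headings).
#'
#' @param release_rate packet release rate (/s).
#' @param v_d downwind advection speed (mm/s).
#' @param v_c crosswind telegraph speed (mm/s).
#' @param lambda_c telegraph switch rate (/s).
#' @param sigma0 initial packet width sigma (mm).
#' @param growth packet variance growth rate (mm^2/s).
#' @param c0 initial peak concentration (a.u.).
#' @param source source position (mm).
#' @param t_total simulated time (s).
#' @param dt time step (s).
#' @param detection_threshold binary odor detection threshold (a.u.).
#' @param init_x,init_y agent initialisation region (mm).
#' @param success_x,success_y success region (mm).
#' @param warmup extra plume spin-up time before t = 0 (s).
#' @param cull_x,cull_y packet culling bounds (mm).
#' @param peak_floor drop packets once their peak falls below this (a.u.).
#' @return A list of class `plume_config`.
#' @export
plume_config <- function(release_rate = 0.75, v_d = 90, v_c = 30,
                         lambda_c = 2, sigma0 = 5, growth = 50, c0 = 10.9,
                         source = c(10, 0), t_total = 75, dt = 1 / 60,
                         detection_threshold = 1,
                         init_x = c(200, 250), init_y = c(-60, 60),
                         success_x = c(0, 25), success_y = c(-12.5, 12.5),
                         warmup = 10, cull_x = 350, cull_y = 200,
                         peak_floor = 1e-3) {
  stopifnot(release_rate >= 0, v_d > 0, lambda_c > 0, sigma0 > 0,
            growth >= 0, c0 > 0, t_total > 0, dt > 0)
  structure(list(release_rate = release_rate, v_d = v_d, v_c = v_c,
                 lambda_c = lambda_c, sigma0 = sigma0, growth = growth,
                 c0 = c0, source = source, t_total = t_total, dt = dt,
                 detection_threshold = detection_threshold, init_x = init_x,
                 init_y = init_y, success_x = success_x,
                 success_y = success_y, warmup = warmup, cull_x = cull_x,
                 cull_y = cull_y, peak_floor = peak_floor),
            class = "plume_config")
}

#' Bilateral elliptical odor sensor configuration
#'
#' Agents sample odor over an elliptical region (semi-major axis
#' perpendicular to the heading) at a fixed point density, split into left
#' and right halves whose mean concentrations feed the Hassenstein-Reichardt
#' motion correlator.
#'
#' @param semi_major semi-major axis (mm, perpendicular to heading).
#' @param semi_minor semi-minor axis (mm, along heading).
#' @param sample_density grid density (points/mm).
#' @param motion_threshold HRC motion-signal threshold.
#' @param motion_lag correlator delay in steps (fixed 1).
#' @return A list of class `sensor_config`.
#' @export
sensor_config <- function(semi_major = 0.75, semi_minor = 0.25,
                          sample_density = 6.5, motion_threshold = 0.01,
                          motion_lag = 1L) {
  stopifnot(semi_major > 0, semi_minor > 0, sample_density > 0)
  structure(list(semi_major = semi_major, semi_minor = semi_minor,
                 sample_density = sample_density,
                 motion_threshold = motion_threshold,
                 motion_lag = as.integer(motion_lag)),
            class = "sensor_config")
}

#' Sensor sample points in the agent frame
#'
#' @param sensor a [sensor_config()].
#' @return A data.frame with lateral offset `a` (mm, positive to the
#'   agent's left), longitudinal offset `b` (mm, along heading) and `side`
#'   (+1 left, -1 right).
#' @export
sensor_points <- function(sensor = sensor_config()) {
  sp <- 1 / sensor$sample_density
  amax <- sensor$semi_major
  bmax <- sensor$semi_minor
  a <- (seq_len(ceiling(amax / sp)) - 0.5) * sp
  a <- c(-rev(a), a)
  b <- seq(-bmax, bmax, by = sp)
  b <- b - mean(b)
  g <- expand.grid(a = a, b = b)
  g <- g[(g$a / amax)^2 + (g$b / bmax)^2 <= 1, ]
  g$side <- ifelse(g$a > 0, 1L, -1L)
  rownames(g) <- NULL
  g
}

#' Simulate the Gaussian-packet plume
#'
#' @param config a [plume_config()].
#' @param seed RNG seed.
#' @return A list of class `plume_sim` containing the per-step packet table
#'   in compressed (CSR) layout plus the configuration.
#' @export
simulate_plume <- function(config = plume_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$release_rate == 0) {
    n_steps <- as.integer(round(config$t_total / config$dt))
    out <- list(offsets = integer(n_steps + 1), x = numeric(0),
                y = numeric(0), sig2 = numeric(0), peak = numeric(0),
                rcut = numeric(0), n_steps = n_steps, dt = config$dt)
  } else {
    out <- cpp_simulate_plume(config$t_total, config$warmup, config$dt,
                              config$release_rate, config$v_d, config$v_c,
                              config$lambda_c, config$sigma0^2,
                              config$growth, config$c0, config$source[1],
                              config$source[2], config$cull_x, config$cull_y,
                              config$peak_floor)
  }
  out$config <- config
  class(out) <- "plume_sim"
  out
}

#' @export
print.plume_sim <- function(x, ...) {
  cat(sprintf("plume_sim: %d steps, %.3g live packets per step on average\n",
              x$n_steps, length(x$x) / max(1, x$n_steps)))
  invisible(x)
}

#' Packet states at one time step
#'
#' @param plume a `plume_sim`.
#' @param step 1-based step index.
#' @return A data.frame of live packets (`x`, `y`, `sig2`, `peak`).
#' @export
plume_packets_at <- function(plume, step) {
  i0 <- plume$offsets[step] + 1L
  i1 <- plume$offsets[step + 1L]
  if (i1 < i0) {
    return(data.frame(x = numeric(0), y = numeric(0), sig2 = numeric(0),
                      peak = numeric(0)))
  }
  data.frame(x = plume$x[i0:i1], y = plume$y[i0:i1],
             sig2 = plume$sig2[i0:i1], peak = plume$peak[i0:i1])
}

#' Left/right sensor concentrations at a pose
#'
#' Reference implementation of the bilateral odor sampling: averages the
#' Gaussian contributions of all packets over the sample points of each
#' sensor half.
#'
#' @param x,y,theta agent pose (mm, deg).
#' @param packets a data.frame of packets (`x`, `y`, `sig2`, `peak`).
#' @param sensor a [sensor_config()].
#' @return Named vector `c(C_L, C_R)`.
#' @export
sensor_concentrations <- function(x, y, theta, packets,
                                  sensor = sensor_config()) {
  pts <- sensor_points(sensor)
  rad <- theta * pi / 180
  h <- c(cos(rad), sin(rad))
  l <- c(-sin(rad), cos(rad))
  px <- x + pts$b * h[1] + pts$a * l[1]
  py <- y + pts$b * h[2] + pts$a * l[2]
  conc <- numeric(nrow(pts))
  for (j in seq_len(nrow(packets))) {
    d2 <- (px - packets$x[j])^2 + (py - packets$y[j])^2
    conc <- conc + packets$peak[j] * exp(-d2 / (2 * packets$sig2[j]))
  }
  c(C_L = mean(conc[pts$side > 0]), C_R = mean(conc[pts$side < 0]))
}

#' Hassenstein-Reichardt odor-motion correlator
#'
#' `C_L(t - dt) C_R(t) - C_L(t) C_R(t - dt)`: positive values indicate
#' odor motion from the agent's left, negative from the right; swapping the
#' channels flips the sign exactly.
#'
#' @param C_L_prev,C_R_prev previous-step concentrations.
#' @param C_L,C_R current concentrations.
#' @return The correlator value.
#' @export
hrc_motion <- function(C_L_prev, C_R_prev, C_L, C_R) {
  C_L_prev * C_R - C_L * C_R_prev
}

navigate_par_vector <- function(params) {
  kp <- params$kernel_params
  c(params$lambda0, params$lambda1, params$lambda2,
    params$mu0, params$mu1, params$mu2,
    params$tau_dur, params$duration_floor, params$speed_floor,
    params$a0, params$g, kp$tau_g, kp$tau_d,
    kp$tau_N, kp$tau_ND, kp$tau_fast, kp$tau_slow)
}

#' Agent-based plume navigation
#'
#' Simulates agents executing the full turning model inside a packet plume
#' (or odor-free world). Each agent binarizes its own sensor signal at the
#' detection threshold; the binary signal drives its novelty, offset and
#' two-timescale bias kernels. When a turn is initiated while the
#' Hassenstein-Reichardt motion signal exceeds threshold, the rotation sign
#' is chosen toward the vector sum of the upwind and against-motion
#' directions; otherwise direction follows the upwind-bias sigmoid.
#' Ablations replace the novelty response in the turn-rate and/or
#' turn-speed channel by a population-average novelty trace (computed from a
#' full-model pass on the same plume).
#'
#' @param plume a `plume_sim`, or a [plume_config()] (simulated on the
#'   fly), or `NULL` for the odor-free control (then `config` supplies the
#'   world geometry).
#' @param params a [turn_model_params()] (the bias kernel used while
#'   navigating is the two-timescale integrator).
#' @param n_agents number of agents.
#' @param sensor a [sensor_config()].
#' @param speed constant ground speed (mm/s, default 10, the study's mean
#'   walking speed).
#' @param motion enable odor-motion sensing.
#' @param ablation one of "none", "rate", "speed", "both".
#' @param nbar population-average novelty trace for the ablation; computed
#'   from a first full-model pass when missing.
#' @param seed RNG seed.
#' @param config world geometry when `plume` is NULL.
#' @param collect_nbar also return this run's population-average novelty
#'   trace.
#' @return A list of class `nav_result`: `success` (0/1 per agent), final
#'   positions, per-agent odor-onset counts, `nbar` when collected, and the
#'   configuration used.
#' @export
navigate <- function(plume = NULL, params = turn_model_params(),
                     n_agents = 1000, sensor = sensor_config(), speed = 10,
                     motion = TRUE,
                     ablation = c("none", "rate", "speed", "both"),
                     nbar = NULL, seed = NULL, config = NULL,
                     collect_nbar = FALSE) {
  ablation <- match.arg(ablation)
  if (inherits(plume, "plume_config")) {
    plume <- simulate_plume(plume, seed = seed)
    seed <- NULL
  }
  cfg <- if (!is.null(plume)) plume$config else
    if (!is.null(config)) config else plume_config(release_rate = 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(cfg$t_total / cfg$dt))
  x0 <- runif(n_agents, cfg$init_x[1], cfg$init_x[2])
  y0 <- runif(n_agents, cfg$init_y[1], cfg$init_y[2])
  th0 <- runif(n_agents, 90, 270)
  pts <- sensor_points(sensor)
  plume_list <- if (is.null(plume)) list() else
    plume[c("offsets", "x", "y", "sig2", "peak", "rcut")]
  ablate_rate <- ablation %in% c("rate", "both")
  ablate_speed <- ablation %in% c("speed", "both")
  if ((ablate_rate || ablate_speed) && is.null(nbar)) {
    first <- cpp_navigate(plume_list, n_steps, cfg$dt, x0, y0, th0, speed,
                          navigate_par_vector(params),
                          cfg$detection_threshold, sensor$motion_threshold,
                          motion, FALSE, FALSE, numeric(0), pts$a, pts$b,
                          as.integer(pts$side),
                          c(cfg$success_x, cfg$success_y), TRUE)
    nbar <- first$nbar
  }
  res <- cpp_navigate(plume_list, n_steps, cfg$dt, x0, y0, th0, speed,
                      navigate_par_vector(params), cfg$detection_threshold,
                      sensor$motion_threshold, motion, ablate_rate,
                      ablate_speed,
                      if (is.null(nbar)) numeric(0) else nbar,
                      pts$a, pts$b, as.integer(pts$side),
                      c(cfg$success_x, cfg$success_y), collect_nbar)
  structure(list(success = res$success, x = res$x, y = res$y,
                 n_onsets = res$n_onsets,
                 nbar = if (collect_nbar) res$nbar else nbar,
                 n_agents = n_agents, motion = motion, ablation = ablation,
                 config = cfg),
            class = "nav_result")
}

#' @export
print.nav_result <- function(x, ...) {
  cat(sprintf(
    "nav_result: %d agents, success %.3g%% (motion %s, ablation %s)\n",
    x$n_agents, 100 * mean(x$success), if (x$motion) "on" else "off",
    x$ablation))
  invisible(x)
}

#' Navigation success rate with bootstrap error
#'
#' @param result a `nav_result` (or 0/1 vector).
#' @param n_boot bootstrap resamples (default 1000).
#' @return Named vector: `fraction`, `stderr` (bootstrap SD of the mean).
#' @export
success_rate <- function(result, n_boot = 1000) {
  s <- if (inherits(result, "nav_result")) result$success else result
  n <- length(s)
  means <- vapply(seq_len(n_boot), function(b) {
    mean(s[sample.int(n, n, replace = TRUE)])
  }, 0)
  c(fraction = mean(s), stderr = sd(means))
}

#' Ratio of success rates between two conditions
#'
#' Two independent sets of bootstrap resamples (one per condition) yield the
#' distribution of the success-rate ratio; its SD is the reported error.
#'
#' @param num,den `nav_result`s or 0/1 vectors (ratio = num / den).
#' @param n_boot bootstrap resamples per condition.
#' @return Named vector: `ratio`, `stderr`.
#' @export
success_ratio <- function(num, den, n_boot = 1000) {
  a <- if (inherits(num, "nav_result")) num$success else num
  b <- if (inherits(den, "nav_result")) den$success else den
  ra <- vapply(seq_len(n_boot), function(i) {
    mean(a[sample.int(length(a), length(a), replace = TRUE)])
  }, 0)
  rb <- vapply(seq_len(n_boot), function(i) {
    mean(b[sample.int(length(b), length(b), replace = TRUE)])
  }, 0)
  r <- ra / rb
  c(ratio = mean(a) / mean(b), stderr = sd(r[is.finite(r)]))
}

#' Two-proportion Z-test between navigation conditions
#'
#' @param a,b `nav_result`s or 0/1 vectors.
#' @return Named vector: `z`, `p_value` (two-sided).
#' @export
success_z_test <- function(a, b) {
  sa <- if (inherits(a, "nav_result")) a$success else a
  sb <- if (inherits(b, "nav_result")) b$success else b
  p1 <- mean(sa); p2 <- mean(sb)
  n1 <- length(sa); n2 <- length(sb)
  p <- (sum(sa) + sum(sb)) / (n1 + n2)
  z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  c(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Sector-averaged odor encounter frequency of a plume
#'
#' Mean rate of upward threshold crossings of the concentration at probe
#' points uniformly distributed over the circular sector with apex at the
#' source, half-angle `atan(v_c / v_d)` and the given radius.
#'
#' @param plume a `plume_sim` (or a [plume_config()], simulated on the
#'   fly with `seed`).
#' @param n_probe number of probe points (default 10000).
#' @param radius sector radius (mm, default 250).
#' @param seed RNG seed (probe placement and, if needed, the plume).
#' @return Named vector: `frequency_hz` (sector average), `n_probe`.
#' @export
plume_encounter_frequency <- function(plume, n_probe = 10000, radius = 250,
                                      seed = NULL) {
  if (inherits(plume, "plume_config")) plume <- simulate_plume(plume, seed)
  else if (!is.null(seed)) set.seed(seed)
  cfg <- plume$config
  half <- atan(cfg$v_c / cfg$v_d)
  r <- radius * sqrt(runif(n_probe))
  ang <- runif(n_probe, -half, half)
  px <- cfg$source[1] + r * cos(ang)
  py <- cfg$source[2] + r * sin(ang)
  crossings <- cpp_probe_crossings(
    plume[c("offsets", "x", "y", "sig2", "peak", "rcut", "n_steps")],
    px, py, cfg$detection_threshold, 0L)
  c(frequency_hz = mean(crossings) / cfg$t_total, n_probe = n_probe)
}

#' Calibrate packet amplitude to a target encounter frequency
#'
#' Tunes the packet peak-concentration scale `c0` (log-scale bisection) so
#' the plume's sector-average encounter frequency at the detection threshold
#' matches a target.
#'
#' @param config starting [plume_config()].
#' @param target target sector-average encounter frequency (Hz).
#' @param n_probe probes per evaluation.
#' @param seed RNG seed.
#' @param c0_range search range for `c0`.
#' @param n_iter bisection iterations.
#' @return The calibrated `plume_config`.
#' @export
calibrate_plume_packets <- function(config = plume_config(), target = 0.2,
                                    n_probe = 2000, seed = 1,
                                    c0_range = c(1.5, 200), n_iter = 12) {
  f_of <- function(c0) {
    cfg <- config
    cfg$c0 <- c0
    unname(plume_encounter_frequency(cfg, n_probe = n_probe,
                                     seed = seed)["frequency_hz"])
  }
  lo <- log(c0_range[1]); hi <- log(c0_range[2])
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (f_of(exp(mid)) < target) lo <- mid else hi <- mid
  }
  config$c0 <- exp((lo + hi) / 2)
  config
}
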
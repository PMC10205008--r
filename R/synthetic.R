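#' Measurement/gait noise configuration for synthetic trajectories
#'
#' White Gaussian angular-speed noise (emulating walking-gait and tracking
#' fluctuations) followed by the tracking pipeline's Savitzky-Golay
#' smoothing, plus a two-state telegraph walking-speed process.
#'
#' In addition to the stationary gait noise, brief tracking-artefact spikes
#' are injected: short (2-4 frame) sharp reorientations whose net angular
#' change magnitude is Gaussian with the configured mean and SD. These
#' emulate the fast tracking glitches that motivate the minimum-turn-duration
#' rule; their default magnitude scale (SD 4.5 deg) matches the artefact
#' component measured in the study's event diagnostics.
#'
#' @param gait_sd angular-speed noise SD before smoothing (deg/s).
#' @param smooth_window Savitzky-Golay window (frames, odd; 21 = 0.35 s at
#'   60 Hz); 0 disables smoothing.
#' @param smooth_order polynomial order (default 4).
#' @param artefact_rate tracking-artefact rate (/s; 0 disables).
#' @param artefact_mean,artefact_sd net |angular change| magnitude of an
#'   artefact (deg).
#' @param stop_rate walk-to-stop transition rate (/s).
#' @param walk_rate stop-to-walk transition rate (/s).
#' @param stopped_speed,walking_speed speed levels (mm/s).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(gait_sd = 10, smooth_window = 21, smooth_order = 4,
                         artefact_rate = 0.5, artefact_mean = 6,
                         artefact_sd = 4.5, stop_rate = 0.2, walk_rate = 1.0,
                         stopped_speed = 0.5, walking_speed = 10) {
  stopifnot(gait_sd >= 0, stop_rate >= 0, walk_rate >= 0, artefact_rate >= 0)
  if (smooth_window > 0) {
    if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
    if (smooth_window <= smooth_order) {
      stop("smooth_window must exceed smooth_order")
    }
  }
  structure(list(gait_sd = gait_sd, smooth_window = smooth_window,
                 smooth_order = smooth_order, artefact_rate = artefact_rate,
                 artefact_mean = artefact_mean, artefact_sd = artefact_sd,
                 stop_rate = stop_rate, walk_rate = walk_rate,
                 stopped_speed = stopped_speed,
                 walking_speed = walking_speed),
            class = "noise_config")
}

#' Inject measurement noise into simulated angular-velocity traces
#'
#' Adds per-frame white Gaussian noise to the angular velocity, applies the
#' configured Savitzky-Golay filter, and re-integrates the heading from the
#' smoothed angular velocity so the trajectory stays internally consistent.
#'
#' @param sim a `population_sim` (with stored traces) or a list with
#'   matrices `omega`, `theta` and scalar `dt`.
#' @param noise a [noise_config()].
#' @return The input with `omega` and `theta` replaced by their noisy,
#'   smoothed versions.
#' @export
add_measurement_noise <- function(sim, noise = noise_config()) {
  if (is.null(sim$omega)) stop("simulation has no stored traces")
  om <- sim$omega
  if (noise$gait_sd > 0) {
    om <- om + matrix(rnorm(length(om), 0, noise$gait_sd), nrow(om))
  }
  if (noise$smooth_window > 0) {
    for (a in seq_len(ncol(om))) {
      om[, a] <- signal::sgolayfilt(om[, a], p = noise$smooth_order,
                                    n = noise$smooth_window)
    }
  }
  # tracking-artefact spikes survive the tracking pipeline's smoothing, so
  # they are injected on the smoothed traces
  if (noise$artefact_rate > 0) {
    n <- nrow(om)
    dt <- sim$dt
    for (a in seq_len(ncol(om))) {
      n_art <- stats::rpois(1, noise$artefact_rate * n * dt)
      if (n_art == 0) next
      starts <- sample.int(n - 4L, n_art)
      for (s in starts) {
        nfr <- sample(2:4, 1)
        mag <- abs(rnorm(1, noise$artefact_mean, noise$artefact_sd))
        sgn <- sample(c(-1, 1), 1)
        om[s:(s + nfr - 1L), a] <- om[s:(s + nfr - 1L), a] +
          sgn * mag / (nfr * dt)
      }
    }
  }
  th <- sim$theta
  th0 <- th[1, ]
  dt <- sim$dt
  th <- apply(om, 2, function(w) cumsum(c(0, w[-length(w)])) * dt)
  th <- sweep(th, 2, th0, "+") %% 360
  sim$omega <- om
  sim$theta <- th
  sim
}

#' Telegraph walking-speed traces
#'
#' Two-state stop/walk process: exponential holding times with the
#' configured transition rates, emitting the stopped or walking speed level.
#'
#' @param n_frames,dt trace geometry.
#' @param n_agents number of independent traces.
#' @param noise a [noise_config()].
#' @return A numeric matrix (frames x agents) of speeds (mm/s).
#' @export
simulate_walking_speed <- function(n_frames, dt, n_agents,
                                   noise = noise_config()) {
  out <- matrix(noise$walking_speed, n_frames, n_agents)
  p_walk <- noise$walk_rate / max(noise$walk_rate + noise$stop_rate, 1e-12)
  for (a in seq_len(n_agents)) {
    walking <- runif(1) < p_walk
    i <- 1L
    while (i <= n_frames) {
      rate <- if (walking) noise$stop_rate else noise$walk_rate
      len <- if (rate > 0) max(1L, round(rexp(1, rate) / dt)) else
        n_frames
      j <- min(n_frames, i + len - 1L)
      out[i:j, a] <- if (walking) noise$walking_speed else
        noise$stopped_speed
      walking <- !walking
      i <- j + 1L
    }
  }
  out
}

#' Generate a synthetic tracked-trajectory dataset
#'
#' Wraps [simulate_population()] and [add_measurement_noise()] to emulate the
#' study's tracked trajectories: per environment, model-generated turns at
#' 60 Hz riding on gait/measurement angular-speed noise, a telegraph
#' walking-speed channel, and ground-truth turn-event tables written
#' alongside as the oracle for segmentation tests.
#'
#' @param envs data.frame with `frequency` and `duration` columns (see
#'   [environment_grid()]), or a list of [stimulus_protocol()] objects.
#' @param params a [turn_model_params()].
#' @param n_agents agents per environment.
#' @param noise a [noise_config()]; set `gait_sd = 0` and
#'   `smooth_window = 0` for noise-free output.
#' @param seed RNG seed.
#' @param out_dir output directory; created if missing. `NULL` keeps
#'   everything in memory.
#' @param n_repeats ON/OFF block pairs per session (default 4).
#' @return Invisibly, a list with one element per environment: the
#'   trajectory data.frame, the ground-truth events, the protocol, and the
#'   file paths when written.
#' @export
generate_dataset <- function(envs, params = turn_model_params(),
                             n_agents = 240, noise = noise_config(),
                             seed = 1, out_dir = NULL, n_repeats = 4L) {
  protocols <- if (is.data.frame(envs)) {
    lapply(seq_len(nrow(envs)), function(i) {
      stimulus_protocol(envs$frequency[i], envs$duration[i],
                        n_repeats = n_repeats)
    })
  } else {
    envs
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  set.seed(seed)
  out <- vector("list", length(protocols))
  for (i in seq_along(protocols)) {
    p <- protocols[[i]]
    sim <- simulate_population(p, params, n_agents)
    truth <- sim$events
    noisy <- add_measurement_noise(sim, noise)
    speed <- simulate_walking_speed(length(sim$t), sim$dt, n_agents, noise)
    traj <- as_trajectory_df(noisy, speed = speed)
    tag <- sprintf("f%g_d%g", p$frequency, p$pulse_duration)
    paths <- NULL
    if (!is.null(out_dir)) {
      tf <- file.path(out_dir, paste0("trajectories_", tag, ".tsv"))
      gf <- file.path(out_dir, paste0("ground_truth_", tag, ".tsv"))
      write_trajectories(traj, tf)
      write_events(truth, gf)
      write_protocol(p, file.path(out_dir, paste0("protocol_", tag, ".cfg")))
      paths <- c(trajectories = tf, ground_truth = gf)
    }
    out[[i]] <- list(trajectories = traj, ground_truth = truth,
                     protocol = p, paths = paths)
    names(out)[i] <- tag
  }
  if (!is.null(out_dir)) {
    manifest <- c(sprintf("seed=%d", seed),
                  sprintf("n_agents=%d", n_agents),
                  sprintf("n_environments=%d", length(protocols)),
                  sprintf("gait_sd=%g", noise$gait_sd),
                  sprintf("generated=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    writeLines(manifest, file.path(out_dir, "manifest.cfg"))
  }
  invisible(out)
}
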
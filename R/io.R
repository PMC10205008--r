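#' Convert a population simulation to the standard trajectory table
#'
#' One row per (agent, frame): `agent_id`, `frame`, `t_s`, `theta_deg`,
#' `omega_deg_s`, `turning_flag`, `speed_mm_s`. Angles are stored
#' unreflected; reflection is applied at analysis time only.
#'
#' @param sim a `population_sim` with stored traces.
#' @param speed optional speed matrix (frames x agents); NA when absent.
#' @return A trajectory data.frame.
#' @export
as_trajectory_df <- function(sim, speed = NULL) {
  if (is.null(sim$omega)) stop("simulation has no stored traces")
  n <- length(sim$t)
  na <- ncol(sim$omega)
  data.frame(
    agent_id = rep(seq_len(na), each = n),
    frame = rep(seq_len(n), na),
    t_s = rep(sim$t, na),
    theta_deg = as.numeric(sim$theta),
    omega_deg_s = as.numeric(sim$omega),
    turning_flag = as.integer(sim$turning),
    speed_mm_s = if (is.null(speed)) NA_real_ else as.numeric(speed))
}

#' Write / read trajectory tables
#'
#' Tab-delimited text with a header; times in seconds, angles in degrees,
#' speeds in mm/s. `read_trajectories` validates the grid (uniform sampling
#' per agent, headings in \[0, 360)) and reports malformed rows with line
#' numbers.
#'
#' @param traj a trajectory data.frame (see [as_trajectory_df()]).
#' @param path file path.
#' @return `read_trajectories` returns the validated data.frame;
#'   `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  write.table(traj, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  x <- read.delim(path, check.names = FALSE)
  required <- c("agent_id", "frame", "t_s", "theta_deg", "omega_deg_s")
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- intersect(c("t_s", "theta_deg", "omega_deg_s", "speed_mm_s"),
                        names(x))
  for (cc in num_cols) {
    bad <- !is.na(x[[cc]]) & !is.finite(suppressWarnings(as.numeric(x[[cc]])))
    if (any(bad)) {
      stop("malformed value in column ", cc, " at line ",
           which(bad)[1] + 1L)
    }
  }
  bad_theta <- x$theta_deg < 0 | x$theta_deg >= 360
  if (any(bad_theta, na.rm = TRUE)) {
    stop("theta_deg out of [0, 360) at line ", which(bad_theta)[1] + 1L)
  }
  for (id in unique(x$agent_id)) {
    ts <- x$t_s[x$agent_id == id]
    if (length(ts) > 1) {
      d <- diff(ts)
      if (any(abs(d - d[1]) > 1e-6)) {
        stop("non-uniform sampling for agent ", id)
      }
    }
  }
  if (!"speed_mm_s" %in% names(x)) x$speed_mm_s <- NA_real_
  x
}

#' Write / read turn-event tables
#'
#' @param events a data.frame of turn events (ground truth or detected).
#' @param path file path.
#' @return `read_events` returns the data.frame; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' End-to-end parameter-recovery pipeline
#'
#' Chains the pipeline stages from one configuration: generate a synthetic
#' dataset, segment every environment, and refit the turn-rate, turn-speed,
#' turn-duration and baseline-bias models. Stages run in dependency order
#' and any stage failure halts downstream stages while keeping upstream
#' artifacts.
#'
#' @param envs environment grid (data.frame with `frequency`, `duration`).
#' @param params generating [turn_model_params()].
#' @param n_agents agents per environment.
#' @param noise a [noise_config()]; the default recovery chain runs
#'   noise-free.
#' @param seed RNG seed.
#' @param out_dir optional directory for the intermediate files.
#' @param n_repeats ON/OFF block pairs per session.
#' @param rate_n_starts random restarts for the turn-rate likelihood fit.
#' @return A list with the fitted `rate`, `speed`, `duration` and
#'   `baseline_bias` `flynav_fit` objects plus the segmentations.
#' @export
run_recovery_pipeline <- function(envs, params = turn_model_params(),
                                  n_agents = 60,
                                  noise = noise_config(gait_sd = 0,
                                                       smooth_window = 0),
                                  seed = 1, out_dir = NULL, n_repeats = 4L,
                                  rate_n_starts = 2) {
  ds <- generate_dataset(envs, params, n_agents, noise, seed = seed,
                         out_dir = out_dir, n_repeats = n_repeats)
  segs <- list()
  signals <- list()
  for (i in seq_along(ds)) {
    traj <- if (!is.null(ds[[i]]$paths)) {
      read_trajectories(ds[[i]]$paths[["trajectories"]])
    } else {
      ds[[i]]$trajectories
    }
    segs[[i]] <- detect_turns(traj)
    signals[[i]] <- render_signal(ds[[i]]$protocol)
  }
  rate_fit <- fit_turn_rate(segs, signals, n_starts = rate_n_starts)
  sp <- collect_turn_covariates(segs, signals, rate_fit$params)
  speed_fit <- fit_turn_speed(sp$mean_speed, sp$N, sp$OFF,
                              speed_floor = params$speed_floor)
  dur_fit <- fit_turn_duration(sp$duration,
                               duration_floor = params$duration_floor)
  base <- sp[sp$no_signal, , drop = FALSE]
  bias_fit <- fit_baseline_bias(base$theta_start, base$upwind)
  list(rate = rate_fit, speed = speed_fit, duration = dur_fit,
       baseline_bias = bias_fit, segmentations = segs, dataset = ds)
}

#' Kernel covariates at detected turn starts
#'
#' Evaluates N(t) and OFF(t) (at the supplied timescales) at every detected
#' turn start, pooling environments; also flags turns falling in the
#' signal-free tail of each OFF block (last 10 s of the repeat), used for
#' the baseline-bias fit.
#'
#' @param segs list of [detect_turns()] results.
#' @param signals list of matching `signal_trace` objects.
#' @param rate_params named vector with `tau_N`, `tau_ND`, `tau_fast`,
#'   `tau_slow` (e.g. from [fit_turn_rate()]).
#' @param block_len,tail_len repeat length and signal-free tail (s).
#' @return A data.frame with per-turn `mean_speed`, `duration`,
#'   `theta_start`, `upwind`, `N`, `OFF`, `no_signal`, `env`.
#' @export
collect_turn_covariates <- function(segs, signals, rate_params,
                                    block_len = 30, tail_len = 10) {
  out <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- signals[[i]]
    ev <- segs[[i]]$events
    N <- cpp_novelty(s$t, s$onsets, rate_params[["tau_N"]],
                     rate_params[["tau_ND"]])
    OFF <- pmax(0, cpp_exp_filter(s$t, s$onsets, s$offsets,
                                  rate_params[["tau_slow"]]) -
                   cpp_exp_filter(s$t, s$onsets, s$offsets,
                                  rate_params[["tau_fast"]]))
    tmod <- s$t[ev$start_frame] %% block_len
    out[[i]] <- data.frame(
      mean_speed = ev$mean_speed, duration = ev$duration,
      theta_start = if (is.null(ev$theta_start)) NA_real_ else
        ev$theta_start,
      upwind = ev$upwind, N = N[ev$start_frame], OFF = OFF[ev$start_frame],
      no_signal = tmod >= block_len - tail_len, env = i)
  }
  do.call(rbind, out)
}
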
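#' Segmentation configuration
#'
#' Thresholds for turn/fixation event detection and the sliding-window
#' estimators: the minimum angular speed for a turn (25 deg/s), the minimum
#' turn duration (0.18 s), the maximum fixation duration used when building
#' the turn-rate likelihood (1.5 s), and the rectangular smoothing window
#' (0.25 s).
#'
#' @param speed_threshold minimum turn angular speed (deg/s).
#' @param min_duration minimum turn duration (s).
#' @param max_fixation likelihood-side fixation cutoff (s).
#' @param window smoothing window width (s).
#' @param dt sample interval (s).
#' @param extend extend supra-threshold cores to the enclosing angular-speed
#'   valleys (recommended; keeps the sub-threshold shoulders of smooth turn
#'   profiles with the event).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(speed_threshold = 25, min_duration = 0.18,
                                max_fixation = 1.5, window = 0.25,
                                dt = 1 / 60, extend = TRUE) {
  stopifnot(speed_threshold > 0, min_duration > 0, max_fixation > 0,
            window > 0, dt > 0)
  structure(list(speed_threshold = speed_threshold,
                 min_duration = min_duration, max_fixation = max_fixation,
                 window = window, dt = dt, extend = isTRUE(extend)),
            class = "segmentation_config")
}

# Coerce input (population_sim or long trajectory data.frame) to per-agent
# omega/theta matrices on a uniform grid.
as_omega_matrices <- function(x, dt = NULL) {
  if (inherits(x, "population_sim")) {
    if (is.null(x$omega)) stop("simulation was run with store_traces = FALSE")
    return(list(omega = x$omega, theta = x$theta, dt = x$dt,
                speed = NULL, agents = seq_len(x$n_agents)))
  }
  if (is.data.frame(x)) {
    ids <- unique(x$agent_id)
    n_by <- table(factor(x$agent_id, levels = ids))
    if (length(unique(n_by)) != 1) {
      stop("trajectories differ in length; segment them separately")
    }
    n <- as.integer(n_by[1])
    x <- x[order(match(x$agent_id, ids), x$frame), ]
    for (id in ids) {
      ts <- x$t_s[x$agent_id == id]
      if (length(ts) > 1) {
        d <- diff(ts)
        if (any(abs(d - d[1]) > 1e-6)) {
          stop("non-uniform sampling for agent ", id)
        }
      }
    }
    dtx <- diff(x$t_s[x$agent_id == ids[1]])[1]
    om <- matrix(x$omega_deg_s, nrow = n)
    th <- matrix(x$theta_deg, nrow = n)
    sp <- if ("speed_mm_s" %in% names(x) && !all(is.na(x$speed_mm_s))) {
      matrix(x$speed_mm_s, nrow = n)
    }
    return(list(omega = om, theta = th, dt = dtx, speed = sp, agents = ids))
  }
  stop("expected a population_sim or a trajectory data.frame")
}

#' Detect turn and fixation events in angular-speed traces
#'
#' Maximal supra-threshold runs of angular speed form event cores; by default
#' each core is extended outward to the enclosing angular-speed valley so the
#' smooth sub-threshold shoulders of a turn belong to it. Events shorter than
#' the minimum duration are absorbed into the surrounding fixation time, so
#' turns and fixations exactly partition each trace. A turn's direction is
#' upwind when the reflected orientation increases net over the event.
#'
#' @param x a `population_sim` or a trajectory data.frame (columns
#'   `agent_id`, `frame`, `t_s`, `theta_deg`, `omega_deg_s`, ...).
#' @param config a [segmentation_config()].
#' @return A list of class `segmentation` with `events` (agent, start/end
#'   frame, t_start, duration, mean_speed, upwind), `fixations` (agent,
#'   start/end frame, duration, censored flag), `n_frames`, `dt`,
#'   `agent_ids`.
#' @export
detect_turns <- function(x, config = segmentation_config()) {
  m <- as_omega_matrices(x)
  if (abs(m$dt - config$dt) > 1e-9) config$dt <- m$dt
  ev <- cpp_detect_turns(m$omega,
                         if (is.null(m$theta)) matrix(0, 0, 0) else m$theta,
                         m$dt, config$speed_threshold, config$min_duration,
                         config$extend)
  n <- nrow(m$omega)
  fx <- fixations_from_events(ev, n, ncol(m$omega), m$dt)
  ev$t_start <- (ev$start_frame - 1) * m$dt
  structure(list(events = ev, fixations = fx, n_frames = n, dt = m$dt,
                 n_agents = ncol(m$omega), agent_ids = m$agents,
                 config = config),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d agents, %d turns, %d fixations\n",
              x$n_agents, nrow(x$events), nrow(x$fixations)))
  invisible(x)
}

# Complement of the turn events: per-agent fixation intervals (inclusive
# frame ranges). A fixation is censored when it touches the trace boundary.
fixations_from_events <- function(ev, n_frames, n_agents, dt) {
  agent <- integer(0); s <- integer(0); e <- integer(0); cens <- logical(0)
  evl <- split(ev[, c("start_frame", "end_frame")], ev$agent)
  for (a in seq_len(n_agents)) {
    key <- as.character(a)
    if (!is.null(evl[[key]]) && nrow(evl[[key]])) {
      b <- evl[[key]]
      fs <- c(1L, b$end_frame + 1L)
      fe <- c(b$start_frame - 1L, n_frames)
    } else {
      fs <- 1L
      fe <- n_frames
    }
    keep <- fe >= fs
    fs <- fs[keep]; fe <- fe[keep]
    agent <- c(agent, rep.int(a, length(fs)))
    s <- c(s, fs)
    e <- c(e, fe)
    cens <- c(cens, fe == n_frames)
  }
  data.frame(agent = agent, start_frame = s, end_frame = e,
             duration = (e - s + 1) * dt, censored = cens)
}

#' Calibrate the turn threshold and minimum duration from data
#'
#' Reproduces the threshold-selection diagnostics: for each candidate angular
#' speed threshold, events are split into supra-threshold "turns" and
#' sub-threshold "fixations" (no duration rule, no extension) and the 95th
#' percentile of the fixation net-angular-change magnitude is recorded; the
#' suggested threshold sits at the inflection (maximum discrete curvature) of
#' that curve. A two-component Gaussian mixture is then fit to the
#' supra-threshold event |change| distribution at the suggested threshold;
#' the standard deviation of the low-mean component divided by the threshold
#' gives the suggested minimum turn duration.
#'
#' @param x a `population_sim` or trajectory data.frame.
#' @param candidate_thresholds candidate thresholds (deg/s) spanning roughly
#'   5-150.
#' @return A list of class `threshold_calibration`: `curve` (threshold,
#'   dtheta95), `threshold`, `mixture` (means, sds, proportions) or NULL,
#'   `low_sd`, `min_duration`, `fallback` flag, and the implied
#'   [segmentation_config()].
#' @export
calibrate_thresholds <- function(x, candidate_thresholds =
                                   exp(seq(log(5), log(150), length.out = 17))) {
  if (length(candidate_thresholds) < 2) stop("need >= 2 candidate thresholds")
  m <- as_omega_matrices(x)
  thr <- sort(candidate_thresholds)
  d95 <- vapply(thr, function(th) {
    dth <- run_dtheta(m$omega, m$dt, th, above = FALSE)
    if (!length(dth)) return(NA_real_)
    unname(quantile(abs(dth), 0.95))
  }, 0)
  # elbow: the curve grows slowest while the threshold sweeps the gap
  # between measurement fluctuations and genuine turns, then accelerates
  # once real turns are absorbed into fixations; suggest the upper end of
  # the slowest-growth segment on log-log axes
  slope <- diff(log(pmax(d95, 1e-12))) / diff(log(thr))
  slope[!is.finite(slope)] <- Inf
  sel <- which.min(slope) + 1L
  threshold <- thr[sel]

  turn_dth <- run_dtheta(m$omega, m$dt, threshold, above = TRUE)
  turn_dth <- if (is.null(turn_dth)) numeric(0) else abs(turn_dth)
  mix <- NULL
  fallback <- FALSE
  low_sd <- NA_real_
  if (length(turn_dth) >= 50) {
    mix <- try(gaussmix2(turn_dth), silent = TRUE)
    if (inherits(mix, "try-error") || !is.finite(mix$sd[1]) ||
        abs(mix$mean[1] - mix$mean[2]) <
          0.5 * (mix$sd[1] + mix$sd[2])) {
      mix <- NULL
      fallback <- TRUE
    } else {
      low <- which.min(mix$mean)
      low_sd <- mix$sd[low]
    }
  } else {
    fallback <- TRUE
  }
  min_duration <- if (fallback) 0.18 else low_sd / threshold
  structure(list(curve = data.frame(threshold = thr, dtheta95 = d95),
                 threshold = threshold, mixture = mix, low_sd = low_sd,
                 min_duration = min_duration, fallback = fallback,
                 config = segmentation_config(speed_threshold = threshold,
                                              min_duration = min_duration,
                                              dt = m$dt)),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("threshold_calibration: threshold %.3g deg/s, min duration %.3g s%s\n",
              x$threshold, x$min_duration,
              if (x$fallback) " (mixture fallback -> defaults)" else ""))
  invisible(x)
}

# |net angular change| over supra- (above = TRUE) or sub-threshold runs.
run_dtheta <- function(omega, dt, threshold, above) {
  out <- vector("list", ncol(omega))
  for (a in seq_len(ncol(omega))) {
    w <- omega[, a]
    ab <- abs(w) >= threshold
    r <- rle(if (above) ab else !ab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    cs <- cumsum(w) * dt
    out[[a]] <- cs[ends[keep]] - cs[starts[keep]] + w[starts[keep]] * dt
  }
  unlist(out)
}

# Two-component univariate Gaussian mixture (unequal variances).
gaussmix2 <- function(x) {
  x <- x[is.finite(x)]
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu <- as.numeric(fit$parameters$mean)
  sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  pr <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  list(mean = mu[ord], sd = sdv[ord], prop = pr[ord], loglik = fit$loglik)
}

rect_smooth <- function(x, width_frames) {
  k <- max(1L, as.integer(round(width_frames)))
  if (k %% 2 == 0) k <- k + 1L
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Sliding-window turn-rate estimate
#'
#' Per frame, the fraction of considered trajectories (in fixation or just
#' transitioned into a turn) that transitioned, divided by dt, smoothed with
#' a rectangular window; bootstrap (resampling trajectories) standard errors.
#' Frames where no trajectory is considered are flagged NA rather than zero.
#'
#' @param seg a [detect_turns()] result.
#' @param config a [segmentation_config()] (window width, dt).
#' @param n_boot bootstrap resamples (default 500).
#' @return A data.frame (class `windowed_estimate`): `t`, `value` (events/s),
#'   `stderr`, `n` (considered trajectories per frame).
#' @export
windowed_turn_rate <- function(seg, config = seg$config, n_boot = 500) {
  n <- seg$n_frames
  na <- seg$n_agents
  dt <- seg$dt
  turning <- matrix(FALSE, n, na)
  start_m <- matrix(FALSE, n, na)
  ev <- seg$events
  for (i in seq_len(nrow(ev))) {
    turning[ev$start_frame[i]:ev$end_frame[i], ev$agent[i]] <- TRUE
    start_m[ev$start_frame[i], ev$agent[i]] <- TRUE
  }
  considered <- (!turning) | start_m
  num <- start_m * 1
  den <- considered * 1
  wf <- config$window / dt
  est_fun <- function(w) {
    nm <- as.numeric(num %*% w)
    dn <- as.numeric(den %*% w)
    v <- ifelse(dn > 0, nm / dn / dt, NA_real_)
    rect_smooth(v, wf)
  }
  w1 <- rep(1, na)
  value <- est_fun(w1)
  boots <- matrix(NA_real_, n, n_boot)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(na, na, replace = TRUE), nbins = na)
    boots[, b] <- est_fun(w)
  }
  out <- data.frame(t = (seq_len(n) - 1) * dt, value = value,
                    stderr = apply(boots, 1, sd, na.rm = TRUE),
                    n = as.numeric(den %*% w1))
  class(out) <- c("windowed_estimate", class(out))
  out
}

#' Sliding-window statistics of turns starting in each window
#'
#' Mean of a per-turn statistic (total mean speed, duration, or the upwind
#' fraction) over all turns starting within the 0.25 s window centred on
#' each frame, with bootstrap (resampling turns) standard errors. Empty
#' windows are flagged NA.
#'
#' @param seg a [detect_turns()] result.
#' @param stat one of "mean_speed", "duration", "upwind_fraction".
#' @param config a [segmentation_config()].
#' @param n_boot bootstrap resamples (default 1000).
#' @return A data.frame (class `windowed_estimate`): `t`, `value`, `stderr`,
#'   `n` (turns per window).
#' @export
windowed_turn_stat <- function(seg, stat = c("mean_speed", "duration",
                                             "upwind_fraction"),
                               config = seg$config, n_boot = 1000) {
  stat <- match.arg(stat)
  ev <- seg$events
  val <- switch(stat, mean_speed = ev$mean_speed, duration = ev$duration,
                upwind_fraction = as.numeric(ev$upwind))
  n <- seg$n_frames
  dt <- seg$dt
  k <- as.integer(round(config$window / dt))
  if (k %% 2 == 0) k <- k + 1L
  win <- rep(1, k)
  roll <- function(x) as.numeric(stats::filter(x, win, sides = 2))
  est_fun <- function(w) {
    s <- roll(tab_weighted(ev$start_frame, val * w, n))
    c_ <- roll(tab_weighted(ev$start_frame, w, n))
    ifelse(c_ > 0, s / c_, NA_real_)
  }
  value <- est_fun(rep(1, nrow(ev)))
  boots <- matrix(NA_real_, n, n_boot)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(nrow(ev), nrow(ev), replace = TRUE),
                  nbins = nrow(ev))
    boots[, b] <- est_fun(w)
  }
  cnt <- as.numeric(stats::filter(tabulate(ev$start_frame, nbins = n), win,
                                  sides = 2))
  out <- data.frame(t = (seq_len(n) - 1) * dt, value = value,
                    stderr = apply(boots, 1, sd, na.rm = TRUE), n = cnt)
  class(out) <- c("windowed_estimate", class(out))
  out
}

tab_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Stop/walk transition-rate estimates
#'
#' A stop is a bout with walking speed below the threshold for longer than
#' the minimum bout duration (shorter dips are absorbed into the surrounding
#' state). Stop-to-walk and walk-to-stop transition rates are estimated
#' per frame as transition fraction / dt among trajectories in the source
#' state, smoothed like the turn rate, with trajectory-bootstrap errors.
#'
#' @param x a trajectory data.frame with a `speed_mm_s` column, or a list
#'   with a `speed` matrix (frames x agents) and `dt`.
#' @param speed_threshold stop threshold (mm/s, default 2).
#' @param min_bout minimum bout duration (s, default 0.1).
#' @param config a [segmentation_config()] (window, dt).
#' @param n_boot bootstrap resamples.
#' @return A list with elements `stop_to_walk` and `walk_to_stop`, each a
#'   `windowed_estimate` data.frame.
#' @export
stop_walk_rates <- function(x, speed_threshold = 2, min_bout = 0.1,
                            config = segmentation_config(), n_boot = 500) {
  if (is.data.frame(x)) {
    m <- as_omega_matrices(x)
    if (is.null(m$speed)) stop("trajectories have no speed channel")
    speed <- m$speed
    dt <- m$dt
  } else {
    speed <- x$speed
    dt <- x$dt
    if (is.null(speed)) stop("no speed matrix supplied")
  }
  n <- nrow(speed)
  na <- ncol(speed)
  min_frames <- ceiling(min_bout / dt) + 1L  # "more than" min_bout
  stopped <- matrix(FALSE, n, na)
  for (a in seq_len(na)) {
    below <- speed[, a] < speed_threshold
    r <- rle(below)
    # absorb short bouts into the preceding state
    if (length(r$lengths) > 1) {
      short <- r$lengths < min_frames
      short[1] <- FALSE
      for (j in which(short)) r$values[j] <- r$values[j - 1]
      r <- rle(inverse.rle(r))
    }
    stopped[, a] <- inverse.rle(r)
  }
  rate_of <- function(from_state) {
    src <- from_state[-n, , drop = FALSE]
    trans <- src & !from_state[-1, , drop = FALSE]
    est_fun <- function(w) {
      nm <- as.numeric(trans %*% w)
      dn <- as.numeric(src %*% w)
      v <- ifelse(dn > 0, nm / dn / dt, NA_real_)
      rect_smooth(v, config$window / dt)
    }
    v <- est_fun(rep(1, na))
    boots <- matrix(NA_real_, n - 1L, n_boot)
    for (b in seq_len(n_boot)) {
      w <- tabulate(sample.int(na, na, replace = TRUE), nbins = na)
      boots[, b] <- est_fun(w)
    }
    out <- data.frame(t = (seq_len(n - 1L) - 1) * dt, value = v,
                      stderr = apply(boots, 1, sd, na.rm = TRUE),
                      n = as.numeric(src %*% rep(1, na)))
    class(out) <- c("windowed_estimate", class(out))
    out
  }
  list(stop_to_walk = rate_of(stopped), walk_to_stop = rate_of(!stopped))
}
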
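#' @title Fit result container
#' @description Named fitted values plus the objective, bounds, data volume
#'   and convergence flag, shared by all estimation stages.
#' @param params named numeric vector of fitted values.
#' @param objective objective value at the optimum (negative log-likelihood
#'   or sum of squared errors).
#' @param bounds two-row matrix (lo/hi) or NULL.
#' @param n data volume (events or frames).
#' @param converged logical.
#' @param details optional list of stage-specific extras.
#' @return A list of class `flynav_fit`.
#' @keywords internal
flynav_fit <- function(params, objective, bounds = NULL, n = NA_integer_,
                       converged = NA, details = list()) {
  structure(list(params = params, objective = objective, bounds = bounds,
                 n = n, converged = converged, details = details),
            class = "flynav_fit")
}

#' @export
print.flynav_fit <- function(x, ...) {
  cat("flynav_fit (objective = ", format(x$objective), ", n = ", x$n,
      if (isTRUE(x$converged)) ", converged" else "", ")\n", sep = "")
  print(round(x$params, 5))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Turn-rate point-process likelihood

# Per-frame (fix_count, turn_count) summaries for one environment, applying
# the maximum-fixation exclusion: fixations longer than the cutoff drop both
# their frames and their terminal turn start.
rate_likelihood_data <- function(seg, signal,
                                 max_fixation = seg$config$max_fixation) {
  n <- seg$n_frames
  fx <- seg$fixations
  ev <- seg$events
  keep <- fx$duration <= max_fixation + 1e-9
  fk <- fx[keep, , drop = FALSE]
  # fixation frame counts via difference array
  d <- numeric(n + 1)
  if (nrow(fk)) {
    add <- tabulate(fk$start_frame, nbins = n + 1)
    sub <- tabulate(pmin(fk$end_frame + 1L, n + 1L), nbins = n + 1)
    d <- add - sub
  }
  fix_count <- cumsum(d)[seq_len(n)]
  # a turn start is kept unless its preceding fixation was excluded
  excl <- fx[!keep & !fx$censored, , drop = FALSE]
  drop_key <- paste(excl$agent, excl$end_frame + 1L)
  ev_keep <- !(paste(ev$agent, ev$start_frame) %in% drop_key)
  turn_count <- tabulate(ev$start_frame[ev_keep], nbins = n)
  list(signal = signal, fix_count = fix_count, turn_count = turn_count,
       dt = seg$dt, n_turns = sum(ev_keep), n_fix_frames = sum(fix_count))
}

rate_nll_counts <- function(th, data_list) {
  # th: lambda0, lambda1, lambda2, q_N, q_ND, q_fast, q_slow (q = log 1/tau)
  tau <- exp(-th[4:7])
  nll <- 0
  for (d in data_list) {
    s <- d$signal
    N <- cpp_novelty(s$t, s$onsets, tau[1], tau[2])
    OFF <- pmax(0, cpp_exp_filter(s$t, s$onsets, s$offsets, tau[4]) -
                   cpp_exp_filter(s$t, s$onsets, s$offsets, tau[3]))
    lam <- th[1] + th[2] * N + th[3] * OFF
    bad <- lam <= 0 & (d$fix_count > 0 | d$turn_count > 0)
    if (any(bad)) {
      return(1e12 * (1 + sum(pmax(0, -lam[bad]))))
    }
    p <- -expm1(-lam * d$dt)
    nll <- nll + sum(d$fix_count * lam) * d$dt -
      sum(d$turn_count[d$turn_count > 0] * log(p[d$turn_count > 0]))
  }
  nll
}

#' Negative log-likelihood of the inhomogeneous-Poisson turn-rate model
#'
#' Exact negative log of the point-process likelihood: each fixation frame
#' contributes `exp(-lambda_t dt)` and each turn-start frame
#' `1 - exp(-lambda_t dt)`, with `lambda_t` from the turn-rate model
#' evaluated on the signal's kernel responses.
#'
#' @param fixation_frames integer frame indices (1-based) of fixation
#'   samples.
#' @param turn_start_frames integer frame indices of fixation-to-turn
#'   transitions.
#' @param signal a `signal_trace`.
#' @param theta named vector or list with `lambda0`, `lambda1`, `lambda2`,
#'   `tau_N`, `tau_ND`, `tau_fast`, `tau_slow` (a [turn_model_params()] also
#'   works).
#' @return The negative log-likelihood in nats.
#' @export
nll_turn_rate <- function(fixation_frames, turn_start_frames, signal, theta) {
  if (inherits(theta, "turn_model_params")) {
    kp <- theta$kernel_params
    theta <- c(lambda0 = theta$lambda0, lambda1 = theta$lambda1,
               lambda2 = theta$lambda2, tau_N = kp$tau_N, tau_ND = kp$tau_ND,
               tau_fast = kp$tau_fast, tau_slow = kp$tau_slow)
  }
  theta <- unlist(theta)
  n <- length(signal$t)
  d <- list(signal = signal,
            fix_count = tabulate(fixation_frames, nbins = n),
            turn_count = tabulate(turn_start_frames, nbins = n),
            dt = signal$dt)
  th <- c(theta[["lambda0"]], theta[["lambda1"]], theta[["lambda2"]],
          log(1 / theta[["tau_N"]]), log(1 / theta[["tau_ND"]]),
          log(1 / theta[["tau_fast"]]), log(1 / theta[["tau_slow"]]))
  rate_nll_counts(th, list(d))
}

#' Maximum-likelihood fit of the turn-rate model
#'
#' Jointly estimates `lambda0`, `lambda1`, `lambda2` and the kernel
#' timescales `tau_N`, `tau_ND`, `tau_fast`, `tau_slow` by bounded
#' quasi-Newton (L-BFGS-B) minimisation of the point-process negative
#' log-likelihood, pooling data across environments. Timescales are
#' parameterised as the log of the inverse timescale with bounds 0.01-1200 s;
#' multiple random starts guard against local minima.
#'
#' @param segs list of [detect_turns()] results, one per environment.
#' @param signals list of matching `signal_trace` objects.
#' @param max_fixation fixation-duration cutoff for the likelihood (s).
#' @param n_starts number of random restarts (default 5).
#' @param init optional named start values (used as the first start).
#' @param tau_bounds timescale bounds in seconds (default `c(0.01, 1200)`).
#' @param maxit,factr L-BFGS-B control settings.
#' @return A `flynav_fit` with fitted values (timescales back-transformed to
#'   seconds).
#' @export
fit_turn_rate <- function(segs, signals, max_fixation = 1.5, n_starts = 5,
                          init = NULL, tau_bounds = c(0.01, 1200),
                          maxit = 400, factr = 1e7) {
  stopifnot(length(segs) == length(signals))
  data_list <- Map(function(sg, si) {
    rate_likelihood_data(sg, si, max_fixation)
  }, segs, signals)
  n_turns <- sum(vapply(data_list, `[[`, 0, "n_turns"))
  n_fix <- sum(vapply(data_list, `[[`, 0, "n_fix_frames"))
  dt <- data_list[[1]]$dt
  crude <- n_turns / ((n_fix + n_turns) * dt)

  q_lo <- log(1 / tau_bounds[2])
  q_hi <- log(1 / tau_bounds[1])
  lower <- c(rep(-Inf, 3), rep(q_lo, 4))
  upper <- c(rep(Inf, 3), rep(q_hi, 4))

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- c(init[["lambda0"]], init[["lambda1"]], init[["lambda2"]],
                     log(1 / init[["tau_N"]]), log(1 / init[["tau_ND"]]),
                     log(1 / init[["tau_fast"]]), log(1 / init[["tau_slow"]]))
  }
  while (length(starts) < n_starts) {
    tf <- sort(exp(runif(2, log(0.05), log(1))))
    starts[[length(starts) + 1]] <- c(
      crude * runif(1, 0.5, 1.5), runif(1, 0, 2) * crude,
      runif(1, 0, 10) * crude,
      log(1 / exp(runif(1, log(0.2), log(10)))),
      log(1 / exp(runif(1, log(0.05), log(2)))),
      log(1 / tf[1]), log(1 / tf[2]))
  }
  best <- NULL
  for (st in starts) {
    fit <- try(optim(st, rate_nll_counts, data_list = data_list,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = maxit, factr = factr)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all turn-rate fits failed")
  p <- best$par
  params <- c(lambda0 = p[1], lambda1 = p[2], lambda2 = p[3],
              tau_N = exp(-p[4]), tau_ND = exp(-p[5]),
              tau_fast = exp(-p[6]), tau_slow = exp(-p[7]))
  flynav_fit(params, best$value,
             bounds = rbind(lo = c(-Inf, -Inf, -Inf, rep(tau_bounds[1], 4)),
                            hi = c(Inf, Inf, Inf, rep(tau_bounds[2], 4))),
             n = n_turns + n_fix, converged = best$convergence == 0,
             details = list(n_turns = n_turns, n_fix_frames = n_fix))
}

# ---------------------------------------------------------------------------
# Turn-speed Gamma likelihood

gamma_speed_nll <- function(mu_par, x, N, OFF) {
  mu <- mu_par[1] + mu_par[2] * N + mu_par[3] * OFF
  if (any(mu <= 0)) return(1e12 * (1 + sum(pmax(0, -mu))))
  sum(2 * log(mu / 2) - log(x) + 2 * x / mu)
}

#' Negative log-likelihood of the Gamma turn-speed model
#'
#' Gamma likelihood with fixed shape 2 and signal-dependent mean for the
#' excess mean turn speeds (total mean speed minus the 25 deg/s floor).
#'
#' @param mu named vector `c(mu0, mu1, mu2)`.
#' @param x excess mean turn speeds (deg/s), all > 0.
#' @param N,OFF kernel values at the turn starts.
#' @return Negative log-likelihood in nats.
#' @export
nll_turn_speed <- function(mu, x, N, OFF) {
  if (any(x <= 0)) stop("excess turn speeds must be > 0")
  gamma_speed_nll(unlist(mu), x, N, OFF)
}

#' Maximum-likelihood fit of the turn-speed model
#'
#' Estimates `mu0`, `mu1`, `mu2` from excess mean turn speeds with the
#' kernel timescales frozen (taken from a previous turn-rate fit). Events
#' with non-positive excess speed (possible only through numerical
#' discretisation of the slowest turns) are dropped with a count reported.
#'
#' @param speeds total mean turn speeds (deg/s).
#' @param N,OFF kernel values at the turn starts.
#' @param speed_floor the minimum turn speed subtracted before fitting.
#' @param n_starts random restarts.
#' @return A `flynav_fit`.
#' @export
fit_turn_speed <- function(speeds, N, OFF, speed_floor = 25, n_starts = 5) {
  x <- speeds - speed_floor
  ok <- x > 0
  x <- x[ok]; N <- N[ok]; OFF <- OFF[ok]
  if (!length(x)) stop("no usable turn events")
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) c(mean(x), 0.1, 0.1) else
      c(mean(x) * runif(1, 0.5, 1.5), runif(1, 0, 100), runif(1, 0, 500))
    fit <- try(optim(st, gamma_speed_nll, x = x, N = N, OFF = OFF,
                     method = "L-BFGS-B",
                     lower = c(1e-3, -Inf, -Inf), upper = rep(Inf, 3),
                     control = list(maxit = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("turn-speed fit failed")
  flynav_fit(c(mu0 = best$par[1], mu1 = best$par[2], mu2 = best$par[3]),
             best$value, n = length(x), converged = best$convergence == 0,
             details = list(n_dropped = sum(!ok)))
}

# ---------------------------------------------------------------------------
# Turn-duration exponential likelihood

#' Maximum-likelihood fit of the turn-duration distribution
#'
#' Excess turn durations (duration minus the 0.18 s floor) are modelled as
#' exponential; the MLE rate is the inverse sample mean and is reported as
#' the timescale `tau_dur`.
#'
#' @param durations total turn durations (s).
#' @param duration_floor minimum turn duration subtracted before fitting.
#' @return A `flynav_fit` with `tau_dur` and the rate `lambda_dur`.
#' @export
fit_turn_duration <- function(durations, duration_floor = 0.18) {
  x <- durations - duration_floor
  if (!length(x)) stop("no turn events supplied")
  if (any(x < 0)) x <- pmax(x, 0)
  tau <- mean(x)
  rate <- 1 / tau
  nll <- -sum(log(rate) - rate * x)
  flynav_fit(c(tau_dur = tau, lambda_dur = rate), nll, n = length(x),
             converged = TRUE)
}

# ---------------------------------------------------------------------------
# Baseline bias

#' Least-squares fit of the baseline upwind bias
#'
#' Restricts turns to signal-free periods, bins them by reflected
#' orientation, and fits the zero-signal sigmoid
#' `1 / (1 + exp(-a0 sin^2 theta))` to the binned upwind fraction by
#' Levenberg-Marquardt (trust-region) least squares.
#'
#' @param theta_start headings (deg) at turn initiation.
#' @param upwind logical/0-1 turn directions.
#' @param n_bins orientation bins over \[0, 180\] (default 8).
#' @return A `flynav_fit` with `a0`; details carry the binned curve.
#' @export
fit_baseline_bias <- function(theta_start, upwind, n_bins = 8) {
  refl <- reflect_orientation(theta_start)
  bins <- cut(refl, breaks = seq(0, 180, length.out = n_bins + 1),
              include.lowest = TRUE)
  p <- tapply(as.numeric(upwind), bins, mean)
  ok <- !is.na(p)
  if (sum(ok) < 2) stop("fewer than 2 populated orientation bins")
  centers <- (seq_len(n_bins) - 0.5) * 180 / n_bins
  cb <- centers[ok]
  pb <- as.numeric(p[ok])
  resid_fun <- function(par) {
    pb - 1 / (1 + exp(-par[1] * sin(cb * pi / 180)^2))
  }
  fit <- minpack.lm::nls.lm(par = c(a0 = 0), fn = resid_fun)
  flynav_fit(c(a0 = unname(coef(fit))), sum(residuals(fit)^2),
             n = length(refl), converged = fit$info %in% 1:4,
             details = list(curve = data.frame(theta = cb, upwind_frac = pb),
                            n_per_bin = as.numeric(table(bins)[ok])))
}

# ---------------------------------------------------------------------------
# Bias-kernel grid search

#' Simulation-based grid search for the upwind-bias kernel parameters
#'
#' Fits the gain(s) and timescale(s) of a bias kernel by brute-force grid
#' search: for every grid point, populations of agents executing the full
#' turning model (turn dynamics frozen) are simulated in each environment
#' and the mean squared error between simulated and observed mean reflected
#' orientation over the fit horizon is accumulated. Gains are spaced
#' linearly, timescales logarithmically (the log of the rate is gridded).
#' Grid-point simulations share a common random seed so that neighbouring
#' points differ only through their parameters; ties break toward the
#' smaller gain.
#'
#' @param data_traces list of observed mean reflected-orientation traces
#'   (one numeric vector per environment).
#' @param signals list of matching `signal_trace` objects.
#' @param params frozen [turn_model_params()] for the turn dynamics.
#' @param kernel one of "R", "I", "F", "H".
#' @param n_grid grid points per parameter (default 20).
#' @param gain_bounds,tau_bounds search bounds (defaults follow the kernel:
#'   R gain 0.15-3 with decay timescale 0.05-5 s; I and F gains 0-16 with
#'   timescales 0.01-5 / 0.05-5 s; H gains 0-4 with timescale 0.05-5 s).
#' @param tau_g_fixed rise timescale frozen during the R-kernel search (s).
#' @param n_agents agents per simulated population (default 240).
#' @param t_fit fit horizon (s, default 20).
#' @param seed RNG seed shared by all grid points.
#' @return A `flynav_fit`; details carry the full objective grid.
#' @export
fit_bias_kernel <- function(data_traces, signals, params,
                            kernel = c("R", "I", "F", "H"), n_grid = 20,
                            gain_bounds = NULL, tau_bounds = NULL,
                            tau_g_fixed = params$kernel_params$tau_g,
                            n_agents = 240, t_fit = 20, seed = 1) {
  kernel <- match.arg(kernel)
  defaults <- list(
    R = list(gain = c(0.15, 3), tau = c(0.05, 5)),
    I = list(gain = c(0, 16), tau = c(0.01, 5)),
    F = list(gain = c(0, 16), tau = c(0.05, 5)),
    H = list(gain = c(0, 4), tau = c(0.05, 5)))
  if (is.null(gain_bounds)) gain_bounds <- defaults[[kernel]]$gain
  if (is.null(tau_bounds)) tau_bounds <- defaults[[kernel]]$tau
  gains <- seq(gain_bounds[1], gain_bounds[2], length.out = n_grid)
  taus <- 1 / exp(seq(log(1 / tau_bounds[1]), log(1 / tau_bounds[2]),
                      length.out = n_grid))
  n_frames <- min(lengths(data_traces),
                  vapply(signals, function(s) length(s$t), 0L),
                  round(t_fit / signals[[1]]$dt))

  u_for <- function(s, tau) {
    switch(kernel,
      R = cpp_two_timescale(s$t, s$onsets, s$offsets, tau_g_fixed, tau),
      I = cpp_exp_filter(s$t, s$onsets, s$offsets, tau),
      F = cpp_onset_filter(s$t, s$onsets, tau),
      H = NULL)
  }
  sim_mse <- function(g, u_list) {
    set.seed(seed)
    mse <- 0
    for (i in seq_along(signals)) {
      init <- runif(n_agents, 0, 360)
      mo <- simulate_mean_orientation(signals[[i]], params, n_agents, init,
                                      g = g, u = u_list[[i]],
                                      n_frames = n_frames)
      mse <- mse + mean((mo - data_traces[[i]][seq_len(n_frames)])^2)
    }
    mse / length(signals)
  }

  if (kernel == "H") {
    obj <- array(NA_real_, c(n_grid, n_grid, n_grid))
    for (k in seq_len(n_grid)) {
      Iu <- lapply(signals, function(s)
        cpp_exp_filter(s$t, s$onsets, s$offsets, taus[k]))
      Fu <- lapply(signals, function(s) cpp_onset_filter(s$t, s$onsets,
                                                         taus[k]))
      for (i in seq_len(n_grid)) {
        for (j in seq_len(n_grid)) {
          u <- Map(function(a, b) gains[i] * a + gains[j] * b, Iu, Fu)
          obj[i, j, k] <- try_mse(sim_mse, 1, u)
        }
      }
    }
    idx <- arrayInd(which.min(obj), dim(obj))
    params_out <- c(g_I = gains[idx[1]], g_F = gains[idx[2]],
                    tau_H = taus[idx[3]])
    best_obj <- obj[idx]
  } else {
    obj <- matrix(NA_real_, n_grid, n_grid, dimnames = list(gains, taus))
    for (j in seq_len(n_grid)) {
      u_list <- lapply(signals, u_for, tau = taus[j])
      for (i in seq_len(n_grid)) {
        obj[i, j] <- try_mse(sim_mse, gains[i], u_list)
      }
    }
    idx <- arrayInd(which.min(obj), dim(obj))
    params_out <- c(g = gains[idx[1]], tau = taus[idx[2]])
    names(params_out)[2] <- switch(kernel, R = "tau_d", I = "tau_I",
                                   F = "tau_F")
    best_obj <- obj[idx]
  }
  flynav_fit(params_out, best_obj,
             bounds = rbind(lo = c(gain_bounds[1], tau_bounds[1]),
                            hi = c(gain_bounds[2], tau_bounds[2])),
             n = length(signals) * n_frames, converged = TRUE,
             details = list(objective_grid = obj, gains = gains,
                            taus = taus, kernel = kernel))
}

try_mse <- function(f, ...) {
  v <- try(f(...), silent = TRUE)
  if (inherits(v, "try-error")) NA_real_ else v
}

# ---------------------------------------------------------------------------
# NR score

#' Normalized-residual (NR) model score
#'
#' Root-mean-square error of the model trace(s) against the data trace(s),
#' divided by the standard deviation of the data, pooled over all time
#' points of all supplied environments. A score below 1 means the model
#' prediction lies within the noise of the data.
#'
#' @param model numeric vector or list of vectors (per environment).
#' @param data matching numeric vector or list.
#' @param data_sd optional externally supplied data standard deviation.
#' @return The pooled NR score; per-environment scores as an attribute when
#'   lists are supplied.
#' @export
nr_score <- function(model, data, data_sd = NULL) {
  if (is.list(model) != is.list(data)) stop("model and data must match")
  if (!is.list(model)) {
    model <- list(model)
    data <- list(data)
  }
  stopifnot(length(model) == length(data))
  res <- unlist(Map(`-`, model, data))
  pooled_sd <- if (is.null(data_sd)) sd(unlist(data)) else data_sd
  if (!is.finite(pooled_sd) || pooled_sd == 0) {
    stop("data standard deviation is zero; NR score undefined")
  }
  out <- sqrt(mean(res^2)) / pooled_sd
  if (length(model) > 1) {
    per <- vapply(seq_along(model), function(i) {
      sqrt(mean((model[[i]] - data[[i]])^2)) / pooled_sd
    }, 0)
    attr(out, "per_environment") <- per
  }
  out
}
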
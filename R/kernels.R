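#' Kernel parameter set
#'
#' Container for the timescales and gains of the six signal-processing
#' responses: the onset-novelty response N (novelty timescale `tau_N`, decay
#' `tau_ND`), the offset response OFF (slow-minus-fast filter pair
#' `tau_slow` > `tau_fast`), the intermittency filter I (`tau_I`), the
#' onset-frequency filter F (`tau_F`), the dual model H (gains `g_I`, `g_F`,
#' shared timescale `tau_H`) and the two-timescale integrator R (rise
#' `tau_g`, decay `tau_d`). Defaults are the study's fitted values.
#'
#' @param tau_N,tau_ND,tau_fast,tau_slow,tau_I,tau_F,tau_H,g_I,g_F,tau_g,tau_d
#'   see Description; timescales in seconds, gains dimensionless.
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(tau_N = 2.04, tau_ND = 0.55, tau_fast = 0.19,
                          tau_slow = 0.22, tau_I = 0.04, tau_F = 0.08,
                          tau_H = 0.1, g_I = 2.7, g_F = 3.2, tau_g = 0.01,
                          tau_d = 0.97) {
  taus <- c(tau_N = tau_N, tau_ND = tau_ND, tau_fast = tau_fast,
            tau_slow = tau_slow, tau_I = tau_I, tau_F = tau_F, tau_H = tau_H)
  if (any(taus <= 0)) stop("all timescales must be > 0")
  if (tau_g < 0 || tau_d < 0) stop("tau_g and tau_d must be >= 0")
  if (tau_fast >= tau_slow) {
    stop("tau_fast must be < tau_slow for a positive offset response")
  }
  structure(list(tau_N = tau_N, tau_ND = tau_ND, tau_fast = tau_fast,
                 tau_slow = tau_slow, tau_I = tau_I, tau_F = tau_F,
                 tau_H = tau_H, g_I = g_I, g_F = g_F, tau_g = tau_g,
                 tau_d = tau_d),
            class = "kernel_params")
}

response_trace <- function(t, value, kernel_id) {
  structure(list(t = t, value = value, kernel_id = kernel_id),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("response_trace [%s]: %d samples, range [%.4g, %.4g]\n",
              x$kernel_id, length(x$t), min(x$value), max(x$value)))
  invisible(x)
}

check_signal <- function(signal) {
  if (!inherits(signal, "signal_trace")) {
    stop("expected a signal_trace (see render_signal())")
  }
  signal
}

#' Onset-novelty response N(t)
#'
#' Spikes at each pulse onset and decays with timescale `tau_ND` until the
#' next onset. The spike amplitude is 1 for the first onset of the session
#' and `1 - exp(-(gap)/tau_N)` for later onsets, where `gap` is the time
#' since the previous onset: closely spaced encounters elicit a suppressed
#' response, encounters after a long blank are treated as novel and elicit
#' the maximal response again.
#'
#' @param signal a `signal_trace`.
#' @param tau_N novelty timescale (s).
#' @param tau_ND response decay timescale (s).
#' @return A `response_trace` with values in \[0, 1\].
#' @export
novelty_response <- function(signal, tau_N, tau_ND) {
  check_signal(signal)
  stopifnot(tau_N > 0, tau_ND > 0)
  v <- cpp_novelty(signal$t, signal$onsets, tau_N, tau_ND)
  response_trace(signal$t, v, "N")
}

#' Offset response OFF(t)
#'
#' The positive part of a slow-minus-fast pair of exponential signal filters,
#' `OFF(t) = max(0, I_slow - I_fast)`. Zero during steady signal presence and
#' transiently positive after offsets; the integrative filters make the peak
#' larger after longer or more intermittent exposure.
#'
#' @param signal a `signal_trace`.
#' @param tau_fast,tau_slow filter timescales (s), `tau_fast < tau_slow`.
#' @return A `response_trace` with non-negative values.
#' @export
off_response <- function(signal, tau_fast, tau_slow) {
  check_signal(signal)
  if (tau_fast >= tau_slow) stop("tau_fast must be < tau_slow")
  islow <- cpp_exp_filter(signal$t, signal$onsets, signal$offsets, tau_slow)
  ifast <- cpp_exp_filter(signal$t, signal$onsets, signal$offsets, tau_fast)
  response_trace(signal$t, pmax(0, islow - ifast), "OFF")
}

#' Intermittency filter I(t)
#'
#' Normalized exponential moving average of the binary signal; for a square
#' wave its asymptotic cycle average equals the signal intermittency.
#'
#' @param signal a `signal_trace`.
#' @param tau integration timescale (s).
#' @return A `response_trace` with values in \[0, 1\].
#' @export
intermittency_filter <- function(signal, tau) {
  check_signal(signal)
  stopifnot(tau > 0)
  v <- cpp_exp_filter(signal$t, signal$onsets, signal$offsets, tau)
  response_trace(signal$t, v, "I")
}

#' Onset-frequency filter F(t)
#'
#' Exponentially filtered train of unit impulses at pulse onsets: F jumps by
#' 1 at each onset and decays with `tau` in between, making it a running
#' estimate of the odor encounter frequency.
#'
#' @param signal a `signal_trace`.
#' @param tau filter timescale (s).
#' @return A non-negative `response_trace`.
#' @export
onset_frequency_filter <- function(signal, tau) {
  check_signal(signal)
  stopifnot(tau > 0)
  v <- cpp_onset_filter(signal$t, signal$onsets, tau)
  response_trace(signal$t, v, "F")
}

#' Dual frequency-and-intermittency response H(t)
#'
#' Pointwise weighted sum `g_I * I(t) + g_F * F(t)` of an intermittency
#' filter and an onset-frequency filter computed with a shared timescale.
#'
#' @param I,F `response_trace` objects on the same time grid (kernel ids
#'   "I" and "F").
#' @param g_I,g_F gains.
#' @return A `response_trace`.
#' @export
dual_response <- function(I, F, g_I, g_F) {
  stopifnot(inherits(I, "response_trace"), inherits(F, "response_trace"))
  if (length(I$t) != length(F$t) || any(abs(I$t - F$t) > 1e-9)) {
    stop("I and F must share the same time grid")
  }
  response_trace(I$t, g_I * I$value + g_F * F$value, "H")
}

#' Two-timescale integrating response R(t)
#'
#' Relaxes toward 1 with rise timescale `tau_g` while the signal is on and
#' decays with `tau_d` while it is off; `tau_g = tau_d` reduces to the single
#' timescale integrator, `tau_g = 0` is the instantaneous-rise limit.
#'
#' @param signal a `signal_trace`.
#' @param tau_g rise timescale (s, >= 0).
#' @param tau_d decay timescale (s, >= 0).
#' @return A `response_trace` with values in \[0, 1\].
#' @export
two_timescale_response <- function(signal, tau_g, tau_d) {
  check_signal(signal)
  stopifnot(tau_g >= 0, tau_d >= 0)
  v <- cpp_two_timescale(signal$t, signal$onsets, signal$offsets, tau_g, tau_d)
  response_trace(signal$t, v, "R")
}

#' Asymptotic cycle-averaged two-timescale response
#'
#' Closed-form asymptotic average of the two-timescale integrator over one
#' period of a square-wave signal with the given frequency and intermittency.
#' With `a = exp(-D/tau_g)` and `b = exp(-(T-D)/tau_d)` (D the pulse
#' duration, T the period), the pulse-onset fixed point is
#' `R* = b(1-a)/(1-ab)` and the cycle average is
#' `(D - (1-R*) tau_g (1-a) + (1-(1-R*) a) tau_d (1-b)) / T`.
#' Equal timescales give exactly the intermittency; `tau_g = 0` and
#' `tau_d = 0` reduce to the fast-rise / fast-decay limit formulas (see
#' [asymptotic_mean_response_limit()]).
#'
#' @param frequency square-wave frequency (Hz).
#' @param intermittency fraction of time the signal is on, in \[0, 1\].
#' @param tau_g,tau_d rise and decay timescales (s, >= 0).
#' @return The asymptotic cycle-averaged response, a number in \[0, 1\].
#' @export
asymptotic_mean_response <- function(frequency, intermittency, tau_g, tau_d) {
  stopifnot(frequency > 0, tau_g >= 0, tau_d >= 0)
  if (intermittency <= 0) return(0)
  if (intermittency >= 1) return(1)
  T <- 1 / frequency
  D <- intermittency * T
  a <- if (tau_g > 0) exp(-D / tau_g) else 0
  b <- if (tau_d > 0) exp(-(T - D) / tau_d) else 0
  rstar <- b * (1 - a) / (1 - a * b)
  on_int <- D - (1 - rstar) * tau_g * (1 - a)
  off_int <- (1 - (1 - rstar) * a) * tau_d * (1 - b)
  (on_int + off_int) / T
}

#' Limit formulas for the asymptotic two-timescale response
#'
#' The fast-rise limit (`tau_g -> 0`):
#' `Int + f * tau_d * (1 - exp((Int - 1) / (f * tau_d)))`, which grows with
#' frequency until f >> 1/tau_d; and the fast-decay limit (`tau_d -> 0`):
#' `Int + f * tau_g * (exp(-Int / (f * tau_g)) - 1)`, which decreases with
#' frequency.
#'
#' @param frequency square-wave frequency (Hz).
#' @param intermittency fraction in \[0, 1\].
#' @param tau surviving timescale (s): `tau_d` for the fast-rise limit,
#'   `tau_g` for the fast-decay limit.
#' @param which `"fast_rise"` or `"fast_decay"`.
#' @return The limiting cycle-averaged response.
#' @export
asymptotic_mean_response_limit <- function(frequency, intermittency, tau,
                                           which = c("fast_rise",
                                                     "fast_decay")) {
  which <- match.arg(which)
  stopifnot(frequency > 0, tau >= 0)
  f <- frequency
  Int <- intermittency
  if (tau == 0) return(Int)
  if (which == "fast_rise") {
    Int + f * tau * (1 - exp((Int - 1) / (f * tau)))
  } else {
    Int + f * tau * (exp(-Int / (f * tau)) - 1)
  }
}
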
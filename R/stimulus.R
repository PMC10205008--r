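#' Square-wave fictive-odor stimulus protocol
#'
#' Builds the block-structured stimulus used throughout: each repeat is a 15 s
#' "ON block" containing regular light pulses at a fixed encounter frequency
#' and duration, followed by a 15 s "OFF block" with no stimulus. Pulse onsets
#' are phase-locked to the block start (first onset at t = 0 of each ON
#' block); a pulse extending past the 15 s ON boundary is truncated there.
#'
#' Protocols whose intermittency (frequency x duration, the fraction of time
#' signal is present) reaches 1 are rejected, as are non-positive frequencies,
#' durations or sample intervals.
#'
#' @param frequency pulse (encounter) frequency in Hz.
#' @param pulse_duration pulse duration in seconds.
#' @param n_repeats number of ON+OFF block pairs (default 4, i.e. a 120 s
#'   session).
#' @param on_block_len,off_block_len block lengths in seconds (15 each).
#' @param dt sample interval in seconds (default 1/60).
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol(0.2, 1, n_repeats = 1)
#' intermittency(p)
#' @export
stimulus_protocol <- function(frequency, pulse_duration, n_repeats = 4L,
                              on_block_len = 15, off_block_len = 15,
                              dt = 1 / 60) {
  stopifnot(is.numeric(frequency), is.numeric(pulse_duration))
  if (frequency <= 0) stop("frequency must be > 0")
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (frequency * pulse_duration >= 1) {
    stop("intermittency = frequency * pulse_duration must be < 1 ",
         "(indeterminable flashes)")
  }
  structure(
    list(frequency = frequency, pulse_duration = pulse_duration,
         n_repeats = as.integer(n_repeats), on_block_len = on_block_len,
         off_block_len = off_block_len, dt = dt),
    class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "stimulus_protocol: %g Hz, %g s pulses, %d repeat(s) of %g s ON / %g s OFF (dt = %.5g s)\n",
    x$frequency, x$pulse_duration, x$n_repeats, x$on_block_len,
    x$off_block_len, x$dt))
  cat(sprintf("  intermittency = %g\n", intermittency(x)))
  invisible(x)
}

#' Signal intermittency of a protocol
#'
#' The fraction of time the odor signal is present: frequency multiplied by
#' pulse duration, in \[0, 1).
#'
#' @param protocol a [stimulus_protocol()].
#' @return A single number in \[0, 1).
#' @export
intermittency <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  protocol$frequency * protocol$pulse_duration
}

#' Pulse onset/offset times of a protocol
#'
#' Onsets are at `k / frequency` within each ON block for k = 0, 1, ... while
#' the onset is strictly before the 15 s block end; offsets are truncated at
#' the block end.
#'
#' @param protocol a [stimulus_protocol()].
#' @return A list with numeric vectors `onsets` and `offsets` (seconds, over
#'   the whole session).
#' @export
protocol_pulses <- function(protocol) {
  p <- protocol
  period <- 1 / p$frequency
  block <- p$on_block_len + p$off_block_len
  k <- seq(0, by = 1, length.out = floor(p$on_block_len / period) + 1)
  on1 <- k * period
  on1 <- on1[on1 < p$on_block_len]
  off1 <- pmin(on1 + p$pulse_duration, p$on_block_len)
  rep_off <- rep(seq_len(p$n_repeats) - 1L, each = length(on1)) * block
  list(onsets = rep_off + on1, offsets = rep_off + off1)
}

#' Render a protocol into a sampled binary signal trace
#'
#' Samples the binary odor signal on the protocol's time grid. A sample at
#' time t carries signal 1 iff t lies in `[onset, offset)` for some pulse
#' (half-open, so pulse edges are never double-counted).
#'
#' @param protocol a [stimulus_protocol()].
#' @return A `signal_trace`: list with `t` (sample times, s), `S` (0/1),
#'   `onsets`, `offsets` (exact pulse-edge times, s) and `dt`.
#' @export
render_signal <- function(protocol) {
  p <- protocol
  pulses <- protocol_pulses(p)
  t_end <- p$n_repeats * (p$on_block_len + p$off_block_len)
  signal_trace(pulses$onsets, pulses$offsets, t_end, p$dt)
}

#' Construct a binary signal trace from explicit pulse times
#'
#' Lower-level constructor used by [render_signal()] and by tests that need
#' irregular pulse trains.
#'
#' @param onsets,offsets strictly increasing pulse edge times (s); equal
#'   lengths, each offset greater than its onset.
#' @param t_end trace end time (s).
#' @param dt sample interval (s).
#' @return A `signal_trace` object.
#' @export
signal_trace <- function(onsets, offsets, t_end, dt = 1 / 60) {
  if (length(onsets) != length(offsets)) {
    stop("onsets and offsets must have equal length")
  }
  if (length(onsets)) {
    if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
    if (any(offsets <= onsets)) stop("each offset must exceed its onset")
    if (any(onsets[-1] < offsets[-length(offsets)])) {
      stop("pulses must not overlap")
    }
  }
  t <- seq(0, t_end - dt / 2, by = dt)
  S <- integer(length(t))
  if (length(onsets)) {
    idx <- findInterval(t, as.vector(rbind(onsets, offsets)))
    S <- as.integer(idx %% 2L == 1L)
  }
  structure(list(t = t, S = S, onsets = as.numeric(onsets),
                 offsets = as.numeric(offsets), dt = dt),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace: %d samples at dt = %.5g s, %d pulse(s), mean S = %.4g\n",
              length(x$t), x$dt, length(x$onsets), mean(x$S)))
  invisible(x)
}

#' The 45-environment stimulus grid
#'
#' All combinations of the study's encounter frequencies (0.2, 0.5, 1, 1.5,
#' 1.75, 2, 2.5, 3, 4, 5 Hz) and pulse durations (0.02, 0.05, 0.1, 0.25, 0.5,
#' 1 s) whose intermittency is below 1.
#'
#' @param frequencies,durations candidate values (defaults: the study grid).
#' @return A data.frame with columns `frequency`, `duration`,
#'   `intermittency`, one row per admissible environment.
#' @export
environment_grid <- function(
    frequencies = c(0.2, 0.5, 1, 1.5, 1.75, 2, 2.5, 3, 4, 5),
    durations = c(0.02, 0.05, 0.1, 0.25, 0.5, 1)) {
  g <- expand.grid(frequency = frequencies, duration = durations,
                   KEEP.OUT.ATTRS = FALSE)
  g$intermittency <- g$frequency * g$duration
  g <- g[g$intermittency < 1, , drop = FALSE]
  g <- g[order(g$frequency, g$duration), ]
  rownames(g) <- NULL
  g
}

#' Write / read a protocol as a flat key-value config file
#'
#' @param protocol a [stimulus_protocol()].
#' @param path file path.
#' @return `read_protocol` returns a [stimulus_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  p <- protocol
  lines <- c(
    sprintf("frequency_hz=%.10g", p$frequency),
    sprintf("duration_s=%.10g", p$pulse_duration),
    sprintf("n_repeats=%d", p$n_repeats),
    sprintf("dt=%.10g", p$dt))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  kv <- read_keyval(path)
  stimulus_protocol(frequency = as.numeric(kv[["frequency_hz"]]),
                    pulse_duration = as.numeric(kv[["duration_s"]]),
                    n_repeats = as.integer(kv[["n_repeats"]]),
                    dt = as.numeric(kv[["dt"]]))
}

read_keyval <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- vapply(parts, function(p) trimws(p[2]), "")
  names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
  as.list(vals)
}
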
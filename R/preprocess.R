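#' Multi-muscle sEMG recording with gait events
#'
#' @param signal Numeric matrix, rows = samples, columns = muscles (>= 2).
#' @param events Strictly increasing 1-based cycle-start sample indices
#'   (heel strikes); cycle i spans samples `[events[i], events[i+1])`.
#' @param muscle_names Optional character vector of channel names.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, events, muscle_names = NULL) {
  signal <- as.matrix(signal)
  events <- as.integer(events)
  if (ncol(signal) < 2L) {
    abort("at least two muscles are required", class = "choosyn_domain")
  }
  if (any(diff(events) <= 0)) {
    abort("events must be strictly increasing", class = "choosyn_event_order")
  }
  if (events[1] < 1L || events[length(events)] > nrow(signal)) {
    abort("events must lie within the recording", class = "choosyn_event_order")
  }
  if (is.null(muscle_names)) {
    muscle_names <- colnames(signal) %||% sprintf("M%02d", seq_len(ncol(signal)))
  }
  colnames(signal) <- muscle_names
  structure(list(signal = signal, events = events,
                 muscle_names = muscle_names),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> ", nrow(x$signal), " samples x ", ncol(x$signal),
      " muscles, ", length(x$events), " events\n", sep = "")
  invisible(x)
}

#' Segment gait cycles and time-normalize to 1000 samples
#'
#' Each cycle `[e_i, e_{i+1})` is resampled to exactly 1000 samples by
#' linear interpolation on a uniform grid; samples after the last event (a
#' trailing partial cycle) are discarded. k+1 events therefore yield k
#' cycles.
#'
#' @param rec An [emg_recording()] (or `simulated_recording`).
#' @param cycle_length Samples per normalized cycle (default 1000).
#' @return A list of muscles x 1000 matrices, one per complete cycle.
#' @export
segment_and_normalize <- function(rec, cycle_length = 1000L) {
  events <- rec$events
  if (length(events) < 2L) {
    abort("at least two events (one complete cycle) are required",
          class = "choosyn_no_complete_cycle")
  }
  if (any(diff(events) <= 0)) {
    abort("events must be strictly increasing", class = "choosyn_event_order")
  }
  sig <- rec$signal
  m <- ncol(sig)
  lapply(seq_len(length(events) - 1L), function(i) {
    e0 <- events[i]
    e1 <- events[i + 1L]
    L <- e1 - e0
    xout <- e0 + (seq_len(cycle_length) - 1L) * (L / cycle_length)
    x <- e0:min(e1, nrow(sig))
    out <- vapply(seq_len(m), function(mu) {
      approx(x = x, y = sig[x, mu], xout = xout, method = "linear")$y
    }, numeric(cycle_length))
    t(out)                      # muscles x cycle_length
  })
}

# zero-phase Butterworth with odd-mirror edge padding (the padding keeps
# the forward-backward pass free of start-up transients)
butter_sos_filtfilt <- function(x, n, w, type) {
  flt <- signal::butter(n, w, type = type)
  np <- min(length(x) - 1L, 300L)
  pre <- 2 * x[1] - x[seq(np + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - np)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(np + 1L):(np + length(x))]
}

#' Extract amplitude envelopes from segmented cycles
#'
#' Per muscle, over the concatenation of all cycles (to avoid per-cycle edge
#' transients): zero-phase 8th-order Butterworth high-pass at 35 Hz, channel
#' demeaning, full-wave rectification, zero-phase 5th-order Butterworth
#' low-pass at 12 Hz; residual negative values from low-pass ringing are
#' clipped to 0, and the walk is re-split into cycles. The frequency axis is
#' nominal: 1000 samples per normalized cycle are treated as `fs` Hz.
#'
#' @param cycles A list of muscles x 1000 matrices from
#'   [segment_and_normalize()].
#' @param fs Nominal sampling rate in Hz (default 1000).
#' @param highpass_hz,lowpass_hz Cutoffs in Hz (defaults 35 and 12).
#' @return A list of non-negative envelope matrices, same shapes as input.
#' @export
envelope_pipeline <- function(cycles, fs = 1000,
                              highpass_hz = 35, lowpass_hz = 12) {
  if (highpass_hz >= fs / 2 || lowpass_hz >= fs / 2) {
    abort("filter cutoffs must be below the Nyquist frequency",
          class = "choosyn_filter_design")
  }
  m <- nrow(cycles[[1]])
  L <- ncol(cycles[[1]])
  walk <- do.call(cbind, cycles)            # m x (L * n_cycles)
  env <- t(vapply(seq_len(m), function(mu) {
    x <- butter_sos_filtfilt(walk[mu, ], 8, highpass_hz / (fs / 2), "high")
    x <- abs(x - mean(x))
    x <- butter_sos_filtfilt(x, 5, lowpass_hz / (fs / 2), "low")
    pmax(x, 0)
  }, numeric(ncol(walk))))
  lapply(seq_along(cycles), function(i) {
    env[, ((i - 1L) * L + 1L):(i * L), drop = FALSE]
  })
}

#' Normalize envelope amplitude per muscle
#'
#' Each muscle is divided by its global maximum over all cycles of the
#' walk, so every channel lies in \[0, 1\]. A channel whose maximum is 0 is
#' left untouched, with a warning.
#'
#' @param cycles A list of envelope matrices (muscles x samples).
#' @return A list with elements `cycles` (normalized) and `maxima`
#'   (per-muscle global maxima, for traceability).
#' @export
normalize_amplitude <- function(cycles) {
  if (length(cycles) == 0) {
    abort("at least one cycle is required", class = "choosyn_domain")
  }
  maxima <- apply(do.call(cbind, cycles), 1, max)
  if (any(maxima == 0)) {
    warn(sprintf("muscle(s) %s have an all-zero envelope; left unscaled",
                 paste(which(maxima == 0), collapse = ", ")))
  }
  scale <- ifelse(maxima > 0, maxima, 1)
  list(cycles = lapply(cycles, function(cy) cy / scale), maxima = maxima)
}

#' Group normalized cycles into concatenated 10-cycle subgroups
#'
#' Consecutive, non-overlapping blocks of 10 cycles are concatenated along
#' time; with N cycles the number of subgroups is `floor(N / 10)` and any
#' leftover cycles are discarded.
#'
#' @param cycles A list of muscles x 1000 matrices (N >= 10).
#' @param per_subgroup Cycles per subgroup (default 10).
#' @return An object of class `subgroup_envelopes`: `subgroups` (list of
#'   muscles x 10,000 matrices), `n_subgroups`, and `normalization_maxima`
#'   if present on the input.
#' @export
make_subgroups <- function(cycles, per_subgroup = 10L) {
  N <- length(cycles)
  n_sub <- N %/% per_subgroup
  if (n_sub < 1L) {
    abort(sprintf("at least %d cycles are required (got %d)",
                  per_subgroup, N),
          class = "choosyn_insufficient_cycles")
  }
  subgroups <- lapply(seq_len(n_sub), function(g) {
    do.call(cbind, cycles[((g - 1L) * per_subgroup + 1L):(g * per_subgroup)])
  })
  structure(list(subgroups = subgroups, n_subgroups = n_sub),
            class = "subgroup_envelopes")
}

#' @export
print.subgroup_envelopes <- function(x, ...) {
  cat("<subgroup_envelopes> ", x$n_subgroups, " subgroups of ",
      ncol(x$subgroups[[1]]), " samples x ", nrow(x$subgroups[[1]]),
      " muscles\n", sep = "")
  invisible(x)
}

#' Full preprocessing: recording to 10-cycle subgroup envelopes
#'
#' Convenience wrapper chaining [segment_and_normalize()],
#' [envelope_pipeline()], [normalize_amplitude()] and [make_subgroups()].
#'
#' @inheritParams segment_and_normalize
#' @inheritParams envelope_pipeline
#' @return A `subgroup_envelopes` object (with `normalization_maxima`).
#' @export
preprocess_emg <- function(rec, fs = 1000) {
  cycles <- segment_and_normalize(rec)
  env <- envelope_pipeline(cycles, fs = fs)
  nrm <- normalize_amplitude(env)
  subs <- make_subgroups(nrm$cycles)
  subs$normalization_maxima <- nrm$maxima
  subs
}
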
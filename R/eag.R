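#' Multi-position EAG recording
#'
#' Container for electroantennogram voltage traces recorded consecutively
#' at several proximo-distal positions on the funiculus for one odorant
#' and one individual, with the paired control (solvent puff) traces.
#'
#' @param traces Numeric matrix (time x position) of voltages in mV, or a
#'   data frame with columns `time_s`, `v_pos0`, ..., `v_pos{N-1}`.
#' @param time_s Time base in seconds (ignored when `traces` is a data
#'   frame carrying its own `time_s` column).
#' @param sampling_rate_hz Sampling rate (default 500).
#' @param stimulus_onset_s Stimulus onset time in seconds.
#' @param stimulus_duration_s Odor puff duration (default 0.2 s).
#' @param control_traces Optional matrix (or list of matrices, averaged on
#'   use) of control traces with the same shape and time base.
#' @param odorant,individual,species Metadata labels.
#' @return An object of class `eag_recording`.
#' @export
eag_recording <- function(traces, time_s = NULL,
                          sampling_rate_hz = 500,
                          stimulus_onset_s,
                          stimulus_duration_s = 0.2,
                          control_traces = NULL,
                          odorant = NA_character_,
                          individual = NA_character_,
                          species = NA_character_) {
  if (is.data.frame(traces)) {
    if (!"time_s" %in% names(traces)) {
      stop_validation("Trace data frame must contain a `time_s` column.")
    }
    time_s <- traces$time_s
    vcols <- grep("^v_pos[0-9]+$", names(traces), value = TRUE)
    if (length(vcols) == 0L) {
      stop_validation("Trace data frame must contain `v_pos0`... columns.")
    }
    vcols <- vcols[order(as.integer(sub("^v_pos", "", vcols)))]
    traces <- as.matrix(traces[vcols])
  }
  traces <- as.matrix(traces)
  if (is.null(time_s)) {
    time_s <- (seq_len(nrow(traces)) - 1L) / sampling_rate_hz
  }
  if (length(time_s) != nrow(traces)) {
    stop_validation("`time_s` length must equal the number of samples.")
  }
  if (any(!is.finite(traces))) {
    stop_validation("Traces contain non-finite voltages.")
  }
  if (any(diff(time_s) <= 0)) {
    stop_validation("`time_s` must be strictly increasing.")
  }
  if (stimulus_onset_s - min(time_s) < 0.5 - 1e-9 ||
      max(time_s) - stimulus_onset_s < 0.5 - 1e-9) {
    stop_validation("Need >= 0.5 s of recording on both sides of stimulus onset.")
  }
  norm_ctrl <- function(ct) {
    ct <- as.matrix(ct)
    if (!all(dim(ct) == dim(traces))) {
      stop_validation("Control traces must have the same shape as the traces.")
    }
    unname(ct)
  }
  if (!is.null(control_traces)) {
    control_traces <- if (is.list(control_traces) && !is.matrix(control_traces)) {
      lapply(control_traces, norm_ctrl)
    } else {
      list(norm_ctrl(control_traces))
    }
  }
  structure(
    list(
      time_s = as.numeric(time_s),
      traces = unname(traces),
      control_traces = control_traces,
      sampling_rate_hz = sampling_rate_hz,
      stimulus_onset_s = stimulus_onset_s,
      stimulus_duration_s = stimulus_duration_s,
      odorant = odorant,
      individual = individual,
      species = species
    ),
    class = "eag_recording"
  )
}

#' @export
print.eag_recording <- function(x, ...) {
  cat(sprintf(
    "<eag_recording> %s / %s / %s: %d positions, %d samples at %g Hz, onset %g s\n",
    x$species, x$individual, x$odorant, ncol(x$traces), nrow(x$traces),
    x$sampling_rate_hz, x$stimulus_onset_s))
  invisible(x)
}

#' Zero-phase Gaussian smoothing of a voltage trace
#'
#' Convolves the trace with a unit-area Gaussian kernel (standard
#' deviation `width_s`, truncated at 4 standard deviations and
#' renormalized). Edges are handled by reflection so the pre-stimulus
#' baseline window is not distorted by onset ramps.
#'
#' @param x Numeric trace (mV), or a matrix smoothed column-wise.
#' @param width_s Kernel standard deviation in seconds (default 0.02).
#' @param sampling_rate_hz Sampling rate (default 500).
#' @return Smoothed trace, same length as the input.
#' @export
gaussian_smooth <- function(x, width_s = 0.02, sampling_rate_hz = 500) {
  check_scalar_positive(width_s, "width_s")
  if (is.matrix(x)) {
    return(apply(x, 2L, gaussian_smooth, width_s = width_s,
                 sampling_rate_hz = sampling_rate_hz))
  }
  sd_samp <- width_s * sampling_rate_hz
  half <- ceiling(4 * sd_samp)
  n <- length(x)
  if (n <= 2L * half + 1L) {
    stop_validation(
      "Trace (%d samples) is shorter than the smoothing kernel support (%d samples).",
      n, 2L * half + 1L)
  }
  kern <- stats::dnorm(seq(-half, half), sd = sd_samp)
  kern <- kern / sum(kern)
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  out <- stats::filter(padded, kern, sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Subtract the control response from an odor trace
#'
#' Elementwise difference between the odor trace and the control
#' (solvent) trace. When two control stimulations are supplied (one run
#' before and one after the odor series) their mean is subtracted.
#'
#' @param trace Numeric trace or matrix (mV).
#' @param control A control trace/matrix of the same shape, or a list of
#'   them (averaged).
#' @return The control-subtracted trace.
#' @export
subtract_control <- function(trace, control) {
  if (is.list(control) && !is.matrix(control)) {
    control <- Reduce(`+`, control) / length(control)
  }
  if (length(trace) != length(control)) {
    stop_validation("Trace and control must have the same length/shape.")
  }
  trace - control
}

#' Preprocess a recording for amplitude and CSD analysis
#'
#' Smooths every position trace and subtracts the (mean) control.
#'
#' @param recording An [eag_recording()].
#' @param width_s Smoothing kernel standard deviation (default 0.02 s).
#' @return The recording with preprocessed traces (controls dropped).
#' @export
preprocess_recording <- function(recording, width_s = 0.02) {
  if (!inherits(recording, "eag_recording")) {
    stop_validation("`recording` must be an `eag_recording`.")
  }
  tr <- gaussian_smooth(recording$traces, width_s = width_s,
                        sampling_rate_hz = recording$sampling_rate_hz)
  if (!is.null(recording$control_traces)) {
    ctrl <- Reduce(`+`, recording$control_traces) /
      length(recording$control_traces)
    ctrl <- gaussian_smooth(ctrl, width_s = width_s,
                            sampling_rate_hz = recording$sampling_rate_hz)
    tr <- subtract_control(tr, ctrl)
  }
  recording$traces <- tr
  recording$control_traces <- NULL
  recording
}

#' Signed EAG response amplitude
#'
#' The minimum of the trace in the 0.5 s following stimulus onset minus
#' the mean of the trace in the 0.5 s preceding onset. Negative for the
#' canonical negative-going EAG deflection; invariant to DC offsets.
#'
#' @param x Numeric trace (preprocessed), or a matrix (per-column result).
#' @param time_s Time base in seconds.
#' @param onset_s Stimulus onset in seconds.
#' @return Signed amplitude in mV (vector for matrix input).
#' @export
response_amplitude <- function(x, time_s, onset_s) {
  if (is.matrix(x)) {
    return(apply(x, 2L, response_amplitude, time_s = time_s,
                 onset_s = onset_s))
  }
  if (length(x) != length(time_s)) {
    stop_validation("`x` and `time_s` must have equal length.")
  }
  pre <- time_s >= onset_s - 0.5 - 1e-12 & time_s < onset_s
  post <- time_s > onset_s & time_s <= onset_s + 0.5 + 1e-12
  if (!any(pre) || !any(post) ||
      onset_s - min(time_s) < 0.5 - 1e-9 ||
      max(time_s) - onset_s < 0.5 - 1e-9) {
    stop_validation("Need >= 0.5 s of trace on both sides of the onset.")
  }
  min(x[post]) - mean(x[pre])
}

#' Per-position amplitudes of a recording
#'
#' Convenience wrapper: preprocesses the recording and returns the signed
#' response amplitude at every electrode position.
#'
#' @inheritParams preprocess_recording
#' @return A tibble with `position`, `position_norm` (when the number of
#'   positions matches a default regular layout) and `amplitude_mv`.
#' @export
eag_amplitudes <- function(recording, width_s = 0.02) {
  rec <- preprocess_recording(recording, width_s = width_s)
  amps <- response_amplitude(rec$traces, rec$time_s, rec$stimulus_onset_s)
  n <- length(amps)
  tibble::tibble(
    position = seq_len(n) - 1L,
    position_norm = seq(0, 1, length.out = n),
    amplitude_mv = amps
  )
}

#' Absolute response amplitude across positions
#'
#' The antennal sensitivity summary: maximum magnitude of the signed EAG
#' amplitudes over the recording positions. Using the maximum over
#' positions avoids the bias of a single-site EAG toward the selectivity
#' of the nearest receptor neurons.
#'
#' @param amplitudes Signed amplitudes (mV), one per position.
#' @return Scalar amplitude magnitude (mV).
#' @export
absolute_response_amplitude <- function(amplitudes) {
  if (length(amplitudes) < 1L || any(!is.finite(amplitudes))) {
    stop_validation("`amplitudes` must be a non-empty finite numeric vector.")
  }
  max(abs(amplitudes))
}

#' Normalize a panel of per-odorant amplitudes
#'
#' Divides each odorant's absolute response amplitude by the sum over the
#' odor panel, yielding per-individual response fractions that sum to 1
#' (removes inter-individual gain differences before comparative
#' analyses).
#'
#' @param x Non-negative amplitudes, one per odorant (optionally named).
#' @return Fractions summing to 1.
#' @export
normalize_panel <- function(x) {
  if (length(x) < 1L || any(!is.finite(x)) || any(x < 0)) {
    stop_validation("`x` must be non-negative finite amplitudes.")
  }
  s <- sum(x)
  if (s <= 0) {
    stop_validation("All-zero panel: normalization undefined.")
  }
  x / s
}
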
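## Electrophysiology and functional-outcome computations: CMAP amplitude,
## average SMUP, MUNE, twitch/tetanic torque, grip strength, recovery %.

#' Recorded waveform (EMG or torque trace)
#'
#' @param samples Numeric sample series (mV for EMG, mN.m for torque).
#' @param sampling_rate Sampling rate (Hz), > 0.
#' @param stimulus_times Stimulus onset times (ms from trace start).
#' @param units Unit string, for bookkeeping.
#' @return An object of class `tnt_waveform`.
#' @export
waveform <- function(samples, sampling_rate, stimulus_times = numeric(),
                     units = "") {
  if (!is.numeric(samples) || length(samples) < 2) {
    stop_input("a waveform needs at least 2 numeric samples")
  }
  check_scalar_number(sampling_rate, "sampling_rate", lower = 1e-12)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 stimulus_times = as.numeric(stimulus_times),
                 units = units),
            class = "tnt_waveform")
}

wave_time_ms <- function(w) (seq_along(w$samples) - 1) / w$sampling_rate * 1000

#' CMAP amplitude of an EMG trace
#'
#' The baseline is the mean of a pre-stimulus window. `baseline_to_peak`
#' is the largest absolute deviation from baseline within the response
#' window (the convention used for supramaximal CMAP recordings);
#' `peak_to_peak` is max minus min within the response window.
#'
#' @param w A [waveform()].
#' @param mode `"baseline_to_peak"` (default) or `"peak_to_peak"`.
#' @param baseline_window Pre-stimulus window length (ms, default 5).
#' @param response_window Post-stimulus window length (ms, default 50).
#' @return Amplitude in the waveform's units (mV for EMG).
#' @export
cmap_amplitude <- function(w, mode = c("baseline_to_peak", "peak_to_peak"),
                           baseline_window = 5, response_window = 50) {
  stopifnot(inherits(w, "tnt_waveform"))
  mode <- match.arg(mode)
  t <- wave_time_ms(w)
  stim <- if (length(w$stimulus_times) > 0) w$stimulus_times[1] else 0
  pre <- t >= (stim - baseline_window) & t < stim
  baseline <- if (any(pre)) mean(w$samples[pre]) else 0
  resp <- t >= stim & t <= stim + response_window
  if (!any(resp)) stop_input("analysis error: empty response window")
  s <- w$samples[resp]
  switch(mode,
         baseline_to_peak = max(abs(s - baseline)),
         peak_to_peak = max(s) - min(s))
}

#' Incremental-stimulation response series
#'
#' Ordered peak-to-peak response levels at increasing submaximal stimulus
#' intensity, used for single motor unit potential (SMUP) estimation. The
#' series conventionally starts at the subthreshold (zero-response) level
#' followed by `n_increments` incremental response levels.
#'
#' @param amplitudes Nondecreasing (within noise) response levels (mV).
#' @param n_increments Number of increments the series represents
#'   (default `length(amplitudes) - 1`).
#' @return An object of class `increment_series`.
#' @export
increment_series <- function(amplitudes, n_increments = length(amplitudes) - 1L) {
  if (!is.numeric(amplitudes) || length(amplitudes) < 2) {
    stop_input("analysis error: an increment series needs >= 2 response levels")
  }
  structure(list(amplitudes = as.numeric(amplitudes),
                 n_increments = as.integer(n_increments)),
            class = "increment_series")
}

#' Average single motor unit potential (SMUP)
#'
#' The average SMUP is the mean of the successive peak-to-peak amplitude
#' differences between consecutive incremental submaximal response levels
#' (10 increments by convention). Negative successive differences
#' (alternation noise) are floored at zero with a warning, keeping the
#' number of increments fixed. The telescoped form
#' `(last - first) / n` is available as an alternative and is identical
#' when no flooring occurs.
#'
#' @param series An [increment_series()] or a numeric vector of response
#'   levels.
#' @param method `"successive"` (default) or `"telescoped"`.
#' @return Average SMUP amplitude (mV).
#' @export
smup_average <- function(series, method = c("successive", "telescoped")) {
  method <- match.arg(method)
  a <- if (inherits(series, "increment_series")) series$amplitudes else
    as.numeric(series)
  if (length(a) < 2) {
    stop_input("analysis error: need at least 2 response levels")
  }
  d <- diff(a)
  if (any(d < 0)) {
    warning("negative successive increment(s) floored at 0", call. = FALSE)
    d <- pmax(d, 0)
  }
  switch(method,
         successive = mean(d),
         telescoped = (a[length(a)] - a[1]) / (length(a) - 1))
}

#' Motor unit number estimation (MUNE)
#'
#' MUNE is the maximum CMAP peak-to-peak amplitude divided by the average
#' SMUP. The real-valued ratio is returned unrounded; the nearest integer
#' is attached as attribute `"rounded"`.
#'
#' @param max_cmap_pp Maximum CMAP peak-to-peak amplitude (mV).
#' @param avg_smup Average SMUP amplitude (mV), > 0.
#' @return MUNE (dimensionless), with attribute `rounded`.
#' @export
mune <- function(max_cmap_pp, avg_smup) {
  if (!is.numeric(avg_smup) || length(avg_smup) != 1 || !is.finite(avg_smup) ||
      avg_smup <= 0) {
    stop_input("analysis error: average SMUP must be a positive number")
  }
  out <- max_cmap_pp / avg_smup
  attr(out, "rounded") <- round(out)
  out
}

#' Peak torque of a twitch or tetanic contraction
#'
#' Twitch: maximum baseline-corrected torque after a single stimulus.
#' Tetanic: maximum over the response to a 150 Hz x 1 s stimulus train;
#' the mean over the final `plateau_window` ms of the trace (the fused
#' plateau) is attached as attribute `"plateau_mean"`.
#'
#' @param w A [waveform()] of torque samples (mN.m).
#' @param kind `"twitch"` or `"tetanic"`.
#' @param plateau_window Plateau averaging window for tetanic traces (ms).
#' @return Peak torque (mN.m); tetanic results carry `plateau_mean`.
#' @export
peak_torque <- function(w, kind = c("twitch", "tetanic"),
                        plateau_window = 200) {
  stopifnot(inherits(w, "tnt_waveform"))
  kind <- match.arg(kind)
  t <- wave_time_ms(w)
  stim <- if (length(w$stimulus_times) > 0) w$stimulus_times[1] else 0
  pre <- t < stim
  baseline <- if (any(pre)) mean(w$samples[pre]) else 0
  resp <- t >= stim
  if (!any(resp)) stop_input("analysis error: empty response window")
  s <- w$samples[resp] - baseline
  peak <- max(s, 0)
  if (kind == "tetanic") {
    tail_idx <- t >= (max(t) - plateau_window)
    attr(peak, "plateau_mean") <- mean(w$samples[tail_idx] - baseline)
  }
  peak
}

#' Mean grip strength over trials
#'
#' Arithmetic mean of the trial forces; the protocol uses three trials
#' per hindlimb, so a different trial count draws a warning.
#'
#' @param trials Numeric vector of trial forces (>= 1 value).
#' @return Mean force, in the input units.
#' @export
grip_strength <- function(trials) {
  if (!is.numeric(trials) || length(trials) < 1) {
    stop_input("analysis error: grip strength needs at least one trial")
  }
  if (length(trials) != 3) {
    warning(sprintf("grip strength averaged over %d trial(s), not 3",
                    length(trials)), call. = FALSE)
  }
  mean(trials)
}

#' Functional recovery percentage
#'
#' `100 * treated / healthy`: the injured (treated) measure normalized to
#' the healthy control. Values above 100% are reported as-is. Invariant
#' under common rescaling of both inputs.
#'
#' @param treated Measure from the injured/treated side.
#' @param healthy Healthy-control measure, > 0 (recycled over `treated`).
#' @return Recovery percentage(s).
#' @export
recovery_percent <- function(treated, healthy) {
  if (!is.numeric(healthy) || any(!is.finite(healthy)) || any(healthy <= 0)) {
    stop_input("analysis error: healthy control measure must be > 0")
  }
  100 * treated / healthy
}
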
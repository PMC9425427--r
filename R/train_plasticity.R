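# Per-pulse quantification of 60-pulse train responses at -40 mV:
# normalized amplitudes, paired-pulse ratio, last/first ratio, first-pulse
# latency, slow-current flag.

#' Train response container
#'
#' @param amplitudes Per-pulse amplitudes (pA), averaged across sweeps.
#' @param first_latency Mean first-pulse onset latency (ms).
#' @param slow_current Slow-current flag (see [detect_slow_current()]).
#' @return An object of class `train_response` with fields `amplitudes`,
#'   `normalized` (amplitudes relative to the first pulse; first element is
#'   exactly 1), `ppr` (second/first), `last_first` (last/first),
#'   `first_latency`, `slow_current`.
#' @export
train_response <- function(amplitudes, first_latency = NA_real_,
                           slow_current = NA) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 2L) stop("a train response needs >= 2 pulses")
  if (amplitudes[1] <= 0) stop("first-pulse amplitude must be positive")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  normalized <- amplitudes / amplitudes[1]
  structure(list(
    amplitudes = amplitudes, normalized = normalized,
    ppr = normalized[2], last_first = normalized[length(normalized)],
    first_latency = first_latency, slow_current = slow_current
  ), class = "train_response")
}

#' @export
print.train_response <- function(x, ...) {
  cat(sprintf("<train_response> %d pulses | first %.0f pA | PPR %.2f | last/first %.2f | latency %.2f ms | slow current: %s\n",
              length(x$amplitudes), x$amplitudes[1], x$ppr, x$last_first,
              x$first_latency, x$slow_current))
  invisible(x)
}

#' Segment per-pulse oIPSC amplitudes from a train recording
#'
#' For every pulse of the 20 Hz train, the amplitude is measured relative to a
#' local baseline taken in the 2 ms immediately preceding that pulse's light
#' onset (the 10 ms decay tail of the previous IPSC has not fully settled at
#' 20 Hz, so a global baseline would bias later pulses). A pulse with no
#' detected event contributes amplitude 0 (a release failure), not a missing
#' value. Amplitudes are averaged across sweeps before normalization to the
#' first pulse.
#'
#' @param rec A -40 mV whole-cell [recording()] with a train protocol.
#' @param config A [detector_config()]; the -40 mV preset looks for outward
#'   events with a 0.5 ms monotonic rise within 5 ms of each pulse.
#' @param local_baseline_window Width of the pre-pulse local baseline (ms).
#' @return A [train_response()], or `NULL` when the first pulse evoked no
#'   event in any sweep (non-responding cell).
#' @export
segment_train_amplitudes <- function(rec, config = preset_minus40(40),
                                     local_baseline_window = 2) {
  stopifnot(inherits(rec, "recording"))
  if (rec$protocol$kind != "train") stop("protocol must be a train")
  onsets <- rec$protocol$pulse_onsets
  np <- length(onsets)
  ns <- n_sweeps(rec)
  dt <- dt_ms(rec)
  amp <- matrix(0, nrow = ns, ncol = np)
  lat1 <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    x <- rec$sweeps[s, ]
    # global pre-train noise estimate; the 2 ms local window is too short for
    # a stable MAD
    g0 <- max(1L, round((onsets[1] - config$baseline_window) / dt) + 1L)
    noise <- robust_sd(x[g0:(round(onsets[1] / dt))])
    for (p in seq_len(np)) {
      i_on <- round(onsets[p] / dt) + 1L
      lb0 <- max(1L, i_on - round(local_baseline_window / dt))
      local_base <- stats::median(x[lb0:(i_on - 1L)])
      ev <- detect_oipsc(x, onsets[p], config,
                         sampling_rate = rec$sampling_rate,
                         baseline_value = local_base, noise_sd = noise)
      if (!is.null(ev)) {
        amp[s, p] <- ev$amplitude
        if (p == 1L) lat1[s] <- ev$latency
      }
    }
  }
  mean_amp <- colMeans(amp)
  if (mean_amp[1] <= 0) return(NULL)  # non-responding cell
  train_response(mean_amp,
                 first_latency = mean(lat1, na.rm = TRUE),
                 slow_current = detect_slow_current(rec))
}

#' Paired-pulse ratio
#'
#' @param response A [train_response()].
#' @return `amplitudes[2] / amplitudes[1]`.
#' @export
compute_ppr <- function(response) {
  stopifnot(inherits(response, "train_response"))
  if (response$amplitudes[1] <= 0) stop("zero first-pulse amplitude")
  response$amplitudes[2] / response$amplitudes[1]
}

#' Detect a slow sustained current outlasting the train
#'
#' Flags cells in which the median current in the 500 ms after the last pulse
#' (taken from 25 ms after the last onset so the final fast oIPSC has decayed;
#' the median is robust to any residual brief events) deviates from the
#' pre-train baseline by more than `threshold_mult` x the baseline noise SD of
#' the sweep-averaged trace.
#'
#' @param rec A train [recording()].
#' @param window_ms Post-train analysis window (ms).
#' @param settle_ms Gap after the last pulse onset before the window starts
#'   (ms).
#' @param threshold_mult Threshold in units of the robust baseline noise SD.
#' @return `TRUE`/`FALSE`.
#' @export
detect_slow_current <- function(rec, window_ms = 500, settle_ms = 25,
                                threshold_mult = 5) {
  stopifnot(inherits(rec, "recording"))
  onsets <- rec$protocol$pulse_onsets
  dt <- dt_ms(rec)
  avg <- colMeans(rec$sweeps)
  b0 <- max(1L, round((onsets[1] - 500) / dt) + 1L)
  b1 <- round(onsets[1] / dt)
  base <- avg[b0:b1]
  base_med <- stats::median(base)
  noise <- robust_sd(base)
  p0 <- round((onsets[length(onsets)] + settle_ms) / dt) + 1L
  p1 <- min(length(avg), round((onsets[length(onsets)] + settle_ms + window_ms) / dt))
  post_med <- stats::median(avg[p0:p1])
  # 1 pA absolute floor guards the degenerate noiseless case, where any
  # residual decay tail would otherwise trip a zero threshold
  abs(post_med - base_med) > max(threshold_mult * noise, 1)
}
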
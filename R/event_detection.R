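# Detection of optogenetically evoked IPSCs in voltage-clamp sweeps, QC and
# per-cell connectivity classification.
#
# An oIPSC is a fast-onset event: a monotonic excursion of the (lightly
# smoothed) current in the configured polarity lasting `monotonic_window` ms,
# starting within `search_window` ms of the light onset, whose amplitude
# relative to the pre-stimulus baseline clears the noise floor. The -70 mV
# high-chloride configuration looks for inward events (monotonic decrease for
# 1.5 ms within 20 ms of the pulse); the -40 mV low-chloride configuration
# looks for outward events (monotonic increase for 0.5 ms within 5 ms).

#' Detector configuration
#'
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param monotonic_window Required monotonic run length (ms).
#' @param search_window Window after light onset in which the run must start
#'   (ms); must be >= `monotonic_window`.
#' @param baseline_window Pre-stimulus window used for the local baseline and
#'   robust noise estimate (ms).
#' @param min_amplitude Noise floor (pA). `NULL` (default) uses
#'   `max(5 x MAD-based noise SD of the baseline window, 5 pA)`.
#' @param smoothing_width Moving-average width used when testing monotonicity
#'   (ms). Strict sample-wise monotonicity at 10 kHz would reject real noisy
#'   events, so per-sample counter-steps up to 2.5 x the noise SD of one
#'   smoothed step are tolerated.
#' @param amplitude_window Window after event onset in which the peak is
#'   sought (ms).
#' @param peak_smoothing Moving-average width used only to locate the peak
#'   (ms). The amplitude itself is the mean of the raw samples within
#'   `peak_average/2` of that location, which keeps the estimate unbiased both
#'   on noise-free traces and at low signal-to-noise (a plain extremum is
#'   biased upward by noise selection).
#' @param peak_average Total width of the raw-sample average around the peak
#'   location (ms).
#' @return An object of class `detector_config`.
#' @seealso [preset_minus70()], [preset_minus40()]
#' @export
detector_config <- function(polarity = c("inward", "outward"),
                            monotonic_window = 1.5, search_window = 20,
                            baseline_window = 50, min_amplitude = NULL,
                            smoothing_width = 0.3, amplitude_window = 50,
                            peak_smoothing = 1, peak_average = 0.5) {
  polarity <- match.arg(polarity)
  if (monotonic_window <= 0) stop("monotonic_window must be positive")
  if (search_window < monotonic_window)
    stop("search_window must be >= monotonic_window")
  structure(list(polarity = polarity, monotonic_window = monotonic_window,
                 search_window = search_window,
                 baseline_window = baseline_window,
                 min_amplitude = min_amplitude,
                 smoothing_width = smoothing_width,
                 amplitude_window = amplitude_window,
                 peak_smoothing = peak_smoothing,
                 peak_average = peak_average),
            class = "detector_config")
}

#' @rdname detector_config
#' @export
preset_minus70 <- function() {
  detector_config("inward", monotonic_window = 1.5, search_window = 20)
}

#' @rdname detector_config
#' @param amplitude_window Extremum window (ms); the -40 mV preset uses the
#'   inter-pulse interval of the 20 Hz train.
#' @export
preset_minus40 <- function(amplitude_window = 50) {
  detector_config("outward", monotonic_window = 0.5, search_window = 5,
                  amplitude_window = amplitude_window)
}

# moving-average smoothing; edges keep the raw samples
smooth_trace <- function(x, width_ms, dt) {
  k <- max(1L, round(width_ms / dt))
  if (k <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

robust_sd <- function(x) stats::mad(x)

#' Detect an evoked IPSC after one light pulse
#'
#' Scans the `search_window` after `light_onset` for the earliest sample that
#' starts a monotonic run of length `monotonic_window` in the configured
#' polarity, evaluated on the smoothed trace: per-sample counter-steps are
#' tolerated up to 2.5 x the noise SD of one smoothed step (strict sample-wise
#' monotonicity at 10 kHz would reject real noisy events), the first step must
#' point in the event direction, and the net excursion over the run must be
#' positive and clear 3 x its own noise SD. The event amplitude is the magnitude of
#' the extremum within `amplitude_window` ms of the detected onset relative to
#' the median of the pre-stimulus `baseline_window`; candidates below the
#' noise floor are skipped. Ties (several qualifying onsets) resolve to the
#' earliest, since latency is defined from the light onset.
#'
#' @param sweep Numeric vector of current samples (pA) for one sweep.
#' @param light_onset Light onset time (ms, sweep-relative).
#' @param config A [detector_config()].
#' @param sampling_rate Sampling rate (Hz).
#' @param baseline_value,noise_sd Optional externally supplied local baseline
#'   (pA) and noise SD (pA); used by the train segmentation, which measures
#'   each pulse against the 2 ms immediately preceding it.
#' @return A one-row data frame (`onset_time`, `latency`, `peak_value`,
#'   `amplitude`) or `NULL` if no qualifying event.
#' @export
detect_oipsc <- function(sweep, light_onset, config = preset_minus70(),
                         sampling_rate = 10000, baseline_value = NULL,
                         noise_sd = NULL) {
  stopifnot(inherits(config, "detector_config"))
  dt <- 1000 / sampling_rate
  n <- length(sweep)
  i_on <- round(light_onset / dt) + 1L
  W <- max(1L, round(config$monotonic_window / dt))
  S <- round(config$search_window / dt)
  if (is.null(baseline_value)) {
    b0 <- i_on - round(config$baseline_window / dt)
    if (b0 < 1L) stop("trace does not cover the pre-stimulus baseline window")
    base_seg <- sweep[b0:(i_on - 1L)]
    baseline_value <- stats::median(base_seg)
    if (is.null(noise_sd)) noise_sd <- robust_sd(base_seg)
  } else if (is.null(noise_sd)) {
    stop("noise_sd must accompany an external baseline_value")
  }
  if (i_on + S + W > n) stop("trace too short for the search window")

  sm <- smooth_trace(sweep, config$smoothing_width, dt)
  k_s <- max(1L, round(config$smoothing_width / dt))
  # tolerances are scaled to the noise of the quantity they threshold: one
  # smoothed-sample step has SD noise*sqrt(2)/k_s, the net excursion over the
  # monotonic window has SD noise*sqrt(2/k_s)
  tol_step <- 2.5 * noise_sd * sqrt(2) / k_s
  sd_net <- noise_sd * sqrt(2 / k_s)
  d <- diff(sm)
  sign_dir <- if (config$polarity == "inward") -1 else 1
  dd <- sign_dir * d                       # steps in event direction positive
  viol <- dd < -tol_step                   # beyond-tolerance counter-steps
  cviol <- cumsum(viol)
  min_amp <- config$min_amplitude %||% max(5 * noise_sd, 5)
  A <- round(config$amplitude_window / dt)

  # candidate run starts: latency strictly > 0, within the search window
  starts <- (i_on + 1L):(i_on + S)
  run_clean <- cviol[starts + W - 1L] - cviol[starts - 1L] == 0L
  net <- sign_dir * (sm[starts + W] - sm[starts])
  net_dir <- net > 0 & net >= 3 * sd_net
  # the first step must be a real move in the event direction (1.5 x the
  # smoothed-step noise SD), not a coin-flip noise step, or starts in the
  # pre-onset noise would anchor the onset early on large events
  first_dir <- dd[starts] > 0 & dd[starts] >= 1.5 * noise_sd * sqrt(2) / k_s
  # the run must also make headway in its first third, for the same reason
  W_e <- max(2L, ceiling(W / 3))
  net_early <- sign_dir * (sm[starts + W_e] - sm[starts])
  early_ok <- net_early > 0 & net_early >= 2 * sd_net
  sm_pk <- smooth_trace(sweep, config$peak_smoothing, dt)
  h <- max(0L, round(config$peak_average / (2 * dt)))
  for (t0 in starts[run_clean & net_dir & first_dir & early_ok]) {
    win <- t0:min(n, t0 + A)
    i_pk <- win[if (config$polarity == "inward") which.min(sm_pk[win])
                else which.max(sm_pk[win])]
    avg_idx <- max(1L, i_pk - h):min(n, i_pk + h)
    peak_value <- mean(sweep[avg_idx])
    amplitude <- abs(peak_value - baseline_value)
    in_dir <- sign_dir * (peak_value - baseline_value) > 0
    if (in_dir && amplitude >= min_amp) {
      onset_time <- (t0 - 1L) * dt
      return(data.frame(onset_time = onset_time,
                        latency = onset_time - light_onset,
                        peak_value = peak_value, amplitude = amplitude))
    }
  }
  NULL
}

#' Detect oIPSCs on every sweep of a recording
#'
#' @param rec A whole-cell [recording()].
#' @param config A [detector_config()].
#' @param pulse Pulse index of the protocol to analyze (default first).
#' @return List with one element per sweep: the [detect_oipsc()] result or
#'   `NULL`.
#' @export
detect_oipsc_sweeps <- function(rec, config = preset_minus70(), pulse = 1L) {
  stopifnot(inherits(rec, "recording"))
  onset <- rec$protocol$pulse_onsets[pulse]
  lapply(seq_len(n_sweeps(rec)), function(s) {
    detect_oipsc(rec$sweeps[s, ], onset, config,
                 sampling_rate = rec$sampling_rate)
  })
}

#' Classify a cell's monosynaptic connectivity from per-sweep detections
#'
#' A cell shows an oIPSC only if events were detected in strictly more than
#' 50% of the recorded sweeps; rare sweeps where a miniature IPSC lands in the
#' detection window are thereby outvoted. Amplitude and latency are averaged
#' across the event-bearing sweeps and are `NA` for unconnected cells.
#'
#' @param detections List of per-sweep [detect_oipsc()] results (`NULL` for
#'   event-free sweeps); order-invariant.
#' @return List with `connected`, `n_sweeps`, `n_event_sweeps`,
#'   `mean_amplitude` (pA), `mean_latency` (ms).
#' @export
classify_cell_connectivity <- function(detections) {
  if (length(detections) == 0L) stop("at least one sweep is required")
  has_event <- !vapply(detections, is.null, logical(1))
  n <- length(detections)
  k <- sum(has_event)
  connected <- k / n > 0.5
  if (connected) {
    amps <- vapply(detections[has_event], function(e) e$amplitude, numeric(1))
    lats <- vapply(detections[has_event], function(e) e$latency, numeric(1))
    mean_amplitude <- mean(amps)
    mean_latency <- mean(lats)
  } else {
    mean_amplitude <- NA_real_
    mean_latency <- NA_real_
  }
  list(connected = connected, n_sweeps = n, n_event_sweeps = k,
       mean_amplitude = mean_amplitude, mean_latency = mean_latency)
}

#' QC result
#'
#' @param pass Did the cell pass?
#' @param reason `"ok"` iff `pass`; otherwise one of `"rs_too_high"`,
#'   `"rs_drift"`, `"chr2_contaminated"`, `"no_tonic_firing"`.
#' @param review Flag the cell for manual review without excluding it.
#' @return An object of class `qc_result`.
#' @export
qc_result <- function(pass, reason = if (pass) "ok" else stop("reason required"),
                      review = FALSE) {
  reason <- match.arg(reason, c("ok", "rs_too_high", "rs_drift",
                                "chr2_contaminated", "no_tonic_firing"))
  if (pass != (reason == "ok")) stop("reason must be 'ok' iff pass")
  structure(list(pass = pass, reason = reason, review = review),
            class = "qc_result")
}

#' Series-resistance quality control
#'
#' Cells with any Rs above 25 MOhm, or with more than a 30% change in Rs over
#' the recording (referenced to the first sweep), are excluded.
#'
#' @param rs_log Numeric vector of per-sweep series resistances (MOhm).
#' @param rs_max Absolute threshold (MOhm).
#' @param max_drift Maximum fractional change relative to the first sweep.
#' @return A [qc_result()].
#' @export
qc_series_resistance <- function(rs_log, rs_max = 25, max_drift = 0.30) {
  if (length(rs_log) < 1L) stop("empty Rs log")
  if (any(rs_log > rs_max)) return(qc_result(FALSE, "rs_too_high"))
  if ((max(rs_log) - min(rs_log)) / rs_log[1] > max_drift)
    return(qc_result(FALSE, "rs_drift"))
  qc_result(TRUE)
}

#' Assess whether gabazine abolished the evoked response
#'
#' After a 4 min GBZ wash-in the light stimulus is reassessed; the response is
#' `"blocked"` if the GBZ-condition recording no longer classifies as
#' connected. Cells that were not connected at baseline return
#' `"not_applicable"`.
#'
#' @param baseline,gbz [recording()] objects from the same cell and protocol.
#' @param config A [detector_config()].
#' @param pulse Pulse index to assess.
#' @return `"blocked"`, `"not_blocked"`, or `"not_applicable"`.
#' @export
assess_gbz_block <- function(baseline, gbz, config = preset_minus70(),
                             pulse = 1L) {
  if (baseline$cell_id != gbz$cell_id)
    stop("baseline and GBZ recordings come from different cells")
  if (baseline$protocol$kind != gbz$protocol$kind ||
      !isTRUE(all.equal(baseline$protocol$pulse_onsets,
                        gbz$protocol$pulse_onsets)))
    stop("protocol mismatch between baseline and GBZ recordings")
  base_cls <- classify_cell_connectivity(detect_oipsc_sweeps(baseline, config,
                                                             pulse))
  if (!base_cls$connected) return("not_applicable")
  gbz_cls <- classify_cell_connectivity(detect_oipsc_sweeps(gbz, config,
                                                            pulse))
  if (gbz_cls$connected) "not_blocked" else "blocked"
}

#' Flag opsin contamination of the recorded cell
#'
#' A cell is excluded as ChR2-contaminated when its evoked current is both
#' GBZ-insensitive and of sub-millisecond onset latency (a direct photocurrent
#' rather than a synaptic event). A GBZ-insensitive response with latency
#' >= 1 ms does not meet the exclusion rule but is flagged for review.
#'
#' @param classification Result of [classify_cell_connectivity()] on the
#'   baseline recording.
#' @param gbz_status Result of [assess_gbz_block()].
#' @return A [qc_result()].
#' @export
exclude_chr2_contamination <- function(classification, gbz_status) {
  if (identical(gbz_status, "not_blocked")) {
    if (isTRUE(classification$mean_latency < 1))
      return(qc_result(FALSE, "chr2_contaminated"))
    return(qc_result(TRUE, review = TRUE))
  }
  qc_result(TRUE)
}
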
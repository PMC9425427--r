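# Loose-seal spike detection, dopamine-identity waveform check, and the
# 2-SD tonic-firing suppression classification.

#' Spike train detected from one loose-seal sweep
#'
#' @param spike_times Strictly increasing spike times (ms) with at least a
#'   2 ms refractory gap between consecutive spikes.
#' @param waveform_total_duration Mean total spike-waveform duration (ms), or
#'   `NA` when no waveform could be measured.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, waveform_total_duration = NA_real_) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1L) {
    if (is.unsorted(spike_times, strictly = TRUE))
      stop("spike_times must be strictly increasing")
    if (any(diff(spike_times) < 2))
      stop("spike_times violate the 2 ms refractory gap")
  }
  structure(list(spike_times = spike_times,
                 waveform_total_duration = waveform_total_duration,
                 n_spikes = length(spike_times)),
            class = "spike_train")
}

#' Detect spikes in a loose-seal sweep
#'
#' Band-passes the trace (default 100-2000 Hz, 2nd-order Butterworth, applied
#' forward-backward for zero phase), thresholds at `threshold_mult` x the
#' MAD-based noise SD of the filtered trace, and takes each suprathreshold
#' excursion's extremum as a spike time, enforcing a 2 ms refractory period
#' (the larger excursion wins). The waveform total duration is measured on the
#' unfiltered spike-triggered average as the span where the absolute signal
#' exceeds 10% of its peak.
#'
#' @param sweep Numeric vector of current samples (pA).
#' @param sampling_rate Sampling rate (Hz).
#' @param band Band-pass corner frequencies (Hz).
#' @param threshold_mult Detection threshold in units of the robust noise SD.
#' @param refractory Minimum spacing between spikes (ms).
#' @param snippet_halfwidth Half-width of the waveform snippet (ms).
#' @return A [spike_train()].
#' @export
detect_spikes <- function(sweep, sampling_rate = 10000, band = c(100, 2000),
                          threshold_mult = 6, refractory = 2,
                          snippet_halfwidth = 5) {
  if (length(sweep) < 10L) stop("trace too short for spike detection")
  dt <- 1000 / sampling_rate
  bf <- signal::butter(2, band / (sampling_rate / 2), type = "pass")
  bp <- signal::filtfilt(bf, sweep)
  # 1 pA absolute floor keeps the threshold meaningful on noiseless traces,
  # where the MAD of the filtered trace collapses toward zero
  thr <- max(threshold_mult * stats::mad(bp), 1)
  if (!any(abs(bp) > thr)) return(spike_train(numeric(0)))
  above <- abs(bp) > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  peak_idx <- vapply(keep, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(abs(bp[seg]))]
  }, integer(1))
  peak_amp <- abs(bp[peak_idx])

  # drop excursions far smaller than the typical detected one: band-pass
  # ringing after a genuine spike can re-cross a low threshold
  ref_amp <- stats::quantile(peak_amp, 0.9, names = FALSE)
  ok_amp <- peak_amp >= 0.25 * ref_amp
  peak_idx <- peak_idx[ok_amp]
  peak_amp <- peak_amp[ok_amp]

  # refractory: scan in time order, keep the larger of two close excursions
  ord <- order(peak_idx)
  peak_idx <- peak_idx[ord]; peak_amp <- peak_amp[ord]
  ref_samp <- refractory / dt
  kept <- integer(0)
  for (i in seq_along(peak_idx)) {
    if (length(kept) && peak_idx[i] - kept[length(kept)] < ref_samp) {
      if (peak_amp[i] > abs(bp[kept[length(kept)]]))
        kept[length(kept)] <- peak_idx[i]
    } else kept <- c(kept, peak_idx[i])
  }

  # spike-triggered average of the raw trace, for the waveform-width measure
  hw <- round(snippet_halfwidth / dt)
  ok <- kept - hw >= 1L & kept + hw <= length(sweep)
  dur <- NA_real_
  if (any(ok)) {
    snips <- vapply(kept[ok], function(i) sweep[(i - hw):(i + hw)],
                    numeric(2L * hw + 1L))
    w <- rowMeans(matrix(snips, nrow = 2L * hw + 1L))
    w <- w - stats::median(w[c(1:3, (length(w) - 2):length(w))])
    big <- which(abs(w) > 0.1 * max(abs(w)))
    dur <- (max(big) - min(big) + 1L) * dt
  }
  spike_train((kept - 1L) * dt, waveform_total_duration = dur)
}

#' Dopamine-identity waveform check
#'
#' Dopamine neurons have wide extracellular action-potential waveforms; a cell
#' passes iff its mean spike total duration strictly exceeds 2 ms.
#'
#' @param train A [spike_train()] with at least 5 spikes.
#' @return `TRUE`/`FALSE`.
#' @export
check_da_waveform <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$n_spikes < 5L)
    stop("waveform check requires at least 5 spikes")
  isTRUE(train$waveform_total_duration > 2)
}

#' Per-sweep firing rates around the light train
#'
#' The baseline rate is the spike count in the 3 s before the train start
#' divided by 3; the during rate is the count in the 3 s train window divided
#' by 3. Mean and SD are taken across sweeps.
#'
#' @param trains List of per-sweep [spike_train()] objects.
#' @param protocol A train [stimulus_protocol()] (3 s at 20 Hz by default).
#' @return An object of class `firing_rates`: `per_sweep_baseline`,
#'   `per_sweep_during` (Hz), `baseline_mean`, `baseline_sd`, `during_mean`,
#'   and `max_baseline_gap` (ms, the longest spike-free stretch of any
#'   baseline window, used by the tonic-firing QC).
#' @export
compute_rates <- function(trains, protocol) {
  if (protocol$kind != "train") stop("protocol must be a train")
  if (length(trains) < 1L) stop("at least one sweep is required")
  stim_start <- protocol$pulse_onsets[1]
  win_ms <- protocol$train_duration * 1000
  if (stim_start < win_ms)
    stop("sweep does not cover the baseline window before the train")
  base <- vapply(trains, function(tr) {
    sum(tr$spike_times >= stim_start - win_ms & tr$spike_times < stim_start)
  }, numeric(1)) / (win_ms / 1000)
  during <- vapply(trains, function(tr) {
    sum(tr$spike_times >= stim_start & tr$spike_times < stim_start + win_ms)
  }, numeric(1)) / (win_ms / 1000)
  gap <- vapply(trains, function(tr) {
    st <- tr$spike_times[tr$spike_times >= stim_start - win_ms &
                           tr$spike_times < stim_start]
    max(diff(c(stim_start - win_ms, st, stim_start)))
  }, numeric(1))
  structure(list(
    per_sweep_baseline = base, per_sweep_during = during,
    baseline_mean = mean(base),
    baseline_sd = if (length(base) > 1L) stats::sd(base) else NA_real_,
    during_mean = mean(during), max_baseline_gap = max(gap)
  ), class = "firing_rates")
}

#' Classify suppression of tonic firing
#'
#' A cell is suppressed iff the mean firing rate during the light train is
#' strictly below the baseline mean minus 2 SDs of the per-sweep baseline
#' rates (the mean +/- 2 SD band of the baseline rate).
#'
#' @param rates A [compute_rates()] result over at least 2 sweeps.
#' @return `TRUE`/`FALSE`, or `NA` when the SD is undefined (single sweep;
#'   the cell is not classifiable).
#' @export
classify_suppression <- function(rates) {
  stopifnot(inherits(rates, "firing_rates"))
  if (is.na(rates$baseline_sd)) return(NA)
  rates$during_mean < rates$baseline_mean - 2 * rates$baseline_sd
}

#' Tonic-firing quality control
#'
#' Cells that do not display tonic pacemaker firing are excluded: baseline
#' mean below `min_rate` (default 0.5 Hz) or any baseline window with a
#' spike-free gap longer than `max_gap` (default 2 s).
#'
#' @param rates A [compute_rates()] result.
#' @param min_rate Minimum baseline rate (Hz).
#' @param max_gap Maximum tolerated spike-free baseline gap (ms).
#' @return A [qc_result()].
#' @export
qc_tonic_firing <- function(rates, min_rate = 0.5, max_gap = 2000) {
  stopifnot(inherits(rates, "firing_rates"))
  if (rates$baseline_mean < min_rate || rates$max_baseline_gap > max_gap)
    return(qc_result(FALSE, "no_tonic_firing"))
  qc_result(TRUE)
}

#' Flag GBZ-insensitive light-evoked excitation
#'
#' Opsin-expressing cells show light-evoked excitation that gabazine does not
#' abolish. The cell is excluded iff the during-train rate exceeds the
#' baseline mean + 2 SD band in both the baseline and the GBZ condition.
#'
#' @param rates_baseline,rates_gbz [compute_rates()] results for the two
#'   conditions; `rates_gbz = NULL` means the GBZ condition was not recorded
#'   and the cell passes (not applicable).
#' @return A [qc_result()].
#' @export
exclude_light_evoked_excitation <- function(rates_baseline, rates_gbz) {
  stopifnot(inherits(rates_baseline, "firing_rates"))
  if (is.null(rates_gbz)) return(qc_result(TRUE))
  excited <- function(r) {
    !is.na(r$baseline_sd) &&
      r$during_mean > r$baseline_mean + 2 * r$baseline_sd
  }
  if (excited(rates_baseline) && excited(rates_gbz))
    return(qc_result(FALSE, "chr2_contaminated"))
  qc_result(TRUE)
}
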
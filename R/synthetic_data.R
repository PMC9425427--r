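# Synthetic patch-clamp recording generator with known ground truth.
#
# Emulates the two recording configurations the analysis is defined on:
# whole-cell voltage clamp (light-evoked biexponential IPSCs, Poisson
# miniature IPSCs, Gaussian noise) and loose-seal spike recordings (tonic
# pacemaker firing with low-CV ISIs, multiplicative rate suppression during
# the light train, biphasic spike waveforms).

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' IPSC kinetics parameters
#'
#' Biexponential rise/decay time constants and onset latency statistics for
#' simulated light-evoked IPSCs. Defaults (0.8 ms rise, 10 ms decay, 2 ms mean
#' latency, 0.2 ms jitter) produce the fast-rise, short-latency events the
#' detector is defined on.
#'
#' @param rise_tau,decay_tau Rise/decay time constants (ms), `0 < rise < decay`.
#' @param latency_mean Mean onset latency after light onset (ms).
#' @param latency_jitter_sd Per-event latency jitter SD (ms).
#' @return An object of class `ipsc_kinetics`.
#' @export
ipsc_kinetics <- function(rise_tau = 0.8, decay_tau = 10, latency_mean = 2,
                          latency_jitter_sd = 0.2) {
  if (!(rise_tau > 0 && decay_tau > rise_tau))
    stop("require 0 < rise_tau < decay_tau")
  if (latency_mean <= 0) stop("latency_mean must be positive")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 latency_mean = latency_mean,
                 latency_jitter_sd = latency_jitter_sd),
            class = "ipsc_kinetics")
}

# default per-pulse scale factors: modest depression to a ~0.45 plateau
default_depression_profile <- function(n_pulses = 60) {
  0.45 + 0.55 * exp(-(seq_len(n_pulses) - 1) / 3)
}

#' Per-cell simulation specification
#'
#' Ground truth for every quantity the pipeline estimates from one cell.
#'
#' @param connected Does the cell receive a light-evoked GABAergic input?
#' @param ipsc_amplitude True first-pulse IPSC peak magnitude (pA).
#' @param kinetics An [ipsc_kinetics()] object.
#' @param release_probability Per-pulse release probability in `[0, 1]`.
#' @param depression_profile Multiplicative per-pulse scale factors (first
#'   element must be exactly 1; all positive).
#' @param gbz_blocks Does gabazine abolish the evoked response? (`FALSE`
#'   models opsin-contaminated cells whose evoked current is GBZ-insensitive.)
#' @param chr2_contaminated Does the recorded cell itself express the opsin,
#'   producing a GBZ-insensitive short-latency (<1 ms) photocurrent and
#'   time-locked spikes?
#' @param baseline_rate Tonic firing rate (Hz).
#' @param isi_cv Coefficient of variation of the inter-spike interval.
#' @param suppression_factor Multiplicative rate scale in `[0, 1]` applied
#'   during the light train (0 = complete silencing, 1 = no effect).
#' @param spike_total_duration Total duration of the extracellular spike
#'   waveform (ms).
#' @param mini_rate Miniature IPSC rate (Hz).
#' @param mini_amplitude_range Range of mini amplitudes (pA).
#' @param noise_sd Gaussian recording noise SD (pA), whole-cell mode.
#' @param ls_noise_sd Gaussian noise SD (pA), loose-seal mode.
#' @param spike_amplitude Peak loose-seal spike current (pA).
#' @param location Atlas-relative (AP, ML, DV) triple (mm).
#' @return An object of class `sim_cell_spec`.
#' @export
sim_cell_spec <- function(connected = TRUE, ipsc_amplitude = 1200,
                          kinetics = ipsc_kinetics(),
                          release_probability = 1,
                          depression_profile = default_depression_profile(),
                          gbz_blocks = TRUE, chr2_contaminated = FALSE,
                          baseline_rate = 4, isi_cv = 0.1,
                          suppression_factor = 1,
                          spike_total_duration = 2.5,
                          mini_rate = 2, mini_amplitude_range = c(20, 60),
                          noise_sd = 10, ls_noise_sd = 4,
                          spike_amplitude = 100,
                          location = c(-3.1, 1.4, -4.3)) {
  if (release_probability < 0 || release_probability > 1)
    stop("release_probability must lie in [0, 1]")
  if (suppression_factor < 0 || suppression_factor > 1)
    stop("suppression_factor must lie in [0, 1]")
  if (abs(depression_profile[1] - 1) > 1e-12)
    stop("depression_profile[1] must equal 1")
  if (any(depression_profile <= 0))
    stop("depression_profile factors must be positive")
  if (isi_cv <= 0) stop("isi_cv must be positive")
  if (baseline_rate < 0) stop("baseline_rate must be non-negative")
  stopifnot(inherits(kinetics, "ipsc_kinetics"))
  structure(list(
    connected = connected, ipsc_amplitude = ipsc_amplitude,
    kinetics = kinetics, release_probability = release_probability,
    depression_profile = depression_profile, gbz_blocks = gbz_blocks,
    chr2_contaminated = chr2_contaminated, baseline_rate = baseline_rate,
    isi_cv = isi_cv, suppression_factor = suppression_factor,
    spike_total_duration = spike_total_duration, mini_rate = mini_rate,
    mini_amplitude_range = mini_amplitude_range, noise_sd = noise_sd,
    ls_noise_sd = ls_noise_sd, spike_amplitude = spike_amplitude,
    location = location
  ), class = "sim_cell_spec")
}

# Biexponential kernel sampled on the sweep grid, onset at sample `onset_idx`,
# scaled so the sampled peak magnitude equals `amp` exactly.
add_biexp_event <- function(trace, onset_idx, amp, sign, rise, decay, dt) {
  n <- length(trace)
  if (onset_idx > n) return(trace)
  idx <- onset_idx:n
  t_rel <- (idx - onset_idx) * dt
  kern <- exp(-t_rel / decay) - exp(-t_rel / rise)
  pk <- max(kern)
  if (pk <= 0) return(trace)
  trace[idx] <- trace[idx] + sign * amp * kern / pk
  trace
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Per light pulse, with probability `release_probability`, adds a
#' biexponential IPSC whose sampled peak magnitude equals
#' `ipsc_amplitude * depression_profile[pulse]`, onset at light onset +
#' latency (mean + Gaussian jitter, quantized to the sample grid, never below
#' one sample period). Sign follows the holding potential: inward (negative)
#' at -70 mV high-chloride, outward (positive) at -40 mV low-chloride.
#' Poisson miniature IPSCs and white Gaussian noise are superimposed. With
#' `gbz = TRUE`, GABAergic currents (evoked IPSCs where `gbz_blocks`, and all
#' minis) are removed; opsin-contaminated cells instead receive a
#' GBZ-insensitive inward photocurrent with <1 ms latency on every pulse.
#'
#' @param spec A [sim_cell_spec()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param n_sweeps Number of sweeps.
#' @param holding_potential -70 or -40 (mV).
#' @param gbz Simulate the gabazine wash-in condition?
#' @param sweep_length_ms Sweep duration (ms); default covers the last pulse
#'   plus 600 ms.
#' @param cell_id Cell identifier for the returned [recording()].
#' @param rs_base First-sweep series resistance (MOhm); per-sweep values get
#'   small Gaussian jitter.
#' @return A [recording()] in `whole_cell_vc` mode.
#' @export
simulate_vc_recording <- function(spec, protocol, seed = NULL, n_sweeps = 10,
                                  holding_potential = -70, gbz = FALSE,
                                  sweep_length_ms = NULL, cell_id = "sim",
                                  rs_base = 15) {
  stopifnot(inherits(spec, "sim_cell_spec"))
  k <- spec$kinetics
  fs <- 10000
  dt <- 1000 / fs
  if (is.null(sweep_length_ms))
    sweep_length_ms <- max(protocol$pulse_onsets) + 600
  n <- round(sweep_length_ms / dt) + 1L
  sgn <- if (holding_potential <= -55) -1 else 1
  n_pulses <- length(protocol$pulse_onsets)
  profile <- spec$depression_profile
  if (length(profile) < n_pulses)
    stop("depression_profile shorter than the pulse train")
  with_seed(seed, {
    sweeps <- matrix(0, nrow = n_sweeps, ncol = n)
    for (s in seq_len(n_sweeps)) {
      tr <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd)
            else numeric(n)
      evoked_present <- spec$connected && !(gbz && spec$gbz_blocks)
      if (evoked_present) {
        for (p in seq_len(n_pulses)) {
          if (stats::runif(1) > spec$release_probability) next
          lat <- k$latency_mean +
            if (k$latency_jitter_sd > 0) stats::rnorm(1, 0, k$latency_jitter_sd) else 0
          lat <- max(dt, round(lat / dt) * dt)
          onset_idx <- round((protocol$pulse_onsets[p] + lat) / dt) + 1L
          tr <- add_biexp_event(tr, onset_idx,
                                spec$ipsc_amplitude * profile[p], sgn,
                                k$rise_tau, k$decay_tau, dt)
        }
      }
      if (spec$chr2_contaminated) {
        # direct photocurrent: GBZ-insensitive, inward, latency < 1 ms, with
        # the sustained time course of an opsin current under a 5 ms pulse
        for (p in seq_len(n_pulses)) {
          onset_idx <- round((protocol$pulse_onsets[p] + 0.5) / dt) + 1L
          tr <- add_biexp_event(tr, onset_idx, 500, -1, 0.2, 20, dt)
        }
      }
      if (spec$mini_rate > 0 && !gbz) {
        n_mini <- stats::rpois(1, spec$mini_rate * sweep_length_ms / 1000)
        if (n_mini > 0) {
          times <- stats::runif(n_mini, 0, sweep_length_ms)
          amps <- stats::runif(n_mini, spec$mini_amplitude_range[1],
                               spec$mini_amplitude_range[2])
          for (m in seq_len(n_mini)) {
            tr <- add_biexp_event(tr, round(times[m] / dt) + 1L, amps[m],
                                  sgn, k$rise_tau, k$decay_tau, dt)
          }
        }
      }
      sweeps[s, ] <- tr
    }
    rs_log <- rs_base + stats::rnorm(n_sweeps, 0, 0.3)
    pharm <- c("TTX_4AP", "NBQX_AP5", if (gbz) "GBZ")
    recording(cell_id = cell_id, mode = "whole_cell_vc", sweeps = sweeps,
              protocol = protocol, holding_potential = holding_potential,
              pharmacology = pharm, rs_log = rs_log)
  })
}

# Truncated-Gaussian ISI spike times over [0, total_ms] via time rescaling:
# the integrated-rate map compresses the train window by `factor`, so the
# ISI process stays stationary while the instantaneous rate scales.
sim_spike_times <- function(rate_hz, cv, total_ms, window = NULL, factor = 1) {
  if (rate_hz <= 0) return(numeric(0))
  mu <- 1000 / rate_hz
  warped_total <- if (is.null(window)) total_ms else {
    total_ms - (window[2] - window[1]) * (1 - factor)
  }
  n_draw <- ceiling(warped_total / mu * 1.6) + 25L
  isi <- pmax(stats::rnorm(n_draw, mu, cv * mu), 2)
  tau <- cumsum(isi)
  while (tau[length(tau)] < warped_total) {
    isi2 <- pmax(stats::rnorm(n_draw, mu, cv * mu), 2)
    tau <- c(tau, tau[length(tau)] + cumsum(isi2))
  }
  tau <- tau[tau <= warped_total]
  if (is.null(window)) return(tau)
  t0 <- window[1]; t1 <- window[2]
  w_end <- t0 + factor * (t1 - t0)   # warped time at window end
  t <- tau
  inside <- tau > t0 & tau <= w_end
  after <- tau > w_end
  if (factor > 0) t[inside] <- t0 + (tau[inside] - t0) / factor
  t[after] <- t1 + (tau[after] - w_end)
  sort(t)
}

# Biphasic extracellular spike template of total duration D: one sine cycle
# with the repolarizing lobe at half amplitude, so the dominant first lobe
# gives an unambiguous alignment point.
render_spikes <- function(trace, spike_times_ms, amp, duration_ms, dt) {
  n_template <- max(3L, round(duration_ms / dt))
  tt <- seq_len(n_template) * dt
  template <- amp * sin(2 * pi * tt / duration_ms)
  template[tt > duration_ms / 2] <- 0.5 * template[tt > duration_ms / 2]
  n <- length(trace)
  for (st in spike_times_ms) {
    i0 <- round(st / dt) + 1L
    idx <- i0:min(n, i0 + n_template - 1L)
    if (idx[1] > n || idx[1] < 1L) next
    trace[idx] <- trace[idx] + template[seq_along(idx)]
  }
  trace
}

#' Simulate a loose-seal spike recording
#'
#' Tonic pacemaker spiking from a truncated-Gaussian ISI process (mean
#' `1/baseline_rate`, CV `isi_cv`, 2 ms refractory floor). During the light
#' train window the instantaneous rate is multiplied by `suppression_factor`,
#' implemented by ISI rescaling inside the window so the point process stays
#' stationary. Each spike is rendered as a biphasic (single sine cycle)
#' waveform of total duration `spike_total_duration`; Gaussian noise of SD
#' `ls_noise_sd` is added. Opsin-contaminated cells receive one extra
#' time-locked spike per light pulse (GBZ-insensitive). With `gbz = TRUE` the
#' GABAergic suppression is absent (factor forced to 1).
#'
#' @inheritParams simulate_vc_recording
#' @param sweep_length_ms Sweep duration (ms); default covers the train plus a
#'   200 ms tail.
#' @return A [recording()] in `loose_seal` mode.
#' @export
simulate_loose_seal_recording <- function(spec, protocol, seed = NULL,
                                          n_sweeps = 10, gbz = FALSE,
                                          sweep_length_ms = NULL,
                                          cell_id = "sim") {
  stopifnot(inherits(spec, "sim_cell_spec"))
  fs <- 10000
  dt <- 1000 / fs
  if (is.null(sweep_length_ms)) {
    tail_ms <- if (protocol$kind == "train") 200 else 600
    sweep_length_ms <- max(protocol$pulse_onsets) + tail_ms
  }
  n <- round(sweep_length_ms / dt) + 1L
  window <- if (protocol$kind == "train") {
    c(protocol$pulse_onsets[1],
      protocol$pulse_onsets[1] + protocol$train_duration * 1000)
  }
  factor <- if (gbz) 1 else spec$suppression_factor
  with_seed(seed, {
    sweeps <- matrix(0, nrow = n_sweeps, ncol = n)
    for (s in seq_len(n_sweeps)) {
      tr <- if (spec$ls_noise_sd > 0) stats::rnorm(n, 0, spec$ls_noise_sd)
            else numeric(n)
      st <- sim_spike_times(spec$baseline_rate, spec$isi_cv, sweep_length_ms,
                            window = window, factor = factor)
      if (spec$chr2_contaminated)
        st <- sort(c(st, protocol$pulse_onsets + 1))
      tr <- render_spikes(tr, st, spec$spike_amplitude,
                          spec$spike_total_duration, dt)
      sweeps[s, ] <- tr
    }
    pharm <- c("NBQX_AP5", if (gbz) "GBZ")
    recording(cell_id = cell_id, mode = "loose_seal", sweeps = sweeps,
              protocol = protocol, pharmacology = pharm)
  })
}

#' Cohort simulation specification
#'
#' Parameterizes one circuit's cohort: the number of cells, the connection
#' and suppression probabilities (or explicit per-cell truth vectors for
#' fixture cohorts), the cohort-level lognormal amplitude distribution, and
#' the 3-D Gaussian cell-location distribution.
#'
#' @param circuit Circuit configuration (see [cell_record()]).
#' @param n_cells Number of cells (>= 1).
#' @param p_connected Probability a cell is connected.
#' @param p_suppressed_given_connected Probability a connected cell's tonic
#'   firing is suppressed by the train.
#' @param amplitude_meanlog,amplitude_sdlog Lognormal parameters for the true
#'   IPSC amplitude (pA); defaults give a ~1.2 nA median spanning ~0.2-4.5 nA.
#' @param amplitude_range Truncation range for amplitude draws (pA).
#' @param location_mean,location_sd Mean and SD of the per-circuit (AP, ML,
#'   DV) Gaussian (mm).
#' @param connected_truth,suppressed_truth Optional logical vectors of length
#'   `n_cells` fixing the per-cell ground truth (fixture mode); when supplied
#'   they override the probabilities.
#' @param seed Integer seed.
#' @param n_sweeps Sweeps per recording.
#' @param modality `"whole_cell"`, `"loose_seal"`, or `"both"`.
#' @param include_train Also simulate the -40 mV train-protocol recording.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(circuit, n_cells, p_connected = 0.6,
                        p_suppressed_given_connected = 0.7,
                        amplitude_meanlog = log(1200), amplitude_sdlog = 0.65,
                        amplitude_range = c(200, 4500),
                        location_mean = c(-3.1, 1.4, -4.3),
                        location_sd = c(0.25, 0.25, 0.2),
                        connected_truth = NULL, suppressed_truth = NULL,
                        seed = 1, n_sweeps = 10,
                        modality = c("both", "whole_cell", "loose_seal"),
                        include_train = FALSE) {
  circuit <- match.arg(circuit, CIRCUITS)
  modality <- match.arg(modality)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (any(c(p_connected, p_suppressed_given_connected) < 0) ||
      any(c(p_connected, p_suppressed_given_connected) > 1))
    stop("probabilities must lie in [0, 1]")
  if (!is.null(connected_truth) && length(connected_truth) != n_cells)
    stop("connected_truth must have length n_cells")
  if (!is.null(suppressed_truth) && length(suppressed_truth) != n_cells)
    stop("suppressed_truth must have length n_cells")
  structure(list(
    circuit = circuit, n_cells = n_cells, p_connected = p_connected,
    p_suppressed_given_connected = p_suppressed_given_connected,
    amplitude_meanlog = amplitude_meanlog, amplitude_sdlog = amplitude_sdlog,
    amplitude_range = amplitude_range, location_mean = location_mean,
    location_sd = location_sd, connected_truth = connected_truth,
    suppressed_truth = suppressed_truth, seed = seed, n_sweeps = n_sweeps,
    modality = modality, include_train = include_train
  ), class = "cohort_spec")
}

#' Simulate a whole cohort with ground truth
#'
#' Draws per-cell ground truth from the cohort spec (or uses the explicit
#' truth vectors in fixture mode), simulates the recordings each cell carries
#' (whole-cell single-pulse at -70 mV with a GBZ condition for connected
#' cells, loose-seal 20 Hz/3 s train, optionally the -40 mV train protocol),
#' and returns the cells together with a ground-truth table.
#'
#' @param cohort A [cohort_spec()].
#' @return List with `cells` (list of [cell_record()]) and `truth` (tibble:
#'   one row per cell with every simulated ground-truth quantity).
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  with_seed(cohort$seed, {
    nc <- cohort$n_cells
    connected <- if (!is.null(cohort$connected_truth))
      as.logical(cohort$connected_truth)
    else stats::runif(nc) < cohort$p_connected
    suppressed <- if (!is.null(cohort$suppressed_truth))
      as.logical(cohort$suppressed_truth)
    else connected & (stats::runif(nc) < cohort$p_suppressed_given_connected)
    amp <- pmin(pmax(stats::rlnorm(nc, cohort$amplitude_meanlog,
                                   cohort$amplitude_sdlog),
                     cohort$amplitude_range[1]), cohort$amplitude_range[2])
    rate <- stats::runif(nc, 2, 6)
    lat <- stats::runif(nc, 1.2, 3)
    loc <- cbind(stats::rnorm(nc, cohort$location_mean[1], cohort$location_sd[1]),
                 stats::rnorm(nc, cohort$location_mean[2], cohort$location_sd[2]),
                 stats::rnorm(nc, cohort$location_mean[3], cohort$location_sd[3]))
    cell_seeds <- sample.int(1e8, nc)

    cells <- vector("list", nc)
    for (i in seq_len(nc)) {
      id <- sprintf("%s_%03d", cohort$circuit, i)
      spec <- sim_cell_spec(
        connected = connected[i], ipsc_amplitude = amp[i],
        kinetics = ipsc_kinetics(latency_mean = lat[i]),
        baseline_rate = rate[i],
        suppression_factor = if (suppressed[i]) 0 else 1,
        location = loc[i, ]
      )
      recs <- list()
      if (cohort$modality %in% c("both", "whole_cell")) {
        sp <- single_pulse_protocol()
        recs$vc_baseline <- simulate_vc_recording(
          spec, sp, seed = cell_seeds[i], n_sweeps = cohort$n_sweeps,
          cell_id = id)
        if (connected[i])
          recs$vc_gbz <- simulate_vc_recording(
            spec, sp, seed = cell_seeds[i] + 1L, n_sweeps = cohort$n_sweeps,
            gbz = TRUE, cell_id = id)
      }
      if (cohort$modality %in% c("both", "loose_seal")) {
        tp <- train_protocol(start = 3000)
        recs$ls_baseline <- simulate_loose_seal_recording(
          spec, tp, seed = cell_seeds[i] + 2L, n_sweeps = cohort$n_sweeps,
          cell_id = id)
        if (spec$chr2_contaminated)
          recs$ls_gbz <- simulate_loose_seal_recording(
            spec, tp, seed = cell_seeds[i] + 3L, n_sweeps = cohort$n_sweeps,
            gbz = TRUE, cell_id = id)
      }
      if (cohort$include_train) {
        tp40 <- train_protocol(start = 500)
        recs$train_baseline <- simulate_vc_recording(
          spec, tp40, seed = cell_seeds[i] + 4L, n_sweeps = cohort$n_sweeps,
          holding_potential = -40, cell_id = id)
      }
      cells[[i]] <- cell_record(id, cohort$circuit, loc[i, ], recs)
    }
    truth <- tibble::tibble(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      circuit = cohort$circuit,
      connected = connected, suppressed = suppressed,
      ipsc_amplitude_pA = amp, onset_latency_ms = lat,
      baseline_rate_hz = rate,
      suppression_factor = ifelse(suppressed, 0, 1),
      gbz_blocks = TRUE, chr2_contaminated = FALSE,
      AP = loc[, 1], ML = loc[, 2], DV = loc[, 3]
    )
    list(cells = cells, truth = truth)
  })
}

#' Write a simulated cohort to a dataset directory
#'
#' Serializes the cells with [write_dataset()] and the ground truth as a
#' `ground_truth.csv` sidecar (ignored by [read_dataset()]).
#'
#' @param sim Result of [simulate_cohort()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sim, path) {
  write_dataset(sim$cells, path)
  utils::write.csv(as.data.frame(sim$truth),
                   file.path(path, "ground_truth.csv"), row.names = FALSE)
  invisible(path)
}
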
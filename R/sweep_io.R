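# Data model and serialization for sweep-organized slice recordings.
#
# Unit conventions, fixed package-wide: current in pA, time in ms, voltage in
# mV, resistance in MOhm. Inward current is negative (standard voltage-clamp
# sign convention). Each sweep starts at t = 0 ms and light onsets are
# sweep-relative. Cohort report tables convert amplitudes to nA.

CIRCUITS <- c("SNr_to_DLSproj", "SNr_to_DMSproj", "DLS_loop", "DMS_loop",
              "ascending_spiral", "descending_spiral")
PROJECTION_TARGETS <- c("DLS", "DMS")
RECORDING_MODES <- c("whole_cell_vc", "loose_seal")
PHARMACOLOGY <- c("TTX_4AP", "NBQX_AP5", "GBZ")

# projection target implied by each circuit configuration (the recorded cell)
CIRCUIT_PROJECTION <- c(
  SNr_to_DLSproj = "DLS", SNr_to_DMSproj = "DMS",
  DLS_loop = "DLS", DMS_loop = "DMS",
  ascending_spiral = "DLS", descending_spiral = "DMS"
)

#' Stimulus protocol for optogenetic stimulation
#'
#' Describes the light stimulus delivered in every sweep of a recording:
#' either a single pulse or a train. Defaults follow common slice-CRACM
#' practice: 5 ms pulses, trains at 20 Hz for 3 s (60 pulses), nominal
#' irradiance ~10 mW/mm^2.
#'
#' @param kind `"single_pulse"` or `"train"`.
#' @param pulse_onsets Numeric vector of sweep-relative light onset times (ms),
#'   strictly increasing. A single-pulse protocol has exactly one onset; train
#'   onsets must be spaced by `1000/train_frequency` ms to within one sample
#'   period at 10 kHz.
#' @param pulse_width Light pulse width (ms).
#' @param train_frequency Train rate (Hz); required for `kind = "train"`.
#' @param train_duration Train duration (s); required for `kind = "train"`.
#' @param nominal_irradiance Light intensity at the slice (mW/mm^2), metadata
#'   only.
#' @return An object of class `stimulus_protocol`.
#' @seealso [single_pulse_protocol()], [train_protocol()]
#' @export
stimulus_protocol <- function(kind, pulse_onsets, pulse_width = 5,
                              train_frequency = NULL, train_duration = NULL,
                              nominal_irradiance = 10) {
  kind <- match.arg(kind, c("single_pulse", "train"))
  pulse_onsets <- as.numeric(pulse_onsets)
  if (length(pulse_onsets) < 1L || any(!is.finite(pulse_onsets)))
    stop("pulse_onsets must be finite times (ms)")
  if (is.unsorted(pulse_onsets, strictly = TRUE))
    stop("pulse_onsets must be strictly increasing")
  if (pulse_width <= 0) stop("pulse_width must be positive")
  if (kind == "single_pulse") {
    if (length(pulse_onsets) != 1L)
      stop("single_pulse protocol must have exactly one onset")
  } else {
    if (is.null(train_frequency) || is.null(train_duration))
      stop("train protocol requires train_frequency and train_duration")
    ipi <- 1000 / train_frequency
    gaps <- diff(pulse_onsets)
    if (length(gaps) && any(abs(gaps - ipi) > 0.1 + 1e-9))
      stop("train onsets must be spaced by 1/train_frequency (within one sample period)")
  }
  structure(list(
    kind = kind, pulse_width = pulse_width, pulse_onsets = pulse_onsets,
    train_frequency = train_frequency, train_duration = train_duration,
    nominal_irradiance = nominal_irradiance
  ), class = "stimulus_protocol")
}

#' @param onset Light onset time within the sweep (ms).
#' @rdname stimulus_protocol
#' @export
single_pulse_protocol <- function(onset = 100, pulse_width = 5) {
  stimulus_protocol("single_pulse", pulse_onsets = onset,
                    pulse_width = pulse_width)
}

#' @param start Train start time within the sweep (ms).
#' @param frequency Train rate (Hz).
#' @param duration Train duration (s).
#' @rdname stimulus_protocol
#' @export
train_protocol <- function(start = 3000, frequency = 20, duration = 3,
                           pulse_width = 5) {
  n_pulses <- round(frequency * duration)
  onsets <- start + (seq_len(n_pulses) - 1) * 1000 / frequency
  stimulus_protocol("train", pulse_onsets = onsets, pulse_width = pulse_width,
                    train_frequency = frequency, train_duration = duration)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$kind == "single_pulse") {
    cat(sprintf("<stimulus_protocol> single %g ms pulse at %g ms\n",
                x$pulse_width, x$pulse_onsets[1]))
  } else {
    cat(sprintf("<stimulus_protocol> train: %g Hz for %g s (%d x %g ms pulses from %g ms)\n",
                x$train_frequency, x$train_duration, length(x$pulse_onsets),
                x$pulse_width, x$pulse_onsets[1]))
  }
  invisible(x)
}

#' One cell x one protocol recording
#'
#' Sweep-organized current recording: a matrix of current samples (pA), one
#' row per sweep, plus stimulus and acquisition metadata. Whole-cell
#' voltage-clamp recordings carry a per-sweep series-resistance log; loose-seal
#' recordings carry neither `rs_log` nor a holding potential.
#'
#' @param cell_id Cell identifier (character).
#' @param mode `"whole_cell_vc"` or `"loose_seal"`.
#' @param sweeps Numeric matrix of current samples (pA), one row per sweep;
#'   all sweeps equal length by construction.
#' @param protocol A [stimulus_protocol()].
#' @param sampling_rate Acquisition rate (Hz), default 10 kHz.
#' @param holding_potential Holding potential (mV; -70 or -40); `NULL` for
#'   loose seal.
#' @param sweep_interval Interval between sweep starts (s), default 30 s.
#' @param pharmacology Character subset of `c("TTX_4AP", "NBQX_AP5", "GBZ")`.
#' @param rs_log Series resistance per sweep (MOhm), whole-cell only.
#' @return An object of class `recording`.
#' @export
recording <- function(cell_id, mode, sweeps, protocol, sampling_rate = 10000,
                      holding_potential = NULL, sweep_interval = 30,
                      pharmacology = character(), rs_log = NULL) {
  mode <- match.arg(mode, RECORDING_MODES)
  if (!is.matrix(sweeps)) sweeps <- matrix(sweeps, nrow = 1)
  storage.mode(sweeps) <- "double"
  if (nrow(sweeps) < 1L) stop("recording needs at least one sweep")
  if (!inherits(protocol, "stimulus_protocol"))
    stop("protocol must be a stimulus_protocol")
  if (length(pharmacology) && !all(pharmacology %in% PHARMACOLOGY))
    stop("unknown pharmacology value for cell ", cell_id)
  if (mode == "loose_seal") {
    if (!is.null(rs_log))
      stop("loose-seal recordings carry no rs_log (cell ", cell_id, ")")
    holding_potential <- NULL
  } else {
    if (!is.null(rs_log) && length(rs_log) != nrow(sweeps))
      stop("rs_log must have one value per sweep (cell ", cell_id, ")")
  }
  sweep_ms <- (ncol(sweeps) - 1) * 1000 / sampling_rate
  if (max(protocol$pulse_onsets) > sweep_ms)
    stop("protocol onsets extend past the sweep for cell ", cell_id)
  structure(list(
    cell_id = as.character(cell_id), mode = mode,
    holding_potential = holding_potential, sampling_rate = sampling_rate,
    sweeps = sweeps, sweep_interval = sweep_interval, protocol = protocol,
    pharmacology = sort(pharmacology), rs_log = rs_log
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> cell %s | %s | %d sweeps x %d samples @ %g kHz\n",
              x$cell_id, x$mode, nrow(x$sweeps), ncol(x$sweeps),
              x$sampling_rate / 1000))
  print(x$protocol)
  invisible(x)
}

n_sweeps <- function(rec) nrow(rec$sweeps)

# sample period in ms
dt_ms <- function(rec_or_rate) {
  if (inherits(rec_or_rate, "recording")) 1000 / rec_or_rate$sampling_rate
  else 1000 / rec_or_rate
}

#' Per-cell record: metadata plus recordings keyed by condition
#'
#' @param cell_id Cell identifier.
#' @param circuit Circuit configuration, one of
#'   `"SNr_to_DLSproj"`, `"SNr_to_DMSproj"`, `"DLS_loop"`, `"DMS_loop"`,
#'   `"ascending_spiral"`, `"descending_spiral"`.
#' @param location Numeric triple, atlas-relative (AP, ML, DV) in mm.
#' @param recordings Named list of [recording()] objects. Recognized keys:
#'   `vc_baseline`, `vc_gbz` (whole-cell voltage clamp, before/after gabazine),
#'   `ls_baseline`, `ls_gbz` (loose seal), `train_baseline`, `train_gbz`
#'   (-40 mV train protocol).
#' @param projection_target `"DLS"` or `"DMS"`; defaults to the target implied
#'   by `circuit` and must be consistent with it.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(cell_id, circuit, location, recordings = list(),
                        projection_target = NULL) {
  circuit <- match.arg(circuit, CIRCUITS)
  implied <- unname(CIRCUIT_PROJECTION[circuit])
  if (is.null(projection_target)) projection_target <- implied
  projection_target <- match.arg(projection_target, PROJECTION_TARGETS)
  if (projection_target != implied)
    stop("circuit ", circuit, " implies projection_target ", implied,
         " (cell ", cell_id, ")")
  location <- as.numeric(location)
  if (length(location) != 3L || any(!is.finite(location)))
    stop("location must be a finite (AP, ML, DV) triple (cell ", cell_id, ")")
  if (length(recordings)) {
    if (is.null(names(recordings)) || any(names(recordings) == ""))
      stop("recordings must be a named list (cell ", cell_id, ")")
    ok <- vapply(recordings, inherits, logical(1), what = "recording")
    if (!all(ok)) stop("recordings must be recording objects (cell ",
                       cell_id, ")")
  }
  structure(list(
    cell_id = as.character(cell_id), circuit = circuit,
    projection_target = projection_target,
    location = stats::setNames(location, c("AP", "ML", "DV")),
    recordings = recordings
  ), class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s | %s -> %s | AP %.2f ML %.2f DV %.2f | %d recording(s): %s\n",
              x$cell_id, x$circuit, x$projection_target,
              x$location[1], x$location[2], x$location[3],
              length(x$recordings), paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dataset serialization: JSON manifest + one CSV trace file per recording.
# Traces: column time_ms then sweep_1..sweep_n, full double precision.

trace_file_name <- function(cell_id, condition) {
  paste0(gsub("[^A-Za-z0-9_.-]", "_", cell_id), "__", condition, ".csv")
}

write_trace_csv <- function(rec, path) {
  n <- ncol(rec$sweeps)
  tab <- cbind(time_ms = (seq_len(n) - 1) * dt_ms(rec), t(rec$sweeps))
  colnames(tab) <- c("time_ms", paste0("sweep_", seq_len(nrow(rec$sweeps))))
  utils::write.csv(format(as.data.frame(tab), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

read_trace_csv <- function(path, cell_id) {
  if (!file.exists(path))
    stop("missing trace file for cell ", cell_id, ": ", basename(path))
  tab <- utils::read.csv(path, check.names = FALSE)
  sweep_cols <- grep("^sweep_", names(tab))
  if (!length(sweep_cols)) stop("no sweep columns in ", basename(path))
  sweeps <- t(as.matrix(tab[, sweep_cols, drop = FALSE]))
  if (any(!is.finite(sweeps)))
    stop("sweep-length mismatch or non-finite samples for cell ", cell_id,
         " in ", basename(path))
  sweeps
}

protocol_to_list <- function(p) {
  list(kind = p$kind, pulse_width = p$pulse_width,
       pulse_onsets = p$pulse_onsets, train_frequency = p$train_frequency,
       train_duration = p$train_duration,
       nominal_irradiance = p$nominal_irradiance)
}

protocol_from_list <- function(l) {
  stimulus_protocol(l$kind, pulse_onsets = unlist(l$pulse_onsets),
                    pulse_width = l$pulse_width,
                    train_frequency = l$train_frequency,
                    train_duration = l$train_duration,
                    nominal_irradiance = l$nominal_irradiance %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset of cell records to disk
#'
#' Lays out a directory with `manifest.json` (cells, recordings, protocols,
#' pharmacology, series-resistance logs) and one CSV trace file per recording
#' under `traces/`. [read_dataset()] on the result reproduces the input:
#' bit-exact metadata, traces within float round-trip (<= 1e-6 pA).
#'
#' @param records List of [cell_record()] objects.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  if (inherits(records, "cell_record")) records <- list(records)
  dir.create(file.path(path, "traces"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create dataset directory ", path)
  manifest <- list(format = "cracm-dataset", version = 1L, cells = list())
  for (cell in records) {
    stopifnot(inherits(cell, "cell_record"))
    recs <- list()
    for (cond in names(cell$recordings)) {
      rec <- cell$recordings[[cond]]
      fn <- trace_file_name(cell$cell_id, cond)
      write_trace_csv(rec, file.path(path, "traces", fn))
      recs[[cond]] <- list(
        mode = rec$mode, holding_potential = rec$holding_potential,
        sampling_rate = rec$sampling_rate, sweep_interval = rec$sweep_interval,
        n_sweeps = nrow(rec$sweeps), pharmacology = as.list(rec$pharmacology),
        rs_log = rec$rs_log, protocol = protocol_to_list(rec$protocol),
        trace_file = fn
      )
    }
    manifest$cells[[length(manifest$cells) + 1L]] <- list(
      cell_id = cell$cell_id, circuit = cell$circuit,
      projection_target = cell$projection_target,
      location = as.list(cell$location), recordings = recs
    )
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset of cell records from disk
#'
#' Loads and fully validates a directory written by [write_dataset()] (or by
#' [simulate_cohort()]'s writer). Every structural invariant is enforced on
#' load: equal-length sweeps, known enum values, protocol consistency, no
#' rs_log on loose-seal recordings. A `ground_truth.csv` sidecar, if present,
#' is ignored. Loading never silently drops sweeps or cells.
#'
#' @param path Dataset directory containing `manifest.json`.
#' @return List of [cell_record()] objects.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf)
  lapply(manifest$cells, function(cl) {
    recs <- list()
    for (cond in names(cl$recordings)) {
      rl <- cl$recordings[[cond]]
      sweeps <- read_trace_csv(file.path(path, "traces", rl$trace_file),
                               cl$cell_id)
      if (!is.null(rl$n_sweeps) && nrow(sweeps) != rl$n_sweeps)
        stop("sweep count mismatch for cell ", cl$cell_id, " (", cond, ")")
      recs[[cond]] <- recording(
        cell_id = cl$cell_id, mode = rl$mode, sweeps = sweeps,
        protocol = protocol_from_list(rl$protocol),
        sampling_rate = rl$sampling_rate,
        holding_potential = rl$holding_potential,
        sweep_interval = rl$sweep_interval %||% 30,
        pharmacology = unlist(rl$pharmacology) %||% character(),
        rs_log = if (!is.null(rl$rs_log)) unlist(rl$rs_log)
      )
    }
    cell_record(cl$cell_id, cl$circuit, unlist(cl$location), recs,
                projection_target = cl$projection_target)
  })
}

#' Write a results table to CSV
#'
#' One row per cell (or per circuit) in a delimited table with a stable
#' column order: the columns of `results` are written in their existing
#' order, after moving `cell_id`/`circuit` first when present.
#'
#' @param results A data frame (per-cell results or a cohort summary).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  results <- as.data.frame(results)
  lead <- intersect(c("cell_id", "circuit"), names(results))
  results <- results[, c(lead, setdiff(names(results), lead)), drop = FALSE]
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
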
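# Orchestration: simulate/load -> detect -> firing -> train -> cohort, as one
# reproducible, seeded run.

#' Analyze one cell end to end
#'
#' Applies every per-cell stage that the cell's recordings support:
#' series-resistance QC and oIPSC connectivity classification on the
#' whole-cell recording (with GBZ block assessment and opsin-contamination
#' exclusion when a GBZ condition exists), spike detection, waveform check,
#' tonic-firing QC and the 2-SD suppression call on the loose-seal recording
#' (with GBZ-insensitive excitation exclusion when applicable), and train
#' segmentation (PPR, last/first, slow current) on the -40 mV train
#' recording. Cells failing a QC rule have the corresponding classification
#' set to `NA` and carry the exclusion reason.
#'
#' @param cell A [cell_record()].
#' @param detector [detector_config()] for the -70 mV single-pulse assay.
#' @param train_detector [detector_config()] for the -40 mV train assay.
#' @return One-row tibble of per-cell results.
#' @export
analyze_cell <- function(cell, detector = preset_minus70(),
                         train_detector = preset_minus40(40)) {
  stopifnot(inherits(cell, "cell_record"))
  out <- tibble::tibble(
    cell_id = cell$cell_id, circuit = cell$circuit,
    projection_target = cell$projection_target,
    AP = cell$location[["AP"]], ML = cell$location[["ML"]],
    DV = cell$location[["DV"]],
    rs_qc = NA_character_, connected = NA, n_sweeps = NA_integer_,
    n_event_sweeps = NA_integer_, mean_amplitude_pA = NA_real_,
    mean_latency_ms = NA_real_, gbz_status = NA_character_,
    excluded = FALSE, exclusion_reason = NA_character_,
    da_waveform = NA, spike_duration_ms = NA_real_,
    baseline_rate_hz = NA_real_, baseline_rate_sd = NA_real_,
    during_rate_hz = NA_real_, tonic_qc = NA_character_, suppressed = NA,
    responding_train = NA, ppr = NA_real_, last_first = NA_real_,
    first_latency_ms = NA_real_, slow_current = NA
  )
  recs <- cell$recordings

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for cell ", cell$cell_id, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(recs$vc_baseline)) stage("detect", {
    vc <- recs$vc_baseline
    rs <- if (!is.null(vc$rs_log)) qc_series_resistance(vc$rs_log)
          else qc_result(TRUE)
    out$rs_qc <- rs$reason
    if (rs$pass) {
      cls <- classify_cell_connectivity(detect_oipsc_sweeps(vc, detector))
      out$connected <- cls$connected
      out$n_sweeps <- cls$n_sweeps
      out$n_event_sweeps <- cls$n_event_sweeps
      out$mean_amplitude_pA <- cls$mean_amplitude
      out$mean_latency_ms <- cls$mean_latency
      if (!is.null(recs$vc_gbz)) {
        out$gbz_status <- assess_gbz_block(vc, recs$vc_gbz, detector)
        chr2 <- exclude_chr2_contamination(cls, out$gbz_status)
        if (!chr2$pass) {
          out$excluded <- TRUE
          out$exclusion_reason <- chr2$reason
          out$connected <- NA
        }
      }
    } else {
      out$excluded <- TRUE
      out$exclusion_reason <- rs$reason
    }
  })

  if (!is.null(recs$ls_baseline)) stage("firing", {
    ls <- recs$ls_baseline
    trains <- lapply(seq_len(n_sweeps(ls)), function(s)
      detect_spikes(ls$sweeps[s, ], sampling_rate = ls$sampling_rate))
    all_times <- unlist(lapply(trains, `[[`, "spike_times"))
    durs <- vapply(trains, `[[`, numeric(1), "waveform_total_duration")
    out$spike_duration_ms <- mean(durs, na.rm = TRUE)
    if (length(all_times) >= 5L)
      out$da_waveform <- isTRUE(out$spike_duration_ms > 2)
    rates <- compute_rates(trains, ls$protocol)
    out$baseline_rate_hz <- rates$baseline_mean
    out$baseline_rate_sd <- rates$baseline_sd
    out$during_rate_hz <- rates$during_mean
    tonic <- qc_tonic_firing(rates)
    out$tonic_qc <- tonic$reason
    rates_gbz <- if (!is.null(recs$ls_gbz)) {
      trains_gbz <- lapply(seq_len(n_sweeps(recs$ls_gbz)), function(s)
        detect_spikes(recs$ls_gbz$sweeps[s, ],
                      sampling_rate = recs$ls_gbz$sampling_rate))
      compute_rates(trains_gbz, recs$ls_gbz$protocol)
    }
    excit <- exclude_light_evoked_excitation(rates, rates_gbz)
    if (!tonic$pass || !excit$pass) {
      out$excluded <- TRUE
      out$exclusion_reason <- if (!tonic$pass) tonic$reason else excit$reason
    } else {
      out$suppressed <- classify_suppression(rates)
    }
  })

  if (!is.null(recs$train_baseline)) stage("train", {
    tr <- segment_train_amplitudes(recs$train_baseline, train_detector)
    out$responding_train <- !is.null(tr)
    if (!is.null(tr)) {
      out$ppr <- tr$ppr
      out$last_first <- tr$last_first
      out$first_latency_ms <- tr$first_latency
      out$slow_current <- tr$slow_current
    }
  })

  out
}

#' Analyze a list of cells
#'
#' @param cells List of [cell_record()] objects.
#' @inheritParams analyze_cell
#' @return Tibble with one row per cell ([analyze_cell()] output).
#' @export
analyze_cells <- function(cells, detector = preset_minus70(),
                          train_detector = preset_minus40(40)) {
  if (length(cells) == 0L) stop("empty dataset: no cells to analyze")
  do.call(rbind, lapply(cells, analyze_cell, detector = detector,
                        train_detector = train_detector))
}

#' Pipeline run configuration
#'
#' Bundles everything a reproducible run needs. Either `dataset_path` (a
#' directory readable by [read_dataset()]) or `cohorts` (a list of
#' [cohort_spec()] objects to simulate) must be given. Tunable defaults equal
#' the assay's standard values: -70 mV preset (inward, 1.5 ms monotonic run,
#' 20 ms search), -40 mV preset (outward, 0.5 ms, 5 ms), FDR rate q = 0.05.
#'
#' @param dataset_path Optional dataset directory.
#' @param cohorts Optional list of [cohort_spec()] objects.
#' @param seed Integer master seed for simulated cohorts.
#' @param q Target FDR for cross-circuit comparisons.
#' @param detector,train_detector Detector configurations.
#' @param output_dir Optional directory for result tables and the run
#'   manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dataset_path = NULL, cohorts = NULL, seed = 1,
                       q = 0.05, detector = preset_minus70(),
                       train_detector = preset_minus40(40),
                       output_dir = NULL) {
  if (is.null(dataset_path) && is.null(cohorts))
    stop("either dataset_path or cohorts must be supplied")
  if (!is.null(cohorts)) {
    if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
    stopifnot(all(vapply(cohorts, inherits, logical(1), "cohort_spec")))
  }
  structure(list(dataset_path = dataset_path, cohorts = cohorts, seed = seed,
                 q = q, detector = detector, train_detector = train_detector,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the dataset, analyzes every cell, summarizes each
#' circuit, and runs the cross-circuit statistics: Kruskal-Wallis on oIPSC
#' amplitudes and latencies over connected cells with pairwise post-hoc
#' comparisons under two-stage FDR control, and per-circuit location
#' regression where both classes are present. Identical config and seed give
#' identical outputs. When `output_dir` is set, writes `cell_results.csv`,
#' `cohort_summary.csv`, `comparisons.csv`, `location_regression.csv` and a
#' JSON `run_manifest.json` (config echo, seed, package version).
#'
#' @param config A [run_config()].
#' @return List with `cell_results`, `cohort_summary`, `comparisons`,
#'   `location_regression`, `truth` (simulated runs only), and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$cohorts)) {
    sims <- lapply(seq_along(config$cohorts), function(i) {
      spec <- config$cohorts[[i]]
      spec$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
      simulate_cohort(spec)
    })
    cells <- unlist(lapply(sims, `[[`, "cells"), recursive = FALSE)
    truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  } else {
    cells <- read_dataset(config$dataset_path)
  }
  if (length(cells) == 0L) stop("empty dataset: no cells to analyze")

  cell_results <- analyze_cells(cells, config$detector, config$train_detector)
  included <- cell_results[!cell_results$excluded, , drop = FALSE]
  if (nrow(included) == 0L) stop("all cells excluded by QC")

  summaries <- do.call(rbind, lapply(split(included, included$circuit),
                                     summarize_cohort))

  # cross-circuit comparisons over connected cells
  comparisons <- NULL
  conn <- included[!is.na(included$connected) & included$connected, ,
                   drop = FALSE]
  for (meas in c("mean_amplitude_pA", "mean_latency_ms")) {
    groups <- split(conn[[meas]], conn$circuit)
    groups <- groups[vapply(groups, length, integer(1)) > 0L]
    if (length(groups) >= 2L) {
      kw <- kruskal_wallis(groups)
      ph <- pairwise_posthoc(groups, q = config$q)
      comparisons <- rbind(comparisons, tibble::tibble(
        measure = meas, test = "Kruskal-Wallis", group1 = NA, group2 = NA,
        statistic = kw$statistic, p_value = kw$p_value, discovery = NA
      ), tibble::tibble(
        measure = meas, test = "Wilcoxon (BKY FDR)", group1 = ph$group1,
        group2 = ph$group2, statistic = ph$statistic, p_value = ph$p_value,
        discovery = ph$discovery
      ))
    }
  }

  # per-circuit location regression where feasible
  loc_reg <- NULL
  for (circ in unique(included$circuit)) {
    sub <- included[included$circuit == circ & !is.na(included$connected), ,
                    drop = FALSE]
    if (nrow(sub) >= 10L && length(unique(sub$connected)) == 2L) {
      reg <- suppressWarnings(location_connection_regression(
        sub[, c("AP", "ML", "DV")], sub$connected))
      loc_reg <- rbind(loc_reg, tibble::tibble(
        circuit = circ, term = reg$coefficients$term,
        estimate = reg$coefficients$estimate,
        std_error = reg$coefficients$std_error,
        p_value = reg$coefficients$p_value,
        lr_p_value = reg$lr_p_value, separation = reg$separation,
        n = reg$n
      ))
    }
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(cell_results,
                        file.path(config$output_dir, "cell_results.csv"))
    write_results_table(summaries,
                        file.path(config$output_dir, "cohort_summary.csv"))
    if (!is.null(comparisons))
      write_results_table(comparisons,
                          file.path(config$output_dir, "comparisons.csv"))
    if (!is.null(loc_reg))
      write_results_table(loc_reg,
                          file.path(config$output_dir,
                                    "location_regression.csv"))
    manifest <- list(
      package = "cracm",
      version = as.character(utils::packageVersion("cracm")),
      seed = config$seed, q = config$q,
      n_cells = length(cells),
      simulated = !is.null(config$cohorts),
      dataset_path = config$dataset_path
    )
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(cell_results = cell_results, cohort_summary = summaries,
       comparisons = comparisons, location_regression = loc_reg,
       truth = truth, output_dir = config$output_dir)
}
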
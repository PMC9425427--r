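test_that("unconnected noiseless cells give flat zero sweeps", {
  spec <- sim_cell_spec(connected = FALSE, noise_sd = 0, mini_rate = 0)
  rec <- simulate_vc_recording(spec, single_pulse_protocol(), seed = 1,
                               n_sweeps = 5)
  expect_true(all(rec$sweeps == 0))
  expect_identical(dim(rec$sweeps), c(5L, 7001L))
})

test_that("noiseless evoked events match ground truth exactly", {
  rec <- simulate_vc_recording(clean_spec(500, 2), single_pulse_protocol(100),
                               seed = 1, n_sweeps = 5)
  for (s in 1:5) {
    sweep <- rec$sweeps[s, ]
    expect_lt(abs(max(abs(sweep)) - 500), 0.1)   # peak equals ground truth
    expect_true(all(sweep <= 0))                 # inward at -70 mV
    # first departure from zero is one sample after onset + latency
    expect_equal(which(sweep != 0)[1], round((100 + 2) / 0.1) + 2)
  }
  # outward polarity at -40 mV
  rec40 <- simulate_vc_recording(clean_spec(500, 2), single_pulse_protocol(100),
                                 seed = 1, n_sweeps = 2,
                                 holding_potential = -40)
  expect_true(all(rec40$sweeps >= 0))
  expect_lt(abs(max(rec40$sweeps[1, ]) - 500), 0.1)
})

test_that("geometric depression produces closed-form per-pulse peaks", {
  spec <- clean_spec(1000, 2, depression_profile = 0.9^(0:59))
  rec <- simulate_vc_recording(spec, train_protocol(start = 500), seed = 2,
                               n_sweeps = 1, holding_potential = -40)
  onsets <- rec$protocol$pulse_onsets
  sweep <- rec$sweeps[1, ]
  for (k in c(1, 2, 5, 10, 20)) {
    i0 <- round(onsets[k] / 0.1) + 1
    win <- i0:(i0 + 499)
    local_base <- sweep[i0]   # residual tail of preceding pulses
    peak <- max(sweep[win]) - local_base
    expect_equal(peak, 1000 * 0.9^(k - 1), tolerance = 0.01)
  }
})

test_that("latency jitter never places an event before one sample period", {
  spec <- sim_cell_spec(TRUE, 500,
                        ipsc_kinetics(latency_mean = 0.05,
                                      latency_jitter_sd = 0.3),
                        noise_sd = 0, mini_rate = 0)
  rec <- simulate_vc_recording(spec, single_pulse_protocol(100), seed = 3,
                               n_sweeps = 10)
  i_on <- round(100 / 0.1) + 1
  for (s in 1:10) {
    first <- which(rec$sweeps[s, ] != 0)[1]
    expect_gte(first, i_on + 2)  # onset >= light onset + 1 sample
  }
})

test_that("loose-seal spike counts track rate and suppression ground truth", {
  tp <- train_protocol(start = 3000)
  # factor 0: ~12 baseline spikes, none during the train
  base_counts <- c(); during_counts <- c()
  for (i in 1:20) {
    spec <- sim_cell_spec(baseline_rate = 4, isi_cv = 0.1,
                          suppression_factor = 0, ls_noise_sd = 0)
    rec <- simulate_loose_seal_recording(spec, tp, seed = 100 + i,
                                         n_sweeps = 1)
    tr <- detect_spikes(rec$sweeps[1, ])
    base_counts <- c(base_counts, sum(tr$spike_times < 3000))
    during_counts <- c(during_counts,
                       sum(tr$spike_times >= 3000 & tr$spike_times < 6000))
  }
  expect_equal(mean(base_counts), 12, tolerance = 0.15)
  expect_lte(mean(during_counts), 0.3)

  # factor 1: during rate statistically equal to baseline
  diffs <- vapply(1:20, function(i) {
    spec <- sim_cell_spec(baseline_rate = 4, isi_cv = 0.1,
                          suppression_factor = 1, ls_noise_sd = 0)
    rec <- simulate_loose_seal_recording(spec, tp, seed = 200 + i,
                                         n_sweeps = 1)
    tr <- detect_spikes(rec$sweeps[1, ])
    (sum(tr$spike_times >= 3000 & tr$spike_times < 6000) -
        sum(tr$spike_times < 3000)) / 3
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 0.15)

  # zero rate: no spikes at all
  quiet <- simulate_loose_seal_recording(
    sim_cell_spec(baseline_rate = 0, ls_noise_sd = 0), tp, seed = 5,
    n_sweeps = 1)
  expect_true(all(quiet$sweeps == 0))
})

test_that("identical spec and seed give bit-identical recordings", {
  spec <- sim_cell_spec(baseline_rate = 4)
  tp <- train_protocol(start = 3000)
  a <- simulate_loose_seal_recording(spec, tp, seed = 77, n_sweeps = 3)
  b <- simulate_loose_seal_recording(spec, tp, seed = 77, n_sweeps = 3)
  expect_identical(a$sweeps, b$sweeps)
  c <- simulate_loose_seal_recording(spec, tp, seed = 78, n_sweeps = 3)
  expect_false(identical(a$sweeps, c$sweeps))

  v1 <- simulate_vc_recording(spec, single_pulse_protocol(), seed = 9,
                              n_sweeps = 3)
  v2 <- simulate_vc_recording(spec, single_pulse_protocol(), seed = 9,
                              n_sweeps = 3)
  expect_identical(v1$sweeps, v2$sweeps)
})

test_that("cohort simulation honours truth vectors and probabilities", {
  fix <- simulate_cohort(cohort_spec(
    "SNr_to_DLSproj", 26, connected_truth = rep(c(TRUE, FALSE), c(18, 8)),
    seed = 1, n_sweeps = 5, modality = "whole_cell"))
  expect_length(fix$cells, 26)
  expect_equal(sum(fix$truth$connected), 18)
  # connected cells carry a GBZ condition, unconnected do not
  expect_true(all(vapply(fix$cells[1:18], function(cl)
    "vc_gbz" %in% names(cl$recordings), logical(1))))
  expect_false(any(vapply(fix$cells[19:26], function(cl)
    "vc_gbz" %in% names(cl$recordings), logical(1))))

  none <- simulate_cohort(cohort_spec("DMS_loop", 8, p_connected = 0,
                                      seed = 2, n_sweeps = 5,
                                      modality = "whole_cell"))
  expect_false(any(none$truth$connected))

  # empirical connected fraction within 3 SE of p under Bernoulli sampling
  big <- simulate_cohort(cohort_spec("DLS_loop", 200, p_connected = 0.5,
                                     seed = 3, n_sweeps = 5,
                                     modality = "whole_cell"))
  expect_lt(abs(mean(big$truth$connected) - 0.5), 3 * sqrt(0.25 / 200))

  expect_error(cohort_spec("DLS_loop", 5, connected_truth = c(TRUE, FALSE)),
               "length n_cells")
  expect_error(cohort_spec("DLS_loop", 0), "n_cells")
  expect_error(cohort_spec("DLS_loop", 5, p_connected = 1.2), "\\[0, 1\\]")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(sim_cell_spec(release_probability = 1.5), "\\[0, 1\\]")
  expect_error(sim_cell_spec(suppression_factor = -0.1), "\\[0, 1\\]")
  expect_error(sim_cell_spec(depression_profile = c(0.9, 0.8)), "equal 1")
  expect_error(sim_cell_spec(depression_profile = c(1, -0.1)), "positive")
  expect_error(sim_cell_spec(isi_cv = 0), "positive")
  expect_error(ipsc_kinetics(rise_tau = 10, decay_tau = 5), "rise_tau")
})
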
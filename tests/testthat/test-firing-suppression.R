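test_that("spike detection recovers counts and waveform width", {
  expect_equal(detect_spikes(rnorm(30000, 0, 4))$n_spikes, 0)
  expect_error(detect_spikes(numeric(0)), "short")

  tp <- train_protocol(start = 3000)
  # near-regular 4 Hz pacemaker: 12 +- 1 baseline spikes per 3 s window
  for (i in 1:5) {
    spec <- sim_cell_spec(baseline_rate = 4, isi_cv = 0.01,
                          suppression_factor = 1)
    rec <- simulate_loose_seal_recording(spec, tp, seed = 500 + i,
                                         n_sweeps = 1)
    tr <- detect_spikes(rec$sweeps[1, ])
    expect_gte(sum(tr$spike_times < 3000), 11)
    expect_lte(sum(tr$spike_times < 3000), 13)
    expect_equal(tr$waveform_total_duration, 2.5, tolerance = 0.3 / 2.5)
    expect_true(all(diff(tr$spike_times) >= 2))
  }
  # a narrower simulated waveform is measured as narrower
  narrow <- simulate_loose_seal_recording(
    sim_cell_spec(baseline_rate = 4, spike_total_duration = 1.2), tp,
    seed = 52, n_sweeps = 1)
  expect_lt(detect_spikes(narrow$sweeps[1, ])$waveform_total_duration, 2)
})

test_that("the dopamine waveform criterion is a strict 2 ms boundary", {
  five <- seq(0, 40, by = 10)
  expect_true(check_da_waveform(spike_train(five, 2.5)))
  expect_false(check_da_waveform(spike_train(five, 2.0)))
  expect_false(check_da_waveform(spike_train(five, 1.2)))
  expect_error(check_da_waveform(spike_train(c(0, 10), 2.5)), "at least 5")
  expect_error(spike_train(c(10, 5)), "strictly increasing")
  expect_error(spike_train(c(10, 11)), "refractory")
})

test_that("rate computation does the window arithmetic", {
  tp <- train_protocol(start = 3000)
  r <- compute_rates(list(make_train(12, 0)), tp)
  expect_equal(r$baseline_mean, 4)
  expect_equal(r$during_mean, 0)
  expect_true(is.na(r$baseline_sd))   # single sweep

  r3 <- compute_rates(replicate(3, make_train(12, 6), simplify = FALSE), tp)
  expect_equal(r3$baseline_sd, 0)     # identical sweeps
  expect_equal(r3$during_mean, 2)

  expect_error(compute_rates(list(make_train(12, 0)),
                             train_protocol(start = 1000)), "baseline window")
  expect_error(compute_rates(list(), tp), "at least one sweep")
})

test_that("suppression is a strict 2-SD rule and needs >= 2 sweeps", {
  tp <- train_protocol(start = 3000)
  # per-sweep baseline counts 12, 14, 10 -> mean 4 Hz, sd 2/3 Hz,
  # threshold = 4 - 4/3 = 8/3 Hz = 8 spikes per 3 s window
  at_boundary <- compute_rates(list(make_train(12, 8), make_train(14, 8),
                                    make_train(10, 8)), tp)
  expect_equal(at_boundary$during_mean,
               at_boundary$baseline_mean - 2 * at_boundary$baseline_sd)
  expect_false(classify_suppression(at_boundary))     # strict inequality

  below <- compute_rates(list(make_train(12, 7), make_train(14, 7),
                              make_train(10, 7)), tp)
  expect_true(classify_suppression(below))

  same <- compute_rates(list(make_train(12, 12), make_train(14, 14)), tp)
  expect_false(classify_suppression(same))            # during == baseline

  expect_true(is.na(classify_suppression(compute_rates(list(make_train(12, 0)),
                                                       tp))))
})

test_that("tonic-firing QC excludes silent and bursty cells", {
  tp <- train_protocol(start = 3000)
  expect_true(qc_tonic_firing(compute_rates(list(make_train(12, 12)),
                                            tp))$pass)
  silent <- qc_tonic_firing(compute_rates(list(make_train(0, 0)), tp))
  expect_false(silent$pass)
  expect_identical(silent$reason, "no_tonic_firing")
  # ~0.3 Hz: one spike in 3 s leaves a > 2 s gap
  sparse <- compute_rates(list(spike_train(1500, 2.5)), tp)
  expect_false(qc_tonic_firing(sparse)$pass)
})

test_that("suppression classifier recovers ground truth over a cohort", {
  tp <- train_protocol(start = 3000)
  classify_sim <- function(factor, seed) {
    spec <- sim_cell_spec(baseline_rate = runif(1, 2, 6), isi_cv = 0.1,
                          suppression_factor = factor)
    rec <- simulate_loose_seal_recording(spec, tp, seed = seed, n_sweeps = 5)
    trains <- lapply(1:5, function(s) detect_spikes(rec$sweeps[s, ]))
    classify_suppression(compute_rates(trains, tp))
  }
  set.seed(600)
  suppressed <- vapply(1:40, function(i) classify_sim(0, 600 + i), logical(1))
  not_suppressed <- vapply(1:40, function(i) classify_sim(1, 700 + i),
                           logical(1))
  expect_gte(mean(suppressed), 0.99)
  expect_lte(mean(not_suppressed), 0.05)
})

test_that("GBZ-insensitive excitation is excluded, GABAergic effects are not", {
  tp <- train_protocol(start = 3000)
  rates_for <- function(spec, seed, gbz = FALSE) {
    rec <- simulate_loose_seal_recording(spec, tp, seed = seed, n_sweeps = 5,
                                         gbz = gbz)
    compute_rates(lapply(1:5, function(s) detect_spikes(rec$sweeps[s, ])), tp)
  }
  opsin <- sim_cell_spec(baseline_rate = 4, suppression_factor = 1,
                         chr2_contaminated = TRUE)
  ex <- exclude_light_evoked_excitation(rates_for(opsin, 41),
                                        rates_for(opsin, 42, gbz = TRUE))
  expect_false(ex$pass)
  expect_identical(ex$reason, "chr2_contaminated")

  # a suppressed cell is never flagged as excited
  supp <- sim_cell_spec(baseline_rate = 4, suppression_factor = 0)
  expect_true(exclude_light_evoked_excitation(
    rates_for(supp, 43), rates_for(supp, 44, gbz = TRUE))$pass)

  # excitation only at baseline (abolished by GBZ) is not contamination
  base_excited <- rates_for(opsin, 45)
  gbz_normal <- rates_for(sim_cell_spec(baseline_rate = 4,
                                        suppression_factor = 1), 46)
  expect_true(exclude_light_evoked_excitation(base_excited, gbz_normal)$pass)
  # no GBZ condition recorded: not applicable
  expect_true(exclude_light_evoked_excitation(base_excited, NULL)$pass)
})
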
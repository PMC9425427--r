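test_that("no event is reported on flat or out-of-window traces", {
  expect_null(detect_oipsc(rep(0, 3000), 100, preset_minus70()))

  # event with 25 ms latency falls outside the 20 ms search window
  late <- simulate_vc_recording(clean_spec(500, 25), single_pulse_protocol(100),
                                seed = 1, n_sweeps = 1)
  expect_null(detect_oipsc(late$sweeps[1, ], 100, preset_minus70()))

  expect_error(detect_oipsc(rep(0, 100), 5, preset_minus70()), "short|baseline")
})

test_that("noise-free events are recovered with exact amplitude and latency", {
  rec <- simulate_vc_recording(clean_spec(500, 2), single_pulse_protocol(100),
                               seed = 1, n_sweeps = 3)
  for (s in 1:3) {
    ev <- detect_oipsc(rec$sweeps[s, ], 100, preset_minus70())
    expect_false(is.null(ev))
    expect_equal(ev$amplitude, 500, tolerance = 1 / 500)
    expect_lt(abs(ev$latency - 2), 0.2 + 1e-9)
    expect_lt(ev$peak_value, 0)
  }
})

test_that("detector meets sensitivity, bias and false-positive bounds", {
  set.seed(401)
  # 200 events in the hardest SNR decade, 5-10x the 10 pA noise floor
  hits <- 0; rel_err <- c()
  for (i in 1:200) {
    A <- runif(1, 50, 100)
    spec <- sim_cell_spec(TRUE, A, ipsc_kinetics(latency_mean = 2),
                          noise_sd = 10, mini_rate = 0)
    rec <- simulate_vc_recording(spec, single_pulse_protocol(100),
                                 seed = 7000 + i, n_sweeps = 1)
    ev <- detect_oipsc(rec$sweeps[1, ], 100, preset_minus70())
    if (!is.null(ev)) {
      hits <- hits + 1
      rel_err <- c(rel_err, (ev$amplitude - A) / A)
    }
  }
  expect_gte(hits / 200, 0.95)
  expect_lte(abs(mean(rel_err)), 0.05)

  # event-free noisy sweeps: false-positive rate at the default noise floor
  fp <- sum(vapply(1:200, function(i) {
    !is.null(detect_oipsc(rnorm(3000, 0, 10), 100, preset_minus70()))
  }, logical(1)))
  expect_lte(fp / 200, 0.01)
})

test_that("connectivity calls use a strict sweep majority, order-invariantly", {
  ev <- function(amp = 400, lat = 2) data.frame(
    onset_time = 100 + lat, latency = lat, peak_value = -amp, amplitude = amp)
  six <- c(replicate(6, ev(), simplify = FALSE), vector("list", 4))
  five <- c(replicate(5, ev(), simplify = FALSE), vector("list", 5))
  expect_true(classify_cell_connectivity(six)$connected)
  expect_false(classify_cell_connectivity(five)$connected)
  expect_true(is.na(classify_cell_connectivity(five)$mean_amplitude))

  full <- replicate(10, ev(400), simplify = FALSE)
  cls <- classify_cell_connectivity(full)
  expect_true(cls$connected)
  expect_equal(cls$mean_amplitude, 400)
  expect_equal(cls$mean_latency, 2)

  set.seed(1)
  shuffled <- classify_cell_connectivity(sample(six))
  expect_identical(shuffled[c("connected", "n_event_sweeps")],
                   classify_cell_connectivity(six)[c("connected",
                                                     "n_event_sweeps")])
  expect_error(classify_cell_connectivity(list()), "at least one sweep")
})

test_that("series-resistance QC applies the 25 MOhm and 30% drift rules", {
  expect_true(qc_series_resistance(c(15, 16, 15))$pass)
  r1 <- qc_series_resistance(c(15, 26))
  expect_false(r1$pass); expect_identical(r1$reason, "rs_too_high")
  r2 <- qc_series_resistance(c(10, 13.5))
  expect_false(r2$pass); expect_identical(r2$reason, "rs_drift")
  expect_true(qc_series_resistance(c(25, 25))$pass)       # strict >
  expect_true(qc_series_resistance(c(10, 13))$pass)       # exactly 30%
  expect_error(qc_series_resistance(numeric(0)), "empty")
})

test_that("GBZ block assessment distinguishes synaptic from opsin currents", {
  sp <- single_pulse_protocol(100)
  syn <- sim_cell_spec(TRUE, 800, gbz_blocks = TRUE, noise_sd = 10)
  b <- simulate_vc_recording(syn, sp, seed = 31, n_sweeps = 6)
  g <- simulate_vc_recording(syn, sp, seed = 32, n_sweeps = 6, gbz = TRUE)
  expect_identical(assess_gbz_block(b, g), "blocked")

  opsin <- sim_cell_spec(connected = FALSE, chr2_contaminated = TRUE,
                         noise_sd = 10, mini_rate = 0)
  bo <- simulate_vc_recording(opsin, sp, seed = 33, n_sweeps = 6)
  go <- simulate_vc_recording(opsin, sp, seed = 34, n_sweeps = 6, gbz = TRUE)
  expect_identical(assess_gbz_block(bo, go), "not_blocked")
  cls <- classify_cell_connectivity(detect_oipsc_sweeps(bo))
  expect_lt(cls$mean_latency, 1)
  chr2 <- exclude_chr2_contamination(cls, "not_blocked")
  expect_false(chr2$pass)
  expect_identical(chr2$reason, "chr2_contaminated")

  # unconnected baseline: GBZ assessment is not applicable
  none <- sim_cell_spec(connected = FALSE, noise_sd = 10, mini_rate = 0)
  bn <- simulate_vc_recording(none, sp, seed = 35, n_sweeps = 6)
  gn <- simulate_vc_recording(none, sp, seed = 36, n_sweeps = 6, gbz = TRUE)
  expect_identical(assess_gbz_block(bn, gn), "not_applicable")

  mism <- simulate_vc_recording(syn, single_pulse_protocol(200), seed = 37,
                                n_sweeps = 6)
  expect_error(assess_gbz_block(b, mism), "protocol mismatch")
})

test_that("contamination rule needs both GBZ insensitivity and <1 ms latency", {
  fast <- list(connected = TRUE, mean_latency = 0.6)
  slow <- list(connected = TRUE, mean_latency = 1.8)
  expect_false(exclude_chr2_contamination(fast, "not_blocked")$pass)
  expect_true(exclude_chr2_contamination(fast, "blocked")$pass)
  slow_res <- exclude_chr2_contamination(slow, "not_blocked")
  expect_true(slow_res$pass)
  expect_true(slow_res$review)   # flagged for review, not excluded
  expect_error(qc_result(TRUE, "rs_drift"), "iff")
})
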
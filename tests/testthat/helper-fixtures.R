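# Shared builders for small simulated fixtures.

# noiseless, mini-free spec for exact-value checks
clean_spec <- function(amplitude = 500, latency = 2, ...) {
  sim_cell_spec(connected = TRUE, ipsc_amplitude = amplitude,
                kinetics = ipsc_kinetics(latency_mean = latency,
                                         latency_jitter_sd = 0),
                noise_sd = 0, mini_rate = 0, ...)
}

# spike train with n_base evenly spaced baseline spikes in [0, 3000) and
# n_during evenly spaced spikes in [3000, 6000), for rate arithmetic tests
make_train <- function(n_base, n_during, base_win = c(0, 3000),
                       during_win = c(3000, 6000)) {
  sp <- function(n, win) if (n > 0) win[1] + (seq_len(n) - 0.5) *
      diff(win) / n else numeric(0)
  spike_train(c(sp(n_base, base_win), sp(n_during, during_win)),
              waveform_total_duration = 2.5)
}

# independent tie-corrected Kruskal-Wallis H, straight from the rank formula
kw_oracle <- function(groups) {
  x <- unlist(groups)
  n <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  rbar <- split(r, rep(seq_along(groups), n))
  H <- 12 / (N * (N + 1)) *
    sum(n * (vapply(rbar, mean, numeric(1)) - (N + 1) / 2)^2)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# second, independently written two-stage FDR implementation, built on
# p.adjust()'s BH-adjusted p-values rather than a step-up index search
bky_oracle <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  padj <- stats::p.adjust(p, method = "BH")
  r1 <- sum(padj <= q1)
  if (r1 == 0L) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  padj <= q1 * m / (m - r1)
}
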
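test_that("self-coherency is exactly 1 and self-iCOH exactly 0", {
  set.seed(3)
  ep <- generated_epochs(function(tr, ch, n) rnorm(n), n_trials = 6)
  co <- coherency(ep, c("Cz", "Cz"))
  expect_true(all(abs(co$coherence - 1) < 1e-10))
  expect_true(all(abs(co$icoh) < 1e-10))

  icm <- icoh_matrix(ep, band = c(8, 13))
  expect_true(all(diag(icm$abs) == 0))
  expect_true(all(diag(icm$signed) == 0))
})

test_that("coherency magnitude carries the expected estimator bias", {
  # independent white noise: E|R|^2 ~ 1/n_segments
  set.seed(4)
  ep <- generated_epochs(function(tr, ch, n) rnorm(n), n_trials = 40)
  co <- coherency(ep, c("C3", "C4"))
  msc <- mean(co$coherence[co$freq >= 4 & co$freq <= 40]^2)
  expect_lt(msc, 2 / 40)
  expect_gt(msc, 1 / (2 * 40))

  expect_error(
    coherency(subset_trials_for_test(ep, 1), c("C3", "C4")),
    class = "kibci_config_error")
})

test_that("quarter-period lag shows up in the imaginary part", {
  # y lags x by a quarter period at 10 Hz: R(10 Hz) ~ 0 + 1i
  fs <- 160
  lag <- round(fs / 10 / 4)                       # 4 samples = 25 ms
  set.seed(6)
  n <- round(7 * fs)
  src <- matrix(0, 30, n + lag)
  for (tr in seq_len(30)) {
    src[tr, ] <- kibci:::band_noise(n + lag, fs, c(9.5, 10.5))
  }
  ep <- generated_epochs(function(tr, ch, n_s) {
    # C3 carries the advanced copy, so FC3 = C3 delayed by `lag`
    if (ch == 7) src[tr, lag + 1:n_s] + 0.05 * rnorm(n_s)      # C3
    else if (ch == 1) src[tr, 1:n_s] + 0.05 * rnorm(n_s)       # FC3
    else rnorm(n_s)
  }, n_trials = 30)
  co <- coherency(ep, c("C3", "FC3"))
  at10 <- which.min(abs(co$freq - 10))
  expect_gt(Im(co$coherency[at10]), 0.9)
  expect_lt(abs(Re(co$coherency[at10])), 0.25)
})

test_that("zero-lag mixing is invisible to iCOH but not to coherence", {
  # y = x + independent noise: classic volume-conduction surrogate
  set.seed(7)
  fs <- 160
  n <- round(7 * fs)
  base <- matrix(rnorm(40 * n), 40, n)
  ep <- generated_epochs(function(tr, ch, n_s) {
    if (ch == 7) base[tr, ]
    else if (ch == 1) base[tr, ] + 0.3 * rnorm(n_s)
    else rnorm(n_s)
  }, n_trials = 40)
  co <- coherency(ep, c("C3", "FC3"))
  band <- co$freq >= 8 & co$freq <= 13
  expect_gt(mean(co$coherence[band]), 0.8)
  expect_lt(mean(abs(co$icoh[band])), 0.05)
})

test_that("a lagged-coupled channel pair dominates the band matrix", {
  cfg <- sim_config(
    n_runs = 5, trials_per_run = test_counts(0, 0, 0, 8), fs = 160,
    erd_depth = depth_profile(),
    coupling = list(chan_a = "C3", chan_b = "FC3", lag = 0.024,
                    gain = 8, band = c(8, 13), conditions = "KI-LMI"))
  hits <- vapply(1:3, function(s) {
    ep <- extract_epochs(synthesize_session(cfg, seed = 60 + s))
    ed <- tidy(icoh_matrix(ep, band = c(8, 13)))
    top <- ed[which.max(ed$icoh_abs), ]
    setequal(c(top$channel_a, top$channel_b), c("C3", "FC3"))
  }, TRUE)
  expect_true(all(hits))

  # band |iCOH| grows with the coupling gain
  vals <- vapply(c(2, 5, 8), function(g) {
    cfg$coupling$gain <- g
    ep <- extract_epochs(synthesize_session(cfg, seed = 64))
    icm <- icoh_matrix(ep, band = c(8, 13))
    icm$abs["C3", "FC3"]
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("matrix invariants and the grand average hold", {
  set.seed(9)
  ep <- generated_epochs(function(tr, ch, n) rnorm(n), n_trials = 10)
  m1 <- icoh_matrix(ep, band = c(8, 13))
  expect_true(all(abs(m1$signed + t(m1$signed)) < 1e-12))   # antisymmetry
  expect_true(all(m1$abs >= 0 & m1$abs <= 1))
  expect_equal(m1$abs, t(m1$abs))

  avg <- icoh_grand_average(list(m1, m1, m1))
  expect_equal(avg$abs, m1$abs)
  expect_equal(avg$n_trials, 3 * m1$n_trials)

  m_neg <- m1
  m_neg$signed <- -m1$signed
  avg2 <- icoh_grand_average(list(m1, m_neg))
  expect_true(all(abs(avg2$signed) < 1e-12))

  m_other <- m1
  m_other$montage <- rev(m1$montage)
  expect_error(icoh_grand_average(list(m1, m_other)),
               class = "kibci_config_error")

  expect_error(icoh_matrix(ep, band = c(0.01, 0.02)),
               class = "kibci_config_error")

  edges <- top_edges(m1, k = 5)
  expect_equal(nrow(edges), 5)
  expect_true(all(diff(edges$icoh_abs) <= 0))
})
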
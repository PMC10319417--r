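test_that("instantaneous power matches closed forms for pure tones", {
  # amplitude-4 tone at 10 Hz: in-band power A^2/2, away from window edges
  ep <- sine_epochs(freq = 10, amp = 4, n_trials = 3)
  ip <- instantaneous_power(ep, band = c(8, 13), condition = "no-LMI")
  cz <- match("Cz", ep$montage)
  mid <- ip$time > 1 & ip$time < 3
  expect_equal(mean(ip$power[cz, mid]), 16 / 2, tolerance = 0.02)
  expect_equal(unname(ip$base_power[cz]), 8, tolerance = 0.02)

  # out-of-band tone is rejected by the 8-13 Hz band-pass
  ep50 <- sine_epochs(freq = 50, amp = 4, n_trials = 3)
  ip50 <- instantaneous_power(ep50, band = c(8, 13), condition = "no-LMI")
  expect_lt(max(ip50$power[cz, ]), 8 * 1e-3)

  expect_error(instantaneous_power(ep, band = c(8, 200)),
               class = "kibci_config_error")
})

test_that("longer smoothing windows keep the mean, cut the variance", {
  set.seed(5)
  ep <- generated_epochs(function(tr, ch, n) rnorm(n), n_trials = 4)
  p1 <- instantaneous_power(ep, band = c(8, 30), window = 0.25)
  p2 <- instantaneous_power(ep, band = c(8, 30), window = 0.5)
  cz <- 9
  expect_equal(mean(p1$power[cz, ]), mean(p2$power[cz, ]),
               tolerance = 0.05)
  expect_lt(var(p2$power[cz, ]), var(p1$power[cz, ]))
})

test_that("ERD identities hold for constructed power ratios", {
  # stationary tone: ERD(t) ~ 0 throughout, mean ERD ~ 0
  flat <- sine_epochs(freq = 10, amp = 4, n_trials = 3)
  tc <- erd_timecourse(flat, band = c(8, 13), channels = "Cz")
  expect_lt(max(abs(tc$erd)), 2)
  em <- erd_mean(flat, bands = list(alpha = c(8, 13)), channels = "Cz")
  expect_equal(em$erd_mean, 0, tolerance = 1)

  # task amplitude sqrt(0.5) x baseline: ERD plateau and mean at -50
  half <- sine_epochs(freq = 10, amp = 4, task_amp = 4 * sqrt(0.5),
                      n_trials = 3)
  tc50 <- erd_timecourse(half, band = c(8, 13), channels = "Cz")
  plateau <- tc50$erd[tc50$time > 1 & tc50$time < 3]
  expect_lt(abs(mean(plateau) + 50), 1.5)
  em50 <- erd_mean(half, bands = list(alpha = c(8, 13)), channels = "Cz")
  expect_lt(abs(em50$erd_mean + 50), 1.5)

  # floor: power is nonnegative so ERD >= -100 everywhere
  expect_true(all(tc50$erd >= -100))
})

test_that("simulated ERD depth is recovered at the modulated channel", {
  ep <- extract_epochs(synthesize_session(recovery_cfg(0.3), seed = 51))
  em <- erd_mean(ep, bands = list(wide = c(8, 30)),
                 conditions = c("rest", "no-LMI"), channels = "Cz")
  expect_lt(abs(em$erd_mean[em$condition == "no-LMI"] + 30), 5)
  expect_lt(abs(em$erd_mean[em$condition == "rest"]), 5)

  # mean ERD agrees with the time-average of the ERD(t) trace
  tc <- erd_timecourse(ep, band = c(8, 30), conditions = "no-LMI",
                       channels = "Cz")
  expect_lt(abs(mean(tc$erd) - em$erd_mean[em$condition == "no-LMI"]), 1)
})

test_that("trial-average-then-normalize differs from per-trial ERD", {
  # heterogeneous trial amplitudes: averaging powers before normalizing
  # (the implemented order) weights strong trials more than normalizing
  # each trial first would
  amps <- c(1, 1, 1, 6, 6, 6)
  set.seed(8)
  ep <- generated_epochs(function(tr, ch, n) {
    t <- (seq_len(n) - 0.5) / 160 - 3
    g <- ifelse(t >= 0 & t < 3.5, sqrt(ifelse(tr <= 3, 0.9, 0.4)), 1)
    amps[tr] * g * sin(2 * pi * 10 * t + tr)
  }, n_trials = 6)
  ip <- instantaneous_power(ep, band = c(8, 13), keep_trials = TRUE)
  cz <- 9
  task_mask <- ip$trial_time >= 0.5 & ip$trial_time < 3.5
  base_mask <- ip$trial_time >= -2.5 & ip$trial_time < -1.5
  pooled <- (mean(ip$power[cz, ]) - ip$base_power[cz]) /
    ip$base_power[cz] * 100
  per_trial <- mean(vapply(seq_len(6), function(tr) {
    pt <- mean(ip$trials[tr, cz, task_mask])
    pb <- mean(ip$trials[tr, cz, base_mask])
    (pt - pb) / pb * 100
  }, 0))
  # per-trial normalization lands near the unweighted mean of the two
  # depths; pooled normalization is pulled toward the strong trials
  expect_gt(abs(pooled - per_trial), 5)
})

test_that("minimum ERD and arrival times follow their definitions", {
  ramp <- tibble::tibble(condition = "no-LMI", channel = "Cz",
                         time = seq(0, 2, by = 0.1),
                         erd = seq(0, -40, length.out = 21))
  res <- emin_arrival(ramp)
  expect_equal(res$e_min, -40)
  expect_equal(res$t_arrival, 2)
  expect_true(res$reached)

  # numeric reference: first crossing, not the minimum's time
  res20 <- emin_arrival(ramp, reference = -20)
  expect_equal(res20$t_arrival, 1)

  flat <- dplyr::mutate(ramp, erd = 0)
  res_flat <- emin_arrival(flat, reference = -10)
  expect_false(res_flat$reached)
  expect_true(is.na(res_flat$t_arrival))
})

test_that("relative power in dB matches closed forms", {
  ep <- sine_epochs(freq = 10, amp = 4, n_trials = 4)
  same <- relative_power_db(ep, band = c(8, 13), condition = "no-LMI",
                            reference_condition = "no-LMI",
                            channels = "Cz")
  expect_lt(max(abs(same$db)), 1e-9)

  # halved power vs own baseline: ~ -3.01 dB on the plateau
  half <- sine_epochs(freq = 10, amp = 4, task_amp = 4 * sqrt(0.5),
                      n_trials = 4)
  own <- relative_power_db(half, band = c(8, 13), condition = "no-LMI",
                           channels = "Cz")
  plateau <- own$db[own$time > 1 & own$time < 3]
  expect_lt(abs(mean(plateau) - 10 * log10(0.5)), 0.1)

  # scale check: a power ratio of 10^-2.1 reads -21 dB
  expect_equal(10 * log10(10^-2.1), -21)
})
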
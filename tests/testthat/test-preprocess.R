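# one small session shared across the blocks in this file
local_session <- local({
  cfg <- sim_config(n_runs = 2, fs = 160)
  synthesize_session(cfg, seed = 41)
})

test_that("epoching produces correctly sized, correctly placed windows", {
  ep <- extract_epochs(local_session)
  expect_equal(dim(ep$data), c(32, 16, 7 * 160))
  expect_equal(dim(epoch_window(ep, "baseline"))[3], 1 * 160)
  expect_equal(dim(epoch_window(ep, "task"))[3], 3 * 160)
  expect_identical(ep$labels, local_session$schedule$condition)
  expect_equal(sum(ep$flagged), 0)

  # translation equivariance: shifting signal and schedule by the same
  # integer sample count leaves epochs unchanged
  shift <- 160L
  shifted <- local_session
  shifted$data <- cbind(matrix(0, 16, shift), local_session$data)
  shifted$schedule$cue_onset <- shifted$schedule$cue_onset + 1
  shifted$schedule$task_onset <- shifted$schedule$task_onset + 1
  ep2 <- extract_epochs(shifted)
  expect_equal(ep2$data, ep$data)
})

test_that("full-protocol session yields one epoch pair per scheduled trial", {
  cfg <- sim_config(fs = 160)                    # full 12-run paradigm
  ses <- synthesize_session(cfg, seed = 42)
  ep <- extract_epochs(ses)
  expect_equal(dim(ep$data)[1], 192)
  expect_equal(as.integer(table(ep$labels)), rep(48L, 4))
})

test_that("out-of-bounds trials are flagged and reported, not dropped", {
  ses <- local_session
  ses$schedule$task_onset[1] <- 1          # full window starts before t=0
  expect_warning(ep <- extract_epochs(ses), "outside the recording")
  expect_equal(dim(ep$data)[1], 32)
  expect_true(ep$flagged[1])
  expect_match(ep$flag_reason[1], "out of recording bounds")
})

test_that("peak-to-peak rejection uses a strict threshold on any channel", {
  ep <- extract_epochs(local_session)
  clean <- suppressMessages(reject_artifacts(ep, 200))
  expect_equal(sum(clean$flagged), 0)      # synthetic amplitudes << 200

  # exactly-at-threshold peak-to-peak is kept (strict inequality)
  spike <- function(extreme) {
    data <- array(0, dim = c(2, 16, 7 * 160))
    data[, 1, 600] <- extreme          # inside the task window
    data[, 1, 620] <- -extreme
    epoch_set(data, labels = rep("rest", 2), fs = 160,
              montage = sensorimotor_montage())
  }
  at <- spike(100)                     # p2p exactly 200.0
  expect_equal(sum(suppressMessages(reject_artifacts(at, 200))$flagged), 0)
  over <- spike(100.5)                 # p2p 201
  expect_equal(sum(suppressMessages(reject_artifacts(over, 200))$flagged), 2)

  # injected 300 uV transients flag every trial
  hit <- inject_artifacts(local_session, rate = 1, amplitude = 300,
                          seed = 1)
  ep_hit <- suppressMessages(reject_artifacts(extract_epochs(hit), 200))
  expect_true(all(ep_hit$flagged))

  # idempotence and input immutability
  twice <- suppressMessages(reject_artifacts(ep_hit, 200))
  expect_identical(twice$flagged, ep_hit$flagged)
  expect_equal(sum(ep$flagged), 0)

  # pluggable predicate hook
  pred <- function(b, t) max(abs(t)) > 0
  all_flagged <- suppressMessages(reject_artifacts(ep, 1e6, predicate = pred))
  expect_true(all(all_flagged$flagged))
})

test_that("subsampling is uniform, seeded and guarded", {
  cfg <- sim_config(n_runs = 6, trials_per_run = test_counts(8, 0, 8, 0),
                    fs = 160)
  ep <- extract_epochs(synthesize_session(cfg, seed = 43))  # 48 per cond

  sub <- subsample_trials(ep, 40, seed = 1)
  expect_equal(as.integer(table(droplevels(sub$labels))), c(40L, 40L))

  # n equal to available count: identity selection
  all48 <- subsample_trials(ep, 48, seed = 1)
  expect_equal(dim(all48$data)[1], 96)

  a <- subsample_trials(ep, 40, seed = 1)
  b <- subsample_trials(ep, 40, seed = 1)
  c <- subsample_trials(ep, 40, seed = 2)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))

  err <- expect_error(
    subsample_trials(ep, 49, conditions = "rest"),
    class = "kibci_insufficient_trials")
  expect_match(conditionMessage(err), "rest")
  expect_match(conditionMessage(err), "48")
})
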
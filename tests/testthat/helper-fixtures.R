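# Shared fixture builders. Simulations in tests run at fs = 160 Hz (all
# analysis bands sit below 32 Hz) with reduced trial counts; the
# generator's paradigm defaults are exercised where the property under
# test is about the paradigm itself.

test_counts <- function(rest = 4, vrest = 4, nolmi = 4, kilmi = 4) {
  c("rest" = rest, "V-rest" = vrest, "no-LMI" = nolmi, "KI-LMI" = kilmi)
}

# zero ERD everywhere except explicit (condition, channel) = depth entries
depth_profile <- function(..., montage = sensorimotor_montage()) {
  depth <- erd_depth_profile(montage)
  depth[, ] <- 0
  mods <- list(...)
  for (m in mods) depth[m$condition, m$channels] <- m$depth
  depth
}

# 40 rest + 40 single-condition trials with one modulated channel
recovery_cfg <- function(d, condition = "no-LMI", channel = "Cz",
                         fs = 160) {
  sim_config(
    n_runs = 10,
    trials_per_run = test_counts(rest = 4, vrest = 0,
                                 nolmi = if (condition == "no-LMI") 4 else 0,
                                 kilmi = if (condition == "KI-LMI") 4 else 0),
    fs = fs,
    erd_depth = depth_profile(list(condition = condition,
                                   channels = channel, depth = d)))
}

# deterministic sinusoid epochs: every trial the same tone, optional
# distinct task-window amplitude (half-open windows as in extract_epochs)
sine_epochs <- function(freq, amp = 4, task_amp = amp, n_trials = 6,
                        fs = 160, montage = sensorimotor_montage()) {
  full <- c(-3, 4)
  n <- round(diff(full) * fs)
  t <- full[1] + (seq_len(n) - 0.5) / fs
  base_wave <- amp * sin(2 * pi * freq * t)
  task_wave <- task_amp * sin(2 * pi * freq * t)
  wave <- ifelse(t >= 0 & t < 3.5, task_wave, base_wave)
  data <- array(0, dim = c(n_trials, length(montage), n))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_along(montage)) data[tr, ch, ] <- wave
  }
  epoch_set(data, labels = rep("no-LMI", n_trials), fs = fs,
            montage = montage)
}

# epochs whose channels are built from supplied per-trial generator
# functions: gen(ch, n_samples) -> numeric
generated_epochs <- function(gen, n_trials, fs = 160,
                             montage = sensorimotor_montage(),
                             labels = rep("no-LMI", n_trials)) {
  n <- round(7 * fs)
  data <- array(0, dim = c(n_trials, length(montage), n))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_along(montage)) data[tr, ch, ] <- gen(tr, ch, n)
  }
  epoch_set(data, labels = labels, fs = fs, montage = montage)
}

subset_trials_for_test <- function(epochs, idx) {
  kibci:::subset_epochs(epochs, idx)
}

# direct periodogram band power of one window of a session channel --
# an oracle independent of the package's Butterworth filtering path
fft_band_power <- function(v, fs, band) {
  n <- length(v)
  v <- v - mean(v)
  p <- Mod(stats::fft(v))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  2 * sum(p[sel])
}

# mean task-window and baseline-window band power over a session's trials
# of one condition, via the periodogram oracle
oracle_power_ratio <- function(session, condition, channel, band) {
  fs <- session$fs
  sched <- session$schedule
  ch <- match(channel, session$montage)
  idx <- which(sched$condition == condition)
  ti <- round(sched$task_onset * fs)
  task_p <- vapply(idx, function(k) {
    fft_band_power(session$data[ch, (ti[k] + round(0.5 * fs) + 1):
                                  (ti[k] + round(3.5 * fs))], fs, band)
  }, 0)
  base_p <- vapply(idx, function(k) {
    fft_band_power(session$data[ch, (ti[k] - round(2.5 * fs) + 1):
                                  (ti[k] - round(1.5 * fs))], fs, band)
  }, 0)
  mean(task_p) / mean(base_p)
}
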
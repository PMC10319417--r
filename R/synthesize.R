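# Spectral-domain signal generators, all built by shaping the Fourier
# spectrum of white noise; exact band limits and an exact 1/f^a profile
# matter more here than waveform realism.

# 1/f^exponent background, unit RMS, flat below 1 Hz to keep power finite
pink_noise <- function(n, fs, exponent = 1) {
  freqs <- seq(0, fs / 2, by = fs / n)
  shape <- pmax(freqs, 1) ^ (-exponent / 2)
  shape[1] <- 0
  spectrum_noise(n, fs, shape)
}

# band-limited Gaussian noise, unit RMS, raised-cosine edges (~1 Hz roll-off)
band_noise <- function(n, fs, band, roll = 1) {
  freqs <- seq(0, fs / 2, by = fs / n)
  shape <- numeric(length(freqs))
  core <- freqs >= band[1] & freqs <= band[2]
  shape[core] <- 1
  lo <- freqs >= band[1] - roll & freqs < band[1]
  shape[lo] <- 0.5 * (1 + cos(pi * (band[1] - freqs[lo]) / roll))
  hi <- freqs > band[2] & freqs <= band[2] + roll
  shape[hi] <- 0.5 * (1 + cos(pi * (freqs[hi] - band[2]) / roll))
  spectrum_noise(n, fs, shape)
}

# constant-envelope narrowband oscillation, unit RMS: the instantaneous
# phase of a band-limited Gaussian process, amplitude fixed. Band power is
# then set by the amplitude parameter rather than by envelope statistics,
# which keeps the injected ERD depth recoverable at the paradigm's short
# 1-s baseline.
band_oscillation <- function(n, fs, band, roll = 1) {
  freqs <- seq(0, fs / 2, by = fs / n)
  shape <- numeric(length(freqs))
  core <- freqs >= band[1] & freqs <= band[2]
  shape[core] <- 1
  lo <- freqs >= band[1] - roll & freqs < band[1]
  shape[lo] <- 0.5 * (1 + cos(pi * (band[1] - freqs[lo]) / roll))
  hi <- freqs > band[2] & freqs <= band[2] + roll
  shape[hi] <- 0.5 * (1 + cos(pi * (freqs[hi] - band[2]) / roll))
  m <- length(shape)
  z <- complex(real = rnorm(m), imaginary = rnorm(m)) * shape
  z[1] <- 0
  # one-sided spectrum -> analytic signal; cos(phase) has constant envelope
  full <- c(2 * z, rep(complex(real = 0), n - m))[seq_len(n)]
  za <- fft(full, inverse = TRUE) / n
  x <- Re(za) / pmax(Mod(za), .Machine$double.eps)
  x / stats::sd(x)
}

# inverse-FFT of white complex Gaussian spectrum x real amplitude shape,
# returned standardized to unit RMS
spectrum_noise <- function(n, fs, half_shape) {
  m <- length(half_shape)            # = floor(n/2) + 1
  z <- complex(real = rnorm(m), imaginary = rnorm(m)) * half_shape
  z[1] <- 0
  full <- if (n %% 2 == 0) {
    z[m] <- complex(real = Re(z[m]), imaginary = 0)
    c(z, Conj(z[(m - 1):2]))
  } else {
    c(z, Conj(z[m:2]))
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Synthesize a raw EEG session from a configuration and schedule
#'
#' Every channel is the sum of a 1/f background and alpha (8-13 Hz) and
#' beta (14-30 Hz) narrowband oscillations (constant-envelope processes
#' with band-limited random instantaneous phase). During each trial's task
#' segment the rhythm amplitude at channels with a nonzero ERD depth for
#' that trial's condition is scaled by `sqrt(1 - depth)`, ramping linearly
#' over `erd_latency` seconds from task onset — the amplitude-domain
#' counterpart of a fractional band-power drop of `depth`. Optionally a
#' lagged shared narrowband source is mixed into a channel pair during
#' matching task windows (`cfg$coupling`), and high-amplitude transients
#' are injected at `cfg$artifact_rate`.
#'
#' @param cfg A [sim_config()].
#' @param schedule A [build_trial_schedule()] result consistent with `cfg`;
#'   built from `seed` when omitted.
#' @param seed Integer seed controlling every random draw; identical seeds
#'   give byte-identical sessions.
#' @return An `eeg_session`: a list with `data` (16 x n_samples matrix,
#'   microvolt), `fs`, `montage`, `schedule`, `seed_used` and
#'   `artifact_trials` (row indices of `schedule` that received injected
#'   transients).
#' @export
#' @examples
#' cfg <- sim_config(n_runs = 1, fs = 250)
#' ses <- synthesize_session(cfg, seed = 7)
#' dim(ses$data)
synthesize_session <- function(cfg, schedule = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(schedule)) schedule <- build_trial_schedule(cfg, seed = seed)
  stopifnot(inherits(schedule, "trial_schedule"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  fs <- cfg$fs
  duration <- max(schedule$task_onset) + cfg$timing$task + cfg$timing$relax
  n <- ceiling(duration * fs)
  n_ch <- length(cfg$montage)

  task_len <- round(cfg$timing$task * fs)
  ramp_len <- max(1L, round(cfg$erd_latency * fs))
  task_idx0 <- round(schedule$task_onset * fs)   # 0-based sample of task onset

  alpha_rng <- c(8, 13)
  beta_rng <- c(14, 30)

  data <- matrix(0, nrow = n_ch, ncol = n,
                 dimnames = list(cfg$montage, NULL))
  for (ch in seq_len(n_ch)) {
    gain <- channel_gain(n, cfg$erd_depth[, ch], schedule$condition,
                         task_idx0, task_len, ramp_len)
    x <- cfg$noise_amp * pink_noise(n, fs, cfg$noise_exponent)
    x <- x + cfg$alpha_amp[ch] * band_oscillation(n, fs, alpha_rng) * gain
    x <- x + cfg$beta_amp[ch] * band_oscillation(n, fs, beta_rng) * gain
    data[ch, ] <- x
  }

  if (!is.null(cfg$coupling)) {
    data <- add_lagged_coupling(data, cfg, schedule, task_idx0, task_len)
  }

  session <- structure(
    list(data = data, fs = fs, montage = cfg$montage, schedule = schedule,
         seed_used = as.integer(seed), artifact_trials = integer(0)),
    class = "eeg_session")

  if (cfg$artifact_rate > 0) {
    session <- inject_artifacts(session, rate = cfg$artifact_rate,
                                amplitude = cfg$artifact_amp,
                                seed = as.integer(seed) + 1L)
  }
  session
}

# multiplicative amplitude envelope for one channel: 1 at baseline,
# sqrt(1 - depth) during task segments of modulated conditions
channel_gain <- function(n, depth_by_cond, conditions, task_idx0, task_len,
                         ramp_len) {
  gain <- rep(1, n)
  for (k in seq_along(conditions)) {
    d <- depth_by_cond[[as.character(conditions[k])]]
    if (d <= 0) next
    g <- sqrt(1 - d)
    i0 <- task_idx0[k] + 1L
    i1 <- min(task_idx0[k] + task_len, n)
    seg <- i0:i1
    ramp <- pmin((seq_along(seg) - 1) / ramp_len, 1)
    gain[seg] <- 1 + (g - 1) * ramp
  }
  gain
}

# shared narrowband source added to chan_a and, lag samples later, chan_b
add_lagged_coupling <- function(data, cfg, schedule, task_idx0, task_len) {
  cp <- cfg$coupling
  stopifnot(all(c("chan_a", "chan_b", "lag", "gain", "band") %in% names(cp)))
  conds <- cp$conditions %||% "all"
  fs <- cfg$fs
  n <- ncol(data)
  lag_smp <- round(cp$lag * fs)
  src <- cp$gain * band_noise(n + abs(lag_smp), fs, cp$band)
  ia <- match(cp$chan_a, cfg$montage)
  ib <- match(cp$chan_b, cfg$montage)
  if (is.na(ia) || is.na(ib)) {
    abort("coupling channels must be montage labels.",
          class = "kibci_config_error")
  }
  active <- if (identical(conds, "all")) seq_len(nrow(schedule)) else
    which(as.character(schedule$condition) %in% conds)
  for (k in active) {
    i0 <- task_idx0[k] + 1L
    i1 <- min(task_idx0[k] + task_len, n)
    seg <- i0:i1
    data[ia, seg] <- data[ia, seg] + src[seg + lag_smp]
    data[ib, seg] <- data[ib, seg] + src[seg]      # b lags a by `lag`
  }
  data
}

#' Inject high-amplitude transient artifacts into a session
#'
#' Adds a half-sine "blink-like" transient (default 0.3 s) to the
#' frontal-most channel row of a Bernoulli-selected subset of trials,
#' centred early in the task segment so the transient lands inside the
#' analysis windows. Used to exercise peak-to-peak artifact rejection.
#'
#' @param session An `eeg_session`.
#' @param rate Per-trial probability of receiving a transient, in `[0, 1]`.
#' @param amplitude Peak amplitude of the transient in microvolt.
#' @param seed Integer seed for the Bernoulli draw.
#' @param channels Channel labels receiving the transient; defaults to the
#'   frontocentral row.
#' @param duration Transient duration in seconds.
#' @return A new `eeg_session` with `artifact_trials` listing affected
#'   schedule rows. The input is not modified.
#' @export
inject_artifacts <- function(session, rate, amplitude = 300, seed = 1L,
                             channels = NULL, duration = 0.3) {
  stopifnot(inherits(session, "eeg_session"))
  if (rate < 0 || rate > 1) {
    abort("`rate` must lie in [0, 1].", class = "kibci_config_error")
  }
  if (amplitude <= 0) {
    abort("`amplitude` must be positive.", class = "kibci_config_error")
  }
  if (rate == 0) return(session)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  channels <- channels %||%
    grep("^FC", session$montage, value = TRUE)
  ch_idx <- match(channels, session$montage)
  stopifnot(!anyNA(ch_idx))

  fs <- session$fs
  pulse <- amplitude * sin(pi * seq(0, 1, length.out = round(duration * fs)))
  hit <- which(runif(nrow(session$schedule)) < rate)
  data <- session$data
  for (k in hit) {
    # centred at task onset + 1 s: inside both rejection windows' trial
    start <- round((session$schedule$task_onset[k] + 1) * fs)
    seg <- start + seq_along(pulse)
    seg <- seg[seg <= ncol(data)]
    data[ch_idx, seg] <- sweep(data[ch_idx, seg, drop = FALSE], 2,
                               pulse[seq_along(seg)], "+")
  }
  out <- session
  out$data <- data
  out$artifact_trials <- sort(union(session$artifact_trials, hit))
  out
}

#' @export
print.eeg_session <- function(x, ...) {
  cat("<eeg_session>\n")
  cat(sprintf("  %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat(sprintf("  %d scheduled trials, %d with injected artifacts, seed %d\n",
              nrow(x$schedule), length(x$artifact_trials), x$seed_used))
  invisible(x)
}
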
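#' Condition labels of the four-condition paradigm
#'
#' The paradigm interleaves two rest-type conditions (quiet rest, and rest
#' with Achilles-tendon vibration, "V-rest") and two motor-imagery
#' conditions (imagery alone, "no-LMI", and imagery with the vibration-
#' induced kinesthetic illusion, "KI-LMI").
#'
#' @return Character vector of the four condition labels, in canonical order.
#' @export
#' @examples
#' mi_conditions()
mi_conditions <- function() {
  c("rest", "V-rest", "no-LMI", "KI-LMI")
}

#' Default 16-channel sensorimotor montage
#'
#' A 10-10 system grid over the sensorimotor strip: the frontocentral,
#' central and centroparietal rows. Cz overlies the mesial cortex where the
#' lower-limb representation sits.
#'
#' @return Character vector of 16 channel labels.
#' @export
sensorimotor_montage <- function() {
  c("FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP1", "CPz", "CP2")
}

#' Canonical analysis frequency bands
#'
#' @return Named list of `c(low, high)` ranges in Hz: alpha 8-13,
#'   beta 14-30 and their union 8-30.
#' @export
mi_bands <- function() {
  list(alpha = c(8, 13), beta = c(14, 30), alpha_beta = c(8, 30))
}

#' Default ERD depth profile for the four conditions
#'
#' Fractional task-window power reductions per (condition, channel).
#' Rest carries no modulation. V-rest carries a slight midline depression
#' (vibration alone weakly engages the sensorimotor cortex). Imagery
#' conditions modulate the midline (Cz, CPz) and paracentral channels, with
#' the kinesthetic-illusion condition deeper and with a stronger
#' left-hemisphere (contralateral) component.
#'
#' @param montage Channel labels (defaults to [sensorimotor_montage()]).
#' @return A 4 x 16 numeric matrix, rows named by condition, columns by
#'   channel, values in `[0, 1)`.
#' @export
erd_depth_profile <- function(montage = sensorimotor_montage()) {
  depth <- matrix(0, nrow = 4, ncol = length(montage),
                  dimnames = list(mi_conditions(), montage))
  set_d <- function(cond, chans, d) {
    chans <- intersect(chans, montage)
    depth[cond, chans] <<- d
    invisible(NULL)
  }
  set_d("V-rest", c("Cz", "CPz"), 0.05)
  set_d("no-LMI", c("C1", "C2"), 0.15)
  set_d("no-LMI", "CPz", 0.20)
  set_d("no-LMI", "Cz", 0.30)
  set_d("KI-LMI", "C3", 0.15)
  set_d("KI-LMI", c("C1", "C2"), 0.25)
  set_d("KI-LMI", "CPz", 0.35)
  set_d("KI-LMI", "Cz", 0.45)
  depth
}

#' Simulation configuration for a synthetic recording session
#'
#' Describes one subject-session of the four-condition paradigm: run/trial
#' bookkeeping, segment timing, montage, the spectral composition of each
#' channel (1/f background plus alpha and beta narrowband rhythms), the
#' per-condition ERD modulation, optional artifact injection and optional
#' lagged inter-channel coupling.
#'
#' Defaults reproduce the study paradigm: 12 runs of 16 trials (4 trials of
#' each of the four conditions per run, so 48 per condition and 192 per
#' session), cross 2 s / cue 1 s / task 3.5 s / relax 4 s segment timing,
#' 1200 Hz sampling.
#'
#' @param n_runs Number of runs per session.
#' @param trials_per_run Named integer vector: trials per condition within
#'   each run. Names must be the four condition labels.
#' @param fs Sampling rate in Hz. Must exceed twice the highest simulated
#'   oscillation frequency.
#' @param montage Character vector of 16 unique channel labels.
#' @param timing Named list of segment durations in seconds:
#'   `cross`, `cue`, `task`, `relax`.
#' @param alpha_amp,beta_amp RMS amplitude (microvolt) of the alpha
#'   (8-13 Hz) and beta (14-30 Hz) narrowband components; scalar or one
#'   value per channel.
#' @param noise_amp RMS amplitude (microvolt) of the broadband 1/f
#'   background.
#' @param noise_exponent Spectral exponent of the background
#'   (power ~ 1/f^exponent).
#' @param erd_depth Condition x channel matrix of fractional power
#'   reductions in `[0, 1)` applied to both rhythm components during the
#'   task segment. Row names must be the condition labels; the `rest` row
#'   must be zero.
#' @param erd_latency Seconds after task onset over which the amplitude
#'   ramps linearly from baseline to its attenuated level.
#' @param artifact_rate Probability per trial of an injected high-amplitude
#'   transient (see [inject_artifacts()]).
#' @param artifact_amp Peak amplitude (microvolt) of injected transients.
#' @param coupling `NULL`, or a list describing a lagged shared source
#'   between two channels, with elements `chan_a`, `chan_b`, `lag` (s),
#'   `gain` (RMS microvolt), `band` (`c(low, high)` Hz) and `conditions`
#'   (labels during whose task windows the source is active, or `"all"`).
#' @return An object of class `sim_config` (a validated list).
#' @seealso [build_trial_schedule()], [synthesize_session()]
#' @export
#' @examples
#' cfg <- sim_config(fs = 250)
#' cfg$n_runs
sim_config <- function(n_runs = 12,
                       trials_per_run = c("rest" = 4, "V-rest" = 4,
                                          "no-LMI" = 4, "KI-LMI" = 4),
                       fs = 1200,
                       montage = sensorimotor_montage(),
                       timing = list(cross = 2, cue = 1, task = 3.5, relax = 4),
                       alpha_amp = 10,
                       beta_amp = 5,
                       noise_amp = 5,
                       noise_exponent = 1,
                       erd_depth = erd_depth_profile(montage),
                       erd_latency = 0.5,
                       artifact_rate = 0,
                       artifact_amp = 300,
                       coupling = NULL) {
  conds <- mi_conditions()
  if (n_runs < 1 || n_runs != round(n_runs)) {
    abort("`n_runs` must be a positive integer.", class = "kibci_config_error")
  }
  if (is.null(names(trials_per_run)) ||
      !setequal(names(trials_per_run), conds)) {
    abort("`trials_per_run` must be named with the four condition labels.",
          class = "kibci_config_error")
  }
  trials_per_run <- trials_per_run[conds]
  if (any(trials_per_run < 0) || all(trials_per_run == 0) ||
      any(trials_per_run != round(trials_per_run))) {
    abort("`trials_per_run` must be non-negative integers, not all zero.",
          class = "kibci_config_error")
  }
  if (anyDuplicated(montage) || length(montage) != 16L) {
    abort("`montage` must contain exactly 16 unique channel labels.",
          class = "kibci_config_error")
  }
  stopifnot(is.list(timing),
            all(c("cross", "cue", "task", "relax") %in% names(timing)))
  if (fs <= 2 * 30) {
    abort("`fs` must exceed twice the highest simulated frequency (30 Hz).",
          class = "kibci_config_error")
  }
  erd_depth <- as.matrix(erd_depth)
  if (!setequal(rownames(erd_depth), conds) ||
      !identical(colnames(erd_depth)[order(colnames(erd_depth))],
                 montage[order(montage)])) {
    abort("`erd_depth` must be a condition x channel matrix matching the montage.",
          class = "kibci_config_error")
  }
  erd_depth <- erd_depth[conds, montage, drop = FALSE]
  if (any(erd_depth < 0) || any(erd_depth >= 1)) {
    abort("`erd_depth` entries must lie in [0, 1).",
          class = "kibci_config_error")
  }
  if (any(erd_depth["rest", ] != 0)) {
    abort("`erd_depth` must be zero for the rest condition.",
          class = "kibci_config_error")
  }
  if (artifact_rate < 0 || artifact_rate > 1) {
    abort("`artifact_rate` must lie in [0, 1].", class = "kibci_config_error")
  }
  recycle16 <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, 16L)
    if (length(x) != 16L || any(x < 0)) {
      abort(paste0("`", what, "` must be a non-negative scalar or one value per channel."),
            class = "kibci_config_error")
    }
    setNames(as.numeric(x), montage)
  }
  structure(
    list(n_runs = as.integer(n_runs),
         trials_per_run = trials_per_run,
         fs = fs,
         montage = montage,
         timing = timing,
         alpha_amp = recycle16(alpha_amp, "alpha_amp"),
         beta_amp = recycle16(beta_amp, "beta_amp"),
         noise_amp = noise_amp,
         noise_exponent = noise_exponent,
         erd_depth = erd_depth,
         erd_latency = erd_latency,
         artifact_rate = artifact_rate,
         artifact_amp = artifact_amp,
         coupling = coupling),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_trial <- sum(x$trials_per_run) * x$n_runs
  cat("<sim_config>\n")
  cat(sprintf("  %d runs x %d trials = %d trials, fs = %g Hz\n",
              x$n_runs, sum(x$trials_per_run), n_trial, x$fs))
  cat(sprintf("  timing: cross %g s | cue %g s | task %g s | relax %g s\n",
              x$timing$cross, x$timing$cue, x$timing$task, x$timing$relax))
  mod <- colnames(x$erd_depth)[colSums(x$erd_depth) > 0]
  cat(sprintf("  ERD-modulated channels: %s\n",
              paste(mod, collapse = ", ")))
  invisible(x)
}

# duration of one trial slot in seconds
trial_slot_duration <- function(timing) {
  timing$cross + timing$cue + timing$task + timing$relax
}
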
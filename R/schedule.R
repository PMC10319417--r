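#' Build a randomized trial schedule for a session
#'
#' Lays out the cue paradigm: within every run the configured number of
#' trials per condition is shuffled uniformly, and trials are placed on a
#' fixed time grid (cross, cue, task, relax segments back to back). Trial
#' timing is expressed by two onsets per trial: `cue_onset` (text cue
#' appears) and `task_onset` (task segment starts, the t = 0 reference used
#' by all downstream windows).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return A `trial_schedule`: a tibble with columns `run`, `trial`
#'   (1-based within run), `condition` (factor over [mi_conditions()]),
#'   `cue_onset` and `task_onset` (seconds into the session), carrying the
#'   segment timing as an attribute.
#' @export
#' @examples
#' sched <- build_trial_schedule(sim_config(fs = 250), seed = 1)
#' nrow(sched)   # 192 trials: 8 rest-type + 8 imagery-type in each of 12 runs
#' table(sched$condition)
build_trial_schedule <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  slot <- trial_slot_duration(cfg$timing)
  per_run <- sum(cfg$trials_per_run)
  run_len <- per_run * slot
  conds <- rep(names(cfg$trials_per_run), times = cfg$trials_per_run)

  rows <- purrr::map(seq_len(cfg$n_runs), function(r) {
    order_r <- sample(conds)
    start <- (r - 1) * run_len + (seq_len(per_run) - 1) * slot
    tibble(run = r,
           trial = seq_len(per_run),
           condition = order_r,
           cue_onset = start + cfg$timing$cross,
           task_onset = start + cfg$timing$cross + cfg$timing$cue)
  })
  out <- dplyr::bind_rows(rows)
  out$condition <- factor(out$condition, levels = mi_conditions())
  out <- tibble::new_tibble(out, timing = cfg$timing, seed = as.integer(seed),
                            class = "trial_schedule")
  out
}

# save/restore helpers so seeded generators do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
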
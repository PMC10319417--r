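#' Window a continuous session into per-trial epochs
#'
#' Cuts one full segment per scheduled trial (default t = -3 to +4 s
#' relative to task onset: the whole cross/cue period, the task period and
#' 0.5 s of the relaxation), from which the two analysis windows are
#' derived: a 1-s baseline from the cross period (t = -2.5 to -1.5 s) and
#' a 3-s task window (t = 0.5 to 3.5 s; the first 0.5 s after task onset
#' is skipped because cue-locked transients contaminate it). Keeping the
#' full segment lets band-pass filters run over a continuous stretch so
#' filter edge transients stay outside the analysis windows. All windows
#' are half-open `[start, end)` in samples.
#'
#' A trial whose segment falls outside the recording is kept, zero-filled,
#' flagged and reported — never silently dropped.
#'
#' @param session An `eeg_session`.
#' @param baseline_window,task_window Two-element numeric vectors, seconds
#'   relative to task onset.
#' @param full_window Extent of the stored per-trial segment, seconds
#'   relative to task onset; must contain both analysis windows.
#' @return An `epoch_set`: list with `data` (trial x channel x sample
#'   array over `full_window`), `labels` (condition factor), `flagged`
#'   (logical per trial), `flag_reason`, `fs`, `montage`, and the three
#'   window definitions. Use [epoch_window()] to pull a windowed array.
#' @export
extract_epochs <- function(session, baseline_window = c(-2.5, -1.5),
                           task_window = c(0.5, 3.5),
                           full_window = c(-3, 4)) {
  stopifnot(inherits(session, "eeg_session"))
  if (baseline_window[1] < full_window[1] ||
      task_window[2] > full_window[2]) {
    abort("`full_window` must contain the baseline and task windows.",
          class = "kibci_config_error")
  }
  fs <- session$fs
  sched <- session$schedule
  n_trial <- nrow(sched)
  n_ch <- nrow(session$data)
  nf <- round(diff(full_window) * fs)

  data <- array(0, dim = c(n_trial, n_ch, nf))
  flagged <- logical(n_trial)
  reason <- character(n_trial)

  origin <- round(sched$task_onset * fs)      # 0-based sample of t = 0
  f0 <- origin + round(full_window[1] * fs)
  n_total <- ncol(session$data)

  for (k in seq_len(n_trial)) {
    fi <- f0[k] + seq_len(nf)
    if (min(fi) < 1 || max(fi) > n_total) {
      flagged[k] <- TRUE
      reason[k] <- "window out of recording bounds"
      next
    }
    data[k, , ] <- session$data[, fi]
  }
  if (any(flagged)) {
    warn(sprintf("%d trial(s) flagged: windows outside the recording.",
                 sum(flagged)))
  }
  structure(
    list(data = data,
         labels = sched$condition,
         flagged = flagged, flag_reason = reason,
         fs = fs, montage = session$montage,
         baseline_window = baseline_window, task_window = task_window,
         full_window = full_window),
    class = "epoch_set")
}

#' Construct an epoch set from an array
#'
#' Wraps an already-epoched trial x channel x sample array (e.g. data
#' epoched by other software, or test signals built in code) in the
#' container the analysis functions consume. The array must span
#' `full_window` at rate `fs`.
#'
#' @param data Trial x channel x sample numeric array.
#' @param labels Condition label per trial (factor or character).
#' @param fs Sampling rate in Hz.
#' @param montage Channel labels, one per array column.
#' @param baseline_window,task_window,full_window Windows in seconds
#'   relative to task onset, as in [extract_epochs()].
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, montage,
                      baseline_window = c(-2.5, -1.5),
                      task_window = c(0.5, 3.5),
                      full_window = c(-3, 4)) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(labels),
            dim(data)[2] == length(montage))
  if (dim(data)[3] != round(diff(full_window) * fs)) {
    abort("array sample count must equal the full window length times fs.",
          class = "kibci_config_error")
  }
  structure(
    list(data = data, labels = factor(labels),
         flagged = logical(dim(data)[1]),
         flag_reason = character(dim(data)[1]),
         fs = fs, montage = montage,
         baseline_window = baseline_window, task_window = task_window,
         full_window = full_window),
    class = "epoch_set")
}

#' Extract a windowed trial array from an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param segment `"baseline"`, `"task"`, `"full"`, or a numeric
#'   `c(start, end)` in seconds relative to task onset.
#' @return Trial x channel x sample array over the half-open window.
#' @export
epoch_window <- function(epochs, segment = "task") {
  stopifnot(inherits(epochs, "epoch_set"))
  win <- if (is.numeric(segment)) segment
  else switch(segment,
              baseline = epochs$baseline_window,
              task = epochs$task_window,
              full = epochs$full_window,
              abort("unknown segment.", class = "kibci_config_error"))
  fs <- epochs$fs
  i0 <- round((win[1] - epochs$full_window[1]) * fs)
  n <- round(diff(win) * fs)
  if (i0 < 0 || i0 + n > dim(epochs$data)[3]) {
    abort("requested window exceeds the stored segment.",
          class = "kibci_config_error")
  }
  epochs$data[, , i0 + seq_len(n), drop = FALSE]
}

# time stamps (window centres of samples) for a window, s re task onset
window_times <- function(epochs, segment = "task") {
  win <- switch(segment, baseline = epochs$baseline_window,
                task = epochs$task_window, full = epochs$full_window)
  n <- round(diff(win) * epochs$fs)
  win[1] + (seq_len(n) - 0.5) / epochs$fs
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>\n")
  cat(sprintf(
    "  %d trials x %d channels, t = %g..%g s at %g Hz (baseline %g..%g, task %g..%g)\n",
    dim(x$data)[1], dim(x$data)[2], x$full_window[1], x$full_window[2],
    x$fs, x$baseline_window[1], x$baseline_window[2],
    x$task_window[1], x$task_window[2]))
  tab <- table(x$labels[!x$flagged])
  cat("  clean trials:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      sprintf("(%d flagged)\n", sum(x$flagged)))
  invisible(x)
}

#' Number of unflagged trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer count.
#' @export
n_clean_trials <- function(epochs) sum(!epochs$flagged)

#' Flag trials by peak-to-peak amplitude
#'
#' A trial is flagged when any electrode's peak-to-peak value in either the
#' baseline or the task window strictly exceeds the threshold (a trial with
#' peak-to-peak exactly at the threshold is kept). An optional predicate
#' hook supports custom criteria in place of the visual-inspection step
#' that cannot be automated.
#'
#' @param epochs An `epoch_set`.
#' @param p2p_threshold Peak-to-peak threshold in microvolt (default 200).
#' @param predicate Optional `function(baseline_mat, task_mat)` returning
#'   `TRUE` to flag, called per trial with channel x sample matrices.
#' @return A new `epoch_set` with updated flags (flags accumulate: the
#'   operation is idempotent and never unflags).
#' @export
reject_artifacts <- function(epochs, p2p_threshold = 200, predicate = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (p2p_threshold <= 0) {
    abort("`p2p_threshold` must be positive.", class = "kibci_config_error")
  }
  base <- epoch_window(epochs, "baseline")
  task <- epoch_window(epochs, "task")
  p2p <- function(mat) max(apply(mat, 1, function(v) max(v) - min(v)))
  out <- epochs
  n_before <- sum(out$flagged)
  for (k in seq_len(dim(task)[1])) {
    if (out$flagged[k]) next
    bmat <- matrix(base[k, , ], nrow = dim(base)[2])
    tmat <- matrix(task[k, , ], nrow = dim(task)[2])
    hit <- p2p(bmat) > p2p_threshold || p2p(tmat) > p2p_threshold
    if (!hit && !is.null(predicate)) hit <- isTRUE(predicate(bmat, tmat))
    if (hit) {
      out$flagged[k] <- TRUE
      out$flag_reason[k] <- sprintf("peak-to-peak > %g uV", p2p_threshold)
    }
  }
  inform(sprintf("reject_artifacts: %d newly flagged, %d total of %d trials.",
                 sum(out$flagged) - n_before, sum(out$flagged),
                 length(out$flagged)))
  out
}

#' Randomly subsample unflagged trials per condition
#'
#' Uniform selection without replacement among the clean trials of each
#' requested condition, reproducible under the seed. Trials not selected
#' (and all flagged trials) are removed from the returned epoch set.
#'
#' @param epochs An `epoch_set`.
#' @param n_per_condition Number of trials to keep per condition
#'   (default 40, the standard per-task count after rejection).
#' @param conditions Conditions to sample; defaults to all conditions
#'   present among clean trials.
#' @param seed Integer seed.
#' @return A new, smaller `epoch_set`.
#' @export
subsample_trials <- function(epochs, n_per_condition = 40,
                             conditions = NULL, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  conditions <- conditions %||%
    as.character(unique(epochs$labels[!epochs$flagged]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  keep <- integer(0)
  for (cond in conditions) {
    avail <- which(!epochs$flagged & epochs$labels == cond)
    if (length(avail) < n_per_condition) {
      abort(sprintf(
        "condition '%s': %d clean trials available, %d requested.",
        cond, length(avail), n_per_condition),
        class = "kibci_insufficient_trials")
    }
    keep <- c(keep, sort(sample(avail, n_per_condition)))
  }
  keep <- sort(keep)
  subset_epochs(epochs, keep)
}

# index an epoch_set by trial rows
subset_epochs <- function(epochs, idx) {
  out <- epochs
  out$data <- epochs$data[idx, , , drop = FALSE]
  out$labels <- epochs$labels[idx]
  out$flagged <- epochs$flagged[idx]
  out$flag_reason <- epochs$flag_reason[idx]
  out
}
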
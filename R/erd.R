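# Band-power engine shared by the ERD functions.
#
# Implements the classical ERD pipeline: zero-phase band-pass filtering of
# every trial, squaring of the amplitude samples, averaging across trials,
# then smoothing over a moving time window (default 0.25 s, dense
# one-sample hop). Baseline power is the time average of the trial-averaged
# power over the baseline window.

butter_band <- function(band, fs, order = 4) {
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    abort(sprintf("band [%g, %g] Hz must lie inside (0, %g).",
                  band[1], band[2], nyq),
          class = "kibci_config_error")
  }
  signal::butter(order, band / nyq, type = "pass")
}

# squared magnitude response |H(e^{-iw})|^2 of an IIR filter on the FFT
# grid of length n: the transfer function of forward-backward (zero-phase)
# application of that filter
zerophase_response <- function(filt, n) {
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(complex(imaginary = -w))
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.numeric(Mod(num / den)^2)
}

# zero-phase band-pass of many series at once: odd-reflection padding at
# both ends (so the filter sees warmed-up samples, not a hard edge), then
# the squared Butterworth magnitude response applied on the FFT grid of
# every column
zerophase_filter_mat <- function(mat, filt, pad = nrow(mat) %/% 4) {
  n <- nrow(mat)
  pad <- min(pad, n - 1)
  top <- 2 * matrix(mat[1, ], pad, ncol(mat), byrow = TRUE) -
    mat[(pad + 1):2, , drop = FALSE]
  bot <- 2 * matrix(mat[n, ], pad, ncol(mat), byrow = TRUE) -
    mat[(n - 1):(n - pad), , drop = FALSE]
  ext <- rbind(top, mat, bot)
  gain <- zerophase_response(filt, nrow(ext))
  y <- Re(stats::mvfft(stats::mvfft(ext) * gain, inverse = TRUE)) / nrow(ext)
  y[pad + seq_len(n), , drop = FALSE]
}

# zero-phase filter one [trial, ch, sample] array -> same dims
band_filter_epochs <- function(x, filt) {
  d <- dim(x)
  mat <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])   # sample x (trial*ch)
  y <- zerophase_filter_mat(mat, filt)
  aperm(array(y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}

# filter + square one segment array [trial, ch, sample] -> same dims
squared_band_amplitude <- function(x, filt) {
  band_filter_epochs(x, filt)^2
}

moving_average_valid <- function(v, w) {
  sm <- stats::filter(v, rep(1 / w, w), sides = 2)
  as.numeric(sm[!is.na(sm)])
}

#' Trial-averaged instantaneous band power
#'
#' Band-pass filters every unflagged trial (zero-phase 4th-order
#' Butterworth), squares the samples, averages across trials, and smooths
#' the trial-averaged power with a centred moving window. Smoothing windows
#' truncated at segment edges are dropped, so the returned time grid is
#' slightly shorter than the segment.
#'
#' The whole stored per-trial segment is filtered in one pass so that
#' filter edge transients fall outside the analysis windows; the returned
#' grid is then cut to the requested segment.
#'
#' @param epochs An `epoch_set`.
#' @param band `c(low, high)` in Hz.
#' @param condition Condition label(s) whose trials enter the average;
#'   `NULL` means all unflagged trials.
#' @param window Moving-average window length in seconds (default 0.25).
#' @param segment `"task"`, `"baseline"` or `"full"`.
#' @param keep_trials If `TRUE`, also return the per-trial squared
#'   amplitude array (unsmoothed, full segment).
#' @return A list: `power` (channel x time matrix, trial-averaged and
#'   smoothed), `time` (seconds relative to task onset), `base_power`
#'   (per-channel baseline power: time average of the trial-averaged
#'   power over the baseline window), `n_trials`, and optionally `trials`
#'   with its `trial_time` grid.
#' @export
instantaneous_power <- function(epochs, band, condition = NULL,
                                window = 0.25, segment = "task",
                                keep_trials = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  filt <- butter_band(band, epochs$fs)
  idx <- which(!epochs$flagged &
                 (if (is.null(condition)) TRUE
                  else epochs$labels %in% condition))
  if (length(idx) == 0) {
    abort("no unflagged trials for the requested condition.",
          class = "kibci_config_error")
  }
  x <- epochs$data[idx, , , drop = FALSE]
  sq <- squared_band_amplitude(x, filt)
  avg <- apply(sq, c(2, 3), mean)                       # ch x sample
  full_t <- window_times(epochs, "full")

  base_mask <- full_t >= epochs$baseline_window[1] &
    full_t < epochs$baseline_window[2]
  base_power <- rowMeans(avg[, base_mask, drop = FALSE])

  w <- max(1L, round(window * epochs$fs))
  sm <- t(apply(avg, 1, moving_average_valid, w = w))
  drop_each <- (ncol(avg) - ncol(sm)) / 2
  sm_t <- full_t[(drop_each + 1):(drop_each + ncol(sm))]

  win <- switch(segment, full = epochs$full_window,
                task = epochs$task_window,
                baseline = epochs$baseline_window)
  seg_mask <- sm_t >= win[1] & sm_t < win[2]

  out <- list(power = sm[, seg_mask, drop = FALSE], time = sm_t[seg_mask],
              base_power = base_power,
              n_trials = length(idx), band = band,
              montage = epochs$montage)
  if (keep_trials) {
    out$trials <- sq
    out$trial_time <- full_t
  }
  out
}

#' ERD time course in percent
#'
#' Computes the instantaneous event-related desynchronization
#' `ERD(t) = (P_t - P_base) / P_base * 100` from trial-averaged band power,
#' per channel and condition: negative values are power decreases (ERD),
#' positive values increases (ERS). Since power is nonnegative the curve is
#' bounded below by -100.
#'
#' @inheritParams instantaneous_power
#' @param conditions Condition labels to compute (default: all present).
#' @param channels Channel labels to keep (default: all).
#' @return An `erd_result` tibble: `condition`, `channel`, `time` (s,
#'   relative to task onset), `erd` (%), with the band and window as
#'   attributes.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_runs = 2, fs = 250)
#' ep <- extract_epochs(synthesize_session(cfg, seed = 1))
#' erd <- erd_timecourse(ep, band = c(8, 30), conditions = "KI-LMI",
#'                       channels = "Cz")
#' head(erd)
#' }
erd_timecourse <- function(epochs, band = c(8, 30), conditions = NULL,
                           channels = NULL, window = 0.25) {
  conditions <- conditions %||%
    as.character(sort(unique(epochs$labels[!epochs$flagged])))
  channels <- channels %||% epochs$montage
  ch_idx <- match(channels, epochs$montage)
  stopifnot(!anyNA(ch_idx))

  rows <- purrr::map(conditions, function(cond) {
    ip <- instantaneous_power(epochs, band, condition = cond,
                              window = window)
    if (any(ip$base_power[ch_idx] <= 0)) {
      abort("baseline power is zero: ERD undefined.",
            class = "kibci_degenerate_input")
    }
    purrr::map(seq_along(ch_idx), function(j) {
      ch <- ch_idx[j]
      tibble(condition = cond, channel = channels[j], time = ip$time,
             erd = (ip$power[ch, ] - ip$base_power[ch]) /
               ip$base_power[ch] * 100)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, band = band, window = window,
                     class = "erd_result")
}

#' Mean ERD over the task window
#'
#' The scalar summary `(P_task - P_base) / P_base * 100` per channel, band
#' and condition, where `P_task` and `P_base` are time averages of the
#' trial-averaged power over the task and baseline windows. These are the
#' values used for topography export and channel-level statistics.
#'
#' @inheritParams erd_timecourse
#' @param bands Named list of `c(low, high)` ranges (default
#'   [mi_bands()]).
#' @return A tibble: `condition`, `channel`, `band`, `erd_mean` (%).
#' @export
erd_mean <- function(epochs, bands = mi_bands(), conditions = NULL,
                     channels = NULL) {
  conditions <- conditions %||%
    as.character(sort(unique(epochs$labels[!epochs$flagged])))
  channels <- channels %||% epochs$montage
  ch_idx <- match(channels, epochs$montage)
  stopifnot(!anyNA(ch_idx))
  if (is.numeric(bands)) bands <- list(band = bands)

  full_t <- window_times(epochs, "full")
  base_mask <- full_t >= epochs$baseline_window[1] &
    full_t < epochs$baseline_window[2]
  task_mask <- full_t >= epochs$task_window[1] &
    full_t < epochs$task_window[2]

  purrr::imap(bands, function(rng, band_name) {
    filt <- butter_band(rng, epochs$fs)
    purrr::map(conditions, function(cond) {
      idx <- which(!epochs$flagged & epochs$labels == cond)
      sq <- squared_band_amplitude(epochs$data[idx, , , drop = FALSE], filt)
      avg <- apply(sq, c(2, 3), mean)
      p_task <- rowMeans(avg[, task_mask, drop = FALSE])
      p_base <- rowMeans(avg[, base_mask, drop = FALSE])
      if (any(p_base[ch_idx] <= 0)) {
        abort("baseline power is zero: ERD undefined.",
              class = "kibci_degenerate_input")
      }
      tibble(condition = cond, channel = channels, band = band_name,
             erd_mean = (p_task[ch_idx] - p_base[ch_idx]) /
               p_base[ch_idx] * 100)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Minimum ERD and arrival time of an ERD trace
#'
#' `e_min` is the lowest ERD value over the task window; the arrival time
#' is the first time the trace reaches a reference level. With
#' `reference = "self-min"` the reference is the trace's own minimum (the
#' arrival time is then the time of the minimum); passing a numeric
#' reference (e.g. another condition's `e_min`) gives the time to first
#' reach that level, `NA` with `reached = FALSE` when never reached.
#'
#' @param erd An `erd_result` (or any tibble with `condition`, `channel`,
#'   `time`, `erd`).
#' @param reference `"self-min"` or a numeric ERD level in percent.
#' @return A tibble: `condition`, `channel`, `e_min` (%), `t_min` (s),
#'   `t_arrival` (s or `NA`), `reached` (logical).
#' @export
emin_arrival <- function(erd, reference = "self-min") {
  stopifnot(all(c("condition", "channel", "time", "erd") %in% names(erd)))
  erd |>
    dplyr::group_by(.data$condition, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      i_min <- which.min(df$erd)
      ref <- if (identical(reference, "self-min")) df$erd[i_min] else reference
      hit <- which(df$erd <= ref)
      tibble(e_min = df$erd[i_min],
             t_min = df$time[i_min],
             t_arrival = if (length(hit)) df$time[hit[1]] else NA_real_,
             reached = length(hit) > 0)
    }) |>
    dplyr::ungroup()
}

#' Relative power in decibel against a reference condition
#'
#' `10 * log10(P_t(condition) / P_t(reference))` on the task-window time
#' grid, both numerator and denominator trial-averaged and smoothed with
#' the same moving window. With `reference_condition = NULL` the
#' denominator is the condition's own baseline power (a log-scaled ERD
#' trace). Note this decibel quantity is a different scale from the
#' percent ERD: a 21% power drop is about -1.0 dB.
#'
#' @inheritParams erd_timecourse
#' @param condition Condition of interest.
#' @param reference_condition Reference condition, or `NULL` for the own
#'   baseline.
#' @return A tibble: `channel`, `time`, `db`.
#' @export
relative_power_db <- function(epochs, band = c(8, 13), condition,
                              reference_condition = NULL, channels = NULL,
                              window = 0.25) {
  channels <- channels %||% epochs$montage
  ch_idx <- match(channels, epochs$montage)
  ip <- instantaneous_power(epochs, band, condition = condition,
                            window = window)
  if (is.null(reference_condition)) {
    ref_power <- matrix(ip$base_power, nrow = length(ip$base_power),
                        ncol = ncol(ip$power))
  } else {
    ipr <- instantaneous_power(epochs, band, condition = reference_condition,
                               window = window)
    ref_power <- ipr$power
  }
  if (any(ref_power[ch_idx, ] <= 0) || any(ip$power[ch_idx, ] <= 0)) {
    abort("nonpositive power: decibel ratio undefined.",
          class = "kibci_degenerate_input")
  }
  purrr::map(seq_along(ch_idx), function(j) {
    ch <- ch_idx[j]
    tibble(channel = channels[j], time = ip$time,
           db = 10 * log10(ip$power[ch, ] / ref_power[ch, ]))
  }) |> dplyr::bind_rows()
}

#' @describeIn erd_timecourse Plot ERD traces per channel and condition.
#' @param object,... An `erd_result` and ignored extra arguments.
#' @method autoplot erd_result
#' @export
autoplot.erd_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$erd,
                               colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time from task onset (s)", y = "ERD (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
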
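# Cross-spectral machinery: one task epoch = one Welch segment, Hann
# tapered, spectra averaged across trials. With 3-s epochs the frequency
# resolution is ~0.33 Hz.

# FFT of every (trial, channel) task epoch after demeaning and tapering
epoch_spectra <- function(epochs, segment = "task") {
  x <- epoch_window(epochs, segment)
  idx <- which(!epochs$flagged)
  x <- x[idx, , , drop = FALSE]
  d <- dim(x)
  if (d[1] < 2) {
    abort("coherency needs at least 2 trials (single-segment coherence is degenerate).",
          class = "kibci_config_error")
  }
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(d[3]) / (d[3] + 1)))
  nf <- floor(d[3] / 2) + 1
  spec <- array(complex(real = 0), dim = c(d[1], d[2], nf))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      v <- x[tr, ch, ]
      v <- (v - mean(v)) * taper
      spec[tr, ch, ] <- fft(v)[seq_len(nf)]
    }
  }
  list(spec = spec, freq = (seq_len(nf) - 1) * epochs$fs / d[3],
       n_trials = d[1], labels = epochs$labels[idx])
}

#' Complex coherency between two channels
#'
#' `R_xy(f) = S_xy(f) / sqrt(S_xx(f) S_yy(f))` with cross- and auto-spectra
#' averaged across trials (each Hann-tapered task epoch is one segment).
#' The cross-spectrum convention is `S_xy = <X(f) * Conj(Y(f))>`, so a
#' channel y lagging x by a quarter period at f gives `Im R_xy(f) ~ +1`.
#' `|R| <= 1` by Cauchy-Schwarz.
#'
#' @param epochs An `epoch_set`.
#' @param pair Two channel labels `c(x, y)`.
#' @param condition Optional condition label(s) restricting the trials.
#' @param segment `"task"` (default) or `"baseline"`.
#' @return A tibble: `freq` (Hz), `coherency` (complex), `coherence`
#'   (`|R|`), `icoh` (`Im R`).
#' @export
coherency <- function(epochs, pair, condition = NULL, segment = "task") {
  stopifnot(length(pair) == 2)
  ep <- epochs
  if (!is.null(condition)) {
    ep <- subset_epochs(epochs, which(epochs$labels %in% condition))
  }
  sp <- epoch_spectra(ep, segment)
  ix <- match(pair[1], epochs$montage)
  iy <- match(pair[2], epochs$montage)
  stopifnot(!anyNA(c(ix, iy)))
  X <- sp$spec[, ix, ]
  Y <- sp$spec[, iy, ]
  sxy <- colMeans(X * Conj(Y))
  sxx <- colMeans(Mod(X)^2)
  syy <- colMeans(Mod(Y)^2)
  r <- sxy / sqrt(sxx * syy)
  tibble(freq = sp$freq, coherency = r, coherence = Mod(r), icoh = Im(r))
}

#' Band-averaged imaginary-coherency matrix over all channel pairs
#'
#' Computes `iCOH(f) = Im R_xy(f)` for every channel pair and averages
#' `|Im R|` over the in-band frequency bins (absolute value before
#' averaging, so opposite-phase bins do not cancel; the signed band mean is
#' retained alongside). The imaginary part discards zero-lag
#' (volume-conducted) mixing: a signal is not time-lagged with itself, so
#' the diagonal is identically zero and the signed matrix is antisymmetric.
#'
#' @inheritParams coherency
#' @param band `c(low, high)` in Hz.
#' @return An `icoh_matrix`: list with `abs` (symmetric 16 x 16 matrix of
#'   band-mean `|Im R|`), `signed` (antisymmetric band-mean `Im R`),
#'   `band`, `n_trials`, `montage`.
#' @export
icoh_matrix <- function(epochs, band, condition = NULL, segment = "task") {
  ep <- epochs
  if (!is.null(condition)) {
    ep <- subset_epochs(epochs, which(epochs$labels %in% condition))
  }
  sp <- epoch_spectra(ep, segment)
  in_band <- which(sp$freq >= band[1] & sp$freq <= band[2])
  if (length(in_band) == 0) {
    abort("band contains no frequency bins at this resolution.",
          class = "kibci_config_error")
  }
  n_ch <- dim(sp$spec)[2]
  chan_spec <- function(ch) matrix(sp$spec[, ch, in_band],
                                   nrow = sp$n_trials)   # trials x bins
  specs <- lapply(seq_len(n_ch), chan_spec)
  auto <- sapply(specs, function(m) colMeans(Mod(m)^2))  # bins x ch
  vabs <- matrix(0, n_ch, n_ch, dimnames = list(epochs$montage,
                                                epochs$montage))
  vsgn <- vabs
  for (i in seq_len(n_ch - 1)) {
    for (j in (i + 1):n_ch) {
      sxy <- colMeans(specs[[i]] * Conj(specs[[j]]))
      im <- Im(sxy / sqrt(auto[, i] * auto[, j]))
      vabs[i, j] <- vabs[j, i] <- mean(abs(im))
      vsgn[i, j] <- mean(im)
      vsgn[j, i] <- -mean(im)
    }
  }
  structure(list(abs = vabs, signed = vsgn, band = band,
                 n_trials = sp$n_trials, montage = epochs$montage),
            class = "icoh_matrix")
}

#' Grand average of connectivity matrices
#'
#' Elementwise mean of the absolute and signed band matrices across
#' sessions/subjects; trial counts add.
#'
#' @param matrices List of `icoh_matrix` objects with identical montage
#'   and band.
#' @return An `icoh_matrix`.
#' @export
icoh_grand_average <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "icoh_matrix")))
  m1 <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(m$montage, m1$montage) || !identical(m$band, m1$band)) {
      abort("grand average requires identical montage and band.",
            class = "kibci_config_error")
    }
  }
  structure(list(
    abs = Reduce(`+`, lapply(matrices, `[[`, "abs")) / length(matrices),
    signed = Reduce(`+`, lapply(matrices, `[[`, "signed")) / length(matrices),
    band = m1$band,
    n_trials = sum(vapply(matrices, `[[`, 1, "n_trials")),
    montage = m1$montage), class = "icoh_matrix")
}

#' @export
print.icoh_matrix <- function(x, ...) {
  cat("<icoh_matrix>\n")
  cat(sprintf("  band %g-%g Hz, %d trials, %d channels\n",
              x$band[1], x$band[2], x$n_trials, length(x$montage)))
  top <- utils::head(dplyr::arrange(tidy(x), dplyr::desc(.data$icoh_abs)), 3)
  cat("  strongest edges:",
      paste(sprintf("%s-%s %.3f", top$channel_a, top$channel_b,
                    top$icoh_abs), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a connectivity matrix into an edge list
#'
#' @param x An `icoh_matrix`.
#' @param ... Unused.
#' @return A tibble: `channel_a`, `channel_b`, `band`, `icoh_abs`,
#'   `icoh_signed` (one row per unordered pair).
#' @method tidy icoh_matrix
#' @export
tidy.icoh_matrix <- function(x, ...) {
  n <- length(x$montage)
  idx <- which(upper.tri(x$abs), arr.ind = TRUE)
  tibble(channel_a = x$montage[idx[, 1]],
         channel_b = x$montage[idx[, 2]],
         band = sprintf("%g-%g Hz", x$band[1], x$band[2]),
         icoh_abs = x$abs[idx],
         icoh_signed = x$signed[idx])
}

#' Strongest connectivity edges
#'
#' Display helper mirroring connectivity maps that draw only the strongest
#' lines.
#'
#' @param x An `icoh_matrix`.
#' @param k Number of edges to keep (default 20).
#' @return Edge tibble of the top-`k` pairs by `icoh_abs`.
#' @export
top_edges <- function(x, k = 20) {
  tidy(x) |>
    dplyr::arrange(dplyr::desc(.data$icoh_abs)) |>
    utils::head(k)
}

#' @describeIn icoh_matrix Heatmap of the band-averaged `|iCOH|` matrix.
#' @param object,... An `icoh_matrix` and ignored extra arguments.
#' @method autoplot icoh_matrix
#' @export
autoplot.icoh_matrix <- function(object, ...) {
  df <- tidy(object)
  df$channel_a <- factor(df$channel_a, levels = object$montage)
  df$channel_b <- factor(df$channel_b, levels = object$montage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_a,
                                   y = .data$channel_b,
                                   fill = .data$icoh_abs)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "|iCOH|") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Imaginary coherency, %g-%g Hz",
                                  object$band[1], object$band[2])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
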
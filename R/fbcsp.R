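#' Filter-bank sub-bands
#'
#' The six 7-32 Hz sub-bands used by the FBCSP feature extractor.
#'
#' @return Named list of `c(low, high)` ranges in Hz.
#' @export
fbcsp_bands <- function() {
  list("7-12" = c(7, 12), "12-16" = c(12, 16), "16-20" = c(16, 20),
       "20-24" = c(20, 24), "24-28" = c(24, 28), "28-32" = c(28, 32))
}

#' Band-pass filtered copies of task epochs
#'
#' Applies a zero-phase band-pass per sub-band to the task-window array.
#'
#' @param x Trial x channel x sample array, or an `epoch_set` (its task
#'   array is used).
#' @param fs Sampling rate in Hz (taken from the epoch set when given).
#' @param bands Named list of ranges (default [fbcsp_bands()]).
#' @return Named list of filtered trial x channel x sample arrays.
#' @export
filter_bank <- function(x, fs = NULL, bands = fbcsp_bands()) {
  if (inherits(x, "epoch_set")) {
    fs <- x$fs
    x <- epoch_window(x, "task")
  }
  stopifnot(length(dim(x)) == 3, !is.null(fs))
  lapply(bands, function(rng) {
    band_filter_epochs(x, butter_band(rng, fs))
  })
}

# per-trial channel covariances of a trial x channel x sample array:
# [trial, ch, ch], each from the row-centred trial matrix
trial_covariances <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[2]))
  for (tr in seq_len(d[1])) {
    m <- x[tr, , ]
    m <- m - rowMeans(m)
    out[tr, , ] <- tcrossprod(m) / ncol(m)
  }
  out
}

# per-band per-trial covariances for a filter-bank output
band_trial_covariances <- function(banded) lapply(banded, trial_covariances)

# average trace-normalized covariance over trials; accepts an array or a
# [trial, ch, ch] covariance stack
class_covariance <- function(x) {
  covs <- if (length(dim(x)) == 3 && dim(x)[2] == dim(x)[3] &&
                is_cov_stack(x)) x else trial_covariances(x)
  d <- dim(covs)
  acc <- matrix(0, d[2], d[2])
  for (tr in seq_len(d[1])) {
    cc <- covs[tr, , ]
    acc <- acc + cc / sum(diag(cc))
  }
  acc / d[1]
}

is_cov_stack <- function(x) isTRUE(attr(x, "cov_stack"))

as_cov_stack <- function(covs) {
  attr(covs, "cov_stack") <- TRUE
  covs
}

# log-variance features from cached per-trial covariances: the variance of
# a spatially filtered component is diag(W C_trial W"), and the sample-
# variance scaling cancels in the normalized log features
csp_features_from_covs <- function(filters, covs) {
  w_sel <- filters$w[filters$selected, , drop = FALSE]
  n_tr <- dim(covs)[1]
  feat <- matrix(0, n_tr, nrow(w_sel))
  for (tr in seq_len(n_tr)) {
    v <- diag(w_sel %*% covs[tr, , ] %*% t(w_sel))
    feat[tr, ] <- log(v / sum(v))
  }
  feat
}

#' Fit common spatial patterns for a two-class problem
#'
#' Solves the generalized eigenproblem `Sigma_a w = lambda (Sigma_a +
#' Sigma_b) w` on trace-normalized average class covariances, by Cholesky
#' whitening of the composite covariance followed by a symmetric
#' eigendecomposition. Filters (rows of `W`) are sorted by descending
#' eigenvalue and normalized so `W (Sigma_a + Sigma_b) W' = I`; the
#' eigenvalue of filter k is the fraction of composite-covariance variance
#' carried by class a along that filter, so class-swapped fits map
#' `lambda -> 1 - lambda` with the filter order reversed. The first and
#' last `n_pairs` filters are the discriminative set.
#'
#' @param x_a,x_b Trial x channel x sample arrays for the two classes, or
#'   precomputed covariance matrices.
#' @param n_pairs Number of filter pairs to select (default 2, i.e. 4
#'   components).
#' @return A `csp_filters` object: list with `w` (all filters, channels as
#'   columns), `eigenvalues`, `selected` (row indices of the `2 * n_pairs`
#'   selected filters), `n_pairs`.
#' @export
csp_fit <- function(x_a, x_b, n_pairs = 2) {
  cov_a <- if (is.matrix(x_a)) x_a else class_covariance(x_a)
  cov_b <- if (is.matrix(x_b)) x_b else class_covariance(x_b)
  stopifnot(identical(dim(cov_a), dim(cov_b)))
  n_ch <- nrow(cov_a)
  if (2 * n_pairs > n_ch) {
    abort("`n_pairs` too large for the channel count.",
          class = "kibci_config_error")
  }
  comp <- cov_a + cov_b
  ev <- eigen(comp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    gamma <- 1e-6
    comp <- (1 - gamma) * comp + gamma * mean(diag(comp)) * diag(n_ch)
    cov_a <- (1 - gamma) * cov_a + gamma * mean(diag(cov_a)) * diag(n_ch)
    inform("csp_fit: rank-deficient composite covariance, shrinkage applied.")
  }
  L <- chol(comp)                       # comp = L' L (upper triangular L)
  # M = L'^-1 Sigma_a L^-1 is symmetric; eigenvectors V give W = L^-1 V
  M <- backsolve(L, t(backsolve(L, t(cov_a), transpose = TRUE)),
                 transpose = TRUE)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  ord <- order(-es$values, seq_len(n_ch))
  w <- t(backsolve(L, es$vectors))[ord, , drop = FALSE]
  # deterministic sign: largest-magnitude coefficient positive
  for (k in seq_len(nrow(w))) {
    pivot <- which.max(abs(w[k, ]))
    if (w[k, pivot] < 0) w[k, ] <- -w[k, ]
  }
  structure(list(w = w, eigenvalues = es$values[ord],
                 selected = c(seq_len(n_pairs),
                              (n_ch - n_pairs + 1):n_ch),
                 n_pairs = n_pairs),
            class = "csp_filters")
}

#' Log-variance CSP features
#'
#' Projects every trial through the selected spatial filters and returns
#' the log of each component's share of the projected variance,
#' `log(var_k / sum(var))` — invariant to a global scaling of the epoch.
#'
#' @param filters A `csp_filters` object.
#' @param x Trial x channel x sample array.
#' @return Trial x component feature matrix.
#' @export
csp_features <- function(filters, x) {
  stopifnot(inherits(filters, "csp_filters"), length(dim(x)) == 3)
  w_sel <- filters$w[filters$selected, , drop = FALSE]
  d <- dim(x)
  feat <- matrix(0, d[1], nrow(w_sel))
  for (tr in seq_len(d[1])) {
    z <- w_sel %*% (x[tr, , ] - rowMeans(x[tr, , ]))
    v <- apply(z, 1, stats::var)
    feat[tr, ] <- log(v / sum(v))
  }
  feat
}

# mutual information (bits) between a continuous feature and class labels,
# equal-frequency histogram estimator
feature_mi <- function(f, labels, n_bins = NULL) {
  n <- length(f)
  n_bins <- n_bins %||% max(2L, ceiling(log2(n)) + 1L)
  cuts <- unique(stats::quantile(f, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(cuts) < 3) return(0)       # (near-)constant feature
  bin <- cut(f, breaks = cuts, include.lowest = TRUE)
  joint <- table(bin, labels) / n
  pb <- rowSums(joint)
  pc <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(pb, pc)[nz]))
}

#' Mutual-information feature selection
#'
#' Ranks features by the estimated mutual information between each feature
#' and the class label (equal-frequency histogram estimator) and returns
#' the indices of the top `k`, ties broken toward the lower index.
#'
#' @param features Trial x feature matrix.
#' @param labels Class labels (two levels).
#' @param k Number of features to select (default 8).
#' @return Integer vector of `k` column indices, in rank order.
#' @export
mibif_select <- function(features, labels, k = 8) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (k > ncol(features)) {
    abort("`k` exceeds the number of candidate features.",
          class = "kibci_config_error")
  }
  mi <- apply(features, 2, feature_mi, labels = labels)
  order(-mi, seq_along(mi))[seq_len(k)]
}
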
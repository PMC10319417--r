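#' The four condition pairings used for evaluation
#'
#' D1: rest vs V-rest; D2: rest vs no-LMI; D3: rest vs KI-LMI;
#' D4: V-rest vs KI-LMI (the simulated-online pairing).
#'
#' @return Named list mapping `D1`..`D4` to `c(class0, class1)` condition
#'   labels; the second condition is the positive class.
#' @export
dataset_pairings <- function() {
  list(D1 = c("rest", "V-rest"),
       D2 = c("rest", "no-LMI"),
       D3 = c("rest", "KI-LMI"),
       D4 = c("V-rest", "KI-LMI"))
}

#' Assemble a balanced two-class dataset from an epoch set
#'
#' Subsamples `n_per_class` clean trials of each of the pairing's two
#' conditions and relabels them 0/1 (second condition positive).
#'
#' @param epochs An `epoch_set`.
#' @param pairing A pairing name (`"D1"`..`"D4"`) or a length-2 character
#'   vector of condition labels.
#' @param n_per_class Trials per class (default 40).
#' @param seed Integer seed for the subsampling.
#' @return A `dataset_pair`: list with `x` (trial x channel x sample task
#'   array), `y` (factor `0`/`1`), `conditions`, `name`, `fs`, `montage`.
#' @export
make_dataset_pair <- function(epochs, pairing = "D3", n_per_class = 40,
                              seed = 1L) {
  if (is.character(pairing) && length(pairing) == 1) {
    name <- pairing
    conds <- dataset_pairings()[[pairing]]
    if (is.null(conds)) {
      abort("unknown pairing; use D1..D4 or two condition labels.",
            class = "kibci_config_error")
    }
  } else {
    stopifnot(length(pairing) == 2)
    conds <- pairing
    name <- paste(pairing, collapse = "/")
  }
  sub <- subsample_trials(epochs, n_per_condition = n_per_class,
                          conditions = conds, seed = seed)
  y <- factor(ifelse(sub$labels == conds[2], "1", "0"), levels = c("0", "1"))
  structure(list(x = epoch_window(sub, "task"), y = y,
                 conditions = conds, name = name,
                 fs = sub$fs, montage = sub$montage),
            class = "dataset_pair")
}

#' Fit the FBCSP feature pipeline on training trials
#'
#' Per sub-band CSP filters, pooled log-variance features, and
#' mutual-information selection of the top features — fitted entirely on
#' the supplied (training) trials.
#'
#' @param x Trial x channel x sample array (task windows); may be `NULL`
#'   when `band_covs` is supplied.
#' @param y Binary factor labels.
#' @param fs Sampling rate in Hz.
#' @param bands Sub-band list (default [fbcsp_bands()]).
#' @param n_pairs CSP filter pairs per band (default 2).
#' @param k Number of features kept by MI selection (default 8).
#' @param banded Optional precomputed [filter_bank()] output for `x`
#'   (band-pass filtering is trial-wise and label-free, so it may be
#'   shared across cross-validation folds without leakage).
#' @param band_covs Optional per-band, per-trial covariance stacks (the
#'   internal cache used by [train_eval_cv()]); overrides `x`/`banded`.
#' @return An `fbcsp_model`: per-band filters, selected feature indices,
#'   band bookkeeping.
#' @export
fbcsp_fit <- function(x, y, fs, bands = fbcsp_bands(), n_pairs = 2, k = 8,
                      banded = NULL, band_covs = NULL) {
  stopifnot(nlevels(factor(y)) == 2)
  y <- factor(y)
  if (is.null(band_covs)) {
    banded <- banded %||% filter_bank(x, fs = fs, bands = bands)
    band_covs <- band_trial_covariances(banded)
  }
  ia <- y == levels(y)[1]
  filters <- lapply(band_covs, function(cv) {
    csp_fit(class_covariance(as_cov_stack(cv[ia, , , drop = FALSE])),
            class_covariance(as_cov_stack(cv[!ia, , , drop = FALSE])),
            n_pairs = n_pairs)
  })
  feats <- do.call(cbind,
                   purrr::map2(filters, band_covs, csp_features_from_covs))
  sel <- mibif_select(feats, y, k = k)
  structure(list(bands = bands, filters = filters, selected = sel,
                 n_pairs = n_pairs, k = k, fs = fs,
                 n_features = ncol(feats)),
            class = "fbcsp_model")
}

#' Extract selected FBCSP features for new trials
#'
#' @param model An `fbcsp_model`.
#' @param x Trial x channel x sample array.
#' @param banded Optional precomputed [filter_bank()] output for `x`.
#' @param band_covs Optional per-band, per-trial covariance stacks.
#' @return Trial x k feature matrix (columns in MI rank order).
#' @export
fbcsp_transform <- function(model, x, banded = NULL, band_covs = NULL) {
  stopifnot(inherits(model, "fbcsp_model"))
  if (is.null(band_covs)) {
    banded <- banded %||% filter_bank(x, fs = model$fs, bands = model$bands)
    band_covs <- band_trial_covariances(banded)
  }
  feats <- do.call(cbind, purrr::map2(model$filters, band_covs,
                                      csp_features_from_covs))
  feats[, model$selected, drop = FALSE]
}

#' Tidy method for FBCSP models: per-band filter eigenvalues
#' @param x An `fbcsp_model`.
#' @param ... Unused.
#' @return A tibble: `band`, `component`, `eigenvalue`, `selected_csp`.
#' @method tidy fbcsp_model
#' @export
tidy.fbcsp_model <- function(x, ...) {
  purrr::imap(x$filters, function(f, nm) {
    tibble(band = nm, component = seq_along(f$eigenvalues),
           eigenvalue = f$eigenvalues,
           selected_csp = seq_along(f$eigenvalues) %in% f$selected)
  }) |> dplyr::bind_rows()
}

subset_banded <- function(banded, idx) {
  lapply(banded, function(b) b[idx, , , drop = FALSE])
}

stratified_folds <- function(y, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  assign_class <- function(idx) {
    reps <- ceiling(length(idx) / folds)
    sample(rep(seq_len(folds), reps)[seq_along(idx)])
  }
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- assign_class(idx)
  }
  fold
}

default_svm_grid <- function() {
  list(cost = 2 ^ seq(-3, 7, by = 2), gamma = 2 ^ seq(-7, 3, by = 2))
}

# nested inner CV grid search for the RBF-SVM: the whole FBCSP pipeline
# (CSP filters, MI selection) is refitted on every inner-training split so
# the inner validation estimate is leakage-free; ties -> smaller cost,
# then smaller gamma
svm_grid_search <- function(x, y, grid, inner_folds, fs, n_pairs, k, seed,
                            band_covs = NULL) {
  fold <- stratified_folds(y, inner_folds, seed)
  band_covs <- band_covs %||% band_trial_covariances(filter_bank(x, fs = fs))
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  correct <- numeric(nrow(combos))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2) next
    covs_tr <- subset_banded(band_covs, tr)
    inner_model <- fbcsp_fit(x = NULL, y[tr], fs = fs,
                             n_pairs = n_pairs, k = k, band_covs = covs_tr)
    feat_tr <- fbcsp_transform(inner_model, x = NULL, band_covs = covs_tr)
    feat_va <- fbcsp_transform(inner_model, x = NULL,
                               band_covs = subset_banded(band_covs, !tr))
    for (i in seq_len(nrow(combos))) {
      fit <- e1071::svm(x = feat_tr, y = y[tr], kernel = "radial",
                        cost = combos$cost[i], gamma = combos$gamma[i],
                        scale = TRUE)
      correct[i] <- correct[i] + sum(predict(fit, feat_va) == y[!tr])
    }
  }
  acc <- correct / length(y)
  best <- order(-acc, combos$cost, combos$gamma)[1]
  list(cost = combos$cost[best], gamma = combos$gamma[best],
       inner_accuracy = acc[best])
}

#' Cross-validated FBCSP + RBF-SVM evaluation of a dataset pair
#'
#' Stratified outer k-fold cross-validation (default 5). Within every
#' outer training fold the full pipeline is re-fitted from scratch — CSP
#' filters per sub-band, mutual-information feature selection, and an
#' inner cross-validated grid search for the SVM cost `C` and RBF width
#' `gamma` — so no information from the held-out fold reaches any fitting
#' step. Confusion counts are pooled over the outer folds before the
#' accuracy/F1 formulas are applied; per-fold metrics are retained.
#'
#' @param pair A `dataset_pair` (see [make_dataset_pair()]).
#' @param folds Outer folds (default 5).
#' @param grid Named list with `cost` and `gamma` candidate vectors
#'   (default `C = 2^-3..2^7`, `gamma = 2^-7..2^3`).
#' @param inner_folds Folds of the inner tuning loop (default 3).
#' @param n_pairs,k FBCSP hyperparameters (see [fbcsp_fit()]).
#' @param seed Integer seed (fold assignment and inner splits).
#' @param fold_assignment Optional integer vector of precomputed outer
#'   fold ids, overriding the seeded assignment.
#' @return An `eval_report`: pooled confusion counts, accuracy and F1 (%),
#'   per-fold metrics, per-trial predictions, chosen hyperparameters.
#' @export
train_eval_cv <- function(pair, folds = 5, grid = default_svm_grid(),
                          inner_folds = 3, n_pairs = 2, k = 8, seed = 1L,
                          fold_assignment = NULL) {
  stopifnot(inherits(pair, "dataset_pair"))
  y <- pair$y
  if (min(table(y)) < folds) {
    abort("fewer trials per class than folds.",
          class = "kibci_config_error")
  }
  fold <- fold_assignment %||% stratified_folds(y, folds, seed)
  stopifnot(length(fold) == length(y))

  band_covs <- band_trial_covariances(filter_bank(pair$x, fs = pair$fs))
  pred_all <- factor(rep(NA, length(y)), levels = levels(y))
  params <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    covs_tr <- subset_banded(band_covs, tr)
    model <- fbcsp_fit(x = NULL, y[tr], fs = pair$fs,
                       n_pairs = n_pairs, k = k, band_covs = covs_tr)
    feat_tr <- fbcsp_transform(model, x = NULL, band_covs = covs_tr)
    tuned <- svm_grid_search(pair$x[tr, , , drop = FALSE], y[tr], grid,
                             inner_folds, fs = pair$fs, n_pairs = n_pairs,
                             k = k, seed = as.integer(seed) + f,
                             band_covs = covs_tr)
    fit <- e1071::svm(x = feat_tr, y = y[tr], kernel = "radial",
                      cost = tuned$cost, gamma = tuned$gamma, scale = TRUE)
    feat_te <- fbcsp_transform(model, x = NULL,
                               band_covs = subset_banded(band_covs, !tr))
    pred_all[!tr] <- predict(fit, feat_te)
    params[[f]] <- tibble(fold = f, cost = tuned$cost, gamma = tuned$gamma,
                          inner_accuracy = 100 * tuned$inner_accuracy)
  }

  conf <- confusion_counts(truth = y, predicted = pred_all)
  per_fold <- purrr::map(seq_len(folds), function(f) {
    in_fold <- fold == f
    cf <- confusion_counts(y[in_fold], pred_all[in_fold])
    m <- compute_metrics(cf)
    tibble(fold = f, n = sum(in_fold), accuracy = m$accuracy, f1 = m$f1)
  }) |> dplyr::bind_rows()

  pooled <- compute_metrics(conf)
  structure(list(
    name = pair$name, conditions = pair$conditions,
    confusion = conf,
    accuracy = pooled$accuracy, f1 = pooled$f1,
    per_fold = dplyr::left_join(per_fold, dplyr::bind_rows(params),
                                by = "fold"),
    predictions = tibble(trial = seq_along(y), fold = fold,
                         truth = y, predicted = pred_all),
    folds = folds, seed = as.integer(seed)),
    class = "eval_report")
}

confusion_counts <- function(truth, predicted) {
  list(tp = sum(truth == "1" & predicted == "1"),
       fp = sum(truth == "0" & predicted == "1"),
       fn = sum(truth == "1" & predicted == "0"),
       tn = sum(truth == "0" & predicted == "0"))
}

#' Accuracy and F1 score from confusion counts
#'
#' `Acc = (TP + TN) / (TP + TN + FP + FN)` and the F1 score (harmonic mean
#' of precision and recall), both in percent. When precision or recall is
#' undefined (no positive predictions, or no positive truths) F1 is
#' returned as `NA` rather than raising.
#'
#' @param confusion A list or named vector with `tp`, `fp`, `fn`, `tn`.
#' @return A list with `accuracy` and `f1` in percent.
#' @export
#' @examples
#' compute_metrics(list(tp = 40, fp = 0, fn = 0, tn = 40))
compute_metrics <- function(confusion) {
  cf <- as.list(confusion)
  counts <- as.numeric(cf[c("tp", "fp", "fn", "tn")])
  if (any(counts < 0) || anyNA(counts)) {
    abort("confusion counts must be non-negative.",
          class = "kibci_config_error")
  }
  total <- sum(counts)
  if (total == 0) {
    abort("empty confusion matrix.", class = "kibci_config_error")
  }
  acc <- (cf$tp + cf$tn) / total * 100
  if (cf$tp + cf$fp == 0 || cf$tp + cf$fn == 0) {
    # precision or recall undefined (no positive predictions, or no
    # positive truths): F1 reported as a sentinel, not forced to 0
    f1 <- NA_real_
  } else {
    prec <- cf$tp / (cf$tp + cf$fp)
    rec <- cf$tp / (cf$tp + cf$fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec) * 100
  }
  list(accuracy = acc, f1 = f1)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (%s vs %s)\n", x$name,
              x$conditions[1], x$conditions[2]))
  cat(sprintf("  pooled over %d folds: accuracy %.2f%%, F1 %.2f%%\n",
              x$folds, x$accuracy, x$f1))
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$fn,
              x$confusion$tn))
  invisible(x)
}

#' Tidy method for evaluation reports: per-fold metrics
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per fold: `fold`, `n`, `accuracy`, `f1`,
#'   `cost`, `gamma`, `inner_accuracy`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' Glance method for evaluation reports
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble: pooled `accuracy` and `f1`, fold mean/SD of
#'   accuracy, confusion counts.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(name = x$name,
         accuracy = x$accuracy, f1 = x$f1,
         fold_mean_accuracy = mean(x$per_fold$accuracy),
         fold_sd_accuracy = stats::sd(x$per_fold$accuracy),
         tp = x$confusion$tp, fp = x$confusion$fp,
         fn = x$confusion$fn, tn = x$confusion$tn)
}

#' @describeIn train_eval_cv Per-fold accuracy plot with the pooled value.
#' @param object,... An `eval_report` and ignored extra arguments.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 50, colour = "grey50") +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = sprintf("%s: pooled accuracy %.1f%%",
                                  object$name, object$accuracy)) +
    ggplot2::theme_minimal()
}
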
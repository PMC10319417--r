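#' Reference per-subject F1 table
#'
#' Published per-subject F1 scores (16 subjects, three pairings) of the
#' kinesthetic-illusion motor-imagery study this package models, shipped
#' as a worked aggregation example and test fixture: Class1 = imagery vs
#' rest without illusion (offline), Class2 = imagery vs rest with illusion
#' (offline), Class3 = illusion-imagery vs vibration-rest (simulated
#' online).
#'
#' @return A tibble: `subject` (`H1`..`H16`), `class` (`Class1`..`Class3`),
#'   `pairing`, `f1` (%).
#' @export
f1_reference_scores <- function() {
  path <- system.file("extdata", "subject_f1_reference.csv",
                      package = "kibci", mustWork = TRUE)
  tb <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  tb$subject <- factor(tb$subject, levels = paste0("H", 1:16))
  tb
}

#' The illusion-responder subject subset
#'
#' The eleven subjects whose simulated-online performance improved when
#' vibration was added to both task and rest. (The study also lists six
#' below-70% "BCI-illiterate" subjects but then refers to "these five
#' subjects"; the six-ID list is what is reproduced here, under
#' `illiterate`.)
#'
#' @return Named list of subject-ID character vectors: `improved` (11
#'   subjects) and `illiterate` (6 subjects).
#' @export
subject_subsets <- function() {
  list(improved = paste0("H", c(1, 4, 6, 8, 9, 11, 12, 13, 14, 15, 16)),
       illiterate = paste0("H", c(1, 2, 4, 11, 13, 15)))
}

#' Aggregate a per-subject score column
#'
#' Arithmetic mean and SD over subjects, optionally restricted to a
#' subset. Rounding is applied only at this reporting boundary; pass
#' `digits = NULL` for full precision.
#'
#' @param data A tibble with a `subject` column and the value column.
#' @param value Column to aggregate (tidy-eval).
#' @param subjects Optional character vector of subject IDs.
#' @param digits Decimal places for the reported mean/SD (default 1).
#' @return A one-row tibble: `n`, `mean`, `sd`.
#' @export
#' @examples
#' f1_reference_scores() |>
#'   dplyr::filter(class == "Class2") |>
#'   aggregate_scores(f1)
aggregate_scores <- function(data, value, subjects = NULL, digits = 1) {
  value <- rlang::enquo(value)
  col <- rlang::as_name(value)
  if (!col %in% names(data)) {
    abort(sprintf("column '%s' not found.", col),
          class = "kibci_config_error")
  }
  if (!is.null(subjects)) {
    data <- dplyr::filter(data, .data$subject %in% subjects)
    if (nrow(data) == 0) {
      abort("subject subset selects no rows.",
            class = "kibci_config_error")
    }
  }
  v <- dplyr::pull(data, !!value)
  if (anyNA(v)) abort("missing values in the aggregated field.",
                      class = "kibci_config_error")
  out <- tibble(n = length(v), mean = mean(v), sd = stats::sd(v))
  if (!is.null(digits)) {
    out$mean <- round(out$mean, digits)
    out$sd <- round(out$sd, digits)
  }
  out
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Shapiro-Wilk normality gate
#'
#' Group statistics in this package assume normal samples; this gate backs
#' that assumption. A constant vector is degenerate and reported as a
#' fail with `NA` p.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (pass when `p > alpha`).
#' @return One-row tibble: `pass`, `p`, `method`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 3)
  if (stats::sd(values) == 0) {
    return(tibble(pass = FALSE, p = NA_real_,
                  method = "shapiro-wilk (degenerate: constant)"))
  }
  p <- shapiro.test(values)$p.value
  tibble(pass = p > alpha, p = p, method = "shapiro-wilk")
}

#' Paired two-sided t-test with normality gate
#'
#' Tests paired per-subject values (e.g. mean ERD of two imagery
#' conditions, or per-subject accuracies of two pairings). When the
#' differences fail the Shapiro-Wilk gate the function falls back to a
#' Wilcoxon signed-rank test and flags the divergence in `method`.
#' Zero-variance differences are degenerate and reported with `NA`
#' statistics rather than raising.
#'
#' @param a,b Equal-length numeric vectors (length >= 3), paired by
#'   subject.
#' @param gate_alpha Normality-gate level (default 0.05).
#' @return One-row tibble: `statistic`, `df`, `p`, `mean_diff`, `stars`,
#'   `method`, `normality_p`.
#' @export
#' @examples
#' paired_ttest(c(76, 70.1, 74.9), c(63.9, 66.8, 78.7))
paired_ttest <- function(a, b, gate_alpha = 0.05) {
  if (length(a) != length(b)) {
    abort("paired vectors must have equal length.",
          class = "kibci_config_error")
  }
  stopifnot(length(a) >= 3)
  d <- a - b
  if (stats::sd(d) == 0) {
    # identical vectors: no effect, t = 0. A nonzero constant shift has
    # zero-variance differences and an unbounded t: degenerate.
    if (mean(d) == 0) {
      return(tibble(statistic = 0, df = length(d) - 1, p = 1,
                    mean_diff = 0, stars = "",
                    method = "paired t", normality_p = NA_real_))
    }
    return(tibble(statistic = NA_real_, df = NA_real_, p = NA_real_,
                  mean_diff = mean(d), stars = "",
                  method = "paired t (degenerate: zero-variance differences)",
                  normality_p = NA_real_))
  }
  gate <- normality_gate(d, alpha = gate_alpha)
  if (isTRUE(gate$pass)) {
    ht <- t.test(a, b, paired = TRUE)
    tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value, mean_diff = mean(d),
           stars = significance_stars(ht$p.value),
           method = "paired t", normality_p = gate$p)
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    tibble(statistic = unname(ht$statistic), df = NA_real_,
           p = ht$p.value, mean_diff = mean(d),
           stars = significance_stars(ht$p.value),
           method = "wilcoxon signed-rank (normality gate failed)",
           normality_p = gate$p)
  }
}

#' One-sample two-sided t-test against chance level
#'
#' Used to test per-subject accuracies against the 50% chance level of a
#' balanced two-class problem.
#'
#' @param values Numeric vector (length >= 3).
#' @param mu Null value (default 50).
#' @param gate_alpha Normality-gate level.
#' @return One-row tibble like [paired_ttest()].
#' @export
one_sample_ttest <- function(values, mu = 50, gate_alpha = 0.05) {
  stopifnot(length(values) >= 3)
  if (stats::sd(values) == 0) {
    if (mean(values) == mu) {
      return(tibble(statistic = 0, df = length(values) - 1, p = 1,
                    mean_diff = 0, stars = "",
                    method = "one-sample t", normality_p = NA_real_))
    }
    return(tibble(statistic = NA_real_, df = NA_real_, p = NA_real_,
                  mean_diff = mean(values) - mu, stars = "",
                  method = "one-sample t (degenerate: constant values)",
                  normality_p = NA_real_))
  }
  gate <- normality_gate(values, alpha = gate_alpha)
  if (isTRUE(gate$pass)) {
    ht <- t.test(values, mu = mu)
    tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value, mean_diff = mean(values) - mu,
           stars = significance_stars(ht$p.value),
           method = "one-sample t", normality_p = gate$p)
  } else {
    ht <- suppressWarnings(wilcox.test(values, mu = mu))
    tibble(statistic = unname(ht$statistic), df = NA_real_,
           p = ht$p.value, mean_diff = mean(values) - mu,
           stars = significance_stars(ht$p.value),
           method = "wilcoxon signed-rank (normality gate failed)",
           normality_p = gate$p)
  }
}

#' Group report over per-subject evaluation results
#'
#' Convenience wrapper producing the study-style group table: per-pairing
#' mean and SD of accuracy/F1, plus paired contrasts between pairings and
#' one-sample tests against chance.
#'
#' @param results Tibble with columns `subject`, `pairing`, `accuracy`,
#'   `f1` (one row per subject x pairing).
#' @param contrasts List of `c(pairing_a, pairing_b)` pairs to test with
#'   [paired_ttest()] on accuracy.
#' @param holm Apply Holm correction across the contrast p-values
#'   (default `FALSE`, matching reports that test uncorrected).
#' @return A list of tibbles: `summary`, `vs_chance`, `contrasts`.
#' @export
group_report <- function(results, contrasts = list(), holm = FALSE) {
  stopifnot(all(c("subject", "pairing", "accuracy", "f1") %in%
                  names(results)))
  summary <- results |>
    dplyr::group_by(.data$pairing) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     mean_f1 = mean(.data$f1),
                     sd_f1 = stats::sd(.data$f1), .groups = "drop")
  vs_chance <- results |>
    dplyr::group_by(.data$pairing) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) >= 3) return(one_sample_ttest(df$accuracy, mu = 50))
      mdiff <- mean(df$accuracy) - 50
      tibble(statistic = NA_real_, df = NA_real_, p = NA_real_,
             mean_diff = mdiff, stars = "",
             method = "skipped (n < 3)", normality_p = NA_real_)
    }) |> dplyr::ungroup()
  ct <- purrr::map(contrasts, function(cc) {
    wide <- results |>
      dplyr::filter(.data$pairing %in% cc) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "pairing",
                         values_from = "accuracy")
    res <- paired_ttest(wide[[cc[1]]], wide[[cc[2]]])
    dplyr::mutate(res, contrast = paste(cc, collapse = " vs "),
                  .before = 1)
  }) |> dplyr::bind_rows()
  if (holm && nrow(ct) > 0) {
    ct$p_holm <- stats::p.adjust(ct$p, method = "holm")
  }
  list(summary = summary, vs_chance = vs_chance, contrasts = ct)
}
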
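test_that("reference F1 table aggregates to its printed row summaries", {
  tb <- f1_reference_scores()
  expect_equal(nrow(tb), 48)
  row_means <- tb |>
    dplyr::group_by(class) |>
    dplyr::group_modify(~ aggregate_scores(.x, f1)) |>
    dplyr::ungroup()
  expect_equal(row_means$mean, c(74.3, 81.9, 76.4))

  # improvement from adding the illusion to imagery, offline
  full <- tb |>
    dplyr::group_by(class) |>
    dplyr::group_modify(~ aggregate_scores(.x, f1, digits = NULL)) |>
    dplyr::ungroup()
  expect_equal(round(full$mean[2] - full$mean[1], 1), 7.6)

  # eleven-subject improved subset, simulated-online vs offline baseline
  improved <- subject_subsets()$improved
  expect_length(improved, 11)
  c3 <- aggregate_scores(dplyr::filter(tb, class == "Class3"), f1,
                         subjects = improved, digits = 2)
  c1 <- aggregate_scores(dplyr::filter(tb, class == "Class1"), f1,
                         subjects = improved, digits = 2)
  expect_equal(c3$mean, 79.24)
  expect_equal(c1$mean, 72.6)

  # single-subject subset returns that subject's value
  one <- aggregate_scores(dplyr::filter(tb, class == "Class1"), f1,
                          subjects = "H3", digits = NULL)
  expect_equal(one$mean, 78.7)
  expect_equal(one$n, 1)

  expect_error(aggregate_scores(tb, not_a_column),
               class = "kibci_config_error")
  # permutation invariance
  shuffled <- tb[sample(nrow(tb)), ]
  expect_equal(aggregate_scores(shuffled, f1), aggregate_scores(tb, f1))
})

test_that("t statistics match closed forms and degenerate conventions", {
  a <- c(76, 70.1, 74.9)
  b <- c(63.9, 66.8, 78.7)
  res <- paired_ttest(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$statistic, t_manual, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-abs(t_manual), df = 2),
               tolerance = 1e-10)

  same <- paired_ttest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  shifted <- paired_ttest(a + 5, a)
  expect_true(is.na(shifted$statistic))
  expect_match(shifted$method, "degenerate")

  expect_error(paired_ttest(1:4, 1:3), class = "kibci_config_error")

  one <- one_sample_ttest(c(65.0, 74.3, 86.25), mu = 50)
  v <- c(65.0, 74.3, 86.25)
  expect_equal(one$statistic, (mean(v) - 50) / (sd(v) / sqrt(3)),
               tolerance = 1e-10)
  expect_gt(one$statistic, 0)

  flat <- one_sample_ttest(c(50, 50, 50), mu = 50)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
})

test_that("the normality gate passes normal data and fails skewed data", {
  set.seed(21)
  pass_rate <- mean(vapply(1:400, function(i)
    normality_gate(rnorm(50))$pass, TRUE))
  expect_equal(pass_rate, 0.95, tolerance = 0.04)

  fail_rate <- mean(vapply(1:100, function(i)
    !normality_gate(rexp(50))$pass, TRUE))
  expect_gt(fail_rate, 0.9)

  const <- normality_gate(rep(1, 10))
  expect_false(const$pass)
  expect_match(const$method, "degenerate")

  # failing data routes the paired test to the Wilcoxon fallback
  set.seed(22)
  x <- rexp(40)^3
  res <- paired_ttest(x + 0.2, rep(0, 40))
  expect_match(res$method, "wilcoxon")
})

test_that("group report summarises, tests against chance and contrasts", {
  set.seed(23)
  results <- tidyr::expand_grid(subject = paste0("S", 1:8),
                                pairing = c("D2", "D3"))
  results$accuracy <- ifelse(results$pairing == "D3", 80, 70) + rnorm(16, 0, 3)
  results$f1 <- results$accuracy - 1
  rep <- group_report(results, contrasts = list(c("D3", "D2")))
  expect_equal(nrow(rep$summary), 2)
  expect_equal(rep$summary$n, c(8, 8))
  expect_true(all(rep$vs_chance$p < 0.01))
  expect_equal(nrow(rep$contrasts), 1)
  expect_gt(rep$contrasts$mean_diff, 5)
  expect_lt(rep$contrasts$p, 0.05)

  stars <- kibci:::significance_stars(c(0.2, 0.03, 0.004, 2e-4, NA))
  expect_equal(stars, c("", "*", "**", "***", ""))
})
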
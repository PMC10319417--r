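test_that("filter bank routes energy to the right sub-band", {
  ep10 <- sine_epochs(freq = 10, amp = 4, n_trials = 2)
  fb <- filter_bank(ep10)
  v <- vapply(fb, function(b) var(b[1, 9, ]), 0)
  expect_equal(unname(which.max(v)), 1)                 # 7-12 Hz
  expect_gt(v[["7-12"]], 100 * max(v[names(v) != "7-12"]))

  ep30 <- sine_epochs(freq = 30, amp = 4, n_trials = 2)
  v30 <- vapply(filter_bank(ep30), function(b) var(b[1, 9, ]), 0)
  expect_equal(unname(which.max(v30)), 6)               # 28-32 Hz

  # white noise spreads evenly over the equal-width bands 2..6
  set.seed(11)
  epw <- generated_epochs(function(tr, ch, n) rnorm(n), n_trials = 6)
  vw <- vapply(filter_bank(epw), function(b) mean(apply(b[, 9, ], 1, var)),
               0)[2:6]
  expect_lt(max(vw) / min(vw), 1.2 / 0.8)
})

test_that("CSP solves the two-class eigenproblem exactly", {
  # analytic case: 4x variance on channel 1 -> eigenvalue 4/(4+1)
  f <- csp_fit(diag(c(4, 1, 1, 1)), diag(1, 4), n_pairs = 1)
  expect_equal(f$eigenvalues[1], 0.8, tolerance = 1e-12)
  expect_equal(abs(f$w[1, ]) / max(abs(f$w[1, ])), c(1, 0, 0, 0),
               tolerance = 1e-10)

  # no discriminative direction: all eigenvalues 1/2
  g <- csp_fit(diag(1, 4), diag(1, 4), n_pairs = 1)
  expect_equal(g$eigenvalues, rep(0.5, 4), tolerance = 1e-12)

  # label swap reverses order and maps lambda -> 1 - lambda
  set.seed(12)
  a <- crossprod(matrix(rnorm(600), 100, 6)) / 100
  b <- crossprod(matrix(rnorm(600), 100, 6)) / 100
  fab <- csp_fit(a, b, n_pairs = 1)
  fba <- csp_fit(b, a, n_pairs = 1)
  expect_equal(fab$eigenvalues, rev(1 - fba$eigenvalues),
               tolerance = 1e-10)
})

test_that("CSP filters match the whitening-eigendecomposition oracle", {
  oracle_csp <- function(ca, cb) {
    es <- eigen(ca + cb, symmetric = TRUE)
    p <- diag(1 / sqrt(es$values)) %*% t(es$vectors)    # whitener
    eo <- eigen(p %*% ca %*% t(p), symmetric = TRUE)
    w <- t(t(p) %*% eo$vectors)[order(-eo$values), , drop = FALSE]
    for (k in seq_len(nrow(w))) {
      pivot <- which.max(abs(w[k, ]))
      if (w[k, pivot] < 0) w[k, ] <- -w[k, ]
    }
    list(w = w, eigenvalues = sort(eo$values, decreasing = TRUE))
  }
  set.seed(13)
  worst <- 0
  for (i in 1:50) {
    ca <- crossprod(matrix(rnorm(6 * 300), 300, 6)) / 300
    cb <- crossprod(matrix(rnorm(6 * 300), 300, 6)) / 300
    f <- csp_fit(ca, cb, n_pairs = 1)
    o <- oracle_csp(ca, cb)
    worst <- max(worst, max(abs(f$w - o$w)),
                 max(abs(f$eigenvalues - o$eigenvalues)))
  }
  expect_lt(worst, 1e-8)
})

test_that("log-variance features are normalized and scale-invariant", {
  set.seed(14)
  x <- array(rnorm(4 * 6 * 200), dim = c(4, 6, 200))
  f <- csp_fit(diag(c(4, 1, 1, 1, 1, 1)), diag(1, 6), n_pairs = 1)
  feat <- csp_features(f, x)
  expect_equal(dim(feat), c(4, 2))
  expect_equal(csp_features(f, x * 7.3), feat, tolerance = 1e-12)

  # equal component variances give log(1/2) each
  iso <- csp_fit(diag(1, 2), diag(1, 2), n_pairs = 1)
  xi <- array(0, dim = c(1, 2, 1000))
  xi[1, 1, ] <- rnorm(1000)
  xi[1, 2, ] <- rnorm(1000)
  fi <- csp_features(iso, xi)
  expect_equal(unname(fi[1, ]), rep(log(0.5), 2), tolerance = 0.15)
})

test_that("mutual-information selection finds the informative feature", {
  picked <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    y <- factor(rep(c(0, 1), each = 40))
    feats <- matrix(rnorm(80 * 10), 80, 10)
    feats[, 4] <- as.numeric(y) + 0.1 * rnorm(80)
    mibif_select(feats, y, k = 1) == 4
  }, TRUE)
  expect_gte(sum(picked), 95)

  # k = total is the identity (rank order aside)
  set.seed(15)
  feats <- matrix(rnorm(60 * 5), 60, 5)
  y <- factor(rep(c(0, 1), 30))
  expect_setequal(mibif_select(feats, y, k = 5), 1:5)
  expect_error(mibif_select(feats, y, k = 6), class = "kibci_config_error")

  # constant feature scores zero MI, never beats an informative one
  feats[, 2] <- 1
  feats[, 5] <- as.numeric(y) + 0.2 * rnorm(60)
  expect_equal(mibif_select(feats, y, k = 1), 5L)

  # MI of an independent feature shrinks toward 0 with n
  mi_at <- function(n, s) {
    set.seed(s)
    kibci:::feature_mi(rnorm(n), factor(rep(c(0, 1), n / 2)))
  }
  small <- mean(vapply(1:20, function(s) mi_at(100, s), 0))
  large <- mean(vapply(1:20, function(s) mi_at(4000, s), 0))
  expect_lt(large, small / 2)
  expect_lt(large, 0.01)
})
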
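test_that("SNR matches hand computations and flags zero variance", {
  expect_equal(snr_db(c(1, -1, 1, -1)), 0)
  expect_equal(snr_db(c(10, 10, 10, 14)), 10 * log10(124 / 3),
               tolerance = 1e-12)
  expect_warning(s <- snr_db(c(60, 60, 60)), "zero-variance")
  expect_true(is.infinite(s))
  expect_true(attr(s, "zero_variance"))
  expect_error(snr_db(5), "2 values")
})

test_that("SNR identity and scale invariance hold on random series", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(50, mean = runif(1, 40, 100), sd = runif(1, 0.5, 10))
    pop_var <- mean((x - mean(x))^2)
    expect_equal(snr_db(x), 10 * log10(1 + mean(x)^2 / pop_var),
                 tolerance = 1e-9)
    expect_equal(snr_db(3.7 * x), snr_db(x), tolerance = 1e-9)
  }
})

test_that("correlations behave as Pearson and Spearman should", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlations(x, 2 * x + 1)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)

  xc <- c(-2, -1, 0, 1, 2)
  rc <- correlations(xc, xc^3)
  expect_equal(rc$spearman_rho, 1)
  expect_lt(rc$pearson_r, 1)

  rr <- correlations(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(rr$spearman_rho, 0.6)

  expect_error(correlations(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(correlations(1:3, 1:4), "length")
})

test_that("error metrics match hand computation and brute force", {
  expect_equal(error_metrics(1:5, 1:5), list(mae = 0, rmse = 0))
  m <- error_metrics(c(0, 0, 0), c(1, -1, 3))
  expect_equal(m$mae, 5 / 3)
  expect_equal(m$rmse, sqrt(11 / 3))
  m2 <- error_metrics(1:4, 1:4 + 2.5)
  expect_equal(m2$mae, m2$rmse)
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(30); b <- rnorm(30)
    acc_a <- 0; acc_s <- 0
    for (j in seq_along(a)) {
      acc_a <- acc_a + abs(b[j] - a[j])
      acc_s <- acc_s + (b[j] - a[j])^2
    }
    m3 <- error_metrics(a, b)
    expect_equal(m3$mae, acc_a / 30)
    expect_equal(m3$rmse, sqrt(acc_s / 30))
    expect_gte(m3$rmse, m3$mae)
  }
})

test_that("Bland-Altman bias and limits follow the sample-sd convention", {
  ba0 <- bland_altman(1:10, 1:10)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  ba5 <- bland_altman(1:10, 1:10 + 5)
  expect_equal(c(ba5$bias, ba5$loa_low, ba5$loa_high), c(5, 5, 5))
  ba <- bland_altman(c(0, 0), c(0, 2))
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_high, 1 + 1.96 * sqrt(2))
  expect_equal(ba$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(ba$points$mean, c(0, 1))
  expect_equal(ba$points$diff, c(0, 2))
})

test_that("signed-rank statistic and exact p match the enumerated examples", {
  w1 <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))   # diffs 1, 2, 3
  expect_equal(w1$statistic, 0)
  expect_equal(w1$p_value, 0.25)
  w2 <- wilcoxon_signed_rank(c(2, 0, 4), c(1, 2, 1))   # diffs 1, -2, 3
  expect_equal(w2$statistic, 2)
  expect_equal(w2$p_value, 0.75)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "degenerate")
})

test_that("exact p equals full sign-pattern enumeration for small n", {
  brute_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
    count <- 0
    for (mask in 0:(2^n - 1)) {
      signs <- as.integer(intToBits(mask))[1:n]
      if (sum(r[signs == 1]) <= w_obs) count <- count + 1
    }
    min(1, 2 * count / 2^n)
  }
  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    a <- sample(0:6, n, replace = TRUE)
    b <- sample(0:6, n, replace = TRUE)
    if (all(a == b)) a[1] <- a[1] + 1
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, brute_p(a - b), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
})

test_that("exact p agrees with the standard test when there are no ties", {
  set.seed(19)
  for (i in 1:10) {
    # distinct absolute differences so the exact distribution applies
    d <- sample(c(-1, 1), 12, replace = TRUE) * sample(1:1000, 12)
    a <- abs(d) + pmax(-d, 0)
    b <- abs(d) + pmax(d, 0)  # a - b = -d, all |d| distinct
    got <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample p uses the tie-corrected normal approximation", {
  set.seed(29)
  a <- rnorm(60, 1, 2)
  b <- rnorm(60, 0, 2)
  got <- wilcoxon_signed_rank(a, b)
  expect_equal(got$method, "normal")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("Cliff's delta matches brute force, labels, and antisymmetry", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(3, 1, 2))$delta, 0)
  expect_equal(cliffs_delta(c(1, 2, 3), c(3, 1, 2))$magnitude, "negligible")
  cd <- cliffs_delta(c(1, 2), c(3, 4))
  expect_equal(cd$delta, -1)
  expect_equal(cd$magnitude, "large")
  cd2 <- cliffs_delta(c(1, 3), c(2, 4))
  expect_equal(cd2$delta, -0.5)
  expect_equal(cd2$magnitude, "large")
  expect_error(cliffs_delta(numeric(0), 1), "empty")

  brute <- function(a, b) {
    gt <- 0; lt <- 0
    for (x in a) for (y in b) {
      if (x > y) gt <- gt + 1
      if (x < y) lt <- lt + 1
    }
    (gt - lt) / (length(a) * length(b))
  }
  set.seed(6)
  for (i in 1:25) {
    a <- sample(0:8, sample(3:10, 1), replace = TRUE)
    b <- sample(0:8, sample(3:10, 1), replace = TRUE)
    expect_equal(cliffs_delta(a, b)$delta, brute(a, b), tolerance = 1e-12)
    expect_equal(cliffs_delta(a, b)$delta, -cliffs_delta(b, a)$delta)
  }
})

test_that("magnitude labels switch at the conventional cutoffs", {
  expect_equal(cliffs_magnitude(0.146), "negligible")
  expect_equal(cliffs_magnitude(-0.2), "small")
  expect_equal(cliffs_magnitude(0.4), "medium")
  expect_equal(cliffs_magnitude(-0.474), "large")
})

test_that("agreement report satisfies its internal consistency invariants", {
  set.seed(44)
  g <- seq(0, by = 0.25, length.out = 400)
  ref <- hr_series(g, 70 + cumsum(rnorm(400, 0, 0.3)), "uniform_4hz", "faros")
  test <- hr_series(g, ref$bpm + rnorm(400, 1, 2), "uniform_4hz", "e4")
  rep <- agreement_report(ref, test)
  expect_gte(rep$rmse_bpm, rep$mae_bpm)
  expect_true(rep$ba_loa_low_bpm <= rep$ba_bias_bpm &
                rep$ba_bias_bpm <= rep$ba_loa_high_bpm)
  expect_true(abs(rep$pearson_r) <= 1 && abs(rep$spearman_rho) <= 1)
  expect_equal(rep$n_samples, 400L)
})
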
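#' Signal-to-noise ratio of a heart-rate series, in dB
#'
#' Signal power is the mean of the squared HR values; noise power is the
#' average squared deviation from the mean (population variance). The SNR is
#' `10 * log10(P_signal / P_noise)`. A constant series has zero noise power
#' and returns `Inf` with attribute `zero_variance = TRUE` and a warning.
#'
#' @param values Numeric HR values, length >= 2.
#' @return SNR in dB.
#' @export
snr_db <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for SNR", call. = FALSE)
  p_signal <- mean(values^2)
  p_noise <- mean((values - mean(values))^2)
  if (p_noise == 0) {
    warning("zero-variance series: SNR is infinite", call. = FALSE)
    return(structure(Inf, zero_variance = TRUE))
  }
  10 * log10(p_signal / p_noise)
}

#' Pearson and Spearman correlation between paired HR series
#'
#' @param ref,test Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return List with `pearson_r` and `spearman_rho` (average ranks for ties).
#' @export
correlations <- function(ref, test) {
  if (length(ref) != length(test)) stop("length mismatch", call. = FALSE)
  if (length(ref) < 3L) stop("need >= 3 pairs", call. = FALSE)
  if (stats::sd(ref) == 0 || stats::sd(test) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  list(pearson_r = stats::cor(ref, test, method = "pearson"),
       spearman_rho = stats::cor(ref, test, method = "spearman"))
}

#' Mean absolute error and root mean square error
#'
#' @param ref,test Equal-length numeric vectors; `ref` is the reference
#'   device.
#' @return List with `mae` and `rmse` (same units as the inputs).
#' @export
error_metrics <- function(ref, test) {
  if (length(ref) != length(test)) stop("length mismatch", call. = FALSE)
  if (!length(ref)) stop("empty input", call. = FALSE)
  d <- test - ref
  list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `test - ref` (wrist minus chest device); the bias is
#' their mean and the limits of agreement are `bias +/- k * sd` with sample
#' standard deviation (n - 1) and `k = 1.96` by default (95 percent limits).
#'
#' @param ref,test Equal-length numeric vectors, length >= 2.
#' @param k Limits-of-agreement multiplier.
#' @return List with `bias`, `loa_low`, `loa_high` and a data frame `points`
#'   of pairwise means and differences for plotting.
#' @export
bland_altman <- function(ref, test, k = 1.96) {
  if (length(ref) != length(test)) stop("length mismatch", call. = FALSE)
  if (length(ref) < 2L) stop("need >= 2 pairs", call. = FALSE)
  d <- test - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - k * s, loa_high = bias + k * s,
       points = data.frame(mean = (ref + test) / 2, diff = d))
}

# exact null distribution of the signed-rank sum: probabilities of the
# doubled rank sums 0..sum(2r), via the generating-function convolution
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  dp <- numeric(total + 1L)
  dp[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dp[seq_len(total + 1L - r)])
    dp <- dp + shifted
  }
  dp / 2^length(ranks2)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' average ranks for ties. The reported statistic is `min(W+, W-)`. The
#' two-sided p-value is exact (full enumeration of the signed-rank
#' distribution, ties included) for up to `exact_limit` nonzero pairs, and a
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param exact_limit Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `statistic`, `p_value`, `n` (nonzero pairs) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero: test degenerate", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)

  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    dp <- signed_rank_distribution(ranks2)
    w2 <- as.integer(round(2 * w))
    p <- min(1, 2 * sum(dp[seq_len(w2 + 1L)]))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{a_i > b_j\} - #\{a_i < b_j\}) / (n * m)` over all cross
#' pairs, with the conventional magnitude labels: |delta| < 0.147
#' negligible, < 0.33 small, < 0.474 medium, otherwise large.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `delta` in \[-1, 1\] and `magnitude`.
#' @export
cliffs_delta <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  delta <- mean(sign(outer(a, b, "-")))
  mag <- cliffs_magnitude(delta)
  list(delta = delta, magnitude = mag)
}

cliffs_magnitude <- function(delta) {
  ad <- abs(delta)
  if (ad < 0.147) "negligible"
  else if (ad < 0.33) "small"
  else if (ad < 0.474) "medium"
  else "large"
}

#' Device-agreement report for one scene
#'
#' Computes the per-device SNR and the paired-comparison statistics
#' (Pearson/Spearman correlation, MAE, RMSE, Bland-Altman bias and limits)
#' between the reference (chest ECG) and test (wrist PPG) HR series on their
#' shared 4 Hz grid.
#'
#' @param hr_ref,hr_test `uniform_4hz` [hr_series()] objects on the same
#'   grid.
#' @param ba_k Bland-Altman limits multiplier (default 1.96).
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(hr_ref, hr_test, ba_k = 1.96) {
  if (length(hr_ref$bpm) != length(hr_test$bpm))
    stop("series must share the 4 Hz grid", call. = FALSE)
  x <- hr_ref$bpm
  y <- hr_test$bpm
  cors <- correlations(x, y)
  errs <- error_metrics(x, y)
  ba <- bland_altman(x, y, k = ba_k)
  structure(
    list(snr_db = c(ref = as.numeric(snr_db(x)), test = as.numeric(snr_db(y))),
         pearson_r = cors$pearson_r, spearman_rho = cors$spearman_rho,
         mae_bpm = errs$mae, rmse_bpm = errs$rmse,
         ba_bias_bpm = ba$bias, ba_loa_low_bpm = ba$loa_low,
         ba_loa_high_bpm = ba$loa_high, ba_points = ba$points,
         n_samples = length(x)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> n=%d, SNR ref=%.1f dB test=%.1f dB, r=%.2f, rho=%.2f,\n",
    "  MAE=%.2f bpm, RMSE=%.2f bpm, bias=%.2f [%.2f, %.2f] bpm\n"),
    x$n_samples, x$snr_db["ref"], x$snr_db["test"], x$pearson_r,
    x$spearman_rho, x$mae_bpm, x$rmse_bpm, x$ba_bias_bpm,
    x$ba_loa_low_bpm, x$ba_loa_high_bpm))
  invisible(x)
}
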
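# Cohort statistics: summaries with t confidence intervals, Pearson
# correlation with its t-test, two-way random-effects intraclass correlation
# for absolute agreement, and statistical power of the correlation test
# (Fisher-z approximation and the exact sampling distribution of r).

#' Summary statistics with a 95% confidence interval
#'
#' Sample mean, sample SD (n-1 denominator) and the t-based 95% CI
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector, length >= 2.
#' @return Object of class `"summary_stat"` with `n`, `mean`, `sd`,
#'   `ci95_low`, `ci95_high`.
#' @export
summary_stat <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("summary_stat needs at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s,
                 ci95_low = m - half, ci95_high = m + half),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("n = %d, mean %.3f +/- %.3f (95%% CI %.3f to %.3f)\n",
              x$n, x$mean, x$sd, x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variance.
#' @return Object of class `"correlation_result"` with `r`, `p_two_sided`,
#'   `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("pearson_cor needs n >= 3")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(r = r, p_two_sided = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, two-sided p = %.3g)\n", x$r, x$n, x$p_two_sided))
  invisible(x)
}

#' Intraclass correlation, two-way random, absolute agreement, single rater
#'
#' ICC(2,1) from the two-way ANOVA mean squares of a subjects x raters
#' matrix:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC, MSE are the row (subject), column (rater) and residual
#' mean squares.  This is the standard form for intra-/inter-observer
#' landmark reliability.
#'
#' @param ratings Numeric matrix, subjects in rows (>= 5), raters in columns
#'   (>= 2), no missing cells.
#' @return Object of class `"icc_result"` with `icc`, `model`, `n_subjects`,
#'   `n_raters`.
#' @export
icc_absolute_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5L) stop("ICC needs at least 5 subjects")
  if (k < 2L) stop("ICC needs at least 2 raters")
  if (anyNA(ratings)) stop("ICC input has missing cells")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc,
                 model = "two-way random, absolute agreement, single rater",
                 n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (%d subjects x %d raters; %s)\n",
              x$icc, x$n_subjects, x$n_raters, x$model))
  invisible(x)
}

# log of Gauss hypergeometric 2F1(a, b; c; z) by series, 0 <= z < 1.
# Converges quickly here because c is large (c = n - 1/2).
.log_2f1 <- function(a, b, cc, z) {
  total <- 1
  term <- 1
  for (k in seq_len(5000L)) {
    term <- term * (a + k - 1) * (b + k - 1) / (cc + k - 1) * z / k
    total <- total + term
    if (term < 1e-16 * total) break
  }
  log(total)
}

# Density of the sample correlation coefficient r for a bivariate normal
# population with correlation rho and sample size n (Hotelling's form).
.dcorr <- function(r, rho, n) {
  lf <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) +
    .log_2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2)
  exp(lf)
}

#' Critical sample correlation of the two-sided t-test
#'
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @return The value of |r| at which the two-sided test on n - 2 df rejects.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Power of the Pearson correlation test
#'
#' Probability of rejecting `rho = 0` when the population correlation is
#' `rho`.  `method = "exact"` integrates the exact bivariate-normal sampling
#' density of r beyond the critical r of the t-test; `method = "fisher_z"`
#' uses the normal approximation on `atanh(r)`.  The two agree within about
#' 0.02 for n >= 50; exact is the default.
#'
#' @param rho Population correlation, |rho| < 1.
#' @param alpha Significance level in (0, 1).
#' @param n Sample size (>= 4).
#' @param tails `"two"` (default) or `"one"`.
#' @param method `"exact"` (default) or `"fisher_z"`.
#' @return Power as a probability.
#' @export
correlation_power <- function(rho, alpha = 0.05, n, tails = c("two", "one"),
                              method = c("exact", "fisher_z")) {
  tails <- match.arg(tails)
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n < 4) stop("power computation needs n >= 4")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  a_tail <- if (tails == "two") alpha / 2 else alpha
  if (method == "fisher_z") {
    za <- stats::qnorm(1 - a_tail)
    zr <- sqrt(n - 3) * atanh(rho)
    pw <- stats::pnorm(zr - za)
    if (tails == "two") pw <- pw + stats::pnorm(-zr - za)
    return(pw)
  }
  tc <- stats::qt(1 - a_tail, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  f <- Vectorize(function(r) .dcorr(r, rho, n))
  upper <- stats::integrate(f, rc, 1, rel.tol = 1e-9)$value
  if (tails == "one") return(upper)
  lower <- stats::integrate(f, -1, -rc, rel.tol = 1e-9)$value
  upper + lower
}
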
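# Cohort-level analysis: per-parameter summaries, correlations of each
# distance with femoral width, and post hoc power of the correlation test.

#' Analyze a cohort of knee measurements
#'
#' Computes, for each of the five distances and four ratios, the summary
#' statistics with 95% CI; the Pearson correlation of each distance (and
#' each ratio) with ML; and the post hoc power of the correlation test at
#' the supplied reference correlation.
#'
#' @param measurements Data frame of per-knee measurements.
#' @param power_rho Reference correlation for the post hoc power computation
#'   (default 0.3).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"cohort_report"` with `summary` (data frame),
#'   `correlations` (data frame), `power`, `n`.
#' @export
cohort_report <- function(measurements, power_rho = 0.3, alpha = 0.05) {
  if (!is.data.frame(measurements)) {
    measurements <- measurement_table(measurements)
  }
  pars <- c("me_fj", "le_fj", "me_ej", "le_ej", "ml",
            "ratio_me_fj", "ratio_le_fj", "ratio_me_ej", "ratio_le_ej")
  summ <- do.call(rbind, lapply(pars, function(p) {
    st <- summary_stat(measurements[[p]])
    data.frame(parameter = p, n = st$n, mean = st$mean, sd = st$sd,
               ci95_low = st$ci95_low, ci95_high = st$ci95_high,
               stringsAsFactors = FALSE)
  }))
  with_ml <- setdiff(pars, "ml")
  cors <- do.call(rbind, lapply(with_ml, function(p) {
    ct <- pearson_cor(measurements$ml, measurements[[p]])
    data.frame(parameter = p, r_with_ml = ct$r, p_two_sided = ct$p_two_sided,
               n = ct$n, stringsAsFactors = FALSE)
  }))
  pw <- correlation_power(rho = power_rho, alpha = alpha,
                          n = nrow(measurements), tails = "two",
                          method = "exact")
  structure(list(summary = summ, correlations = cors, power = pw,
                 power_rho = power_rho, alpha = alpha,
                 n = nrow(measurements)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d knees\n\nSummary (mm; ratios dimensionless):\n", x$n))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %7.3f +/- %6.3f  (95%% CI %7.3f to %7.3f)\n",
                s$parameter[i], s$mean[i], s$sd[i], s$ci95_low[i], s$ci95_high[i]))
  }
  cat("\nCorrelation with ML:\n")
  co <- x$correlations
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-12s r = %6.3f  (p = %.3g)\n",
                co$parameter[i], co$r_with_ml[i], co$p_two_sided[i]))
  }
  cat(sprintf("\nPost hoc power (rho = %.2f, alpha = %.2f, two-sided, exact): %.3f\n",
              x$power_rho, x$alpha, x$power))
  invisible(x)
}

#' Write a cohort report to CSV and text
#'
#' @param report A `"cohort_report"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(report, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_summary.csv"))
  p2 <- file.path(dir, paste0(prefix, "_correlations.csv"))
  p3 <- file.path(dir, paste0(prefix, "_report.txt"))
  utils::write.csv(report$summary, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(report$correlations, p2, row.names = FALSE, quote = FALSE)
  con <- file(p3, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(c(p1, p2, p3))
}
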
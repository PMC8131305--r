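#' Rater summaries and contingency tables
#'
#' A rater summary holds the applied-stimulus count and the number of
#' stimuli the rater (software or human observer) marked as eliciting a
#' reflex.
#'
#' @param rater rater label.
#' @param applied number of applied stimuli.
#' @param detected number of detected reflexes, `0 <= detected <=
#'   applied`.
#' @return One-row data frame of class `rater_summary`.
#' @export
rater_summary <- function(rater, applied, detected) {
  if (detected < 0 || detected > applied)
    stopf("detected must lie in [0, applied]")
  out <- data.frame(rater = rater, applied = applied, detected = detected)
  class(out) <- c("rater_summary", "data.frame")
  out
}

as_table_2x2 <- function(s1, s2) {
  matrix(c(s1$detected, s1$applied - s1$detected,
           s2$detected, s2$applied - s2$detected),
         nrow = 2, byrow = TRUE,
         dimnames = list(c(s1$rater, s2$rater), c("detected", "undetected")))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Two raters' detected/undetected counts, 1 degree of freedom. The
#' Yates continuity correction is off by default and applied only when
#' requested.
#'
#' @param table 2x2 matrix of non-negative counts (rows = raters,
#'   columns = detected/undetected).
#' @param continuity_correction apply the Yates correction.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  if (!all(dim(table) == c(2, 2)) || any(table < 0))
    stopf("need a 2x2 table of non-negative counts")
  if (sum(table) == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("degenerate table: zero margin", class = "degenerate_table_error")
  ct <- stats::chisq.test(table, correct = continuity_correction)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value), df = 1L)
}

#' All pairwise rater comparisons with Bonferroni correction
#'
#' Runs the 2x2 chi-square test for every pair of raters and adjusts
#' the p-values by the Bonferroni factor (the number of pairs, capped
#' at 1).
#'
#' @param summaries data frame with columns `rater, applied, detected`
#'   (one row per rater); all raters must share the same applied total.
#' @param continuity_correction apply the Yates correction to every
#'   test.
#' @return Data frame: `rater1, rater2, statistic, p_raw, p_adjusted`.
#' @export
pairwise_rater_tests <- function(summaries, continuity_correction = FALSE) {
  k <- nrow(summaries)
  if (k < 2) stopf("need at least two raters")
  if (length(unique(summaries$applied)) != 1)
    stopf("all raters must share the same applied total",
          class = "input_error")
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ct <- chi_square_2x2(as_table_2x2(summaries[i1, ], summaries[i2, ]),
                         continuity_correction)
    data.frame(rater1 = summaries$rater[i1], rater2 = summaries$rater[i2],
               statistic = ct$statistic, p_raw = ct$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out
}

#' Pearson correlation between stimulation level and motion-vector length
#'
#' Standard Pearson r with the two-sided t-test p-value, used per
#' patient and electrode to relate stimulus intensity to the length of
#' the tendon motion vector in pixels.
#'
#' @param levels stimulation levels.
#' @param amplitudes motion-vector lengths (px).
#' @param electrode optional label carried into the result.
#' @return List of class `correlation_result`: `r, p_value, n,
#'   electrode`.
#' @export
pearson_correlation <- function(levels, amplitudes, electrode = NA) {
  if (length(levels) != length(amplitudes) || length(levels) < 3)
    stopf("need >= 3 paired observations")
  if (sd(levels) == 0 || sd(amplitudes) == 0)
    stopf("zero variance: correlation undefined",
          class = "undefined_correlation_error")
  ct <- stats::cor.test(levels, amplitudes, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(levels), electrode = electrode),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.3f, p = %.4g, n = %d%s\n", x$r, x$p_value,
              x$n, if (is.na(x$electrode)) "" else paste0(" (", x$electrode, ")")))
  invisible(x)
}

#' Bundled per-patient rater counts
#'
#' Per-patient applied-stimulus and detected-reflex counts for the
#' software detector and three human observers (experienced surgeon,
#' intermediate and unexperienced observer) from a six-patient clinical
#' eSR evaluation (387 stimuli in total). Lets the statistics layer run
#' without any video input.
#'
#' @param path CSV path; defaults to the bundled file.
#' @return Data frame: `patient, applied, software, experienced,
#'   intermediate, unexperienced`.
#' @export
load_rater_counts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rater_counts.csv",
                                package = "stapetrack", mustWork = TRUE)
  utils::read.csv(path)
}

#' Overall and per-patient detection rates from per-patient counts
#'
#' @param counts data frame as returned by [load_rater_counts()].
#' @return List with `overall` (data frame `rater, applied, detected,
#'   rate_pct`) and `per_patient` (percentage matrix, patients x
#'   raters).
#' @export
detection_rates <- function(counts) {
  raters <- setdiff(names(counts), c("patient", "applied"))
  overall <- data.frame(
    rater = raters,
    applied = sum(counts$applied),
    detected = vapply(raters, function(r) sum(counts[[r]]), numeric(1)))
  overall$rate_pct <- 100 * overall$detected / overall$applied
  per_patient <- sapply(raters, function(r) 100 * counts[[r]] / counts$applied)
  rownames(per_patient) <- counts$patient
  list(overall = overall, per_patient = per_patient)
}

#' Full rater statistics report
#'
#' Detection rates plus all pairwise chi-square comparisons with
#' Bonferroni adjustment, from per-patient counts.
#'
#' @param counts data frame as from [load_rater_counts()].
#' @param continuity_correction apply the Yates correction.
#' @return List of class `rater_stats`: `rates`, `pairwise`.
#' @export
rater_stats <- function(counts, continuity_correction = FALSE) {
  rates <- detection_rates(counts)
  summaries <- data.frame(rater = rates$overall$rater,
                          applied = rates$overall$applied,
                          detected = rates$overall$detected)
  pw <- pairwise_rater_tests(summaries, continuity_correction)
  structure(list(rates = rates, pairwise = pw), class = "rater_stats")
}

#' @export
print.rater_stats <- function(x, ...) {
  cat("Detection rates:\n")
  o <- x$rates$overall
  for (i in seq_len(nrow(o)))
    cat(sprintf("  %-14s %3d/%3d (%.1f%%)\n", o$rater[i], o$detected[i],
                o$applied[i], o$rate_pct[i]))
  cat("Pairwise chi-square (Bonferroni-adjusted):\n")
  p <- x$pairwise
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-14s vs %-14s X2 = %6.2f  p = %.2g  p_adj = %.2g\n",
                p$rater1[i], p$rater2[i], p$statistic[i], p$p_raw[i],
                p$p_adjusted[i]))
  invisible(x)
}
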
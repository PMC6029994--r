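#' @title Evaluation statistics
#' @name metrics
#' @description
#' Test-retest intraclass correlation in the (BMS - WMS)/(BMS + WMS) form,
#' signed percent error, and paired-comparison summaries.
NULL

#' Test-retest table constructor
#'
#' @param subject subject identifiers
#' @param region region labels
#' @param vt_test,vt_retest paired V_T estimates (> 0)
#' @return data.frame of class `test_retest_table`
#' @export
test_retest_table <- function(subject, region, vt_test, vt_retest) {
  n <- length(subject)
  if (length(region) == 1L) region <- rep(region, n)
  if (length(region) != n || length(vt_test) != n || length(vt_retest) != n)
    stop_invalid("all columns must have equal length")
  check_finite(c(vt_test, vt_retest), "V_T values")
  if (any(vt_test <= 0) || any(vt_retest <= 0))
    stop_invalid("V_T values must be > 0")
  structure(data.frame(subject = subject, region = region,
                       vt_test = vt_test, vt_retest = vt_retest),
            class = c("test_retest_table", "data.frame"))
}

#' Intraclass correlation coefficient for test-retest V_T
#'
#' One-way ANOVA decomposition over subjects with two repeats each:
#' \deqn{ICC = (BMS - WMS) / (BMS + WMS)} where BMS is the between-subject
#' mean square (df = n - 1) and WMS the within-subject mean square between
#' test and retest (df = n, one per subject). The score lies in
#' \[-1, +1\], +1 meaning maximum reliability.
#'
#' @param table [test_retest_table]
#' @param region region to score (one of the table's region labels)
#' @return ICC score; `NA` with a `"diagnostic"` attribute when all values
#'   are identical (BMS + WMS = 0, ICC undefined)
#' @export
icc <- function(table, region) {
  stopifnot(inherits(table, "test_retest_table"))
  d <- table[table$region == region, , drop = FALSE]
  if (nrow(d) < 2) stop_invalid("need >= 2 subjects with complete pairs")
  x <- cbind(d$vt_test, d$vt_retest)
  n <- nrow(x)
  grand <- mean(x)
  subj_mean <- rowMeans(x)
  bms <- 2 * sum((subj_mean - grand)^2) / (n - 1)
  wms <- sum((x - subj_mean)^2) / n          # 1 df per subject, k = 2
  if (bms + wms == 0) {
    out <- NA_real_
    attr(out, "diagnostic") <- "all values identical; ICC undefined"
    return(out)
  }
  (bms - wms) / (bms + wms)
}

#' Signed percent error
#'
#' `100 * (estimate - reference) / reference`. Antisymmetric under swapping
#' arguments only up to the change of reference (documented, not an
#' identity).
#'
#' @param estimate estimated value(s)
#' @param reference reference value(s), nonzero
#' @return signed percent error(s)
#' @export
percent_error <- function(estimate, reference) {
  if (any(reference == 0)) stop_invalid("reference must be nonzero")
  100 * (estimate - reference) / reference
}

#' Paired comparison summary
#'
#' Mean difference, SD of the differences, paired t statistic and two-sided
#' p-value for two equal-length measurement vectors.
#'
#' @param values_a,values_b paired measurements, length >= 2
#' @return list with `mean_diff`, `sd_diff`, `t`, `p`, `n`, `degenerate`
#'   (`TRUE` with `t`/`p` `NA` when the difference SD is zero)
#' @export
paired_summary <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop_invalid("length mismatch")
  if (length(values_a) < 2) stop_invalid("need >= 2 pairs")
  d <- values_a - values_b
  sd_d <- stats::sd(d)
  # relative guard: a constant offset between float vectors can leave a
  # few-ulp residual spread that t.test would choke on
  if (sd_d <= 1e-12 * max(abs(d), 1)) {
    return(list(mean_diff = mean(d), sd_diff = sd_d, t = NA_real_,
                p = NA_real_, n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(mean_diff = mean(d), sd_diff = sd_d, t = unname(tt$statistic),
       p = tt$p.value, n = length(d), degenerate = FALSE)
}
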
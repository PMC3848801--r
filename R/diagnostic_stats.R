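# 2x2 machinery, diagnostic performance with Wilson intervals, crude odds
# ratios, chi-square/Fisher selection, ROC AUC with DeLong variance and the
# paired DeLong AUC comparison.

#' Build a 2x2 table of a binary classifier against malignancy truth
#'
#' @param predicted Logical vector of test results.
#' @param truth Logical vector: `TRUE` for malignant.
#' @param na.rm Drop pairs where either element is missing (default `TRUE`;
#'   pairwise deletion).
#' @return Object of class `two_by_two`: list with integer counts `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
#' @examples
#' two_by_two(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
two_by_two <- function(predicted, truth, na.rm = TRUE) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  if (na.rm) {
    keep <- !is.na(predicted) & !is.na(truth)
    predicted <- predicted[keep]; truth <- truth[keep]
  } else if (anyNA(predicted) || anyNA(truth))
    stop("missing values in predictions or truth")
  out <- list(tp = sum(predicted & truth), fn = sum(!predicted & truth),
              fp = sum(predicted & !truth), tn = sum(!predicted & !truth))
  class(out) <- "two_by_two"
  out
}

as_two_by_two <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  t <- as.numeric(t)
  if (length(t) != 4L || any(t < 0) || any(t != round(t)))
    stop("expected a two_by_two object or four non-negative counts (tp, fn, fp, tn)")
  structure(list(tp = t[1L], fn = t[2L], fp = t[3L], tn = t[4L]),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              truth = c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf.level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`, bounds inside `[0, 1]`.
#' @export
wilson_ci <- function(x, n, conf.level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Diagnostic performance of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, PPV `tp/(tp+fp)` and
#' NPV `tn/(tn+fn)`, with Wilson score confidence intervals. PPV (NPV) is a
#' missing result, not zero, when no subject tests positive (negative).
#'
#' @param t A `two_by_two` object, or counts `c(tp, fn, fp, tn)`.
#' @param conf.level Confidence level for the Wilson intervals.
#' @return Object of class `diagnostic_performance`: list of point estimates
#'   (proportions in `[0,1]`), `*_ci` bounds, and `n_cases` / `n_controls`.
#' @export
#' @examples
#' performance(c(41, 19, 36, 80))  # sensitivity 41/60 = 68.3%
performance <- function(t, conf.level = 0.95) {
  t <- as_two_by_two(t)
  n1 <- t$tp + t$fn; n0 <- t$fp + t$tn
  if (n1 == 0L || n0 == 0L)
    stop("both malignant and benign subjects are required")
  est <- function(x, n) if (n == 0L) NA_real_ else x / n
  ci <- function(x, n) if (n == 0L) c(NA_real_, NA_real_)
        else wilson_ci(x, n, conf.level)
  out <- list(
    sensitivity = est(t$tp, n1), sensitivity_ci = ci(t$tp, n1),
    specificity = est(t$tn, n0), specificity_ci = ci(t$tn, n0),
    ppv = est(t$tp, t$tp + t$fp), ppv_ci = ci(t$tp, t$tp + t$fp),
    npv = est(t$tn, t$tn + t$fn), npv_ci = ci(t$tn, t$tn + t$fn),
    n_cases = n1, n_controls = n0, conf.level = conf.level)
  class(out) <- "diagnostic_performance"
  out
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  fmt <- function(p, ci) sprintf("%5.1f%% (%.1f to %.1f)",
                                 100 * p, 100 * ci[1L], 100 * ci[2L])
  cat("sensitivity", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("specificity", fmt(x$specificity, x$specificity_ci), "\n")
  cat("ppv        ", if (is.na(x$ppv)) "NA" else fmt(x$ppv, x$ppv_ci), "\n")
  cat("npv        ", if (is.na(x$npv)) "NA" else fmt(x$npv, x$npv_ci), "\n")
  invisible(x)
}

#' Crude (unadjusted) odds ratio
#'
#' Cross-product odds ratio with a Woolf (log-normal) confidence interval.
#' When any cell is zero, the Haldane-Anscombe correction adds 0.5 to every
#' cell (flagged in the result). When two cells in the same row or column
#' are zero the odds ratio is undefined and every estimate is `NA`.
#'
#' @inheritParams performance
#' @return Object of class `odds_ratio_result`: list with `or`, `ci_low`,
#'   `ci_high`, `corrected` (Haldane-Anscombe applied), and the cell counts.
#' @export
#' @examples
#' odds_ratio(c(33, 27, 26, 90))  # cluster pain: OR about 4.2
odds_ratio <- function(t, conf.level = 0.95) {
  t <- as_two_by_two(t)
  cells <- c(t$tp, t$fn, t$fp, t$tn)
  degenerate <- (t$tp == 0 && t$fn == 0) || (t$fp == 0 && t$tn == 0) ||
                (t$tp == 0 && t$fp == 0) || (t$fn == 0 && t$tn == 0)
  corrected <- any(cells == 0) && !degenerate
  out <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              corrected = corrected, counts = cells, conf.level = conf.level)
  if (!degenerate) {
    cc <- cells + if (corrected) 0.5 else 0
    lor <- log(cc[1L]) + log(cc[4L]) - log(cc[2L]) - log(cc[3L])
    se <- sqrt(sum(1 / cc))
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$or <- exp(lor)
    out$ci_low <- exp(lor - z * se)
    out$ci_high <- exp(lor + z * se)
  }
  class(out) <- "odds_ratio_result"
  out
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f to %.2f)%s\n", x$or, x$ci_low, x$ci_high,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Association test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, switching to Fisher's
#' exact test (two-sided, point-probability method) when any *expected* cell
#' count is below 5. Degenerate margins give a missing result.
#'
#' @inheritParams performance
#' @return List with `p_value` and `method` (`"chi_square"` or `"fisher"`).
#' @export
association_test <- function(t) {
  t <- as_two_by_two(t)
  m <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2L, 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p_value = NA_real_, method = NA_character_))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- stats::fisher.test(m)$p.value
    list(p_value = min(p, 1), method = "fisher")
  } else {
    p <- stats::chisq.test(m, correct = FALSE)$p.value
    list(p_value = p, method = "chi_square")
  }
}

# midrank placement values: for each case, the fraction of controls it beats
# (ties half credit), and vice versa
placements <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rx) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - ry) / n1
  list(v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' ROC AUC with DeLong confidence interval
#'
#' Mann-Whitney estimator (half credit for ties) with a normal-approximation
#' confidence interval based on the DeLong placement-value variance.
#'
#' @param scores Numeric classifier scores (higher = more malignant).
#' @param labels Logical truth: `TRUE` for malignant.
#' @param conf.level Confidence level.
#' @return Object of class `auc_result`: list with `auc`, `se`, `ci`.
#' @export
#' @examples
#' auc(c(0.9, 0.2, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
auc <- function(scores, labels, conf.level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) stop("both classes must be represented")
  pl <- placements(scores, labels)
  a <- mean(pl$v10)
  v <- stats::var(pl$v10) / pl$n1 + stats::var(pl$v01) / pl$n0
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(v)
  out <- list(auc = a, se = se,
              ci = c(max(0, a - z * se), min(1, a + z * se)),
              n_cases = pl$n1, n_controls = pl$n0)
  class(out) <- "auc_result"
  out
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f to %.3f)\n", x$auc, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' DeLong test for two paired ROC AUCs
#'
#' Compares the AUCs of two classifiers scored on the same subjects, using
#' the DeLong covariance of paired placement values (midranks for ties).
#' When the variance of the AUC difference is zero (e.g. identical scores),
#' the difference carries no evidence and `p_value` is 1 with
#' `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Paired numeric scores on identical subjects.
#' @param labels Logical truth: `TRUE` for malignant.
#' @return List with `auc_a`, `auc_b`, `difference`, `z`, `p_value`,
#'   `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired scores and labels must have equal length")
  labels <- as.logical(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) stop("both classes must be represented")
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("at least two subjects per class are required for the DeLong variance")
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  a1 <- mean(pa$v10); a2 <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / pa$n1 +
       (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / pa$n0
  if (v <= .Machine$double.eps) {
    # no sampling variance in the difference: identical classifiers carry no
    # evidence (p = 1); a nonzero difference with zero variance is maximally
    # consistent (p -> 0)
    same <- abs(a1 - a2) <= .Machine$double.eps^0.5
    return(list(auc_a = a1, auc_b = a2, difference = a1 - a2,
                z = if (same) 0 else sign(a1 - a2) * Inf,
                p_value = if (same) 1 else 0, degenerate = TRUE))
  }
  z <- (a1 - a2) / sqrt(v)
  list(auc_a = a1, auc_b = a2, difference = a1 - a2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}
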
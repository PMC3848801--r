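# ROMA predictive index, menopause-stratified marker classification and
# ROC-derived (Youden) cutoff estimation.

#' ROMA predictive index
#'
#' Logistic-scale predictive index for ovarian malignancy combining serum
#' HE4 and CA125 with menopause-specific coefficients (see
#' [roma_coefficients()]). Strictly increasing in both markers within each
#' stratum.
#'
#' @param he4 HE4 in pmol/L, strictly positive.
#' @param ca125 CA125 in U/mL, strictly positive.
#' @param menopausal `"pre"` or `"post"` (recycled).
#' @param coefficients Coefficient set, defaults to [roma_coefficients()].
#' @return Numeric vector of predictive-index values.
#' @seealso [roma_percent()]
#' @export
#' @examples
#' roma_pi(he4 = 100, ca125 = 50, menopausal = "post")  # approx -0.437
roma_pi <- function(he4, ca125, menopausal, coefficients = roma_coefficients()) {
  n <- max(length(he4), length(ca125), length(menopausal))
  he4 <- rep_len(as.numeric(he4), n)
  ca125 <- rep_len(as.numeric(ca125), n)
  menopausal <- rep_len(as.character(menopausal), n)
  if (!all(menopausal %in% MENOPAUSAL))
    stop("menopausal status must be 'pre' or 'post'")
  ok <- !is.na(he4) & !is.na(ca125)
  if (any(ok & (he4 <= 0 | ca125 <= 0)))
    stop("marker values must be strictly positive")
  out <- rep(NA_real_, n)
  for (s in MENOPAUSAL) {
    i <- ok & menopausal == s
    cf <- coefficients[[s]]
    out[i] <- cf[["intercept"]] + cf[["log_he4"]] * log(he4[i]) +
      cf[["log_ca125"]] * log(ca125[i])
  }
  out
}

#' ROMA risk on the percent scale
#'
#' `100 * exp(pi) / (1 + exp(pi))`: the logistic transform of the predictive
#' index, in (0, 100).
#'
#' @param pi Predictive-index values from [roma_pi()].
#' @return Numeric vector of percent risks.
#' @export
#' @examples
#' roma_percent(0)        # 50
#' roma_percent(-0.437)   # approx 39.25
roma_percent <- function(pi) 100 * stats::plogis(pi)

#' Classify markers with menopause-stratified cutoffs
#'
#' A marker is positive when its value strictly exceeds the cutoff for the
#' subject's menopausal stratum; values exactly at the cutoff are negative.
#' ROMA is computed from the subject's HE4 and CA125 and compared on the
#' percent scale. Missing marker values give `NA` (a missing result, not a
#' negative one).
#'
#' @param cohort Validated cohort data.frame, or a list/data.frame with
#'   `ca125`, `he4`, `menopausal` columns.
#' @param marker `"ca125"`, `"he4"` or `"roma"`.
#' @param cutoffs Cutoff table as returned by [default_cutoffs()].
#' @return Logical vector (with `NA` where the marker is missing).
#' @export
#' @examples
#' x <- data.frame(ca125 = 30, he4 = 60, menopausal = c("pre", "post"))
#' marker_positive(x, "ca125")  # FALSE (30 <= 69.8), TRUE (30 > 21.7)
marker_positive <- function(cohort, marker = c("ca125", "he4", "roma"),
                            cutoffs = default_cutoffs()) {
  marker <- match.arg(marker)
  men <- as.character(cohort$menopausal)
  if (anyNA(men) || !all(men %in% MENOPAUSAL))
    stop("menopausal status must be known ('pre'/'post') for every record")
  value <- if (marker == "roma")
    roma_percent(roma_pi(cohort$he4, cohort$ca125, men))
  else as.numeric(cohort[[marker]])
  value > cutoffs[men, marker]
}

#' Youden-optimal ROC cutoff
#'
#' Scans the midpoints between adjacent sorted unique values and returns the
#' one maximizing Youden's J (sensitivity + specificity - 1) under the
#' "positive if value > cutoff" convention. Ties in J are broken toward the
#' larger cutoff (higher specificity). Depends on the data only through
#' ranks, so it is invariant to strictly monotone transforms of the values.
#'
#' @param values Numeric marker values.
#' @param labels Logical (or 0/1) truth: `TRUE` for malignant.
#' @param criterion Cutoff criterion; only `"youden"` is implemented.
#' @return List with `cutoff`, `youden`, `sensitivity` and `specificity` at
#'   the chosen cutoff.
#' @export
#' @examples
#' optimal_cutoff(c(10, 20, 30, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
optimal_cutoff <- function(values, labels, criterion = "youden") {
  criterion <- match.arg(criterion)
  values <- as.numeric(values)
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("both classes must be represented")
  u <- sort(unique(values))
  if (length(u) < 2L) stop("values are constant; no cutoff is estimable")
  candidates <- (u[-length(u)] + u[-1L]) / 2
  n1 <- sum(labels); n0 <- sum(!labels)
  sens <- vapply(candidates, function(c_) sum(labels & values > c_) / n1,
                 numeric(1))
  spec <- vapply(candidates, function(c_) sum(!labels & values <= c_) / n0,
                 numeric(1))
  j <- sens + spec - 1
  i <- max(which(j >= max(j) - 1e-12))  # ties -> larger cutoff
  list(cutoff = candidates[i], youden = j[i], sensitivity = sens[i],
       specificity = spec[i])
}
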
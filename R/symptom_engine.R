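# Symptom dichotomization, Ward agglomerative clustering of binary symptom
# indicators, cluster positivity and the Symptom Index.

#' Dichotomize a symptom observation
#'
#' A symptom is positive when it is present, reported on more than 12 days
#' per month (frequency category `"13-19"` or `">20"`), and began within the
#' last year (onset category other than `">12"` months). Severity is recorded
#' in the questionnaire but plays no role here.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param present Logical: was the symptom reported at all?
#' @param freq Frequency category (days/month), one of [frequency_levels()],
#'   or `NA` when absent.
#' @param onset Onset category (months), one of [onset_levels()], or `NA`
#'   when absent.
#' @return Logical vector of dichotomized positivity.
#' @export
#' @examples
#' dichotomize_symptom(TRUE, "13-19", "3-4")   # TRUE
#' dichotomize_symptom(TRUE, "7-12", "1-2")    # FALSE: 12 days/month or fewer
#' dichotomize_symptom(TRUE, ">20", ">12")     # FALSE: predates the last year
dichotomize_symptom <- function(present, freq, onset) {
  n <- max(length(present), length(freq), length(onset))
  present <- rep_len(as.logical(present), n)
  freq <- rep_len(as.character(freq), n)
  onset <- rep_len(as.character(onset), n)
  if (anyNA(present)) stop("'present' must not contain missing values")
  bad <- !is.na(freq) & !(freq %in% FREQ_LEVELS)
  if (any(bad)) stop("invalid frequency category: ", freq[which(bad)[1L]])
  bad <- !is.na(onset) & !(onset %in% ONSET_LEVELS)
  if (any(bad)) stop("invalid onset category: ", onset[which(bad)[1L]])
  if (any(present & (is.na(freq) | is.na(onset))))
    stop("present symptoms must carry frequency and onset categories")
  present & freq %in% FREQ_POSITIVE & onset %in% ONSET_POSITIVE
}

#' Dichotomize every symptom of a cohort
#'
#' @param cohort Validated cohort data.frame.
#' @return Logical matrix, patients x 22 symptoms, with symptom ids as
#'   column names and `patient_id` as row names.
#' @export
dichotomize_cohort <- function(cohort) {
  out <- vapply(SYMPTOMS, function(s)
    dichotomize_symptom(cohort[[paste0(s, "_present")]],
                        cohort[[paste0(s, "_freq")]],
                        cohort[[paste0(s, "_onset")]]),
    logical(nrow(cohort)))
  out <- matrix(out, nrow = nrow(cohort),
                dimnames = list(cohort$patient_id, SYMPTOMS))
  out
}

#' Symptoms eligible for clustering
#'
#' The panel minus symptoms that depend on menopausal status or sexual
#' activity (menstrual irregularity, bleeding after menopause, pain during
#' intercourse, bleeding with intercourse), symptoms too rare to cluster
#' (constipation, diarrhea), and weight loss, whose frequency cannot be
#' ascertained.
#'
#' @return Character vector of 15 symptom ids in questionnaire order.
#' @export
eligible_symptoms <- function() setdiff(SYMPTOMS, WARD_EXCLUDED)

#' Ward agglomerative clustering of binary symptom indicators
#'
#' Clusters the *symptoms* (columns), not the patients: distance is squared
#' Euclidean between 0/1 indicator columns, and each merge minimizes the
#' increase in within-cluster variance (Ward's criterion),
#' \eqn{\Delta(A,B) = \frac{|A||B|}{|A|+|B|} \lVert \bar x_A - \bar x_B \rVert^2},
#' reported on the squared-distance scale (heights equal
#' \eqn{2\Delta}, so the first merge of two singleton columns equals their
#' squared Euclidean distance). Ties in merge cost are broken toward the
#' pair with the lowest column indices, making the result deterministic.
#'
#' @param x Binary (0/1 or logical) matrix, patients x symptoms, at least two
#'   rows; typically the [eligible_symptoms()] columns of
#'   [dichotomize_cohort()] output.
#' @param k Number of groups at which to cut the dendrogram
#'   (default 9: the six canonical pairs plus three singletons).
#' @return Object of class `ward_clustering`: list with `merge_sequence`
#'   (data.frame of merged cluster labels and heights), `partition` (named
#'   integer vector, symptom -> group at the `k`-cut), `k`, and
#'   `constant_columns` (flagged, not dropped).
#' @export
ward_cluster <- function(x, k = 9L) {
  x <- as.matrix(x) * 1
  if (nrow(x) < 2L) stop("at least 2 patients are required")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- ncol(x)
  if (k < 1L || k > p) stop("k must be between 1 and the number of columns")
  constant <- colnames(x)[apply(x, 2L, function(v) length(unique(v)) == 1L)]
  if (length(constant) > 0L)
    warning("constant columns: ", paste(constant, collapse = ", "))

  # active clusters: member column indices and centroid columns
  members <- as.list(seq_len(p))
  centroid <- lapply(seq_len(p), function(j) x[, j])
  sizes <- rep(1L, p)
  labels <- colnames(x)
  alive <- rep(TRUE, p)
  merges <- data.frame(step = integer(0), cluster_a = character(0),
                       cluster_b = character(0), height = numeric(0),
                       stringsAsFactors = FALSE)
  partitions <- vector("list", p)  # partition with (p - step) groups
  partitions[[p]] <- stats::setNames(seq_len(p), labels)

  cost <- function(i, j)
    2 * sizes[i] * sizes[j] / (sizes[i] + sizes[j]) *
      sum((centroid[[i]] - centroid[[j]])^2)

  for (step in seq_len(p - 1L)) {
    idx <- which(alive)
    best <- NULL
    best_cost <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      d <- cost(i, j)
      if (d < best_cost - 1e-12) { best <- c(i, j); best_cost <- d }
      # ties: keep earlier (lowest-index) pair, i.e. do nothing
    }
    i <- best[1L]; j <- best[2L]
    merges <- rbind(merges, data.frame(
      step = step, cluster_a = labels[i], cluster_b = labels[j],
      height = best_cost, stringsAsFactors = FALSE))
    centroid[[i]] <- (sizes[i] * centroid[[i]] + sizes[j] * centroid[[j]]) /
      (sizes[i] + sizes[j])
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    labels[i] <- paste0(labels[i], "+", labels[j])
    alive[j] <- FALSE
    part <- integer(p)
    for (g in seq_along(which(alive)))
      part[members[[which(alive)[g]]]] <- g
    partitions[[p - step]] <- stats::setNames(part, colnames(x))
  }

  out <- list(merge_sequence = merges, partition = partitions[[k]], k = k,
              partitions = partitions, constant_columns = constant)
  class(out) <- "ward_clustering"
  out
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat("Ward clustering of", length(x$partition), "symptoms;",
      "cut at k =", x$k, "\n")
  grp <- split(names(x$partition), x$partition)
  for (g in grp) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Cluster positivity
#'
#' A symptom cluster is positive when *any* member symptom dichotomizes
#' positive ("and/or" semantics).
#'
#' @param dichotomized Logical matrix from [dichotomize_cohort()], or a
#'   validated cohort data.frame (dichotomized on the fly).
#' @param cluster Cluster name (one of `names(cluster_definitions())`) or a
#'   character vector of member symptom ids.
#' @return Logical vector, one element per patient.
#' @export
cluster_positive <- function(dichotomized, cluster) {
  d <- as_dichotomized(dichotomized)
  members <- if (is.character(cluster) && length(cluster) == 1L &&
                 cluster %in% names(CLUSTERS)) CLUSTERS[[cluster]]
             else as.character(cluster)
  bad <- setdiff(members, colnames(d))
  if (length(bad) > 0L) stop("unknown symptoms: ", paste(bad, collapse = ", "))
  unname(rowSums(d[, members, drop = FALSE]) > 0L)
}

as_dichotomized <- function(x) {
  if (is.data.frame(x)) dichotomize_cohort(x)
  else if (is.matrix(x) && is.logical(x)) x
  else stop("expected a cohort data.frame or a logical dichotomized matrix")
}

#' The Symptom Index
#'
#' Positive when any of the `abdomen`, `pain` or `eating` clusters is
#' positive, i.e. when at least one of abdominal bloating, increased abdomen
#' size, pelvic pain, abdominal pain, unable to eat normally, or feeling full
#' quickly dichotomizes positive. Monotone in the symptom panel: turning any
#' further symptom positive can never make a positive index negative.
#'
#' @inheritParams cluster_positive
#' @return Logical vector, one element per patient.
#' @export
#' @examples
#' m <- matrix(FALSE, 1, 22, dimnames = list("p1", symptom_panel()))
#' m[, "pelvic_pain"] <- TRUE
#' symptom_index(m)
symptom_index <- function(dichotomized) {
  d <- as_dichotomized(dichotomized)
  out <- rep(FALSE, nrow(d))
  for (cl in SI_CLUSTERS) out <- out | cluster_positive(d, cl)
  out
}

#' Score a cohort: per-cluster positivity and the Symptom Index
#'
#' @param cohort Validated cohort data.frame.
#' @return `cohort` with appended logical columns `cluster_<name>` for each
#'   canonical cluster, `isolated_<symptom>` for each isolated symptom, and
#'   `si`.
#' @export
score_cohort <- function(cohort) {
  d <- dichotomize_cohort(cohort)
  for (cl in names(CLUSTERS))
    cohort[[paste0("cluster_", cl)]] <- cluster_positive(d, cl)
  for (s in ISOLATED)
    cohort[[paste0("isolated_", s)]] <- d[, s]
  cohort$si <- symptom_index(d)
  cohort
}
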
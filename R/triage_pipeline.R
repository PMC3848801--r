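# End-to-end orchestration: dichotomize, score clusters and the SI, classify
# markers, assemble every comparison table, and emit referral
# recommendations.

#' Pipeline configuration
#'
#' @param cutoffs Marker cutoff table ([default_cutoffs()]).
#' @param referral_policy `"or"` (refer when SI positive OR CA125 positive;
#'   default, favouring sensitivity) or `"and"` (refer only when both are
#'   positive, favouring PPV).
#' @param conf.level Confidence level used throughout.
#' @return List of class `triage_config`.
#' @export
triage_config <- function(cutoffs = default_cutoffs(),
                          referral_policy = c("or", "and"),
                          conf.level = 0.95) {
  out <- list(cutoffs = cutoffs,
              referral_policy = match.arg(referral_policy),
              conf.level = conf.level)
  class(out) <- "triage_config"
  out
}

# resolve a feature name to a logical score vector; NA where not assessable
feature_scores <- function(cohort, feature, cutoffs = default_cutoffs()) {
  d <- dichotomize_cohort(cohort)
  if (is.function(feature)) return(feature(cohort))
  if (feature %in% names(CLUSTERS)) return(cluster_positive(d, feature))
  if (feature %in% SYMPTOMS) return(d[, feature])
  if (feature == "si") return(symptom_index(d))
  if (feature %in% MARKERS) return(marker_positive(cohort, feature, cutoffs))
  stop("unknown feature: ", feature)
}

TABLE3_FEATURES <- c("abdomen", "pain", "eating", "miscellaneous",
                     "digestion", "back_pain", "able_to_feel_abdominal_mass",
                     "bladder", "leg_swelling")

#' Run the full triage analysis on a cohort
#'
#' Builds, in order: the per-symptom prevalence table with pairwise group
#' comparisons (the only table controls contribute to -- they are excluded
#' from everything downstream); the cluster/isolated-symptom prevalence
#' table with crude odds ratios (malignant vs benign); the diagnostic
#' performance table for clusters, isolated symptoms and the Symptom Index;
#' the stage-stratified prevalence/odds-ratio table for the SI clusters and
#' markers; the SI-stratified marker evaluation (AUC and performance of each
#' marker within all / SI-negative / SI-positive subsets, for all-malignant
#' and stage-I-only contrasts, with paired DeLong comparisons); and the
#' per-patient referral recommendation. Records with missing markers are
#' kept in symptom tables and dropped pairwise from marker tables, with the
#' denominators reported.
#'
#' @param cohort Validated cohort data.frame (or a `synthetic_cohort`).
#' @param config A [triage_config()].
#' @return Object of class `triage_report`: list of data.frames
#'   `symptom_prevalence`, `cluster_prevalence`, `performance`,
#'   `stage_stratified`, `si_marker`, `referral`, plus `counts` (records
#'   retained at each step).
#' @export
run_triage <- function(cohort, config = triage_config()) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$records
  validate_cohort(cohort)
  if (sum(cohort$group == "malignant") == 0L ||
      sum(cohort$group == "benign") == 0L)
    stop("cohort must contain both malignant and benign records")

  d <- dichotomize_cohort(cohort)
  grp <- cohort$group

  # --- symptom prevalence with pairwise group comparisons -----------------
  pairs <- list(c("malignant", "benign"), c("malignant", "control"),
                c("benign", "control"))
  symptom_prevalence <- do.call(rbind, lapply(SYMPTOMS, function(s) {
    row <- data.frame(symptom = s, stringsAsFactors = FALSE)
    for (g in GROUPS) {
      n <- sum(grp == g)
      x <- sum(d[grp == g, s])
      row[[paste0(g, "_n")]] <- n
      row[[paste0(g, "_count")]] <- x
      row[[paste0(g, "_percent")]] <- if (n > 0L) 100 * x / n else NA_real_
    }
    for (pr in pairs) {
      nm <- paste0("p_", substr(pr[1L], 1L, 3L), "_vs_", substr(pr[2L], 1L, 3L))
      row[[nm]] <- if (all(pr %in% grp)) {
        i <- grp %in% pr
        association_test(two_by_two(d[i, s], grp[i] == pr[1L]))$p_value
      } else NA_real_
    }
    row
  }))

  # controls are excluded from every subsequent analysis
  tumors <- cohort[grp != "control", , drop = FALSE]
  dt <- d[grp != "control", , drop = FALSE]
  truth <- tumors$group == "malignant"

  # --- cluster prevalence and crude odds ratios ---------------------------
  cluster_prevalence <- do.call(rbind, lapply(TABLE3_FEATURES, function(f) {
    sc <- feature_scores(tumors, f, config$cutoffs)
    t <- two_by_two(sc, truth)
    or <- odds_ratio(t, config$conf.level)
    at <- association_test(t)
    data.frame(feature = f,
               malignant_count = t$tp, malignant_n = t$tp + t$fn,
               malignant_percent = 100 * t$tp / (t$tp + t$fn),
               benign_count = t$fp, benign_n = t$fp + t$tn,
               benign_percent = 100 * t$fp / (t$fp + t$tn),
               or = or$or, or_ci_low = or$ci_low, or_ci_high = or$ci_high,
               p_value = at$p_value, method = at$method,
               stringsAsFactors = FALSE)
  }))

  # --- diagnostic performance of clusters, isolated symptoms, SI ----------
  performance_table <- do.call(rbind, lapply(c(TABLE3_FEATURES, "si"),
                                             function(f) {
    sc <- feature_scores(tumors, f, config$cutoffs)
    pf <- performance(two_by_two(sc, truth), config$conf.level)
    data.frame(feature = f,
               sensitivity = 100 * pf$sensitivity,
               sensitivity_ci_low = 100 * pf$sensitivity_ci[1L],
               sensitivity_ci_high = 100 * pf$sensitivity_ci[2L],
               specificity = 100 * pf$specificity,
               specificity_ci_low = 100 * pf$specificity_ci[1L],
               specificity_ci_high = 100 * pf$specificity_ci[2L],
               ppv = 100 * pf$ppv, npv = 100 * pf$npv,
               stringsAsFactors = FALSE)
  }))

  # --- stage-stratified prevalence and odds ratios ------------------------
  stage_features <- c("abdomen", "pain", "eating", "si", MARKERS)
  stage_stratified <- do.call(rbind, lapply(stage_features, function(f) {
    sc <- feature_scores(tumors, f, config$cutoffs)
    strata <- list(stage_I = truth & tumors$stage == "I",
                   stage_II_IV = truth & tumors$stage %in% c("II", "III", "IV"),
                   all_malignant = truth,
                   benign = !truth)
    row <- data.frame(feature = f, stringsAsFactors = FALSE)
    for (nm in names(strata)) {
      v <- sc[strata[[nm]]]
      row[[paste0(nm, "_n")]] <- sum(!is.na(v))
      row[[paste0(nm, "_percent")]] <-
        if (sum(!is.na(v)) > 0L) 100 * mean(v, na.rm = TRUE) else NA_real_
    }
    ors <- stage_stratified_or(tumors, f, config)
    for (nm in names(ors)) {
      row[[paste0("or_", nm)]] <- ors[[nm]]$or
      row[[paste0("or_", nm, "_ci_low")]] <- ors[[nm]]$ci_low
      row[[paste0("or_", nm, "_ci_high")]] <- ors[[nm]]$ci_high
    }
    row
  }))

  # --- SI-stratified marker evaluation ------------------------------------
  si_marker <- do.call(rbind, lapply(c("all_malignant", "stage_I_only"),
    function(contrast) do.call(rbind, lapply(MARKERS, function(m) {
      ev <- si_stratified_marker_eval(tumors, m, contrast, config)
      do.call(rbind, lapply(names(ev$subsets), function(ss) {
        e <- ev$subsets[[ss]]
        data.frame(contrast = contrast, subset = ss, marker = m,
                   n = e$n, auc = e$auc,
                   auc_ci_low = e$auc_ci[1L], auc_ci_high = e$auc_ci[2L],
                   sensitivity = 100 * e$sensitivity,
                   specificity = 100 * e$specificity,
                   ppv = 100 * e$ppv, npv = 100 * e$npv,
                   stringsAsFactors = FALSE)
      }))
    }))))
  delong <- do.call(rbind, lapply(c("all_malignant", "stage_I_only"),
    function(contrast) do.call(rbind,
      lapply(c("all", "si_negative", "si_positive"), function(ss) {
        cmp <- marker_delong_comparisons(tumors, ss, contrast)
        if (is.null(cmp)) return(NULL)
        cmp$contrast <- contrast; cmp$subset <- ss
        cmp
      }))))

  # --- referral ------------------------------------------------------------
  si <- symptom_index(dt)
  ca <- marker_positive(tumors, "ca125", config$cutoffs)
  referral <- referral_decision(si, ca, policy = config$referral_policy)
  referral <- cbind(data.frame(patient_id = tumors$patient_id,
                               stringsAsFactors = FALSE), referral)

  out <- list(symptom_prevalence = symptom_prevalence,
              cluster_prevalence = cluster_prevalence,
              performance = performance_table,
              stage_stratified = stage_stratified,
              si_marker = si_marker,
              delong_comparisons = delong,
              referral = referral,
              counts = c(total = nrow(cohort),
                         controls_excluded = sum(grp == "control"),
                         analyzed = nrow(tumors)),
              config = config)
  class(out) <- "triage_report"
  out
}

#' @export
print.triage_report <- function(x, ...) {
  cat("triage report:", x$counts[["analyzed"]], "tumor records analyzed (",
      x$counts[["controls_excluded"]], "controls excluded )\n")
  si <- x$performance[x$performance$feature == "si", ]
  cat(sprintf("  SI sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              si$sensitivity, si$specificity, si$ppv, si$npv))
  cat("  referral:", sum(x$referral$category == "refer"), "refer /",
      sum(x$referral$category == "routine_workup"), "routine work-up\n")
  invisible(x)
}

#' Stage-stratified crude odds ratios for one feature
#'
#' Four contrasts: all malignant vs benign, stage I vs benign, stage II-IV
#' vs benign, and stage II-IV vs stage I. Records where the feature is not
#' assessable (missing marker) are dropped pairwise; an empty stratum gives
#' a missing-result sentinel for its contrasts.
#'
#' @param cohort Cohort data.frame of tumor records (controls, if present,
#'   are ignored).
#' @param feature Feature name (cluster name, `"si"`, symptom id, or marker
#'   name) or a scoring function `cohort -> logical`.
#' @param config A [triage_config()].
#' @return Named list of [odds_ratio()] results: `all_vs_benign`,
#'   `I_vs_benign`, `II_IV_vs_benign`, `II_IV_vs_I`.
#' @export
stage_stratified_or <- function(cohort, feature, config = triage_config()) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$records
  cohort <- cohort[cohort$group != "control", , drop = FALSE]
  sc <- feature_scores(cohort, feature, config$cutoffs)
  g <- ifelse(cohort$group == "benign", "benign",
              ifelse(cohort$stage == "I", "I", "II_IV"))
  contrast <- function(a, b) {
    i <- g %in% c(a, b) & !is.na(sc)
    if (sum(g[i] == a) == 0L || sum(g[i] == b) == 0L) {
      out <- odds_ratio(c(0L, 0L, 0L, 0L))   # degenerate -> NA sentinel
      return(out)
    }
    odds_ratio(two_by_two(sc[i], g[i] == a), config$conf.level)
  }
  all_t <- two_by_two(sc[!is.na(sc)], g[!is.na(sc)] != "benign")
  list(all_vs_benign = odds_ratio(all_t, config$conf.level),
       I_vs_benign = contrast("I", "benign"),
       II_IV_vs_benign = contrast("II_IV", "benign"),
       II_IV_vs_I = contrast("II_IV", "I"))
}

#' Marker performance within Symptom-Index strata
#'
#' Evaluates one marker's AUC and cutoff-based performance in three subsets
#' (all tumor records, SI-negative, SI-positive) for the chosen contrast:
#' `"all_malignant"` (every malignant vs benign) or `"stage_I_only"`
#' (stage II-IV records dropped entirely). Subsets with a single class give
#' missing-result sentinels.
#'
#' @inheritParams stage_stratified_or
#' @param marker `"ca125"`, `"he4"` or `"roma"`.
#' @param contrast `"all_malignant"` or `"stage_I_only"`.
#' @return List with `marker`, `contrast` and `subsets`: per subset, `n`,
#'   `auc`, `auc_ci`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
si_stratified_marker_eval <- function(cohort, marker,
                                      contrast = c("all_malignant",
                                                   "stage_I_only"),
                                      config = triage_config()) {
  contrast <- match.arg(contrast)
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$records
  cohort <- cohort[cohort$group != "control", , drop = FALSE]
  if (contrast == "stage_I_only")
    cohort <- cohort[cohort$group == "benign" | cohort$stage == "I", ,
                     drop = FALSE]
  si <- symptom_index(dichotomize_cohort(cohort))
  value <- if (marker == "roma")
    roma_percent(roma_pi(cohort$he4, cohort$ca125, cohort$menopausal))
  else as.numeric(cohort[[marker]])
  pos <- marker_positive(cohort, marker, config$cutoffs)
  truth <- cohort$group == "malignant"
  subsets <- list(all = rep(TRUE, nrow(cohort)), si_negative = !si,
                  si_positive = si)
  out <- lapply(subsets, function(keep) {
    keep <- keep & !is.na(value)
    n <- sum(keep)
    if (length(unique(truth[keep])) < 2L)
      return(list(n = n, auc = NA_real_, auc_ci = c(NA_real_, NA_real_),
                  sensitivity = NA_real_, specificity = NA_real_,
                  ppv = NA_real_, npv = NA_real_))
    a <- auc(value[keep], truth[keep], config$conf.level)
    pf <- performance(two_by_two(pos[keep], truth[keep]), config$conf.level)
    list(n = n, auc = a$auc, auc_ci = a$ci,
         sensitivity = pf$sensitivity, specificity = pf$specificity,
         ppv = pf$ppv, npv = pf$npv)
  })
  list(marker = marker, contrast = contrast, subsets = out)
}

# pairwise DeLong comparisons of the three markers within an SI subset
marker_delong_comparisons <- function(tumors, subset, contrast) {
  if (contrast == "stage_I_only")
    tumors <- tumors[tumors$group == "benign" | tumors$stage == "I", ,
                     drop = FALSE]
  si <- symptom_index(dichotomize_cohort(tumors))
  keep <- switch(subset, all = rep(TRUE, nrow(tumors)),
                 si_negative = !si, si_positive = si)
  tumors <- tumors[keep, , drop = FALSE]
  ok <- !is.na(tumors$ca125) & !is.na(tumors$he4)
  tumors <- tumors[ok, , drop = FALSE]
  truth <- tumors$group == "malignant"
  if (sum(truth) < 2L || sum(!truth) < 2L) return(NULL)
  scores <- list(ca125 = tumors$ca125, he4 = tumors$he4,
                 roma = roma_percent(roma_pi(tumors$he4, tumors$ca125,
                                             tumors$menopausal)))
  combos <- list(c("he4", "ca125"), c("he4", "roma"), c("ca125", "roma"))
  do.call(rbind, lapply(combos, function(cb) {
    dl <- delong_test(scores[[cb[1L]]], scores[[cb[2L]]], truth)
    data.frame(comparison = paste(cb, collapse = "_vs_"),
               auc_a = dl$auc_a, auc_b = dl$auc_b,
               difference = dl$difference, p_value = dl$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' Referral recommendation
#'
#' Default policy (`"or"`): refer when the Symptom Index or CA125 is
#' positive -- the sensitivity-first reading of symptom-plus-CA125 triage,
#' under which a woman with negative SI and negative CA125 gets routine
#' work-up. The `"and"` policy refers only when both are positive
#' (PPV-first). Missing CA125 contributes as `missing_as` (default
#' `FALSE`: the decision then rests on the SI alone).
#'
#' @param si_positive Logical vector: Symptom Index result.
#' @param ca125_positive Logical vector: CA125 classification (may contain
#'   `NA`).
#' @param policy `"or"` or `"and"`.
#' @param missing_as Logical value substituted for missing CA125 results.
#' @return data.frame with `category` (`"refer"` / `"routine_workup"`) and
#'   the basis flags `si_positive`, `ca125_positive`.
#' @export
#' @examples
#' referral_decision(TRUE, FALSE)                  # refer
#' referral_decision(FALSE, FALSE)                 # routine_workup
#' referral_decision(TRUE, FALSE, policy = "and")  # routine_workup
referral_decision <- function(si_positive, ca125_positive,
                              policy = c("or", "and"), missing_as = FALSE) {
  policy <- match.arg(policy)
  n <- max(length(si_positive), length(ca125_positive))
  si_positive <- rep_len(as.logical(si_positive), n)
  ca125_positive <- rep_len(as.logical(ca125_positive), n)
  ca <- ifelse(is.na(ca125_positive), missing_as, ca125_positive)
  refer <- if (policy == "or") si_positive | ca else si_positive & ca
  data.frame(category = ifelse(refer, "refer", "routine_workup"),
             si_positive = si_positive, ca125_positive = ca125_positive,
             stringsAsFactors = FALSE)
}

#' Write a triage report to disk
#'
#' One CSV per table plus a JSON summary.
#'
#' @param report A `triage_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_triage_report <- function(report, dir) {
  stopifnot(inherits(report, "triage_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("symptom_prevalence", "cluster_prevalence", "performance",
              "stage_stratified", "si_marker", "delong_comparisons",
              "referral")
  for (tb in tables)
    utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  si <- report$performance[report$performance$feature == "si", ]
  summary <- list(counts = as.list(report$counts),
                  si = as.list(si),
                  referrals = sum(report$referral$category == "refer"))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
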
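# End-to-end pipeline: table assembly, exclusion of controls, stage and SI
# stratification, referral policies, determinism.

make_run_cohort <- function(seed = 5) {
  spec <- default_paper_spec()
  spec$n <- c(malignant = 40L, benign = 60L, control = 30L)
  generate_cohort(spec, seed = seed)$records
}

test_that("run_triage refuses degenerate cohorts", {
  cohort <- make_run_cohort()
  controls_only <- cohort[cohort$group == "control", ]
  expect_error(run_triage(controls_only), "malignant and benign")
  no_benign <- cohort[cohort$group != "benign", ]
  expect_error(run_triage(no_benign), "malignant and benign")
})

test_that("the report is deterministic and internally consistent", {
  cohort <- make_run_cohort()
  r1 <- run_triage(cohort)
  r2 <- run_triage(cohort)
  expect_identical(r1, r2)

  # conservation: per-feature malignant/benign denominators equal group sizes
  expect_true(all(r1$cluster_prevalence$malignant_n == 40L))
  expect_true(all(r1$cluster_prevalence$benign_n == 60L))
  expect_equal(r1$counts[["analyzed"]], 100L)
  expect_equal(r1$counts[["controls_excluded"]], 30L)

  # every odds ratio is recomputable from the report's own counts
  cp <- r1$cluster_prevalence
  for (i in seq_len(nrow(cp))) {
    tp <- cp$malignant_count[i]; fn <- cp$malignant_n[i] - tp
    fp <- cp$benign_count[i]; tn <- cp$benign_n[i] - fp
    expect_equal(cp$or[i], odds_ratio(c(tp, fn, fp, tn))$or, tolerance = 1e-12)
  }

  # SI-stratified subsets partition each marker's records
  sm <- r1$si_marker
  for (ct in unique(sm$contrast)) for (m in unique(sm$marker)) {
    rows <- sm[sm$contrast == ct & sm$marker == m, ]
    expect_equal(rows$n[rows$subset == "all"],
                 sum(rows$n[rows$subset != "all"]))
  }

  # referral covers every analyzed record
  expect_equal(nrow(r1$referral), 100L)
})

test_that("controls contribute only to the symptom prevalence table", {
  cohort <- make_run_cohort()
  with_controls <- run_triage(cohort)
  without <- run_triage(cohort[cohort$group != "control", ])
  for (tb in c("cluster_prevalence", "performance", "stage_stratified",
               "si_marker", "delong_comparisons", "referral"))
    expect_identical(with_controls[[tb]], without[[tb]])
  # and the prevalence table reports controls where present
  expect_equal(with_controls$symptom_prevalence$control_n[1], 30L)
  expect_true(all(is.na(without$symptom_prevalence$p_mal_vs_con)))
})

test_that("symptom prevalence p-values match the module-level tests", {
  cohort <- make_run_cohort()
  r <- run_triage(cohort)
  d <- dichotomize_cohort(cohort)
  i <- cohort$group %in% c("malignant", "benign")
  want <- association_test(two_by_two(d[i, "pelvic_pain"],
                                      cohort$group[i] == "malignant"))$p_value
  row <- r$symptom_prevalence[r$symptom_prevalence$symptom == "pelvic_pain", ]
  expect_equal(row$p_mal_vs_ben, want)
})

test_that("stage-stratified odds ratios are consistent cross-products", {
  cohort <- make_run_cohort()
  ors <- stage_stratified_or(cohort, "si")
  for (nm in names(ors)) {
    cc <- ors[[nm]]$counts
    if (ors[[nm]]$corrected) cc <- cc + 0.5
    if (!is.na(ors[[nm]]$or))
      expect_equal(ors[[nm]]$or, cc[1] * cc[4] / (cc[2] * cc[3]),
                   tolerance = 1e-12)
  }

  # a feature with identical prevalence in both strata has OR exactly 1
  constant_feature <- function(cohort) rep(c(TRUE, FALSE),
                                           length.out = nrow(cohort))
  cohort_sorted <- cohort[order(cohort$group), ]
  # build a feature that is positive for exactly half of each group
  sc <- unlist(lapply(split(seq_len(nrow(cohort_sorted)),
                            cohort_sorted$group),
                      function(ix) rep(c(TRUE, FALSE), length.out = length(ix))))
  f <- function(ch) sc[match(ch$patient_id, cohort_sorted$patient_id)]
  or_all <- stage_stratified_or(cohort_sorted, f)$all_vs_benign
  expect_equal(or_all$or, 1, tolerance = 0.1)  # halves may differ by one record

  # empty stratum gives a missing-result sentinel
  no_late <- cohort[cohort$group == "benign" | cohort$stage == "I", ]
  ors <- stage_stratified_or(no_late, "si")
  expect_true(is.na(ors$II_IV_vs_benign$or))
  expect_false(is.na(ors$I_vs_benign$or))
})

test_that("SI-stratified marker evaluation handles perfect and degenerate subsets", {
  # hand-built cohort: CA125 separates perfectly
  cohort <- make_cohort(
    make_patient("m1", "malignant", ca125 = 500, he4 = 200,
                 positive = "pelvic_pain"),
    make_patient("m2", "malignant", ca125 = 400, he4 = 180,
                 positive = "abdominal_bloating"),
    make_patient("m3", "malignant", ca125 = 300, he4 = 220),
    make_patient("b1", "benign", ca125 = 10, he4 = 40,
                 positive = "pelvic_pain"),
    make_patient("b2", "benign", ca125 = 12, he4 = 35),
    make_patient("b3", "benign", ca125 = 9, he4 = 30)
  )
  ev <- si_stratified_marker_eval(cohort, "ca125", "all_malignant")
  expect_equal(ev$subsets$all$auc, 1)
  expect_equal(ev$subsets$all$sensitivity, 1)
  expect_equal(ev$subsets$all$specificity, 1)
  # SI-positive subset: m1, m2, b1 -> still both classes
  expect_equal(ev$subsets$si_positive$n, 3)
  expect_equal(ev$subsets$si_positive$auc, 1)

  # stage-I-only contrast drops stage II-IV records entirely
  cohort2 <- cohort
  cohort2$stage[cohort2$patient_id == "m3"] <- "III"
  ev2 <- si_stratified_marker_eval(cohort2, "ca125", "stage_I_only")
  expect_equal(ev2$subsets$all$n, 5)

  # single-class subset: missing-result sentinel
  cohort3 <- cohort
  for (s in symptom_panel()) {  # no benign record is SI positive
    cohort3[4, paste0(s, c("_present", "_freq", "_onset", "_severity"))] <-
      list(FALSE, NA_character_, NA_character_, NA_real_)
  }
  ev3 <- si_stratified_marker_eval(cohort3, "ca125", "all_malignant")
  expect_true(is.na(ev3$subsets$si_positive$auc))
})

test_that("referral decisions follow the configured policy", {
  r <- referral_decision(c(TRUE, FALSE, FALSE, TRUE),
                         c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$category,
               c("refer", "refer", "routine_workup", "refer"))

  r <- referral_decision(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                         policy = "and")
  expect_equal(r$category, c("routine_workup", "routine_workup", "refer"))

  # missing CA125 defaults to the SI alone
  r <- referral_decision(c(TRUE, FALSE), c(NA, NA))
  expect_equal(r$category, c("refer", "routine_workup"))

  # under the AND policy, refer implies SI positive
  set.seed(31)
  si <- runif(50) < 0.5
  ca <- ifelse(runif(50) < 0.2, NA, runif(50) < 0.5)
  r <- referral_decision(si, ca, policy = "and")
  expect_true(all(si[r$category == "refer"]))
})

test_that("a report writes to disk as CSV tables plus a JSON summary", {
  cohort <- make_run_cohort()
  report <- run_triage(cohort)
  dir <- withr::local_tempdir()
  write_triage_report(report, dir)
  expect_true(file.exists(file.path(dir, "performance.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- utils::read.csv(file.path(dir, "cluster_prevalence.csv"))
  expect_equal(back$malignant_count, report$cluster_prevalence$malignant_count)
})
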
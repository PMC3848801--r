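# Builders for small in-code cohorts.

# one patient with every symptom absent; override symptoms via `positive`
# (dichotomized-positive), `subthreshold` (present but below the frequency
# rule) or `longstanding` (frequent but predating the last year)
make_patient <- function(id = "p1", group = "benign",
                         stage = if (group == "malignant") "I" else "none",
                         histology = switch(group,
                                            malignant = "epithelial_invasive",
                                            benign = "non_neoplastic",
                                            control = "none"),
                         age = 50, bmi = 27, menopausal = "post",
                         ca125 = 15, he4 = 40,
                         positive = character(0),
                         subthreshold = character(0),
                         longstanding = character(0)) {
  df <- data.frame(patient_id = id, group = group, stage = stage,
                   histology = histology, age = age, bmi = bmi,
                   menopausal = menopausal, ca125 = ca125, he4 = he4,
                   stringsAsFactors = FALSE)
  for (s in symptom_panel()) {
    pr <- FALSE; fr <- NA_character_; on <- NA_character_; sev <- NA_real_
    if (s %in% positive) { pr <- TRUE; fr <- "13-19"; on <- "3-4"; sev <- 2 }
    if (s %in% subthreshold) { pr <- TRUE; fr <- "7-12"; on <- "1-2"; sev <- 1 }
    if (s %in% longstanding) { pr <- TRUE; fr <- ">20"; on <- ">12"; sev <- 3 }
    df[[paste0(s, "_present")]] <- pr
    df[[paste0(s, "_freq")]] <- fr
    df[[paste0(s, "_onset")]] <- on
    df[[paste0(s, "_severity")]] <- sev
  }
  df
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# a small mixed cohort: 3 malignant, 3 benign (deterministic)
small_tumor_cohort <- function() {
  make_cohort(
    make_patient("m1", "malignant", stage = "I", ca125 = 120, he4 = 150,
                 positive = c("pelvic_pain", "abdominal_bloating")),
    make_patient("m2", "malignant", stage = "III", ca125 = 600, he4 = 300,
                 positive = c("feeling_full_quickly", "fatigue"),
                 menopausal = "pre"),
    make_patient("m3", "malignant", stage = "II", ca125 = 90, he4 = 120,
                 subthreshold = "back_pain"),
    make_patient("b1", "benign", ca125 = 12, he4 = 45,
                 positive = "frequent_urination"),
    make_patient("b2", "benign", ca125 = 30, he4 = 60, menopausal = "pre",
                 longstanding = "pelvic_pain"),
    make_patient("b3", "benign", ca125 = 8, he4 = 35)
  )
}
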
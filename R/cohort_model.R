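# Patient-level cohort representation, validation and delimited-text I/O,
# plus the packaged fixture tables of printed study counts.

# deterministic column order for a cohort data.frame
cohort_columns <- function() {
  base <- c("patient_id", "group", "stage", "histology", "age", "bmi",
            "menopausal", "ca125", "he4")
  sym <- as.vector(t(outer(SYMPTOMS, c("present", "freq", "onset", "severity"),
                           paste, sep = "_")))
  c(base, sym)
}

#' Validate a patient-level cohort
#'
#' Checks the cohort invariants: unique patient ids; `group`, `stage`,
#' `histology` and `menopausal` drawn from their enumerations; `stage != "none"`
#' exactly for malignant records; strictly positive finite marker values where
#' present; one observation per panel symptom with category labels from the
#' questionnaire enumerations; and absent categories whenever a symptom is
#' not present.
#'
#' @param cohort data.frame, one row per patient (see [read_cohort()] for the
#'   column layout).
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending row and column.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))

  fail <- function(row, col, msg)
    stop(sprintf("cohort validation error at row %d, column '%s': %s",
                 row, col, msg), call. = FALSE)
  bad_level <- function(col, levels) {
    v <- cohort[[col]]
    i <- which(!(v %in% levels))
    if (length(i) > 0L)
      fail(i[1L], col, sprintf("'%s' is not one of {%s}",
                               v[i[1L]], paste(levels, collapse = ", ")))
  }

  if (anyDuplicated(cohort$patient_id)) {
    d <- cohort$patient_id[duplicated(cohort$patient_id)][1L]
    stop("duplicate patient_id: ", d, call. = FALSE)
  }
  bad_level("group", GROUPS)
  bad_level("stage", STAGES)
  bad_level("histology", HISTOLOGIES)
  bad_level("menopausal", MENOPAUSAL)

  i <- which((cohort$group == "malignant") != (cohort$stage != "none"))
  if (length(i) > 0L)
    fail(i[1L], "stage", "stage must be I-IV for malignant records and 'none' otherwise")

  for (m in c("ca125", "he4")) {
    v <- cohort[[m]]
    i <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(i) > 0L)
      fail(i[1L], m, "marker values must be strictly positive finite or missing")
  }

  for (s in SYMPTOMS) {
    pr <- cohort[[paste0(s, "_present")]]
    fr <- cohort[[paste0(s, "_freq")]]
    on <- cohort[[paste0(s, "_onset")]]
    if (!is.logical(pr) || anyNA(pr))
      fail(which(is.na(pr))[1L] %||% 1L, paste0(s, "_present"),
           "must be TRUE/FALSE with no missing values")
    i <- which(!is.na(fr) & !(fr %in% FREQ_LEVELS))
    if (length(i) > 0L)
      fail(i[1L], paste0(s, "_freq"),
           sprintf("'%s' is not a frequency category", fr[i[1L]]))
    i <- which(!is.na(on) & !(on %in% ONSET_LEVELS))
    if (length(i) > 0L)
      fail(i[1L], paste0(s, "_onset"),
           sprintf("'%s' is not an onset category", on[i[1L]]))
    i <- which(!pr & (!is.na(fr) | !is.na(on)))
    if (length(i) > 0L)
      fail(i[1L], paste0(s, "_present"),
           "absent symptoms must have missing frequency and onset")
    i <- which(pr & (is.na(fr) | is.na(on)))
    if (length(i) > 0L)
      fail(i[1L], paste0(s, "_present"),
           "present symptoms must have frequency and onset categories")
  }
  invisible(cohort)
}

`%||%` <- function(a, b) if (length(a) == 0L || is.na(a[1L])) b else a

#' Read a patient-level cohort from CSV
#'
#' One row per patient; symptom observations as
#' `<symptom>_present` / `<symptom>_freq` / `<symptom>_onset` /
#' `<symptom>_severity` columns with explicit category labels. Missing marker
#' values are preserved as `NA`, never coerced to zero. The file is validated
#' on read (see [validate_cohort()]).
#'
#' @param path Path to a CSV file written by [write_cohort()] or of the same
#'   layout.
#' @return Validated cohort data.frame in canonical column order.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  classes <- c(patient_id = "character", group = "character",
               stage = "character", histology = "character",
               age = "numeric", bmi = "numeric", menopausal = "character",
               ca125 = "numeric", he4 = "numeric")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = NA)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0L)
    stop("cohort file is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, cohort_columns()]
  for (col in names(classes))
    df[[col]] <- if (classes[[col]] == "numeric") as.numeric(df[[col]])
                 else as.character(df[[col]])
  for (s in SYMPTOMS) {
    pc <- paste0(s, "_present")
    df[[pc]] <- as.logical(df[[pc]])
    for (suf in c("_freq", "_onset")) df[[paste0(s, suf)]] <- as.character(df[[paste0(s, suf)]])
    df[[paste0(s, "_severity")]] <- as.numeric(df[[paste0(s, "_severity")]])
  }
  validate_cohort(df)
  df
}

#' Write a patient-level cohort to CSV
#'
#' Deterministic column order; categories written as their labels; missing
#' values written as empty fields so that missing markers round-trip as `NA`.
#'
#' @param cohort Validated cohort data.frame (or an empty, zero-row cohort).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) > 0L) validate_cohort(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(cohort[, cohort_columns(), drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Zero-row cohort skeleton
#'
#' @return A cohort data.frame with the canonical columns and no rows.
#' @export
empty_cohort <- function() {
  cols <- cohort_columns()
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (col in c("age", "bmi", "ca125", "he4",
                paste0(SYMPTOMS, "_severity"))) df[[col]] <- numeric(0)
  for (col in paste0(SYMPTOMS, "_present")) df[[col]] <- logical(0)
  df
}

#' Packaged fixture tables of printed study counts
#'
#' Loads the per-symptom positives by group, the per-cluster/isolated-symptom
#' positives by tumor group, and the group sizes, as printed. Counts and
#' printed percentages are stored separately because a few printed
#' percentages imply slightly drifted denominators (untabulated missing
#' questionnaire responses); worked examples use counts with the nominal
#' denominators 60/116/150.
#'
#' @return Object of class `fixture_tables`: a list with `symptom_counts`
#'   (symptom, group, count, percent), `cluster_counts` (feature, counts and
#'   printed percents per tumor group plus the printed odds ratio and CI) and
#'   `group_sizes` (named integer vector).
#' @export
#' @examples
#' fx <- load_fixtures()
#' subset(fx$symptom_counts, symptom == "pelvic_pain" & group == "malignant")
load_fixtures <- function() {
  dir <- system.file("extdata", package = "ovatriage", mustWork = TRUE)
  symptom_counts <- utils::read.csv(file.path(dir, "symptom_counts.csv"),
                                    stringsAsFactors = FALSE)
  cluster_counts <- utils::read.csv(file.path(dir, "cluster_counts.csv"),
                                    stringsAsFactors = FALSE)
  group_sizes <- c(malignant = 60L, benign = 116L, control = 150L)
  stopifnot(all(symptom_counts$count <= group_sizes[symptom_counts$group]))
  out <- list(symptom_counts = symptom_counts,
              cluster_counts = cluster_counts,
              group_sizes = group_sizes)
  class(out) <- "fixture_tables"
  out
}

#' Export fixture tables as JSON
#'
#' @param fixtures A `fixture_tables` object from [load_fixtures()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixtures_json <- function(fixtures, path) {
  stopifnot(inherits(fixtures, "fixture_tables"))
  payload <- unclass(fixtures)
  payload$group_sizes <- as.list(payload$group_sizes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
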
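# Shared vocabulary: symptom panel, questionnaire categories, canonical
# symptom clusters, marker cutoffs and ROMA coefficients.

#' The 22-symptom questionnaire panel
#'
#' Symptom identifiers in questionnaire order. Each subject carries one
#' observation (presence, frequency category, onset category, severity) per
#' symptom.
#'
#' @return Character vector of 22 symptom identifiers.
#' @export
#' @examples
#' symptom_panel()
symptom_panel <- function() SYMPTOMS

SYMPTOMS <- c(
  "pelvic_pain", "abdominal_pain", "back_pain", "indigestion",
  "unable_to_eat_normally", "feeling_full_quickly", "nausea_or_vomiting",
  "weight_loss", "abdominal_bloating", "increased_abdomen_size",
  "able_to_feel_abdominal_mass", "urinary_urgency", "frequent_urination",
  "constipation", "diarrhea", "menstrual_irregularity",
  "bleeding_after_menopause", "pain_during_intercourse",
  "bleeding_with_intercourse", "fatigue", "leg_swelling",
  "difficulty_breathing"
)

# symptoms excluded from clustering: menopause/sexual-activity dependent,
# too rare, or with unascertainable frequency
WARD_EXCLUDED <- c(
  "menstrual_irregularity", "bleeding_after_menopause",
  "pain_during_intercourse", "bleeding_with_intercourse",
  "constipation", "diarrhea", "weight_loss"
)

#' Questionnaire category labels
#'
#' Frequency is recorded in days per month, onset as the number of the
#' previous 12 months during which the symptom occurred (`">12"` meaning the
#' symptom predates the last year).
#'
#' @name categories
#' @return Character vector of ordered category labels.
#' @export
frequency_levels <- function() FREQ_LEVELS

#' @rdname categories
#' @export
onset_levels <- function() ONSET_LEVELS

FREQ_LEVELS <- c("<1", "1-2", "3-6", "7-12", "13-19", ">20")
ONSET_LEVELS <- c("<1", "1-2", "3-4", "5-6", "7-9", "10-12", ">12")

# frequency categories meaning "more than 12 days per month"
FREQ_POSITIVE <- c("13-19", ">20")
# onset categories meaning "began within the last year"
ONSET_POSITIVE <- c("<1", "1-2", "3-4", "5-6", "7-9", "10-12")

GROUPS <- c("malignant", "benign", "control")
STAGES <- c("I", "II", "III", "IV", "none")
HISTOLOGIES <- c("epithelial_invasive", "epithelial_borderline",
                 "epithelial_benign", "germ_line", "sex_cord_stromal",
                 "non_neoplastic", "none")
MENOPAUSAL <- c("pre", "post")
MARKERS <- c("ca125", "he4", "roma")

#' Canonical symptom cluster definitions
#'
#' The six clusters of paired symptoms identified by Ward clustering of the
#' eligible binary symptom indicators, used for all scoring: a cluster is
#' positive when any member symptom is positive. Three further symptoms
#' (back pain, leg swelling, able to feel abdominal mass) never agglomerate
#' and are scored in isolation; they belong to no cluster.
#'
#' @return Named list mapping cluster name (`abdomen`, `pain`, `eating`,
#'   `digestion`, `miscellaneous`, `bladder`) to its member symptom ids.
#' @seealso [isolated_symptoms()], [symptom_index()]
#' @export
#' @examples
#' cluster_definitions()$abdomen
cluster_definitions <- function() CLUSTERS

CLUSTERS <- list(
  abdomen       = c("abdominal_bloating", "increased_abdomen_size"),
  pain          = c("pelvic_pain", "abdominal_pain"),
  eating        = c("unable_to_eat_normally", "feeling_full_quickly"),
  digestion     = c("indigestion", "nausea_or_vomiting"),
  miscellaneous = c("fatigue", "difficulty_breathing"),
  bladder       = c("urinary_urgency", "frequent_urination")
)

# clusters whose disjunction defines the Symptom Index
SI_CLUSTERS <- c("abdomen", "pain", "eating")

#' Symptoms outside every cluster
#'
#' @return Character vector of the three isolated symptom ids.
#' @export
isolated_symptoms <- function() ISOLATED

ISOLATED <- c("back_pain", "leg_swelling", "able_to_feel_abdominal_mass")

#' Default menopause-stratified marker cutoffs
#'
#' ROC-derived (Youden) cutoffs above which CA125 (U/mL), HE4 (pmol/L) and
#' the ROMA risk (percent scale) are called positive, stratified by
#' menopausal status. These ship as frozen constants; data-driven
#' recalibration is available through [optimal_cutoff()].
#'
#' @return A data.frame with one row per stratum (`pre`, `post`) and columns
#'   `ca125`, `he4`, `roma`.
#' @export
#' @examples
#' default_cutoffs()
default_cutoffs <- function() {
  data.frame(
    stratum = c("pre", "post"),
    ca125   = c(69.8, 21.7),
    he4     = c(41.6, 96.6),
    roma    = c(5.01, 18.2),
    row.names = c("pre", "post")
  )
}

#' ROMA predictive-index coefficients
#'
#' Menopause-specific logistic coefficients combining `ln(HE4)` and
#' `ln(CA125)` into the ROMA predictive index:
#' pre-menopausal \eqn{PI = -12.0 + 2.38 \ln HE4 + 0.0626 \ln CA125};
#' post-menopausal \eqn{PI = -8.09 + 1.04 \ln HE4 + 0.732 \ln CA125}.
#' Exposed as data so that platform-specific refits can be substituted.
#'
#' @return Named list with `pre` and `post` numeric vectors
#'   (`intercept`, `log_he4`, `log_ca125`).
#' @export
roma_coefficients <- function() {
  list(
    pre  = c(intercept = -12.0, log_he4 = 2.38, log_ca125 = 0.0626),
    post = c(intercept = -8.09, log_he4 = 1.04, log_ca125 = 0.732)
  )
}
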
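# Tri-state marker logic. Markers are "positive" / "negative" /
# "unavailable"; composites follow Kleene three-valued logic, which is the
# only completion consistent with both the OR- and AND-form CSF composites
# when a single analyte is missing.

TRI <- c("positive", "negative", "unavailable")

tri <- function(positive, available) {
  out <- ifelse(available, ifelse(positive, "positive", "negative"),
                "unavailable")
  out[available & is.na(positive)] <- "unavailable"
  out
}

tri_or <- function(a, b) {
  ifelse(a == "positive" | b == "positive", "positive",
  ifelse(a == "negative" & b == "negative", "negative", "unavailable"))
}

tri_and <- function(a, b) {
  ifelse(a == "negative" | b == "negative", "negative",
  ifelse(a == "positive" & b == "positive", "positive", "unavailable"))
}

#' Dichotomization cutoffs for the prodromal-AD research criteria
#'
#' Defaults are the published operating points: hippocampal-type episodic
#' memory impairment when RAVLT delayed recall < 3 *and* delayed
#' recognition < 10; significant medial temporal atrophy when the Scheltens
#' rating is >= 3; positive CSF markers when Tau > 93 pg/ml or
#' amyloid-beta 1-42 < 192 pg/ml. Boundary strictness is exactly as
#' printed: recall of 3, Scheltens of 3 (positive), Tau of 93 and
#' amyloid of 192 sit on the stated sides of their cutoffs.
#'
#' @param ravlt_recall_cut Positive if recall `<` this value.
#' @param ravlt_recognition_cut Positive if recognition `<` this value.
#' @param scheltens_cut Positive if rating `>=` this value.
#' @param tau_cut Positive if Tau `>` this value (pg/ml).
#' @param abeta_cut Positive if amyloid-beta 1-42 `<` this value (pg/ml).
#' @param csf_combination_for_likelihood `"or"` (default) or `"and"`: which
#'   CSF composite feeds the likelihood-of-AD categories.
#' @return A `criteria_cutoffs` list.
#' @export
criteria_cutoffs <- function(ravlt_recall_cut = 3, ravlt_recognition_cut = 10,
                             scheltens_cut = 3, tau_cut = 93, abeta_cut = 192,
                             csf_combination_for_likelihood = c("or", "and")) {
  csf_combination_for_likelihood <- match.arg(csf_combination_for_likelihood)
  stopifnot(is.finite(ravlt_recall_cut), is.finite(ravlt_recognition_cut),
            is.finite(scheltens_cut), is.finite(tau_cut), is.finite(abeta_cut))
  structure(list(ravlt_recall_cut = ravlt_recall_cut,
                 ravlt_recognition_cut = ravlt_recognition_cut,
                 scheltens_cut = scheltens_cut,
                 tau_cut = tau_cut, abeta_cut = abeta_cut,
                 csf_combination_for_likelihood = csf_combination_for_likelihood),
            class = "criteria_cutoffs")
}

#' Dichotomize a cohort's markers
#'
#' Applies the cutoffs to every subject, yielding tri-state marker
#' statuses. Missingness is represented (never an error): the MTA status is
#' `unavailable` iff the Scheltens rating is missing, and each CSF analyte
#' status is `unavailable` iff that analyte is missing. The OR and AND CSF
#' composites are derived with Kleene logic, so with both analytes missing
#' they are `unavailable`.
#'
#' RAVLT scores are assumed always measured; a missing RAVLT score makes
#' `ravlt_positive` `NA`.
#'
#' @param cohort An `mci_cohort` data frame (or any data frame with the
#'   canonical feature columns).
#' @param cutoffs A [criteria_cutoffs()].
#' @return A `marker_status` data frame with columns `subject_id`,
#'   `ravlt_positive` (logical) and tri-state columns `mta`, `tau`,
#'   `abeta`, `csf_or`, `csf_and`.
#' @export
dichotomize <- function(cohort, cutoffs = criteria_cutoffs()) {
  col <- function(nm) {   # absent column == missing for every subject
    v <- cohort[[nm]]
    if (is.null(v)) rep(NA_real_, nrow(cohort)) else v
  }
  scheltens <- col("scheltens"); tau_v <- col("csf_tau")
  abeta_v <- col("csf_abeta42")
  mta  <- tri(scheltens >= cutoffs$scheltens_cut, !is.na(scheltens))
  tau  <- tri(tau_v > cutoffs$tau_cut, !is.na(tau_v))
  abeta <- tri(abeta_v < cutoffs$abeta_cut, !is.na(abeta_v))
  out <- data.frame(
    subject_id = cohort$subject_id,
    ravlt_positive = col("ravlt_recall") < cutoffs$ravlt_recall_cut &
      col("ravlt_recognition") < cutoffs$ravlt_recognition_cut,
    mta = mta, tau = tau, abeta = abeta,
    csf_or = tri_or(tau, abeta), csf_and = tri_and(tau, abeta),
    stringsAsFactors = FALSE)
  class(out) <- c("marker_status", "data.frame")
  out
}

#' Assign the likelihood-of-AD category
#'
#' Four-way research-criteria classification by the pattern of positive,
#' negative and unavailable markers, with a fifth `indeterminate` bucket
#' for patterns the published definitions do not cover:
#' \itemize{
#'   \item `high`: memory criterion, MTA and CSF all positive;
#'   \item `intermediate`: memory criterion positive, one of MTA/CSF
#'     positive and the other unavailable;
#'   \item `uninformative`: memory criterion positive, one of MTA/CSF
#'     positive and the other negative;
#'   \item `low`: memory criterion negative, MTA and CSF both measured and
#'     negative;
#'   \item `indeterminate`: anything else (e.g. memory-positive with both
#'     biomarkers missing, or memory-negative with a missing modality).
#' }
#' The CSF side uses the OR composite by default
#' (`csf_combination_for_likelihood`).
#'
#' @param status A `marker_status` from [dichotomize()].
#' @param csf_combination `"or"` or `"and"`.
#' @return Factor with levels `high`, `intermediate`, `uninformative`,
#'   `low`, `indeterminate`.
#' @export
assign_likelihood <- function(status, csf_combination = c("or", "and")) {
  csf_combination <- match.arg(csf_combination)
  csf <- if (csf_combination == "or") status$csf_or else status$csf_and
  mta <- status$mta
  r <- status$ravlt_positive
  cat <- rep("indeterminate", nrow(status))
  one_pos_one_unavail <- (mta == "positive" & csf == "unavailable") |
                         (csf == "positive" & mta == "unavailable")
  one_pos_one_neg <- (mta == "positive" & csf == "negative") |
                     (csf == "positive" & mta == "negative")
  cat[r & mta == "positive" & csf == "positive"] <- "high"
  cat[r & one_pos_one_unavail] <- "intermediate"
  cat[r & one_pos_one_neg] <- "uninformative"
  cat[!r & mta == "negative" & csf == "negative"] <- "low"
  cat[is.na(r)] <- "indeterminate"
  factor(cat, levels = c("high", "intermediate", "uninformative", "low",
                         "indeterminate"))
}

criteria_rules <- list(
  r1      = c("ravlt"),
  r2      = c("mta"),
  r3a     = c("csf_or"),
  r3b     = c("csf_and"),
  r1_2    = c("ravlt", "mta"),
  r1_3a   = c("ravlt", "csf_or"),
  r1_2_3a = c("ravlt", "mta", "csf_or"),
  r1_2_3b = c("ravlt", "mta", "csf_and")
)

#' Rule identifiers for the criteria combinations
#' @return Character vector: `r1` (RAVLT), `r2` (visual MTA), `r3a`
#'   (Tau or abeta), `r3b` (Tau and abeta), and their conjunctions
#'   `r1_2`, `r1_3a`, `r1_2_3a`, `r1_2_3b`.
#' @export
rule_ids <- function() names(criteria_rules)

#' Predict conversion under one criteria combination
#'
#' A rule names one or more markers; the prediction is `predict_converter`
#' iff every named marker is positive, `not_evaluable` iff any named
#' marker is unavailable, otherwise `predict_nonconverter`.
#'
#' @param status A `marker_status` from [dichotomize()].
#' @param rule_id One of [rule_ids()].
#' @return Factor with levels `predict_converter`, `predict_nonconverter`,
#'   `not_evaluable`.
#' @export
predict_rule <- function(status, rule_id) {
  if (!rule_id %in% names(criteria_rules))
    stop("unknown rule_id '", rule_id, "'; see rule_ids()")
  markers <- criteria_rules[[rule_id]]
  tri_m <- lapply(markers, function(m) {
    if (m == "ravlt") tri(status$ravlt_positive, !is.na(status$ravlt_positive))
    else status[[m]]
  })
  any_unavail <- Reduce(`|`, lapply(tri_m, function(v) v == "unavailable"))
  all_pos <- Reduce(`&`, lapply(tri_m, function(v) v == "positive"))
  factor(ifelse(any_unavail, "not_evaluable",
         ifelse(all_pos, "predict_converter", "predict_nonconverter")),
         levels = c("predict_converter", "predict_nonconverter",
                    "not_evaluable"))
}

#' Subjects evaluable under a rule
#'
#' The modality-specific denominator for a rule's accuracy metrics:
#' subjects for whom [predict_rule()] is not `not_evaluable`.
#'
#' @param cohort An `mci_cohort`.
#' @param rule_id One of [rule_ids()].
#' @param cutoffs A [criteria_cutoffs()].
#' @return The subset of `cohort` rows, same class.
#' @export
evaluable_subset <- function(cohort, rule_id, cutoffs = criteria_cutoffs()) {
  pred <- predict_rule(dichotomize(cohort, cutoffs), rule_id)
  cohort[pred != "not_evaluable", , drop = FALSE]
}
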
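# Published reference counts from the ADNI-based evaluation study that
# this package's pipeline mirrors. Bundled so that the arithmetic of every
# printed summary statistic can be re-derived offline from raw counts.

#' Published reference counts
#'
#' The raw counts behind the study's printed summary tables:
#' \describe{
#'   \item{cohort}{391 MCI subjects, 158 converters, 15 reverters; per-group
#'     CSF availability 115/84.}
#'   \item{conversion}{Per-criterion evaluable-case and converter counts
#'     (the conversion-rate table): RAVLT-positive, MTA-positive, CSF OR /
#'     AND composites, and the four likelihood categories.}
#'   \item{category_dsi / category_clinician}{Six-level diagnosis by final
#'     three-way outcome (AD / Healthy / MCI) count matrices for the
#'     automatic DSI classification and for the clinician assisted by the
#'     tool.}
#' }
#'
#' @return Nested list of integer counts.
#' @export
reference_counts <- function() {
  cat_tab <- function(ad, healthy, mci) {
    m <- cbind(AD = ad, Healthy = healthy, MCI = mci)
    rownames(m) <- category_row_names
    m
  }
  list(
    cohort = list(n_total = 391L, n_converters = 158L, n_reverters = 15L,
                  csf_n = c(nonconverter = 115L, converter = 84L)),
    conversion = list(
      baseline     = c(cases = 391L, converters = 158L),
      ravlt        = c(cases = 136L, converters = 72L),
      mta          = c(cases = 92L,  converters = 51L),
      csf_or       = c(cases = 150L, converters = 76L),
      csf_and      = c(cases = 84L,  converters = 48L),
      high         = c(cases = 20L,  converters = 13L),
      low          = c(cases = 29L,  converters = 2L),
      intermediate = c(cases = 21L,  converters = 12L),
      uninformative = c(cases = 58L, converters = 37L)),
    category_dsi = cat_tab(ad = c(2L, 9L, 27L, 58L, 51L, 11L),
                           healthy = c(9L, 4L, 2L, 0L, 0L, 0L),
                           mci = c(43L, 51L, 53L, 46L, 20L, 5L)),
    category_clinician = cat_tab(ad = c(6L, 15L, 18L, 43L, 31L, 45L),
                                 healthy = c(12L, 3L, 0L, 0L, 0L, 0L),
                                 mci = c(64L, 46L, 34L, 38L, 19L, 17L))
  )
}

# Expand a count matrix (six categories x AD/Healthy/MCI) into per-subject
# category and label vectors so category_table() can recompute the table.
expand_category_counts <- function(m) {
  cats <- rep(rep(1:6, 3), as.vector(m))
  labs <- rep(rep(colnames(m), each = 6), as.vector(m))
  list(categories = cats, final_labels = labs)
}

# Rule confusion cells implied by the published counts: evaluable cases n
# with x converters among them, against the evaluable-subset totals.
rule_cells <- function(rule, counts = reference_counts()) {
  cv <- counts$conversion[[rule]]
  pos_total <- if (rule %in% c("csf_or", "csf_and"))
    counts$cohort$csf_n[["converter"]] else counts$cohort$n_converters
  neg_total <- if (rule %in% c("csf_or", "csf_and"))
    counts$cohort$csf_n[["nonconverter"]]
  else counts$cohort$n_total - counts$cohort$n_converters
  tp <- cv[["converters"]]
  fp <- cv[["cases"]] - tp
  list(tp = tp, fp = fp, fn = pos_total - tp, tn = neg_total - fp)
}

#' Verify the published summary tables from their raw counts
#'
#' Recomputes every bundled summary target from [reference_counts()] using
#' the package's evaluation operations and compares with the printed
#' values: overall and pooled non-AD accuracies of the two six-category
#' tables, baseline and likelihood-group conversion rates, and the
#' sensitivity/specificity/accuracy of the RAVLT and CSF-OR rules.
#'
#' @return Data frame with columns `target`, `description`, `computed`,
#'   `expected`, `pass`; all-pass means the printed arithmetic reproduces.
#' @export
verify_reference_tables <- function() {
  rc <- reference_counts()
  tgt <- list()
  add <- function(id, desc, computed, expected)
    tgt[[length(tgt) + 1L]] <<- data.frame(
      target = id, description = desc, computed = as.numeric(computed),
      expected = as.numeric(expected), stringsAsFactors = FALSE)

  dsi_tab <- do.call(category_table, expand_category_counts(rc$category_dsi))
  cli_tab <- do.call(category_table, expand_category_counts(rc$category_clinician))
  add("t1", "overall accuracy, automatic DSI six-category table",
      attr(dsi_tab, "overall_accuracy_percent"), 72)
  add("t2", "overall accuracy, clinician-with-tool six-category table",
      attr(cli_tab, "overall_accuracy_percent"), 71)
  add("t3", "baseline 3-year conversion rate (%)",
      conversion_rate(rc$conversion$baseline[["converters"]],
                      rc$conversion$baseline[["cases"]]), 40)
  add("t4", "conversion rate in the high-likelihood group (%)",
      conversion_rate(rc$conversion$high[["converters"]],
                      rc$conversion$high[["cases"]]), 65)
  add("t5", "conversion rate in the low-likelihood group (%)",
      conversion_rate(rc$conversion$low[["converters"]],
                      rc$conversion$low[["cases"]]), 7)
  rav <- rule_cells("ravlt", rc)
  rav_cs <- confusion_from_counts(rav$tp, rav$fp, rav$tn, rav$fn)
  add("t6", "RAVLT rule sensitivity (%)", rav_cs$sensitivity$percent, 46)
  add("t7", "RAVLT rule specificity (%)", rav_cs$specificity$percent, 73)
  add("t8", "RAVLT rule accuracy (%)", rav_cs$accuracy$percent, 62)
  csf <- rule_cells("csf_or", rc)
  csf_cs <- confusion_from_counts(csf$tp, csf$fp, csf$tn, csf$fn)
  add("t9", "CSF OR-composite rule sensitivity (%)", csf_cs$sensitivity$percent, 90)
  add("t10", "CSF OR-composite rule accuracy (%)", csf_cs$accuracy$percent, 59)
  add("t11", "pooled non-AD accuracy, automatic DSI table (%)",
      dsi_tab["pooled_non_ad", "accuracy_percent"], 81)
  add("t12", "pooled non-AD accuracy, clinician table (%)",
      cli_tab["pooled_non_ad", "accuracy_percent"], 80)

  out <- do.call(rbind, tgt)
  out$pass <- out$computed == out$expected
  out
}
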
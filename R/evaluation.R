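#' Half-up integer percent
#'
#' Rounds `100 * p` half-up to an integer, matching the printed-table
#' style (45.57 -> 46, 90.48 -> 90, 0.5 boundary rounds up).
#'
#' @param p Proportion(s) in [0,1].
#' @return Integer percent(s).
#' @export
percent_round <- function(p) as.integer(floor(100 * p + 0.5 + 1e-9))

#' Exact binomial confidence interval
#'
#' Central Clopper-Pearson interval via beta quantiles; the lower bound is
#' exactly 0 when `successes == 0` and the upper exactly 1 when
#' `successes == n`.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(low, high)` with attribute `percent`, the
#'   half-up integer-percent endpoints.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("invalid counts: successes=", successes, ", n=", n)
  a <- (1 - level) / 2
  low  <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  structure(c(low = low, high = high),
            percent = percent_round(c(low, high)))
}

#' Conversion rate as a printed percentage
#'
#' @param n_converters,n_total Counts, `n_total >= 1`.
#' @return Half-up integer percent.
#' @export
conversion_rate <- function(n_converters, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_converters < 0 || n_converters > n_total) stop("invalid counts")
  percent_round(n_converters / n_total)
}

#' Confusion summary of a binary classifier
#'
#' Counts TP/FP/TN/FN treating `converter` as the positive class
#' (reverters are labelled `nonconverter`), with sensitivity, specificity
#' and accuracy, exact binomial CIs for each, and the half-up
#' integer-percent forms. `not_evaluable` predictions are excluded and
#' counted in `n_not_evaluable`.
#'
#' @param predictions Factor/character: `predict_converter`/`converter`,
#'   `predict_nonconverter`/`nonconverter`, `not_evaluable`.
#' @param labels Factor/character: `converter` / `nonconverter`.
#' @param level CI level.
#' @return A `confusion_summary` list.
#' @export
confusion <- function(predictions, labels, level = 0.95) {
  stopifnot(length(predictions) == length(labels))
  pred <- sub("^predict_", "", as.character(predictions))
  lab <- as.character(labels)
  keep <- pred != "not_evaluable"
  n_ne <- sum(!keep)
  pred <- pred[keep]; lab <- lab[keep]
  if (!length(pred)) stop("zero evaluable subjects")
  stopifnot(all(pred %in% c("converter", "nonconverter")),
            all(lab %in% c("converter", "nonconverter")))
  tp <- sum(pred == "converter" & lab == "converter")
  fn <- sum(pred == "nonconverter" & lab == "converter")
  fp <- sum(pred == "converter" & lab == "nonconverter")
  tn <- sum(pred == "nonconverter" & lab == "nonconverter")
  confusion_from_counts(tp, fp, tn, fn, level = level, n_not_evaluable = n_ne)
}

#' Confusion summary from counts
#'
#' Same result as [confusion()] when only the four cells are known (as in
#' published tables).
#'
#' @param tp,fp,tn,fn Cell counts.
#' @param level CI level.
#' @param n_not_evaluable Count of excluded subjects (metadata).
#' @return A `confusion_summary`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, level = 0.95,
                                  n_not_evaluable = 0L) {
  n <- tp + fp + tn + fn
  if (n < 1) stop("zero evaluable subjects")
  metric <- function(x, d) {
    if (d == 0)   # e.g. no true positives among the evaluable subjects
      return(list(estimate = NA_real_, percent = NA_integer_,
                  ci = c(NA_real_, NA_real_),
                  ci_percent = c(NA_integer_, NA_integer_)))
    p <- x / d
    ci <- binomial_ci(x, d, level)
    list(estimate = p, percent = percent_round(p),
         ci = as.numeric(ci), ci_percent = attr(ci, "percent"))
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, n_evaluable = n,
                 n_not_evaluable = n_not_evaluable,
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp),
                 accuracy = metric(tp + tn, n)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  fmt <- function(m) sprintf("%d (%d-%d)", m$percent, m$ci_percent[1],
                             m$ci_percent[2])
  cat("<confusion_summary> n =", x$n_evaluable,
      if (x$n_not_evaluable) paste0("(", x$n_not_evaluable, " not evaluable)"),
      "\n  TP", x$TP, " FP", x$FP, " TN", x$TN, " FN", x$FN, "\n")
  cat("  sensitivity", fmt(x$sensitivity),
      " specificity", fmt(x$specificity),
      " accuracy", x$accuracy$percent, "\n")
  invisible(x)
}

#' McNemar's paired test on per-subject correctness
#'
#' Compares two classifiers on the same subjects via the discordant pairs
#' b (A correct, B wrong) and c (A wrong, B correct). Exact two-sided
#' binomial test when `b + c <= exact_limit` (default 25), otherwise the
#' chi-square approximation with continuity correction. Zero discordant
#' pairs give p = 1 with `no_discordance = TRUE`.
#'
#' @param correct_a,correct_b Logical vectors of per-subject correctness.
#' @param exact_limit Switch point between exact and asymptotic forms.
#' @return List: `p_value`, `b`, `c`, `method`, `no_discordance`.
#' @export
mcnemar_test <- function(correct_a, correct_b, exact_limit = 25) {
  stopifnot(length(correct_a) == length(correct_b),
            is.logical(correct_a), is.logical(correct_b))
  keep <- !is.na(correct_a) & !is.na(correct_b)
  b <- sum(correct_a[keep] & !correct_b[keep])
  cc <- sum(!correct_a[keep] & correct_b[keep])
  nd <- b + cc
  if (nd == 0)
    return(list(p_value = 1, b = b, c = cc, method = "none",
                no_discordance = TRUE))
  if (nd <= exact_limit) {
    k <- min(b, cc)
    p <- min(1, 2 * stats::pbinom(k, nd, 0.5))
    method <- "exact_binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq_cc"
  }
  list(p_value = p, b = b, c = cc, method = method, no_discordance = FALSE)
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement between two categorical raters on
#' the same label set. Undefined (NA, with a warning) when expected
#' agreement is 1, i.e. both raters use a single identical category.
#'
#' @param ratings_a,ratings_b Equal-length vectors (factor, character or
#'   integer).
#' @return Kappa in [-1, 1], or `NA` when degenerate.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b))
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    warning("kappa undefined: degenerate single-category marginals")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Collapse six-level diagnoses to the binary scale
#'
#' Levels 1-3 (indications of non-AD) -> `nonconverter`; levels 4-6 ->
#' `converter`.
#'
#' @param categories Integer vector of categories 1-6.
#' @return Factor `nonconverter`/`converter`.
#' @export
collapse_scale <- function(categories) {
  stopifnot(all(categories %in% 1:6))
  factor(ifelse(categories >= 4, "converter", "nonconverter"),
         levels = c("nonconverter", "converter"))
}

category_row_names <- c("clear_non_ad", "probable_non_ad", "subtle_non_ad",
                        "subtle_ad", "probable_ad", "clear_ad")

#' Six-category accuracy table
#'
#' Cross-tabulates the six-level diagnosis against the three-way final
#' diagnosis (`AD`, `Healthy`, `MCI`), with row shares of the cohort and
#' row accuracies: in levels 1-3 a `Healthy` or `MCI` outcome is correct
#' (reverters still belong to the non-AD group), in levels 4-6 `AD` is.
#' Pooled non-AD (1-3) and AD (4-6) rows and the overall accuracy are
#' appended.
#'
#' @param categories Integer vector 1-6 per subject.
#' @param final_labels Factor/character in `AD` / `Healthy` / `MCI`.
#' @return A `category_accuracy_table` data frame with columns `AD`,
#'   `Healthy`, `MCI`, `total`, `share_percent`, `accuracy_percent`;
#'   overall accuracy in `attr(, "overall_accuracy_percent")`.
#' @export
category_table <- function(categories, final_labels) {
  stopifnot(length(categories) == length(final_labels),
            all(categories %in% 1:6))
  lab <- as.character(final_labels)
  bad <- setdiff(unique(lab), c("AD", "Healthy", "MCI"))
  if (length(bad)) stop("unknown final diagnosis label(s): ",
                        paste(bad, collapse = ", "))
  n <- length(categories)
  cat_f <- factor(categories, levels = 1:6)
  lab_f <- factor(lab, levels = c("AD", "Healthy", "MCI"))
  tab <- table(cat_f, lab_f)
  counts <- as.data.frame.matrix(tab)
  rownames(counts) <- category_row_names
  counts$total <- rowSums(tab)
  correct <- ifelse(1:6 <= 3, counts$Healthy + counts$MCI, counts$AD)
  pooled <- function(rows, name) {
    s <- colSums(counts[rows, c("AD", "Healthy", "MCI")])
    tot <- sum(counts$total[rows])
    data.frame(AD = s[["AD"]], Healthy = s[["Healthy"]], MCI = s[["MCI"]],
               total = tot, row.names = name)
  }
  out <- rbind(counts[1:3, ], pooled(1:3, "pooled_non_ad"),
               counts[4:6, ], pooled(4:6, "pooled_ad"))
  corr_all <- c(correct[1:3], sum(correct[1:3]), correct[4:6], sum(correct[4:6]))
  out$share_percent <- percent_round(out$total / n)
  out$accuracy_percent <- ifelse(out$total > 0,
                                 percent_round(corr_all / pmax(out$total, 1)),
                                 NA_integer_)
  attr(out, "overall_accuracy_percent") <-
    percent_round((sum(correct[1:3]) + sum(correct[4:6])) / n)
  class(out) <- c("category_accuracy_table", "data.frame")
  out
}

#' Rule-level evaluation of a cohort
#'
#' Convenience wrapper: dichotomize, predict under `rule_id`, and compute
#' the [confusion()] summary. By default metrics use the evaluable subset
#' (modality-specific denominators); with
#' `denominators = "all_subjects"`, `not_evaluable` predictions count as
#' `predict_nonconverter` over the whole cohort (sensitivity analysis).
#'
#' @param cohort An `mci_cohort`.
#' @param rule_id One of [rule_ids()].
#' @param cutoffs A [criteria_cutoffs()].
#' @param denominators `"evaluable"` (default) or `"all_subjects"`.
#' @return A `confusion_summary`.
#' @export
evaluate_rule <- function(cohort, rule_id, cutoffs = criteria_cutoffs(),
                          denominators = c("evaluable", "all_subjects")) {
  denominators <- match.arg(denominators)
  pred <- predict_rule(dichotomize(cohort, cutoffs), rule_id)
  if (denominators == "all_subjects")
    pred[pred == "not_evaluable"] <- "predict_nonconverter"
  confusion(pred, outcome_labels(cohort))
}
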
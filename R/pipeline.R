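#' Pipeline run configuration
#'
#' Exactly one cohort source: a [cohort_spec()] plus simulation seed, or a
#' cohort CSV path.
#'
#' @param spec A `cohort_spec` (ignored if `cohort_path` given).
#' @param seed Simulation seed for the spec route.
#' @param cohort_path Optional path to an existing cohort CSV.
#' @param cutoffs A [criteria_cutoffs()].
#' @param dsi_cutoff Binary DSI decision cutoff.
#' @param split_prop,split_seed Stratified train fraction and seed for the
#'   DSI reference split.
#' @param in_sample If `TRUE`, fit and score the DSI on the whole cohort
#'   (exploratory); default fits on the training half and evaluates both
#'   arms on the held-out half.
#' @param denominators `"evaluable"` or `"all_subjects"` for rule metrics.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = default_cohort_spec(), seed = 1L,
                       cohort_path = NULL, cutoffs = criteria_cutoffs(),
                       dsi_cutoff = 0.50, split_prop = 0.5,
                       split_seed = NULL, in_sample = FALSE,
                       denominators = c("evaluable", "all_subjects"),
                       out_dir = "dsindex_run") {
  structure(list(spec = spec, seed = as.integer(seed),
                 cohort_path = cohort_path, cutoffs = cutoffs,
                 dsi_cutoff = dsi_cutoff, split_prop = split_prop,
                 split_seed = if (is.null(split_seed)) as.integer(seed) + 1L
                              else as.integer(split_seed),
                 in_sample = in_sample,
                 denominators = match.arg(denominators),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON/YAML
#'
#' Recognised keys mirror the [run_config()] arguments; `spec` may be a
#' path to a cohort-spec file.
#'
#' @param path Config file (`.json`, `.yaml`, `.yml`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(x$spec)) args$spec <- read_cohort_spec(x$spec)
  for (nm in c("seed", "cohort_path", "dsi_cutoff", "split_prop",
               "split_seed", "in_sample", "denominators", "out_dir"))
    if (!is.null(x[[nm]])) args[[nm]] <- x[[nm]]
  if (!is.null(x$cutoffs)) args$cutoffs <- do.call(criteria_cutoffs, x$cutoffs)
  do.call(run_config, args)
}

#' Run the full criteria-vs-DSI comparison
#'
#' Simulates (or loads) a cohort, runs the dichotomized-criteria arm and
#' the DSI arm on byte-identical subject data, evaluates both, and writes
#' a reproducible report bundle to `config$out_dir`:
#' \itemize{
#'   \item `cohort.csv` — the cohort analysed;
#'   \item `predictions.csv` — per subject: marker statuses, likelihood
#'     category, all eight rule predictions, DSI, six-level category and
#'     binary call;
#'   \item `conversion_rates.csv` — likelihood-group conversion rates;
#'   \item `rule_metrics.csv` — sensitivity/specificity/accuracy with CIs
#'     for each rule and for the DSI arm;
#'   \item `category_accuracy.csv` — six-category accuracy table of the
#'     DSI arm;
#'   \item `mcnemar.csv` — pairwise McNemar p-values between all
#'     classifiers on the common evaluable subjects;
#'   \item `manifest.json` — seeds, config echo, package version.
#' }
#' Rerunning with the same config reproduces every file byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `predictions`, `rule_metrics`, `conversion_rates`, `category_table`,
#'   `mcnemar`, `manifest`).
#' @export
run_comparison <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
            else generate_cohort(config$spec, config$seed)

  # DSI arm: fit references on the training half, evaluate on the held-out
  # half (or in-sample if requested); the criteria arm is evaluated on the
  # same evaluation subjects.
  if (config$in_sample) {
    train <- eval_cohort <- cohort
  } else {
    halves <- split_cohort(cohort, config$split_prop, config$split_seed)
    train <- halves$train; eval_cohort <- halves$test
  }
  model <- fit_dsi_model(train)
  scores <- score_cohort(eval_cohort, model, config$dsi_cutoff)

  status <- dichotomize(eval_cohort, config$cutoffs)
  likelihood <- assign_likelihood(
    status, config$cutoffs$csf_combination_for_likelihood)
  preds <- data.frame(status, likelihood = likelihood,
                      stringsAsFactors = FALSE)
  for (rid in rule_ids()) preds[[rid]] <- predict_rule(status, rid)
  preds <- merge(preds, scores, by = "subject_id", sort = FALSE)
  preds <- preds[order(preds$subject_id), ]

  labels <- outcome_labels(eval_cohort)
  n_ind <- sum(likelihood == "indeterminate")
  if (n_ind) message(n_ind, " subject(s) with indeterminate likelihood")

  conv <- do.call(rbind, lapply(levels(likelihood), function(lv) {
    idx <- likelihood == lv
    data.frame(likelihood = lv, cases = sum(idx),
               converters = sum(labels[idx] == "converter"),
               rate_percent = if (any(idx))
                 conversion_rate(sum(labels[idx] == "converter"), sum(idx))
               else NA_integer_, stringsAsFactors = FALSE)
  }))
  conv <- rbind(data.frame(likelihood = "baseline", cases = length(labels),
                           converters = sum(labels == "converter"),
                           rate_percent = conversion_rate(
                             sum(labels == "converter"), length(labels)),
                           stringsAsFactors = FALSE), conv)

  metric_row <- function(id, cs) data.frame(
    classifier = id, n = cs$n_evaluable, TP = cs$TP, FP = cs$FP,
    TN = cs$TN, FN = cs$FN,
    sensitivity = cs$sensitivity$percent,
    sens_lo = cs$sensitivity$ci_percent[1], sens_hi = cs$sensitivity$ci_percent[2],
    specificity = cs$specificity$percent,
    spec_lo = cs$specificity$ci_percent[1], spec_hi = cs$specificity$ci_percent[2],
    accuracy = cs$accuracy$percent, stringsAsFactors = FALSE)
  na_row <- function(id) data.frame(
    classifier = id, n = 0L, TP = NA, FP = NA, TN = NA, FN = NA,
    sensitivity = NA, sens_lo = NA, sens_hi = NA, specificity = NA,
    spec_lo = NA, spec_hi = NA, accuracy = NA, stringsAsFactors = FALSE)
  rules_cs <- lapply(stats::setNames(rule_ids(), rule_ids()), function(rid)
    tryCatch(evaluate_rule(eval_cohort, rid, config$cutoffs,
                           config$denominators),
             error = function(e) NULL))   # e.g. modality absent for everyone
  dsi_cs <- confusion(scores$call, labels)
  metrics <- do.call(rbind, c(lapply(rule_ids(), function(rid)
    if (is.null(rules_cs[[rid]])) na_row(rid)
    else metric_row(rid, rules_cs[[rid]])), list(metric_row("dsi", dsi_cs))))

  cat_tab <- category_table(scores$category, final_diagnosis_labels(eval_cohort))

  # pairwise McNemar on subjects evaluable under both classifiers
  correct_of <- function(id) {
    pred <- if (id == "dsi") as.character(scores$call)
            else sub("^predict_", "", as.character(preds[[id]]))
    ifelse(pred == "not_evaluable", NA,
           pred == sub("^predict_", "", as.character(labels)))
  }
  ids <- c(rule_ids(), "dsi")
  mc <- expand.grid(classifier_a = ids, classifier_b = ids,
                    stringsAsFactors = FALSE)
  mc <- mc[mc$classifier_a < mc$classifier_b, ]
  mc_res <- lapply(seq_len(nrow(mc)), function(i) {
    ca <- correct_of(mc$classifier_a[i]); cb <- correct_of(mc$classifier_b[i])
    keep <- !is.na(ca) & !is.na(cb)
    m <- mcnemar_test(ca[keep], cb[keep])
    data.frame(mc[i, ], n_common = sum(keep), b = m$b, c = m$c,
               p_value = m$p_value, method = m$method,
               stringsAsFactors = FALSE)
  })
  mc_tab <- do.call(rbind, mc_res)

  manifest <- list(
    package = "dsindex",
    version = as.character(utils::packageVersion("dsindex")),
    cohort_source = if (is.null(config$cohort_path)) "simulated" else "csv",
    seed = config$seed, split_seed = config$split_seed,
    split_prop = config$split_prop, in_sample = config$in_sample,
    dsi_cutoff = config$dsi_cutoff, denominators = config$denominators,
    n_total = nrow(cohort), n_evaluated = nrow(eval_cohort),
    n_indeterminate_likelihood = n_ind,
    cutoffs = unclass(config$cutoffs))

  p <- function(f) file.path(config$out_dir, f)
  write_cohort(cohort, p("cohort.csv"))
  utils::write.csv(preds, p("predictions.csv"), row.names = FALSE, na = "")
  utils::write.csv(conv, p("conversion_rates.csv"), row.names = FALSE)
  utils::write.csv(metrics, p("rule_metrics.csv"), row.names = FALSE)
  utils::write.csv(cbind(row = rownames(cat_tab), as.data.frame(cat_tab)),
                   p("category_accuracy.csv"), row.names = FALSE)
  utils::write.csv(mc_tab, p("mcnemar.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, model = model, predictions = preds,
                 conversion_rates = conv, rule_metrics = metrics,
                 category_table = cat_tab, mcnemar = mc_tab,
                 manifest = manifest))
}
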
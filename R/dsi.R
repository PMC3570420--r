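# Disease State Index engine.
#
# A feature's evidence is read off the two empirical reference
# distributions (healthy-side "negative" and disease-side "positive"):
# fitness(x) = FN(x) / (FN(x) + FP(x)), where FN is the fraction of the
# positive population on the normal side of x and FP the fraction of the
# negative population on the abnormal side, both with midpoint handling of
# ties. Relevance weights are Youden's J at the best threshold. The
# composite is a relevance-weighted mean aggregated up a modality tree,
# skipping branches with no observed data. No RNG anywhere in this module.

# mid-ECDF: fraction strictly below x plus half the fraction equal
mid_cdf <- function(sorted_values, x) {
  n <- length(sorted_values)
  below <- findInterval(x, sorted_values, left.open = TRUE)  # "< x" via open left
  upto  <- findInterval(x, sorted_values)                    # "<= x"
  (below + 0.5 * (upto - below)) / n
}

#' Fit a per-feature reference distribution
#'
#' Stores the empirical negative (control) and positive (disease) reference
#' samples for one feature and caches its relevance weight. Deterministic.
#'
#' @param values_neg,values_pos Numeric reference samples; missing values
#'   are dropped. At least 2 values per population are required.
#' @param direction `"high"` if large values indicate disease, `"low"`
#'   otherwise.
#' @param name Feature name (used in error messages and fingerprints).
#' @return A `feature_reference` with the sorted samples, `direction` and
#'   cached `relevance`.
#' @export
fit_feature_reference <- function(values_neg, values_pos,
                                  direction = c("high", "low"),
                                  name = "feature") {
  direction <- match.arg(direction)
  values_neg <- sort(values_neg[!is.na(values_neg)])
  values_pos <- sort(values_pos[!is.na(values_pos)])
  if (length(values_neg) < 2L || length(values_pos) < 2L)
    stop("feature '", name, "': need at least 2 non-missing reference ",
         "values per population (got ", length(values_neg), " negative, ",
         length(values_pos), " positive)")
  ref <- structure(list(name = name, neg = values_neg, pos = values_pos,
                        direction = direction, relevance = NA_real_),
                   class = "feature_reference")
  ref$relevance <- relevance(ref)
  ref
}

#' Per-feature fitness of a measurement
#'
#' Positions a measured value between the two reference populations:
#' 0 = clearly control-like, 1 = clearly disease-like. For
#' `direction = "high"`, `FN(x)` is the positive-population mid-ECDF at x
#' (disease cases that look normal at threshold x) and `FP(x)` is the
#' negative-population upper tail; `fitness = FN / (FN + FP)`. The
#' `direction = "low"` case mirrors this. When x falls strictly between the
#' two supports both terms vanish and the value is maximally ambiguous;
#' the 0/0 guard returns 0.5.
#'
#' @param x Numeric vector of measurements (no missing values; skip missing
#'   features before calling).
#' @param ref A [fit_feature_reference()] result.
#' @return Fitness values in [0,1].
#' @export
fitness <- function(x, ref) {
  stopifnot(inherits(ref, "feature_reference"), all(is.finite(x)))
  if (ref$direction == "high") {
    fn <- mid_cdf(ref$pos, x)          # positives looking normal (<= x)
    fp <- 1 - mid_cdf(ref$neg, x)      # negatives looking abnormal (> x)
  } else {
    fn <- 1 - mid_cdf(ref$pos, x)
    fp <- mid_cdf(ref$neg, x)
  }
  out <- ifelse(fn + fp == 0, 0.5, fn / (fn + fp))
  pmin(pmax(out, 0), 1)
}

#' Relevance (separability weight) of a feature
#'
#' Maximum of Youden's J = sensitivity + specificity - 1 over candidate
#' thresholds, the midpoints of adjacent pooled order statistics (plus the
#' trivial all-one-side thresholds). 0 for identical populations, 1 for
#' perfectly separable ones. Deterministic; direction-aware.
#'
#' @param ref A `feature_reference`.
#' @return Youden's J in [0,1].
#' @export
relevance <- function(ref) {
  pooled <- sort(unique(c(ref$neg, ref$pos)))
  mids <- if (length(pooled) > 1)
    (pooled[-1] + pooled[-length(pooled)]) / 2 else numeric(0)
  cand <- c(pooled[1] - 1, mids, pooled[length(pooled)] + 1)
  if (ref$direction == "high") {
    sens <- vapply(cand, function(t) mean(ref$pos > t), 0)
    spec <- vapply(cand, function(t) mean(ref$neg <= t), 0)
  } else {
    sens <- vapply(cand, function(t) mean(ref$pos < t), 0)
    spec <- vapply(cand, function(t) mean(ref$neg >= t), 0)
  }
  max(0, max(sens + spec - 1))
}

#' Default modality grouping tree
#'
#' Root with four branches — demographics/genetics, neuropsychology, MRI,
#' CSF — and the given features as leaves, mirroring the tool's modality
#' panels. Features not matched to a branch are attached to a residual
#' `other` branch.
#'
#' @param features Character vector of leaf feature names.
#' @return A named list of branch -> leaf names (the `dsi_model` tree).
#' @export
dsi_default_tree <- function(features) {
  branches <- list(
    demographics_genetics = c("age", "education_years", "male", "apoe4"),
    neuropsychology = c("mmse", "ravlt_recall", "ravlt_recognition",
                        "adas_cog11", "adas_cog13", "clock_drawing",
                        "digit_span_forward", "digit_span_backward",
                        "category_fluency", "tmt_a", "tmt_b", "digit_symbol"),
    mri = c("scheltens"),
    csf = c("csf_tau", "csf_abeta42"))
  tree <- lapply(branches, intersect, x = features)
  leftover <- setdiff(features, unlist(tree))
  if (length(leftover)) tree$other <- leftover
  tree[vapply(tree, length, 0L) > 0L]
}

#' Fit a Disease State Index model on a labelled cohort
#'
#' Builds one [fit_feature_reference()] per feature, using converters as
#' the positive reference population and non-converters (including
#' reverters) as the negative one, plus the modality grouping tree used
#' for composite aggregation. Abnormality directions default to the
#' cohort-spec conventions and may be overridden.
#'
#' @param cohort A labelled `mci_cohort` (training data).
#' @param features Leaf features to include; default every feature column
#'   with at least 2 observed values per group.
#' @param tree Branch list as from [dsi_default_tree()].
#' @param directions Named character vector feature -> `"high"`/`"low"`;
#'   defaults taken from [default_cohort_spec()], `"high"` otherwise.
#' @return A `dsi_model` (list of references + tree).
#' @export
fit_dsi_model <- function(cohort, features = NULL, tree = NULL,
                          directions = NULL) {
  lab <- outcome_labels(cohort)
  if (is.null(features)) features <- cohort_features(cohort)
  if (is.null(directions)) {
    spec <- default_cohort_spec()
    directions <- vapply(spec$features, `[[`, "", "abnormal_direction")
    # binary risk features: carrying the allele / being male is coded 1
    directions[c("male", "apoe4")] <- "high"
  }
  usable <- character(0)
  refs <- list()
  for (nm in features) {
    vn <- cohort[[nm]][lab == "nonconverter"]
    vp <- cohort[[nm]][lab == "converter"]
    if (sum(!is.na(vn)) < 2L || sum(!is.na(vp)) < 2L) next
    dir <- if (nm %in% names(directions)) directions[[nm]] else "high"
    refs[[nm]] <- fit_feature_reference(vn, vp, dir, name = nm)
    usable <- c(usable, nm)
  }
  if (!length(refs)) stop("no feature has enough reference data to fit")
  if (is.null(tree)) tree <- dsi_default_tree(usable)
  structure(list(references = refs, tree = tree), class = "dsi_model")
}

#' @export
print.dsi_model <- function(x, ...) {
  cat("<dsi_model> ", length(x$references), " features in ",
      length(x$tree), " branches\n", sep = "")
  for (b in names(x$tree))
    cat("  ", b, ": ", paste(x$tree[[b]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Composite Disease State Index for one subject
#'
#' Leaf DSI values are per-feature fitnesses; missing features are
#' skipped. Each branch DSI is the relevance-weighted mean of its observed
#' leaves; branch relevance is the mean relevance of those leaves. The
#' root composite is the relevance-weighted mean over branches with at
#' least one observed leaf. A subject with no observed model feature is a
#' scoring error.
#'
#' @param subject A single-row data frame (or list) of feature values.
#' @param model A [fit_dsi_model()] result.
#' @param cutoff Binary decision cutoff on the composite (default 0.50).
#' @return A `dsi_result`: `dsi` (composite), `category` (1-6), `call`
#'   (`converter`/`nonconverter`), `n_used`, `n_missing`, and `nodes`, a
#'   data frame of per-node DSI/relevance/observed counts (the disease
#'   state fingerprint).
#' @export
composite_dsi <- function(subject, model, cutoff = 0.50) {
  refs <- model$references
  leaf_fit <- leaf_rel <- numeric(0)
  for (nm in names(refs)) {
    x <- subject[[nm]]
    if (is.null(x) || length(x) == 0L || is.na(x)) next
    leaf_fit[nm] <- fitness(as.numeric(x), refs[[nm]])
    leaf_rel[nm] <- refs[[nm]]$relevance
  }
  n_model <- length(refs)
  if (length(leaf_fit) == 0L)
    stop("cannot score subject: all ", n_model, " model features missing")

  nodes <- data.frame(node = character(), parent = character(),
                      dsi = numeric(), relevance = numeric(),
                      n_observed = integer(), n_features = integer(),
                      stringsAsFactors = FALSE)
  add_node <- function(node, parent, dsi, rel, n_obs, n_feat)
    rbind(nodes, data.frame(node = node, parent = parent, dsi = dsi,
                            relevance = rel, n_observed = n_obs,
                            n_features = n_feat, stringsAsFactors = FALSE))
  branch_dsi <- branch_rel <- numeric(0)
  for (b in names(model$tree)) {
    leaves <- intersect(model$tree[[b]], names(refs))
    obs <- intersect(leaves, names(leaf_fit))
    if (length(obs)) {
      w <- leaf_rel[obs]
      d <- if (sum(w) > 0) sum(w * leaf_fit[obs]) / sum(w) else mean(leaf_fit[obs])
      r <- mean(leaf_rel[obs])
      branch_dsi[b] <- d; branch_rel[b] <- r
      nodes <- add_node(b, "root", d, r, length(obs), length(leaves))
    } else {
      nodes <- add_node(b, "root", NA_real_, NA_real_, 0L, length(leaves))
    }
    for (nm in leaves)
      nodes <- add_node(nm, b,
                        if (nm %in% obs) leaf_fit[[nm]] else NA_real_,
                        refs[[nm]]$relevance,
                        as.integer(nm %in% obs), 1L)
  }
  w <- branch_rel
  root <- if (sum(w) > 0) sum(w * branch_dsi) / sum(w) else mean(branch_dsi)
  root <- min(max(root, 0), 1)
  nodes <- rbind(data.frame(node = "root", parent = NA_character_, dsi = root,
                            relevance = mean(branch_rel),
                            n_observed = length(leaf_fit),
                            n_features = n_model, stringsAsFactors = FALSE),
                 nodes)
  structure(list(dsi = root, category = dsi_category(root),
                 call = dsi_classify(root, cutoff),
                 n_used = length(leaf_fit),
                 n_missing = n_model - length(leaf_fit),
                 nodes = nodes),
            class = "dsi_result")
}

#' @export
print.dsi_result <- function(x, ...) {
  cat(sprintf("<dsi_result> DSI %.3f  category %d  call %s  (%d features, %d missing)\n",
              x$dsi, x$category, x$call, x$n_used, x$n_missing))
  invisible(x)
}

#' Score every subject of a cohort
#'
#' @param cohort An `mci_cohort`.
#' @param model A `dsi_model`.
#' @param cutoff Binary decision cutoff.
#' @return Data frame: `subject_id`, `dsi`, `category`, `call`, `n_used`,
#'   `n_missing`.
#' @export
score_cohort <- function(cohort, model, cutoff = 0.50) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- composite_dsi(cohort[i, , drop = FALSE], model, cutoff)
    data.frame(subject_id = cohort$subject_id[i], dsi = r$dsi,
               category = r$category, call = r$call, n_used = r$n_used,
               n_missing = r$n_missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$call <- factor(out$call, levels = c("nonconverter", "converter"))
  out
}

#' Six-level DSI category
#'
#' Uniform binning of the [0,1] index: (1) clear non-AD `< 0.17`,
#' (2) probable non-AD `[0.17, 0.33)`, (3) subtle non-AD `[0.33, 0.50)`,
#' (4) subtle AD `[0.50, 0.67)`, (5) probable AD `[0.67, 0.83)`,
#' (6) clear AD `>= 0.83`.
#'
#' @param value Numeric vector in [0,1].
#' @return Integer categories 1-6.
#' @export
dsi_category <- function(value) {
  if (any(value < 0 | value > 1)) stop("DSI value outside [0, 1]")
  findInterval(value, c(0.17, 0.33, 0.50, 0.67, 0.83)) + 1L
}

#' Binary DSI call
#' @param value DSI in [0,1].
#' @param cutoff Decision cutoff; `converter` iff `value >= cutoff`.
#' @return Character vector `"converter"`/`"nonconverter"`.
#' @export
dsi_classify <- function(value, cutoff = 0.50) {
  if (any(value < 0 | value > 1)) stop("DSI value outside [0, 1]")
  ifelse(value >= cutoff, "converter", "nonconverter")
}

#' Export / read a disease state fingerprint
#'
#' Writes the per-node breakdown of a [composite_dsi()] result (node tree
#' with DSI, relevance, observed-feature counts, composite, category and
#' call) as JSON. Branches with no observed data carry `"no_data": true`.
#' The round trip through [read_fingerprint()] is lossless.
#'
#' @param result A `dsi_result`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_fingerprint` returns the parsed list.
#' @export
export_fingerprint <- function(result, path) {
  nodes <- result$nodes
  nodes$no_data <- nodes$n_observed == 0L
  out <- list(dsi = result$dsi, category = result$category,
              call = result$call, n_used = result$n_used,
              n_missing = result$n_missing, nodes = nodes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname export_fingerprint
#' @export
read_fingerprint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
  x
}

#' Stratified train/test split of a cohort
#'
#' Splits within each outcome group so both halves keep the group mix; the
#' honest desk-scale analogue of scoring patients against previously known
#' reference populations.
#'
#' @param cohort An `mci_cohort`.
#' @param prop Training fraction (default 0.5).
#' @param seed Integer seed.
#' @return List with `train` and `test` cohorts.
#' @export
split_cohort <- function(cohort, prop = 0.5, seed = 1L) {
  stopifnot(prop > 0, prop < 1)
  local_seed(seed)
  in_train <- logical(nrow(cohort))
  for (g in levels(cohort$group)) {
    idx <- which(cohort$group == g)
    n_tr <- round(length(idx) * prop)
    in_train[sample(idx, n_tr)] <- TRUE
  }
  list(train = cohort[in_train, , drop = FALSE],
       test = cohort[!in_train, , drop = FALSE])
}
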
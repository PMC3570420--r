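#' Describe one cohort feature
#'
#' A feature entry of a [cohort_spec()]: the group-conditional generative
#' parameters for a single baseline measurement. Continuous and integer
#' features are Gaussian within each outcome group (integer features are
#' rounded half-up after drawing); binary features are Bernoulli.
#'
#' @param name Canonical column name (e.g. `"ravlt_recall"`).
#' @param kind One of `"continuous"`, `"integer"`, `"binary"`.
#' @param mean_neg,sd_neg,mean_pos,sd_pos Group-conditional mean and SD for
#'   the non-converter (`neg`) and converter (`pos`) groups; required for
#'   continuous/integer kinds.
#' @param p_neg,p_pos Success probabilities for binary kind.
#' @param clip_min,clip_max Instrument range; values are clipped here after
#'   rounding. Defaults are unbounded.
#' @param abnormal_direction `"high"` if larger values indicate disease
#'   (e.g. CSF Tau), `"low"` otherwise (e.g. RAVLT recall).
#' @return A `cohort_feature` list.
#' @export
cohort_feature <- function(name, kind = c("continuous", "integer", "binary"),
                           mean_neg = NULL, sd_neg = NULL,
                           mean_pos = NULL, sd_pos = NULL,
                           p_neg = NULL, p_pos = NULL,
                           clip_min = -Inf, clip_max = Inf,
                           abnormal_direction = c("high", "low")) {
  kind <- match.arg(kind)
  abnormal_direction <- match.arg(abnormal_direction)
  if (kind == "binary") {
    if (is.null(p_neg) || is.null(p_pos))
      stop("binary feature '", name, "' needs p_neg and p_pos")
    stopifnot(p_neg >= 0, p_neg <= 1, p_pos >= 0, p_pos <= 1)
  } else {
    if (is.null(mean_neg) || is.null(sd_neg) || is.null(mean_pos) || is.null(sd_pos))
      stop("feature '", name, "' needs mean/sd for both groups")
    if (sd_neg < 0 || sd_pos < 0)
      stop("feature '", name, "': negative sd")
  }
  if (clip_min > clip_max)
    stop("feature '", name, "': clip_min > clip_max")
  structure(list(name = name, kind = kind,
                 mean_neg = mean_neg, sd_neg = sd_neg,
                 mean_pos = mean_pos, sd_pos = sd_pos,
                 p_neg = p_neg, p_pos = p_pos,
                 clip_min = clip_min, clip_max = clip_max,
                 abnormal_direction = abnormal_direction),
            class = "cohort_feature")
}

#' Construct a cohort specification
#'
#' The machine-readable description of a synthetic MCI cohort:
#' stratum sizes, per-feature group-conditional distributions, and exact
#' modality-missingness counts. [generate_cohort()] realises it.
#'
#' @param n_total Total number of subjects.
#' @param n_converters Number of 3-year AD converters.
#' @param n_reverters Number of subjects who reverted to normal cognition;
#'   drawn from the non-converter stratum (their features follow the
#'   non-converter distributions).
#' @param features List of [cohort_feature()] entries.
#' @param missingness List with per-group counts, each a length-2 vector
#'   `c(nonconverter, converter)`: `mri_present`, `csf_present`,
#'   `both_present`, and optionally `apoe_observed`. Counts are hit exactly
#'   in every generated cohort, not in expectation.
#' @param correlation Optional within-group equicorrelation coefficient for
#'   a Gaussian-copula draw across features (default 0 = independent given
#'   group).
#' @return A `cohort_spec` object.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_total, n_converters, n_reverters, features,
                        missingness, correlation = 0) {
  spec <- structure(list(n_total = as.integer(n_total),
                         n_converters = as.integer(n_converters),
                         n_reverters = as.integer(n_reverters),
                         features = stats::setNames(
                           features, vapply(features, `[[`, "", "name")),
                         missingness = missingness,
                         correlation = correlation),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants: stratum arithmetic, non-negative SDs,
#' clip ordering, and feasibility of the joint modality-missingness counts.
#'
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_converters > n_total)
      stop("n_converters exceeds n_total")
    if (n_reverters > n_total - n_converters)
      stop("n_reverters exceeds the non-converter stratum")
    if (correlation < 0 || correlation >= 1)
      stop("correlation must be in [0, 1) (shared-factor equicorrelation)")
  })
  for (f in spec$features) {
    if (f$kind != "binary" && (f$sd_neg < 0 || f$sd_pos < 0))
      stop("feature '", f$name, "': negative sd")
    if (f$clip_min > f$clip_max)
      stop("feature '", f$name, "': clip_min > clip_max")
  }
  m <- spec$missingness
  n_group <- c(spec$n_total - spec$n_converters, spec$n_converters)
  for (nm in c("mri_present", "csf_present", "both_present"))
    if (length(m[[nm]]) != 2L)
      stop("missingness$", nm, " must have one count per group")
  for (g in 1:2) {
    mri <- m$mri_present[g]; csf <- m$csf_present[g]; both <- m$both_present[g]
    if (both > min(mri, csf))
      stop("both_present exceeds min(mri_present, csf_present) in group ", g)
    if (mri > n_group[g] || csf > n_group[g])
      stop("modality count exceeds group size in group ", g)
    if (n_group[g] - mri - csf + both < 0)
      stop("infeasible missingness cell counts in group ", g)
    if (!is.null(m$apoe_observed) && m$apoe_observed[g] > n_group[g])
      stop("apoe_observed exceeds group size in group ", g)
  }
  invisible(spec)
}

#' Default ADNI-like cohort specification
#'
#' Encodes the published demographic/clinical summary of a 391-subject MCI
#' cohort followed for three years: 158 AD converters and 233
#' non-converters (15 of whom reverted to normal cognition), per-group
#' means and SDs for the neuropsychological battery, Scheltens medial
#' temporal atrophy rating and CSF analytes, APOE e4 carrier frequencies,
#' and the exact modality availability counts (387 with MRI, 199 with CSF,
#' 195 with both).
#'
#' Instrument clips follow the scales: MMSE 24-30 (the cohort's inclusion
#' range), RAVLT recall/recognition 0-15, Scheltens 0-4, clock drawing 0-5,
#' timed tests and CSF concentrations strictly positive.
#'
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function() {
  f <- list(
    cohort_feature("age", "continuous", 75, 8, 74, 7,
                   clip_min = 55, clip_max = 95, abnormal_direction = "low"),
    cohort_feature("education_years", "integer", 16, 3, 16, 3,
                   clip_min = 0, clip_max = 25, abnormal_direction = "low"),
    cohort_feature("male", "binary", p_neg = 158 / 233, p_pos = 95 / 158),
    cohort_feature("apoe4", "binary", p_neg = 66 / 198, p_pos = 145 / 193),
    cohort_feature("mmse", "integer", 27.3, 1.8, 26.7, 1.7,
                   clip_min = 24, clip_max = 30, abnormal_direction = "low"),
    cohort_feature("ravlt_recall", "integer", 3.7, 3.6, 1.5, 2.1,
                   clip_min = 0, clip_max = 15, abnormal_direction = "low"),
    cohort_feature("ravlt_recognition", "integer", 10.3, 3.5, 8.7, 3.6,
                   clip_min = 0, clip_max = 15, abnormal_direction = "low"),
    cohort_feature("adas_cog11", "continuous", 10.3, 4.2, 13.3, 4.1,
                   clip_min = 0, clip_max = 70, abnormal_direction = "high"),
    cohort_feature("adas_cog13", "continuous", 16.7, 6.1, 21.6, 5.4,
                   clip_min = 0, clip_max = 85, abnormal_direction = "high"),
    cohort_feature("clock_drawing", "integer", 4.4, 0.8, 3.9, 1.1,
                   clip_min = 0, clip_max = 5, abnormal_direction = "low"),
    cohort_feature("digit_span_forward", "integer", 8.2, 2.0, 8.2, 2.0,
                   clip_min = 0, clip_max = 14, abnormal_direction = "low"),
    cohort_feature("digit_span_backward", "integer", 6.2, 2.2, 6.0, 1.8,
                   clip_min = 0, clip_max = 14, abnormal_direction = "low"),
    cohort_feature("category_fluency", "integer", 16.3, 4.9, 15.3, 4.8,
                   clip_min = 0, clip_max = 60, abnormal_direction = "low"),
    cohort_feature("tmt_a", "continuous", 41.8, 20.1, 49.7, 25.9,
                   clip_min = 1, clip_max = 300, abnormal_direction = "high"),
    cohort_feature("tmt_b", "continuous", 115.7, 67.5, 151.1, 67.5,
                   clip_min = 1, clip_max = 500, abnormal_direction = "high"),
    cohort_feature("digit_symbol", "integer", 38.5, 11.2, 33.8, 11.0,
                   clip_min = 0, clip_max = 93, abnormal_direction = "low"),
    cohort_feature("scheltens", "integer", 1.8, 0.9, 2.2, 0.9,
                   clip_min = 0, clip_max = 4, abnormal_direction = "high"),
    cohort_feature("csf_tau", "continuous", 93, 61, 118, 57,
                   clip_min = 1, clip_max = Inf, abnormal_direction = "high"),
    cohort_feature("csf_abeta42", "continuous", 178, 58, 144, 39,
                   clip_min = 1, clip_max = Inf, abnormal_direction = "low")
  )
  # Per-group both-present counts are pinned down by the published totals:
  # all 4 MRI-missing subjects had CSF, so both = csf_present - mri_missing.
  cohort_spec(
    n_total = 391, n_converters = 158, n_reverters = 15,
    features = f,
    missingness = list(
      mri_present  = c(230L, 157L),
      csf_present  = c(115L, 84L),
      both_present = c(112L, 83L),
      # converter denominator 193 exceeds the group size, so only the
      # non-converter remainder (233 - 198 = 35) is treated as missing
      apoe_observed = c(198L, 158L)
    ),
    correlation = 0
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_total, " subjects (",
      x$n_converters, " converters, ", x$n_reverters, " reverters), ",
      length(x$features), " features\n", sep = "")
  cat("  MRI present:  ", sum(x$missingness$mri_present),
      "; CSF present: ", sum(x$missingness$csf_present),
      "; both: ", sum(x$missingness$both_present), "\n", sep = "")
  invisible(x)
}

spec_to_list <- function(spec) {
  list(n_total = spec$n_total, n_converters = spec$n_converters,
       n_reverters = spec$n_reverters,
       features = lapply(unname(spec$features), function(f)
         f[!vapply(f, is.null, TRUE)]),
       missingness = spec$missingness, correlation = spec$correlation)
}

list_to_spec <- function(x) {
  feats <- lapply(x$features, function(f) {
    do.call(cohort_feature, c(
      f[intersect(names(f), c("name", "kind", "mean_neg", "sd_neg", "mean_pos",
                              "sd_pos", "p_neg", "p_pos", "abnormal_direction"))],
      list(clip_min = if (is.null(f$clip_min)) -Inf else f$clip_min,
           clip_max = if (is.null(f$clip_max)) Inf else f$clip_max)))
  })
  cohort_spec(x$n_total, x$n_converters, x$n_reverters, feats,
              lapply(x$missingness, as.integer),
              if (is.null(x$correlation)) 0 else x$correlation)
}

#' Read / write a cohort specification
#'
#' Serialises a [cohort_spec()] to JSON or YAML, chosen by file extension
#' (`.json`, `.yaml`/`.yml`). Infinite clips are stored as the strings
#' `"-Inf"`/`"Inf"` in JSON.
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `read_cohort_spec` returns a `cohort_spec`; `write_cohort_spec`
#'   returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- spec_to_list(spec)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    x$features <- lapply(x$features, function(f) {
      f$clip_min <- if (is.infinite(f$clip_min)) as.character(f$clip_min) else f$clip_min
      f$clip_max <- if (is.infinite(f$clip_max)) as.character(f$clip_max) else f$clip_max
      f
    })
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$features <- lapply(x$features, function(f) {
    for (nm in c("clip_min", "clip_max"))
      if (!is.null(f[[nm]]) && is.character(f[[nm]])) f[[nm]] <- as.numeric(f[[nm]])
    f
  })
  list_to_spec(x)
}
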
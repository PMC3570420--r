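cohort_id_cols <- c("subject_id", "group", "mri_present", "csf_present")
cohort_groups <- c("stable_mci", "reverter", "converter")

#' Write / read a cohort CSV
#'
#' One row per subject; columns `subject_id`, `group`, `mri_present`,
#' `csf_present`, then the feature columns. Missing values are empty cells,
#' so `write_cohort()` followed by `read_cohort()` is the identity.
#'
#' `read_cohort()` validates on load: known group labels, unique subject
#' ids, numeric feature cells, Scheltens ratings (when present) integer in
#' 0-4, non-negative RAVLT scores, strictly positive CSF concentrations,
#' and consistency between the modality flags and the corresponding
#' feature columns. An empty file yields an empty cohort with a warning.
#'
#' @param cohort An `mci_cohort` data frame.
#' @param path CSV file path.
#' @return `read_cohort` returns an `mci_cohort`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty cohort file: ", path)
    out <- data.frame(subject_id = character(), group = factor(character(),
                      levels = cohort_groups),
                      mri_present = logical(), csf_present = logical())
    class(out) <- c("mci_cohort", "data.frame")
    return(out)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(c("subject_id", "group"), names(df))
  if (length(missing_cols))
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  feature_cols <- setdiff(names(df), cohort_id_cols)

  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in ", path)
  bad_group <- setdiff(unique(df$group), cohort_groups)
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  for (nm in feature_cols) {
    if (!is.numeric(df[[nm]]) && !is.logical(df[[nm]]))
      stop("non-numeric values in feature column '", nm, "'")
  }
  check_range <- function(nm, ok, what) {
    v <- df[[nm]]
    if (!is.null(v) && any(!is.na(v) & !ok(v)))
      stop("column '", nm, "': ", what)
  }
  check_range("scheltens", function(v) v >= 0 & v <= 4 & v == floor(v),
              "Scheltens rating must be an integer in 0-4")
  check_range("ravlt_recall", function(v) v >= 0 & v == floor(v),
              "RAVLT scores must be non-negative integers")
  check_range("ravlt_recognition", function(v) v >= 0 & v == floor(v),
              "RAVLT scores must be non-negative integers")
  check_range("csf_tau", function(v) v > 0, "CSF values must be positive")
  check_range("csf_abeta42", function(v) v > 0, "CSF values must be positive")

  # Derive or cross-check modality flags against the feature columns
  if (is.null(df$mri_present) && !is.null(df$scheltens))
    df$mri_present <- !is.na(df$scheltens)
  if (is.null(df$csf_present) && !is.null(df$csf_tau))
    df$csf_present <- !is.na(df$csf_tau) | !is.na(df$csf_abeta42)
  if (!is.null(df$mri_present) && !is.null(df$scheltens) &&
      any(!df$mri_present & !is.na(df$scheltens)))
    stop("Scheltens value present for a subject flagged MRI-absent")
  if (!is.null(df$csf_present))
    for (nm in intersect(c("csf_tau", "csf_abeta42"), names(df)))
      if (any(!df$csf_present & !is.na(df[[nm]])))
        stop(nm, " present for a subject flagged CSF-absent")

  df$group <- factor(df$group, levels = cohort_groups)
  df <- df[c(intersect(cohort_id_cols, names(df)),
             setdiff(names(df), cohort_id_cols))]
  class(df) <- c("mci_cohort", "data.frame")
  df
}

#' Feature column names of a cohort
#' @param cohort An `mci_cohort`.
#' @return Character vector of feature column names.
#' @export
cohort_features <- function(cohort) setdiff(names(cohort), cohort_id_cols)
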
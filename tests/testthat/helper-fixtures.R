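# Small programmatic fixtures used across test files.

# fully-observed toy spec: every subject has MRI, CSF and every feature
toy_spec <- function(features, n_neg, n_pos, n_rev = 0, correlation = 0) {
  cohort_spec(n_neg + n_pos, n_pos, n_rev, features,
              missingness = list(mri_present = c(n_neg, n_pos),
                                 csf_present = c(n_neg, n_pos),
                                 both_present = c(n_neg, n_pos)),
              correlation = correlation)
}

gauss_feature <- function(name, mu_n, sd_n, mu_p, sd_p, dir = "high")
  cohort_feature(name, "continuous", mu_n, sd_n, mu_p, sd_p,
                 abnormal_direction = dir)

# hand-built reference whose fitness/relevance are whatever the samples give
make_ref <- function(neg, pos, direction = "high", name = "f",
                     relevance_override = NULL) {
  ref <- fit_feature_reference(neg, pos, direction, name)
  if (!is.null(relevance_override)) ref$relevance <- relevance_override
  ref
}

# marker_status data frame built directly from tri-state atoms
make_status <- function(ravlt_positive, mta, csf) {
  data.frame(subject_id = sprintf("S%03d", seq_along(mta)),
             ravlt_positive = ravlt_positive, mta = mta,
             tau = csf, abeta = csf, csf_or = csf, csf_and = csf,
             stringsAsFactors = FALSE)
}
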
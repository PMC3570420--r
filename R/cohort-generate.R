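# Seed hygiene: every stochastic entry point takes an explicit seed, uses a
# private RNG state, and restores the caller's .Random.seed on exit.
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  expr <- if (is.null(old))
    quote(rm(".Random.seed", envir = globalenv()))
  else bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(seed)
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate a synthetic MCI cohort
#'
#' Realises a [cohort_spec()] into one subject-per-row cohort data frame.
#' Group labels, reverter selection, feature draws and modality missingness
#' all come from a single RNG stream seeded by `seed`, so the same
#' `spec` + `seed` reproduce the cohort bit for bit.
#'
#' Continuous features are Gaussian within group and clipped to the
#' instrument range; integer features are additionally rounded half-up
#' before clipping; binary features are Bernoulli. Missingness counts
#' (MRI, CSF, both) are hit exactly in every cohort by partitioning each
#' group into the four availability cells and assigning subjects to cells
#' by random permutation. Reverters are sampled uniformly from the
#' non-converters and keep non-converter feature distributions.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A data frame of class `mci_cohort`: columns `subject_id`,
#'   `group` (`converter` / `stable_mci` / `reverter`), `mri_present`,
#'   `csf_present`, then one column per feature (`NA` = missing). The seed
#'   is recorded in `attr(, "seed")`.
#' @export
generate_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  local_seed(seed)

  n_neg <- spec$n_total - spec$n_converters
  n_grp <- c(n_neg, spec$n_converters)
  group <- c(rep("stable_mci", n_neg), rep("converter", spec$n_converters))
  if (spec$n_reverters > 0)
    group[sample.int(n_neg, spec$n_reverters)] <- "reverter"

  feats <- spec$features
  p <- length(feats)
  draw_group <- function(g) {   # g = 1 non-converter, 2 converter
    n <- n_grp[g]
    z <- matrix(stats::rnorm(n * p), n, p)
    if (spec$correlation != 0) {
      # single-parameter Gaussian copula: equicorrelated latent normals
      shared <- stats::rnorm(n)
      z <- sqrt(spec$correlation) * shared + sqrt(1 - spec$correlation) * z
    }
    out <- matrix(NA_real_, n, p, dimnames = list(NULL, names(feats)))
    for (j in seq_len(p)) {
      f <- feats[[j]]
      if (f$kind == "binary") {
        pr <- if (g == 1) f$p_neg else f$p_pos
        out[, j] <- as.numeric(stats::pnorm(z[, j]) < pr)
      } else {
        mu <- if (g == 1) f$mean_neg else f$mean_pos
        sd <- if (g == 1) f$sd_neg else f$sd_pos
        x <- mu + sd * z[, j]
        if (f$kind == "integer") x <- round_half_up(x)
        out[, j] <- pmin(pmax(x, f$clip_min), f$clip_max)
      }
    }
    out
  }
  values <- rbind(draw_group(1), draw_group(2))

  m <- spec$missingness
  mri <- logical(spec$n_total); csf <- logical(spec$n_total)
  offset <- c(0L, n_neg)
  for (g in 1:2) {
    n <- n_grp[g]
    both  <- m$both_present[g]
    mri_only <- m$mri_present[g] - both
    csf_only <- m$csf_present[g] - both
    cell <- rep.int(c("both", "mri", "csf", "none"),
                    c(both, mri_only, csf_only, n - both - mri_only - csf_only))
    cell <- cell[sample.int(n)]
    idx <- offset[g] + seq_len(n)
    mri[idx] <- cell %in% c("both", "mri")
    csf[idx] <- cell %in% c("both", "csf")
    if (!is.null(m$apoe_observed) && "apoe4" %in% colnames(values)) {
      miss <- n - m$apoe_observed[g]
      if (miss > 0)
        values[offset[g] + sample.int(n, miss), "apoe4"] <- NA_real_
    }
  }
  if ("scheltens" %in% colnames(values)) values[!mri, "scheltens"] <- NA_real_
  for (nm in intersect(c("csf_tau", "csf_abeta42"), colnames(values)))
    values[!csf, nm] <- NA_real_

  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(spec$n_total)),
    group = factor(group, levels = c("stable_mci", "reverter", "converter")),
    mri_present = mri, csf_present = csf,
    values, stringsAsFactors = FALSE)
  attr(cohort, "seed") <- seed
  class(cohort) <- c("mci_cohort", "data.frame")
  cohort
}

#' Binary outcome labels of a cohort
#'
#' Reverters are counted as non-converters (they remain in the non-AD group
#' at follow-up).
#'
#' @param cohort An `mci_cohort` data frame.
#' @return Factor with levels `nonconverter`, `converter`.
#' @export
outcome_labels <- function(cohort) {
  factor(ifelse(cohort$group == "converter", "converter", "nonconverter"),
         levels = c("nonconverter", "converter"))
}

#' Three-way final diagnosis labels
#'
#' `AD` for converters, `Healthy` for reverters, `MCI` for stable cases —
#' the label set used by the six-category accuracy table.
#'
#' @inheritParams outcome_labels
#' @return Factor with levels `AD`, `Healthy`, `MCI`.
#' @export
final_diagnosis_labels <- function(cohort) {
  factor(c(stable_mci = "MCI", reverter = "Healthy", converter = "AD")
         [as.character(cohort$group)],
         levels = c("AD", "Healthy", "MCI"))
}

#' Simulate a clinician re-rating of DSI-based six-level diagnoses
#'
#' Stand-in for an independent human rater: perturbs each DSI value with
#' Gaussian noise of SD `disagreement_sd`, clips to [0,1] and re-bins on
#' the six-level scale. With `disagreement_sd = 0` this reproduces the
#' deterministic binning, giving kappa = 1 against [dsi_category()].
#'
#' @param dsi_values Numeric vector of DSI values in [0,1].
#' @param disagreement_sd Non-negative noise SD on the DSI scale.
#' @param seed Integer seed.
#' @return Integer vector of categories 1-6.
#' @export
simulate_rater <- function(dsi_values, disagreement_sd, seed) {
  if (disagreement_sd < 0) stop("disagreement_sd must be non-negative")
  stopifnot(all(dsi_values >= 0 & dsi_values <= 1))
  local_seed(seed)
  noisy <- dsi_values + stats::rnorm(length(dsi_values), 0, disagreement_sd)
  dsi_category(pmin(pmax(noisy, 0), 1))
}
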
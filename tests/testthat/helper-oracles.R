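# Independent oracles: deliberately naive re-derivations of the package's
# quantities, kept free of any package internals.

# fitness by literal counting with midpoint ties
oracle_fitness <- function(x, neg, pos, direction) {
  cdf_mid <- function(v, q) (sum(v < q) + 0.5 * sum(v == q)) / length(v)
  if (direction == "high") {
    fn <- cdf_mid(pos, x)
    fp <- 1 - cdf_mid(neg, x)
  } else {
    fn <- 1 - cdf_mid(pos, x)
    fp <- cdf_mid(neg, x)
  }
  if (fn + fp == 0) 0.5 else fn / (fn + fp)
}

# Youden's J by exhaustive scan over a fine threshold set around every value
oracle_relevance <- function(neg, pos, direction) {
  vals <- sort(unique(c(neg, pos)))
  eps <- min(diff(vals), 1) / 4
  cand <- sort(c(vals - eps, vals, vals + eps))
  j <- vapply(cand, function(t) {
    if (direction == "high") mean(pos > t) + mean(neg <= t) - 1
    else mean(pos < t) + mean(neg >= t) - 1
  }, 0)
  max(0, max(j))
}

# brute-force recursive composite over an explicit two-level tree
oracle_composite <- function(leaf_fitness, leaf_relevance, tree) {
  branch_dsi <- branch_rel <- numeric(0)
  for (b in names(tree)) {
    obs <- intersect(tree[[b]], names(leaf_fitness))
    if (!length(obs)) next
    w <- leaf_relevance[obs]
    branch_dsi[b] <- if (sum(w) > 0) sum(w * leaf_fitness[obs]) / sum(w)
                     else mean(leaf_fitness[obs])
    branch_rel[b] <- mean(leaf_relevance[obs])
  }
  if (sum(branch_rel) > 0) sum(branch_rel * branch_dsi) / sum(branch_rel)
  else mean(branch_dsi)
}

# literal transcription of the published likelihood definitions
oracle_likelihood <- function(ravlt_pos, mta, csf) {
  if (is.na(ravlt_pos)) return("indeterminate")
  if (ravlt_pos && mta == "positive" && csf == "positive") return("high")
  if (ravlt_pos && ((mta == "positive" && csf == "unavailable") ||
                    (csf == "positive" && mta == "unavailable")))
    return("intermediate")
  if (ravlt_pos && ((mta == "positive" && csf == "negative") ||
                    (csf == "positive" && mta == "negative")))
    return("uninformative")
  if (!ravlt_pos && mta == "negative" && csf == "negative") return("low")
  "indeterminate"
}

# every 2 x 3 x 3 tri-state marker combination
all_marker_combos <- function() {
  expand.grid(ravlt_positive = c(TRUE, FALSE),
              mta = c("positive", "negative", "unavailable"),
              csf = c("positive", "negative", "unavailable"),
              stringsAsFactors = FALSE)
}

# naive confusion recount
oracle_confusion <- function(pred, lab) {
  keep <- pred != "not_evaluable"
  pred <- sub("^predict_", "", pred[keep]); lab <- lab[keep]
  c(tp = sum(pred == "converter" & lab == "converter"),
    fp = sum(pred == "converter" & lab == "nonconverter"),
    tn = sum(pred == "nonconverter" & lab == "nonconverter"),
    fn = sum(pred == "nonconverter" & lab == "converter"))
}

# kappa from first principles on the contingency table
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) / n * colSums(tab) / n)
  (po - pe) / (1 - pe)
}
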
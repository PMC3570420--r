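test_that("confusion reproduces the published table rows from their counts", {
  # RAVLT rule: 136 positive of whom 72 converted; cohort 158/233
  cs <- confusion_from_counts(tp = 72, fp = 64, tn = 169, fn = 86)
  expect_equal(cs$sensitivity$percent, 46L)
  expect_equal(cs$specificity$percent, 73L)
  expect_equal(cs$accuracy$percent, 62L)
  expect_equal(cs$sensitivity$ci_percent, c(38L, 54L))
  # CSF OR rule: 150 positive of whom 76 converted; CSF subset 84/115
  cs <- confusion_from_counts(tp = 76, fp = 74, tn = 41, fn = 8)
  expect_equal(cs$sensitivity$percent, 90L)
  expect_equal(cs$accuracy$percent, 59L)
  expect_equal(cs$n_evaluable, 199L)
})

test_that("confusion agrees with a brute-force recount; edge cases behave", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    pred <- sample(c("predict_converter", "predict_nonconverter",
                     "not_evaluable"), n, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    lab <- sample(c("converter", "nonconverter"), n, replace = TRUE)
    if (all(pred == "not_evaluable")) next
    o <- oracle_confusion(pred, lab)
    cs <- confusion(pred, lab)
    expect_equal(c(cs$TP, cs$FP, cs$TN, cs$FN),
                 unname(o[c("tp", "fp", "tn", "fn")]))
    expect_equal(cs$accuracy$estimate, (o[["tp"]] + o[["tn"]]) / sum(o))
    expect_equal(cs$n_not_evaluable, sum(pred == "not_evaluable"))
  }
  perfect <- confusion(rep("converter", 4), rep("converter", 4))
  expect_equal(perfect$sensitivity$percent, 100L)
  expect_equal(perfect$accuracy$percent, 100L)
  expect_error(confusion(rep("not_evaluable", 3),
                         rep("converter", 3)), "zero evaluable")
})

test_that("Clopper-Pearson intervals match the exact binomial oracle", {
  # oracle: stats::binom.test's exact interval
  set.seed(23)
  cases <- rbind(c(72, 158), c(0, 20), c(20, 20),
                 cbind(sample(0:50, 10), 50))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; n <- cases[i, 2]
    ci <- binomial_ci(x, n)
    expect_equal(as.numeric(ci), as.numeric(binom.test(x, n)$conf.int[1:2]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(binomial_ci(0, 10))[1], 0)
  expect_equal(unname(binomial_ci(10, 10))[2], 1)
  expect_equal(attr(binomial_ci(72, 158), "percent"), c(38L, 54L))
  expect_error(binomial_ci(5, 4), "invalid")
})

test_that("Clopper-Pearson coverage is at least nominal (conservative)", {
  set.seed(24)
  n <- 50; reps <- 400
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(reps, n, p)
    cover <- vapply(x, function(xi) {
      ci <- binomial_ci(xi, n)
      ci[["low"]] <= p && p <= ci[["high"]]
    }, TRUE)
    expect_gte(mean(cover), 0.94)
  }
})

test_that("conversion_rate rounds half-up like the printed tables", {
  expect_equal(conversion_rate(13, 20), 65L)
  expect_equal(conversion_rate(2, 29), 7L)
  expect_equal(conversion_rate(0, 17), 0L)
  expect_equal(conversion_rate(1, 8), 13L)      # 12.5 rounds up
  expect_error(conversion_rate(1, 0), "n_total")
  expect_error(conversion_rate(5, 4), "invalid")
})

test_that("McNemar: exact and asymptotic branches, conventions, symmetry", {
  # balanced discordants -> p = 1 (the published comparison value)
  a <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 10))
  b <- c(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 10))
  expect_equal(mcnemar_test(a, b)$p_value, 1)
  # b=10, c=0 -> exact two-sided 2 * 0.5^10
  a <- c(rep(TRUE, 10), rep(TRUE, 5))
  b <- c(rep(FALSE, 10), rep(TRUE, 5))
  m <- mcnemar_test(a, b)
  expect_equal(m$b + m$c, 10)
  expect_equal(m$p_value, 2 * 0.5^10)
  expect_lt(m$p_value, 0.01)
  # identical vectors -> flagged no-discordance, p = 1
  m <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(m$no_discordance)
  expect_equal(m$p_value, 1)
  # symmetry, and agreement with the stats oracles on random data
  set.seed(25)
  for (i in 1:10) {
    n <- sample(c(30, 200), 1)
    a <- sample(c(TRUE, FALSE), n, replace = TRUE)
    b <- sample(c(TRUE, FALSE), n, replace = TRUE)
    m1 <- mcnemar_test(a, b); m2 <- mcnemar_test(b, a)
    expect_equal(m1$p_value, m2$p_value)
    if (m1$no_discordance) next
    if (m1$method == "exact_binomial" && m1$b != m1$c) {
      expect_equal(m1$p_value,
                   binom.test(m1$b, m1$b + m1$c, 0.5)$p.value)
    } else if (m1$method == "chisq_cc") {
      tab <- table(a, b)
      expect_equal(m1$p_value, mcnemar.test(tab, correct = TRUE)$p.value)
    }
  }
})

test_that("Cohen's kappa: identities, oracle agreement, collapse behaviour", {
  x <- sample(1:6, 50, replace = TRUE)
  expect_equal(cohen_kappa(x, x), 1)
  expect_warning(k <- cohen_kappa(rep(1, 5), rep(1, 5)), "degenerate")
  expect_true(is.na(k))
  set.seed(26)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:4, 60, replace = TRUE)
    expect_equal(cohen_kappa(a, b), oracle_kappa(a, b))
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
    perm <- c(3, 1, 4, 2)
    expect_equal(cohen_kappa(perm[a], perm[b]), cohen_kappa(a, b))
  }
  # independent ratings, large n: kappa ~ 0 within 3 SE (~3/sqrt(n))
  set.seed(27)
  a <- sample(1:6, 4000, replace = TRUE)
  b <- sample(1:6, 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 3 / sqrt(4000))
  # raters agreeing on the side of 0.50 but not within side: binary kappa 1
  a <- c(1, 2, 3, 4, 5, 6, 1, 4)
  b <- c(2, 3, 1, 5, 6, 4, 3, 6)
  expect_equal(cohen_kappa(collapse_scale(a), collapse_scale(b)), 1)
  expect_lt(cohen_kappa(a, b), 1)
})

test_that("category_table reproduces the published six-category tables", {
  rc <- reference_counts()
  tab <- do.call(category_table, dsindex:::expand_category_counts(rc$category_dsi))
  expect_equal(attr(tab, "overall_accuracy_percent"), 72L)
  expect_equal(tab["pooled_non_ad", "accuracy_percent"], 81L)
  expect_equal(tab["pooled_non_ad", "share_percent"], 51L)
  expect_equal(tab["clear_non_ad", "accuracy_percent"], 96L)
  expect_equal(sum(tab[c(1:3, 5:7), "total"]), 391)
  # counts give 11/16 = 69% where the source prints 80%; we compute from counts
  expect_equal(tab["clear_ad", "accuracy_percent"], 69L)

  tab6 <- do.call(category_table, dsindex:::expand_category_counts(rc$category_clinician))
  expect_equal(attr(tab6, "overall_accuracy_percent"), 71L)
  expect_equal(tab6["pooled_non_ad", "accuracy_percent"], 80L)

  # degenerate: everything category 6 and truly AD
  tab1 <- category_table(rep(6, 10), rep("AD", 10))
  expect_equal(attr(tab1, "overall_accuracy_percent"), 100L)
  expect_equal(tab1["clear_ad", "accuracy_percent"], 100L)
  expect_error(category_table(1:3, c("AD", "MCI", "Zombie")), "unknown")
})
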
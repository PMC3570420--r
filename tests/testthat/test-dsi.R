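test_that("fitness matches the counting oracle and honours the 0/0 guard", {
  neg <- c(1, 2, 3); pos <- c(4, 5, 6)
  ref <- fit_feature_reference(neg, pos, "high")
  expect_equal(fitness(3.5, ref), 0.5)          # between supports: FN=FP=0
  expect_equal(fitness(7, ref), 1)              # deep positive-only tail
  expect_equal(fitness(0, ref), 0)              # deep negative-only tail

  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:10, 2)
    a <- sample(0:8, n[1], replace = TRUE)
    b <- sample(0:8, n[2], replace = TRUE)
    dir <- sample(c("high", "low"), 1)
    ref <- fit_feature_reference(a, b, dir)
    for (x in c(sample(0:8, 3), 2.5))
      expect_equal(fitness(x, ref), oracle_fitness(x, sort(a), sort(b), dir))
  }
})

test_that("relevance equals the exhaustive Youden sweep", {
  expect_equal(fit_feature_reference(c(1, 2, 3), c(4, 5, 6), "high")$relevance, 1)
  expect_equal(fit_feature_reference(c(1, 2, 3), c(1, 2, 3), "high")$relevance, 0)
  expect_equal(fit_feature_reference(c(1, 3), c(2, 4), "high")$relevance, 0.5)

  set.seed(7)
  for (i in 1:20) {
    a <- sample(0:9, sample(4:10, 1), replace = TRUE)
    b <- sample(0:9, sample(4:10, 1), replace = TRUE)
    dir <- sample(c("high", "low"), 1)
    expect_equal(fit_feature_reference(a, b, dir)$relevance,
                 oracle_relevance(a, b, dir))
  }

  # reference populations drawn from the CSF Tau parameters (scaled down
  # from the spec's 1e4 per group); sweep oracle within +-0.02
  set.seed(12)
  a <- rnorm(2000, 93, 61); b <- rnorm(2000, 118, 57)
  ref <- fit_feature_reference(a, b, "high")
  expect_lt(abs(ref$relevance - oracle_relevance(a, b, "high")), 0.02)
})

test_that("label-swap with direction flip maps fitness to 1 - f, relevance invariant", {
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30, 1)
    ref <- fit_feature_reference(a, b, "high")
    swapped <- fit_feature_reference(b, a, "low")
    for (x in c(-1, 0, 0.5, 1, 2, a[1], b[1]))
      expect_equal(fitness(x, ref) + fitness(x, swapped), 1)
    expect_equal(ref$relevance, swapped$relevance)
  }
})

test_that("reference fitting validates its inputs", {
  expect_error(fit_feature_reference(numeric(0), c(1, 2), "high", "tau"), "tau")
  expect_error(fit_feature_reference(c(1, NA), c(1, 2), "high", "x"),
               "at least 2")
})

test_that("composite DSI is the relevance-weighted tree mean", {
  # single-feature model: composite equals that feature's fitness
  co <- data.frame(subject_id = "s", x = 5)
  m <- structure(list(references = list(x = make_ref(c(1, 2, 3, 4), c(6, 7, 8, 9))),
                      tree = list(b = "x")), class = "dsi_model")
  r <- composite_dsi(co, m)
  expect_equal(r$dsi, fitness(5, m$references$x))
  expect_equal(r$n_used, 1L)

  # two-leaf flat tree with fitnesses {0.2, 0.8}, equal relevances -> 0.5
  refs <- list(
    # at x = 2: FN = 1/5, FP = 4/5 -> fitness 0.2
    a = make_ref(c(0, 3, 3, 3, 3), c(1, 3, 3, 3, 3), relevance_override = 1),
    # at x = 2: FN = 4/5, FP = 1/5 -> fitness 0.8
    b = make_ref(c(0, 0, 0, 0, 3), c(0, 0, 0, 0, 3), relevance_override = 1))
  expect_equal(fitness(2, refs$a), 0.2)
  expect_equal(fitness(2, refs$b), 0.8)
  m2 <- structure(list(references = refs, tree = list(flat = c("a", "b"))),
                  class = "dsi_model")
  expect_equal(composite_dsi(data.frame(a = 2, b = 2), m2)$dsi, 0.5)

  # all fitnesses 1 -> composite 1 (convexity)
  expect_equal(composite_dsi(data.frame(a = 7.5, b = 7.5), m2)$dsi, 1)

  # all features missing is a scoring error
  expect_error(composite_dsi(data.frame(a = NA, b = NA), m2), "missing")
})

test_that("composite agrees with brute-force recursion on random trees", {
  set.seed(15)
  co <- generate_cohort(toy_spec(list(
    gauss_feature("f1", 0, 1, 1, 1), gauss_feature("f2", 0, 1, 2, 1),
    gauss_feature("f3", 5, 2, 4, 2, dir = "low"),
    gauss_feature("f4", 0, 1, 0.2, 1)), 60, 60), 3L)
  tree <- list(g1 = c("f1", "f2"), g2 = c("f3"), g3 = c("f4"))
  model <- fit_dsi_model(co, features = paste0("f", 1:4), tree = tree)
  rel <- vapply(model$references, `[[`, 0, "relevance")
  for (i in 1:15) {
    subj <- co[sample(nrow(co), 1), ]
    drop <- sample(paste0("f", 1:4), sample(0:2, 1))
    subj[drop] <- NA
    obs <- setdiff(paste0("f", 1:4), drop)
    lf <- vapply(obs, function(nm)
      fitness(subj[[nm]], model$references[[nm]]), 0)
    expect_equal(composite_dsi(subj, model)$dsi,
                 oracle_composite(lf, rel[obs], tree))
  }
})

test_that("removing a feature equals scoring against a model without that leaf", {
  set.seed(16)
  co <- generate_cohort(toy_spec(list(
    gauss_feature("f1", 0, 1, 1, 1), gauss_feature("f2", 0, 1, 2, 1),
    gauss_feature("f3", 5, 2, 4, 2, dir = "low")), 50, 50), 8L)
  full <- fit_dsi_model(co, features = c("f1", "f2", "f3"),
                        tree = list(g1 = c("f1", "f2"), g2 = "f3"))
  reduced <- full
  reduced$references$f2 <- NULL
  reduced$tree$g1 <- "f1"
  subj <- co[1, ]
  subj$f2 <- NA
  expect_equal(composite_dsi(subj, full)$dsi,
               composite_dsi(co[1, ], reduced)$dsi)
})

test_that("composite stays in [0,1] and is monotone in any observed fitness", {
  set.seed(17)
  co <- generate_cohort(toy_spec(list(
    gauss_feature("f1", 0, 1, 1.5, 1), gauss_feature("f2", 10, 3, 8, 3, dir = "low")),
    80, 80), 9L)
  model <- fit_dsi_model(co, features = c("f1", "f2"))
  d <- score_cohort(co, model)$dsi
  expect_true(all(d >= 0 & d <= 1))
  # raising an abnormal-high feature raises its fitness, hence the composite
  s <- co[5, ]
  base <- composite_dsi(s, model)$dsi
  s$f1 <- s$f1 + 3
  expect_gte(composite_dsi(s, model)$dsi, base)
})

test_that("six-level binning and the 0.50 binary call follow the scale", {
  expect_equal(dsi_category(c(0, 0.169999, 0.17, 0.33, 0.499, 0.50, 0.67,
                              0.829, 0.83, 1)),
               c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 5L, 6L, 6L))
  expect_error(dsi_category(1.2), "outside")
  expect_error(dsi_classify(-0.1), "outside")
  expect_equal(dsi_classify(c(0.49, 0.50)), c("nonconverter", "converter"))
  expect_equal(collapse_scale(dsi_category(0.50)), factor("converter",
               levels = c("nonconverter", "converter")))
})

test_that("fingerprint export round-trips and flags empty branches", {
  co <- generate_cohort(default_cohort_spec(), 31L)
  halves <- split_cohort(co, 0.5, 2L)
  model <- fit_dsi_model(halves$train)
  subj <- halves$test[which(!halves$test$csf_present)[1], ]
  res <- composite_dsi(subj, model)
  path <- withr::local_tempfile(fileext = ".json")
  export_fingerprint(res, path)
  back <- read_fingerprint(path)
  expect_equal(back$dsi, res$dsi)
  expect_equal(back$category, res$category)
  nodes <- back$nodes
  expect_true(nodes$no_data[nodes$node == "csf"])   # missing CSF branch
  expect_true(is.na(nodes$dsi[nodes$node == "csf"]))
  expect_equal(nodes$dsi[nodes$node == "root"], res$dsi)
  got <- res$nodes; got$no_data <- got$n_observed == 0L
  expect_equal(nodes, got, ignore_attr = TRUE)
})

test_that("stratified split keeps group proportions and is seeded", {
  co <- generate_cohort(default_cohort_spec(), 41L)
  h1 <- split_cohort(co, 0.5, 5L)
  h2 <- split_cohort(co, 0.5, 5L)
  expect_identical(h1$train$subject_id, h2$train$subject_id)
  expect_equal(nrow(h1$train) + nrow(h1$test), 391L)
  expect_equal(sum(h1$train$group == "converter"), 79L)
  expect_equal(sum(h1$test$group == "converter"), 79L)
})
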
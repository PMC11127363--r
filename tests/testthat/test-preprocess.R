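make_cohort <- function(n = 400, seed = 1, base_rate = 0.08) {
  benchmark_cohort(n = n, base_rate = base_rate, seed = seed)
}

test_that("train/test split sizes and missing-target exclusion are exact", {
  coh <- make_cohort(800, seed = 2)
  # plant missing targets
  coh$labels$diabetes_like[c(3, 50, 700)] <- NA
  sp <- split_train_test(coh, "diabetes_like", ratio = 0.8, seed = 5)
  n_ok <- sum(!is.na(coh$labels$diabetes_like))
  expect_equal(length(sp$train), round(0.8 * n_ok))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_setequal(c(sp$train, sp$test), which(!is.na(coh$labels$diabetes_like)))
  # the 693-row arithmetic case
  coh693 <- make_cohort(800, seed = 3)
  keep <- which(!is.na(coh693$labels$diabetes_like))[1:693]
  coh693 <- phrflow:::subset_cohort(coh693, keep)
  sp693 <- split_train_test(coh693, "diabetes_like", 0.8, seed = 1)
  expect_equal(length(sp693$train), 554)
  expect_equal(length(sp693$test), 139)
})

test_that("fitted chain has the declared output dimension and robust scaling", {
  coh <- make_cohort(500, seed = 4)
  plan <- benchmark_plan(coh)
  sp <- split_train_test(coh, "diabetes_like", seed = 2)
  pp <- fit_preprocessor(coh, sp$train, plan, seed = 2)
  tf <- transform_cohort(pp, coh, sp$train)
  p_in <- ncol(coh$features)
  grp <- sum(vapply(plan$pca_groups, function(g) length(g$members), 0L))
  kept <- sum(vapply(plan$pca_groups, function(g) g$k, 0L))
  expect_equal(ncol(tf$x), p_in - length(plan$drop_features) - grp + kept)
  expect_equal(ncol(tf$cond), 2)
  # robust scaling: median 0, IQR 1 on non-degenerate plain columns
  plain <- tf$x[, pp$plain_cols, drop = FALSE]
  expect_lt(max(abs(apply(plain, 2, stats::median))), 1e-9)
  expect_lt(max(abs(apply(plain, 2, stats::IQR) - 1)), 1e-9)
  # log-transform preserves within-feature ordering
  v <- coh$features$triglyceride
  ok <- !is.na(v)
  expect_equal(order(v[ok]), order(log1p(v)[ok]))
})

test_that("transform is pure, idempotent across calls, and leakage-proof", {
  coh <- make_cohort(400, seed = 6)
  plan <- benchmark_plan(coh)
  sp <- split_train_test(coh, "diabetes_like", seed = 3)
  pp1 <- fit_preprocessor(coh, sp$train, plan, seed = 3)
  t1 <- transform_cohort(pp1, coh, sp$test)
  t2 <- transform_cohort(pp1, coh, sp$test)
  expect_identical(t1, t2)
  # corrupt every test row: the fitted state and train transform are unchanged
  coh2 <- coh
  coh2$features[sp$test, ] <- coh2$features[sp$test, ] * 100 + 7
  pp2 <- fit_preprocessor(coh2, sp$train, plan, seed = 3)
  expect_identical(pp1[setdiff(names(pp1), "plan")],
                   pp2[setdiff(names(pp2), "plan")])
  expect_identical(transform_cohort(pp1, coh, sp$train)$x,
                   transform_cohort(pp2, coh2, sp$train)$x)
  # schema guard
  coh3 <- coh
  coh3$features$bmi <- NULL
  expect_error(transform_cohort(pp1, coh3), "schema")
})

test_that("imputation leaves observed cells untouched and fills missing ones", {
  coh <- make_cohort(400, seed = 8)
  plan <- benchmark_plan(coh)
  sp <- split_train_test(coh, "diabetes_like", seed = 1)
  pp <- fit_preprocessor(coh, sp$train, plan, seed = 1)
  tf <- transform_cohort(pp, coh, sp$train)
  expect_false(anyNA(tf$x))
  # observed cells: scaled value equals (log-transformed) original scaled
  j <- "bmi"
  obs <- which(!is.na(coh$features[[j]][sp$train]))[1:20]
  raw <- coh$features[[j]][sp$train][obs]
  expect_equal(tf$x[obs, j],
               (raw - pp$center[[j]]) / pp$scale[[j]],
               tolerance = 1e-12)
})

test_that("no-missing training data makes the imputer an identity", {
  coh <- make_cohort(300, seed = 9)
  coh$features <- coh$complete  # strip missingness
  plan <- benchmark_plan(coh)
  sp <- split_train_test(coh, "diabetes_like", seed = 4)
  pp <- fit_preprocessor(coh, sp$train, plan, seed = 4)
  expect_equal(pp$n_rounds, 0)
})

test_that("constant columns scale center-only and PCA captures collinearity", {
  n <- 120
  feats <- list(feature_spec("a", "gaussian"),
                feature_spec("b", "gaussian"),
                feature_spec("cst", "gaussian", scale = 1))
  demo <- scale_demographics(default_demographics(), n)
  coh <- generate_cohort(demo, feats,
                         list(disease_rule("y", "a", "above", 0)), seed = 2)
  coh$features$cst <- 5  # degenerate column
  coh$complete$cst <- 5
  coh$features$b <- 2 * coh$features$a + 1  # perfectly correlated pair
  plan <- preprocess_plan("y", drop_features = character(),
                          pca_groups = list(ab = list(members = c("a", "b"), k = 1)))
  sp <- split_train_test(coh, "y", seed = 1)
  pp <- fit_preprocessor(coh, sp$train, plan, seed = 1)
  tf <- transform_cohort(pp, coh, sp$train)
  expect_true(all(tf$x[, "cst"] == 0))
  # one component of a perfectly correlated pair carries >= 99.9% variance
  ev <- pp$pca$ab$sdev^2
  expect_gt(ev[1] / sum(ev), 0.999)
})

test_that("a serialized preprocessor replays transforms identically", {
  coh <- make_cohort(300, seed = 12)
  plan <- benchmark_plan(coh)
  sp <- split_train_test(coh, "diabetes_like", seed = 2)
  pp <- fit_preprocessor(coh, sp$train, plan, seed = 2)
  tmp <- tempfile(fileext = ".json")
  save_preprocessor(pp, tmp)
  pp2 <- load_preprocessor(tmp)
  t1 <- transform_cohort(pp, coh, sp$test)
  t2 <- transform_cohort(pp2, coh, sp$test)
  expect_equal(t2$x, t1$x, tolerance = 1e-12)
  expect_equal(t2$cond, t1$cond, tolerance = 1e-12)
})

test_that("plan validation rejects overlapping roles", {
  expect_error(preprocess_plan("y", drop_features = "a", log_features = "a"),
               "disjoint")
  expect_error(preprocess_plan("y", pca_groups = list(
    g1 = list(members = c("a", "b"), k = 1),
    g2 = list(members = c("b", "c"), k = 1))), "disjoint")
})
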
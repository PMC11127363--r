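test_that("split plan reproduces the extreme-imbalance protocol arithmetic", {
  y <- c(rep(0, 693), rep(1, 13))
  plan <- make_split_plan(y, seed = 9)
  expect_equal(length(plan$train), 554)
  expect_equal(length(plan$test_pool), 139)
  expect_equal(sort(vapply(plan$affected_subsets, length, 0L), decreasing = TRUE),
               c(3, 3, 3, 2, 2))
  expect_true(all(plan$base_rates > 0.013 & plan$base_rates < 0.022))
  # conservation: the subsets partition all affected rows
  expect_setequal(unlist(plan$affected_subsets), which(y == 1))
  for (f in plan$folds)
    expect_length(intersect(plan$train, f), 0)
  # minimal case: 10 unaffected / 5 affected
  y2 <- c(rep(0, 10), rep(1, 5))
  p2 <- make_split_plan(y2, seed = 1)
  expect_equal(length(p2$test_pool), 2)
  for (f in p2$folds) expect_equal(length(f), 3)
  expect_error(make_split_plan(c(rep(0, 10), rep(1, 4)), seed = 1), "n_folds")
})

test_that("supervised plan is stratified and conserves the base rate", {
  y <- c(rep(0, 400), rep(1, 40))
  plan <- make_supervised_plan(y, seed = 3)
  expect_equal(sum(y[plan$train] == 1), 32)
  expect_equal(sum(y[plan$train] == 0), 320)
  expect_equal(plan$base_rates, 8 / 88)
  expect_setequal(c(plan$train, plan$folds[[1]]), seq_along(y))
})

test_that("oracle and anti-oracle scorers bound the fold metrics", {
  with_seed(5, {
    n <- 300
    y <- c(rep(1, 12), rep(0, n - 12))[sample(n)]
    x <- cbind(y + stats::rnorm(n, sd = 1e-6), stats::rnorm(n))
    cond <- cbind(stats::runif(n), stats::rbinom(n, 1, 0.5))
  })
  plan <- make_split_plan(y, seed = 2)
  oracle <- new_scorer("oracle", fit = function(x, cond, y, seed) NULL,
                       score = function(m, x, cond) x[, 1],
                       semisupervised = TRUE)
  ev <- evaluate_model(oracle, plan, x, cond, y)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$auprc, 1)
  anti <- new_scorer("anti", fit = function(x, cond, y, seed) NULL,
                     score = function(m, x, cond) -x[, 1],
                     semisupervised = TRUE)
  expect_equal(evaluate_model(anti, plan, x, cond, y)$auroc, 0)
  bad <- new_scorer("bad", fit = function(x, cond, y, seed) NULL,
                    score = function(m, x, cond) rep(NaN, nrow(x)),
                    semisupervised = TRUE)
  expect_error(evaluate_model(bad, plan, x, cond, y), "non-finite")
})

test_that("positive undersampling removes the right count and nothing else", {
  y <- c(rep(1, 230), rep(0, 476))
  keep <- undersample_positives(y, 0.95, seed = 4)
  n_pos <- sum(y[keep] == 1)
  expect_true(n_pos %in% c(11, 12))  # round(0.95 * 230) removed
  expect_equal(sum(y[keep] == 0), 476)
  expect_equal(n_pos / length(keep), 0.02, tolerance = 0.15)
  expect_equal(undersample_positives(y, 0, seed = 1), seq_along(y))
  y4 <- c(1, 1, 1, 1, rep(0, 10))
  expect_equal(sum(y4[undersample_positives(y4, 0.5, seed = 1)] == 1), 2)
  expect_error(undersample_positives(y, 1), "fraction")
})

test_that("repetition summaries are deterministic with honest intervals", {
  f_const <- function(seed) c(m = 0.7)
  s <- run_repetitions(f_const, n = 10, seed_base = 5)
  expect_equal(unname(s$ci_halfwidth["m"]), 0)
  f_rand <- function(seed) with_seed(seed, c(m = stats::runif(1)))
  s1 <- run_repetitions(f_rand, n = 10, seed_base = 5)
  s2 <- run_repetitions(f_rand, n = 10, seed_base = 5)
  expect_identical(s1$values, s2$values)
  expect_equal(unname(s1$ci_halfwidth["m"]),
               1.96 * stats::sd(s1$values[, "m"]) / sqrt(10))
})

test_that("random-scorer AUROC confidence intervals cover one half", {
  covered <- 0
  for (trial in 1:100) {
    s <- run_repetitions(function(seed) with_seed(seed, {
      y <- c(rep(1, 20), rep(0, 180))
      c(auroc = auroc(stats::runif(200), y))
    }), n = 20, seed_base = trial * 1000)
    lo <- s$mean["auroc"] - s$ci_halfwidth["auroc"]
    hi <- s$mean["auroc"] + s$ci_halfwidth["auroc"]
    if (lo <= 0.5 && 0.5 <= hi) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("latent diagnostics summarize the two classes and flag absent ones", {
  with_seed(13, {
    z0 <- matrix(stats::rnorm(400 * 6), 400, 6)
    z1 <- matrix(stats::rnorm(40 * 6, mean = 2), 40, 6)
  })
  z <- rbind(z0, z1); y <- c(rep(0, 400), rep(1, 40))
  dg <- diagnostics(z, y)
  expect_equal(dg$sqnorm$mean_sqnorm[dg$sqnorm$class == "unaffected"], 6,
               tolerance = 0.15)
  expect_gt(dg$sqnorm$mean_sqnorm[dg$sqnorm$class == "affected"],
            dg$sqnorm$mean_sqnorm[dg$sqnorm$class == "unaffected"])
  w <- stats::wilcox.test(rowSums(z1^2), rowSums(z0^2), alternative = "greater")
  expect_lt(w$p.value, 1e-6)
  dg0 <- diagnostics(z0, rep(0, 400))
  expect_false(dg0$sqnorm$present[dg0$sqnorm$class == "affected"])
  tmp <- tempfile()
  diagnostics(z, y, out_dir = tmp)
  expect_true(file.exists(file.path(tmp, "diagnostics_marginals.csv")))
})
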
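test_that("default demographics reproduce the study margin exactly", {
  demo <- default_demographics()
  expect_equal(demo$total, 706)
  coh <- generate_cohort(demo, phr_feature_catalog(), seed = 7)
  expect_equal(nrow(coh$features), 706)
  expect_equal(sum(coh$gender == 1), 315)
  expect_equal(sum(coh$gender == 0), 391)
  # per-bin fidelity: counts are taken verbatim, never sampled
  for (i in seq_len(nrow(demo$bins))) {
    b <- demo$bins[i, ]
    in_bin <- coh$age >= b$min_age & coh$age <= b$max_age
    expect_equal(sum(in_bin & coh$gender == 1), b$male)
    expect_equal(sum(in_bin & coh$gender == 0), b$female)
  }
})

test_that("empty demographics yield an empty cohort without error", {
  demo <- demographics_spec(data.frame(label = "a", min_age = 20, max_age = 29,
                                       male = 0, female = 0))
  coh <- generate_cohort(demo, phr_feature_catalog(),
                         list(disease_rule("d", "bmi", "above", 25)), seed = 1)
  expect_equal(nrow(coh$features), 0)
  expect_equal(ncol(coh$labels), 1)
})

test_that("generation is deterministic and rules referencing unknown features fail", {
  demo <- scale_demographics(default_demographics(), 200)
  feats <- phr_feature_catalog()
  a <- generate_cohort(demo, feats, seed = 3)
  b <- generate_cohort(demo, feats, seed = 3)
  expect_identical(a$features, b$features)
  expect_identical(a$age, b$age)
  expect_error(generate_cohort(demo, feats,
                               list(disease_rule("d", "nope", "above", 1))),
               "unknown feature")
})

test_that("lognormal features are right-skewed and the log transform tames them", {
  feats <- list(feature_spec("tg", "lognormal", location = 4.5, scale = 0.5))
  demo <- scale_demographics(default_demographics(), 10000)
  coh <- generate_cohort(demo, feats, seed = 11)
  v <- coh$complete$tg
  expect_true(all(v > 0))
  sk_raw <- skewness_moment(v)
  sk_log <- skewness_moment(log(v))
  expect_gt(sk_raw, 0)
  expect_lt(abs(sk_log), abs(sk_raw))
})

test_that("labels are deterministic functions of the complete features", {
  coh <- benchmark_cohort(n = 800, base_rate = 0.05, seed = 5)
  rule <- coh$rules[[1]]
  expect_identical(coh$labels$diabetes_like, apply_rule(coh$complete, rule))
  # on observed data, missing biomarkers yield missing labels
  obs_lab <- apply_rule(coh$features, rule)
  expect_true(all(is.na(obs_lab[is.na(coh$features[[rule$biomarker]])])))
})

test_that("block correlation and condition effects match their specification", {
  feats <- list(
    feature_spec("b1", "gaussian", block_id = "blk", block_rho = 0.7),
    feature_spec("b2", "gaussian", block_id = "blk", block_rho = 0.7),
    feature_spec("b3", "gaussian", block_id = "blk", block_rho = 0.7),
    feature_spec("aging", "gaussian", scale = 5, age_coef = 0.3))
  demo <- scale_demographics(default_demographics(), 10000)
  coh <- generate_cohort(demo, feats, seed = 2)
  cm <- stats::cor(coh$complete[, c("b1", "b2", "b3")])
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off - 0.7) < 0.05))
  slope <- stats::coef(stats::lm(coh$complete$aging ~ coh$age))[2]
  expect_gt(slope, 0)
})

test_that("base-rate calibration hits its target within 20% relative error", {
  feats <- phr_feature_catalog()
  demo <- default_demographics()
  rule <- calibrate_base_rate(disease_rule("dia", "glucose", "above", NA),
                              0.02, feats, demo, seed = 4)
  coh <- generate_cohort(scale_demographics(demo, 50000), feats, list(rule),
                         seed = 99)
  rate <- mean(coh$labels$dia == 1, na.rm = TRUE)
  expect_gt(rate, 0.016)
  expect_lt(rate, 0.024)
  # symmetric gaussian at target 0.5: threshold near the biomarker median
  r50 <- calibrate_base_rate(disease_rule("m", "fructosamine", "above", NA),
                             0.5, feats, demo, seed = 4)
  expect_lt(abs(r50$threshold - 240), 1.5)
  expect_error(calibrate_base_rate(disease_rule("m", "bmi", "above", NA),
                                   1.5, feats, demo), "between 0 and 1")
})

test_that("prevalence summary matches hand counts and handles missing labels", {
  coh <- list(labels = data.frame(
    dia = c(rep(1, 13), rep(0, 693)),
    obe = c(rep(1, 230), rep(0, 476)),
    gone = rep(NA_integer_, 706)))
  s <- summarize_prevalence(coh)
  expect_equal(s$count[s$label == "dia"], 13)
  expect_equal(s$percent[s$label == "dia"], 1.8)
  expect_equal(s$count[s$label == "obe"], 230)
  expect_equal(s$percent[s$label == "obe"], 32.6)
  expect_equal(s$count[s$label == "gone"], 0)
  expect_true(is.na(s$percent[s$label == "gone"]))
})
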
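# Comparator models: class-weighted supervised classifiers with 5-fold CV
# tuning, and the classical one-class detectors (one-class SVM, isolation
# forest, Gaussian mixture).

supervised_backends <- c("lgbm", "xgboost", "random_forest", "svm")

xgb_fit <- function(X, y, pars, class_weight, seed) {
  spw <- if (class_weight) sum(y == 0) / max(sum(y == 1), 1) else 1
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = pars$eta,
                  max_depth = pars$max_depth, tree_method = "hist",
                  scale_pos_weight = spw, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = pars$nrounds, verbose = 0)
}

xgb_score <- function(m, X) predict(m, xgboost::xgb.DMatrix(X, nthread = 1))

cv_auprc <- function(X, y, pars, class_weight, fit_fun, score_fun, seed,
                     k = 5L) {
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in c(0, 1)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  vals <- vapply(seq_len(k), function(i) {
    tr <- folds != i; te <- !tr
    if (length(unique(y[te])) < 2 || sum(y[tr] == 1) == 0) return(NA_real_)
    m <- fit_fun(X[tr, , drop = FALSE], y[tr], pars, class_weight, seed)
    auprc(score_fun(m, X[te, , drop = FALSE]), y[te])
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Supervised classification scorer
#'
#' Class-weighted supervised classifiers returning a continuous risk score
#' (probability or decision value). When a hyperparameter `grid` with more
#' than one row is given, the combination maximizing 5-fold cross-validated
#' AUPRC on the training rows is selected before the final refit. `"lgbm"`
#' and `"xgboost"` both name the histogram gradient-boosted tree model
#' (xgboost backend with `tree_method = "hist"`).
#'
#' @param model one of `"lgbm"`, `"xgboost"`, `"random_forest"`, `"svm"`.
#' @param class_weight use inverse-frequency class weights.
#' @param grid optional data.frame of hyperparameter combinations
#'   (boosting: `max_depth`, `eta`, `nrounds`; forest: `num_trees`, `mtry`;
#'   svm: `cost`, `gamma`).
#' @return a `phr_scorer` with `semisupervised = FALSE`.
#' @export
supervised_scorer <- function(model = c("lgbm", "xgboost", "random_forest", "svm"),
                              class_weight = TRUE, grid = NULL) {
  model <- match.arg(model)
  new_scorer(
    name = model,
    semisupervised = FALSE,
    fit = function(x, cond, y, seed) {
      if (length(unique(y)) < 2)
        stop("supervised training needs both classes present")
      X <- cbind(x, cond)
      if (model %in% c("lgbm", "xgboost")) {
        default <- data.frame(max_depth = 4, eta = 0.1, nrounds = 150)
        g <- grid %||% default
        fit_fun <- function(X, y, pars, cw, seed) xgb_fit(X, y, pars, cw, seed)
        score_fun <- function(m, X) xgb_score(m, X)
        pars <- pick_pars(g, X, y, class_weight, fit_fun, score_fun, seed)
        list(kind = "xgb", model = fit_fun(X, y, pars, class_weight, seed))
      } else if (model == "random_forest") {
        default <- data.frame(num_trees = 300, mtry = NA)
        g <- grid %||% default
        fit_fun <- function(X, y, pars, cw, seed) {
          mtry <- if (is.na(pars$mtry)) floor(sqrt(ncol(X))) else pars$mtry
          cwts <- if (cw) length(y) / (2 * c(sum(y == 0), sum(y == 1))) else c(1, 1)
          ranger::ranger(y = factor(y, levels = c(0, 1)), x = as.data.frame(X),
                         num.trees = pars$num_trees, mtry = mtry,
                         probability = TRUE, class.weights = cwts,
                         seed = seed, num.threads = 1)
        }
        score_fun <- function(m, X) predict(m, as.data.frame(X),
                                            num.threads = 1)$predictions[, "1"]
        pars <- pick_pars(g, X, y, class_weight, fit_fun, score_fun, seed)
        list(kind = "rf", model = fit_fun(X, y, pars, class_weight, seed))
      } else {
        default <- data.frame(cost = 1, gamma = 1 / ncol(X))
        g <- grid %||% default
        fit_fun <- function(X, y, pars, cw, seed) {
          wts <- if (cw) {
            w <- length(y) / (2 * c(sum(y == 0), sum(y == 1)))
            stats::setNames(w, c("0", "1"))
          } else NULL
          with_seed(seed,
            e1071::svm(X, factor(y, levels = c(0, 1)), cost = pars$cost,
                       gamma = pars$gamma, kernel = "radial",
                       class.weights = wts))
        }
        score_fun <- function(m, X) {
          dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
          # orient the decision value so that larger means class "1"
          if (colnames(dv)[1] == "0/1") -drop(dv) else drop(dv)
        }
        pars <- pick_pars(g, X, y, class_weight, fit_fun, score_fun, seed)
        list(kind = "svm", model = fit_fun(X, y, pars, class_weight, seed),
             score_fun = score_fun)
      }
    },
    score = function(model, x, cond) {
      X <- cbind(x, cond)
      switch(model$kind,
             xgb = xgb_score(model$model, X),
             rf = predict(model$model, as.data.frame(X),
                          num.threads = 1)$predictions[, "1"],
             svm = model$score_fun(model$model, X))
    })
}

pick_pars <- function(grid, X, y, class_weight, fit_fun, score_fun, seed) {
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  scores <- vapply(seq_len(nrow(grid)), function(i)
    cv_auprc(X, y, grid[i, , drop = FALSE], class_weight, fit_fun, score_fun,
             seed), 0)
  grid[which.max(scores), , drop = FALSE]
}

#' Classical semi-supervised (one-class) scorers
#'
#' All three detectors are fitted on unaffected rows only (asserted) and
#' return scores oriented so that higher means more anomalous:
#' * `one_class_svm` — RBF one-class SVM; score is the negated decision
#'   value (distance inside the normal region).
#' * `isolation_forest` — random isolation trees; anomalies have shorter
#'   average path lengths.
#' * `gmm` — Gaussian mixture density fitted by EM with the component count
#'   chosen from `gmm_components` by BIC; score is the negative log-density.
#'
#' @param model one of `"one_class_svm"`, `"isolation_forest"`, `"gmm"`.
#' @param nu one-class SVM margin parameter.
#' @param n_trees,sample_size isolation-forest size parameters.
#' @param gmm_components candidate mixture sizes.
#' @return a `phr_scorer`.
#' @export
semisupervised_scorer <- function(model = c("one_class_svm", "isolation_forest", "gmm"),
                                  nu = 0.1, n_trees = 100L, sample_size = 256L,
                                  gmm_components = c(1L, 2L, 4L, 8L)) {
  model <- match.arg(model)
  new_scorer(
    name = model,
    semisupervised = TRUE,
    fit = function(x, cond, y, seed) {
      assert_unaffected(y)
      X <- cbind(x, cond)
      switch(model,
        one_class_svm = with_seed(seed,
          e1071::svm(X, y = NULL, type = "one-classification", nu = nu,
                     kernel = "radial")),
        isolation_forest = iso_forest(X, n_trees = n_trees,
                                      sample_size = sample_size, seed = seed),
        gmm = with_seed(seed,
          mclust::densityMclust(X, G = gmm_components, verbose = FALSE,
                                plot = FALSE)))
    },
    score = function(m, x, cond) {
      X <- cbind(x, cond)
      switch(model,
        one_class_svm = -drop(attr(predict(m, X, decision.values = TRUE),
                                   "decision.values")),
        isolation_forest = iso_score(m, X),
        gmm = -log(pmax(predict(m, X, what = "dens"), 1e-300)))
    })
}
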
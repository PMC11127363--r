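# Uniform scorer interface: fit(x, cond, y, seed) -> model,
# score(model, x, cond) -> numeric (higher = more positive / anomalous).

#' Construct a scorer
#'
#' A scorer bundles a `fit` function and a `score` function under one
#' interface so that [evaluate_model()] and the sweep machinery can treat
#' the flow, supervised classifiers and one-class detectors uniformly.
#'
#' @param name display name.
#' @param fit function `(x, cond, y, seed) -> model`. Semi-supervised
#'   scorers receive `y` only so they can assert it is all zero.
#' @param score function `(model, x, cond) -> numeric`, higher = more
#'   positive/anomalous.
#' @param semisupervised logical; semi-supervised scorers must never see
#'   affected rows at fit time.
#' @return an object of class `phr_scorer`.
#' @export
new_scorer <- function(name, fit, score, semisupervised = TRUE) {
  structure(list(name = name, fit = fit, score = score,
                 semisupervised = semisupervised),
            class = "phr_scorer")
}

assert_unaffected <- function(y) {
  if (!is.null(y) && any(y == 1, na.rm = TRUE))
    stop("protocol violation: affected samples passed to a semi-supervised fit")
}

#' Conditional-normalizing-flow scorer
#'
#' Fits the CNF on unaffected training rows by maximum likelihood and scores
#' test rows by the latent anomaly score `-exp(-||z||^2 / 2)`.
#'
#' @param n_blocks,hidden,alpha,psi,learnable_base flow hyperparameters, see
#'   [flow_config()].
#' @param epochs,batch_size,lr_max,lr_min,cycle,warmup,altub,clip training
#'   hyperparameters, see [train_config()].
#' @return a `phr_scorer`.
#' @export
cnf_scorer <- function(n_blocks = 3L, hidden = 32L, alpha = 1.9, psi = "tanh",
                       learnable_base = FALSE, epochs = 120L, batch_size = 128L,
                       lr_max = 3e-3, lr_min = 1e-5, cycle = 40L, warmup = 4L,
                       altub = FALSE, clip = 2) {
  new_scorer(
    name = "cnf",
    fit = function(x, cond, y, seed) {
      assert_unaffected(y)
      fc <- flow_config(d = ncol(x), d_c = ncol(cond), n_blocks = n_blocks,
                        hidden = hidden, alpha = alpha, psi = psi,
                        learnable_base = learnable_base, seed = seed)
      tc <- train_config(epochs = epochs, batch_size = batch_size,
                         lr_max = lr_max, lr_min = lr_min, cycle = cycle,
                         warmup = warmup, altub = altub, clip = clip,
                         seed = seed)
      train_flow(x, cond, fc, tc, labels = y)$state
    },
    score = function(model, x, cond) anomaly_score(flow_forward(x, cond, model)$z),
    semisupervised = TRUE)
}

#' Constant (uninformative) scorer
#'
#' Assigns every row the same score; its AUPRC equals the base rate, making
#' it the natural floor for imbalanced comparisons.
#'
#' @return a `phr_scorer`.
#' @export
constant_scorer <- function() {
  new_scorer("constant",
             fit = function(x, cond, y, seed) NULL,
             score = function(model, x, cond) rep(0, nrow(x)),
             semisupervised = TRUE)
}
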
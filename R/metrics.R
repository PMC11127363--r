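# Ranking metrics for imbalanced binary outcomes.

check_binary <- function(labels) {
  if (anyNA(labels)) stop("labels contain NA")
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) stop("labels must be coded 0/1")
  labels
}

#' Area under the ROC curve
#'
#' Mann--Whitney form: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counted one half.
#'
#' @param scores numeric scores, higher = more positive/anomalous.
#' @param labels 0/1 vector, 1 = positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision--recall curve (average precision)
#'
#' Step-wise average precision: \eqn{\sum_k (R_k - R_{k-1}) P_k} over distinct
#' score thresholds in decreasing order, with tied scores grouped atomically.
#' No linear interpolation of precision is used, so an uninformative constant
#' scorer obtains exactly the base rate.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- check_binary(labels)
  if (sum(labels == 1) == 0) stop("AUPRC needs at least one positive")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # ends of tie groups
  tp <- tp[last]; fp <- fp[last]
  P <- sum(labels == 1)
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Compare two models' repeated metric samples with Welch's t-test
#'
#' Two-sided unequal-variance t-test on the retained per-repetition metric
#' values of two [run_repetitions()] summaries (or raw numeric vectors).
#' Degenerate zero-variance inputs are resolved deterministically: `p = 1`
#' when both samples are constant and equal, `p = 0` when constant and
#' different.
#'
#' @param a,b `phr_repsummary` objects or numeric vectors.
#' @param metric metric column to compare when summaries are given.
#' @return list with `t` and `p`.
#' @export
compare_models <- function(a, b, metric = "auprc") {
  va <- if (inherits(a, "phr_repsummary")) a$values[, metric] else as.numeric(a)
  vb <- if (inherits(b, "phr_repsummary")) b$values[, metric] else as.numeric(b)
  if (length(va) < 2 || length(vb) < 2)
    stop("Welch's t-test needs at least two repetitions per model")
  if (stats::var(va) == 0 && stats::var(vb) == 0) {
    if (mean(va) == mean(vb)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(va) - mean(vb)) * Inf, p = 0))
  }
  tt <- stats::t.test(va, vb, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
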
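# Base-rate-preserving evaluation protocol: split plans, per-fold metrics,
# repeated-split confidence intervals, undersampling sweeps, diagnostics.

#' Base-rate-preserving split plan for anomaly detection
#'
#' Unaffected rows are split 8:2 into a training pool and a shared test pool;
#' affected rows are partitioned into `n_folds` disjoint subsets of
#' near-equal size (differing by at most one). Each test fold is the full
#' unaffected test pool joined with one affected subset, so every fold's
#' positive proportion stays close to the cohort base rate.
#'
#' @param labels 0/1 vector (NA rows are excluded).
#' @param seed integer seed.
#' @param train_ratio unaffected train fraction.
#' @param n_folds number of affected subsets (default 5).
#' @return an object of class `phr_split_plan` with elements `train`,
#'   `test_pool`, `folds` (list of index vectors), `base_rates`, `mode`.
#' @export
make_split_plan <- function(labels, seed = 1L, train_ratio = 0.8, n_folds = 5L) {
  ok <- which(!is.na(labels))
  y <- labels[ok]
  unaff <- ok[y == 0]; aff <- ok[y == 1]
  if (length(aff) < n_folds)
    stop("only ", length(aff), " affected samples; need at least ", n_folds,
         " (reduce n_folds)")
  with_seed(seed, {
    n_tr <- round(train_ratio * length(unaff))
    train <- sort(sample(unaff, n_tr))
    pool <- setdiff(unaff, train)
    shuf <- sample(aff)
    sizes <- rep(length(aff) %/% n_folds, n_folds)
    extra <- length(aff) %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    subsets <- lapply(seq_len(n_folds), function(i) sort(shuf[starts[i]:ends[i]]))
    folds <- lapply(subsets, function(s) c(pool, s))
    structure(list(train = train, test_pool = pool, affected_subsets = subsets,
                   folds = folds,
                   base_rates = vapply(subsets, function(s)
                     length(s) / (length(s) + length(pool)), 0),
                   cohort_base_rate = length(aff) / length(ok),
                   mode = "anomaly", seed = seed),
              class = "phr_split_plan")
  })
}

#' Stratified split plan for supervised comparators
#'
#' Supervised classifiers need affected rows at training time, so they are
#' evaluated under a stratified 8:2 split: `train_ratio` of each class goes
#' to training and the single held-out fold keeps the cohort base rate.
#'
#' @inheritParams make_split_plan
#' @return a `phr_split_plan` with `mode = "supervised"` and one fold.
#' @export
make_supervised_plan <- function(labels, seed = 1L, train_ratio = 0.8) {
  ok <- which(!is.na(labels))
  y <- labels[ok]
  unaff <- ok[y == 0]; aff <- ok[y == 1]
  if (length(aff) < 2) stop("need at least 2 affected samples")
  with_seed(seed, {
    tr_u <- sort(sample(unaff, round(train_ratio * length(unaff))))
    tr_a <- sort(sample(aff, round(train_ratio * length(aff))))
    test <- sort(c(setdiff(unaff, tr_u), setdiff(aff, tr_a)))
    structure(list(train = sort(c(tr_u, tr_a)), test_pool = setdiff(unaff, tr_u),
                   affected_subsets = list(setdiff(aff, tr_a)),
                   folds = list(test),
                   base_rates = length(setdiff(aff, tr_a)) / length(test),
                   cohort_base_rate = length(aff) / length(ok),
                   mode = "supervised", seed = seed),
              class = "phr_split_plan")
  })
}

#' @export
print.phr_split_plan <- function(x, ...) {
  cat("<phr_split_plan> mode = ", x$mode, ", train n = ", length(x$train),
      ", ", length(x$folds), " test fold(s)\n", sep = "")
  cat("  fold base rates: ", paste(signif(x$base_rates, 3), collapse = ", "),
      " (cohort ", signif(x$cohort_base_rate, 3), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a scorer under a split plan
#'
#' Fits the scorer on the plan's training rows (for semi-supervised scorers
#' these contain no affected samples by construction, and the zero-label
#' contract is asserted) and computes AUROC/AUPRC on every test fold.
#'
#' @param scorer a scorer from [cnf_scorer()], [supervised_scorer()],
#'   [semisupervised_scorer()], or [new_scorer()].
#' @param plan a `phr_split_plan`.
#' @param x,cond,y full feature matrix, condition matrix and 0/1 labels.
#' @param seed seed forwarded to the scorer fit.
#' @return list with `per_fold` data.frame and mean `auroc`/`auprc`.
#' @export
evaluate_model <- function(scorer, plan, x, cond, y, seed = 1L) {
  tr <- plan$train
  if (scorer$semisupervised && sum(y[tr] == 1, na.rm = TRUE) > 0)
    stop("protocol violation: affected samples in semi-supervised training rows")
  model <- scorer$fit(x[tr, , drop = FALSE], cond[tr, , drop = FALSE],
                      y[tr], seed)
  rows <- lapply(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    s <- scorer$score(model, x[f, , drop = FALSE], cond[f, , drop = FALSE])
    if (anyNA(s) || any(!is.finite(s))) stop("scorer returned non-finite scores")
    data.frame(fold = i, auroc = auroc(s, y[f]), auprc = auprc(s, y[f]),
               base_rate = mean(y[f] == 1))
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, auroc = mean(per_fold$auroc),
       auprc = mean(per_fold$auprc), model = model)
}

#' Undersample positive rows
#'
#' Removes `round(fraction * n_pos)` affected rows uniformly at random;
#' unaffected rows are untouched.
#'
#' @param labels 0/1 vector (NA allowed; NA rows are retained).
#' @param fraction fraction of positives to remove, in `[0, 1)`.
#' @param seed integer seed.
#' @return sorted integer vector of retained row indices.
#' @export
undersample_positives <- function(labels, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  pos <- which(!is.na(labels) & labels == 1)
  n_drop <- round(fraction * length(pos))
  if (n_drop == 0) return(seq_along(labels))
  drop <- with_seed(seed, sample(pos, n_drop))
  sort(setdiff(seq_along(labels), drop))
}

#' Repeat a seeded experiment and summarize with 95% confidence intervals
#'
#' Calls `fun(seed_base + i)` for `i = 1..n`; `fun` must return a named
#' numeric vector of metrics. The summary reports the mean and the
#' normal-approximation 95% half-width `1.96 * sd / sqrt(n)` per metric, and
#' retains the per-repetition values for model comparisons.
#'
#' @param fun function of a single integer seed.
#' @param n number of repetitions (default 50).
#' @param seed_base base seed.
#' @return an object of class `phr_repsummary`.
#' @export
run_repetitions <- function(fun, n = 50L, seed_base = 0L) {
  if (n < 2) stop("need at least 2 repetitions")
  vals <- do.call(rbind, lapply(seq_len(n), function(i) fun(seed_base + i)))
  structure(list(mean = colMeans(vals),
                 ci_halfwidth = 1.96 * apply(vals, 2, stats::sd) / sqrt(n),
                 n = n, values = vals, seed_base = seed_base),
            class = "phr_repsummary")
}

#' @export
print.phr_repsummary <- function(x, ...) {
  cat("<phr_repsummary> n = ", x$n, " repetitions\n", sep = "")
  for (m in names(x$mean))
    cat(sprintf("  %s: %.4f +/- %.4f\n", m, x$mean[m], x$ci_halfwidth[m]))
  invisible(x)
}

#' Latent-space diagnostics of a fitted flow
#'
#' Per-class marginal summaries of the latent coordinates and the shared
#' histogram of squared norms `||z||^2`. For a well-fit flow, unaffected test
#' samples should resemble the standard normal (mean `||z||^2` near the
#' dimension) while affected samples sit farther from the origin.
#'
#' @param z latent matrix from [flow_forward()].
#' @param labels 0/1 vector aligned with the rows of `z`.
#' @param breaks number of histogram bins.
#' @param out_dir optional directory; when given, the tables are written as
#'   `diagnostics_marginals.csv` and `diagnostics_sqnorm.csv`.
#' @return list with data.frames `marginals`, `sqnorm`, `histogram`.
#' @export
diagnostics <- function(z, labels, breaks = 30L, out_dir = NULL) {
  z <- as.matrix(z)
  sq <- rowSums(z^2)
  classes <- c(unaffected = 0, affected = 1)
  marg <- do.call(rbind, lapply(names(classes), function(cl) {
    idx <- which(labels == classes[[cl]])
    if (length(idx) == 0)
      return(data.frame(class = cl, coordinate = NA_integer_, n = 0L,
                        mean = NA_real_, sd = NA_real_, present = FALSE))
    data.frame(class = cl, coordinate = seq_len(ncol(z)), n = length(idx),
               mean = colMeans(z[idx, , drop = FALSE]),
               sd = apply(z[idx, , drop = FALSE], 2, stats::sd),
               present = TRUE)
  }))
  sqn <- do.call(rbind, lapply(names(classes), function(cl) {
    idx <- which(labels == classes[[cl]])
    if (length(idx) == 0)
      return(data.frame(class = cl, n = 0L, mean_sqnorm = NA_real_,
                        median_sqnorm = NA_real_, present = FALSE))
    data.frame(class = cl, n = length(idx), mean_sqnorm = mean(sq[idx]),
               median_sqnorm = stats::median(sq[idx]), present = TRUE)
  }))
  br <- seq(0, max(sq) * (1 + 1e-8), length.out = breaks + 1L)
  histo <- do.call(rbind, lapply(names(classes), function(cl) {
    idx <- which(labels == classes[[cl]])
    cnt <- if (length(idx) > 0)
      graphics::hist(sq[idx], breaks = br, plot = FALSE)$counts
    else rep(NA_integer_, breaks)
    data.frame(class = cl, bin_low = head(br, -1), bin_high = br[-1],
               count = cnt)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(marg, file.path(out_dir, "diagnostics_marginals.csv"),
                     row.names = FALSE)
    utils::write.csv(histo, file.path(out_dir, "diagnostics_sqnorm.csv"),
                     row.names = FALSE)
  }
  list(marginals = marg, sqnorm = sqn, histogram = histo)
}
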
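# Classical resampling wrappers for class imbalance: SMOTE and ADASYN
# minority oversampling, and Tomek-link majority cleaning.

knn_indices <- function(D, i, pool, k) {
  cand <- setdiff(pool, i)
  cand[order(D[i, cand])[seq_len(min(k, length(cand)))]]
}

#' Apply a resampling method to a labeled training set
#'
#' * `smote` draws synthetic minority rows on segments between a minority
#'   row and one of its `k` nearest minority neighbours until the classes
#'   are balanced (a balanced input is returned unchanged).
#' * `adasyn` does the same but allocates synthetic counts per minority row
#'   in proportion to the fraction of majority points among its `k` nearest
#'   neighbours, concentrating generation near the class boundary.
#' * `tomek_link` removes the majority member of every Tomek link (mutual
#'   opposite-class nearest-neighbour pair); no rows are added.
#'
#' @param name one of `"tomek_link"`, `"smote"`, `"adasyn"`.
#' @param x numeric feature matrix.
#' @param y 0/1 labels (1 = minority assumed; checked).
#' @param k neighbour count for the oversamplers.
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with resampled `x`, `y`, and `synthetic` (logical flag per
#'   returned row; all `FALSE` for `tomek_link`).
#' @export
apply_resampler <- function(name = c("tomek_link", "smote", "adasyn"),
                            x, y, k = 5L, seed = 1L) {
  name <- match.arg(name)
  x <- as.matrix(x); y <- as.integer(y)
  if (length(unique(y)) < 2) stop("resampling needs both classes present")
  n_min <- sum(y == 1); n_maj <- sum(y == 0)
  if (n_min > n_maj) stop("expected class 1 to be the minority class")
  if (name == "tomek_link") {
    D <- as.matrix(stats::dist(x))
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    drop <- integer(0)
    for (i in seq_along(y)) {
      j <- nn[i]
      if (nn[j] == i && y[i] != y[j]) {
        maj <- if (y[i] == 0) i else j
        drop <- c(drop, maj)
      }
    }
    keep <- setdiff(seq_along(y), unique(drop))
    return(list(x = x[keep, , drop = FALSE], y = y[keep],
                synthetic = rep(FALSE, length(keep))))
  }
  # oversamplers
  if (n_min < k + 1)
    stop("minority class has ", n_min, " rows; SMOTE/ADASYN need at least ",
         k + 1, " (reduce k)")
  n_syn <- n_maj - n_min
  if (n_syn == 0)
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
  min_idx <- which(y == 1)
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  counts <- if (name == "smote") {
    with_seed(seed, tabulate(sample(seq_along(min_idx), n_syn, replace = TRUE),
                             nbins = length(min_idx)))
  } else {
    r <- vapply(min_idx, function(i) {
      nb <- order(D[i, ])[seq_len(k)]
      sum(y[nb] == 0) / k
    }, 0)
    if (sum(r) == 0) r <- rep(1, length(min_idx))
    largest_remainder_round(n_syn * r / sum(r), n_syn)
  }
  with_seed(seed + 1L, {
    new_rows <- vector("list", length(min_idx))
    for (ii in seq_along(min_idx)) {
      if (counts[ii] == 0) next
      i <- min_idx[ii]
      nbs <- knn_indices(D, i, min_idx, k)
      pick <- nbs[sample.int(length(nbs), counts[ii], replace = TRUE)]
      u <- stats::runif(counts[ii])
      new_rows[[ii]] <- x[rep(i, counts[ii]), , drop = FALSE] +
        u * (x[pick, , drop = FALSE] - x[rep(i, counts[ii]), , drop = FALSE])
    }
    syn <- do.call(rbind, new_rows)
    list(x = rbind(x, syn), y = c(y, rep(1L, nrow(syn))),
         synthetic = c(rep(FALSE, length(y)), rep(TRUE, nrow(syn))))
  })
}

#' Resampled variant of a supervised scorer
#'
#' Wraps a [supervised_scorer()] so the training rows are passed through
#' [apply_resampler()] before fitting; scoring is unchanged.
#'
#' @param scorer a supervised `phr_scorer`.
#' @param resampler resampler name, see [apply_resampler()].
#' @param k neighbour count.
#' @return a `phr_scorer`.
#' @export
resampled_scorer <- function(scorer, resampler, k = 5L) {
  new_scorer(
    name = paste0(scorer$name, "+", resampler),
    semisupervised = FALSE,
    fit = function(x, cond, y, seed) {
      X <- cbind(x, cond)
      rs <- apply_resampler(resampler, X, y, k = k, seed = seed)
      nc <- ncol(cond)
      p <- ncol(rs$x)
      scorer$fit(rs$x[, seq_len(p - nc), drop = FALSE],
                 rs$x[, p - nc + seq_len(nc), drop = FALSE], rs$y, seed)
    },
    score = scorer$score)
}
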
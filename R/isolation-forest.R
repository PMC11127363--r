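# Isolation forest: random binary trees on subsamples; anomalies are
# isolated in fewer splits, giving shorter expected path lengths.

harmonic <- function(k) if (k < 1) 0 else log(k) + 0.5772156649015329

avg_path <- function(n) if (n <= 1) 0 else 2 * harmonic(n - 1) - 2 * (n - 1) / n

iso_tree_build <- function(X, depth, max_depth) {
  n <- nrow(X)
  if (n <= 1 || depth >= max_depth)
    return(list(leaf = TRUE, size = n))
  spread <- apply(X, 2, function(v) diff(range(v)))
  usable <- which(spread > 0)
  if (length(usable) == 0) return(list(leaf = TRUE, size = n))
  j <- usable[sample.int(length(usable), 1L)]
  cut <- stats::runif(1, min(X[, j]), max(X[, j]))
  left <- X[, j] < cut
  list(leaf = FALSE, feature = j, cut = cut,
       left = iso_tree_build(X[left, , drop = FALSE], depth + 1L, max_depth),
       right = iso_tree_build(X[!left, , drop = FALSE], depth + 1L, max_depth))
}

iso_path_length <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + avg_path(tree$size))
  if (x[tree$feature] < tree$cut)
    iso_path_length(tree$left, x, depth + 1)
  else iso_path_length(tree$right, x, depth + 1)
}

#' Fit an isolation forest
#'
#' @param X numeric matrix of unaffected training rows.
#' @param n_trees number of isolation trees.
#' @param sample_size subsample size per tree (capped at `nrow(X)`).
#' @param seed integer seed.
#' @return an object of class `phr_isoforest`.
#' @export
iso_forest <- function(X, n_trees = 100L, sample_size = 256L, seed = 1L) {
  X <- as.matrix(X)
  ss <- min(sample_size, nrow(X))
  max_depth <- ceiling(log2(max(ss, 2)))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(nrow(X), ss)
    iso_tree_build(X[idx, , drop = FALSE], 0L, max_depth)
  }))
  structure(list(trees = trees, sample_size = ss, c_n = avg_path(ss)),
            class = "phr_isoforest")
}

#' Isolation-forest anomaly scores
#'
#' `2^(-E[path length] / c(n))` in (0, 1); higher = more anomalous.
#'
#' @param forest a `phr_isoforest`.
#' @param X rows to score.
#' @return numeric scores.
#' @export
iso_score <- function(forest, X) {
  X <- as.matrix(X)
  apply(X, 1, function(x) {
    h <- mean(vapply(forest$trees, iso_path_length, 0, x = x))
    2^(-h / forest$c_n)
  })
}
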
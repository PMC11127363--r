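# Leakage-guarded preprocessing: log transform, feature filtering, 8:2
# split, chained-regression imputation, robust scaling, group-wise PCA.

#' Preprocessing plan
#'
#' Declares which features are log-transformed, which are dropped (always
#' including the biomarker that defines the target label, to avoid label
#' leakage), which groups of multicollinear features are collapsed by PCA,
#' and the target label. Age and gender never enter the feature matrix: they
#' are routed to the condition matrix.
#'
#' @param target_label name of the binary label column to model.
#' @param drop_features features removed before modeling (the target's
#'   defining biomarker must be listed here).
#' @param log_features right-skewed features transformed by `log(1 + x)`.
#' @param pca_groups named list; each element is `list(members = <chr>,
#'   k = <int>)` giving the features collapsed together and the number of
#'   principal components kept (default 1).
#' @return an object of class `phr_plan`.
#' @export
preprocess_plan <- function(target_label, drop_features = character(),
                            log_features = character(), pca_groups = list()) {
  if (length(intersect(log_features, drop_features)) > 0)
    stop("log_features and drop_features must be disjoint")
  mem <- unlist(lapply(pca_groups, `[[`, "members"))
  if (anyDuplicated(mem)) stop("PCA group members must be pairwise disjoint")
  if (any(mem %in% drop_features)) stop("PCA group member listed in drop_features")
  pca_groups <- lapply(pca_groups, function(g) {
    g$k <- as.integer(g$k %||% 1L); g
  })
  structure(list(target_label = target_label, drop_features = drop_features,
                 log_features = log_features, pca_groups = pca_groups),
            class = "phr_plan")
}

#' Convenience plan built from a cohort's own specification
#'
#' Log-transforms all lognormal features and drops the biomarker that defines
#' `target_label`.
#'
#' @param cohort a `phr_cohort`.
#' @param target_label label to model.
#' @param pca_groups optional PCA groups (see [preprocess_plan()]).
#' @param extra_drop additional features to drop.
#' @return a `phr_plan`.
#' @export
default_plan <- function(cohort, target_label, pca_groups = list(),
                         extra_drop = character()) {
  logf <- vapply(Filter(function(f) f$family == "lognormal", cohort$feats),
                 `[[`, "", "name")
  rule <- Filter(function(r) r$label_name == target_label, cohort$rules)
  if (length(rule) == 0) stop("no rule defines label '", target_label, "'")
  biom <- rule[[1]]$biomarker
  preprocess_plan(target_label,
                  drop_features = union(biom, extra_drop),
                  log_features = setdiff(logf, union(biom, extra_drop)),
                  pca_groups = pca_groups)
}

#' Train/test split of rows with an observed target
#'
#' Rows with a missing target label are excluded before splitting. The train
#' set holds `round(ratio * n)` of the remaining rows, drawn at random.
#'
#' @param cohort a `phr_cohort`.
#' @param target_label label column used to filter missing targets.
#' @param ratio train fraction in (0, 1).
#' @param seed integer seed.
#' @return list with sorted integer vectors `train` and `test`.
#' @export
split_train_test <- function(cohort, target_label, ratio = 0.8, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  y <- cohort$labels[[target_label]]
  if (is.null(y)) stop("unknown target label '", target_label, "'")
  keep <- which(!is.na(y))
  if (length(keep) == 0) stop("no rows with an observed target")
  n_train <- round(ratio * length(keep))
  with_seed(seed, {
    train <- sort(sample(keep, n_train))
    list(train = train, test = setdiff(keep, train))
  })
}

ridge_fit <- function(A, b, lambda) {
  # A includes an intercept column; the intercept is not penalized
  p <- ncol(A)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  solve(crossprod(A) + pen, crossprod(A, b))
}

#' Fit the preprocessing chain on training rows only
#'
#' Order of operations: `log(1 + x)` on the declared skewed features, drop of
#' filtered features, chained-regression (ridge) imputation of missing
#' values, robust scaling (median / IQR; zero-IQR columns are centered only),
#' then PCA within each declared multicollinear group. Every parameter is
#' estimated from `train_idx` rows alone; [transform_cohort()] replays the
#' fitted chain as a pure function, so test rows can never influence it.
#'
#' @param cohort a `phr_cohort`.
#' @param train_idx integer indices of training rows.
#' @param plan a `phr_plan`.
#' @param seed seed controlling the imputation column order.
#' @param max_iter maximum chained-imputation rounds.
#' @param tol convergence tolerance on imputed values.
#' @param ridge ridge penalty of the per-column regressions.
#' @return an object of class `phr_preprocessor`.
#' @export
fit_preprocessor <- function(cohort, train_idx, plan, seed = 1L,
                             max_iter = 10L, tol = 1e-3, ridge = 1e-3) {
  stopifnot(inherits(plan, "phr_plan"))
  if (length(train_idx) == 0) stop("empty training set")
  X <- as.matrix(cohort$features)
  missing_cols <- setdiff(c(plan$log_features, plan$drop_features,
                            unlist(lapply(plan$pca_groups, `[[`, "members"))),
                          colnames(X))
  if (length(missing_cols) > 0)
    stop("plan references unknown features: ", paste(missing_cols, collapse = ", "))
  for (f in plan$log_features) X[, f] <- log1p(X[, f])
  keep_cols <- setdiff(colnames(X), plan$drop_features)
  Xtr <- X[train_idx, keep_cols, drop = FALSE]

  med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  cols_na <- keep_cols[colSums(is.na(Xtr)) > 0]
  ord <- with_seed(seed, sample(cols_na))
  M <- Xtr
  for (j in keep_cols) M[is.na(M[, j]), j] <- med[[j]]
  betas <- list()
  n_rounds <- 0L
  if (length(ord) > 0 && ncol(Xtr) > 1) {
    for (r in seq_len(max_iter)) {
      round_betas <- list()
      max_change <- 0
      for (j in ord) {
        obs <- !is.na(Xtr[, j])
        A <- cbind(1, M[, setdiff(keep_cols, j), drop = FALSE])
        beta <- ridge_fit(A[obs, , drop = FALSE], M[obs, j], ridge)
        round_betas[[j]] <- beta
        if (any(!obs)) {
          pred <- drop(A[!obs, , drop = FALSE] %*% beta)
          max_change <- max(max_change, max(abs(pred - M[!obs, j])))
          M[!obs, j] <- pred
        }
      }
      betas[[r]] <- round_betas
      n_rounds <- r
      if (max_change < tol) break
    }
  }

  center <- apply(M, 2, stats::median)
  iqr <- apply(M, 2, stats::IQR)
  scl <- ifelse(iqr > 0, iqr, 1)
  S <- sweep(sweep(M, 2, center), 2, scl, "/")

  pca <- list()
  for (gname in names(plan$pca_groups)) {
    g <- plan$pca_groups[[gname]]
    k_max <- min(length(g$members), nrow(S) - 1L)
    k <- g$k
    if (k > k_max) {
      warning("PCA group '", gname, "': reducing components from ", k,
              " to ", k_max)
      k <- k_max
    }
    pr <- stats::prcomp(S[, g$members, drop = FALSE], center = TRUE, scale. = FALSE)
    pca[[gname]] <- list(members = g$members, k = k,
                         center = pr$center,
                         rotation = pr$rotation[, seq_len(k), drop = FALSE],
                         sdev = pr$sdev)
  }
  group_members <- unlist(lapply(pca, `[[`, "members"))
  plain_cols <- setdiff(keep_cols, group_members)
  pc_names <- unlist(lapply(names(pca), function(g)
    paste0(g, "_pc", seq_len(pca[[g]]$k))))
  ages <- cohort$age[train_idx]
  age_center <- stats::median(ages)
  age_scale <- stats::IQR(ages); if (age_scale == 0) age_scale <- 1

  structure(list(plan = plan, keep_cols = keep_cols, med = med, imp_order = ord,
                 betas = betas, n_rounds = n_rounds, center = center,
                 scale = scl, pca = pca, plain_cols = plain_cols,
                 feature_names = c(plain_cols, pc_names),
                 age_center = age_center, age_scale = age_scale),
            class = "phr_preprocessor")
}

impute_replay <- function(state, Xk) {
  M <- Xk
  for (j in state$keep_cols) M[is.na(M[, j]), j] <- state$med[[j]]
  if (state$n_rounds > 0) {
    for (r in seq_len(state$n_rounds)) {
      for (j in state$imp_order) {
        na_j <- is.na(Xk[, j])
        if (!any(na_j)) next
        A <- cbind(1, M[na_j, setdiff(state$keep_cols, j), drop = FALSE])
        M[na_j, j] <- drop(A %*% state$betas[[r]][[j]])
      }
    }
  }
  M
}

#' Apply a fitted preprocessing chain
#'
#' Pure function of the fitted state: the same rows always map to the same
#' output and nothing about the rows being transformed feeds back into the
#' state. Age and gender are routed to the condition matrix (age robustly
#' scaled with training parameters, gender kept as its 0/1 code) and never
#' appear among the features.
#'
#' @param state a `phr_preprocessor` from [fit_preprocessor()].
#' @param cohort a `phr_cohort` with the same feature schema as at fit time.
#' @param rows integer row indices (default: all rows).
#' @return list with matrix `x` (features), matrix `cond` (`age`, `gender`),
#'   vector `y` (target labels, possibly `NA`), and `rows`.
#' @export
transform_cohort <- function(state, cohort, rows = NULL) {
  stopifnot(inherits(state, "phr_preprocessor"))
  X <- as.matrix(cohort$features)
  needed <- union(state$plan$log_features, state$keep_cols)
  if (!all(needed %in% colnames(X)))
    stop("schema mismatch: cohort lacks features seen at fit time")
  rows <- rows %||% seq_len(nrow(X))
  for (f in state$plan$log_features) X[, f] <- log1p(X[, f])
  Xk <- X[rows, state$keep_cols, drop = FALSE]
  M <- impute_replay(state, Xk)
  S <- sweep(sweep(M, 2, state$center), 2, state$scale, "/")
  parts <- list(S[, state$plain_cols, drop = FALSE])
  for (gname in names(state$pca)) {
    p <- state$pca[[gname]]
    pcs <- sweep(S[, p$members, drop = FALSE], 2, p$center) %*% p$rotation
    colnames(pcs) <- paste0(gname, "_pc", seq_len(p$k))
    parts <- c(parts, list(pcs))
  }
  x <- do.call(cbind, parts)[, state$feature_names, drop = FALSE]
  cond <- cbind(age = (cohort$age[rows] - state$age_center) / state$age_scale,
                gender = as.numeric(cohort$gender[rows]))
  y <- cohort$labels[[state$plan$target_label]]
  list(x = x, cond = cond, y = if (!is.null(y)) y[rows] else NULL, rows = rows)
}

#' @export
print.phr_preprocessor <- function(x, ...) {
  cat("<phr_preprocessor> ", length(x$keep_cols), " input features -> ",
      length(x$feature_names), " model features (+2 condition columns)\n",
      sep = "")
  cat("  imputation rounds: ", x$n_rounds, ", PCA groups: ",
      length(x$pca), "\n", sep = "")
  invisible(x)
}
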
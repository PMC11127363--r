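# Plain-text persistence: cohort CSV with a YAML sidecar, and JSON archives
# for fitted flow and preprocessor states.

#' Write a cohort to CSV with a YAML sidecar
#'
#' The CSV holds features, `age`, `gender` and label columns (missing values
#' as empty cells); the sidecar records which columns are conditions and
#' labels, the right-skewed (lognormal) features, and block memberships.
#'
#' @param cohort a `phr_cohort`.
#' @param csv_path output CSV path.
#' @param meta_path sidecar path (default: `csv_path` with `.yaml`).
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, csv_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.csv$", ".yaml", csv_path)
  df <- cbind(cohort$features,
              age = cohort$age, gender = cohort$gender, cohort$labels)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  blocks <- list()
  for (f in cohort$feats) {
    if (!is.null(f$block_id)) {
      blocks[[f$block_id]]$members <- c(blocks[[f$block_id]]$members, f$name)
      blocks[[f$block_id]]$rho <- f$block_rho
    }
  }
  meta <- list(
    condition_columns = c("age", "gender"),
    label_columns = names(cohort$labels),
    feature_columns = names(cohort$features),
    skewed_features = vapply(
      Filter(function(f) f$family == "lognormal", cohort$feats), `[[`, "", "name"),
    blocks = blocks,
    rules = lapply(cohort$rules, function(r)
      list(label_name = r$label_name, biomarker = r$biomarker,
           direction = r$direction, threshold = r$threshold)))
  yaml::write_yaml(meta, meta_path)
  invisible(c(csv = csv_path, meta = meta_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param csv_path CSV path.
#' @param meta_path sidecar path (default: `csv_path` with `.yaml`).
#' @return a `phr_cohort` (without the latent `complete` table or the
#'   generating specifications, which are not stored).
#' @export
read_cohort <- function(csv_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.csv$", ".yaml", csv_path)
  meta <- yaml::read_yaml(meta_path)
  df <- utils::read.csv(csv_path, check.names = FALSE)
  feats <- lapply(meta$feature_columns, function(nm) {
    fam <- if (nm %in% meta$skewed_features) "lognormal" else "gaussian"
    feature_spec(nm, fam)
  })
  rules <- lapply(meta$rules, function(r)
    disease_rule(r$label_name, r$biomarker, r$direction, r$threshold))
  structure(list(
    features = df[, meta$feature_columns, drop = FALSE],
    age = df$age, gender = df$gender,
    labels = df[, meta$label_columns, drop = FALSE],
    complete = NULL, feats = feats, rules = rules, demo = NULL),
    class = "phr_cohort")
}

#' Serialize a fitted flow to JSON
#'
#' Named-array archive with the configuration (and its content hash) as a
#' header; [load_flow_state()] refuses an archive whose hash does not match
#' its stored configuration.
#'
#' @param state a `phr_flow`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_flow_state <- function(state, path) {
  obj <- list(format = "phrflow/flow-state/1",
              config = unclass(state$config), hash = state$hash,
              d1 = state$d1, d2 = state$d2,
              perms = state$perms, par = state$par)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a flow serialized by [save_flow_state()]
#'
#' @param path archive path.
#' @return a `phr_flow`.
#' @export
load_flow_state <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = FALSE)
  cfg <- obj$config
  config <- flow_config(d = cfg$d, d_c = cfg$d_c, n_blocks = cfg$n_blocks,
                        hidden = cfg$hidden, alpha = cfg$alpha, psi = cfg$psi,
                        learnable_base = cfg$learnable_base, seed = cfg$seed)
  if (!identical(fnv1a32(unclass(config)), obj$hash))
    stop("flow archive hash does not match its configuration")
  template <- init_flow(config)
  # JSON stores matrices as row-major nested arrays; rebuild against the
  # template's shapes
  rebuild <- function(x, tmpl) {
    if (is.list(tmpl)) {
      keys <- if (is.null(names(tmpl))) seq_along(tmpl) else names(tmpl)
      out <- lapply(keys, function(k) rebuild(x[[k]], tmpl[[k]]))
      names(out) <- names(tmpl)
      return(out)
    }
    v <- as.numeric(unlist(x))
    if (!is.null(dim(tmpl)))
      matrix(v, nrow(tmpl), ncol(tmpl), byrow = TRUE)
    else v
  }
  par <- rebuild(obj$par, template$par)
  perms <- lapply(obj$perms, function(p)
    list(perm = as.integer(unlist(p$perm)), invperm = as.integer(unlist(p$invperm))))
  structure(list(config = config, par = par, perms = perms,
                 d1 = template$d1, d2 = template$d2, hash = obj$hash),
            class = "phr_flow")
}

#' Serialize a fitted preprocessor to JSON
#'
#' Single-archive persistence of every fitted parameter: medians, imputation
#' coefficients by round and column, robust centers/scales, PCA loadings,
#' condition scaling and the plan — enough for [transform_cohort()] to be
#' replayed elsewhere.
#'
#' @param state a `phr_preprocessor`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_preprocessor <- function(state, path) {
  obj <- list(format = "phrflow/preprocessor/1",
              plan = unclass(state$plan),
              keep_cols = state$keep_cols, med = as.list(state$med),
              imp_order = state$imp_order, n_rounds = state$n_rounds,
              betas = lapply(state$betas, function(r) lapply(r, as.numeric)),
              center = as.list(state$center), scale = as.list(state$scale),
              pca = lapply(state$pca, function(p)
                list(members = p$members, k = p$k,
                     center = as.list(p$center),
                     rotation = as.numeric(p$rotation), sdev = p$sdev)),
              plain_cols = state$plain_cols,
              feature_names = state$feature_names,
              age_center = state$age_center, age_scale = state$age_scale)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a preprocessor serialized by [save_preprocessor()]
#'
#' @param path archive path.
#' @return a `phr_preprocessor`.
#' @export
load_preprocessor <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = FALSE)
  plan <- preprocess_plan(obj$plan$target_label,
                          drop_features = unlist(obj$plan$drop_features),
                          log_features = unlist(obj$plan$log_features),
                          pca_groups = lapply(obj$plan$pca_groups, function(g)
                            list(members = unlist(g$members), k = g$k)))
  pca <- lapply(obj$pca, function(p) {
    members <- unlist(p$members)
    list(members = members, k = p$k,
         center = unlist(p$center),
         rotation = matrix(as.numeric(unlist(p$rotation)),
                           nrow = length(members), ncol = p$k,
                           dimnames = list(members, NULL)),
         sdev = as.numeric(unlist(p$sdev)))
  })
  structure(list(plan = plan, keep_cols = unlist(obj$keep_cols),
                 med = unlist(obj$med),
                 imp_order = as.character(unlist(obj$imp_order)),
                 betas = lapply(obj$betas, function(r)
                   lapply(r, function(b) matrix(as.numeric(unlist(b))))),
                 n_rounds = obj$n_rounds,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 pca = pca, plain_cols = unlist(obj$plain_cols),
                 feature_names = unlist(obj$feature_names),
                 age_center = obj$age_center, age_scale = obj$age_scale),
            class = "phr_preprocessor")
}
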
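# Synthetic PHR cohort generation: demographics, feature families,
# threshold-defined disease labels, and base-rate calibration.

#' Demographic specification for a synthetic cohort
#'
#' One row per age bin with the number of male and female participants.
#' Bin ranges must not overlap and counts must be nonnegative.
#'
#' @param bins data.frame with columns `label`, `min_age`, `max_age`,
#'   `male`, `female`.
#' @return an object of class `phr_demographics`.
#' @seealso [default_demographics()] for the bundled default layout.
#' @export
demographics_spec <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("label", "min_age", "max_age", "male", "female") %in% names(bins)))
  if (any(bins$male < 0) || any(bins$female < 0))
    stop("demographic counts must be nonnegative")
  if (any(bins$min_age > bins$max_age))
    stop("age bin with min_age > max_age")
  if (nrow(bins) > 1) {
    o <- order(bins$min_age)
    if (any(bins$min_age[o][-1] <= bins$max_age[o][-nrow(bins)]))
      stop("age bins overlap")
  }
  structure(list(bins = bins, total = sum(bins$male) + sum(bins$female)),
            class = "phr_demographics")
}

#' Default cohort demographics
#'
#' Age/gender layout of a 706-participant general-population cohort of South
#' Korean adults (ages 19--59): 315 men and 391 women across five age bins.
#'
#' @return a `phr_demographics` object with total 706.
#' @export
default_demographics <- function() {
  demographics_spec(data.frame(
    label   = c("19", "20-29", "30-39", "40-49", "50-59"),
    min_age = c(19, 20, 30, 40, 50),
    max_age = c(19, 29, 39, 49, 59),
    male    = c(0, 45, 98, 104, 68),
    female  = c(1, 127, 130, 89, 44)
  ))
}

#' Rescale a demographic specification to a new total
#'
#' Scales every (bin, gender) count proportionally, rounding by largest
#' remainder so the new counts sum exactly to `n_total`.
#'
#' @param demo a `phr_demographics` object.
#' @param n_total target number of participants.
#' @return a `phr_demographics` object with total `n_total`.
#' @export
scale_demographics <- function(demo, n_total) {
  stopifnot(inherits(demo, "phr_demographics"), n_total >= 0)
  b <- demo$bins
  cnt <- c(b$male, b$female)
  if (demo$total == 0) stop("cannot scale an empty demographic spec")
  new <- largest_remainder_round(cnt * n_total / demo$total, n_total)
  k <- nrow(b)
  b$male <- new[seq_len(k)]
  b$female <- new[k + seq_len(k)]
  demographics_spec(b)
}

#' Feature specification
#'
#' Describes one synthetic feature: its marginal family, optional membership
#' in an equicorrelated block, linear age/gender effects on its mean (on the
#' log scale for lognormal features), and a completely-at-random missing rate.
#'
#' @param name feature name.
#' @param family one of `"gaussian"`, `"lognormal"` (right-skewed, strictly
#'   positive), `"ordinal"` (latent-Gaussian cut into `n_levels` grades).
#' @param location,scale mean and standard deviation of the latent Gaussian
#'   (for `"lognormal"`, the log-scale mean and standard deviation).
#' @param age_coef,gender_coef additive shift of the (latent) mean per year of
#'   age and for gender code 1 (male) versus 0 (female).
#' @param block_id optional tag; features sharing a `block_id` are generated
#'   from a single-factor model with pairwise correlation `block_rho`.
#' @param block_rho pairwise correlation within the block, in (0, 1).
#' @param missing_rate probability in `[0, 1]` that an entry is masked.
#' @param n_levels number of grades for ordinal features.
#' @return an object of class `phr_feature`.
#' @export
feature_spec <- function(name, family = c("gaussian", "lognormal", "ordinal"),
                         location = 0, scale = 1, age_coef = 0, gender_coef = 0,
                         block_id = NULL, block_rho = NULL,
                         missing_rate = 0, n_levels = 5L) {
  family <- match.arg(family)
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (scale <= 0) stop("scale must be positive")
  if (!is.null(block_id) && (is.null(block_rho) || block_rho <= 0 || block_rho >= 1))
    stop("block members need block_rho in (0, 1)")
  structure(list(name = name, family = family, location = location,
                 scale = scale, age_coef = age_coef, gender_coef = gender_coef,
                 block_id = block_id, block_rho = block_rho,
                 missing_rate = missing_rate, n_levels = as.integer(n_levels)),
            class = "phr_feature")
}

#' Threshold rule defining a binary disease label
#'
#' Disease status is a deterministic function of one biomarker: affected when
#' the biomarker lies `"above"` (or `"below"`) `threshold`. Rows with a
#' missing biomarker yield a missing label when the rule is applied to
#' observed (post-missingness) data.
#'
#' @param label_name name of the binary label column.
#' @param biomarker name of the defining feature.
#' @param direction `"above"` or `"below"`.
#' @param threshold cut point in biomarker units.
#' @return an object of class `phr_rule`.
#' @export
disease_rule <- function(label_name, biomarker, direction = c("above", "below"),
                         threshold) {
  direction <- match.arg(direction)
  structure(list(label_name = label_name, biomarker = biomarker,
                 direction = direction, threshold = threshold),
            class = "phr_rule")
}

#' Apply a disease rule to a feature table
#'
#' @param features data.frame of feature values (may contain `NA`).
#' @param rule a `phr_rule`.
#' @return integer vector of 0/1 labels with `NA` where the biomarker is
#'   missing.
#' @export
apply_rule <- function(features, rule) {
  if (!rule$biomarker %in% names(features))
    stop("rule '", rule$label_name, "' references unknown feature '",
         rule$biomarker, "'")
  v <- features[[rule$biomarker]]
  if (rule$direction == "above") as.integer(v > rule$threshold)
  else as.integer(v < rule$threshold)
}

#' Generate a synthetic PHR cohort
#'
#' Draws a cohort whose demographic margin matches `demo` exactly (ages
#' uniform within bins, gender coded 0 = female / 1 = male), generates
#' features per their specifications (single-factor equicorrelated blocks,
#' age/gender mean shifts, lognormal right-skew), derives binary disease
#' labels from the complete latent values via the threshold rules, and only
#' then injects completely-at-random missingness.
#'
#' @param demo a `phr_demographics`.
#' @param feats list of `phr_feature` specifications.
#' @param rules list of `phr_rule` label definitions.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return an object of class `phr_cohort`: a list with `features` (observed,
#'   with `NA`s), `age`, `gender`, `labels`, and the complete pre-missingness
#'   feature table in `complete`.
#' @export
generate_cohort <- function(demo, feats, rules = list(), seed = 1L) {
  stopifnot(inherits(demo, "phr_demographics"))
  fnames <- vapply(feats, function(f) f$name, "")
  if (anyDuplicated(fnames)) stop("duplicate feature names")
  for (r in rules)
    if (!r$biomarker %in% fnames)
      stop("rule '", r$label_name, "' references unknown feature '",
           r$biomarker, "'")
  n <- demo$total
  if (n == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, length(fnames),
                                  dimnames = list(NULL, fnames)))
    labs <- as.data.frame(matrix(integer(0), 0, length(rules),
                                 dimnames = list(NULL, vapply(rules, `[[`, "", "label_name"))))
    return(structure(list(features = empty, age = numeric(0),
                          gender = integer(0), labels = labs, complete = empty,
                          feats = feats, rules = rules, demo = demo),
                     class = "phr_cohort"))
  }
  with_seed(seed, {
    age <- integer(0); gender <- integer(0)
    for (i in seq_len(nrow(demo$bins))) {
      b <- demo$bins[i, ]
      nb <- b$male + b$female
      if (nb == 0) next
      span <- b$max_age - b$min_age + 1L
      age <- c(age, b$min_age + sample.int(span, nb, replace = TRUE) - 1L)
      gender <- c(gender, rep(c(1L, 0L), c(b$male, b$female)))
    }
    perm <- sample.int(n)
    age <- age[perm]; gender <- gender[perm]

    block_ids <- unique(unlist(lapply(feats, function(f) f$block_id)))
    factors <- lapply(stats::setNames(block_ids, block_ids),
                      function(id) stats::rnorm(n))
    complete <- matrix(NA_real_, n, length(feats),
                       dimnames = list(NULL, fnames))
    for (f in feats) {
      eps <- stats::rnorm(n)
      z <- if (!is.null(f$block_id))
        sqrt(f$block_rho) * factors[[f$block_id]] + sqrt(1 - f$block_rho) * eps
      else eps
      lin <- f$location + f$age_coef * age + f$gender_coef * gender
      complete[, f$name] <- switch(f$family,
        gaussian  = lin + f$scale * z,
        lognormal = exp(lin + f$scale * z),
        ordinal   = {
          lat <- lin + f$scale * z
          qs <- stats::quantile(lat, probs = seq_len(f$n_levels - 1L) / f$n_levels,
                                names = FALSE)
          as.numeric(findInterval(lat, qs) + 1L)
        })
    }
    complete <- as.data.frame(complete)
    labels <- as.data.frame(lapply(stats::setNames(rules, vapply(rules, `[[`, "", "label_name")),
                                   function(r) apply_rule(complete, r)))
    if (length(rules) == 0)
      labels <- as.data.frame(matrix(integer(0), n, 0))
    observed <- complete
    for (f in feats) {
      if (f$missing_rate > 0) {
        mask <- stats::runif(n) < f$missing_rate
        observed[mask, f$name] <- NA_real_
      }
    }
    structure(list(features = observed, age = as.numeric(age), gender = gender,
                   labels = labels, complete = complete, feats = feats,
                   rules = rules, demo = demo),
              class = "phr_cohort")
  })
}

#' @export
print.phr_cohort <- function(x, ...) {
  cat("<phr_cohort> ", nrow(x$features), " participants, ",
      ncol(x$features), " features, ", ncol(x$labels), " labels\n", sep = "")
  if (nrow(x$features) > 0)
    cat("  males: ", sum(x$gender == 1), ", females: ", sum(x$gender == 0),
        ", ages ", min(x$age), "-", max(x$age), "\n", sep = "")
  invisible(x)
}

#' Calibrate a disease rule to a target prevalence
#'
#' Sets the rule threshold to the empirical `(1 - target_rate)` (for
#' direction `"above"`) or `target_rate` (for `"below"`) quantile of the
#' biomarker on a large simulated cohort, so the realized prevalence lands
#' close to `target_rate`.
#'
#' @param rule a `phr_rule`.
#' @param target_rate desired prevalence in (0, 1).
#' @param feats,demo cohort specification used for the calibration draw.
#' @param seed integer seed.
#' @param n_sim size of the calibration cohort.
#' @return the rule with its threshold replaced.
#' @export
calibrate_base_rate <- function(rule, target_rate, feats, demo, seed = 1L,
                                n_sim = 50000L) {
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= 1)
    stop("target_rate must lie strictly between 0 and 1")
  big <- scale_demographics(demo, n_sim)
  coh <- generate_cohort(big, feats, rules = list(), seed = seed)
  v <- coh$complete[[rule$biomarker]]
  if (is.null(v)) stop("biomarker '", rule$biomarker, "' not in feature list")
  p <- if (rule$direction == "above") 1 - target_rate else target_rate
  rule$threshold <- stats::quantile(v, p, names = FALSE)
  rule
}

#' Per-label prevalence summary
#'
#' Counts affected participants per label among rows with an observed label;
#' percent is `100 * count / n_observed` rounded to one decimal (`NA` when no
#' label is observed).
#'
#' @param cohort a `phr_cohort` (or any object with a `labels` data.frame).
#' @return data.frame with columns `label`, `count`, `n`, `percent`.
#' @export
summarize_prevalence <- function(cohort) {
  labs <- cohort$labels
  if (is.null(labs) || ncol(labs) == 0) stop("cohort has no labels")
  out <- lapply(names(labs), function(nm) {
    y <- labs[[nm]]
    nn <- sum(!is.na(y))
    cnt <- sum(y == 1, na.rm = TRUE)
    data.frame(label = nm, count = cnt, n = nn,
               percent = if (nn > 0) round(100 * cnt / nn, 1) else NA_real_)
  })
  do.call(rbind, out)
}
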
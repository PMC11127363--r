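# Independent brute-force oracles used to pin expected values.

# AUROC by exhaustive positive/negative pair enumeration, ties = 1/2.
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Step-wise average precision from the full precision-recall staircase,
# computed naively at every distinct threshold.
auprc_brute <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# log|det| of the numerically differentiated Jacobian of f at x.
numeric_logdet <- function(f, x, eps = 1e-6) {
  d <- length(x)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    e <- rep(0, d); e[j] <- eps
    J[, j] <- (f(x + e) - f(x - e)) / (2 * eps)
  }
  as.numeric(determinant(J, logarithm = TRUE)$modulus)
}

# sample skewness by the direct moment formula
skewness_moment <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# a small random non-identity flow state for layer tests
random_flow_state <- function(d, n_blocks = 2, hidden = 8, seed = 1,
                              sd = 0.3, alpha = 1.9, learnable_base = FALSE) {
  cfg <- flow_config(d = d, n_blocks = n_blocks, hidden = hidden,
                     alpha = alpha, learnable_base = learnable_base,
                     seed = seed)
  st <- init_flow(cfg)
  th <- phrflow:::flatten_params(st$par)
  st$par <- phrflow:::unflatten_params(
    with_seed(seed + 99, stats::rnorm(length(th), sd = sd)), st$par)
  st$par$base <- list(mu = rep(0, d), log_sigma = rep(0, d))
  st
}

# toy conditional-gaussian data: correlated block plus age-shifted means
toy_conditional_data <- function(n, d, seed = 1) {
  with_seed(seed, {
    age <- stats::runif(n, -1, 1)
    gen <- stats::rbinom(n, 1, 0.5)
    f <- stats::rnorm(n)
    x <- sapply(seq_len(d), function(j)
      0.7 * f + 0.7 * stats::rnorm(n) + 0.5 * age * (j <= ceiling(d / 2)))
    list(x = x, cond = cbind(age = age, gender = gen))
  })
}
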
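# Conditional normalizing flow: conditional affine transformation,
# volume-preserving GIN coupling blocks with permutation and global offset,
# learnable diagonal-normal base, exact log-likelihood and anomaly score.

#' Flow configuration
#'
#' @param d input dimension (>= 2); always taken from the data, never
#'   hard-coded.
#' @param d_c condition dimension (default 2: age, gender).
#' @param n_blocks number of coupling block units, each holding two GIN
#'   coupling layers with swapped active halves, a fixed permutation and a
#'   global offset.
#' @param hidden width of the subnetwork hidden layers.
#' @param alpha soft-clamp constant of the conditional affine scale,
#'   `a' = alpha * psi(a)`.
#' @param psi clamp activation for the affine scale (default `tanh`).
#' @param learnable_base if `TRUE`, the diagonal-normal base parameters are
#'   trained (periodically, via the AltUB alternation in [train_flow()]);
#'   otherwise the base is frozen at the standard normal.
#' @param seed seed for parameter initialization and the per-block
#'   permutations.
#' @return an object of class `phr_flow_config`.
#' @export
flow_config <- function(d, d_c = 2L, n_blocks = 8L, hidden = 64L, alpha = 1.9,
                        psi = c("tanh", "identity"), learnable_base = FALSE,
                        seed = 1L) {
  psi <- match.arg(psi)
  if (d < 2) stop("d must be >= 2")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(d = as.integer(d), d_c = as.integer(d_c),
                 n_blocks = as.integer(n_blocks), hidden = as.integer(hidden),
                 alpha = alpha, psi = psi, learnable_base = learnable_base,
                 seed = as.integer(seed)),
            class = "phr_flow_config")
}

psi_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
         identity = list(f = identity, df = function(x) rep(1, length(x))))
}

gelu <- function(x) x * stats::pnorm(x)
dgelu <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

mlp_init <- function(n_in, n_out, h) {
  # final layer zero so each layer starts as the identity map
  list(W1 = matrix(stats::rnorm(h * n_in, sd = sqrt(2 / n_in)), h, n_in),
       b1 = rep(0, h),
       W2 = matrix(0, n_out, h),
       b2 = rep(0, n_out))
}

mlp_fwd <- function(p, Q, act) {
  S1 <- add_bias(Q %*% t(p$W1), p$b1)
  H <- if (act == "relu") pmax(S1, 0) else gelu(S1)
  list(out = add_bias(H %*% t(p$W2), p$b2), Q = Q, S1 = S1, H = H)
}

mlp_bwd <- function(p, cache, dOut, act) {
  dH <- dOut %*% p$W2
  dS1 <- if (act == "relu") dH * (cache$S1 > 0) else dH * dgelu(cache$S1)
  list(g = list(W1 = crossprod(dS1, cache$Q), b1 = colSums(dS1),
                W2 = crossprod(dOut, cache$H), b2 = colSums(dOut)),
       dQ = dS1 %*% p$W1)
}

#' Initialize a flow state
#'
#' Subnetwork output layers start at zero, so the freshly initialized flow is
#' the identity map (up to the per-block permutations, whose offsets are also
#' zero) and carries zero log-determinant.
#'
#' @param config a `phr_flow_config`.
#' @return an object of class `phr_flow` holding ordered layer parameters,
#'   the fixed permutations, and the base-distribution parameters.
#' @export
init_flow <- function(config) {
  stopifnot(inherits(config, "phr_flow_config"))
  d <- config$d; h <- config$hidden
  d1 <- ceiling(d / 2); d2 <- d - d1
  with_seed(config$seed, {
    affine <- mlp_init(config$d_c, 2L * d, h)
    perms <- list(); blocks <- list()
    for (b in seq_len(config$n_blocks)) {
      perm <- sample.int(d)
      perms[[b]] <- list(perm = perm, invperm = order(perm))
      blocks[[b]] <- list(
        s1 = mlp_init(d2 + config$d_c, d1, h),
        t1 = mlp_init(d2 + config$d_c, d1, h),
        s2 = mlp_init(d1 + config$d_c, d2, h),
        t2 = mlp_init(d1 + config$d_c, d2, h),
        t_global = rep(0, d))
    }
    par <- list(affine = affine, blocks = blocks,
                base = list(mu = rep(0, d), log_sigma = rep(0, d)))
    structure(list(config = config, par = par, perms = perms,
                   d1 = d1, d2 = d2, hash = fnv1a32(unclass(config))),
              class = "phr_flow")
  })
}

as_row_matrix <- function(x, d) {
  if (is.null(dim(x))) matrix(x, ncol = d, byrow = length(x) == d) else as.matrix(x)
}

.affine_fwd <- function(X, C, p, alpha, psi) {
  d <- ncol(X)
  net <- mlp_fwd(p, C, "gelu")
  a <- net$out[, seq_len(d), drop = FALSE]
  bb <- net$out[, d + seq_len(d), drop = FALSE]
  pf <- psi_fun(psi)
  ap <- alpha * pf$f(a)
  E <- exp(ap)
  list(U = E * X + bb, logdet = rowSums(ap),
       cache = list(net = net, a = a, ap = ap, E = E, X = X))
}

#' Conditional affine transformation
#'
#' `u = exp(a') * x + b` with `(a, b) = SPLIT(s(c))` and `a' = alpha * psi(a)`,
#' where `s` is a linear--GeLU--linear network of the condition only. This is
#' the single layer of the flow that changes volume; its log-determinant is
#' `sum(a')` and depends only on the condition.
#'
#' @param x input vector or matrix (rows = samples).
#' @param c condition vector or matrix.
#' @param params affine layer parameters (`W1`, `b1`, `W2`, `b2`).
#' @param alpha clamp constant.
#' @param psi clamp activation name.
#' @return list with `u` and per-row `logdet`.
#' @export
affine_forward <- function(x, c, params, alpha = 1.9, psi = "tanh") {
  X <- as_row_matrix(x, length(x))
  C <- if (is.null(dim(c))) matrix(c, nrow = nrow(X), ncol = length(c), byrow = TRUE)
       else as.matrix(c)
  r <- .affine_fwd(X, C, params, alpha, psi)
  list(u = r$U, logdet = r$logdet)
}

.gin_fwd <- function(X, C, ps, pt, active, passive) {
  Q <- cbind(X[, passive, drop = FALSE], C)
  sn <- mlp_fwd(ps, Q, "relu")
  raw <- tanh(sn$out)
  cent <- raw - rowMeans(raw)        # zero-sum log-scales: |det J| = 1
  tn <- mlp_fwd(pt, Q, "relu")
  E <- exp(cent)
  U <- X
  U[, active] <- X[, active] * E + tn$out
  list(U = U,
       cache = list(s = sn, t = tn, raw = raw, cent = cent, E = E,
                    X1 = X[, active, drop = FALSE]))
}

.gin_inv <- function(U, C, ps, pt, active, passive) {
  Q <- cbind(U[, passive, drop = FALSE], C)
  raw <- tanh(mlp_fwd(ps, Q, "relu")$out)
  cent <- raw - rowMeans(raw)
  tout <- mlp_fwd(pt, Q, "relu")$out
  X <- U
  X[, active] <- (U[, active] - tout) * exp(-cent)
  X
}

#' Conditional GIN coupling layer
#'
#' The active half is rescaled and shifted conditionally on the passive half
#' and the condition: `u1 = x1 * exp(s~) + t(x2, c)`, `u2 = x2`, where the raw
#' scales `tanh(s(x2, c))` are re-centered to sum to zero across the active
#' coordinates before exponentiation. The layer is therefore exactly
#' volume-preserving (`|det J| = 1`, log-determinant 0).
#'
#' @param x input vector or matrix.
#' @param c condition vector or matrix.
#' @param params list with subnetworks `s` and `t` (each `W1,b1,W2,b2`).
#' @param active,passive integer index sets of the two halves.
#' @return list with `u` and `logdet` (always 0).
#' @export
gin_coupling_forward <- function(x, c, params, active, passive) {
  X <- as_row_matrix(x, length(x))
  C <- if (is.null(dim(c))) matrix(c, nrow = nrow(X), ncol = length(c), byrow = TRUE)
       else as.matrix(c)
  r <- .gin_fwd(X, C, params$s, params$t, active, passive)
  list(u = r$U, logdet = rep(0, nrow(X)))
}

.block_fwd <- function(X, C, blk, perm, d1, d2, keep_cache = FALSE) {
  d <- d1 + d2
  a1 <- seq_len(d1); p1 <- d1 + seq_len(d2)
  g1 <- .gin_fwd(X, C, blk$s1, blk$t1, a1, p1)
  g2 <- .gin_fwd(g1$U, C, blk$s2, blk$t2, p1, a1)
  Y <- add_bias(g2$U[, perm$perm, drop = FALSE], blk$t_global)
  list(U = Y, cache = if (keep_cache) list(g1 = g1$cache, g2 = g2$cache))
}

.block_inv <- function(Y, C, blk, perm, d1, d2) {
  d <- d1 + d2
  a1 <- seq_len(d1); p1 <- d1 + seq_len(d2)
  U <- add_bias(Y, -blk$t_global)[, perm$invperm, drop = FALSE]
  U <- .gin_inv(U, C, blk$s2, blk$t2, p1, a1)
  .gin_inv(U, C, blk$s1, blk$t1, a1, p1)
}

#' One coupling block: two GIN layers, permutation, global offset
#'
#' Applies two GIN coupling layers with swapped active/passive roles, then a
#' fixed permutation `R` and the trainable global offset: `R Coupling(x, c) +
#' t_global`. The block contributes zero log-determinant.
#'
#' @param x,c input and condition (vectors or row matrices).
#' @param state a `phr_flow`.
#' @param block index of the block to apply.
#' @return list with `u` and `logdet` (0).
#' @export
block_forward <- function(x, c, state, block = 1L) {
  X <- as_row_matrix(x, length(x))
  C <- if (is.null(dim(c))) matrix(c, nrow = nrow(X), ncol = length(c), byrow = TRUE)
       else as.matrix(c)
  r <- .block_fwd(X, C, state$par$blocks[[block]], state$perms[[block]],
                  state$d1, state$d2)
  list(u = r$U, logdet = rep(0, nrow(X)))
}

.flow_fwd <- function(X, C, state, keep_cache = FALSE) {
  cfg <- state$config
  af <- .affine_fwd(X, C, state$par$affine, cfg$alpha, cfg$psi)
  U <- af$U
  bcaches <- if (keep_cache) vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    r <- .block_fwd(U, C, state$par$blocks[[b]], state$perms[[b]],
                    state$d1, state$d2, keep_cache)
    U <- r$U
    if (keep_cache) bcaches[[b]] <- r$cache
  }
  list(z = U, logdet = af$logdet,
       cache = if (keep_cache) list(affine = af$cache, blocks = bcaches))
}

#' Map data to the latent space
#'
#' Full forward pass `z = f(x | c)`: conditional affine transformation
#' followed by the stack of coupling blocks. The total log-determinant is the
#' affine layer's (all coupling blocks are volume-preserving).
#'
#' @param x feature matrix (rows = samples) or a single vector.
#' @param c condition matrix or vector.
#' @param state a `phr_flow`.
#' @return list with `z` and per-row `logdet`.
#' @export
flow_forward <- function(x, c, state) {
  X <- as_row_matrix(x, state$config$d)
  C <- if (is.null(dim(c))) matrix(c, nrow = nrow(X), ncol = length(c), byrow = TRUE)
       else as.matrix(c)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite input to flow_forward")
  r <- .flow_fwd(X, C, state)
  list(z = r$z, logdet = r$logdet)
}

#' Invert the flow
#'
#' @param z latent matrix or vector.
#' @param c condition matrix or vector.
#' @param state a `phr_flow`.
#' @return matrix `x` with `flow_forward(x, c, state)$z == z` up to numerical
#'   round-off.
#' @export
flow_inverse <- function(z, c, state) {
  cfg <- state$config
  Z <- as_row_matrix(z, cfg$d)
  C <- if (is.null(dim(c))) matrix(c, nrow = nrow(Z), ncol = length(c), byrow = TRUE)
       else as.matrix(c)
  U <- Z
  for (b in rev(seq_len(cfg$n_blocks)))
    U <- .block_inv(U, C, state$par$blocks[[b]], state$perms[[b]],
                    state$d1, state$d2)
  af <- .affine_fwd(matrix(0, nrow(U), cfg$d), C, state$par$affine,
                    cfg$alpha, cfg$psi)
  (U - af$cache$net$out[, cfg$d + seq_len(cfg$d), drop = FALSE]) / af$cache$E
}

#' Exact log-likelihood under the flow
#'
#' `log p(x | c) = log p_Z(f(x | c)) + log |det df/dx|` with `p_Z` the
#' diagonal-normal base distribution.
#'
#' @inheritParams flow_forward
#' @return numeric vector of per-row log-likelihoods.
#' @export
log_likelihood <- function(x, c, state) {
  r <- flow_forward(x, c, state)
  mu <- state$par$base$mu; sig <- exp(state$par$base$log_sigma)
  Z <- r$z
  ll <- -0.5 * log(2 * pi) * ncol(Z) - sum(state$par$base$log_sigma) -
    0.5 * rowSums(sweep(sweep(Z, 2, mu), 2, sig, "/")^2)
  ll + r$logdet
}

#' Anomaly score of latent outputs
#'
#' `score(z) = -exp(-||z||^2 / 2)`, negatively proportional to the standard
#' normal base density at `z`: strictly increasing in `||z||`, with range
#' `[-1, 0)`. Higher scores indicate more anomalous (disease-like) samples.
#'
#' @param z latent matrix (rows = samples) or vector.
#' @return numeric vector of scores.
#' @export
anomaly_score <- function(z) {
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  -exp(-0.5 * rowSums(Z^2))
}

#' Sample from the fitted conditional density
#'
#' Draws latent points from the base distribution and maps them through the
#' inverse flow at the supplied conditions.
#'
#' @param n number of samples.
#' @param c condition vector (recycled) or matrix with `n` rows.
#' @param state a `phr_flow`.
#' @param seed integer seed.
#' @return matrix of samples in feature space.
#' @export
sample_flow <- function(n, c, state, seed = 1L) {
  d <- state$config$d
  mu <- state$par$base$mu; sig <- exp(state$par$base$log_sigma)
  Z <- with_seed(seed,
    sweep(sweep(matrix(stats::rnorm(n * d), n, d), 2, sig, "*"), 2, mu, "+"))
  C <- if (is.null(dim(c))) matrix(c, nrow = n, ncol = length(c), byrow = TRUE)
       else as.matrix(c)
  flow_inverse(Z, C, state)
}

#' @export
print.phr_flow <- function(x, ...) {
  cfg <- x$config
  cat("<phr_flow> d = ", cfg$d, ", condition dim = ", cfg$d_c, ", ",
      cfg$n_blocks, " coupling blocks (hidden ", cfg$hidden, ")\n", sep = "")
  cat("  alpha = ", cfg$alpha, ", psi = ", cfg$psi,
      ", learnable base: ", cfg$learnable_base, "\n", sep = "")
  invisible(x)
}
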
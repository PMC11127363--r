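# Analytic gradients of the mean negative log-likelihood with respect to
# every flow parameter (reverse-mode, hand-derived; verified against central
# finite differences in the test suite).

zero_like <- function(par) rapply(par, function(x) { x[] <- 0; x }, how = "replace")

.gin_bwd <- function(cache, ps, pt, dU, active, passive) {
  dU1 <- dU[, active, drop = FALSE]
  dX1 <- dU1 * cache$E
  dcent <- dU1 * cache$X1 * cache$E
  draw <- dcent - rowMeans(dcent)            # through the zero-sum re-centering
  dS <- draw * (1 - cache$raw^2)
  bs <- mlp_bwd(ps, cache$s, dS, "relu")
  bt <- mlp_bwd(pt, cache$t, dU1, "relu")
  dQ <- bs$dQ + bt$dQ
  d2 <- length(passive)
  dX <- dU
  dX[, active] <- dX1
  dX[, passive] <- dU[, passive, drop = FALSE] + dQ[, seq_len(d2), drop = FALSE]
  list(dX = dX, gs = bs$g, gt = bt$g)
}

# Mean NLL of a batch plus gradients in the same nested shape as state$par.
nll_grad <- function(state, X, C) {
  cfg <- state$config
  fw <- .flow_fwd(X, C, state, keep_cache = TRUE)
  Z <- fw$z
  n <- nrow(X); d <- ncol(X)
  mu <- state$par$base$mu
  ls <- state$par$base$log_sigma
  sig <- exp(ls)
  Rz <- sweep(Z, 2, mu)
  Rs <- sweep(Rz, 2, sig, "/")
  ll <- -0.5 * d * log(2 * pi) - sum(ls) - 0.5 * rowSums(Rs^2) + fw$logdet
  loss <- -mean(ll)
  if (!is.finite(loss))
    stop("non-finite training loss (mean NLL = ", loss, ")")

  dZ <- sweep(Rs, 2, sig, "/") / n
  g_base <- list(mu = -colSums(sweep(Rz, 2, sig^2, "/")) / n,
                 log_sigma = colSums(1 - Rs^2) / n)

  d1 <- state$d1; d2 <- state$d2
  a1 <- seq_len(d1); p1 <- d1 + seq_len(d2)
  g_blocks <- vector("list", cfg$n_blocks)
  dY <- dZ
  for (b in rev(seq_len(cfg$n_blocks))) {
    blk <- state$par$blocks[[b]]
    cache <- fw$cache$blocks[[b]]
    g_tg <- colSums(dY)
    dU <- dY[, state$perms[[b]]$invperm, drop = FALSE]
    b2 <- .gin_bwd(cache$g2, blk$s2, blk$t2, dU, p1, a1)
    b1 <- .gin_bwd(cache$g1, blk$s1, blk$t1, b2$dX, a1, p1)
    g_blocks[[b]] <- list(s1 = b1$gs, t1 = b1$gt, s2 = b2$gs, t2 = b2$gt,
                          t_global = g_tg)
    dY <- b1$dX
  }

  ac <- fw$cache$affine
  dldet <- rep(-1 / n, n)
  dap <- dY * ac$X * ac$E + matrix(dldet, n, d)
  pf <- psi_fun(cfg$psi)
  da <- dap * cfg$alpha * pf$df(ac$a)
  dS2 <- cbind(da, dY)
  g_affine <- mlp_bwd(state$par$affine, ac$net, dS2, "gelu")$g

  if (!cfg$learnable_base) g_base <- list(mu = rep(0, d), log_sigma = rep(0, d))
  list(loss = loss,
       grads = list(affine = g_affine, blocks = g_blocks, base = g_base))
}
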
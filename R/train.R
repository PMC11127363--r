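# Maximum-likelihood training of the flow on unaffected samples only:
# Adam, cosine-annealing-with-warm-restarts learning rate, gradient
# clipping, and optional AltUB alternation for the base distribution.

#' Training configuration
#'
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param lr_max,lr_min peak and floor learning rates of the schedule.
#' @param cycle restart cycle length in epochs.
#' @param warmup linear warmup epochs at the start of each cycle.
#' @param altub if `TRUE` (requires a flow with `learnable_base = TRUE`), the
#'   base-distribution parameters receive their own update every
#'   `altub_period` optimizer steps, and only then — the AltUB alternation.
#'   Off by default: the alternation can destabilize training on some data.
#' @param altub_period steps between base-distribution updates.
#' @param altub_lr learning rate of the base updates.
#' @param clip global gradient-norm clip.
#' @param seed seed for initialization and batch shuffling.
#' @return an object of class `phr_train_config`.
#' @export
train_config <- function(epochs = 400L, batch_size = 64L, lr_max = 3e-3,
                         lr_min = 1e-5, cycle = 50L, warmup = 5L,
                         altub = FALSE, altub_period = 4L, altub_lr = 1e-2,
                         clip = 2, seed = 1L) {
  if (lr_max <= 0 || lr_min <= 0) stop("learning rates must be positive")
  if (altub_period < 1) stop("altub_period must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_max = lr_max, lr_min = lr_min, cycle = as.integer(cycle),
                 warmup = as.integer(warmup), altub = altub,
                 altub_period = as.integer(altub_period), altub_lr = altub_lr,
                 clip = clip, seed = as.integer(seed)),
            class = "phr_train_config")
}

#' Cosine-annealing-with-warm-restarts learning rate
#'
#' Within each cycle of `cycle` epochs the rate rises linearly from `lr_min`
#' to `lr_max` over the first `warmup` epochs, then follows a half cosine
#' back down to `lr_min`; the schedule restarts every cycle.
#'
#' @param epoch epoch number(s), 1-based.
#' @inheritParams train_config
#' @return learning rate(s).
#' @export
cosine_warmup_lr <- function(epoch, lr_max = 3e-3, lr_min = 1e-5,
                             cycle = 50L, warmup = 5L) {
  t <- (epoch - 1) %% cycle
  ifelse(t < warmup,
         lr_min + (lr_max - lr_min) * (t + 1) / warmup,
         lr_min + 0.5 * (lr_max - lr_min) *
           (1 + cos(pi * (t - warmup) / max(cycle - warmup, 1))))
}

#' Mean negative log-likelihood of a batch
#'
#' @param x,c feature and condition matrices.
#' @param state a `phr_flow`.
#' @return the mean of `-log_likelihood` over rows; errors on a non-finite
#'   result.
#' @export
nll_loss <- function(x, c, state) {
  if (NROW(x) == 0) stop("empty batch")
  v <- -mean(log_likelihood(x, c, state))
  if (!is.finite(v)) stop("non-finite training loss (mean NLL = ", v, ")")
  v
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the conditional normalizing flow
#'
#' Maximum-likelihood (minimum mean NLL) optimization on unaffected samples
#' only: if `labels` are supplied, any affected row aborts with a
#' protocol-violation error — the semi-supervised contract is enforced, not
#' assumed. Training is deterministic for a fixed seed. The returned state is
#' the epoch checkpoint with the lowest training (or, when supplied,
#' validation) NLL.
#'
#' @param x training feature matrix.
#' @param cond training condition matrix (age, gender).
#' @param config a `phr_flow_config` (or an existing `phr_flow` to continue).
#' @param tc a `phr_train_config`.
#' @param labels optional 0/1 labels of the training rows, checked to be all
#'   zero.
#' @param x_val,c_val optional validation set used for checkpoint selection.
#' @return list with `state` (the best `phr_flow`) and `history`
#'   (data.frame: epoch, nll, val_nll, lr).
#' @export
train_flow <- function(x, cond, config, tc = train_config(), labels = NULL,
                       x_val = NULL, c_val = NULL) {
  x <- as.matrix(x); cond <- as.matrix(cond)
  if (!is.null(labels) && any(labels == 1, na.rm = TRUE))
    stop("protocol violation: affected samples present in the training set")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite training features")
  state <- if (inherits(config, "phr_flow")) config else init_flow(config)
  if (ncol(x) != state$config$d)
    stop("feature dimension ", ncol(x), " does not match flow d = ",
         state$config$d)
  cfg <- state$config
  if (tc$altub && !cfg$learnable_base)
    stop("AltUB requires a flow configured with learnable_base = TRUE")
  n <- nrow(x)
  theta <- flatten_params(state$par)
  skel <- state$par
  base_idx <- flat_index_of(state$par, "base")
  ad <- adam_init(length(theta))
  ad_base <- adam_init(length(base_idx))
  hist <- data.frame(epoch = seq_len(tc$epochs), nll = NA_real_,
                     val_nll = NA_real_, lr = NA_real_)
  best <- Inf; best_theta <- theta
  step <- 0L
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      lr <- cosine_warmup_lr(ep, tc$lr_max, tc$lr_min, tc$cycle, tc$warmup)
      idx <- sample.int(n)
      starts <- seq(1L, n, by = tc$batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        bi <- idx[s0:min(s0 + tc$batch_size - 1L, n)]
        state$par <- unflatten_params(theta, skel)
        gr <- nll_grad(state, x[bi, , drop = FALSE], cond[bi, , drop = FALSE])
        ep_loss <- ep_loss + gr$loss * length(bi)
        g <- flatten_params(gr$grads)
        if (tc$altub) g[base_idx] <- 0   # base moves only on AltUB steps
        gn <- sqrt(sum(g^2))
        if (gn > tc$clip) g <- g * (tc$clip / gn)
        up <- adam_step(theta, g, ad, lr)
        theta <- up$theta; ad <- up$st
        step <- step + 1L
        if (tc$altub && step %% tc$altub_period == 0L) {
          gb <- flatten_params(gr$grads)[base_idx]
          upb <- adam_step(theta[base_idx], gb, ad_base, tc$altub_lr)
          theta[base_idx] <- upb$theta; ad_base <- upb$st
        }
      }
      hist$nll[ep] <- ep_loss / n
      hist$lr[ep] <- lr
      crit <- hist$nll[ep]
      if (!is.null(x_val)) {
        state$par <- unflatten_params(theta, skel)
        hist$val_nll[ep] <- nll_loss(x_val, c_val, state)
        crit <- hist$val_nll[ep]
      }
      if (crit < best) { best <- crit; best_theta <- theta }
    }
  })
  state$par <- unflatten_params(best_theta, skel)
  list(state = state, history = hist)
}
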
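test_that("conditional affine transformation matches its closed form", {
  # hand-built parameters: zero weights, bias giving a' = ln 2, b = 1 at d = 1
  p <- list(W1 = matrix(0, 4, 2), b1 = rep(0, 4),
            W2 = matrix(0, 2, 4), b2 = c(atanh(log(2)), 1))
  r <- affine_forward(3, c(0.5, 1), p, alpha = 1, psi = "tanh")
  expect_equal(drop(r$u), 7)
  expect_equal(r$logdet, log(2))
  # zero condition network: identity with zero logdet
  p0 <- list(W1 = matrix(0, 4, 2), b1 = rep(0, 4),
             W2 = matrix(0, 6, 4), b2 = rep(0, 6))
  x <- c(-1, 0.3, 2)
  r0 <- affine_forward(x, c(1, 0), p0, alpha = 1.9)
  expect_equal(drop(r0$u), x)
  expect_equal(r0$logdet, 0)
})

test_that("affine log-determinant equals the numerical Jacobian log|det|", {
  st <- random_flow_state(4, n_blocks = 1, seed = 21)
  cc <- c(0.7, 1)
  f <- function(x) drop(affine_forward(x, cc, st$par$affine, alpha = 1.9)$u)
  x0 <- c(0.2, -1, 0.5, 0.1)
  an <- affine_forward(x0, cc, st$par$affine, alpha = 1.9)$logdet
  expect_equal(an, numeric_logdet(f, x0), tolerance = 1e-4)
})

test_that("GIN coupling preserves volume exactly and leaves the passive half intact", {
  st <- random_flow_state(6, n_blocks = 1, seed = 5)
  prm <- list(s = st$par$blocks[[1]]$s1, t = st$par$blocks[[1]]$t1)
  cc <- c(-0.3, 1)
  x0 <- c(0.4, -0.2, 1.1, 0.3, -0.8, 0.05)
  r <- gin_coupling_forward(x0, cc, prm, active = 1:3, passive = 4:6)
  expect_identical(drop(r$u)[4:6], x0[4:6])   # passive half bit-exact
  expect_equal(r$logdet, rep(0, 1))
  f <- function(x) drop(gin_coupling_forward(x, cc, prm, 1:3, 4:6)$u)
  expect_lt(abs(numeric_logdet(f, x0)), 1e-6)
  # zero subnetworks: exact identity
  z <- list(s = list(W1 = matrix(0, 4, 5), b1 = rep(0, 4),
                     W2 = matrix(0, 3, 4), b2 = rep(0, 3)),
            t = list(W1 = matrix(0, 4, 5), b1 = rep(0, 4),
                     W2 = matrix(0, 3, 4), b2 = rep(0, 3)))
  expect_equal(drop(gin_coupling_forward(x0, cc, z, 1:3, 4:6)$u), x0)
})

test_that("blocks and the full stack invert to machine precision", {
  for (d in c(5, 12, 48)) {
    st <- random_flow_state(d, n_blocks = 3, seed = d)
    with_seed(d + 1, {
      X <- matrix(stats::rnorm(100 * d), 100, d)
      C <- cbind(stats::runif(100, -1, 1), stats::rbinom(100, 1, 0.5))
    })
    fw <- flow_forward(X, C, st)
    expect_lt(max(abs(flow_inverse(fw$z, C, st) - X)), 1e-5)
    # inverse-then-forward too
    Xi <- flow_inverse(X, C, st)
    expect_lt(max(abs(flow_forward(Xi, C, st)$z - X)), 1e-5)
  }
})

test_that("a fresh state is the (permuted) identity with zero logdet", {
  cfg <- flow_config(d = 7, n_blocks = 2, hidden = 8, seed = 2)
  st <- init_flow(cfg)
  with_seed(3, {
    X <- matrix(stats::rnorm(20 * 7), 20, 7)
    C <- matrix(stats::rnorm(40), 20, 2)
  })
  fw <- flow_forward(X, C, st)
  expect_equal(fw$logdet, rep(0, 20))
  comp <- st$perms[[1]]$perm[st$perms[[2]]$perm]  # perm2 after perm1
  expect_equal(fw$z, X[, comp, drop = FALSE], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(flow_forward(rep(c(1, NA), length.out = 7), C[1, ], st),
               "non-finite")
})

test_that("total log-determinant matches the numerical Jacobian of the stack", {
  st <- random_flow_state(6, n_blocks = 2, seed = 8)
  cc <- c(0.4, 0)
  x0 <- with_seed(9, stats::rnorm(6))
  f <- function(x) drop(flow_forward(x, cc, st)$z)
  an <- flow_forward(x0, cc, st)$logdet
  expect_equal(an, numeric_logdet(f, x0), tolerance = 1e-3)
})

test_that("conditioning changes the map without breaking invertibility", {
  st <- random_flow_state(6, n_blocks = 2, seed = 13)
  x0 <- with_seed(1, stats::rnorm(6))
  z1 <- flow_forward(x0, c(0, 0), st)$z
  z2 <- flow_forward(x0, c(1.5, 1), st)$z
  expect_gt(max(abs(z1 - z2)), 1e-3)
  for (cc in list(c(0, 0), c(1.5, 1), c(-2, 0))) {
    z <- flow_forward(x0, cc, st)$z
    expect_lt(max(abs(flow_inverse(z, cc, st) - x0)), 1e-6)
    f <- function(x) drop(flow_forward(x, cc, st)$z)
    expect_equal(flow_forward(x0, cc, st)$logdet, numeric_logdet(f, drop(x0)),
                 tolerance = 1e-3)
  }
})

test_that("log-likelihood has its gaussian closed form under the identity flow", {
  cfg <- flow_config(d = 2, n_blocks = 1, hidden = 4, seed = 1)
  st <- init_flow(cfg)
  expect_equal(log_likelihood(c(0, 0), c(0, 0), st), -log(2 * pi))
  expect_equal(log_likelihood(c(1, 0), c(0.3, 1), st), -log(2 * pi) - 0.5)
})

test_that("mean log-likelihood of flow samples equals the pushforward entropy", {
  st <- random_flow_state(3, n_blocks = 2, seed = 17, sd = 0.2)
  cc <- c(0.5, 1)
  Xs <- sample_flow(20000, cc, st, seed = 4)
  m_ll <- mean(log_likelihood(Xs, cc, st))
  # H[X] = H[Z] - logdet(c); logdet is condition-only, hence constant here
  ld <- flow_forward(matrix(0, 1, 3), cc, st)$logdet
  expected <- -(3 / 2 * log(2 * pi * exp(1)) - ld)
  expect_equal(m_ll, expected, tolerance = 0.02)
})

test_that("the modeled density integrates to one", {
  st <- random_flow_state(2, n_blocks = 2, seed = 23, sd = 0.15, alpha = 0.5)
  cc <- c(0.2, 1)
  h <- 0.05
  g <- seq(-8, 8, by = h)
  grid <- as.matrix(expand.grid(x1 = g, x2 = g))
  ll <- log_likelihood(grid, cc, st)
  mass <- sum(exp(ll)) * h^2
  expect_equal(mass, 1, tolerance = 0.02)
})

test_that("anomaly score is the negated base density kernel", {
  expect_equal(anomaly_score(c(0, 0, 0)), -1)
  z2 <- c(1, 1)  # squared norm 2
  expect_equal(anomaly_score(z2), -exp(-1))
  with_seed(6, {
    Z <- matrix(stats::rnorm(200 * 4), 200, 4)
    s <- anomaly_score(Z)
    expect_true(all(s >= -1 & s < 0))
    dens <- exp(-0.5 * rowSums(Z^2))
    expect_equal(order(s), order(-dens))
  })
})

test_that("analytic parameter gradients match central finite differences", {
  st <- random_flow_state(4, n_blocks = 2, hidden = 6, seed = 31,
                          learnable_base = TRUE)
  st$par$base <- list(mu = with_seed(1, stats::rnorm(4, sd = 0.2)),
                      log_sigma = with_seed(2, stats::rnorm(4, sd = 0.2)))
  with_seed(3, {
    X <- matrix(stats::rnorm(8 * 4), 8, 4)
    C <- matrix(stats::rnorm(16), 8, 2)
  })
  gr <- phrflow:::nll_grad(st, X, C)
  th <- phrflow:::flatten_params(st$par)
  g_an <- phrflow:::flatten_params(gr$grads)
  eps <- 1e-5
  idx <- with_seed(4, sort(sample(length(th), 80)))
  g_num <- vapply(idx, function(i) {
    pl <- th; pl[i] <- pl[i] + eps
    mi <- th; mi[i] <- mi[i] - eps
    sp <- st; sp$par <- phrflow:::unflatten_params(pl, st$par)
    sm <- st; sm$par <- phrflow:::unflatten_params(mi, st$par)
    (phrflow:::nll_grad(sp, X, C)$loss - phrflow:::nll_grad(sm, X, C)$loss) /
      (2 * eps)
  }, 0)
  expect_lt(max(abs(g_an[idx] - g_num)), 1e-6)
})

test_that("flow states survive a JSON round trip and reject config tampering", {
  st <- random_flow_state(5, n_blocks = 2, seed = 41)
  tmp <- tempfile(fileext = ".json")
  save_flow_state(st, tmp)
  st2 <- load_flow_state(tmp)
  with_seed(5, {
    X <- matrix(stats::rnorm(30 * 5), 30, 5)
    C <- matrix(stats::rnorm(60), 30, 2)
  })
  expect_equal(flow_forward(X, C, st2)$z, flow_forward(X, C, st)$z,
               tolerance = 1e-12)
  txt <- readLines(tmp)
  txt <- sub('"alpha":1.9', '"alpha":1.5', txt, fixed = TRUE)
  writeLines(txt, tmp)
  expect_error(load_flow_state(tmp), "hash")
})
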
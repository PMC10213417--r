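test_that("trace_step follows the linear recurrence and zero fixed point", {
  p <- trace_params(alpha_x = 0.5, beta = 1)
  expect_identical(trace_step(0, 0, p), 0)
  x <- trace_step(0, 1, p)          # spike at step 0
  expect_equal(x, 1.0)
  x <- trace_step(x, 1, p)          # spike at step 1
  expect_equal(x, 1.5)
  x <- trace_step(x, 0, p)
  expect_equal(x, 0.75)
})

test_that("saturating trace is soft-bounded by x_max", {
  p <- trace_params(alpha_x = 0.9, beta = 0.5, x_max = 2,
                    variant = "saturating")
  x <- 0
  for (i in 1:500) {
    x <- trace_step(x, 1, p)
    expect_lte(x, 2)
    expect_gte(x, 0)
  }
  # converges to beta * x_max / (1 - alpha + beta), below the bound
  expect_equal(x, 0.5 * 2 / 0.6, tolerance = 1e-6)
})

test_that("slow trace uses its own retention", {
  p <- trace_params(alpha_x = 0.5, alpha_tau = 0.9, beta = 1)
  tr <- trace_state(2, 3)
  tr <- advance_traces(tr, c(1, 0), c(1, 1, 0), p)
  tr2 <- advance_traces(tr, c(0, 0), c(0, 0, 0), p)
  expect_equal(tr2$x_pre, 0.5 * tr$x_pre)
  expect_equal(tr2$x_post_slow, 0.9 * tr$x_post_slow)
  expect_equal(tr2$x_post_slow_prev, tr$x_post_slow)
})

test_that("weight dependence interpolates additive and multiplicative", {
  set.seed(1)
  W <- matrix(runif(12, 0.1, 0.9), 3, 4)
  base <- stdp_params(eta_plus = 0.2, eta_minus = 0.1, w_min = 0, w_max = 1)
  add <- weight_dependence(W, base)
  expect_identical(add$A_plus, matrix(0.2, 3, 4))
  mult <- weight_dependence(W, modifyList(base, list(dependence = "multiplicative")))
  expect_equal(mult$A_plus, 0.2 * (1 - W))
  expect_equal(mult$A_minus, 0.1 * W)
  # example: eta+ 0.2, w_max 1, W 0.5 -> A+ = 0.1
  expect_equal(weight_dependence(matrix(0.5), modifyList(
    base, list(dependence = "multiplicative")))$A_plus[1], 0.1)
  p0 <- modifyList(base, list(dependence = "power", mu = 0))
  p1 <- modifyList(base, list(dependence = "power", mu = 1))
  expect_equal(weight_dependence(W, p0), add)
  expect_equal(weight_dependence(W, p1), mult)
  # continuity in mu and clamped domain outside the soft bounds
  mus <- seq(0, 1, by = 0.1)
  A <- vapply(mus, function(m) {
    weight_dependence(W, modifyList(base, list(dependence = "power",
                                               mu = m)))$A_plus[1, 1]
  }, numeric(1))
  expect_true(all(abs(diff(A)) < 0.2))
  out <- weight_dependence(matrix(c(-0.5, 1.5), 1, 2),
                           modifyList(base, list(dependence = "power",
                                                 mu = 0.5)))
  expect_false(any(is.nan(out$A_plus)))
  expect_false(any(is.nan(out$A_minus)))
})

test_that("pair STDP matches its closed form and is linear in the rates", {
  tr <- trace_state(2, 2)
  tr$x_pre <- c(1.5, 0); tr$x_post <- c(0.3, 0.3)
  W <- matrix(0.5, 2, 2)
  p <- stdp_params(eta_plus = 0.1, eta_minus = 0.05)
  d <- pair_stdp_delta(tr, s_pre = c(0, 0), s_post = c(1, 0), W, p)
  expect_equal(d$d_plus[1, 1], 0.1 * 1.5)   # A+ x_pre s_post
  expect_equal(d$d_plus[2, ], c(0, 0))
  expect_identical(d$d_minus, matrix(0, 2, 2))  # no presynaptic spikes
  d0 <- pair_stdp_delta(tr, c(0, 0), c(0, 0), W, p)
  expect_identical(d0$delta, matrix(0, 2, 2))
  # linearity in eta_plus and eta_minus separately
  s_pre <- c(1, 0); s_post <- c(1, 1)
  d1 <- pair_stdp_delta(tr, s_pre, s_post, W, stdp_params(0.1, 0.05))
  d2 <- pair_stdp_delta(tr, s_pre, s_post, W, stdp_params(0.3, 0.05))
  d3 <- pair_stdp_delta(tr, s_pre, s_post, W, stdp_params(0.1, 0.15))
  expect_equal(d2$d_plus, 3 * d1$d_plus)
  expect_equal(d2$d_minus, d1$d_minus)
  expect_equal(d3$d_minus, 3 * d1$d_minus)
  expect_equal(d3$d_plus, d1$d_plus)
})

test_that("two-spike protocol shows the Hebbian timing window", {
  run_protocol <- function(pre_t, post_t, T_len = 6) {
    p <- trace_params(alpha_x = 0.8, beta = 1)
    sp <- stdp_params(eta_plus = 0.1, eta_minus = 0.1)
    tr <- trace_state(1, 1)
    W <- matrix(0.5, 1, 1)
    total <- 0
    for (t in seq_len(T_len)) {
      s_pre <- as.numeric(t == pre_t)
      s_post <- as.numeric(t == post_t)
      tr <- advance_traces(tr, s_pre, s_post, p)
      total <- total + pair_stdp_delta(tr, s_pre, s_post, W, sp)$delta[1, 1]
    }
    total
  }
  expect_gt(run_protocol(pre_t = 2, post_t = 3), 0)  # pre before post: LTP
  expect_lt(run_protocol(pre_t = 3, post_t = 2), 0)  # post before pre: LTD
  # at lag 0 the updated-traces convention makes the terms cancel exactly
  expect_equal(run_protocol(2, 2), 0)
})

test_that("iterative pair STDP equals the all-pairs decay-kernel sum", {
  # brute-force oracle: every (pre s, post t) spike pair contributes
  # eta * beta * alpha^(t - s) potentiation when s <= t, and symmetric
  # depression when t <= s (equal times appear in both terms)
  all_pairs <- function(s_pre, s_post, alpha, beta, ep, em) {
    n_pre <- nrow(s_pre); n_post <- nrow(s_post); T_len <- ncol(s_pre)
    dW <- matrix(0, n_post, n_pre)
    for (i in seq_len(n_pre)) for (j in seq_len(n_post)) {
      for (t in seq_len(T_len)) {
        for (s in seq_len(T_len)) {
          if (s <= t && s_pre[i, s] == 1 && s_post[j, t] == 1) {
            dW[j, i] <- dW[j, i] + ep * beta * alpha^(t - s)
          }
          if (t <= s && s_pre[i, s] == 1 && s_post[j, t] == 1) {
            dW[j, i] <- dW[j, i] - em * beta * alpha^(s - t)
          }
        }
      }
    }
    dW
  }
  set.seed(11)
  for (rep in 1:5) {
    n_pre <- sample(2:4, 1); n_post <- sample(2:4, 1)
    T_len <- sample(10:20, 1)
    s_pre <- random_raster(n_pre, T_len, 0.3)
    s_post <- random_raster(n_post, T_len, 0.3)
    alpha <- runif(1, 0.5, 0.95); beta <- runif(1, 0.5, 1.5)
    tp <- trace_params(alpha_x = alpha, beta = beta)
    sp <- stdp_params(eta_plus = 0.07, eta_minus = 0.03)
    tr <- trace_state(n_pre, n_post)
    W <- matrix(0.5, n_post, n_pre)
    acc <- matrix(0, n_post, n_pre)
    for (t in seq_len(T_len)) {
      tr <- advance_traces(tr, s_pre[, t], s_post[, t], tp)
      acc <- acc + pair_stdp_delta(tr, s_pre[, t], s_post[, t], W, sp)$delta
    }
    oracle <- all_pairs(s_pre, s_post, alpha, beta, 0.07, 0.03)
    expect_equal(acc, oracle, tolerance = 1e-10)
  }
})

test_that("triplet rule gates LTP on the post spike and collapses to pair", {
  tr <- trace_state(2, 2)
  tr$x_pre <- c(1, 0.5); tr$x_post <- c(0.2, 0.2)
  tr$x_post_slow_prev <- c(0.5, 0.5)
  W <- matrix(0.5, 2, 2)
  p <- stdp_params(eta_plus = 0.1, eta_minus = 0.05, rule = "triplet")
  d <- triplet_stdp_delta(tr, c(0, 0), c(0, 1), W, p)
  expect_equal(d$d_plus[1, ], c(0, 0))            # no post spike, no LTP
  expect_equal(d$d_plus[2, 1], 0.1 * 1 * 0.5)     # A+ x_pre x_slow_prev s_post
  # slow trace pinned at 1 reproduces the pair rule on random rasters
  set.seed(21)
  s_pre <- random_raster(3, 15, 0.4); s_post <- random_raster(2, 15, 0.4)
  tp <- trace_params(alpha_x = 0.7, beta = 0.8)
  pp <- stdp_params(eta_plus = 0.04, eta_minus = 0.09)
  pt <- modifyList(pp, list(rule = "triplet"))
  trp <- trt <- trace_state(3, 2)
  W <- matrix(0.5, 2, 3)
  for (t in 1:15) {
    trp <- advance_traces(trp, s_pre[, t], s_post[, t], tp)
    trt <- advance_traces(trt, s_pre[, t], s_post[, t], tp)
    trt$x_post_slow_prev <- c(1, 1)
    dp <- pair_stdp_delta(trp, s_pre[, t], s_post[, t], W, pp)
    dt <- triplet_stdp_delta(trt, s_pre[, t], s_post[, t], W, pt)
    expect_equal(dt$delta, dp$delta, tolerance = 1e-12)
  }
})

test_that("multiplicative soft bounds confine weights on long random runs", {
  set.seed(31)
  tp <- trace_params(alpha_x = 0.8, beta = 0.3)
  sp <- stdp_params(eta_plus = 0.05, eta_minus = 0.05, w_min = 0, w_max = 1,
                    dependence = "multiplicative")
  tr <- trace_state(3, 3)
  W <- matrix(runif(9, 0.2, 0.8), 3, 3)
  for (t in 1:10000) {
    s_pre <- rbinom(3, 1, 0.2); s_post <- rbinom(3, 1, 0.2)
    tr <- advance_traces(tr, s_pre, s_post, tp)
    W <- W + pair_stdp_delta(tr, s_pre, s_post, W, sp)$delta
  }
  expect_true(all(W >= 0 & W <= 1))
})
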
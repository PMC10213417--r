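test_that("eligibility decays geometrically and obeys its edge cases", {
  E <- eligibility_state(2, 2)
  E$E_plus[] <- 1; E$E_minus[] <- 2
  z <- matrix(0, 2, 2)
  p <- eligibility_params(gamma = 0.9)
  for (i in 1:3) E <- accumulate_eligibility(E, z, z, p)
  expect_equal(E$E_plus, matrix(0.9^3, 2, 2), tolerance = 1e-12)
  expect_equal(E$E_minus, matrix(2 * 0.9^3, 2, 2), tolerance = 1e-12)
  # longer horizon against the closed form
  E$E_plus[] <- 1
  for (i in 1:50) E <- accumulate_eligibility(E, z, z, p)
  expect_equal(E$E_plus[1, 1], 0.9^50, tolerance = 1e-12)
  # alpha_e = 0: pure decay regardless of activity
  E2 <- eligibility_state(2, 2); E2$E_plus[] <- 1
  d <- matrix(5, 2, 2)
  E2 <- accumulate_eligibility(E2, d, d, eligibility_params(0.5, alpha_e = 0))
  expect_equal(E2$E_plus, matrix(0.5, 2, 2))
  # gamma = 0: memoryless
  E3 <- eligibility_state(2, 2); E3$E_plus[] <- 99
  E3 <- accumulate_eligibility(E3, d, d, eligibility_params(0, alpha_e = 2))
  expect_equal(E3$E_plus, 2 * d)
  expect_error(accumulate_eligibility(E3, matrix(0, 3, 3), d, p), "shape")
})

test_that("zero modulation leaves weights bitwise unchanged", {
  set.seed(2)
  W <- matrix(runif(12), 3, 4)
  E <- eligibility_state(4, 3)
  E$E_plus[] <- runif(12); E$E_minus[] <- runif(12)
  m <- modulatory_signal("global", ltp = 0, ltd = 0)
  expect_identical(apply_modulation(W, E, m), W)
})

test_that("modulation modes broadcast consistently and reverse under negation", {
  set.seed(3)
  W <- matrix(runif(12), 3, 4)
  E <- eligibility_state(4, 3)
  E$E_plus[] <- runif(12); E$E_minus[] <- runif(12)
  # worked scalar example
  E1 <- eligibility_state(1, 1); E1$E_plus[1, 1] <- 0.2
  out <- apply_modulation(matrix(0, 1, 1), E1,
                          modulatory_signal("global", 0.5, 0))
  expect_equal(out[1, 1], 0.1)
  # per_post / per_pre with constant payloads equal the global mode
  g <- apply_modulation(W, E, modulatory_signal("global", 0.3, 0.7))
  pp <- apply_modulation(W, E, modulatory_signal("per_post", rep(0.3, 3),
                                                 rep(0.7, 3)))
  pr <- apply_modulation(W, E, modulatory_signal("per_pre", rep(0.3, 4),
                                                 rep(0.7, 4)))
  expect_equal(pp, g)
  expect_equal(pr, g)
  # response-function mode with identity h and unit gains equals global
  rf <- apply_modulation(W, E, modulatory_signal("response_function", 0.3,
                                                 0.7, b = rep(1, 3)))
  expect_equal(rf, g)
  # negation reverses every weight change
  neg <- apply_modulation(W, E, modulatory_signal("global", -0.3, -0.7))
  expect_equal(neg - W, -(g - W))
  # per_pre broadcasts over columns (presynaptic index)
  mpre <- modulatory_signal("per_pre", c(1, 0, 0, 0), rep(0, 4))
  out2 <- apply_modulation(W, E, mpre)
  expect_equal(out2[, 1], W[, 1] + E$E_plus[, 1])
  expect_equal(out2[, 2:4], W[, 2:4])
  expect_error(apply_modulation(W, E, modulatory_signal("per_post",
                                                        rep(1, 4), rep(0, 4))))
})

test_that("plastic layer weights are frozen for any raster when M = 0", {
  set.seed(4)
  topo_mask <- matrix(rbinom(20, 1, 0.5), 4, 5)
  layer <- plastic_layer(matrix(runif(20), 4, 5), mask = topo_mask)
  W0 <- layer$W
  m0 <- modulatory_signal("per_pre", rep(0, 5), rep(0, 5))
  for (t in 1:100) {
    layer <- plastic_layer_step(layer, rbinom(5, 1, 0.4), rbinom(4, 1, 0.4),
                                m0)
  }
  expect_identical(layer$W, W0)
  expect_gt(sum(abs(layer$E$E_plus)), 0)  # eligibilities still evolved
  expect_gt(sum(abs(layer$traces$x_pre)), 0)
})

test_that("plastic_layer_step matches an independent scalar oracle", {
  # single synapse, 5 steps, written out from the defining recurrences
  alpha_x <- 0.6; beta <- 1; eta_p <- 0.2; eta_m <- 0.1
  gamma <- 0.8; alpha_e <- 1.5
  s_pre <- c(1, 0, 1, 0, 0)
  s_post <- c(0, 1, 1, 0, 1)
  Mp <- c(0, 0.5, 0, 0.2, 0.1)
  Mm <- c(0.1, 0, 0.3, 0, 0.2)
  x_pre <- x_post <- Ep <- Em <- 0; W <- 0.5
  for (t in 1:5) {
    x_pre <- alpha_x * x_pre + beta * s_pre[t]
    x_post <- alpha_x * x_post + beta * s_post[t]
    dp <- eta_p * x_pre * s_post[t]
    dm <- eta_m * x_post * s_pre[t]
    Ep <- gamma * Ep + alpha_e * dp
    Em <- gamma * Em + alpha_e * dm
    W <- W + Mp[t] * Ep - Mm[t] * Em
  }
  layer <- plastic_layer(matrix(0.5, 1, 1),
                         trace_params(alpha_x = alpha_x, beta = beta),
                         stdp_params(eta_plus = eta_p, eta_minus = eta_m),
                         eligibility_params(gamma = gamma,
                                            alpha_e = alpha_e))
  for (t in 1:5) {
    layer <- plastic_layer_step(layer, s_pre[t], s_post[t],
                                modulatory_signal("per_pre", Mp[t], Mm[t]))
  }
  expect_equal(layer$W[1, 1], W, tolerance = 1e-12)
  expect_equal(layer$E$E_plus[1, 1], Ep, tolerance = 1e-12)
})

test_that("permuting presynaptic indices permutes the layer state identically", {
  set.seed(6)
  n_pre <- 5; n_post <- 4; T_len <- 30
  W0 <- matrix(runif(n_post * n_pre), n_post, n_pre)
  s_pre <- random_raster(n_pre, T_len, 0.4)
  s_post <- random_raster(n_post, T_len, 0.4)
  Mp <- matrix(rnorm(n_pre * T_len, sd = 0.2), n_pre, T_len)
  perm <- sample(n_pre)
  run <- function(W0, s_pre, Mp) {
    layer <- plastic_layer(W0)
    for (t in seq_len(T_len)) {
      layer <- plastic_layer_step(layer, s_pre[, t], s_post[, t],
                                  modulatory_signal("per_pre", Mp[, t],
                                                    rep(0, n_pre)))
    }
    layer$W
  }
  base <- run(W0, s_pre, Mp)
  permuted <- run(W0[, perm], s_pre[perm, ], Mp[perm, ])
  expect_equal(permuted, base[, perm], tolerance = 1e-12)
})

test_that("plastic chain BPTT gradients match finite differences", {
  set.seed(8)
  n_pre <- 3; n_post <- 3; T_len <- 12
  s_pre <- random_raster(n_pre, T_len, 0.4)
  s_post <- random_raster(n_post, T_len, 0.4)
  Mp <- matrix(rnorm(n_pre * T_len, sd = 0.3), n_pre, T_len)
  Mm <- matrix(rnorm(n_pre * T_len, sd = 0.3), n_pre, T_len)
  loss_w <- matrix(rnorm(n_post * n_pre), n_post, n_pre)
  params <- list(eta_p = matrix(0.05, n_post, n_pre),
                 eta_m = matrix(0.04, n_post, n_pre),
                 alpha_e = matrix(1, n_post, n_pre),
                 gamma = matrix(0.9, 1, 1), alpha_x = matrix(0.7, 1, 1),
                 alpha_tau = matrix(0.95, 1, 1), beta = matrix(0.8, 1, 1),
                 W0 = matrix(0.5, n_post, n_pre))
  for (triplet in c(FALSE, TRUE)) {
    res <- metaspike:::plastic_chain_grad_cpp(params, s_pre, s_post, Mp, Mm,
                                              loss_w, triplet)
    for (key in c("eta_p", "eta_m", "alpha_e", "gamma", "alpha_x",
                  "alpha_tau", "beta")) {
      f <- function(v) {
        pp <- params; pp[[key]][1, 1] <- v
        metaspike:::plastic_chain_grad_cpp(pp, s_pre, s_post, Mp, Mm,
                                           loss_w, triplet)$loss
      }
      g <- res$grads[[key]][1, 1]
      h <- 1e-5
      fd <- (f(params[[key]][1, 1] + h) - f(params[[key]][1, 1] - h)) / (2 * h)
      expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-10), 1e-5)
    }
    # gradient along the modulation path
    fM <- function(v) {
      M2 <- Mp; M2[2, 5] <- v
      metaspike:::plastic_chain_grad_cpp(params, s_pre, s_post, M2, Mm,
                                         loss_w, triplet)$loss
    }
    h <- 1e-5
    fd <- (fM(Mp[2, 5] + h) - fM(Mp[2, 5] - h)) / (2 * h)
    g <- res$grads$Mp[2, 5]
    expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-10), 1e-5)
  }
})
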
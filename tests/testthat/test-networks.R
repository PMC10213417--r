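test_that("topology respects probabilities, determinism, and edge cases", {
  dense <- init_topology(10, 10, p_connect = 1, p_inhibitory = 0, seed = 1)
  expect_true(all(dense$mask == 1))
  expect_true(all(dense$signmask == 1))
  t1 <- init_topology(20, 48, seed = 99)
  t2 <- init_topology(20, 48, seed = 99)
  expect_identical(t1, t2)
  # binomial 99% bounds at the defaults (0.5 connect, 0.2 inhibitory)
  n <- 20 * 48
  k <- sum(t1$mask)
  expect_gte(k, qbinom(0.005, n, 0.5))
  expect_lte(k, qbinom(0.995, n, 0.5))
  ki <- sum(t1$sign[t1$mask == 1] == -1)
  expect_gte(ki, qbinom(0.005, k, 0.2))
  expect_lte(ki, qbinom(0.995, k, 0.2))
})

test_that("encoder produces 196 deterministic currents per image", {
  enc <- conv_encoder(seed = 4)
  zero <- matrix(0, 28, 28)
  e0 <- encode_image(zero, enc)
  expect_equal(dim(e0), c(196, 1))
  expect_identical(encode_image(zero, enc), e0)  # determinism
  expect_lt(diff(range(e0)), 1e-10)  # constant map for a constant image
  set.seed(5)
  img <- matrix(runif(784), 28, 28)
  e1 <- encode_image(img, enc)
  e_rot <- encode_image(t(img)[28:1, ], enc)
  expect_gt(sum(abs(e1 - e_rot)), 1e-3)  # no rotation invariance
  expect_error(encode_image(matrix(0, 20, 20), enc), "28 x 28")
})

test_that("compiled cue inner loop agrees exactly with the R module chain", {
  fit <- tiny_cue_system(seed = 42)
  set.seed(1)
  ep <- generate_cue_episode(fit$task)
  r <- run_inner(fit, ep, grad = FALSE, diag = TRUE)
  k <- meta_constants(fit$omega)
  nm <- nm_snn_forward(ep$raster, r$hidden, ep$fb,
                       list(W1 = fit$omega$W_nm1, W2 = fit$omega$W_nm2,
                            W_head = fit$omega$W_head,
                            b_head = fit$omega$b_head,
                            lambda_m = k$lambda_m),
                       fit$neuron, fit$surrogate)
  expect_equal(nm$modulation, r$modulation, tolerance = 1e-12)
  dp <- dp_snn_forward(ep$raster, r$modulation, fit$omega$W0,
                       fit$omega$W_ro, fit$topology,
                       trace_params(alpha_x = k$alpha_x,
                                    alpha_tau = k$alpha_tau, beta = k$beta),
                       stdp_params(eta_plus = k$eta_plus,
                                   eta_minus = k$eta_minus, rule = "pair"),
                       eligibility_params(gamma = k$gamma,
                                          alpha_e = fit$omega$alpha_e),
                       fit$neuron, fit$surrogate)
  expect_equal(dp$hidden, r$hidden, tolerance = 1e-12)
  expect_equal(dp$W_final, r$W_final, tolerance = 1e-9)
  acc <- rowSums(dp$output[, ep$test_window])
  expect_equal(acc, as.vector(r$acc), tolerance = 1e-9)
  ml <- meta_loss_cue(acc, ep$label_idx, gain = k$gain, bias = k$bias)
  expect_equal(ml$loss, r$loss, tolerance = 1e-9)
  expect_equal(as.numeric(ml$correct), r$correct)
})

test_that("compiled character inner loop agrees with the R module chain", {
  fit <- tiny_char_system(seed = 7)
  corpus <- tiny_corpus()
  set.seed(2)
  ep <- generate_char_episode(corpus, "train", fit$task)
  r <- run_inner(fit, ep, diag = TRUE)
  k <- meta_constants(fit$omega)
  enc <- structure(fit$omega[c("K1", "bn1_gamma", "bn1_beta", "K2",
                               "bn2_gamma", "bn2_beta")],
                   class = "conv_encoder")
  enc_r <- encode_image(ep$images, enc)
  expect_equal(enc_r, r$encodings, tolerance = 1e-10)
  # input layer spikes from constant current injection
  inp <- run_layer(layer_state(196, fit$neuron),
                   diag(6)[rep(1:6, each = fit$task$t_image), , drop = FALSE] |>
                     t(),
                   enc_r, fit$neuron, fit$surrogate)
  expect_equal(inp$raster, r$input_spikes, tolerance = 1e-12)
  # plastic DP side, driven by the compiled run's own modulation stream
  dp <- dp_snn_forward(r$input_spikes, r$modulation, fit$omega$W0,
                       fit$omega$W_ro, fit$topology,
                       trace_params(alpha_x = k$alpha_x,
                                    alpha_tau = k$alpha_tau, beta = k$beta),
                       stdp_params(eta_plus = k$eta_plus,
                                   eta_minus = k$eta_minus, rule = "triplet"),
                       eligibility_params(gamma = k$gamma,
                                          alpha_e = fit$omega$alpha_e),
                       fit$neuron, fit$surrogate)
  expect_equal(dp$hidden, r$hidden, tolerance = 1e-12)
  expect_equal(dp$W_final, r$W_final, tolerance = 1e-9)
  sums <- vapply(ep$windows, function(w) sum(dp$output[1, w]), numeric(1))
  expect_equal(sums, as.vector(r$window_sums), tolerance = 1e-9)
})

test_that("modulation gating: zeroed NM head reproduces the frozen network", {
  fit <- tiny_cue_system(seed = 10)
  fit$omega$W_head[] <- 0
  fit$omega$b_head[] <- 0
  set.seed(3)
  ep <- generate_cue_episode(fit$task)
  r_plastic <- run_inner(fit, ep, diag = TRUE)
  frozen <- fit; frozen$plastic <- FALSE
  r_frozen <- run_inner(frozen, ep, diag = TRUE)
  expect_identical(r_plastic$hidden, r_frozen$hidden)
  expect_identical(r_plastic$loss, r_frozen$loss)
  expect_identical(r_plastic$W_final, fit$omega$W0 * fit$topology$mask)
  expect_true(all(r_plastic$dw_max == 0))
})

test_that("weight changes occur only at steps with nonzero modulation", {
  fit <- tiny_cue_system(seed = 12)
  set.seed(4)
  ep <- generate_cue_episode(fit$task)
  # silence the modulation over a chosen time range via the episode gate
  cpp_ep <- metaspike:::cue_episode_cpp(ep)
  cpp_ep$gate[10:40] <- 0
  r <- metaspike:::cue_inner_cpp(fit$omega, cpp_ep,
                                 metaspike:::cpp_cfg(fit, want_diag = TRUE))
  expect_true(all(r$dw_max[10:40] == 0))
  expect_gt(sum(r$dw_max), 0)
})

test_that("masked synapses carry zero weight, eligibility, and gradient", {
  fit <- tiny_cue_system(seed = 13)
  set.seed(5)
  ep <- generate_cue_episode(fit$task)
  r <- run_inner(fit, ep, grad = TRUE, diag = TRUE)
  off <- fit$topology$mask == 0
  expect_true(all(r$W_final[off] == 0))
  expect_true(all(r$grads$W0[off] == 0))
  expect_true(all(r$grads$log_eta_p[off] == 0))
  # sign preservation: effective weights never cross zero against their type
  W_eff <- pmax(r$W_final, 0) * fit$topology$signmask
  expect_true(all(W_eff[fit$topology$signmask < 0] <= 0))
  expect_true(all(W_eff[fit$topology$signmask > 0] >= 0))
})

test_that("nm_snn_forward gates its output outside allowed windows", {
  set.seed(6)
  params <- list(W1 = matrix(rnorm(64 * 68, sd = 0.2), 64, 68),
                 W2 = matrix(rnorm(64 * 64, sd = 0.2), 64, 64),
                 W_head = matrix(rnorm(40 * 64, sd = 0.1), 40, 64),
                 b_head = matrix(0.05, 40, 1), lambda_m = 0.8)
  sensory <- random_raster(20, 50, 0.5)
  hidden <- random_raster(48, 50, 0.3)
  gate <- as.numeric(seq_len(50) <= 20)
  nm <- nm_snn_forward(sensory, hidden, feedback = NULL, params,
                       gate = gate)
  expect_true(all(nm$modulation[, 21:50] == 0))
  expect_gt(sum(abs(nm$modulation[, 1:20])), 0)
  # all-zero input from rest stays silent (biasless network)
  nm0 <- nm_snn_forward(matrix(0, 20, 30), matrix(0, 48, 30), NULL, params)
  expect_true(all(nm0$raster1 == 0))
  expect_true(all(nm0$raster2 == 0))
})
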
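#' Two-term binary cross-entropy meta-loss for the cue task
#'
#' The two action readouts' activity, summed over the test trial's decision
#' window, is mapped to probabilities through a logistic with trainable gain
#' and bias; the loss is the standard two-term binary cross-entropy against
#' the one-hot cue label,
#' \deqn{L = -\sum_{i=1}^{2} [y_i \log p_i + (1 - y_i) \log(1 - p_i)].}
#' The loss is computed on the test trial only; training trials contribute
#' no outer-loop error.
#'
#' @param activity Length-2 vector of summed decision-window readout
#'   activity (right, left).
#' @param label_idx Correct side: 1 = right, 2 = left.
#' @param gain,bias Logistic gain (> 0) and bias.
#' @return List with `loss`, `p` (the two probabilities), `correct`
#'   (argmax of activity equals the label; ties go to the lowest index),
#'   and `choice`.
#' @export
meta_loss_cue <- function(activity, label_idx, gain = 1, bias = 0) {
  stopifnot(length(activity) == 2, label_idx %in% 1:2, gain > 0)
  z <- gain * activity + bias
  # numerically stable: -log sigma(z) = softplus(-z)
  softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
  y <- c(0, 0); y[label_idx] <- 1
  loss <- sum(softplus(z) - y * z)
  choice <- which.max(activity)
  list(loss = loss, p = stats::plogis(z), correct = choice == label_idx,
       choice = choice)
}

#' Soft-normalized cross-entropy meta-loss for the character task
#'
#' The recognition readout's activity is summed within each phase-2
#' presentation window; the five sums are soft-normalized (softmax after a
#' trainable gain) and scored by cross-entropy against the correct slot.
#' Correctness is argmax over the window sums, ties to the lowest index.
#' Adding a constant to all window sums leaves the loss unchanged.
#'
#' @param sums Vector of per-window summed readout activity.
#' @param slot Correct slot index.
#' @param gain Softmax gain (> 0).
#' @return List with `loss`, `p` (softmax probabilities), `correct`,
#'   `choice`.
#' @export
meta_loss_char <- function(sums, slot, gain = 1) {
  stopifnot(slot >= 1, slot <= length(sums), gain > 0)
  z <- gain * sums
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  choice <- which.max(sums)
  list(loss = -log(p[slot]), p = p, correct = choice == slot,
       choice = choice)
}

# ---- meta-parameter initialization -----------------------------------------

qlogis_ <- function(p) log(p / (1 - p))

# shared plasticity/readout constants in raw (unconstrained) form; retentions
# travel through a logistic, rates through exp, so outer-loop gradient steps
# keep them in range
init_constants <- function(eta0 = 0.005, gamma0 = 0.98, alpha_x0 = 0.9,
                           alpha_tau0 = 0.98, beta0 = 0.3, lambda_m0 = 0.8,
                           gain0 = 0.1) {
  list(log_eta0 = log(eta0), gamma_raw = qlogis_(gamma0),
       ax_raw = qlogis_(alpha_x0), atau_raw = qlogis_(alpha_tau0),
       beta_raw = log(beta0), lam_raw = qlogis_(lambda_m0),
       gain_raw = log(gain0))
}

sc <- function(x) matrix(x, 1, 1)

init_omega_cue <- function(topology, n_in, n_hid, n_out, n_nm,
                           consts = init_constants()) {
  n_z <- n_in + n_hid + 2
  list(
    W_nm1 = matrix(stats::rnorm(n_nm * n_z, sd = 0.08), n_nm, n_z),
    W_nm2 = matrix(stats::rnorm(n_nm * n_nm, sd = 0.10), n_nm, n_nm),
    W_head = matrix(stats::rnorm(2 * n_in * n_nm, sd = 0.001), 2 * n_in, n_nm),
    b_head = matrix(0, 2 * n_in, 1),
    W_ro = matrix(stats::rnorm(n_out * n_hid, sd = 0.1), n_out, n_hid),
    W0 = matrix(stats::runif(n_hid * n_in, 0.02, 0.10), n_hid, n_in) *
      topology$mask,
    log_eta_p = matrix(consts$log_eta0, n_hid, n_in),
    log_eta_m = matrix(consts$log_eta0, n_hid, n_in),
    alpha_e = matrix(1, n_hid, n_in),
    gamma_raw = sc(consts$gamma_raw), ax_raw = sc(consts$ax_raw),
    atau_raw = sc(consts$atau_raw), beta_raw = sc(consts$beta_raw),
    lam_raw = sc(consts$lam_raw), gain_raw = sc(consts$gain_raw),
    bias_ro = sc(0))
}

init_omega_char <- function(topology, n_in, n_hid, n_nm, enc,
                            consts = init_constants()) {
  n_z <- n_in + n_hid
  list(
    K1 = enc$K1, bn1_gamma = enc$bn1_gamma, bn1_beta = enc$bn1_beta,
    K2 = enc$K2, bn2_gamma = enc$bn2_gamma, bn2_beta = enc$bn2_beta,
    W_nm1 = matrix(stats::rnorm(n_nm * n_z, sd = 0.04), n_nm, n_z),
    W_nm2 = matrix(stats::rnorm(n_nm * n_nm, sd = 0.10), n_nm, n_nm),
    W_head = matrix(stats::rnorm(2 * n_in * n_nm, sd = 0.005), 2 * n_in, n_nm),
    b_head = matrix(0, 2 * n_in, 1),
    W_ro = matrix(stats::rnorm(n_hid, sd = 0.3), 1, n_hid),
    W0 = matrix(stats::runif(n_hid * n_in, 0.001, 0.005), n_hid, n_in) *
      topology$mask,
    log_eta_p = matrix(consts$log_eta0, n_hid, n_in),
    log_eta_m = matrix(consts$log_eta0, n_hid, n_in),
    alpha_e = matrix(1, n_hid, n_in),
    gamma_raw = sc(consts$gamma_raw), ax_raw = sc(consts$ax_raw),
    atau_raw = sc(consts$atau_raw), beta_raw = sc(consts$beta_raw),
    lam_raw = sc(consts$lam_raw), gain_raw = sc(consts$gain_raw))
}

#' Transformed plasticity constants of a fitted system
#'
#' Maps the raw outer-loop parameters to their constrained forms: trace and
#' eligibility retentions through the logistic, learning rates and the
#' readout gain through exp.
#'
#' @param omega A meta-parameter list (e.g. `fit$omega`).
#' @return Named list of plain constants (`gamma`, `alpha_x`, `alpha_tau`,
#'   `beta`, `lambda_m`, `gain`, plus `eta_plus`/`eta_minus` matrices).
#' @export
meta_constants <- function(omega) {
  list(gamma = stats::plogis(omega$gamma_raw[1]),
       alpha_x = stats::plogis(omega$ax_raw[1]),
       alpha_tau = stats::plogis(omega$atau_raw[1]),
       beta = exp(omega$beta_raw[1]),
       lambda_m = stats::plogis(omega$lam_raw[1]),
       gain = exp(omega$gain_raw[1]),
       bias = if (!is.null(omega$bias_ro)) omega$bias_ro[1] else 0,
       eta_plus = exp(omega$log_eta_p),
       eta_minus = exp(omega$log_eta_m))
}

# ---- systems ---------------------------------------------------------------

cpp_cfg <- function(system, plastic = system$plastic, want_grad = FALSE,
                    want_diag = FALSE) {
  n <- system$neuron; s <- system$surrogate
  list(signmask = system$topology$signmask, mask = system$topology$mask,
       alpha_u = n$alpha_u, alpha_v = n$alpha_v, u_rest = n$u_rest,
       v_rest = n$v_rest, R = n$R, v_th = n$v_th,
       post_update_u = n$post_update_u,
       surr_shape = if (s$shape == "exp") 0L else 1L,
       surr_scale = s$scale, surr_amp = s$amplitude,
       rule = if (system$rule == "pair") 0L else 1L,
       plastic = plastic, want_grad = want_grad, want_diag = want_diag)
}

cue_episode_cpp <- function(ep) {
  list(raster = ep$raster, fb = ep$fb, label = ep$label_idx,
       win0 = ep$test_window[1], win1 = ep$test_window[length(ep$test_window)],
       gate = rep(1, ncol(ep$raster)))
}

char_episode_cpp <- function(ep) {
  list(images = vapply(ep$images, as.vector, numeric(length(ep$images[[1]]))),
       slot = ep$slot, t_image = ep$t_image, n_phase2 = ep$n_phase2)
}

new_system <- function(kind, task, neuron, surrogate, rule, n_in, n_hid,
                       n_out, n_nm, plastic, consts) {
  topology <- init_topology(n_in, n_hid)
  omega <- if (kind == "cue") {
    init_omega_cue(topology, n_in, n_hid, n_out, n_nm, consts)
  } else {
    init_omega_char(topology, n_in, n_hid, n_nm, conv_encoder(), consts)
  }
  structure(list(kind = kind, task = task, neuron = neuron,
                 surrogate = surrogate, rule = rule, topology = topology,
                 omega = omega, plastic = plastic,
                 n_in = n_in, n_hid = n_hid, n_out = n_out, n_nm = n_nm),
            class = "metaspike_system")
}

#' Simulate one episode through the trained system
#'
#' Runs the coupled DP-SNN / NM-SNN over a full episode (fresh plastic state
#' from the meta-learned initial weights; no resets within the episode) and
#' returns the test loss and correctness; optionally the BPTT meta-gradient
#' and diagnostics (hidden raster, modulation stream, final plastic weights,
#' per-step weight change).
#'
#' @param system A `metaspike_system` or `metaspike_fit`.
#' @param episode A [generate_cue_episode()] or [generate_char_episode()].
#' @param grad Compute meta-gradients with respect to every entry of omega?
#' @param diag Return diagnostics?
#' @return List: `loss`, `correct`, `choice`, plus `grads` and diagnostic
#'   fields when requested.
#' @export
run_inner <- function(system, episode, grad = FALSE, diag = FALSE) {
  cfg <- cpp_cfg(system, want_grad = grad, want_diag = diag)
  if (system$kind == "cue") {
    cue_inner_cpp(system$omega, cue_episode_cpp(episode), cfg)
  } else {
    char_inner_cpp(system$omega, char_episode_cpp(episode), cfg)
  }
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(omega) {
  list(m = lapply(omega, function(x) x * 0),
       v = lapply(omega, function(x) x * 0), t = 0)
}

adam_step <- function(omega, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(omega)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    omega[[k]] <- omega[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(omega = omega, state = state)
}

global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

#' One outer-loop meta-update
#'
#' Averages the BPTT meta-gradient over a batch of episodes, clips it by
#' global norm, and applies one Adam update to the meta-parameters.  All
#' episodes in the batch are simulated from the same omega (omega is
#' constant within episodes; only plastic weights, traces and eligibilities
#' change inside an episode).
#'
#' @param system A `metaspike_system`/`metaspike_fit`.
#' @param episodes List of episodes.
#' @param opt Adam state from a previous call, or `NULL` to initialise.
#' @param lr Learning rate; `lr = 0` leaves omega bitwise unchanged.
#' @param clip Global-norm clipping threshold.
#' @param freeze Character vector of omega entries excluded from the update
#'   (their gradients are zeroed).  By default the readout gain is frozen:
#'   at the chance plateau the loss is locally minimised by shrinking the
#'   gain to zero, which would scale every upstream gradient to zero and
#'   freeze learning permanently.
#' @return List: updated `system`, `opt`, and `metrics` (mean loss, batch
#'   accuracy, gradient norm).
#' @export
outer_step <- function(system, episodes, opt = NULL, lr = 1e-3, clip = 5,
                       freeze = "gain_raw") {
  if (is.null(opt)) opt <- adam_init(system$omega)
  acc_g <- NULL
  loss <- 0; correct <- 0
  for (ep in episodes) {
    r <- run_inner(system, ep, grad = TRUE)
    loss <- loss + r$loss; correct <- correct + r$correct
    if (is.null(acc_g)) {
      acc_g <- r$grads
    } else {
      for (k in names(acc_g)) acc_g[[k]] <- acc_g[[k]] + r$grads[[k]]
    }
  }
  n <- length(episodes)
  for (k in names(acc_g)) acc_g[[k]] <- acc_g[[k]] / n
  for (k in intersect(freeze, names(acc_g))) acc_g[[k]] <- acc_g[[k]] * 0
  gn <- global_norm(acc_g)
  if (is.finite(gn) && gn > clip) {
    for (k in names(acc_g)) acc_g[[k]] <- acc_g[[k]] * (clip / gn)
  }
  if (lr > 0) {
    upd <- adam_step(system$omega, acc_g, opt, lr)
    system$omega <- upd$omega
    # pin masked synapses exactly (their gradients are exactly zero, but
    # keep the invariant explicit against future optimizer changes)
    system$omega$W0 <- system$omega$W0 * system$topology$mask
    opt <- upd$state
  }
  list(system = system, opt = opt,
       metrics = list(loss = loss / n, accuracy = correct / n,
                      grad_norm = gn))
}

# ---- training loops --------------------------------------------------------

train_loop <- function(system, gen_episode, n_outer, batch, lr, clip,
                       eval_every, n_eval, gen_eval, verbose,
                       freeze = "gain_raw", gen_batch = NULL) {
  opt <- NULL
  metrics <- vector("list", n_outer)
  evals <- list()
  for (step in seq_len(n_outer)) {
    eps <- if (is.null(gen_batch)) {
      lapply(seq_len(batch), function(i) gen_episode())
    } else {
      gen_batch(batch)
    }
    res <- outer_step(system, eps, opt, lr = lr, clip = clip,
                      freeze = freeze)
    system <- res$system; opt <- res$opt
    metrics[[step]] <- tibble::tibble(step = step, loss = res$metrics$loss,
                                      accuracy = res$metrics$accuracy,
                                      grad_norm = res$metrics$grad_norm)
    if (eval_every > 0 && (step %% eval_every == 0 || step == n_outer)) {
      ev <- mean(vapply(seq_len(n_eval), function(i) {
        run_inner(system, gen_eval())$correct
      }, numeric(1)))
      evals[[length(evals) + 1]] <-
        tibble::tibble(step = step, accuracy = ev, n = n_eval)
      if (verbose) {
        message(sprintf("step %d  loss %.3f  batch acc %.2f  eval acc %.2f",
                        step, res$metrics$loss, res$metrics$accuracy, ev))
      }
    } else if (verbose && step %% 10 == 0) {
      message(sprintf("step %d  loss %.3f  batch acc %.2f", step,
                      res$metrics$loss, res$metrics$accuracy))
    }
  }
  system$opt <- opt
  system$metrics <- do.call(rbind, metrics)
  system$evals <- if (length(evals)) do.call(rbind, evals) else NULL
  class(system) <- c("metaspike_fit", class(system))
  system
}

#' Meta-train the cue-association system
#'
#' Outer loop of the bilevel optimization: every outer step draws a fresh
#' batch of episodes (new permutations, new side sequences), simulates the
#' coupled plastic system over each whole episode, and updates all
#' meta-parameters — NM-SNN weights, modulation head, readout weights,
#' initial plastic weights, per-synapse STDP rates, eligibility and trace
#' constants — by Adam on the BPTT gradient of the test-trial loss.
#'
#' @param task A [cue_task_config()].
#' @param n_outer Number of outer-loop updates.
#' @param batch Episodes per gradient.
#' @param lr Adam learning rate.
#' @param clip Global-norm gradient clip.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param plastic Set `FALSE` for the non-plastic control: same
#'   architecture, readout (and initial weights) still outer-loop-trained,
#'   but no plasticity and no neuromodulation.
#' @param eval_every Evaluate on fresh held-out episodes every so many
#'   steps (0 = never).
#' @param n_eval Episodes per evaluation.
#' @param neuron,surrogate Neuron and surrogate-gradient configurations.
#' @param rule STDP rule for the plastic input layer (`"pair"` for this
#'   task's protocol).
#' @param n_hid,n_nm Hidden sizes of the DP-SNN and NM-SNN layers.
#' @param consts Initial values for the trainable constants
#'   (see `metaspike:::init_constants`).
#' @param init_fit Optional previous fit to continue from (resume).
#' @param freeze Omega entries excluded from updates (see [outer_step()]).
#' @param antithetic Build each batch from mirrored episode pairs
#'   ([mirror_cue_episode()]); cancels the label-symmetric component of the
#'   gradient noise.
#' @param verbose Print progress.
#' @return A `metaspike_fit` with the trained omega, the topology, per-step
#'   `metrics` (tibble) and periodic `evals`.
#' @export
train_cue <- function(task = cue_task_config(), n_outer = 300, batch = 8,
                      lr = 2e-3, clip = 5, seed = 1, plastic = TRUE,
                      eval_every = 0, n_eval = 100,
                      neuron = neuron_params(), surrogate = surrogate_config(),
                      rule = "pair", n_hid = 48, n_nm = 64,
                      consts = init_constants(), init_fit = NULL,
                      freeze = "gain_raw", antithetic = TRUE,
                      verbose = FALSE) {
  set.seed(seed)
  system <- if (is.null(init_fit)) {
    new_system("cue", task, neuron, surrogate, rule,
               n_in = task$n_sensory, n_hid = n_hid, n_out = 2, n_nm = n_nm,
               plastic = plastic, consts = consts)
  } else {
    init_fit
  }
  system$seed <- seed
  gen_batch <- if (antithetic) {
    function(n) {
      base <- lapply(seq_len(ceiling(n / 2)), function(i)
        generate_cue_episode(task))
      eps <- c(base, lapply(base, mirror_cue_episode, n_group = task$n_group))
      eps[seq_len(n)]
    }
  } else {
    NULL
  }
  train_loop(system,
             gen_episode = function() generate_cue_episode(task),
             gen_batch = gen_batch,
             n_outer = n_outer, batch = batch, lr = lr, clip = clip,
             eval_every = eval_every, n_eval = n_eval,
             gen_eval = function() generate_cue_episode(task),
             verbose = verbose, freeze = freeze)
}

#' Meta-train the character-recognition system
#'
#' As [train_cue()], for the sequential one-shot character task: episodes
#' are drawn from the training split of a glyph corpus, the plastic layer
#' uses the triplet STDP rule, and the convolutional encoder parameters are
#' part of omega.
#'
#' @param corpus A [generate_glyph_corpus()].
#' @param task A [char_task_config()].
#' @inheritParams train_cue
#' @return A `metaspike_fit`.
#' @export
train_char <- function(corpus, task = char_task_config(), n_outer = 300,
                       batch = 32, lr = 2e-3, clip = 5, seed = 1,
                       plastic = TRUE, eval_every = 0, n_eval = 100,
                       neuron = neuron_params(),
                       surrogate = surrogate_config(), rule = "triplet",
                       n_hid = 48, n_nm = 64, consts = init_constants(),
                       init_fit = NULL, freeze = "gain_raw",
                       verbose = FALSE) {
  set.seed(seed)
  n_in <- 196
  system <- if (is.null(init_fit)) {
    new_system("char", task, neuron, surrogate, rule,
               n_in = n_in, n_hid = n_hid, n_out = 1, n_nm = n_nm,
               plastic = plastic, consts = consts)
  } else {
    init_fit
  }
  system$seed <- seed
  train_loop(system,
             gen_episode = function() generate_char_episode(corpus, "train", task),
             n_outer = n_outer, batch = batch, lr = lr, clip = clip,
             eval_every = eval_every, n_eval = n_eval,
             gen_eval = function() generate_char_episode(corpus, "test", task),
             verbose = verbose, freeze = freeze)
}

#' Non-plastic control
#'
#' Trains the identical architecture with plasticity and neuromodulation
#' disabled; the readout, initial weights (and encoder, for the character
#' task) are still outer-loop-trained.  Serves as the chance-level control:
#' without the plastic pathway there is no within-episode learning channel.
#'
#' @param ... Passed to [train_cue()] or [train_char()].
#' @param kind `"cue"` or `"char"`.
#' @param corpus Glyph corpus (character task only).
#' @return A `metaspike_fit`.
#' @export
baseline_nonplastic <- function(kind = c("cue", "char"), corpus = NULL, ...) {
  kind <- match.arg(kind)
  if (kind == "cue") {
    train_cue(..., plastic = FALSE)
  } else {
    train_char(corpus = corpus, ..., plastic = FALSE)
  }
}

# ---- evaluation ------------------------------------------------------------

eval_row <- function(correct, n, level = 0.95) {
  bt <- stats::binom.test(correct, n)
  ci <- stats::binom.test(correct, n, conf.level = level)$conf.int
  tibble::tibble(n = n, correct = correct, accuracy = correct / n,
                 ci_low = ci[1], ci_high = ci[2])
}

#' Evaluate a fitted cue system on fresh episodes
#'
#' No parameter updates occur; each episode is learned online by the plastic
#' synapses alone and scored on its test trial.
#'
#' @param fit A `metaspike_fit` from [train_cue()].
#' @param n_episodes Number of fresh evaluation episodes.
#' @param M Number of cues per trial (default: the training value); trial
#'   durations are recomputed for the requested `M`.
#' @param seed Optional seed for the evaluation episodes.
#' @return A `metaspike_eval` tibble with one row: accuracy and exact
#'   binomial confidence bounds.
#' @export
evaluate_cue <- function(fit, n_episodes = 400, M = NULL, seed = NULL) {
  task <- fit$task
  if (!is.null(M)) task$M <- M
  with_seed(seed, {
    correct <- 0
    for (i in seq_len(n_episodes)) {
      ep <- generate_cue_episode(task)
      correct <- correct + run_inner(fit, ep)$correct
    }
    out <- eval_row(correct, n_episodes)
    out$M <- task$M
    class(out) <- c("metaspike_eval", class(out))
    out
  })
}

#' Evaluate a fitted character system
#'
#' @param fit A `metaspike_fit` from [train_char()].
#' @param corpus The glyph corpus.
#' @param split `"test"` (held-out classes) or `"train"`.
#' @param n_episodes Number of fresh evaluation episodes.
#' @param seed Optional seed.
#' @return A `metaspike_eval` tibble with one row (accuracy, error rate,
#'   exact binomial bounds).
#' @export
evaluate_char <- function(fit, corpus, split = "test", n_episodes = 400,
                          seed = NULL) {
  with_seed(seed, {
    correct <- 0
    for (i in seq_len(n_episodes)) {
      ep <- generate_char_episode(corpus, split, fit$task)
      correct <- correct + run_inner(fit, ep)$correct
    }
    out <- eval_row(correct, n_episodes)
    out$error <- 1 - out$accuracy
    out$split <- split
    class(out) <- c("metaspike_eval", class(out))
    out
  })
}

#' Generalization sweep over the number of cues
#'
#' Evaluates a fitted cue system, without any parameter updates, on episodes
#' with `M` cues for each requested `M`; trial durations are recomputed per
#' `M`.  A system trained at `M = 5` solves nearby cue counts and degrades
#' as `M` grows.
#'
#' @param fit A `metaspike_fit` from [train_cue()].
#' @param M Integer vector of cue counts.
#' @param n_episodes Episodes per `M`.
#' @param seed Optional seed.
#' @return A `metaspike_eval` tibble with one row per `M`.
#' @export
eval_m_sweep <- function(fit, M = 1:15, n_episodes = 200, seed = NULL) {
  rows <- lapply(M, function(m) {
    evaluate_cue(fit, n_episodes = n_episodes, M = m,
                 seed = if (is.null(seed)) NULL else seed + m)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metaspike_eval", class(out))
  out
}

#' Save / load a fitted system
#'
#' Checkpoints hold the full meta-parameter set, topology, configurations,
#' optimizer state and metrics, serialized as RDS.
#'
#' @param fit A `metaspike_fit`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `metaspike_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
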
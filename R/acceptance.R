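#' Desk-scale study runs
#'
#' Reference configurations for validating the full pipeline on one CPU in
#' minutes rather than the multi-hour full-protocol runs (which live in the
#' repository's `scripts/train_full_*.R`).  The task statistics
#' (firing probabilities, group structure, architecture sizes, one-shot
#' protocol) are those of the study; only the problem scale is reduced:
#'
#' * cue task: `M = 3` cues with shortened periods (10 ms cues, 5 ms gaps,
#'   5 ms pre-decision rest, 10 ms decision; 90-step trials, 270-step
#'   episodes), slow current trace (`alpha_u = 0.05`) so cue-period drive
#'   persists into the decision window, 300 outer updates over antithetic
#'   episode pairs;
#' * character task: a 200-class synthetic glyph corpus, 300 outer updates
#'   of batch 32 (episode structure identical to the full protocol).
#'
#' @param seed Integer seed controlling everything: initialization, episode
#'   draws, and evaluation.
#' @param plastic `FALSE` trains the non-plastic control instead.
#' @param n_outer,batch Outer-loop budget.
#' @param corpus Optional pre-built corpus for the character run (built from
#'   `seed` when omitted).
#' @param verbose Print progress.
#' @return A `metaspike_fit`.
#' @name scaled_studies
NULL

#' @rdname scaled_studies
#' @export
scaled_cue_task <- function() {
  cue_task_config(M = 3, t_cue = 10, t_gap = 5, t_pre_decision = 5,
                  t_decision = 10)
}

#' @rdname scaled_studies
#' @export
scaled_cue_study <- function(seed = 1, plastic = TRUE, n_outer = 300,
                             batch = 64, verbose = FALSE) {
  task <- scaled_cue_task()
  neuron <- neuron_params(alpha_u = 0.05, alpha_v = 0.3)
  surrogate <- surrogate_config(amplitude = 0.3)
  set.seed(seed)
  sys <- new_system("cue", task, neuron, surrogate, "pair",
                    n_in = task$n_sensory, n_hid = 48, n_out = 2, n_nm = 64,
                    plastic = plastic, consts = init_constants())
  # weight scale matched to the slow current trace (see the methods
  # vignette), and a salient feedback channel into the NM-SNN
  sys$omega$W0 <- matrix(stats::runif(48 * 20, 0.003, 0.012), 48, 20) *
    sys$topology$mask
  sys$omega$W_nm1[, 69:70] <- matrix(stats::rnorm(64 * 2, sd = 0.4), 64, 2)
  train_cue(task, n_outer = n_outer, batch = batch, lr = 3e-3, clip = 1,
            seed = seed, plastic = plastic, neuron = neuron,
            surrogate = surrogate, init_fit = sys, antithetic = TRUE,
            verbose = verbose)
}

#' @rdname scaled_studies
#' @export
scaled_char_study <- function(seed = 1, plastic = TRUE, n_outer = 300,
                              batch = 32, corpus = NULL, verbose = FALSE) {
  if (is.null(corpus)) {
    corpus <- generate_glyph_corpus(n_classes = 200, samples_per_class = 20,
                                    seed = seed + 1000L)
  }
  fit <- train_char(corpus, n_outer = n_outer, batch = batch, lr = 3e-3,
                    clip = 1, seed = seed, plastic = plastic,
                    verbose = verbose)
  fit$corpus_seed <- seed + 1000L
  fit
}
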
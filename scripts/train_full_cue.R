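#!/usr/bin/env Rscript
# Full-protocol cue-association study: M = 5 with the study durations
# (25 ms cues, 30 ms gaps, 50 ms pre-decision rest, 25 ms decision; 350-step
# trials, 1050-step episodes), trained independently for many seeds and then
# swept over M = 1..15 at evaluation.  This is the multi-hour reproduction
# run; it is not part of the routine test suite.
#
# Usage: Rscript scripts/train_full_cue.R [--seeds N] [--outer N] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(metaspike)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seeds", type = "integer", default = 30L),
  make_option("--outer", type = "integer", default = 2000L),
  make_option("--batch", type = "integer", default = 32L),
  make_option("--episodes", type = "integer", default = 500L,
              help = "evaluation episodes per seed and per M"),
  make_option("--out", type = "character", default = "results/full_cue")
)))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

task <- cue_task_config()     # full study protocol, M = 5
n_seeds <- opts$seeds
acc <- numeric(n_seeds)
for (s in seq_len(n_seeds)) {
  message(sprintf("seed %d / %d", s, n_seeds))
  fit <- train_cue(task, n_outer = opts$outer, batch = opts$batch,
                   lr = 1e-3, clip = 1, seed = s,
                   neuron = neuron_params(alpha_u = 0.05, alpha_v = 0.3),
                   surrogate = surrogate_config(amplitude = 0.3),
                   eval_every = 200, n_eval = 200, verbose = TRUE)
  save_checkpoint(fit, file.path(opts$out, sprintf("cue_seed%02d.rds", s)))
  ev <- evaluate_cue(fit, n_episodes = opts$episodes, seed = 10000 + s)
  acc[s] <- ev$accuracy
  sweep <- eval_m_sweep(fit, M = 1:15, n_episodes = opts$episodes,
                        seed = 20000 + s)
  utils::write.csv(sweep, file.path(opts$out,
                                    sprintf("sweep_seed%02d.csv", s)),
                   row.names = FALSE)
  message(sprintf("  seed %d test accuracy %.3f", s, acc[s]))
}
summary <- data.frame(seed = seq_len(n_seeds), accuracy = acc)
utils::write.csv(summary, file.path(opts$out, "accuracy_by_seed.csv"),
                 row.names = FALSE)
message(sprintf("mean test accuracy over %d seeds: %.3f", n_seeds,
                mean(acc)))
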
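#!/usr/bin/env Rscript
# Full-protocol character study: rotation-augmented glyph corpus (1623 base
# classes x 4 rotations at the full inventory; reduce --classes for smaller
# machines), 2000 outer updates with each gradient computed across 256
# episodes.  This is the multi-hour reproduction run; it is not part of the
# routine test suite.
#
# Usage: Rscript scripts/train_full_char.R [--classes N] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(metaspike)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--classes", type = "integer", default = 1623L,
              help = "base classes before rotation augmentation"),
  make_option("--outer", type = "integer", default = 2000L),
  make_option("--batch", type = "integer", default = 256L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--episodes", type = "integer", default = 1000L),
  make_option("--out", type = "character", default = "results/full_char")
)))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

message("building corpus (rotation-augmented)...")
corpus <- generate_glyph_corpus(n_classes = opts$classes,
                                samples_per_class = 20,
                                rotations = TRUE, seed = opts$seed + 1000L)
message(sprintf("%d classes, %d images", corpus$n_classes,
                length(corpus$images)))

fit <- train_char(corpus, n_outer = opts$outer, batch = opts$batch,
                  lr = 1e-3, clip = 1, seed = opts$seed,
                  eval_every = 100, n_eval = 200, verbose = TRUE)
save_checkpoint(fit, file.path(opts$out, "char_fit.rds"))

ev <- evaluate_char(fit, corpus, "test", n_episodes = opts$episodes,
                    seed = opts$seed + 20000L)
np <- train_char(corpus, n_outer = opts$outer, batch = opts$batch,
                 lr = 1e-3, clip = 1, seed = opts$seed, plastic = FALSE)
evn <- evaluate_char(np, corpus, "test", n_episodes = opts$episodes,
                     seed = opts$seed + 20000L)
out <- data.frame(model = c("plastic", "nonplastic"),
                  error = c(ev$error, evn$error),
                  n = c(ev$n, evn$n))
utils::write.csv(out, file.path(opts$out, "test_error.csv"),
                 row.names = FALSE)
print(out)
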
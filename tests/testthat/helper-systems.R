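# shared builders for small test systems and rasters

tiny_cue_task <- function(M = 3) {
  cue_task_config(M = M, t_cue = 4, t_gap = 2, t_pre_decision = 2,
                  t_decision = 6)
}

tiny_cue_system <- function(seed = 1, plastic = TRUE, rule = "pair") {
  set.seed(seed)
  metaspike:::new_system("cue", tiny_cue_task(), neuron_params(),
                         surrogate_config(amplitude = 0.3), rule,
                         n_in = 20, n_hid = 48, n_out = 2, n_nm = 64,
                         plastic = plastic,
                         consts = metaspike:::init_constants())
}

tiny_char_system <- function(seed = 1, plastic = TRUE) {
  set.seed(seed)
  metaspike:::new_system("char", char_task_config(), neuron_params(),
                         surrogate_config(amplitude = 0.3), "triplet",
                         n_in = 196, n_hid = 48, n_out = 1, n_nm = 64,
                         plastic = plastic,
                         consts = metaspike:::init_constants())
}

tiny_corpus <- function(seed = 5, n_classes = 35) {
  generate_glyph_corpus(n_classes = n_classes, samples_per_class = 4,
                        seed = seed)
}

random_raster <- function(n, T_len, p = 0.3) {
  matrix(rbinom(n * T_len, 1, p), n, T_len)
}

# relative error between an analytic gradient and central finite differences
fd_rel_err <- function(f, x, g, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fd <- (f(xp) - f(xm)) / (2 * h)
    abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-12)
  }, numeric(1))
}
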
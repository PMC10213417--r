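test_that("trial and episode lengths follow the protocol arithmetic", {
  cfg <- cue_task_config()  # study defaults: M = 5, 25/30/50/25 ms at 1 ms
  expect_equal(cue_trial_steps(cfg), 350)
  ep <- generate_cue_episode(cfg)
  expect_equal(ncol(ep$raster), 1050)
  expect_equal(ncol(ep$fb), 1050)
  expect_equal(length(ep$labels), 3)
  cfg2 <- tiny_cue_task()
  expect_equal(cue_trial_steps(cfg2), 3 * 6 + 2 + 6)
})

test_that("unpermuting a deterministic trial recovers the canonical layout", {
  cfg <- cue_task_config(M = 3, p_active = 1, p_base = 1e-9, t_cue = 4,
                         t_gap = 2, t_pre_decision = 2, t_decision = 5)
  set.seed(1)
  perm <- sample(20)
  tr <- generate_cue_trial(cfg, c("R", "L", "R"), perm)
  canonical <- tr$raster[perm, ]  # invert the row placement
  # cue windows: rows 1-5 (right) active for cues 1 and 3, rows 6-10 for 2
  expect_true(all(canonical[1:5, 1:4] == 1))
  expect_true(all(canonical[6:10, 1:4] == 0))
  expect_true(all(canonical[6:10, 7:10] == 1))
  expect_true(all(canonical[1:5, 7:10] == 0))
  # decision window: rows 11-15
  expect_true(all(canonical[11:15, tr$decision_window] == 1))
  expect_true(all(canonical[16:20, ] == 0))
  expect_equal(tr$label, "R")
})

test_that("noise neurons fire at the baseline rate", {
  cfg <- cue_task_config()
  set.seed(2)
  n_trials <- 60
  total <- 0
  for (i in 1:n_trials) {
    tr <- generate_cue_trial(cfg, sample(c("R", "L"), 5, replace = TRUE))
    total <- total + sum(tr$raster[16:20, ])  # canonical noise rows
  }
  n <- n_trials * 5 * 350
  expect_gte(total, qbinom(0.005, n, 0.15))
  expect_lte(total, qbinom(0.995, n, 0.15))
})

test_that("episodes follow the one-shot protocol", {
  cfg <- tiny_cue_task()
  set.seed(3)
  for (i in 1:20) {
    ep <- generate_cue_episode(cfg)
    expect_setequal(ep$labels[1:2], c("R", "L"))  # one trial per class
    expect_true(ep$is_test[3])
    # feedback only in training decision windows, zero in the test trial
    expect_true(all(ep$fb[, ep$decision_windows[[3]]] == 0))
    steps <- cue_trial_steps(cfg)
    expect_true(all(ep$fb[, (2 * steps + 1):(3 * steps)] == 0))
    for (k in 1:2) {
      win <- ep$decision_windows[[k]]
      row <- if (ep$labels[k] == "R") 1 else 2
      expect_true(all(ep$fb[row, win] == 1))
      expect_true(all(ep$fb[3 - row, win] == 0))
    }
    expect_equal(ep$label, ep$labels[3])
  }
})

test_that("labels are majority sides and balanced across episodes", {
  cfg <- cue_task_config(M = 5, t_cue = 2, t_gap = 1, t_pre_decision = 1,
                         t_decision = 2)
  set.seed(4)
  labs <- replicate(400, generate_cue_episode(cfg)$label)
  k <- sum(labs == "R")
  expect_gte(k, qbinom(0.005, 400, 0.5))
  expect_lte(k, qbinom(0.995, 400, 0.5))
  # even M never produces ties (regeneration rule)
  cfg4 <- cue_task_config(M = 4, t_cue = 2, t_gap = 1, t_pre_decision = 1,
                          t_decision = 2)
  for (i in 1:50) {
    ep <- generate_cue_episode(cfg4)
    expect_true(all(ep$labels %in% c("R", "L")))
  }
})

test_that("mirroring swaps sides consistently and preserves the protocol", {
  cfg <- tiny_cue_task()
  set.seed(5)
  ep <- generate_cue_episode(cfg)
  em <- mirror_cue_episode(ep)
  expect_equal(em$label_idx, 3L - ep$label_idx)
  expect_identical(em$fb[1, ], ep$fb[2, ])
  expect_identical(sort(as.vector(em$raster)), sort(as.vector(ep$raster)))
  # double mirror restores the original raster and labels
  emm <- mirror_cue_episode(em)
  expect_identical(emm$raster, ep$raster)
  expect_identical(emm$labels, ep$labels)
  # canonical structure still recoverable through the stored permutation
  canon <- em$raster[em$permutation, ]
  canon0 <- ep$raster[ep$permutation, ]
  expect_identical(canon[11:20, ], canon0[11:20, ])   # decision/noise rows
  expect_identical(canon[1:5, ], canon0[6:10, ])      # sides exchanged
})

test_that("glyph corpus is reproducible with few-shot structure", {
  c1 <- tiny_corpus(seed = 9)
  c2 <- tiny_corpus(seed = 9)
  expect_identical(c1, c2)
  expect_equal(c1$n_classes, 35)
  expect_equal(length(c1$images), 35 * 4)
  expect_true(all(vapply(c1$images, function(x) all(dim(x) == c(28, 28)),
                         logical(1))))
  expect_true(all(vapply(c1$images, function(x) mean(x) > 0.005, logical(1))))
  # rotations register as distinct classes: 4x the base count
  cr <- generate_glyph_corpus(n_classes = 10, samples_per_class = 2,
                              rotations = TRUE, seed = 1)
  expect_equal(cr$n_classes, 40)
  expect_equal(max(cr$class), 40)
  # within-class pixel distance below between-class distance on average
  corpus <- generate_glyph_corpus(n_classes = 20, samples_per_class = 6,
                                  seed = 10)
  d <- function(a, b) mean((a - b)^2)
  set.seed(11)
  within <- replicate(100, {
    cl <- sample(20, 1); idx <- sample(which(corpus$class == cl), 2)
    d(corpus$images[[idx[1]]], corpus$images[[idx[2]]])
  })
  between <- replicate(100, {
    cl <- sample(20, 2); d(corpus$images[[sample(which(corpus$class == cl[1]), 1)]],
                           corpus$images[[sample(which(corpus$class == cl[2]), 1)]])
  })
  expect_lt(mean(within), mean(between))
})

test_that("character episodes follow the phase protocol without leakage", {
  corpus <- tiny_corpus(seed = 12)
  cfg <- char_task_config()
  expect_equal(cfg$episode_steps, 120)
  set.seed(13)
  for (split in c("train", "test")) {
    allowed <- which(corpus$split == split)
    for (i in 1:25) {
      ep <- generate_char_episode(corpus, split, cfg)
      expect_length(ep$images, 6)
      expect_true(all(ep$classes %in% allowed))       # no split leakage
      expect_equal(sum(ep$classes[-1] == ep$classes[1]), 1)
      expect_equal(ep$classes[1 + ep$slot], ep$classes[1])
      # matching image is a different exemplar, distractor classes distinct
      expect_false(identical(ep$images[[1]], ep$images[[1 + ep$slot]]))
      expect_equal(anyDuplicated(ep$classes[-1]), 0)
      expect_equal(ep$phase1_window, 1:20)
      expect_equal(ep$windows[[3]], 61:80)
    }
  }
})

test_that("correct slots are uniform and chance floors hold", {
  corpus <- tiny_corpus(seed = 14)
  set.seed(15)
  slots <- replicate(2000, generate_char_episode(corpus, "train")$slot)
  expect_gt(chisq.test(table(factor(slots, levels = 1:5)))$p.value, 1e-4)
  # label-blind guessing scores at the chance floors
  cfg <- cue_task_config(M = 3, t_cue = 2, t_gap = 1, t_pre_decision = 1,
                         t_decision = 2)
  labs <- replicate(10000, generate_cue_episode(cfg)$label_idx)
  guess <- sample(1:2, 10000, replace = TRUE)
  acc <- mean(guess == labs)
  expect_gt(acc, 0.5 - 2.6 * sqrt(0.25 / 10000) - 0.01)
  expect_lt(acc, 0.5 + 2.6 * sqrt(0.25 / 10000) + 0.01)
  acc_char <- mean(sample(1:5, 2000, replace = TRUE) == slots)
  expect_lt(abs(acc_char - 0.2), 2.6 * sqrt(0.2 * 0.8 / 2000) + 0.01)
})
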
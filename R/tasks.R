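#' Configuration of the permuted one-shot cue-association task
#'
#' A virtual T-maze trial presented to 20 sensory neurons organised in four
#' groups of five: right-side cues, left-side cues, decision-period neurons,
#' and pure noise neurons (canonical rows 1-5, 6-10, 11-15, 16-20).  Each of
#' the `M` cue periods activates one side's group at `p_active` while every
#' other neuron fires at the baseline `p_base`; cue periods are separated by
#' rest gaps, followed by a pre-decision rest and a decision period during
#' which the decision group is active.  The correct answer is the side with
#' the majority of cues.  Within an episode the 20 input rows are freshly
#' permuted, so which neuron carries which role must be learned online.
#'
#' With the defaults (`M = 5`, 25 ms cues, 30 ms gaps, 50 ms pre-decision
#' rest, 25 ms decision) a trial lasts 350 steps at `dt = 1` ms and a
#' 3-trial episode 1050 steps.
#'
#' @param M Number of cues per trial (odd values exclude ties).
#' @param n_group Neurons per group (fixed at 5 in the study protocol).
#' @param p_active Firing probability of an active group, per step.
#' @param p_base Baseline firing probability of every neuron, per step.
#' @param t_cue,t_gap,t_pre_decision,t_decision Durations in steps.
#' @param dt Step size in ms.
#' @param n_shot Labeled trials per class in the training phase (1 = one-shot;
#'   the episode has `2 * n_shot` training trials followed by one test trial).
#' @return An object of class `cue_task_config`.
#' @export
cue_task_config <- function(M = 5, n_group = 5, p_active = 0.75,
                            p_base = 0.15, t_cue = 25, t_gap = 30,
                            t_pre_decision = 50, t_decision = 25, dt = 1,
                            n_shot = 1) {
  stopifnot(M >= 1, n_group >= 1, p_active > p_base, p_base >= 0,
            t_cue >= 1, t_gap >= 0, t_pre_decision >= 0, t_decision >= 1,
            n_shot >= 1)
  structure(list(M = M, n_group = n_group, n_sensory = 4 * n_group,
                 p_active = p_active, p_base = p_base, t_cue = t_cue,
                 t_gap = t_gap, t_pre_decision = t_pre_decision,
                 t_decision = t_decision, dt = dt, n_shot = n_shot),
            class = "cue_task_config")
}

#' Steps in one cue trial
#' @param cfg A [cue_task_config()].
#' @return Integer trial length: `M (t_cue + t_gap) + t_pre_decision +
#'   t_decision`.
#' @export
cue_trial_steps <- function(cfg) {
  cfg$M * (cfg$t_cue + cfg$t_gap) + cfg$t_pre_decision + cfg$t_decision
}

# canonical row groups
cue_groups <- function(cfg) {
  g <- cfg$n_group
  list(right = 1:g, left = g + 1:g, decision = 2 * g + 1:g,
       noise = 3 * g + 1:g)
}

# draw an M-long side sequence; ties (even M) are redrawn, and an optional
# required majority is enforced by redrawing
draw_sides <- function(M, majority = NULL) {
  repeat {
    sides <- sample(c("R", "L"), M, replace = TRUE)
    nr <- sum(sides == "R")
    if (2 * nr == M) next
    maj <- if (2 * nr > M) "R" else "L"
    if (is.null(majority) || maj == majority) {
      return(list(sides = sides, label = maj))
    }
  }
}

#' Generate one cue trial
#'
#' Builds the canonical probability schedule (active cue group at
#' `p_active`, everything else at `p_base`, decision group active during the
#' decision window), samples Bernoulli spikes, and permutes the rows.
#'
#' @param cfg A [cue_task_config()].
#' @param sides Character vector of length `M` with entries `"R"`/`"L"`; the
#'   label is the majority side.
#' @param permutation Permutation of `1:n_sensory`; canonical row `i` is
#'   placed at permuted row `permutation[i]`.
#' @return List with `raster` (`n_sensory x trial_steps`), `label`
#'   (`"R"`/`"L"`), `sides`, and `decision_window` (step indices).
#' @export
generate_cue_trial <- function(cfg, sides,
                               permutation = seq_len(cfg$n_sensory)) {
  stopifnot(length(sides) == cfg$M, all(sides %in% c("R", "L")))
  T_len <- cue_trial_steps(cfg)
  g <- cue_groups(cfg)
  prob <- matrix(cfg$p_base, cfg$n_sensory, T_len)
  for (k in seq_len(cfg$M)) {
    t0 <- (k - 1) * (cfg$t_cue + cfg$t_gap)
    win <- (t0 + 1):(t0 + cfg$t_cue)
    rows <- if (sides[k] == "R") g$right else g$left
    prob[rows, win] <- cfg$p_active
  }
  dec0 <- cfg$M * (cfg$t_cue + cfg$t_gap) + cfg$t_pre_decision
  decision_window <- (dec0 + 1):(dec0 + cfg$t_decision)
  prob[g$decision, decision_window] <- cfg$p_active
  raster <- matrix(stats::rbinom(length(prob), 1, as.vector(prob)),
                   cfg$n_sensory, T_len)
  raster[permutation, ] <- raster
  nr <- sum(sides == "R")
  list(raster = raster, label = if (2 * nr > cfg$M) "R" else "L",
       sides = sides, decision_window = decision_window)
}

#' Generate a full one-shot cue-association episode
#'
#' Draws a fresh uniform permutation of the sensory rows, then presents
#' `n_shot` right-majority and `n_shot` left-majority training trials in
#' random order followed by one test trial with a fresh side sequence — all
#' under the same permutation, concatenated into one continuous raster over
#' which inner-loop learning runs without resets.  The environment feedback
#' stream is `(1, 0)` during the decision window of right-labelled training
#' trials, `(0, 1)` for left, and zero everywhere else, including the whole
#' test trial.
#'
#' @param cfg A [cue_task_config()].
#' @return An object of class `cue_episode`: `raster` (`20 x T`), `fb`
#'   (`2 x T`), `permutation`, `labels` (per trial), `is_test`,
#'   `trial_starts`, `decision_windows` (list of step ranges),
#'   `test_window` (the test trial's decision window), `label` (test label,
#'   `"R"`/`"L"`), and `label_idx` (1 = right, 2 = left).
#' @export
generate_cue_episode <- function(cfg = cue_task_config()) {
  perm <- sample(cfg$n_sensory)
  n_train <- 2 * cfg$n_shot
  majors <- sample(rep(c("R", "L"), cfg$n_shot))
  trials <- vector("list", n_train + 1)
  for (i in seq_len(n_train)) {
    sd_ <- draw_sides(cfg$M, majority = majors[i])
    trials[[i]] <- generate_cue_trial(cfg, sd_$sides, perm)
  }
  sd_ <- draw_sides(cfg$M)
  trials[[n_train + 1]] <- generate_cue_trial(cfg, sd_$sides, perm)

  steps <- cue_trial_steps(cfg)
  T_len <- (n_train + 1) * steps
  raster <- do.call(cbind, lapply(trials, `[[`, "raster"))
  fb <- matrix(0, 2, T_len)
  labels <- vapply(trials, `[[`, "", "label")
  is_test <- c(rep(FALSE, n_train), TRUE)
  decision_windows <- vector("list", n_train + 1)
  for (i in seq_len(n_train + 1)) {
    win <- trials[[i]]$decision_window + (i - 1) * steps
    decision_windows[[i]] <- win
    if (!is_test[i]) {
      fb[if (labels[i] == "R") 1 else 2, win] <- 1
    }
  }
  test_window <- decision_windows[[n_train + 1]]
  structure(list(raster = raster, fb = fb, permutation = perm,
                 labels = labels, is_test = is_test,
                 trial_starts = (0:n_train) * steps + 1,
                 decision_windows = decision_windows,
                 test_window = test_window,
                 label = labels[n_train + 1],
                 label_idx = if (labels[n_train + 1] == "R") 1L else 2L),
            class = "cue_episode")
}

#' Mirror a cue episode (swap left and right throughout)
#'
#' Produces the side-swapped twin of an episode: the realized spike rows of
#' the right-cue group and the left-cue group exchange identities, the two
#' feedback rows swap, and every trial label flips.  Because the task
#' distribution is symmetric under the swap, the mirror is an equally valid
#' sample; training on mirrored pairs cancels the label-symmetric part of
#' the gradient noise exactly (antithetic variates) and leaves the
#' discriminative part.
#'
#' @param ep A [generate_cue_episode()].
#' @param n_group Neurons per group (5 under the study protocol).
#' @return A `cue_episode` with sides swapped.
#' @export
mirror_cue_episode <- function(ep, n_group = 5) {
  perm <- ep$permutation
  right <- perm[seq_len(n_group)]
  left <- perm[n_group + seq_len(n_group)]
  ep$raster[c(right, left), ] <- ep$raster[c(left, right), ]
  ep$fb <- ep$fb[2:1, , drop = FALSE]
  flip <- function(l) ifelse(l == "R", "L", "R")
  ep$labels <- flip(ep$labels)
  ep$label <- flip(ep$label)
  ep$label_idx <- 3L - ep$label_idx
  ep
}

#' Configuration of the sequential character-recognition task
#'
#' One phase-1 image is shown for `t_image` steps, followed by `n_phase2`
#' images shown sequentially for `t_image` steps each.  Exactly one phase-2
#' image belongs to the phase-1 class (a different exemplar); the answer is
#' the phase-2 slot with the highest summed readout activity.  Modulation is
#' allowed only during the phase-1 window.
#'
#' @param t_image Presentation time per image, in steps (default 20).
#' @param n_phase2 Number of phase-2 images (default 5).
#' @param dt Step size in ms.
#' @param image_size Image side length in pixels (the encoder requires 28).
#' @return An object of class `char_task_config`.
#' @export
char_task_config <- function(t_image = 20, n_phase2 = 5, dt = 1,
                             image_size = 28) {
  stopifnot(t_image >= 1, n_phase2 >= 2)
  structure(list(t_image = t_image, n_phase2 = n_phase2, dt = dt,
                 image_size = image_size,
                 episode_steps = (1 + n_phase2) * t_image),
            class = "char_task_config")
}

# render one glyph from stroke parameters; strokes is a list of lists with
# fields x (3 control points), y, w (stroke width, normalized units)
render_glyph <- function(strokes, size = 28, n_samp = 30) {
  px <- (col(matrix(0, size, size)) - 0.5) / size
  py <- (row(matrix(0, size, size)) - 0.5) / size
  d2min <- matrix(Inf, size, size)
  tt <- seq(0, 1, length.out = n_samp)
  sigma2 <- NULL
  img <- matrix(0, size, size)
  for (st in strokes) {
    # quadratic Bezier through the three control points
    bx <- (1 - tt)^2 * st$x[1] + 2 * tt * (1 - tt) * st$x[2] + tt^2 * st$x[3]
    by <- (1 - tt)^2 * st$y[1] + 2 * tt * (1 - tt) * st$y[2] + tt^2 * st$y[3]
    d2min[] <- Inf
    for (k in seq_len(n_samp)) {
      d2 <- (px - bx[k])^2 + (py - by[k])^2
      d2min <- pmin(d2min, d2)
    }
    img <- pmax(img, exp(-d2min / (2 * st$w^2)))
  }
  img
}

rot90k <- function(img, k) {
  k <- k %% 4
  for (i in seq_len(k)) img <- t(img)[ncol(img):1, , drop = FALSE]
  img
}

#' Generate a synthetic glyph corpus
#'
#' A synthetic stand-in for a many-class, few-sample handwritten-character
#' corpus.  Each base class is a random composition of 2-5 curved stroke
#' primitives (quadratic Beziers); samples of a class re-render the
#' prototype under small affine jitter (rotation, scale, translation),
#' stroke-width jitter, and additive pixel noise.  With
#' `rotations = TRUE` each class additionally appears rotated by 90, 180 and
#' 270 degrees, registered as distinct classes (so 1623 base classes become
#' 6492).  Classes are split 80/20 into train/test by class, so test
#' episodes contain only never-trained classes.
#'
#' @param n_classes Number of base classes (>= 10).
#' @param samples_per_class Exemplars per class (default 20).
#' @param image_size Image side length (default 28).
#' @param rotations Register 90/180/270-degree rotations as extra classes.
#' @param p_train Fraction of classes assigned to the training split.
#' @param seed Optional seed; the corpus is reproducible from it.
#' @return An object of class `glyph_corpus`: `images` (list of matrices),
#'   `class` (integer per image), `base_class`, `rotation`, `split`
#'   (per-class `"train"`/`"test"` character vector indexed by class id),
#'   `prototypes` (one clean rendering per class), `n_classes`.
#' @export
generate_glyph_corpus <- function(n_classes = 200, samples_per_class = 20,
                                  image_size = 28, rotations = FALSE,
                                  p_train = 0.8, seed = NULL) {
  stopifnot(n_classes >= 10, samples_per_class >= 2)
  with_seed(seed, {
    rand_strokes <- function() {
      n_str <- sample(2:5, 1)
      lapply(seq_len(n_str), function(i) {
        list(x = stats::runif(3, 0.15, 0.85),
             y = stats::runif(3, 0.15, 0.85),
             w = stats::runif(1, 0.03, 0.055))
      })
    }
    jitter_strokes <- function(strokes) {
      th <- stats::rnorm(1, 0, 5 * pi / 180)
      sc <- stats::runif(1, 0.92, 1.08)
      dx <- stats::runif(1, -0.04, 0.04)
      dy <- stats::runif(1, -0.04, 0.04)
      lapply(strokes, function(st) {
        x0 <- st$x - 0.5; y0 <- st$y - 0.5
        list(x = 0.5 + sc * (cos(th) * x0 - sin(th) * y0) + dx,
             y = 0.5 + sc * (sin(th) * x0 + cos(th) * y0) + dy,
             w = st$w * stats::runif(1, 0.85, 1.15))
      })
    }
    n_rot <- if (rotations) 4L else 1L
    n_total <- n_classes * n_rot
    protos <- vector("list", n_classes)
    proto_imgs <- vector("list", n_total)
    images <- vector("list", n_total * samples_per_class)
    cls <- integer(length(images)); base <- integer(length(images))
    rot <- integer(length(images))
    idx <- 0L
    for (b in seq_len(n_classes)) {
      repeat {
        strokes <- rand_strokes()
        proto <- render_glyph(strokes, image_size)
        if (mean(proto) > 0.02) break  # reject near-blank glyphs
      }
      protos[[b]] <- strokes
      samples <- lapply(seq_len(samples_per_class), function(s) {
        img <- render_glyph(jitter_strokes(strokes), image_size)
        img <- img + matrix(stats::rnorm(image_size^2, 0, 0.05),
                            image_size, image_size)
        pmin(pmax(img, 0), 1)
      })
      for (r in seq_len(n_rot)) {
        cid <- (b - 1L) * n_rot + r
        proto_imgs[[cid]] <- rot90k(proto, r - 1L)
        for (s in seq_len(samples_per_class)) {
          idx <- idx + 1L
          images[[idx]] <- rot90k(samples[[s]], r - 1L)
          cls[idx] <- cid; base[idx] <- b; rot[idx] <- (r - 1L) * 90L
        }
      }
    }
    split <- rep("test", n_total)
    split[sample(n_total, round(p_train * n_total))] <- "train"
    structure(list(images = images, class = cls, base_class = base,
                   rotation = rot, split = split, prototypes = proto_imgs,
                   n_classes = n_total, image_size = image_size,
                   samples_per_class = samples_per_class),
              class = "glyph_corpus")
  })
}

#' Generate one sequential character-recognition episode
#'
#' Samples a phase-1 class uniformly from the requested split, four
#' distractor classes (distinct, same split), and a *different* exemplar of
#' the phase-1 class for the matching phase-2 image; phase-2 slot order is
#' uniform.
#'
#' @param corpus A [generate_glyph_corpus()].
#' @param split `"train"` or `"test"`; episodes never mix splits.
#' @param cfg A [char_task_config()].
#' @return An object of class `char_episode`: `images` (list of
#'   `1 + n_phase2` matrices), `classes` (their class ids), `slot` (correct
#'   phase-2 slot), `windows` (list of step ranges per phase-2 slot),
#'   `phase1_window`, `t_image`.
#' @export
generate_char_episode <- function(corpus, split = c("train", "test"),
                                  cfg = char_task_config()) {
  split <- match.arg(split)
  pool <- which(corpus$split == split)
  n_d <- cfg$n_phase2 - 1
  if (length(pool) < n_d + 2) stop("split has too few classes", call. = FALSE)
  picked <- sample(pool, n_d + 1)
  target <- picked[1]; distractors <- picked[-1]
  t_idx <- which(corpus$class == target)
  ex <- sample(t_idx, 2)  # phase-1 exemplar and a different matching one
  d_imgs <- vapply(distractors, function(cl) sample(which(corpus$class == cl), 1),
                   integer(1))
  slot <- sample(cfg$n_phase2, 1)
  p2 <- integer(cfg$n_phase2)
  p2[slot] <- ex[2]
  p2[-slot] <- d_imgs
  windows <- lapply(seq_len(cfg$n_phase2), function(k) {
    (k * cfg$t_image + 1):((k + 1) * cfg$t_image)
  })
  structure(list(images = corpus$images[c(ex[1], p2)],
                 classes = corpus$class[c(ex[1], p2)],
                 slot = slot, windows = windows,
                 phase1_window = 1:cfg$t_image, t_image = cfg$t_image,
                 n_phase2 = cfg$n_phase2),
            class = "char_episode")
}

#' Load a character image directory as a glyph corpus
#'
#' Adapter for a user-supplied corpus of grayscale PNG images laid out as
#' `dir/<class_name>/<sample>.png`.  Images are resized by nearest-neighbour
#' sampling to the configured size.  This adapter is provided for
#' convenience and is not exercised by the package tests, which use the
#' synthetic generator.
#'
#' @param dir Directory with one subdirectory per class.
#' @param image_size Target side length.
#' @param p_train Fraction of classes assigned to the training split.
#' @param seed Seed for the split assignment.
#' @return A `glyph_corpus`-shaped object.
#' @export
read_glyph_dir <- function(dir, image_size = 28, p_train = 0.8,
                           seed = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading image directories requires the 'png' package",
         call. = FALSE)
  }
  classes <- list.dirs(dir, recursive = FALSE)
  if (length(classes) < 2) stop("no class subdirectories found", call. = FALSE)
  images <- list(); cls <- integer(0)
  for (ci in seq_along(classes)) {
    files <- list.files(classes[ci], pattern = "\\.png$", full.names = TRUE)
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      ri <- round(seq(1, nrow(img), length.out = image_size))
      ci2 <- round(seq(1, ncol(img), length.out = image_size))
      images[[length(images) + 1L]] <- 1 - img[ri, ci2]  # ink = high
      cls <- c(cls, ci)
    }
  }
  n_total <- length(classes)
  split <- with_seed(seed, {
    s <- rep("test", n_total)
    s[sample(n_total, round(p_train * n_total))] <- "train"
    s
  })
  structure(list(images = images, class = cls,
                 base_class = cls, rotation = rep(0L, length(cls)),
                 split = split, prototypes = NULL, n_classes = n_total,
                 image_size = image_size, samples_per_class = NA),
            class = "glyph_corpus")
}
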
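# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Stochastic sparse topology with fixed synapse types
#'
#' Draws an i.i.d. Bernoulli connectivity mask and assigns each connected
#' synapse a persistent type: inhibitory (sign -1) with probability
#' `p_inhibitory`, excitatory (+1) otherwise.  Weights are stored elsewhere
#' as nonnegative magnitudes; the effective weight is
#' `|W| * sign * mask`, so an inhibitory synapse always contributes
#' nonpositive current and plasticity can never flip a synapse's type.
#'
#' @param n_pre,n_post Layer dimensions (weights are `n_post x n_pre`).
#' @param p_connect Connection probability (default 0.5).
#' @param p_inhibitory Inhibitory probability among connected synapses
#'   (default 0.2).
#' @param seed Optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return An object of class `topology` with fields `mask` (0/1 matrix),
#'   `sign` (-1/+1 matrix), and `signmask = sign * mask`.
#' @export
init_topology <- function(n_pre, n_post, p_connect = 0.5, p_inhibitory = 0.2,
                          seed = NULL) {
  stopifnot(p_connect >= 0, p_connect <= 1,
            p_inhibitory >= 0, p_inhibitory <= 1)
  with_seed(seed, {
    mask <- matrix(stats::rbinom(n_post * n_pre, 1, p_connect),
                   n_post, n_pre)
    sign <- matrix(ifelse(stats::runif(n_post * n_pre) < p_inhibitory,
                          -1, 1), n_post, n_pre)
    structure(list(mask = mask, sign = sign, signmask = sign * mask,
                   p_connect = p_connect, p_inhibitory = p_inhibitory),
              class = "topology")
  })
}

#' Convolutional image encoder parameters
#'
#' Two 3x3 same-padding convolutions (1 -> 4 and 4 -> 4 channels), each
#' followed by a per-image, per-channel normalization with trainable scale
#' and shift, a rectifier, and 2x2/stride-2 max pooling.  On a 28x28 input
#' the spatial map shrinks 28 -> 14 -> 7, so the flattened output has
#' `4 * 7 * 7 = 196` entries — the current injected into the 196 spiking
#' input neurons.
#'
#' Kernels are stored flattened as `(out_channels x in_channels*9)` with
#' column index `(c_in - 1) * 9 + (dc + 1) * 3 + (dr + 1) + 1` for spatial
#' offset `(dr, dc)`.
#'
#' @param seed Optional seed for the kernel draw.
#' @return An object of class `conv_encoder` (list of parameter matrices).
#' @export
conv_encoder <- function(seed = NULL) {
  with_seed(seed, {
    structure(list(
      K1 = matrix(stats::rnorm(4 * 9, sd = sqrt(2 / 9)), 4, 9),
      bn1_gamma = matrix(1, 4, 1), bn1_beta = matrix(0, 4, 1),
      K2 = matrix(stats::rnorm(4 * 36, sd = sqrt(2 / 36)), 4, 36),
      bn2_gamma = matrix(1, 4, 1), bn2_beta = matrix(0, 4, 1)),
      class = "conv_encoder")
  })
}

# 3x3 same-padding cross-correlation; chans: list of H x W matrices,
# K: (out x in*9) flattened kernels
conv_same3 <- function(chans, K) {
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  n_out <- nrow(K)
  out <- vector("list", n_out)
  for (oc in seq_len(n_out)) out[[oc]] <- matrix(0, H, W)
  for (ci in seq_along(chans)) {
    pad <- matrix(0, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- chans[[ci]]
    for (dc in -1:1) for (dr in -1:1) {
      kk <- (ci - 1) * 9 + (dc + 1) * 3 + (dr + 1) + 1
      shifted <- pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
      for (oc in seq_len(n_out)) {
        out[[oc]] <- out[[oc]] + K[oc, kk] * shifted
      }
    }
  }
  out
}

inst_norm <- function(chans, gamma, beta, eps = 1e-5) {
  lapply(seq_along(chans), function(c) {
    x <- chans[[c]]
    mu <- mean(x)
    sd_ <- sqrt(mean((x - mu)^2) + eps)
    gamma[c] * (x - mu) / sd_ + beta[c]
  })
}

maxpool2 <- function(chans) {
  lapply(chans, function(x) {
    H <- nrow(x) %/% 2; W <- ncol(x) %/% 2
    out <- matrix(0, H, W)
    for (c in seq_len(W)) for (r in seq_len(H)) {
      out[r, c] <- max(x[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
    }
    out
  })
}

#' Encode grayscale images into input currents
#'
#' Runs the convolutional encoder and flattens channel-major, yielding one
#' 196-entry current vector per image.  The encoding is deterministic per
#' image (normalization statistics are per image and channel).
#'
#' @param images A single `28 x 28` matrix or a list of them.
#' @param enc A [conv_encoder()].
#' @return A `196 x n_images` matrix of input currents.
#' @export
encode_image <- function(images, enc) {
  if (is.matrix(images)) images <- list(images)
  out <- matrix(0, 196, length(images))
  for (j in seq_along(images)) {
    img <- images[[j]]
    if (!all(dim(img) == c(28, 28))) {
      stop("encoder expects 28 x 28 images", call. = FALSE)
    }
    h <- conv_same3(list(img), enc$K1)
    h <- inst_norm(h, enc$bn1_gamma, enc$bn1_beta)
    h <- maxpool2(lapply(h, pmax, 0))
    h <- conv_same3(h, enc$K2)
    h <- inst_norm(h, enc$bn2_gamma, enc$bn2_beta)
    h <- maxpool2(lapply(h, pmax, 0))
    # channel-major flatten: entry (c, pixel) -> (pixel - 1) * 4 + c
    out[, j] <- as.vector(do.call(rbind, lapply(h, as.vector)))
  }
  out
}

#' Forward pass of the plastic task network (DP-SNN)
#'
#' Open-loop reference simulator: given the episode's input spike raster and
#' a time-aligned per-input modulation stream, runs the CUBA hidden layer
#' with the plastic input synapses (pair or triplet STDP, eligibility
#' accumulation, three-factor application) and the fixed linear readout.
#' Plastic weights are stored as magnitudes; the effective weight is
#' `max(W, 0) * sign * mask` so synapse types are preserved.
#'
#' In the closed-loop trained system the modulation stream is produced
#' step-by-step by [nm_snn_forward()] from this network's own hidden
#' activity; the fast path that couples the two lives in compiled code and
#' is verified against this function.
#'
#' @param raster Input spike raster (`n_in x T`).
#' @param modulation Modulation stream (`2 n_in x T`): LTP rows first, then
#'   LTD rows.  Use zeros to freeze the weights.
#' @param W0 Initial plastic weight magnitudes (`n_hid x n_in`).
#' @param W_ro Readout weights (`n_out x n_hid`), non-plastic.
#' @param topology A [init_topology()] for the plastic layer.
#' @param trace_p,stdp_p,elig_p Plasticity parameter objects; `stdp_p$rule`
#'   selects pair vs triplet.
#' @param neuron,cfg Neuron and surrogate configurations.
#' @param gate Optional 0/1 vector of length `T`; modulation is applied only
#'   where `gate == 1` (default: everywhere).
#' @return List with `output` (`n_out x T` readout activity), `hidden`
#'   (`n_hid x T` spike raster), `W_final`, and `dw_max` (per-step maximum
#'   absolute weight change).
#' @export
dp_snn_forward <- function(raster, modulation, W0, W_ro, topology,
                           trace_p = trace_params(),
                           stdp_p = stdp_params(),
                           elig_p = eligibility_params(),
                           neuron = neuron_params(),
                           cfg = surrogate_config(), gate = NULL) {
  T_len <- ncol(raster)
  n_in <- nrow(raster)
  if (ncol(modulation) != T_len) {
    stop("modulation stream not time-aligned with raster", call. = FALSE)
  }
  if (is.null(gate)) gate <- rep(1, T_len)
  layer <- plastic_layer(W0, trace_p, stdp_p, elig_p, mask = topology$mask)
  st <- layer_state(nrow(W0), neuron)
  n_out <- nrow(W_ro)
  output <- matrix(0, n_out, T_len)
  hidden <- matrix(0, nrow(W0), T_len)
  dw_max <- numeric(T_len)
  for (t in seq_len(T_len)) {
    W_eff <- pmax(layer$W, 0) * topology$signmask
    step <- step_cuba(st, drop(W_eff %*% raster[, t]), neuron, cfg)
    st <- step$state
    s_h <- step$s
    hidden[, t] <- s_h
    output[, t] <- W_ro %*% s_h
    W_before <- layer$W
    m <- modulatory_signal("per_pre",
                           ltp = gate[t] * modulation[seq_len(n_in), t],
                           ltd = gate[t] * modulation[n_in + seq_len(n_in), t])
    layer <- plastic_layer_step(layer, raster[, t], s_h, m)
    dw_max[t] <- max(abs(layer$W - W_before))
  }
  list(output = output, hidden = hidden, W_final = layer$W, dw_max = dw_max)
}

#' Forward pass of the neuromodulatory network (NM-SNN)
#'
#' Two fully connected non-plastic CUBA layers read the concatenation of the
#' sensory spikes, the DP-SNN hidden spikes, and (cue task only) the
#' two-dimensional environment feedback.  A trainable linear head maps the
#' second layer's spikes to `2 n_in` values per step — per-presynaptic-input
#' LTP and LTD modulation — smoothed by a first-order low-pass filter with
#' retention `lambda_m` so the emitted signal is graded rather than binary.
#' Outside the allowed window (`gate == 0`) the emitted modulation is exactly
#' zero.
#'
#' @param sensory Sensory spike raster (`n_in x T`).
#' @param hidden DP-SNN hidden spike raster (`n_hid x T`).
#' @param feedback Optional feedback stream (`2 x T`); omit for tasks without
#'   an environment feedback channel.
#' @param params List with `W1`, `W2` (layer weights), `W_head`
#'   (`2 n_in x 64`), `b_head`, and `lambda_m`.
#' @param neuron,cfg Neuron and surrogate configurations.
#' @param gate Optional 0/1 vector of length `T`.
#' @return List with `modulation` (`2 n_in x T`, LTP rows then LTD rows,
#'   gated), `raster1`, `raster2` (the two layers' spikes).
#' @export
nm_snn_forward <- function(sensory, hidden, feedback = NULL, params,
                           neuron = neuron_params(),
                           cfg = surrogate_config(), gate = NULL) {
  T_len <- ncol(sensory)
  if (ncol(hidden) != T_len ||
      (!is.null(feedback) && ncol(feedback) != T_len)) {
    stop("NM-SNN inputs not time-aligned", call. = FALSE)
  }
  if (is.null(gate)) gate <- rep(1, T_len)
  n1 <- nrow(params$W1); n2 <- nrow(params$W2)
  st1 <- layer_state(n1, neuron); st2 <- layer_state(n2, neuron)
  n_mod <- nrow(params$W_head)
  modulation <- matrix(0, n_mod, T_len)
  raster1 <- matrix(0, n1, T_len); raster2 <- matrix(0, n2, T_len)
  m <- rep(0, n_mod)
  for (t in seq_len(T_len)) {
    z <- c(sensory[, t], hidden[, t],
           if (!is.null(feedback)) feedback[, t])
    s1 <- step_cuba(st1, drop(params$W1 %*% z), neuron, cfg)
    st1 <- s1$state
    s2 <- step_cuba(st2, drop(params$W2 %*% s1$s), neuron, cfg)
    st2 <- s2$state
    raster1[, t] <- s1$s; raster2[, t] <- s2$s
    m <- params$lambda_m * m + drop(params$W_head %*% s2$s + params$b_head)
    modulation[, t] <- gate[t] * m
  }
  list(modulation = modulation, raster1 = raster1, raster2 = raster2)
}
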
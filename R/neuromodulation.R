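#' Eligibility-trace parameters
#'
#' Plastic change is not applied to the weights directly: each step's LTP and
#' LTD terms are accumulated into paired eligibility traces that decay with
#' retention `gamma` and are converted into weight change only when a
#' modulatory signal arrives (the three-factor rule).
#'
#' @param gamma Eligibility retention per step, in `[0, 1]`; with no synaptic
#'   activity each entry decays exactly geometrically.
#' @param alpha_e Accumulation rate; scalar or `n_post x n_pre` matrix
#'   (per-synapse, outer-loop-trainable in the meta-learning setting).
#' @return An object of class `eligibility_params`.
#' @export
eligibility_params <- function(gamma = 0.98, alpha_e = 1) {
  stopifnot(gamma >= 0, gamma <= 1)
  structure(list(gamma = gamma, alpha_e = alpha_e),
            class = "eligibility_params")
}

#' Paired LTP/LTD eligibility state
#'
#' @param n_pre,n_post Layer dimensions.
#' @return An `eligibility_state` list with synapse-shaped matrices `E_plus`
#'   and `E_minus` (both `n_post x n_pre`).
#' @export
eligibility_state <- function(n_pre, n_post) {
  structure(list(E_plus = matrix(0, n_post, n_pre),
                 E_minus = matrix(0, n_post, n_pre)),
            class = "eligibility_state")
}

#' Accumulate STDP terms into the eligibility traces
#'
#' `E±' = gamma * E± + alpha_e * delta±` (elementwise).  The increments are
#' the current step's STDP LTP/LTD terms stored as nonnegative magnitudes;
#' sign is re-applied at modulation time, which lets independent LTP and LTD
#' modulation channels scale and reverse each pathway.
#'
#' @param E An [eligibility_state()].
#' @param d_plus,d_minus LTP / LTD increment matrices (from
#'   [pair_stdp_delta()] or [triplet_stdp_delta()]).
#' @param p An [eligibility_params()].
#' @return Updated `eligibility_state`.
#' @export
accumulate_eligibility <- function(E, d_plus, d_minus,
                                   p = eligibility_params()) {
  if (!all(dim(E$E_plus) == dim(d_plus)) ||
      !all(dim(E$E_minus) == dim(d_minus))) {
    stop("eligibility/increment shape mismatch", call. = FALSE)
  }
  E$E_plus <- p$gamma * E$E_plus + p$alpha_e * d_plus
  E$E_minus <- p$gamma * E$E_minus + p$alpha_e * d_minus
  E
}

#' Modulatory signal for three-factor weight application
#'
#' Every mode carries separate LTP and LTD channels:
#' * `"global"`: one scalar per channel;
#' * `"response_function"`: scalar per channel, expanded per postsynaptic
#'   neuron as `h(b_j * M)` with per-neuron feedback gains `b`;
#' * `"per_post"`: one value per postsynaptic neuron;
#' * `"per_pre"`: one value per presynaptic input (the form used by both
#'   study tasks, emitted by the neuromodulatory network).
#'
#' @param mode Broadcasting mode, see above.
#' @param ltp,ltd The LTP / LTD payload: scalars for `"global"` and
#'   `"response_function"`, vectors otherwise.
#' @param b Per-postsynaptic-neuron feedback gains (`"response_function"`
#'   mode only).
#' @param h Scalar response function (`"response_function"` mode only);
#'   default identity, `tanh` is a common alternative.
#' @return An object of class `modulatory_signal`.
#' @export
modulatory_signal <- function(mode = c("global", "response_function",
                                       "per_post", "per_pre"),
                              ltp, ltd, b = NULL, h = identity) {
  mode <- match.arg(mode)
  if (mode %in% c("global", "response_function")) {
    stopifnot(length(ltp) == 1, length(ltd) == 1)
  }
  if (mode == "response_function") stopifnot(!is.null(b))
  structure(list(mode = mode, ltp = ltp, ltd = ltd, b = b, h = h),
            class = "modulatory_signal")
}

# expand a modulation channel to a synapse-shaped matrix
expand_modulation <- function(value, m, n_post, n_pre) {
  switch(m$mode,
    global = matrix(value, n_post, n_pre),
    response_function = {
      if (length(m$b) != n_post) stop("feedback gains b must be per-post",
                                      call. = FALSE)
      matrix(m$h(m$b * value), n_post, n_pre)
    },
    per_post = {
      if (length(value) != n_post) stop("per_post payload length mismatch",
                                        call. = FALSE)
      matrix(value, n_post, n_pre)
    },
    per_pre = {
      if (length(value) != n_pre) stop("per_pre payload length mismatch",
                                       call. = FALSE)
      matrix(value, n_post, n_pre, byrow = TRUE)
    }
  )
}

#' Realize eligibility as weight change under a modulatory signal
#'
#' `W' = W + Mod+ * E_plus - Mod- * E_minus`, with `Mod±` broadcast by the
#' signal's mode.  With all modulation values zero the weights are returned
#' bitwise unchanged: no modulator, no plasticity.
#'
#' @param W Weight matrix (`n_post x n_pre`).
#' @param E An [eligibility_state()].
#' @param m A [modulatory_signal()].
#' @return Updated weight matrix.
#' @export
apply_modulation <- function(W, E, m) {
  n_post <- nrow(W); n_pre <- ncol(W)
  if (!all(dim(E$E_plus) == c(n_post, n_pre))) {
    stop("eligibility/weight shape mismatch", call. = FALSE)
  }
  if (all(m$ltp == 0) && all(m$ltd == 0)) return(W)
  Mp <- expand_modulation(m$ltp, m, n_post, n_pre)
  Mm <- expand_modulation(m$ltd, m, n_post, n_pre)
  W + Mp * E$E_plus - Mm * E$E_minus
}

#' Bundle the mutable state of one plastic synaptic layer
#'
#' @param W Initial weight matrix (`n_post x n_pre`).
#' @param trace_p A [trace_params()].
#' @param stdp_p An [stdp_params()].
#' @param elig_p An [eligibility_params()].
#' @param mask Optional binary connectivity mask shaped like `W`; masked-out
#'   synapses are pinned to zero weight and zero eligibility.
#' @return An object of class `plastic_layer`.
#' @export
plastic_layer <- function(W, trace_p = trace_params(),
                          stdp_p = stdp_params(),
                          elig_p = eligibility_params(), mask = NULL) {
  if (!is.null(mask)) W <- W * mask
  structure(list(W = W,
                 traces = trace_state(ncol(W), nrow(W)),
                 E = eligibility_state(ncol(W), nrow(W)),
                 trace_p = trace_p, stdp_p = stdp_p, elig_p = elig_p,
                 mask = mask),
            class = "plastic_layer")
}

#' One full three-factor update of a plastic layer
#'
#' Composition, once per simulation step: advance traces, compute the STDP
#' LTP/LTD terms from the updated traces and current spikes, accumulate them
#' into the eligibilities, then realize weight change under the modulatory
#' signal.  With a zero signal the weights stay bitwise constant while
#' traces and eligibilities still evolve.
#'
#' @param layer A [plastic_layer()].
#' @param s_pre,s_post Binary spike vectors for the current step.
#' @param m A [modulatory_signal()].
#' @return Updated `plastic_layer`.
#' @export
plastic_layer_step <- function(layer, s_pre, s_post, m) {
  layer$traces <- advance_traces(layer$traces, s_pre, s_post, layer$trace_p)
  d <- if (layer$stdp_p$rule == "pair") {
    pair_stdp_delta(layer$traces, s_pre, s_post, layer$W, layer$stdp_p)
  } else {
    triplet_stdp_delta(layer$traces, s_pre, s_post, layer$W, layer$stdp_p)
  }
  if (!is.null(layer$mask)) {
    d$d_plus <- d$d_plus * layer$mask
    d$d_minus <- d$d_minus * layer$mask
  }
  layer$E <- accumulate_eligibility(layer$E, d$d_plus, d$d_minus,
                                    layer$elig_p)
  layer$W <- apply_modulation(layer$W, layer$E, m)
  if (!is.null(layer$mask)) layer$W <- layer$W * layer$mask
  layer
}
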
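#' Synaptic activity-trace parameters
#'
#' Pre- and post-synaptic spikes are summarised by exponentially decaying
#' activity traces.  With retention factor `alpha_x` (the discrete-time
#' analogue of `1 - 1/tau`), the linear variant increments the trace by a
#' constant `beta` per spike; the saturating variant scales the increment by
#' the distance to `x_max`, soft-bounding the trace to `[0, x_max]`.
#'
#' The slow retention `alpha_tau` drives the second postsynaptic trace used
#' by the triplet STDP rule.  A "slow" trace means *larger* retention, i.e.
#' `alpha_tau > alpha_x`; the two constants are exposed independently and
#' the inequality is not enforced.
#'
#' @param alpha_x Fast-trace retention per step, in `(0, 1)`.
#' @param alpha_tau Slow-trace retention per step, in `(0, 1)`.
#' @param beta Per-spike increment (> 0).
#' @param x_max Saturation bound (> 0), used by the saturating variant only.
#' @param variant `"linear"` (default, used by both study tasks) or
#'   `"saturating"`.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(alpha_x = 0.9, alpha_tau = 0.98, beta = 1,
                         x_max = 2, variant = c("linear", "saturating")) {
  variant <- match.arg(variant)
  stopifnot(alpha_x > 0, alpha_x < 1, alpha_tau > 0, alpha_tau < 1, beta > 0)
  if (variant == "saturating") stopifnot(x_max > 0)
  structure(list(alpha_x = alpha_x, alpha_tau = alpha_tau, beta = beta,
                 x_max = x_max, variant = variant),
            class = "trace_params")
}

#' Advance a synaptic activity trace by one step
#'
#' Linear variant: `x' = alpha * x + beta * s`.
#' Saturating variant: `x' = alpha * x + beta * (x_max - x) * s`.
#'
#' @param x Trace vector (nonnegative).
#' @param s Binary spike vector, same length as `x`.
#' @param p A [trace_params()].
#' @param slow If `TRUE`, decay with `alpha_tau` instead of `alpha_x`.
#' @return Updated trace vector.
#' @export
trace_step <- function(x, s, p = trace_params(), slow = FALSE) {
  if (length(x) != length(s)) stop("trace/spike shape mismatch", call. = FALSE)
  alpha <- if (slow) p$alpha_tau else p$alpha_x
  if (p$variant == "linear") {
    alpha * x + p$beta * s
  } else {
    alpha * x + p$beta * (p$x_max - x) * s
  }
}

#' Trace state for a plastic layer
#'
#' Bundles the presynaptic fast trace, postsynaptic fast trace, postsynaptic
#' slow trace, and the slow trace's value one step earlier (the triplet rule
#' reads the slow trace at `t - 1`).
#'
#' @param n_pre,n_post Layer dimensions.
#' @return A `trace_state` list with fields `x_pre`, `x_post`, `x_post_slow`,
#'   `x_post_slow_prev`.
#' @export
trace_state <- function(n_pre, n_post) {
  structure(list(x_pre = rep(0, n_pre), x_post = rep(0, n_post),
                 x_post_slow = rep(0, n_post),
                 x_post_slow_prev = rep(0, n_post)),
            class = "trace_state")
}

#' Advance all traces of a plastic layer by one step
#'
#' Decay-and-increment of all three traces for the current step's spikes.
#' `x_post_slow_prev` is captured *before* the slow trace is advanced, so the
#' triplet rule can read the one-step-old slow trace after this call.
#'
#' @param traces A [trace_state()].
#' @param s_pre,s_post Binary spike vectors for the pre- and post-synaptic
#'   populations at the current step.
#' @param p A [trace_params()].
#' @return Updated `trace_state`.
#' @export
advance_traces <- function(traces, s_pre, s_post, p = trace_params()) {
  traces$x_post_slow_prev <- traces$x_post_slow
  traces$x_pre <- trace_step(traces$x_pre, s_pre, p)
  traces$x_post <- trace_step(traces$x_post, s_post, p)
  traces$x_post_slow <- trace_step(traces$x_post_slow, s_post, p, slow = TRUE)
  traces
}

#' STDP rule parameters
#'
#' @param eta_plus LTP rate; scalar or `n_post x n_pre` matrix (per synapse).
#' @param eta_minus LTD rate; scalar or matrix as above.
#' @param w_min,w_max Soft lower/upper weight bounds (`w_min < w_max`).
#' @param mu Weight-dependence exponent in `[0, 1]`, used by the `"power"`
#'   dependence; `mu = 0` reproduces `"additive"`, `mu = 1` reproduces
#'   `"multiplicative"`.
#' @param rule `"pair"` or `"triplet"`.
#' @param dependence `"additive"`, `"multiplicative"`, or `"power"`.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(eta_plus = 0.01, eta_minus = 0.01,
                        w_min = 0, w_max = 1, mu = 0,
                        rule = c("pair", "triplet"),
                        dependence = c("additive", "multiplicative", "power")) {
  rule <- match.arg(rule)
  dependence <- match.arg(dependence)
  stopifnot(w_min < w_max, mu >= 0, mu <= 1)
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus,
                 w_min = w_min, w_max = w_max, mu = mu,
                 rule = rule, dependence = dependence),
            class = "stdp_params")
}

#' Weight-dependence factors for STDP
#'
#' Computes the per-synapse LTP and LTD scale factors as a function of the
#' current weights:
#' * additive: `A+ = eta_plus`, `A- = eta_minus` (no weight dependence);
#' * multiplicative: `A+ = eta_plus * (w_max - W)`,
#'   `A- = eta_minus * (W - w_min)`;
#' * power: `A+ = eta_plus * (w_max - W)^mu`,
#'   `A- = eta_minus * (W - w_min)^mu`, with `W` clamped to
#'   `[w_min, w_max]` before exponentiation so fractional powers stay real.
#'
#' @param W Weight matrix (`n_post x n_pre`), finite.
#' @param p An [stdp_params()].
#' @return List with matrices `A_plus` and `A_minus`, shaped like `W`.
#' @export
weight_dependence <- function(W, p = stdp_params()) {
  if (!all(is.finite(W))) stop("non-finite weights", call. = FALSE)
  ep <- p$eta_plus; em <- p$eta_minus
  ones <- array(1, dim(W))
  switch(p$dependence,
    additive = list(A_plus = ep * ones, A_minus = em * ones),
    multiplicative = list(A_plus = ep * (p$w_max - W),
                          A_minus = em * (W - p$w_min)),
    power = {
      Wc <- pmin(pmax(W, p$w_min), p$w_max)
      list(A_plus = ep * (p$w_max - Wc)^p$mu,
           A_minus = em * (Wc - p$w_min)^p$mu)
    }
  )
}

#' Pair-based STDP weight-change terms
#'
#' LTP fires on a postsynaptic spike in proportion to the presynaptic trace;
#' LTD fires on a presynaptic spike in proportion to the postsynaptic trace:
#' \deqn{\Delta W_{ji} = A^+_{ji} x^{pre}_i s^{post}_j
#'                       - A^-_{ji} x^{post}_j s^{pre}_i}
#' Traces must already be advanced to the current step ([advance_traces()]
#' first, then the delta — the convention that makes the Hebbian window hold
#' at lag 0).
#'
#' @param traces A [trace_state()] advanced to the current step.
#' @param s_pre,s_post Binary spike vectors at the current step.
#' @param W Weight matrix (`n_post x n_pre`).
#' @param p An [stdp_params()].
#' @return List with nonnegative-magnitude matrices `d_plus` (LTP term) and
#'   `d_minus` (LTD term), plus their signed sum `delta = d_plus - d_minus`.
#' @export
pair_stdp_delta <- function(traces, s_pre, s_post, W, p = stdp_params()) {
  A <- weight_dependence(W, p)
  d_plus <- A$A_plus * (s_post %o% traces$x_pre)
  d_minus <- A$A_minus * (traces$x_post %o% s_pre)
  list(d_plus = d_plus, d_minus = d_minus, delta = d_plus - d_minus)
}

#' Triplet-based STDP weight-change terms
#'
#' The LTP term couples one presynaptic spike with two postsynaptic events:
#' it is gated by the current postsynaptic spike and additionally scaled by
#' the *slow* postsynaptic trace read one step before the fast traces'
#' evaluation time.  LTD is identical to the pair rule:
#' \deqn{\Delta W_{ji} = A^+_{ji} x^{pre}_i \bar{x}^{post}_j(t-1) s^{post}_j
#'                       - A^-_{ji} x^{post}_j s^{pre}_i}
#' With the slow trace pinned at 1 this reduces exactly to
#' [pair_stdp_delta()].
#'
#' @inheritParams pair_stdp_delta
#' @return Same structure as [pair_stdp_delta()].
#' @export
triplet_stdp_delta <- function(traces, s_pre, s_post, W, p = stdp_params()) {
  A <- weight_dependence(W, p)
  d_plus <- A$A_plus * ((s_post * traces$x_post_slow_prev) %o% traces$x_pre)
  d_minus <- A$A_minus * (traces$x_post %o% s_pre)
  list(d_plus = d_plus, d_minus = d_minus, delta = d_plus - d_minus)
}
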
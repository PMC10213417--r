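#' Neuron parameters for discrete-time CUBA leaky integrate-and-fire layers
#'
#' The current-based (CUBA) LIF neuron keeps two state variables per neuron:
#' a current trace `u` that integrates weighted input spikes and leaks toward
#' `u_rest`, and a membrane potential `v` that integrates `R * u` and leaks
#' toward `v_rest`.  When `v` crosses `v_th` the neuron emits a spike and `v`
#' is hard-reset to `v_rest`.
#'
#' The leak constants are per-step decay fractions: with zero input,
#' `v(t+1) - v_rest = (1 - alpha_v) * (v(t) - v_rest)`.  A leak of 0 means no
#' decay, 1 means full decay within one step.
#'
#' @param alpha_u Current-trace leak fraction per step, in `[0, 1]`.
#' @param alpha_v Membrane-potential leak fraction per step, in `[0, 1]`.
#' @param u_rest Resting current (arbitrary units).
#' @param v_rest Resting potential; also the post-spike reset value.
#' @param R Resistance scale applied to the current trace in the voltage update.
#' @param v_th Firing threshold; must exceed `v_rest`.
#' @param dt Simulation step duration in ms (bookkeeping only; the update
#'   equations are expressed per step).
#' @param post_update_u If `TRUE`, the voltage update uses the current trace
#'   *after* this step's integration rather than before it.  The default
#'   `FALSE` reads the update literally: `v` consumes the pre-update `u`.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params(alpha_u = 0.5, alpha_v = 0.5, v_th = 10)
#' @export
neuron_params <- function(alpha_u = 0.3, alpha_v = 0.3, u_rest = 0,
                          v_rest = 0, R = 1, v_th = 1, dt = 1,
                          post_update_u = FALSE) {
  stopifnot(alpha_u >= 0, alpha_u <= 1, alpha_v >= 0, alpha_v <= 1,
            v_th > v_rest, dt > 0)
  structure(list(alpha_u = alpha_u, alpha_v = alpha_v, u_rest = u_rest,
                 v_rest = v_rest, R = R, v_th = v_th, dt = dt,
                 post_update_u = isTRUE(post_update_u)),
            class = "neuron_params")
}

#' Surrogate-derivative configuration for the spike nonlinearity
#'
#' The forward pass of [spike()] is the exact Heaviside step of
#' `v - v_th`; its true derivative is zero almost everywhere, so
#' backpropagation through time replaces it with a smooth, peaked surrogate.
#' Two families are provided:
#'
#' * `"exp"` (default, SLAYER-style): `amplitude * exp(-scale * |v - v_th|)`.
#' * `"fast_sigmoid"`: `amplitude / (1 + scale * |v - v_th|)^2`.
#'
#' Both peak at `amplitude` when `v == v_th`.
#'
#' @param shape `"exp"` or `"fast_sigmoid"`.
#' @param scale Steepness (> 0); larger values concentrate gradient mass
#'   closer to threshold.
#' @param amplitude Peak backward-pass gain (> 0).
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(shape = c("exp", "fast_sigmoid"),
                             scale = 5, amplitude = 0.5) {
  shape <- match.arg(shape)
  stopifnot(scale > 0, amplitude > 0)
  structure(list(shape = shape, scale = scale, amplitude = amplitude),
            class = "surrogate_config")
}

#' Spike nonlinearity (Heaviside forward, surrogate backward)
#'
#' Forward pass of the threshold nonlinearity: 1 where the membrane potential
#' strictly exceeds the threshold, else 0.  The companion
#' [surrogate_grad()] evaluates the backward-pass derivative contract.
#'
#' @param v Numeric vector of membrane potentials (finite).
#' @param v_th Firing threshold.
#' @param cfg A [surrogate_config()]; unused in the forward pass but kept in
#'   the signature because forward and backward form one operator.
#' @return Binary numeric vector of the same length as `v`.
#' @export
spike <- function(v, v_th, cfg = surrogate_config()) {
  if (!all(is.finite(v))) {
    stop("non-finite membrane potential: numerical divergence", call. = FALSE)
  }
  as.numeric(v > v_th)
}

#' Surrogate derivative of the spike nonlinearity
#'
#' @inheritParams spike
#' @return Numeric vector: the surrogate derivative evaluated at `v - v_th`.
#'   Equals `cfg$amplitude` exactly at `v == v_th`.
#' @export
surrogate_grad <- function(v, v_th, cfg = surrogate_config()) {
  d <- abs(v - v_th)
  switch(cfg$shape,
    exp = cfg$amplitude * exp(-cfg$scale * d),
    fast_sigmoid = cfg$amplitude / (1 + cfg$scale * d)^2
  )
}

#' Create a resting layer state
#'
#' @param n Number of neurons.
#' @param p A [neuron_params()] supplying the resting values.
#' @return A `layer_state` list with fields `u`, `v` and `s` (last spikes).
#' @export
layer_state <- function(n, p = neuron_params()) {
  structure(list(u = rep(p$u_rest, n), v = rep(p$v_rest, n), s = rep(0, n)),
            class = "layer_state")
}

#' One discrete CUBA LIF update step
#'
#' Updates the current trace with the (already weighted) input current,
#' advances the membrane potential, emits spikes, and hard-resets spiking
#' neurons to `v_rest`:
#' \deqn{u' = u - \alpha_u (u - u_{rest}) + I_{in}}
#' \deqn{v' = v - \alpha_v (v - v_{rest}) + R u}
#' where the voltage update consumes the pre-update current trace by default
#' (see `post_update_u` in [neuron_params()]).
#'
#' @param state A `layer_state`.
#' @param I_in Weighted input-current vector (one entry per neuron); for a
#'   layer with weight matrix `W` (post x pre) and presynaptic spikes `s`,
#'   this is `W %*% s`.
#' @param p A [neuron_params()].
#' @param cfg A [surrogate_config()] (forward pass only uses the threshold).
#' @return A list with `state` (updated `layer_state`) and `s` (spike vector).
#' @export
step_cuba <- function(state, I_in, p = neuron_params(),
                      cfg = surrogate_config()) {
  n <- length(state$u)
  if (length(I_in) != n || length(state$v) != n) {
    stop("shape mismatch between layer state and input current", call. = FALSE)
  }
  if (!all(is.finite(state$u)) || !all(is.finite(state$v)) ||
      !all(is.finite(I_in))) {
    stop("non-finite layer state or input: numerical divergence",
         call. = FALSE)
  }
  u_new <- state$u - p$alpha_u * (state$u - p$u_rest) + I_in
  u_for_v <- if (p$post_update_u) u_new else state$u
  v_new <- state$v - p$alpha_v * (state$v - p$v_rest) + p$R * u_for_v
  s <- spike(v_new, p$v_th, cfg)
  v_new[s == 1] <- p$v_rest
  state$u <- u_new
  state$v <- v_new
  state$s <- s
  list(state = state, s = s)
}

#' Run a CUBA layer over an input raster
#'
#' Applies [step_cuba()] sequentially over `T` steps.  The input raster holds
#' presynaptic spikes; each column is weighted through `W` before entering
#' the current trace.
#'
#' @param state Initial `layer_state` (carried state is allowed, so rasters
#'   can be processed in chunks).
#' @param raster Presynaptic spike raster, `n_pre x T` matrix.
#' @param W Weight matrix, `n_post x n_pre`.
#' @param p A [neuron_params()].
#' @param cfg A [surrogate_config()].
#' @return A list with `raster` (`n_post x T` spike raster), `state` (final
#'   state), and `v_trace` (`n_post x T` matrix of post-reset potentials).
#' @export
run_layer <- function(state, raster, W, p = neuron_params(),
                      cfg = surrogate_config()) {
  if (!is.matrix(raster) || ncol(raster) < 1) {
    stop("input raster must be a matrix with at least one time step",
         call. = FALSE)
  }
  T_len <- ncol(raster)
  n_post <- nrow(W)
  out <- matrix(0, n_post, T_len)
  v_trace <- matrix(0, n_post, T_len)
  for (t in seq_len(T_len)) {
    st <- step_cuba(state, drop(W %*% raster[, t]), p, cfg)
    state <- st$state
    out[, t] <- st$s
    v_trace[, t] <- state$v
  }
  list(raster = out, state = state, v_trace = v_trace)
}
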
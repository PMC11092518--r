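#' Tsodyks-Markram synapse parameters
#'
#' Short-term-plasticity parameters for one connection (presynaptic type to
#' postsynaptic type). Each presynaptic spike releases a fraction `R = u x`
#' of synaptic resources, where `u` is the running release probability
#' (facilitation, incremented by `U (1 - u)` at each spike and decaying to 0
#' with time constant `tau_u` between spikes) and `x` is the available
#' resource fraction (depression, reduced by `R` at each spike and recovering
#' to 1 with `tau_x`). The release increments two conductance channels: a
#' fast channel with gain `g_fast` and decay `tau_d_fast` (AMPA- or
#' GABA_A-like) and a slow channel with gain `g_slow` and decay `tau_d_slow`
#' (NMDA- or GABA_B-like).
#'
#' @param g_fast Peak fast conductance gain (nS), non-negative.
#' @param tau_d_fast Fast conductance decay (ms), positive.
#' @param U Baseline release fraction in `[0, 1]`.
#' @param tau_u Facilitation decay constant (ms), positive.
#' @param tau_x Depression recovery constant (ms), positive.
#' @param g_slow Slow conductance gain (nS), non-negative.
#' @param tau_d_slow Slow conductance decay (ms), positive (a shared
#'   simulator-convention default of 150 ms is used by the packaged tables).
#' @return An object of class `tm_params`.
#' @export
tm_params <- function(g_fast, tau_d_fast, U, tau_u, tau_x,
                      g_slow = 0, tau_d_slow = 150) {
  if (U < 0 || U > 1) stop("tm_params: U must be in [0, 1]")
  if (any(c(tau_d_fast, tau_u, tau_x, tau_d_slow) <= 0)) {
    stop("tm_params: all time constants must be positive")
  }
  if (g_fast < 0 || g_slow < 0) stop("tm_params: gains must be non-negative")
  structure(list(g_fast = g_fast, tau_d_fast = tau_d_fast, U = U,
                 tau_u = tau_u, tau_x = tau_x, g_slow = g_slow,
                 tau_d_slow = tau_d_slow),
            class = "tm_params")
}

#' Synapse group: an edge list with short-term-plasticity state
#'
#' Bundles a sparse edge list between two populations with per-edge
#' Tsodyks-Markram state (`u`, `x`) and per-postsynaptic-neuron conductances
#' for the fast and slow receptor channels.
#'
#' @param pre,post Integer vectors of presynaptic and postsynaptic neuron
#'   indices (1-based), one entry per edge.
#' @param weight Non-negative weight multiplier per edge (default all 1:
#'   unitary weights).
#' @param n_pre,n_post Population sizes (defaults: max index seen).
#' @param delay Conduction delay in ms (default 1).
#' @return An object of class `synapse_group` with fields `pre`, `post`,
#'   `weight`, `u`, `x` (per edge), `s_fast`, `s_slow` (per postsynaptic
#'   neuron, nS), `n_pre`, `n_post`, `delay`.
#' @export
synapse_group <- function(pre, post, weight = NULL, n_pre = NULL,
                          n_post = NULL, delay = 1) {
  pre <- as.integer(pre)
  post <- as.integer(post)
  if (length(pre) != length(post)) stop("synapse_group: pre/post length mismatch")
  if (is.null(weight)) weight <- rep(1, length(pre))
  if (any(weight < 0)) stop("synapse_group: weights must be non-negative")
  if (is.null(n_pre)) n_pre <- if (length(pre) > 0) max(pre) else 0L
  if (is.null(n_post)) n_post <- if (length(post) > 0) max(post) else 0L
  if (length(pre) > 0 && (min(pre) < 1 || max(pre) > n_pre)) {
    stop("synapse_group: presynaptic index out of range")
  }
  if (length(post) > 0 && (min(post) < 1 || max(post) > n_post)) {
    stop("synapse_group: postsynaptic index out of range")
  }
  structure(list(pre = pre, post = post, weight = as.numeric(weight),
                 u = rep(0, length(pre)), x = rep(1, length(pre)),
                 s_fast = rep(0, n_post), s_slow = rep(0, n_post),
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 delay = delay),
            class = "synapse_group")
}

#' Apply presynaptic spikes to a synapse group
#'
#' For every edge whose presynaptic neuron is in `spiking`, applies the
#' Tsodyks-Markram release update: `u <- u + U (1 - u)`, release `R = u x`,
#' `x <- x - R`, and increments the postsynaptic fast and slow conductances by
#' `g * weight * R`.
#'
#' @param group A [synapse_group()].
#' @param params A [tm_params()] object.
#' @param spiking Integer vector of presynaptic neuron indices that spiked.
#' @return The updated `synapse_group`.
#' @export
tm_on_spike <- function(group, params, spiking) {
  if (!inherits(group, "synapse_group")) stop("group must be a synapse_group")
  if (!inherits(params, "tm_params")) stop("params must be tm_params")
  spiking <- as.integer(spiking)
  if (length(spiking) > 0 && (min(spiking) < 1 || max(spiking) > group$n_pre)) {
    stop("tm_on_spike: spiking index out of range")
  }
  hit <- group$pre %in% spiking
  if (!any(hit)) return(group)
  u_new <- group$u[hit] + params$U * (1 - group$u[hit])
  release <- u_new * group$x[hit]
  group$u[hit] <- u_new
  group$x[hit] <- group$x[hit] - release
  inc_fast <- params$g_fast * group$weight[hit] * release
  inc_slow <- params$g_slow * group$weight[hit] * release
  post_hit <- group$post[hit]
  group$s_fast <- group$s_fast +
    as.numeric(tapply_sum(inc_fast, post_hit, group$n_post))
  group$s_slow <- group$s_slow +
    as.numeric(tapply_sum(inc_slow, post_hit, group$n_post))
  group
}

# Sum `values` into bins given by `index` over 1..n (dense result).
tapply_sum <- function(values, index, n) {
  out <- numeric(n)
  acc <- rowsum(values, index)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Decay synapse-group state over an interval
#'
#' Applies the exact exponential inter-spike dynamics over `dt` ms:
#' `u` decays toward 0 with `tau_u`, `x` recovers toward 1 with `tau_x`, and
#' the fast/slow conductances decay toward 0 with their respective decay
#' constants. Being closed-form, the update carries no integration error for
#' any `dt`.
#'
#' @param group A [synapse_group()].
#' @param params A [tm_params()] object.
#' @param dt Interval (ms), positive.
#' @return The updated `synapse_group`.
#' @export
tm_decay <- function(group, params, dt) {
  if (dt <= 0) stop("tm_decay: dt must be positive")
  group$u <- group$u * exp(-dt / params$tau_u)
  group$x <- 1 - (1 - group$x) * exp(-dt / params$tau_x)
  group$s_fast <- group$s_fast * exp(-dt / params$tau_d_fast)
  group$s_slow <- group$s_slow * exp(-dt / params$tau_d_slow)
  group
}

#' Voltage-dependent magnesium-block factor
#'
#' Scaling applied to the slow excitatory (NMDA-like) channel:
#' `((v + 80) / 60)^2 / (1 + ((v + 80) / 60)^2)`.
#'
#' @param v Membrane voltage (mV), scalar or vector.
#' @return The block factor in `[0, 1)`.
#' @export
mg_block <- function(v) {
  z <- ((v + 80) / 60)^2
  z / (1 + z)
}

#' Synaptic current from per-channel conductances
#'
#' Computes the total synaptic current per neuron from the four receptor
#' channels: `I = sum_channel s * (E_rev - v)`, with the slow excitatory
#' channel additionally scaled by the voltage-dependent magnesium-block
#' factor. Reversal potentials follow the simulator-default convention:
#' fast/slow excitatory 0 mV, fast inhibitory -70 mV, slow inhibitory -90 mV.
#'
#' @param s_fast_exc,s_slow_exc,s_fast_inh,s_slow_inh Conductances per neuron
#'   (nS) for the four channels; scalars recycle.
#' @param v_post Postsynaptic voltage (mV) per neuron.
#' @param E Named list of reversal potentials with entries `E_fast_exc`,
#'   `E_slow_exc`, `E_fast_inh`, `E_slow_inh` (mV).
#' @return Current per neuron (pA; nS * mV = pA).
#' @export
#' @examples
#' synaptic_current(s_fast_inh = 1, v_post = -50)  # -20 pA, hyperpolarizing
synaptic_current <- function(s_fast_exc = 0, s_slow_exc = 0,
                             s_fast_inh = 0, s_slow_inh = 0, v_post,
                             E = list(E_fast_exc = 0, E_slow_exc = 0,
                                      E_fast_inh = -70, E_slow_inh = -90)) {
  s_fast_exc * (E$E_fast_exc - v_post) +
    s_slow_exc * (E$E_slow_exc - v_post) * mg_block(v_post) +
    s_fast_inh * (E$E_fast_inh - v_post) +
    s_slow_inh * (E$E_slow_inh - v_post)
}
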
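#' Nine-parameter Izhikevich neuron parameters
#'
#' Constructs and validates the parameter set of the nine-parameter Izhikevich
#' dynamical model used for every population in the network. The dynamics are
#' \deqn{C \frac{dv}{dt} = k (v - V_r)(v - V_t) - u + I}
#' \deqn{\frac{du}{dt} = a (b (v - V_r) - u)}
#' with the spike rule: when \eqn{v \ge V_{peak}}, the voltage is reset to
#' `Vreset` and the recovery variable is incremented by `d`.
#'
#' Units are fixed package-wide as pF (C), nS/mV (k), mV (voltages), 1/ms (a),
#' nS (b) and pA (d), so published parameter tables can be used verbatim.
#'
#' @param C Membrane capacitance (pF), positive.
#' @param k Voltage-curvature gain (nS/mV).
#' @param Vr Resting voltage (mV).
#' @param Vt Instantaneous threshold voltage (mV), must exceed `Vr`.
#' @param a Recovery time-scale (1/ms), non-negative.
#' @param b Recovery coupling (nS); may be negative (e.g. CA1 pyramidal cells).
#' @param Vpeak Spike cutoff (mV), must exceed `Vt`.
#' @param Vreset Post-spike reset voltage (mV), below `Vpeak`.
#' @param d Post-spike recovery increment (pA); may be zero (stellate cells).
#' @return An object of class `izh_params`.
#' @export
#' @examples
#' stellate <- izh_params(C = 118, k = 0.62, Vr = -58.53, Vt = -43.52,
#'                        a = 0.005, b = 11.69, Vpeak = 11.48,
#'                        Vreset = -49.52, d = 0)
izh_params <- function(C, k, Vr, Vt, a, b, Vpeak, Vreset, d) {
  vals <- c(C = C, k = k, Vr = Vr, Vt = Vt, a = a, b = b,
            Vpeak = Vpeak, Vreset = Vreset, d = d)
  if (any(!is.finite(vals))) {
    stop("izh_params: all parameters must be finite; got non-finite ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (C <= 0) stop("izh_params: capacitance C must be positive")
  if (!(Vr < Vt && Vt < Vpeak)) {
    stop("izh_params: voltage ordering Vr < Vt < Vpeak violated")
  }
  if (Vreset >= Vpeak) stop("izh_params: Vreset must be below Vpeak")
  if (a < 0) stop("izh_params: recovery rate a must be non-negative")
  structure(as.list(vals), class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat("Izhikevich parameters (9-parameter form):\n")
  print(unlist(x))
  invisible(x)
}

#' Neuron state of an Izhikevich population
#'
#' @param v Membrane voltages (mV), one per neuron.
#' @param u Recovery variables (pA), one per neuron.
#' @return An object of class `neuron_state` with fields `v` and `u`.
#' @export
neuron_state <- function(v, u) {
  if (length(v) != length(u)) stop("neuron_state: v and u lengths differ")
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    bad <- which(!is.finite(v) | !is.finite(u))
    stop("neuron_state: non-finite state at neuron index ", bad[1])
  }
  structure(list(v = as.numeric(v), u = as.numeric(u)), class = "neuron_state")
}

#' Create a population at its resting fixed point
#'
#' Initializes `count` neurons at rest: `v = Vr`, `u = 0`, which is the exact
#' fixed point of the dynamics under zero input current.
#'
#' @param name Population label (kept as an attribute; informational).
#' @param count Number of neurons (positive integer).
#' @param params An [izh_params()] object.
#' @return A `neuron_state` of length `count` with attributes `name` and
#'   `params`.
#' @export
#' @examples
#' cfg <- load_model_config()
#' sc <- make_population("MEC LII Stellate", 1600,
#'                       population_params(cfg, "MEC LII Stellate"))
#' range(sc$v)  # all at -58.53 mV
make_population <- function(name, count, params) {
  if (!inherits(params, "izh_params")) stop("params must be izh_params")
  count <- as.integer(count)
  if (is.na(count) || count <= 0) {
    stop("make_population: count must be a positive integer")
  }
  st <- neuron_state(rep(params$Vr, count), rep(0, count))
  attr(st, "name") <- name
  attr(st, "params") <- params
  st
}

#' Advance an Izhikevich population by one time step
#'
#' Forward-Euler integration with the voltage updated in two half-steps per
#' step (for stability at spike onset), followed by the recovery-variable
#' update and the spike-and-reset rule. Neurons whose voltage reaches `Vpeak`
#' during the step are flagged as spiking, reset to `Vreset`, and have their
#' recovery variable incremented by `d`.
#'
#' @param state A `neuron_state`.
#' @param params An [izh_params()] object shared by all neurons in the state.
#' @param I_input Input current per neuron (pA); scalar or vector.
#' @param dt Time step (ms), in (0, 1].
#' @return A list with `state` (the updated `neuron_state`) and `spiked`
#'   (logical vector of spike flags).
#' @export
#' @examples
#' p <- izh_params(C = 118, k = 0.62, Vr = -58.53, Vt = -43.52, a = 0.005,
#'                 b = 11.69, Vpeak = 11.48, Vreset = -49.52, d = 0)
#' st <- make_population("stellate", 10, p)
#' out <- izh_step(st, p, I_input = 300, dt = 0.5)
izh_step <- function(state, params, I_input, dt) {
  if (!inherits(state, "neuron_state")) stop("state must be a neuron_state")
  if (!inherits(params, "izh_params")) stop("params must be izh_params")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0 || dt > 1) {
    stop("izh_step: dt must be a single value in (0, 1] ms")
  }
  n <- length(state$v)
  I <- rep_len(as.numeric(I_input), n)
  if (any(!is.finite(I))) {
    stop("izh_step: non-finite input current at neuron index ",
         which(!is.finite(I))[1])
  }
  v <- state$v
  u <- state$u
  half <- dt / 2
  for (i in 1:2) {
    v <- v + half * (params$k * (v - params$Vr) * (v - params$Vt) - u + I) / params$C
  }
  u <- u + dt * params$a * (params$b * (v - params$Vr) - u)
  spiked <- v >= params$Vpeak
  if (any(spiked)) {
    v[spiked] <- params$Vreset
    u[spiked] <- u[spiked] + params$d
  }
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    bad <- which(!is.finite(v) | !is.finite(u))
    stop("izh_step: non-finite state after step at neuron index ", bad[1])
  }
  list(state = neuron_state(v, u), spiked = spiked)
}

#' Simulate a single neuron under a constant current
#'
#' Convenience wrapper around [izh_step()] used for excitability checks and
#' convergence testing: integrates one neuron from rest for `duration_ms`
#' under a constant current and returns its spike times.
#'
#' @param params An [izh_params()] object.
#' @param I Constant input current (pA).
#' @param duration_ms Simulated time (ms).
#' @param dt Step (ms).
#' @return Numeric vector of spike times (ms).
#' @export
izh_spike_times <- function(params, I, duration_ms, dt = 0.5) {
  st <- make_population("probe", 1L, params)
  n_steps <- ceiling(duration_ms / dt)
  times <- numeric(0)
  for (step in seq_len(n_steps)) {
    out <- izh_step(st, params, I, dt)
    st <- out$state
    if (out$spiked[1]) times <- c(times, step * dt)
  }
  times
}
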
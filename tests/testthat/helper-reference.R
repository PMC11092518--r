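# Plain-R reference simulator for a feed-forward toy network, mirroring the
# engine's update order (conductance decay -> delayed spike delivery with
# Tsodyks-Markram release -> current computation -> two-half-step Euler with
# reset). Used as an independent cross-check of the compiled engine on small
# problems; built from the exported izh/tm operations plus explicit loops.

r_reference_sim <- function(popA, popB, nA, nB, I_A, groups_spec, dt,
                            duration_ms, delay_ms,
                            E = list(E_fast_exc = 0, E_slow_exc = 0,
                                     E_fast_inh = -70, E_slow_inh = -90)) {
  stA <- make_population("A", nA, popA)
  stB <- make_population("B", nB, popB)
  groups <- lapply(groups_spec, function(g) {
    list(sg = synapse_group(g$pre, g$post, n_pre = nA, n_post = nB),
         tm = g$tm, inhib = g$inhib)
  })
  n_steps <- ceiling(duration_ms / dt)
  delay_steps <- max(1, round(delay_ms / dt))
  buf <- vector("list", delay_steps + 1)
  for (i in seq_along(buf)) buf[[i]] <- integer(0)
  spikesA <- NULL; spikesB <- NULL
  for (step in 0:(n_steps - 1)) {
    # 1. decay all synapse state
    for (k in seq_along(groups)) {
      groups[[k]]$sg <- tm_decay(groups[[k]]$sg, groups[[k]]$tm, dt)
    }
    # 2. deliver delayed presynaptic spikes
    slot <- step %% (delay_steps + 1) + 1
    arriving <- buf[[slot]]
    buf[[slot]] <- integer(0)
    if (length(arriving) > 0) {
      for (k in seq_along(groups)) {
        groups[[k]]$sg <- tm_on_spike(groups[[k]]$sg, groups[[k]]$tm,
                                      arriving)
      }
    }
    # 3. currents
    I_B <- rep(0, nB)
    for (k in seq_along(groups)) {
      g <- groups[[k]]
      if (g$inhib) {
        I_B <- I_B + synaptic_current(s_fast_inh = g$sg$s_fast,
                                      s_slow_inh = g$sg$s_slow,
                                      v_post = stB$v, E = E)
      } else {
        I_B <- I_B + synaptic_current(s_fast_exc = g$sg$s_fast,
                                      s_slow_exc = g$sg$s_slow,
                                      v_post = stB$v, E = E)
      }
    }
    # 4. neuron updates
    outA <- izh_step(stA, popA, I_A, dt)
    stA <- outA$state
    outB <- izh_step(stB, popB, I_B, dt)
    stB <- outB$state
    t_spk <- (step + 1) * dt
    if (any(outA$spiked)) {
      spikesA <- rbind(spikesA, cbind(which(outA$spiked), t_spk))
      out_slot <- (step + delay_steps) %% (delay_steps + 1) + 1
      buf[[out_slot]] <- c(buf[[out_slot]], which(outA$spiked))
    }
    if (any(outB$spiked)) {
      spikesB <- rbind(spikesB, cbind(which(outB$spiked), t_spk))
    }
  }
  list(A = spikesA, B = spikesB)
}

# matching call into the compiled engine for the same toy topology
engine_toy_sim <- function(popA, popB, nA, nB, I_A, groups_spec, dt,
                           duration_ms, delay_ms) {
  mk_pop <- function(name, n, p) {
    c(list(name = name, n = as.integer(n)),
      p[c("C", "k", "Vr", "Vt", "a", "b", "Vpeak", "Vreset", "d")])
  }
  groups <- lapply(groups_spec, function(g) {
    ord <- order(g$pre)
    list(pre_pop = 0L, post_pop = 1L,
         pre = as.integer(g$pre[ord] - 1L), post = as.integer(g$post[ord] - 1L),
         w = rep(1, length(g$pre)),
         g_fast = g$tm$g_fast, tau_d_fast = g$tm$tau_d_fast, U = g$tm$U,
         tau_u = g$tm$tau_u, tau_x = g$tm$tau_x, g_slow = g$tm$g_slow,
         tau_d_slow = g$tm$tau_d_slow, inhib = g$inhib)
  })
  drive <- list(conj_pop = 0L, conj_I0 = I_A, conj_alpha = 0,
                conj_dir = rep(0L, nA), theta4 = rep(0, 4),
                conj_eta = rep(0, nA),
                place_pop = -1L, place_A = 0, place_sigma = 1,
                place_col = integer(0), place_row = integer(0),
                place_colx = numeric(0), place_rowy = numeric(0),
                stell_pop = -1L, settle_ms = 0, settle_amp = numeric(0),
                settle_tau = 1,
                x = 0, y = 0, speed = 0, heading = 0)
  recept <- list(E_fast_exc = 0, E_slow_exc = 0, E_fast_inh = -70,
                 E_slow_inh = -90)
  out <- gridcan:::engine_run(list(mk_pop("A", nA, popA),
                                   mk_pop("B", nB, popB)),
                              groups, recept, drive, dt, duration_ms,
                              delay_ms, list(), TRUE)
  list(A = cbind(out$spikes[[1]]$neuron, out$spikes[[1]]$t_ms),
       B = cbind(out$spikes[[2]]$neuron, out$spikes[[2]]$t_ms))
}
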
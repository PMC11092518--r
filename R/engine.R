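#' Simulation configuration
#'
#' @param dt Integration step (ms), default 0.5.
#' @param seed Integer seed controlling every stochastic element of a run
#'   (settle-pulse heterogeneity; trajectory synthesis is seeded separately
#'   by its own argument).
#' @param record_spikes Record all spikes (default TRUE).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.5, seed = 1, record_spikes = TRUE) {
  if (dt <= 0) stop("sim_config: dt must be positive")
  structure(list(dt = dt, seed = as.integer(seed),
                 record_spikes = record_spikes),
            class = "sim_config")
}

#' Register a probe by sheet coordinates
#'
#' Selects a neuron for voltage/current recording at 1-ms resolution.
#'
#' @param network A [build_network()] result.
#' @param population Population name.
#' @param row,col 0-based sheet coordinates within that population's layout.
#' @return An opaque probe registration used by [run_simulation()].
#' @export
probe <- function(network, population, row, col) {
  p <- match(population, POPULATIONS)
  if (is.na(p)) stop("probe: unknown population '", population, "'")
  layout <- if (population == "MEC LII Stellate") {
    network$sc_layout
  } else if (population %in% POPULATIONS[2:3]) {
    network$sc_layout   # index-matched sheets
  } else {
    network$in_layouts[[p - 3L]]
  }
  idx <- sheet_index(layout, row, col)
  structure(list(pop = p - 1L, idx = idx - 1L, population = population,
                 row = row, col = col),
            class = "sim_probe")
}

# Assemble the engine's group description from a grid_network.
prepare_engine_groups <- function(network) {
  lapply(network$groups, function(g) {
    ord <- order(g$group$pre)
    list(pre_pop = match(g$pre, POPULATIONS) - 1L,
         post_pop = match(g$post, POPULATIONS) - 1L,
         pre = g$group$pre[ord] - 1L, post = g$group$post[ord] - 1L,
         w = g$group$weight[ord],
         g_fast = g$tm$g_fast * g$mult, tau_d_fast = g$tm$tau_d_fast,
         U = g$tm$U, tau_u = g$tm$tau_u, tau_x = g$tm$tau_x,
         g_slow = g$tm$g_slow * g$mult_slow, tau_d_slow = g$tm$tau_d_slow,
         inhib = g$inhib)
  })
}

#' Run the closed-loop simulation
#'
#' Plays a trajectory through the network: a settle phase (zero velocity,
#' baseline conjunctive drive, place drive at the starting position and a
#' decaying heterogeneous excitation pulse that nucleates the activity
#' bumps) precedes trajectory playback and is excluded from the returned
#' record. Within each step the engine decays conductances, delivers spikes
#' that are one conduction delay old, computes synaptic and external
#' currents, advances the neurons, and logs spikes.
#'
#' The run is deterministic: identical network, trajectory and seed give a
#' bit-identical spike record.
#'
#' @param network A [build_network()] result.
#' @param traj A `trajectory` (see [synthesize_trajectory()]).
#' @param config A [sim_config()].
#' @param duration_s Simulated playback duration (s); defaults to the
#'   trajectory duration (it must not exceed it).
#' @param probes List of [probe()] registrations.
#' @param probe_window Length-2 window (s, relative to playback start) during
#'   which probes record; default the whole run.
#' @return An object of class `grid_sim`: list with `spikes` (data.frame
#'   `population`, `neuron`, `t_ms`, times relative to playback start),
#'   `probes` (per probe: `t_ms`, `v`, and a current matrix with one fast and
#'   one slow column per synapse group), `manifest` (all parameters and
#'   seeds), and `network`.
#' @export
run_simulation <- function(network, traj, config = sim_config(),
                           duration_s = NULL, probes = list(),
                           probe_window = NULL) {
  if (!inherits(network, "grid_network")) stop("network must be a grid_network")
  preset <- network$preset
  if (is.null(duration_s)) duration_s <- max(traj$t)
  if (duration_s > max(traj$t) + 1e-9) {
    stop("run_simulation: trajectory shorter than requested duration")
  }
  if (sum(vapply(network$groups, function(g) length(g$group$pre),
                 integer(1))) == 0) {
    stop("run_simulation: network has no synapses")
  }
  res <- resample_trajectory(traj, step_ms = 1)
  n_run_ms <- floor(duration_s * 1000)
  settle_ms <- preset$settle_ms
  n_settle <- as.integer(settle_ms)
  keep <- seq_len(min(n_run_ms, length(res$t_ms)))
  frames <- list(
    x = c(rep(res$x[1], n_settle), res$x[keep]),
    y = c(rep(res$y[1], n_settle), res$y[keep]),
    speed = c(rep(0, n_settle), res$speed[keep]),
    heading = c(rep(res$heading[1], n_settle), res$heading[keep]))

  n_sc <- network$counts[["MEC LII Stellate"]]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  settle_amp <- pmax(0, stats::rnorm(n_sc, preset$settle_pulse,
                                     0.25 * preset$settle_pulse))

  # physiological heterogeneity: random initial membrane phases per neuron
  # and static per-cell jitter of the conjunctive baseline (both seeded)
  pops <- lapply(seq_along(POPULATIONS), function(i) {
    p <- network$params[[POPULATIONS[i]]]
    n <- as.integer(network$counts[i])
    c(list(name = POPULATIONS[i], n = n,
           v0 = p$Vr + stats::runif(n) * (p$Vt - p$Vr)),
      p[c("C", "k", "Vr", "Vt", "a", "b", "Vpeak", "Vreset", "d")])
  })
  conj_jitter <- preset$conj_jitter %||% 15
  conj_eta <- stats::rnorm(network$counts[[2]], 0, conj_jitter)

  theta4 <- atan2(c(0, 1, -1, 0), c(1, 0, 0, -1))  # E, N, S, W
  dir_code <- c(E = 0L, N = 1L, S = 2L, W = 3L)
  conj_dir <- dir_code[as.character(network$directions$label)]

  bank <- network$bank
  drive <- list(
    conj_pop = 1L, conj_I0 = preset$conj_I0, conj_alpha = preset$conj_alpha,
    conj_dir = unname(conj_dir), theta4 = theta4, conj_eta = conj_eta,
    place_pop = 2L, place_A = bank$A, place_sigma = bank$sigma,
    place_col = rep(0:(bank$cols - 1L), bank$rows),
    place_row = rep(0:(bank$rows - 1L), each = bank$cols),
    place_colx = (seq_len(bank$cols) - 0.5) * bank$arena / bank$cols,
    place_rowy = (seq_len(bank$rows) - 0.5) * bank$arena / bank$rows,
    stell_pop = 0L, settle_ms = settle_ms, settle_amp = settle_amp,
    settle_tau = preset$settle_tau,
    x = frames$x, y = frames$y, speed = frames$speed, heading = frames$heading)

  if (is.null(probe_window)) probe_window <- c(0, duration_s)
  probe_list <- lapply(probes, function(p) c(p$pop, p$idx))

  total_ms <- settle_ms + n_run_ms
  out <- engine_run(pops, prepare_engine_groups(network),
                    network$receptors, drive,
                    dt = config$dt, duration_ms = total_ms,
                    delay_ms = network$delay_ms,
                    probes_in = probe_list,
                    record_spikes = config$record_spikes,
                    probe_start_ms = settle_ms + probe_window[1] * 1000,
                    probe_end_ms = settle_ms + probe_window[2] * 1000)

  spk <- do.call(rbind, lapply(seq_along(POPULATIONS), function(p) {
    s <- out$spikes[[p]]
    if (length(s$neuron) == 0) return(NULL)
    data.frame(population = POPULATIONS[p], neuron = s$neuron, t_ms = s$t_ms)
  }))
  if (is.null(spk)) {
    spk <- data.frame(population = character(0), neuron = integer(0),
                      t_ms = numeric(0))
  }
  # settle phase is excluded from analysis
  spk$t_ms <- spk$t_ms - settle_ms
  spk <- spk[spk$t_ms > 0, , drop = FALSE]
  spk$population <- factor(spk$population, levels = POPULATIONS)
  rownames(spk) <- NULL
  attr(spk, "duration_ms") <- n_run_ms

  probes_out <- lapply(seq_along(probes), function(q) {
    pr <- out$probes[[q]]
    colnames(pr$I) <- paste0(rep(names(network$groups), each = 2),
                             c("_fast", "_slow"))
    list(population = probes[[q]]$population, row = probes[[q]]$row,
         col = probes[[q]]$col, t_ms = pr$t_ms - settle_ms, v = pr$v,
         I = pr$I)
  })

  manifest <- list(preset = preset, seed = config$seed, dt = config$dt,
                   duration_s = duration_s, settle_ms = settle_ms,
                   delay_ms = network$delay_ms,
                   counts = as.list(network$counts),
                   package_version = as.character(utils::packageVersion("gridcan")))

  structure(list(spikes = spk, probes = probes_out, manifest = manifest,
                 network = network, final_state = out$final_state),
            class = "grid_sim")
}

#' @export
print.grid_sim <- function(x, ...) {
  cat("Grid-cell CAN simulation: ", x$manifest$duration_s, " s, preset '",
      x$manifest$preset$name, "', seed ", x$manifest$seed, "\n", sep = "")
  print(table(x$spikes$population))
  invisible(x)
}

#' Spike times of one cell
#'
#' @param sim A [run_simulation()] result.
#' @param population Population name.
#' @param neuron 1-based neuron index (or use `row`/`col` sheet coordinates).
#' @param row,col Optional 0-based sheet coordinates (stellate-frame
#'   populations only).
#' @param unit `"s"` (default) or `"ms"`.
#' @return Numeric vector of spike times.
#' @export
spike_times_of <- function(sim, population, neuron = NULL, row = NULL,
                           col = NULL, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  if (is.null(neuron)) {
    neuron <- sheet_index(sim$network$sc_layout, row, col)
  }
  sel <- sim$spikes$population == population & sim$spikes$neuron == neuron
  t <- sim$spikes$t_ms[sel]
  if (unit == "s") t / 1000 else t
}

#' Mean firing rate of each population in a simulation
#'
#' @param sim A [run_simulation()] result.
#' @return Named numeric vector (spikes/s per neuron).
#' @export
population_rates <- function(sim) {
  dur_s <- attr(sim$spikes, "duration_ms") / 1000
  counts <- table(sim$spikes$population)
  rates <- as.numeric(counts) /
    (as.numeric(sim$network$counts[names(counts)]) * dur_s)
  names(rates) <- names(counts)
  rates
}
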
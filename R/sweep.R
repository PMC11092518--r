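IM_PARAM_NAMES <- c("C", "k", "Vr", "Vt", "a", "b", "Vpeak", "Vreset", "d",
                    "V_min", "c")
TM_PARAM_NAMES <- c("g_fast", "tau_d_fast", "U", "tau_u", "tau_x", "g_slow")

# The reset voltage appears in the literature as both "c" and "V_min";
# both aliases resolve to Vreset.
canonical_param <- function(name) {
  if (name %in% c("V_min", "c")) return("Vreset")
  name
}

#' Nine-value sweep grid around a base value
#'
#' @param base Base parameter value (included as the center of the grid).
#' @param span Half-range as a fraction of `base`, default 0.5.
#' @param n Number of values (odd so the base is on the grid), default 9.
#' @return Numeric vector of length `n`.
#' @export
sweep_values <- function(base, span = 0.5, n = 9) {
  if (n %% 2 == 0) stop("sweep_values: n must be odd so the base is included")
  seq(base - abs(base) * span, base + abs(base) * span, length.out = n)
}

#' Specify a two-parameter robustness sweep
#'
#' Defines a grid-score sweep over a pair of model parameters: either
#' Izhikevich excitability parameters of the stellate population (`C`, `k`,
#' `Vr`, `Vt`, `a`, `b`, `Vpeak`, `Vreset`/`V_min`/`c`, `d`) or
#' Tsodyks-Markram parameters of the stellate-to-interneuron connections
#' (`g_fast`, `tau_d_fast`, `U`, `tau_u`, `tau_x`), varied jointly across the
#' three interneuron targets. Each axis carries nine values spanning a stated
#' range that includes the base value.
#'
#' @param param1,param2 Parameter names.
#' @param values1,values2 Nine values per axis; default +/-50% around the
#'   base value from the configuration tables.
#' @param realism1,realism2 Length-2 biologically realistic bounds per
#'   parameter (the teal region); default the full swept range.
#' @param preset Scale preset name, default `"desk"`.
#' @param duration_s Per-cell simulated duration (s), default 180.
#' @param seed Seed shared by every cell of the sweep, default 1.
#' @param traj_seed Seed of the shared synthetic trajectory, default 99.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(param1, param2, values1 = NULL, values2 = NULL,
                       realism1 = NULL, realism2 = NULL, preset = "desk",
                       duration_s = 180, seed = 1, traj_seed = 99) {
  kind <- function(p) {
    if (p %in% IM_PARAM_NAMES) return("im")
    if (p %in% TM_PARAM_NAMES) return("tm")
    stop("sweep_spec: unknown parameter '", p, "'")
  }
  k1 <- kind(param1); k2 <- kind(param2)
  cfg <- load_model_config()
  base_of <- function(p, k) {
    pc <- canonical_param(p)
    if (k == "im") cfg$populations[["MEC LII Stellate"]][[pc]]
    else cfg$connections[["MEC LII Stellate to EC LII Axo-Axonic"]][[pc]]
  }
  if (is.null(values1)) values1 <- sweep_values(base_of(param1, k1))
  if (is.null(values2)) values2 <- sweep_values(base_of(param2, k2))
  if (length(values1) != 9 || length(values2) != 9) {
    stop("sweep_spec: nine values per parameter are required")
  }
  if (is.null(realism1)) realism1 <- range(values1)
  if (is.null(realism2)) realism2 <- range(values2)
  structure(list(param1 = param1, param2 = param2, kind1 = k1, kind2 = k2,
                 values1 = values1, values2 = values2,
                 realism1 = realism1, realism2 = realism2,
                 base1 = base_of(param1, k1), base2 = base_of(param2, k2),
                 preset = preset, duration_s = duration_s, seed = seed,
                 traj_seed = traj_seed),
            class = "sweep_spec")
}

#' Run a grid-score parameter sweep
#'
#' Runs one simulation per grid cell of the sweep (same trajectory, same
#' seed throughout), scores the probed central stellate cell, and assembles
#' the score matrix with its above-threshold, realism and intersection
#' masks. Izhikevich sweeps modify the stellate population; Tsodyks-Markram
#' sweeps modify the three stellate-to-interneuron connections jointly. A
#' simulation that aborts is recorded as a missing cell (`NA`), never as a
#' silent zero.
#'
#' @param spec A [sweep_spec()].
#' @param traj Optional shared `trajectory`; synthesized from
#'   `spec$traj_seed` when omitted.
#' @param threshold Grid-score acceptance threshold, default 0.2.
#' @param rows,cols Optional subsets of row/column indices (1..9) to
#'   evaluate; other cells stay `NA`. Useful for partial sweeps.
#' @param verbose Print progress, default FALSE.
#' @return An object of class `sweep_result`: list with `scores` (9 x 9
#'   matrix, `param1` on rows), `above` (scores >= threshold), `realism`,
#'   `intersection` masks, and `spec`.
#' @export
run_sweep <- function(spec, traj = NULL, threshold = 0.2, rows = 1:9,
                      cols = 1:9, verbose = FALSE) {
  cfg <- load_model_config()
  if (is.null(traj)) {
    traj <- synthesize_trajectory(spec$duration_s, seed = spec$traj_seed,
                                  arena = cfg$arena$size)
  }
  scores <- matrix(NA_real_, 9, 9,
                   dimnames = list(signif(spec$values1, 4),
                                   signif(spec$values2, 4)))
  net0 <- build_network(cfg, spec$preset)
  ctr <- c(floor(net0$sc_layout$rows / 2), floor(net0$sc_layout$cols / 2))
  for (i in rows) {
    for (j in cols) {
      ov <- list(stellate_im = list(), sc_in_tm = list())
      slot1 <- if (spec$kind1 == "im") "stellate_im" else "sc_in_tm"
      slot2 <- if (spec$kind2 == "im") "stellate_im" else "sc_in_tm"
      ov[[slot1]][[canonical_param(spec$param1)]] <- spec$values1[i]
      ov[[slot2]][[canonical_param(spec$param2)]] <- spec$values2[j]
      ov <- Filter(function(x) length(x) > 0, ov)
      scores[i, j] <- tryCatch({
        net <- build_network(cfg, spec$preset, overrides = ov)
        sim <- run_simulation(net, traj, sim_config(seed = spec$seed),
                              duration_s = spec$duration_s)
        st <- spike_times_of(sim, "MEC LII Stellate",
                             row = ctr[1], col = ctr[2])
        gm <- grid_metrics(st, traj)
        gm$score
      }, error = function(e) {
        if (verbose) message("cell (", i, ",", j, ") failed: ",
                             conditionMessage(e))
        NA_real_
      })
      if (verbose) {
        message(sprintf("sweep %s=%.4g %s=%.4g -> %.3f", spec$param1,
                        spec$values1[i], spec$param2, spec$values2[j],
                        scores[i, j]))
      }
    }
  }
  above <- threshold_region(scores, threshold)
  realism <- outer(spec$values1 >= spec$realism1[1] &
                     spec$values1 <= spec$realism1[2],
                   spec$values2 >= spec$realism2[1] &
                     spec$values2 <= spec$realism2[2], "&")
  structure(list(scores = scores, above = above, realism = realism,
                 intersection = above & realism, threshold = threshold,
                 spec = spec),
            class = "sweep_result")
}

#' Above-threshold mask of a score matrix
#'
#' Elementwise `scores >= threshold`; missing entries are excluded (FALSE).
#'
#' @param scores Numeric matrix (NA allowed for missing cells).
#' @param threshold Grid-score threshold, default 0.2.
#' @return Logical matrix of the same shape.
#' @export
threshold_region <- function(scores, threshold = 0.2) {
  mask <- scores >= threshold
  mask[is.na(mask)] <- FALSE
  mask
}

#' Write a sweep score matrix as CSV
#'
#' @param result A [run_sweep()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(result$scores, path, row.names = TRUE)
  invisible(path)
}
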
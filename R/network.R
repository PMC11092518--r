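#' Population names used by the network
#'
#' Fixed population order: stellate grid cells, conjunctive (multipolar
#' pyramidal) cells, CA1 place cells, and the three interneuron types.
#' @export
POPULATIONS <- c("MEC LII Stellate", "EC LI-II Multipolar Pyramidal",
                 "CA1 Pyramidal", "EC LII AxoAxonic", "MEC LII Basket",
                 "EC LII Basket Multipolar")

#' Populations combined for the layer-II rhythm analyses
#' @export
MEC_LII_POPULATIONS <- c("MEC LII Stellate", "EC LII AxoAxonic",
                         "MEC LII Basket", "EC LII Basket Multipolar",
                         "EC LI-II Multipolar Pyramidal")

# Table 2 connection-name lookup per (pre, post) population pair.
CONNECTION_NAMES <- c(
  conj_sc = "EC LI-II Multipolar Pyramidal to MEC LII Stellate",
  ca1_sc = "CA1 Pyramidal to MEC LII Stellate",
  sc_aa = "MEC LII Stellate to EC LII Axo-Axonic",
  sc_ba = "MEC LII Stellate to MEC LII Basket",
  sc_bm = "MEC LII Stellate to EC LII Basket Multipolar",
  aa_sc = "EC LII Axo-Axonic to MEC LII Stellate",
  ba_sc = "MEC LII Basket to MEC LII Stellate",
  bm_sc = "EC LII Basket Multipolar to MEC LII Stellate")

#' Build the full grid-cell network for a scale preset
#'
#' Lays out all six populations on their sheets, assigns preferred
#' directions, builds the eight synapse groups (index-matched conjunctive
#' and phase-mapped place input to stellates, center-surround
#' stellate-interneuron wiring), and attaches the Tsodyks-Markram parameters
#' and per-preset gain multipliers.
#'
#' @param cfg Configuration from [load_model_config()].
#' @param preset_name Scale preset name (`"small"`, `"intermediate"`,
#'   `"large"`, or the reduced `"desk"` preset).
#' @param overrides Optional named list merged over the preset fields (e.g.
#'   `list(conj_I0 = 0)`), plus two special entries: `stellate_im`, a named
#'   list of Izhikevich parameter overrides for the stellate population, and
#'   `sc_in_tm`, a named list of Tsodyks-Markram overrides applied jointly to
#'   the three stellate-to-interneuron groups (the convention used by the
#'   robustness sweeps).
#' @return An object of class `grid_network`.
#' @export
#' @examples
#' cfg <- load_model_config()
#' net <- build_network(cfg, "desk")
#' connectivity_stats(net$groups[["sc_aa"]]$group)$out_mean
build_network <- function(cfg, preset_name, overrides = list()) {
  preset <- get_preset(cfg, preset_name)
  stellate_im <- overrides$stellate_im
  sc_in_tm <- overrides$sc_in_tm
  overrides$stellate_im <- NULL
  overrides$sc_in_tm <- NULL
  for (nm in names(overrides)) preset[[nm]] <- overrides[[nm]]

  n_sc <- preset$sheet_rows * preset$sheet_cols
  sc_layout <- sheet_layout(preset$sheet_rows, preset$sheet_cols)
  directions <- assign_preferred_directions(sc_layout)
  in_layouts <- lapply(1:3, function(i) {
    sheet_layout(preset$in_rows, preset$in_cols, count = preset$in_count[[i]],
                 span_rows = preset$sheet_rows, span_cols = preset$sheet_cols)
  })

  params <- lapply(POPULATIONS, function(nm) population_params(cfg, nm))
  names(params) <- POPULATIONS
  if (!is.null(stellate_im)) {
    p <- params[["MEC LII Stellate"]]
    for (nm in names(stellate_im)) p[[nm]] <- stellate_im[[nm]]
    params[["MEC LII Stellate"]] <-
      do.call(izh_params, p[c("C", "k", "Vr", "Vt", "a", "b",
                              "Vpeak", "Vreset", "d")])
  }
  counts <- c(n_sc, n_sc, n_sc, unlist(preset$in_count))
  names(counts) <- POPULATIONS

  bank <- place_field_bank(preset$sheet_rows, preset$sheet_cols,
                           arena = cfg$arena$size, sigma = preset$place_sigma,
                           A = preset$place_A)

  cs <- list()
  for (i in 1:3) {
    cs[[i]] <- build_cs_connectivity(sc_layout, in_layouts[[i]], preset,
                                     directions)
  }

  tm_for <- function(key) {
    p <- connection_params(cfg, CONNECTION_NAMES[[key]])
    if (startsWith(key, "sc_") && !is.null(sc_in_tm)) {
      for (nm in names(sc_in_tm)) p[[nm]] <- sc_in_tm[[nm]]
      p <- do.call(tm_params, p[c("g_fast", "tau_d_fast", "U", "tau_u",
                                  "tau_x", "g_slow", "tau_d_slow")])
    }
    p
  }

  mult_of <- function(key) {
    base <- switch(key, conj_sc = "mult_conj_sc", ca1_sc = "mult_ca1_sc",
                   sc_aa = , sc_ba = , sc_bm = "mult_sc_in",
                   aa_sc = , ba_sc = , bm_sc = "mult_in_sc")
    fast <- preset[[base]]
    slow <- preset[[paste0(base, "_slow")]]
    list(fast = fast, slow = if (is.null(slow)) fast else slow)
  }
  grp <- function(key, group, pre, post, inhib) {
    m <- mult_of(key)
    list(group = group, pre = pre, post = post, inhib = inhib,
         tm = tm_for(key), mult = m$fast, mult_slow = m$slow)
  }
  SC <- "MEC LII Stellate"
  groups <- list(
    conj_sc = grp("conj_sc", build_one_to_one(sc_layout, sc_layout),
                  "EC LI-II Multipolar Pyramidal", SC, FALSE),
    ca1_sc = grp("ca1_sc",
                 build_place_wiring(bank, sc_layout, preset$phase_gain),
                 "CA1 Pyramidal", SC, FALSE),
    sc_aa = grp("sc_aa", cs[[1]]$sc_to_in, SC, "EC LII AxoAxonic", FALSE),
    sc_ba = grp("sc_ba", cs[[2]]$sc_to_in, SC, "MEC LII Basket", FALSE),
    sc_bm = grp("sc_bm", cs[[3]]$sc_to_in, SC, "EC LII Basket Multipolar",
                FALSE),
    aa_sc = grp("aa_sc", cs[[1]]$in_to_sc, "EC LII AxoAxonic", SC, TRUE),
    ba_sc = grp("ba_sc", cs[[2]]$in_to_sc, "MEC LII Basket", SC, TRUE),
    bm_sc = grp("bm_sc", cs[[3]]$in_to_sc, "EC LII Basket Multipolar", SC,
                TRUE))

  structure(list(config = cfg, preset = preset, params = params,
                 counts = counts, sc_layout = sc_layout,
                 in_layouts = in_layouts, directions = directions,
                 bank = bank, groups = groups,
                 receptors = cfg$receptors, delay_ms = cfg$delay_ms),
            class = "grid_network")
}

#' @export
print.grid_network <- function(x, ...) {
  cat("Grid-cell CAN network, preset '", x$preset$name, "'\n", sep = "")
  cat("  stellate sheet ", x$preset$sheet_rows, "x", x$preset$sheet_cols,
      "; populations: ", paste(x$counts, collapse = "/"), "\n", sep = "")
  cat("  edges per group: ",
      paste(vapply(x$groups, function(g) length(g$group$pre), integer(1)),
            collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Sheet coordinates to neuron index
#'
#' Converts 0-based sheet coordinates `(row, col)` to a 1-based neuron index
#' in a row-major layout.
#'
#' @param layout A [sheet_layout()].
#' @param row,col 0-based sheet coordinates.
#' @return 1-based neuron index.
#' @export
sheet_index <- function(layout, row, col) {
  if (row < 0 || row >= layout$rows || col < 0 || col >= layout$cols) {
    stop("sheet_index: coordinates (", row, ", ", col, ") out of range")
  }
  idx <- row * layout$cols + col + 1L
  if (idx > layout$count) stop("sheet_index: position is vacant")
  as.integer(idx)
}
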
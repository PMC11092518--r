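#' Velocity-tuned drive to conjunctive cells
#'
#' The speed-control function: each conjunctive cell receives a baseline
#' current plus a speed- and direction-modulated component,
#' \deqn{I_i = I_0 + \alpha \, s \, (1 + \cos(h - \theta_i)) / 2,}
#' where `s` is running speed, `h` the running direction, and `theta_i` the
#' cell's preferred direction. The population sum of the tuning factor over
#' the four cardinal directions is 2 for any heading, so total drive depends
#' on speed only; its distribution across cells depends on direction.
#'
#' @param vel A `velocity_signal` (see [velocity_from_trajectory()]) or a
#'   list with scalar `speed` and `heading`.
#' @param directions A [assign_preferred_directions()] result (one preferred
#'   direction per conjunctive cell).
#' @param gains List with `I0` (baseline, pA, >= 0) and `alpha` (speed slope,
#'   pA per cm/s, >= 0).
#' @return A matrix of currents (pA), `length(vel$speed)` rows (time samples)
#'   by `length(directions$label)` columns (cells); a single row for scalar
#'   input.
#' @export
conjunctive_drive <- function(vel, directions, gains) {
  if (is.null(gains$I0) || is.null(gains$alpha)) {
    stop("conjunctive_drive: gains must have I0 and alpha")
  }
  if (gains$I0 < 0 || gains$alpha < 0) {
    stop("conjunctive_drive: gains must be non-negative")
  }
  theta <- atan2(directions$ey, directions$ex)
  tuning <- (1 + cos(outer(vel$heading, theta, "-"))) / 2
  gains$I0 + gains$alpha * vel$speed * tuning
}

#' Bank of Gaussian place fields tiling the arena
#'
#' Field centers tile the arena on a regular `rows x cols` lattice; all
#' fields share one width `sigma` and one peak drive amplitude `A`.
#'
#' @param rows,cols Lattice dimensions (default 40 x 40).
#' @param arena Arena side (cm), default 45.
#' @param sigma Field width (cm), positive; default 5.
#' @param A Peak drive amplitude (pA), default 260.
#' @return An object of class `place_field_bank`: list with `cx`, `cy`
#'   (centers, cm), `sigma`, `A`, `rows`, `cols`, `arena`.
#' @export
place_field_bank <- function(rows = 40, cols = 40, arena = 45, sigma = 5,
                             A = 260) {
  if (sigma <= 0) stop("place_field_bank: sigma must be positive")
  idx <- seq_len(rows * cols) - 1L
  row <- idx %/% cols
  col <- idx %% cols
  structure(list(cx = (col + 0.5) * arena / cols,
                 cy = (row + 0.5) * arena / rows,
                 sigma = sigma, A = A, rows = rows, cols = cols,
                 arena = arena),
            class = "place_field_bank")
}

#' Gaussian place-field drive at a position
#'
#' Current injected into each CA1 place cell when the animal is at
#' `position`: \eqn{I_j = A \exp(-\|p - c_j\|^2 / (2\sigma^2))}.
#'
#' @param position Numeric length-2 vector `(x, y)` in cm.
#' @param bank A [place_field_bank()].
#' @return Current per CA1 cell (pA).
#' @export
place_drive <- function(position, bank) {
  d2 <- (position[1] - bank$cx)^2 + (position[2] - bank$cy)^2
  bank$A * exp(-d2 / (2 * bank$sigma^2))
}

#' Wire place cells onto the stellate sheet through the arena-to-sheet phase map
#'
#' Connects each CA1 place cell to the stellate whose attractor phase
#' corresponds to the cell's field center under the fixed linear
#' arena-to-sheet phase map `phase = phase_gain * position (mod sheet span)`.
#' Every place cell has exactly one outgoing edge, so the group has exactly
#' as many edges as place cells; this wiring makes place input reinforce the
#' attractor state at the animal's true position (drift correction).
#'
#' @param bank A [place_field_bank()].
#' @param grid_layout Stellate [sheet_layout()].
#' @param phase_gain Sheet units per cm.
#' @return A [synapse_group()] from place cells to stellates.
#' @export
build_place_wiring <- function(bank, grid_layout, phase_gain) {
  sx <- grid_layout$span_cols
  sy <- grid_layout$span_rows
  px <- (bank$cx * phase_gain) %% sx
  py <- (bank$cy * phase_gain) %% sy
  col <- floor(px / sx * grid_layout$cols) %% grid_layout$cols
  row <- floor(py / sy * grid_layout$rows) %% grid_layout$rows
  post <- row * grid_layout$cols + col + 1L
  synapse_group(pre = seq_along(post), post = post,
                n_pre = length(post), n_post = grid_layout$count)
}
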
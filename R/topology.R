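#' Lay out a population on a 2-D neural sheet
#'
#' Assigns each neuron of a population a position on a rectangular sheet with
#' periodic (torus) boundary conditions. Positions are expressed in a common
#' coordinate frame (the stellate sheet frame) so that sheets of different
#' sizes can be wired together: a sheet of `rows x cols` cells spanning a
#' frame of `span_rows x span_cols` units places cell `(i, j)` (row-major,
#' 0-based) at `((j + 0.5) * span_cols / cols, (i + 0.5) * span_rows / rows)`.
#'
#' @param rows,cols Sheet dimensions in neurons.
#' @param count Population count; must not exceed `rows * cols`. When smaller
#'   (e.g. 834 interneurons on a 29 x 29 sheet), the last cells of the
#'   row-major order are left vacant.
#' @param span_rows,span_cols Extent of the sheet in frame units (defaults:
#'   `rows`, `cols`, i.e. the native frame).
#' @return An object of class `sheet_layout` with fields `rows`, `cols`,
#'   `count`, `x`, `y` (continuous frame positions per neuron), `col`, `row`
#'   (integer sheet indices, 0-based), `span_rows`, `span_cols` and
#'   `wraparound = TRUE`.
#' @export
#' @examples
#' grid <- sheet_layout(40, 40)
#' ins <- sheet_layout(29, 29, count = 834, span_rows = 40, span_cols = 40)
sheet_layout <- function(rows, cols, count = rows * cols,
                         span_rows = rows, span_cols = cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  count <- as.integer(count)
  if (rows <= 0 || cols <= 0) stop("sheet_layout: dimensions must be positive")
  if (count <= 0 || count > rows * cols) {
    stop("sheet_layout: count must be in 1..rows*cols")
  }
  idx <- seq_len(count) - 1L
  row <- idx %/% cols
  col <- idx %% cols
  structure(list(rows = rows, cols = cols, count = count,
                 row = row, col = col,
                 x = (col + 0.5) * span_cols / cols,
                 y = (row + 0.5) * span_rows / rows,
                 span_rows = span_rows, span_cols = span_cols,
                 wraparound = TRUE),
            class = "sheet_layout")
}

#' Torus distance between point sets in the sheet frame
#'
#' Pairwise Euclidean distances with periodic wrapping at the frame span.
#'
#' @param x1,y1 Coordinates of the first point set.
#' @param x2,y2 Coordinates of the second point set.
#' @param span_x,span_y Frame extent in each axis.
#' @return A `length(x1) x length(x2)` distance matrix.
#' @export
torus_distance <- function(x1, y1, x2, y2, span_x, span_y) {
  dx <- abs(outer(x1, x2, "-"))
  dx <- pmin(dx, span_x - dx)
  dy <- abs(outer(y1, y2, "-"))
  dy <- pmin(dy, span_y - dy)
  sqrt(dx^2 + dy^2)
}

#' Assign cardinal preferred directions on a sheet
#'
#' Deterministic 2 x 2 repeating tiling of the four cardinal directions
#' (N, E in the first row of each tile; W, S in the second), so that each
#' direction covers exactly a quarter of the cells and the direction vectors
#' sum to zero over every tile.
#'
#' @param layout A [sheet_layout()] with even `rows` and `cols` and full
#'   occupancy.
#' @return An object of class `direction_assignment`: a list with `label`
#'   (factor with levels N/E/S/W per cell), `ex`, `ey` (unit vector
#'   components), where north is +y and east is +x.
#' @export
#' @examples
#' dirs <- assign_preferred_directions(sheet_layout(40, 40))
#' table(dirs$label)  # 400 cells per direction
assign_preferred_directions <- function(layout) {
  if (!inherits(layout, "sheet_layout")) stop("layout must be a sheet_layout")
  if (layout$rows %% 2L != 0L || layout$cols %% 2L != 0L) {
    stop("assign_preferred_directions: sheet dimensions must be even")
  }
  if (layout$count != layout$rows * layout$cols) {
    stop("assign_preferred_directions: layout must be fully occupied")
  }
  re <- layout$row %% 2L
  ce <- layout$col %% 2L
  label <- character(layout$count)
  label[re == 0L & ce == 0L] <- "N"
  label[re == 0L & ce == 1L] <- "E"
  label[re == 1L & ce == 0L] <- "W"
  label[re == 1L & ce == 1L] <- "S"
  vecs <- list(N = c(0, 1), E = c(1, 0), S = c(0, -1), W = c(-1, 0))
  ex <- vapply(label, function(l) vecs[[l]][1], numeric(1), USE.NAMES = FALSE)
  ey <- vapply(label, function(l) vecs[[l]][2], numeric(1), USE.NAMES = FALSE)
  structure(list(label = factor(label, levels = c("N", "E", "S", "W")),
                 ex = ex, ey = ey),
            class = "direction_assignment")
}

#' Build the center-surround connectivity between grid cells and interneurons
#'
#' Constructs the two synapse groups that realize the center-surround (CS)
#' inhibitory structure on the torus:
#' \itemize{
#'   \item stellate-to-interneuron: each stellate connects to all
#'     interneurons whose frame position lies within a disc of radius
#'     `disc_radius` centered at the stellate's position displaced by
#'     `xi` frame units along the stellate's preferred direction;
#'   \item interneuron-to-stellate: each interneuron inhibits every stellate
#'     in the annulus `[annulus_inner, annulus_outer)` around its position.
#' }
#' All weights are uniform (unitary).
#'
#' @param grid_layout Stellate [sheet_layout()].
#' @param in_layout Interneuron [sheet_layout()] sharing the stellate frame.
#' @param preset A scale preset (list with `annulus_inner`, `annulus_outer`,
#'   `disc_radius`, `xi`); see [get_preset()].
#' @param directions A [assign_preferred_directions()] result for the grid
#'   layout.
#' @return List with synapse groups `sc_to_in` and `in_to_sc`.
#' @export
build_cs_connectivity <- function(grid_layout, in_layout, preset, directions) {
  if (preset$annulus_inner >= preset$annulus_outer) {
    stop("build_cs_connectivity: empty annulus in preset '",
         preset$name %||% "?", "' (inner >= outer)")
  }
  if (preset$annulus_outer > min(grid_layout$span_rows, grid_layout$span_cols) / 2) {
    stop("build_cs_connectivity: annulus outer radius exceeds half the sheet span")
  }
  sx <- grid_layout$span_cols
  sy <- grid_layout$span_rows

  # stellate -> IN: disc around the direction-offset center
  cx <- (grid_layout$x + preset$xi * directions$ex) %% sx
  cy <- (grid_layout$y + preset$xi * directions$ey) %% sy
  d1 <- torus_distance(cx, cy, in_layout$x, in_layout$y, sx, sy)
  hits <- which(d1 <= preset$disc_radius, arr.ind = TRUE)
  sc_to_in <- synapse_group(pre = hits[, 1], post = hits[, 2],
                            n_pre = grid_layout$count, n_post = in_layout$count)

  # IN -> stellate: annulus [inner, outer)
  d2 <- torus_distance(in_layout$x, in_layout$y, grid_layout$x, grid_layout$y,
                       sx, sy)
  hits2 <- which(d2 >= preset$annulus_inner & d2 < preset$annulus_outer,
                 arr.ind = TRUE)
  in_to_sc <- synapse_group(pre = hits2[, 1], post = hits2[, 2],
                            n_pre = in_layout$count, n_post = grid_layout$count)

  list(sc_to_in = sc_to_in, in_to_sc = in_to_sc)
}

#' Build a one-to-one (index-matched) synapse group
#'
#' @param src_layout,dst_layout Source and destination [sheet_layout()]s (or
#'   any lists with a `count` field) of equal size.
#' @return A [synapse_group()] with bijective index-matched edges.
#' @export
build_one_to_one <- function(src_layout, dst_layout) {
  n <- src_layout$count
  if (n != dst_layout$count) {
    stop("build_one_to_one: population sizes differ (", n, " vs ",
         dst_layout$count, ")")
  }
  synapse_group(pre = seq_len(n), post = seq_len(n), n_pre = n, n_post = n)
}

#' Degree statistics of a synapse group
#'
#' Mean and standard deviation of the out-degree (edges per presynaptic
#' neuron, counting zero-degree neurons) and in-degree (edges per
#' postsynaptic neuron).
#'
#' @param group A non-empty [synapse_group()].
#' @return A list with `out_mean`, `out_sd`, `in_mean`, `in_sd`, `n_edges`.
#' @export
connectivity_stats <- function(group) {
  if (!inherits(group, "synapse_group")) stop("group must be a synapse_group")
  if (length(group$pre) == 0) stop("connectivity_stats: empty synapse group")
  out_deg <- tabulate(group$pre, nbins = group$n_pre)
  in_deg <- tabulate(group$post, nbins = group$n_post)
  list(out_mean = mean(out_deg), out_sd = stats::sd(out_deg),
       in_mean = mean(in_deg), in_sd = stats::sd(in_deg),
       n_edges = length(group$pre))
}

#' Export a synapse group's edge list as CSV
#'
#' Writes columns `pre_index`, `post_index`, `weight` (1-based indices).
#'
#' @param group A [synapse_group()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edges_csv <- function(group, path) {
  utils::write.csv(data.frame(pre_index = group$pre, post_index = group$post,
                              weight = group$weight),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a synapse group edge list from CSV
#'
#' @param path CSV with columns `pre_index`, `post_index`, `weight`.
#' @param n_pre,n_post Population sizes (optional).
#' @return A [synapse_group()].
#' @export
read_edges_csv <- function(path, n_pre = NULL, n_post = NULL) {
  df <- utils::read.csv(path)
  need <- c("pre_index", "post_index", "weight")
  if (!all(need %in% names(df))) {
    stop("read_edges_csv: file must have columns ", paste(need, collapse = ", "))
  }
  synapse_group(df$pre_index, df$post_index, df$weight,
                n_pre = n_pre, n_post = n_post)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
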
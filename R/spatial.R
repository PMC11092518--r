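#' Gaussian kernel smoothing of a 2-D map
#'
#' Truncated-Gaussian convolution used for rate-map smoothing. `NA` entries
#' are treated as missing: they contribute neither to the numerator nor to
#' the kernel normalization.
#'
#' @param m Numeric matrix (may contain `NA`).
#' @param sigma_bins Kernel standard deviation in bins; 0 disables smoothing.
#' @return The smoothed matrix, `NA` where the input was `NA`.
#' @export
gaussian_smooth_2d <- function(m, sigma_bins) {
  if (sigma_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_bins))
  g <- stats::dnorm(-half:half, sd = sigma_bins)
  k <- outer(g, g)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  val <- ifelse(is.na(m), 0, m)
  wgt <- ifelse(is.na(m), 0, 1)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (di in -half:half) {
    ri <- intersect(seq_len(nr), seq_len(nr) - di)
    if (length(ri) == 0) next
    for (dj in -half:half) {
      cj <- intersect(seq_len(nc), seq_len(nc) - dj)
      if (length(cj) == 0) next
      w <- k[di + half + 1, dj + half + 1]
      num[ri, cj] <- num[ri, cj] + w * val[ri + di, cj + dj]
      den[ri, cj] <- den[ri, cj] + w * wgt[ri + di, cj + dj]
    }
  }
  out <- num / den
  out[is.na(m)] <- NA
  out
}

#' Occupancy-normalized spatial firing rate map
#'
#' Bins the arena into square bins, accumulates occupancy time from the
#' trajectory and spike counts from one cell's spike train (spike positions
#' are linearly interpolated from the trajectory), smooths both maps with a
#' truncated Gaussian, and divides. Bins never visited are flagged `NA`
#' rather than zero-filled, and are excluded from all downstream statistics.
#'
#' @param spike_times Spike times (s) of one cell.
#' @param traj A `trajectory` covering the analysis window.
#' @param bin Bin side (cm), default 3.
#' @param sigma_smooth Gaussian smoothing width (cm), default 3; 0 disables
#'   smoothing.
#' @param arena Arena side (cm); defaults to the trajectory's arena.
#' @return An object of class `rate_map`: list with `rate` (spikes/s matrix,
#'   rows = y bins from bottom, cols = x bins), `occupancy` (s, unsmoothed),
#'   `count` (unsmoothed spike counts), `bin`, `sigma_smooth`, `arena`.
#' @export
compute_rate_map <- function(spike_times, traj, bin = 3, sigma_smooth = 3,
                             arena = NULL) {
  if (is.null(arena)) arena <- attr(traj, "arena") %||% 45
  if (nrow(traj) < 2) stop("compute_rate_map: trajectory too short")
  n_bins <- ceiling(arena / bin)
  dt <- c(diff(traj$t), 0)
  dt[length(dt)] <- dt[length(dt) - 1]
  bx <- pmin(pmax(floor(traj$x / bin), 0), n_bins - 1) + 1L
  by <- pmin(pmax(floor(traj$y / bin), 0), n_bins - 1) + 1L
  occ <- matrix(0, n_bins, n_bins)  # [y, x]
  occ_acc <- rowsum(dt, (bx - 1L) * n_bins + by)
  occ[as.integer(rownames(occ_acc))] <- occ_acc[, 1]
  if (sum(occ) <= 0) stop("compute_rate_map: zero total occupancy")
  cnt <- matrix(0, n_bins, n_bins)
  if (length(spike_times) > 0) {
    sx <- stats::approx(traj$t, traj$x, spike_times, rule = 2)$y
    sy <- stats::approx(traj$t, traj$y, spike_times, rule = 2)$y
    sbx <- pmin(pmax(floor(sx / bin), 0), n_bins - 1) + 1L
    sby <- pmin(pmax(floor(sy / bin), 0), n_bins - 1) + 1L
    cnt_acc <- rowsum(rep(1, length(sbx)), (sbx - 1L) * n_bins + sby)
    cnt[as.integer(rownames(cnt_acc))] <- cnt_acc[, 1]
  }
  visited <- occ > 0
  sm_occ <- gaussian_smooth_2d(occ, sigma_smooth / bin)
  sm_cnt <- gaussian_smooth_2d(cnt, sigma_smooth / bin)
  rate <- sm_cnt / sm_occ
  rate[!visited | !(sm_occ > 0)] <- NA
  structure(list(rate = rate, occupancy = occ, count = cnt, bin = bin,
                 sigma_smooth = sigma_smooth, arena = arena),
            class = "rate_map")
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the rate map with itself at every 2-D spatial lag,
#' computed over the bins visited in both copies. Lags with fewer than
#' `min_overlap` overlapping visited bins are masked `NA`.
#'
#' @param map A [compute_rate_map()] result, or a plain matrix (then `bin`
#'   must be given).
#' @param min_overlap Minimum overlapping bins per lag, default 20.
#' @param bin Bin size (cm) when `map` is a matrix.
#' @return An object of class `autocorrelogram`: list with `ac`
#'   (`(2r+1) x (2r+1)` correlation matrix, lag 0 at the center), `bin`,
#'   `n_overlap` (overlap counts per lag).
#' @export
spatial_autocorrelogram <- function(map, min_overlap = 20, bin = NULL) {
  if (inherits(map, "rate_map")) {
    m <- map$rate
    bin <- map$bin
  } else {
    m <- map
    if (is.null(bin)) stop("spatial_autocorrelogram: bin required for matrices")
  }
  ok <- is.finite(m)
  if (sum(ok) < 2) stop("spatial_autocorrelogram: fewer than 2 visited bins")
  if (stats::sd(m[ok]) == 0) {
    warning("spatial_autocorrelogram: constant map, correlation undefined")
    nr <- nrow(m); nc <- ncol(m)
    return(structure(list(ac = matrix(NA_real_, 2 * nr - 1, 2 * nc - 1),
                          bin = bin,
                          n_overlap = matrix(0L, 2 * nr - 1, 2 * nc - 1)),
                     class = "autocorrelogram"))
  }
  nr <- nrow(m); nc <- ncol(m)
  ac <- matrix(NA_real_, 2 * nr - 1, 2 * nc - 1)
  nov <- matrix(0L, 2 * nr - 1, 2 * nc - 1)
  for (di in -(nr - 1):(nr - 1)) {
    r1 <- max(1, 1 + di):min(nr, nr + di)
    r2 <- r1 - di
    for (dj in -(nc - 1):(nc - 1)) {
      c1 <- max(1, 1 + dj):min(nc, nc + dj)
      c2 <- c1 - dj
      a <- m[r1, c1, drop = FALSE]
      b <- m[r2, c2, drop = FALSE]
      keep <- is.finite(a) & is.finite(b)
      n <- sum(keep)
      nov[di + nr, dj + nc] <- n
      if (n >= min_overlap) {
        av <- a[keep]; bv <- b[keep]
        if (stats::sd(av) > 0 && stats::sd(bv) > 0) {
          ac[di + nr, dj + nc] <- stats::cor(av, bv)
        }
      }
    }
  }
  structure(list(ac = ac, bin = bin, n_overlap = nov),
            class = "autocorrelogram")
}

# Rotate a matrix about its center by `angle_deg` with bilinear interpolation.
rotate_matrix <- function(m, angle_deg) {
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  out <- matrix(NA_real_, nr, nc)
  idx <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  dy <- idx$i - cy; dx <- idx$j - cx
  # rotate sampling coordinates backwards
  sy <- cy + cos(th) * dy + sin(th) * dx
  sx <- cx - sin(th) * dy + cos(th) * dx
  i0 <- floor(sy); j0 <- floor(sx)
  fi <- sy - i0; fj <- sx - j0
  valid <- i0 >= 1 & j0 >= 1 & i0 + 1 <= nr & j0 + 1 <= nc
  get <- function(i, j) {
    v <- rep(NA_real_, length(i))
    w <- valid
    v[w] <- m[cbind(i[w], j[w])]
    v
  }
  v00 <- get(i0, j0); v01 <- get(i0, j0 + 1L)
  v10 <- get(i0 + 1L, j0); v11 <- get(i0 + 1L, j0 + 1L)
  vals <- (1 - fi) * ((1 - fj) * v00 + fj * v01) +
    fi * ((1 - fj) * v10 + fj * v11)
  out[cbind(idx$i, idx$j)] <- vals
  out
}

#' Grid score of a spatial autocorrelogram
#'
#' Extracts an annulus around the central peak (inner radius at the first
#' zero crossing of the angularly averaged correlation), rotates the
#' autocorrelogram by 30, 60, 90, 120 and 150 degrees, and computes
#' \deqn{score = \min(r_{60}, r_{120}) - \max(r_{30}, r_{90}, r_{150}),}
#' where \eqn{r_\theta} is the Pearson correlation between the annulus values
#' of the original and rotated maps. The score is maximized over outer annulus
#' radii (swept in one-bin steps up to half the map). Hexagonal structure
#' yields positive scores, square structure negative; a threshold of 0.2 marks
#' an acceptable grid.
#'
#' @param acobj An [spatial_autocorrelogram()] result (or plain matrix).
#' @return The grid score (in `[-2, 2]`), or `NA` when no central peak is
#'   detectable (not a grid).
#' @export
grid_score <- function(acobj) {
  ac <- if (inherits(acobj, "autocorrelogram")) acobj$ac else acobj
  nr <- nrow(ac); nc <- ncol(ac)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  dist <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
  # angular average in 1-bin rings to find the central-peak radius
  max_r <- floor(min(nr, nc) / 2)
  ring_mean <- vapply(seq_len(max_r), function(r) {
    sel <- dist >= (r - 1) & dist < r
    mean(ac[sel], na.rm = TRUE)
  }, numeric(1))
  zc <- which(ring_mean <= 0)[1]
  if (is.na(zc)) return(NA_real_)       # no zero crossing: no central peak
  r_in <- zc
  rots <- c(30, 60, 90, 120, 150)
  rotated <- lapply(rots, function(a) rotate_matrix(ac, a))
  best <- NA_real_
  for (r_out in seq(r_in + 2, max_r)) {
    sel <- dist >= r_in & dist <= r_out
    base <- ac[sel]
    cors <- vapply(rotated, function(rm) {
      v <- rm[sel]
      keep <- is.finite(base) & is.finite(v)
      if (sum(keep) < 20) return(NA_real_)
      if (stats::sd(base[keep]) == 0 || stats::sd(v[keep]) == 0) return(NA_real_)
      stats::cor(base[keep], v[keep])
    }, numeric(1))
    if (any(is.na(cors))) next
    score <- min(cors[2], cors[4]) - max(cors[1], cors[3], cors[5])
    if (is.na(best) || score > best) best <- score
  }
  best
}

#' Detect firing fields in a rate map
#'
#' Finds connected components (4-connectivity) of visited bins above a
#' fraction of the map peak. A component containing several well-separated
#' firing peaks is split at its watershed: each bin is assigned to the
#' nearest constituent peak, so that neighboring grid fields joined by a
#' suprathreshold ridge are measured as separate fields rather than one
#' merged region. Sub-fields (or unsplit components) of at least `min_area`
#' are retained; field size is the diameter of a circle of equal area.
#'
#' @param map A [compute_rate_map()] result.
#' @param threshold Fraction of the map peak, default 0.2.
#' @param min_area Minimum field area (cm^2), default `9 * bin^2`.
#' @param merge_radius Local maxima closer than this (cm) count as one peak,
#'   default `2 * bin`.
#' @return A data.frame with one row per field: `cx`, `cy` (rate-weighted
#'   centroid, cm), `area` (cm^2), `diameter` (cm), `peak` (spikes/s).
#'   Zero rows when no suprathreshold bins exist.
#' @export
detect_fields <- function(map, threshold = 0.2, min_area = NULL,
                          merge_radius = NULL) {
  if (!inherits(map, "rate_map")) stop("map must be a rate_map")
  if (is.null(min_area)) min_area <- 9 * map$bin^2
  if (is.null(merge_radius)) merge_radius <- 2 * map$bin
  m <- map$rate
  peak <- max(m, na.rm = TRUE)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), area = numeric(0),
                      diameter = numeric(0), peak = numeric(0))
  if (!is.finite(peak) || peak <= 0) return(empty)
  above <- !is.na(m) & m >= threshold * peak
  lab <- label_components(above)
  if (max(lab) == 0) return(empty)
  out <- empty
  nr <- nrow(m)
  for (comp in seq_len(max(lab))) {
    sel <- which(lab == comp, arr.ind = TRUE)
    if (nrow(sel) * map$bin^2 < min_area) next
    mx <- component_maxima(m, lab, comp, merge_radius / map$bin)
    # watershed split: assign bins to the nearest peak
    assign_to <- if (nrow(mx) > 1) {
      d2 <- outer(sel[, 1], mx[, 1], "-")^2 + outer(sel[, 2], mx[, 2], "-")^2
      max.col(-d2, ties.method = "first")
    } else {
      rep(1L, nrow(sel))
    }
    for (f in seq_len(nrow(mx))) {
      part <- sel[assign_to == f, , drop = FALSE]
      area <- nrow(part) * map$bin^2
      if (area < min_area) next
      w <- m[part]
      # matrix rows index y bins, cols x bins; bin centers at (i - 0.5) * bin
      cy <- sum((part[, 1] - 0.5) * map$bin * w) / sum(w)
      cx <- sum((part[, 2] - 0.5) * map$bin * w) / sum(w)
      out <- rbind(out, data.frame(cx = cx, cy = cy, area = area,
                                   diameter = 2 * sqrt(area / pi),
                                   peak = max(w)))
    }
  }
  out[order(-out$peak), , drop = FALSE]
}

# Local maxima (8-neighborhood) of `m` within component `comp` of the label
# matrix, merged when closer than `merge_bins`; returns (row, col) pairs.
component_maxima <- function(m, lab, comp, merge_bins) {
  nr <- nrow(m); nc <- ncol(m)
  sel <- which(lab == comp, arr.ind = TRUE)
  is_max <- logical(nrow(sel))
  for (k in seq_len(nrow(sel))) {
    i <- sel[k, 1]; j <- sel[k, 2]
    nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    is_max[k] <- all(m[i, j] >= nb, na.rm = TRUE)
  }
  mx <- sel[is_max, , drop = FALSE]
  if (nrow(mx) <= 1) return(mx)
  # merge nearby maxima, keeping the taller one
  v <- m[mx]
  ord <- order(-v)
  mx <- mx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(mx))
  for (k in 2:nrow(mx)) {
    d <- sqrt((mx[seq_len(k - 1), 1] - mx[k, 1])^2 +
                (mx[seq_len(k - 1), 2] - mx[k, 2])^2)
    if (any(keep[seq_len(k - 1)] & d <= merge_bins)) keep[k] <- FALSE
  }
  mx[keep, , drop = FALSE]
}

# 4-connectivity connected-component labelling via flood fill.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          pos <- (nb[2] - 1L) * nr + nb[1]
          if (mask[pos] && lab[pos] == 0L) {
            lab[pos] <- nxt
            stack <- c(stack, pos)
          }
        }
      }
    }
  }
  lab
}

#' Grid field spacing and orientation from an autocorrelogram
#'
#' Finds local maxima of the autocorrelogram outside the central peak, takes
#' the six peaks nearest the center, and reports the median center-to-peak
#' distance as the field spacing and the angle of the nearest-to-horizontal
#' peak as the grid orientation.
#'
#' @param acobj An [spatial_autocorrelogram()] result.
#' @param bin Bin size (cm); defaults to the autocorrelogram's.
#' @param min_peaks Minimum number of peripheral peaks required, default 3.
#' @return List with `spacing` (cm), `orientation` (degrees in (-90, 90]),
#'   `n_peaks`, `peaks` (data.frame of peak offsets in cm). `spacing` is `NA`
#'   (with the reason in `reason`) when fewer than `min_peaks` peripheral
#'   peaks exist.
#' @export
field_spacing <- function(acobj, bin = NULL, min_peaks = 3) {
  ac <- if (inherits(acobj, "autocorrelogram")) acobj$ac else acobj
  if (is.null(bin)) bin <- acobj$bin
  nr <- nrow(ac); nc <- ncol(ac)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  dist <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
  max_r <- floor(min(nr, nc) / 2)
  ring_mean <- vapply(seq_len(max_r), function(r) {
    sel <- dist >= (r - 1) & dist < r
    mean(ac[sel], na.rm = TRUE)
  }, numeric(1))
  zc <- which(ring_mean <= 0)[1]
  r_in <- if (is.na(zc)) 2 else zc
  # local maxima (8-neighborhood) outside the central region, detected on a
  # lightly smoothed copy; the smoothing plus a 0.1 correlation floor reject
  # single-bin noise maxima so that structureless maps report no spacing
  # rather than a spurious one
  acs <- gaussian_smooth_2d(ac, 1)
  peaks <- NULL
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      v <- acs[i, j]
      if (!is.finite(v) || v < 0.1) next
      if (dist[i, j] <= r_in) next
      nbh <- acs[(i - 1):(i + 1), (j - 1):(j + 1)]
      nbh[2, 2] <- -Inf
      if (all(v >= nbh, na.rm = TRUE)) {
        peaks <- rbind(peaks, c(dy = i - cy, dx = j - cx, val = ac[i, j]))
      }
    }
  }
  if (is.null(peaks) || nrow(peaks) < min_peaks) {
    return(list(spacing = NA_real_, orientation = NA_real_,
                n_peaks = if (is.null(peaks)) 0L else nrow(peaks),
                peaks = NULL, reason = "fewer than min_peaks peripheral peaks"))
  }
  d <- sqrt(peaks[, "dy"]^2 + peaks[, "dx"]^2)
  ord <- order(d)
  take <- ord[seq_len(min(6, length(ord)))]
  sel <- peaks[take, , drop = FALSE]
  spacing <- stats::median(d[take]) * bin
  ang <- atan2(sel[, "dy"], sel[, "dx"]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90       # fold into (-90, 90]
  orientation <- ang[which.min(abs(ang))]
  list(spacing = spacing, orientation = orientation, n_peaks = nrow(peaks),
       peaks = data.frame(dx = sel[, "dx"] * bin, dy = sel[, "dy"] * bin,
                          val = sel[, "val"]),
       reason = NULL)
}

#' Summary grid metrics for one cell
#'
#' Convenience wrapper chaining [compute_rate_map()],
#' [spatial_autocorrelogram()], [grid_score()], [detect_fields()] and
#' [field_spacing()].
#'
#' @param spike_times Spike times (s).
#' @param traj A `trajectory`.
#' @param bin,sigma_smooth See [compute_rate_map()].
#' @return A list of class `grid_metrics`: `score`, `mean_rate`, `peak_rate`
#'   (spikes/s), `field_size` (median equivalent diameter, cm), `spacing`
#'   (cm), `orientation` (deg), `n_fields`, plus the intermediate `map` and
#'   `ac` objects.
#' @export
grid_metrics <- function(spike_times, traj, bin = 3, sigma_smooth = 3) {
  map <- compute_rate_map(spike_times, traj, bin, sigma_smooth)
  acobj <- spatial_autocorrelogram(map)
  score <- grid_score(acobj)
  fields <- detect_fields(map)
  sp <- field_spacing(acobj)
  duration <- max(traj$t) - min(traj$t)
  structure(list(score = score,
                 mean_rate = length(spike_times) / duration,
                 peak_rate = suppressWarnings(max(map$rate, na.rm = TRUE)),
                 field_size = if (nrow(fields) > 0)
                   mean(fields$diameter) else NA_real_,
                 spacing = sp$spacing, orientation = sp$orientation,
                 n_fields = nrow(fields), map = map, ac = acobj),
            class = "grid_metrics")
}
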
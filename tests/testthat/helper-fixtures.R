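# Shared fixtures: constructed rate maps, toy trajectories, and parameter
# shorthands. Everything is generated in code; nothing is read from disk.

stellate_params <- function() {
  izh_params(C = 118, k = 0.62, Vr = -58.53, Vt = -43.52, a = 0.005,
             b = 11.69, Vpeak = 11.48, Vreset = -49.52, d = 0)
}

fast_spiking_params <- function() {
  izh_params(C = 20, k = 1, Vr = -55, Vt = -40, a = 0.15, b = 8,
             Vpeak = 25, Vreset = -55, d = 200)
}

# wrap a plain matrix as a rate_map (rows = y bins, cols = x bins)
as_rate_map <- function(m, bin = 3, occupancy = NULL) {
  if (is.null(occupancy)) occupancy <- matrix(1, nrow(m), ncol(m))
  structure(list(rate = m, occupancy = occupancy, count = m * occupancy,
                 bin = bin, sigma_smooth = 0, arena = ncol(m) * bin),
            class = "rate_map")
}

# map with Gaussian bumps at given centers (cm), sigma (cm) on an
# extent x extent cm map with `bin` cm bins
bump_map <- function(centers, sigma = 5, extent = 150, bin = 3, peak = 10) {
  n <- round(extent / bin)
  xs <- (seq_len(n) - 0.5) * bin
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    dx2 <- outer(rep(1, n), (xs - centers[k, 1])^2)
    dy2 <- outer((xs - centers[k, 2])^2, rep(1, n))
    m <- m + peak * exp(-(dx2 + dy2) / (2 * sigma^2))
  }
  m
}

# hexagonal lattice of bump centers with lattice constant `a` (cm),
# rotated by `angle_deg`, covering a square of side `extent`
hex_centers <- function(a = 47, extent = 150, angle_deg = 0) {
  v1 <- c(a, 0)
  v2 <- c(a / 2, a * sqrt(3) / 2)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v1 <- R %*% v1; v2 <- R %*% v2
  centers <- NULL
  for (i in -6:6) for (j in -6:6) {
    p <- extent / 2 + i * v1 + j * v2
    if (all(p > -a) && all(p < extent + a)) centers <- rbind(centers, t(p))
  }
  centers
}

# straight-line trajectory fixture
line_trajectory <- function(duration = 2, speed = 10, rate_hz = 50,
                            arena = 45) {
  t <- seq(0, duration, by = 1 / rate_hz)
  df <- data.frame(t = t, x = pmin(speed * t, arena), y = rep(1, length(t)))
  class(df) <- c("trajectory", "data.frame")
  attr(df, "arena") <- arena
  df
}

stationary_trajectory <- function(duration = 10, x = 22.5, y = 22.5,
                                  rate_hz = 50, arena = 45) {
  t <- seq(0, duration, by = 1 / rate_hz)
  df <- data.frame(t = t, x = rep(x, length(t)), y = rep(y, length(t)))
  class(df) <- c("trajectory", "data.frame")
  attr(df, "arena") <- arena
  df
}
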
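#' Load an open-field trajectory from CSV
#'
#' Reads a timestamped 2-D trajectory (columns `t` in seconds, `x` and `y` in
#' cm) recorded in a square open-field arena. Positions outside
#' `[0, arena]^2` are clipped to the walls and counted in the
#' `clipped` attribute (with a warning).
#'
#' @param path CSV file with header columns `t`, `x`, `y`.
#' @param arena Arena side length (cm), default 45.
#' @return A `trajectory`: a data.frame with columns `t`, `x`, `y`, class
#'   `c("trajectory", "data.frame")`, and attributes `arena` and `clipped`.
#' @export
load_trajectory <- function(path, arena = 45) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("load_trajectory: file must have columns t, x, y")
  }
  if (nrow(df) == 0) stop("load_trajectory: empty trajectory file")
  if (any(diff(df$t) <= 0)) {
    stop("load_trajectory: time stamps must be strictly increasing")
  }
  n_clip <- sum(df$x < 0 | df$x > arena | df$y < 0 | df$y > arena)
  if (n_clip > 0) {
    warning("load_trajectory: clipped ", n_clip, " out-of-bounds samples")
    df$x <- pmin(pmax(df$x, 0), arena)
    df$y <- pmin(pmax(df$y, 0), arena)
  }
  as_trajectory(df, arena = arena, clipped = n_clip)
}

as_trajectory <- function(df, arena, clipped = 0L) {
  out <- df[, c("t", "x", "y")]
  class(out) <- c("trajectory", "data.frame")
  attr(out, "arena") <- arena
  attr(out, "clipped") <- clipped
  out
}

#' Write a trajectory to CSV
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Synthesize a random-foraging trajectory
#'
#' Generates a smooth random-walk trajectory emulating a rodent foraging in a
#' square open field: the heading performs a wrapped-Gaussian random walk,
#' the speed follows a mean-reverting (Ornstein-Uhlenbeck-like) fluctuation
#' around `mean_speed` clipped at zero, and walls reflect the heading. The
#' result is reproducible under a fixed seed.
#'
#' @param duration Duration (s), positive.
#' @param seed Integer RNG seed.
#' @param mean_speed Target mean running speed (cm/s), default 12.
#' @param heading_persistence In `[0, 1)`: persistence of the heading random
#'   walk (larger values give straighter paths). Default 0.9.
#' @param arena Arena side (cm), default 45.
#' @param rate_hz Sampling rate (Hz), default 50.
#' @return A `trajectory` data.frame (see [load_trajectory()]).
#' @export
#' @examples
#' traj <- synthesize_trajectory(60, seed = 1)
#' range(traj$x)
synthesize_trajectory <- function(duration, seed = 1, mean_speed = 12,
                                  heading_persistence = 0.9, arena = 45,
                                  rate_hz = 50) {
  if (duration <= 0) stop("synthesize_trajectory: duration must be positive")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  dt <- 1 / rate_hz
  n <- ceiling(duration * rate_hz) + 1L
  # heading random walk: sd shrinks with persistence
  sd_h <- (1 - heading_persistence) * pi
  dh <- stats::rnorm(n, 0, sd_h)
  # mean-reverting speed fluctuation, clipped at >= 0
  theta_s <- 0.5                       # reversion rate (1/s)
  sd_s <- 0.45 * mean_speed
  s <- numeric(n)
  s[1] <- mean_speed
  noise <- stats::rnorm(n, 0, sd_s * sqrt(2 * theta_s * dt))
  x <- numeric(n); y <- numeric(n)
  x[1] <- arena / 2; y[1] <- arena / 2
  h <- stats::runif(1, 0, 2 * pi)
  for (i in 2:n) {
    s[i] <- max(0, s[i - 1] + theta_s * (mean_speed - s[i - 1]) * dt + noise[i])
    h <- (h + dh[i]) %% (2 * pi)
    step_x <- s[i] * cos(h) * dt
    step_y <- s[i] * sin(h) * dt
    nx <- x[i - 1] + step_x
    ny <- y[i - 1] + step_y
    # reflective walls
    if (nx < 0) { nx <- -nx; h <- pi - h }
    if (nx > arena) { nx <- 2 * arena - nx; h <- pi - h }
    if (ny < 0) { ny <- -ny; h <- -h }
    if (ny > arena) { ny <- 2 * arena - ny; h <- -h }
    h <- h %% (2 * pi)
    x[i] <- min(max(nx, 0), arena)
    y[i] <- min(max(ny, 0), arena)
  }
  as_trajectory(data.frame(t = (seq_len(n) - 1L) * dt, x = x, y = y),
                arena = arena)
}

#' Extract speed and heading from a trajectory
#'
#' Finite-difference velocity estimation with boxcar smoothing of the
#' velocity components. Heading at rest carries the previous heading forward
#' (undefined-at-rest convention). Speeds above the outlier ceiling are
#' clipped.
#'
#' @param traj A `trajectory` with at least 2 samples.
#' @param smoothing Boxcar window length in samples (odd; default 5).
#' @param speed_cap Outlier ceiling (cm/s), default 90.
#' @return A `velocity_signal`: list with `t`, `speed` (cm/s), `heading`
#'   (radians, east = 0, north = pi/2), one entry per trajectory sample.
#' @export
velocity_from_trajectory <- function(traj, smoothing = 5, speed_cap = 90) {
  n <- nrow(traj)
  if (n < 2) stop("velocity_from_trajectory: need at least 2 samples")
  dt <- diff(traj$t)
  vx <- c(diff(traj$x) / dt, 0)
  vy <- c(diff(traj$y) / dt, 0)
  vx[n] <- vx[n - 1]; vy[n] <- vy[n - 1]
  if (smoothing > 1) {
    k <- rep(1 / smoothing, smoothing)
    vx <- stats::filter(vx, k, sides = 2)
    vy <- stats::filter(vy, k, sides = 2)
    # fill boxcar edge NAs with nearest values
    vx <- fill_edges(as.numeric(vx))
    vy <- fill_edges(as.numeric(vy))
  }
  speed <- sqrt(vx^2 + vy^2)
  heading <- atan2(vy, vx)
  # carry heading forward through rest periods
  at_rest <- speed < 1e-9
  if (any(at_rest)) {
    last <- 0
    for (i in seq_len(n)) {
      if (at_rest[i]) heading[i] <- last else last <- heading[i]
    }
  }
  over <- speed > speed_cap
  if (any(over)) speed[over] <- speed_cap
  structure(list(t = traj$t, speed = speed, heading = heading %% (2 * pi)),
            class = "velocity_signal")
}

fill_edges <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0) return(rep(0, length(v)))
  v[seq_len(ok[1] - 1)] <- v[ok[1]]
  nlast <- ok[length(ok)]
  if (nlast < length(v)) v[(nlast + 1):length(v)] <- v[nlast]
  v
}

#' Resample a trajectory and its velocity signal to a fixed time base
#'
#' Linear interpolation of position, speed and heading (heading interpolated
#' via its unit vector to avoid wrap artifacts) onto a regular grid of
#' `step_ms` milliseconds, as used by the simulation engine.
#'
#' @param traj A `trajectory`.
#' @param step_ms Resampling step (ms), default 1.
#' @param smoothing,speed_cap Passed to [velocity_from_trajectory()].
#' @return List of vectors `t_ms`, `x`, `y`, `speed`, `heading`.
#' @export
resample_trajectory <- function(traj, step_ms = 1, smoothing = 5,
                                speed_cap = 90) {
  vel <- velocity_from_trajectory(traj, smoothing, speed_cap)
  t_ms <- seq(0, floor(max(traj$t) * 1000), by = step_ms)
  ts <- t_ms / 1000
  x <- stats::approx(traj$t, traj$x, ts, rule = 2)$y
  y <- stats::approx(traj$t, traj$y, ts, rule = 2)$y
  speed <- stats::approx(vel$t, vel$speed, ts, rule = 2)$y
  hx <- stats::approx(vel$t, cos(vel$heading), ts, rule = 2)$y
  hy <- stats::approx(vel$t, sin(vel$heading), ts, rule = 2)$y
  list(t_ms = t_ms, x = x, y = y, speed = speed,
       heading = atan2(hy, hx) %% (2 * pi))
}
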
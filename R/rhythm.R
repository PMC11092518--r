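#' Binned population firing rate
#'
#' Combines the spikes of one or more populations into a single binned count
#' series (default 1-ms bins). Total spike count is conserved across binning.
#'
#' @param record A spike record: data.frame with columns `population`,
#'   `neuron`, `t_ms` (as returned by [run_simulation()]).
#' @param populations Character vector of population names to combine;
#'   default all populations present.
#' @param bin Bin width (ms), default 1.
#' @param t_range Length-2 window `[t0, t1)` in ms; default the full record
#'   duration (taken from the record's `duration_ms` attribute when present).
#' @return An object of class `population_rate`: list with `counts` (spikes
#'   per bin), `t_ms` (bin left edges), `bin`, `populations`.
#' @export
population_rate <- function(record, populations = NULL, bin = 1,
                            t_range = NULL) {
  if (is.null(t_range)) {
    dur <- attr(record, "duration_ms")
    if (is.null(dur)) dur <- if (nrow(record) > 0) max(record$t_ms) else 0
    t_range <- c(0, dur)
  }
  if (diff(t_range) <= 0) stop("population_rate: zero-length window")
  if (is.null(populations)) populations <- unique(as.character(record$population))
  sel <- record$population %in% populations &
    record$t_ms >= t_range[1] & record$t_ms < t_range[2]
  times <- record$t_ms[sel]
  n_bins <- ceiling(diff(t_range) / bin)
  counts <- tabulate(pmin(floor((times - t_range[1]) / bin), n_bins - 1) + 1L,
                     nbins = n_bins)
  structure(list(counts = counts,
                 t_ms = t_range[1] + (seq_len(n_bins) - 1L) * bin,
                 bin = bin, populations = populations),
            class = "population_rate")
}

# Gaussian smoothing of a 1-D series (sd in samples).
gaussian_smooth_1d <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Multitaper power spectral density of a population rate
#'
#' The rate series is smoothed with a 3-ms Gaussian moving window (to
#' suppress binning harmonics), demeaned, split into segments, and each
#' segment is tapered with a small family of orthogonal sine tapers; the
#' taper- and segment-averaged periodogram is returned. Sine tapers
#' (Riedel-Sidorenko) provide the variance reduction of the multitaper
#' approach with a closed-form taper family.
#'
#' @param rate A [population_rate()] (1-ms bins) or a plain numeric series.
#' @param fs Sampling rate (Hz); defaults to `1000 / bin` for a
#'   `population_rate`.
#' @param n_tapers Number of sine tapers, default 5.
#' @param segment_s Segment length (s), default 10; series shorter than one
#'   segment are analyzed whole. Series shorter than 2 s are rejected.
#' @param smooth_ms Gaussian pre-smoothing window (ms), default 3; 0 disables.
#' @return An object of class `psd`: list with `freq` (Hz) and `power`
#'   (arbitrary units), restricted to 0-200 Hz.
#' @export
multitaper_psd <- function(rate, fs = NULL, n_tapers = 5, segment_s = 10,
                           smooth_ms = 3) {
  if (inherits(rate, "population_rate")) {
    x <- as.numeric(rate$counts)
    if (is.null(fs)) fs <- 1000 / rate$bin
  } else {
    x <- as.numeric(rate)
    if (is.null(fs)) stop("multitaper_psd: fs required for plain series")
  }
  if (length(x) < 2 * fs) stop("multitaper_psd: series shorter than 2 s")
  if (smooth_ms > 0) x <- gaussian_smooth_1d(x, smooth_ms * fs / 1000)
  seg_len <- min(length(x), round(segment_s * fs))
  n_seg <- floor(length(x) / seg_len)
  tapers <- sine_tapers(seg_len, n_tapers)
  pow <- NULL
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    seg <- seg - mean(seg)
    for (k in seq_len(n_tapers)) {
      sp <- Mod(stats::fft(seg * tapers[, k]))^2 / fs
      pow <- if (is.null(pow)) sp else pow + sp
    }
  }
  pow <- pow / (n_seg * n_tapers)
  n_half <- floor(seg_len / 2)
  freq <- (0:n_half) * fs / seg_len
  keep <- freq <= 200
  structure(list(freq = freq[keep], power = pow[seq_along(freq)][keep]),
            class = "psd")
}

# Orthonormal sine taper family on n samples.
sine_tapers <- function(n, k) {
  t <- seq_len(n)
  sapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1)))
}

#' Band-power fractions of a power spectral density
#'
#' Integrates the PSD over the canonical bands delta (1-4 Hz), theta
#' (4-12 Hz), beta (12-25 Hz) and gamma (25-100 Hz) — closed-left,
#' open-right — and divides by the total 1-100 Hz power, so the four
#' fractions sum to 1.
#'
#' @param psd A [multitaper_psd()] result.
#' @return An object of class `band_power`: named numeric vector with
#'   entries `delta`, `theta`, `beta`, `gamma`.
#' @export
band_fractions <- function(psd) {
  if (max(psd$freq) < 100) {
    stop("band_fractions: PSD must cover 1-100 Hz")
  }
  bands <- list(delta = c(1, 4), theta = c(4, 12), beta = c(12, 25),
                gamma = c(25, 100))
  total_sel <- psd$freq >= 1 & psd$freq < 100
  total <- sum(psd$power[total_sel])
  out <- vapply(bands, function(b) {
    sum(psd$power[psd$freq >= b[1] & psd$freq < b[2]]) / total
  }, numeric(1))
  structure(out, class = "band_power")
}

#' Analytic-signal phase of a series
#'
#' FFT-based analytic signal (Hilbert transform); returns the instantaneous
#' phase in radians.
#'
#' @param x Real numeric series.
#' @return Phase per sample, in `(-pi, pi]`.
#' @export
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Computes the mean resultant vector length (MRVL) of a sample of phases and
#' the Rayleigh test p-value from the standard large-sample approximation.
#'
#' @param phases Phases in radians.
#' @return List with `mrvl` (in `[0, 1]`), `p_value`, `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0) stop("rayleigh_test: empty sample")
  R <- Mod(mean(exp(1i * phases)))
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(mrvl = R, p_value = p, n = n)
}

#' Spike-phase coupling of a spike train to a population-rate rhythm
#'
#' Band-pass filters a reference population rate around a target frequency
#' (by default the spectral peak of the reference within the beta band),
#' assigns each spike the instantaneous phase of the filtered reference at
#' the spike time, and quantifies coupling by the mean resultant vector
#' length with the Rayleigh significance test.
#'
#' The filter is a 2nd-order Butterworth band-pass applied forward and
#' backward (zero-phase, 4th-order magnitude response); phase is extracted
#' from the analytic signal.
#'
#' @param spike_times_ms Spike times (ms) of the population under test.
#' @param reference A [population_rate()] at 1-ms bins serving as the rhythm
#'   reference.
#' @param band Length-2 frequency window (Hz) in which to search for the
#'   reference peak, default `c(12, 25)` (beta).
#' @param half_width Half-width of the band-pass around the peak (Hz),
#'   default 4.
#' @param min_spikes Minimum spike count, default 50.
#' @return An object of class `phase_coupling`: list with `mrvl`, `p_value`,
#'   `n_spikes`, `peak_freq` (Hz), `band` (the filter corners, Hz),
#'   `phases` (per-spike phases, radians).
#' @export
spike_phase_coupling <- function(spike_times_ms, reference, band = c(12, 25),
                                 half_width = 4, min_spikes = 50) {
  if (length(spike_times_ms) < min_spikes) {
    stop("spike_phase_coupling: fewer than ", min_spikes, " spikes")
  }
  fs <- 1000 / reference$bin
  psd <- multitaper_psd(reference)
  in_band <- psd$freq >= band[1] & psd$freq < band[2]
  peak_freq <- psd$freq[in_band][which.max(psd$power[in_band])]
  lo <- max(1, peak_freq - half_width)
  hi <- peak_freq + half_width
  x <- gaussian_smooth_1d(as.numeric(reference$counts), 3 * fs / 1000)
  x <- x - mean(x)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x)
  phase <- analytic_phase(filt)
  idx <- floor((spike_times_ms - reference$t_ms[1]) / reference$bin) + 1L
  keep <- idx >= 1 & idx <= length(phase)
  phases <- phase[idx[keep]]
  rt <- rayleigh_test(phases)
  structure(list(mrvl = rt$mrvl, p_value = rt$p_value, n_spikes = rt$n,
                 peak_freq = peak_freq, band = c(lo, hi), phases = phases),
            class = "phase_coupling")
}
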
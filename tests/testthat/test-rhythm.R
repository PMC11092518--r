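toy_record <- function(times, pops = rep("A", length(times)),
                       neurons = rep(1, length(times))) {
  df <- data.frame(population = pops, neuron = neurons, t_ms = times)
  attr(df, "duration_ms") <- 1000
  df
}

test_that("population rate binning conserves and adds spike counts", {
  rec <- toy_record(c(1.2, 1.7, 500, 999.9, 250),
                    pops = c("A", "A", "B", "B", "A"),
                    neurons = c(1, 2, 1, 1, 1))
  pr <- population_rate(rec)
  expect_equal(sum(pr$counts), 5)
  prA <- population_rate(rec, "A")
  prB <- population_rate(rec, "B")
  expect_equal(prA$counts + prB$counts, pr$counts)
  expect_equal(sum(population_rate(toy_record(numeric(0)))$counts), 0)
  expect_error(population_rate(rec, t_range = c(5, 5)), "zero-length")
})

test_that("a pure 20 Hz rate modulation concentrates power in the beta band", {
  t <- seq_len(20000)
  rate <- structure(list(counts = 5 + 4 * sin(2 * pi * 20 * t / 1000),
                         t_ms = t - 1, bin = 1, populations = "A"),
                    class = "population_rate")
  psd <- multitaper_psd(rate, smooth_ms = 0)
  expect_equal(psd$freq[which.max(psd$power[psd$freq > 0]) + 1], 20,
               tolerance = 0.2)
  bf <- band_fractions(psd)
  expect_gt(bf["beta"], 0.95)
  expect_equal(sum(bf), 1, tolerance = 1e-9)
})

test_that("constant rates carry no power and short series are rejected", {
  const <- structure(list(counts = rep(3, 5000), t_ms = 0:4999, bin = 1,
                          populations = "A"), class = "population_rate")
  psd <- multitaper_psd(const, smooth_ms = 0)
  expect_lt(max(psd$power[psd$freq > 0.5]), 1e-20)
  short <- structure(list(counts = rep(1, 500), t_ms = 0:499, bin = 1,
                          populations = "A"), class = "population_rate")
  expect_error(multitaper_psd(short), "2 s")
})

test_that("white-noise rates give band powers proportional to bandwidth", {
  set.seed(77)
  x <- structure(list(counts = rpois(60000, 4), t_ms = 0:59999, bin = 1,
                      populations = "A"), class = "population_rate")
  bf <- band_fractions(multitaper_psd(x, smooth_ms = 0))
  widths <- c(delta = 3, theta = 8, beta = 13, gamma = 75) / 99
  for (b in names(widths)) {
    expect_equal(unname(bf[b]), unname(widths[b]), tolerance = 0.25,
                 label = paste("band", b))
  }
})

test_that("band fractions are invariant to uniform rate scaling", {
  set.seed(3)
  counts <- rpois(30000, 3) + 2 * sin(2 * pi * 18 * (1:30000) / 1000)
  r1 <- structure(list(counts = counts, t_ms = 0:29999, bin = 1,
                       populations = "A"), class = "population_rate")
  r2 <- r1; r2$counts <- r2$counts * 9.4
  expect_equal(unclass(band_fractions(multitaper_psd(r1))),
               unclass(band_fractions(multitaper_psd(r2))), tolerance = 1e-9)
})

test_that("MRVL statistics behave at the concentrated and uniform limits", {
  rt <- rayleigh_test(rep(1.1, 200))
  expect_equal(rt$mrvl, 1)
  expect_lt(rt$p_value, 1e-10)

  set.seed(54)
  unif <- runif(1e4, -pi, pi)
  ru <- rayleigh_test(unif)
  expect_lt(ru$mrvl, 0.03)          # ~ sqrt(pi)/2/sqrt(n) scale
  expect_gt(ru$p_value, 0.05)

  # invariance under global phase rotation
  ph <- runif(500, -pi, pi)
  shifted <- ((ph + 2.1 + pi) %% (2 * pi)) - pi
  expect_equal(rayleigh_test(ph)$mrvl, rayleigh_test(shifted)$mrvl,
               tolerance = 1e-12)
})

test_that("spike-phase coupling locks onto a built-in beta rhythm", {
  set.seed(8)
  t <- seq_len(60000)
  lam <- pmax(0, 3 + 2.5 * sin(2 * pi * 18 * t / 1000))
  counts <- rpois(60000, lam)
  ref <- structure(list(counts = counts, t_ms = t - 1, bin = 1,
                        populations = "A"), class = "population_rate")
  # spikes drawn from the same modulated intensity -> coupled
  spikes <- t[counts > 0]
  pc <- spike_phase_coupling(spikes, ref)
  expect_equal(pc$peak_freq, 18, tolerance = 1)
  expect_gt(pc$mrvl, 0.1)
  expect_lt(pc$p_value, 0.001)
  # uniformly timed spikes are uncoupled
  pc0 <- spike_phase_coupling(runif(5000, 0, 60000), ref)
  expect_lt(pc0$mrvl, 0.05)
  expect_error(spike_phase_coupling(1:10, ref), "fewer than")
})
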
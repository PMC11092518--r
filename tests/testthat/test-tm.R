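test_that("first-ever spike releases U and increments the fast conductance by g*U", {
  # multipolar-pyramidal -> stellate table row
  tm <- tm_params(g_fast = 11.627, tau_d_fast = 3.380, U = 0.180,
                  tau_u = 49.920, tau_x = 152.856, g_slow = 7.126)
  g <- synapse_group(pre = 1, post = 1, n_pre = 1, n_post = 1)
  g2 <- tm_on_spike(g, tm, 1)
  expect_equal(g2$u, 0.18)
  expect_equal(g2$x, 1 - 0.18)
  expect_equal(g2$s_fast, 11.627 * 0.18)   # 2.09286 nS
  expect_equal(g2$s_slow, 7.126 * 0.18)
})

test_that("zero release fraction never increases conductance", {
  tm <- tm_params(g_fast = 5, tau_d_fast = 3, U = 0, tau_u = 50, tau_x = 150)
  g <- synapse_group(pre = rep(1, 3), post = 1:3, n_pre = 1, n_post = 3)
  for (i in 1:5) {
    g <- tm_on_spike(g, tm, 1)
    g <- tm_decay(g, tm, 10)
  }
  expect_equal(g$s_fast, rep(0, 3))
  expect_equal(g$u, rep(0, 3))
})

test_that("paired pulses match a hand-iterated facilitation/depression oracle", {
  # stellate -> basket table row, 20 ms inter-pulse interval
  U <- 0.167; tau_u <- 49.920; tau_x <- 152.857
  tm <- tm_params(g_fast = 1.050, tau_d_fast = 2.887, U = U,
                  tau_u = tau_u, tau_x = tau_x)
  g <- synapse_group(pre = 1, post = 1, n_pre = 1, n_post = 1)
  g <- tm_on_spike(g, tm, 1)
  g <- tm_decay(g, tm, 20)
  g <- tm_on_spike(g, tm, 1)
  # independent two-step iteration of the update equations
  u1 <- U; x1 <- 1 - U
  u1d <- u1 * exp(-20 / tau_u)
  x1d <- 1 - (1 - x1) * exp(-20 / tau_x)
  u2 <- u1d + U * (1 - u1d)
  R2 <- u2 * x1d
  expect_equal(g$u, u2)
  expect_equal(g$x, x1d - R2)
})

test_that("inter-spike decays are exact exponentials", {
  tm <- tm_params(g_fast = 1, tau_d_fast = 3.380, U = 0.5, tau_u = 49.920,
                  tau_x = 152.856, g_slow = 1, tau_d_slow = 150)
  g <- synapse_group(pre = 1, post = 1, n_pre = 1, n_post = 1)
  g$s_fast[1] <- 1; g$s_slow[1] <- 1; g$u[1] <- 0.5; g$x[1] <- 0
  g2 <- tm_decay(g, tm, 3.380)
  expect_equal(g2$s_fast[1], exp(-1))
  g3 <- tm_decay(g, tm, 49.920)
  expect_equal(g3$u[1], 0.5 * exp(-1))
  g4 <- tm_decay(g, tm, 1e6)        # recovery limit
  expect_equal(g4$x[1], 1, tolerance = 1e-12)
})

test_that("u and x stay in [0,1] under random spike/decay interleavings", {
  set.seed(42)
  tm <- tm_params(g_fast = 2, tau_d_fast = 3, U = 0.3, tau_u = 40,
                  tau_x = 120, g_slow = 1)
  for (rep in 1:10) {
    g <- synapse_group(pre = rep(1:4, each = 3), post = rep(1:3, 4),
                       n_pre = 4, n_post = 3)
    for (ev in 1:60) {
      if (runif(1) < 0.5) {
        g <- tm_on_spike(g, tm, sample(1:4, sample(1:3, 1)))
      } else {
        g <- tm_decay(g, tm, runif(1, 0.1, 50))
      }
      expect_true(all(g$u >= 0 & g$u <= 1))
      expect_true(all(g$x >= 0 & g$x <= 1))
      expect_true(all(g$s_fast >= 0))
    }
  }
})

test_that("a periodic train with fast-decaying facilitation depresses monotonically", {
  tm <- tm_params(g_fast = 1, tau_d_fast = 3, U = 0.4, tau_u = 5,
                  tau_x = 400)   # tau_u far below the 100-ms ISI
  g <- synapse_group(pre = 1, post = 1, n_pre = 1, n_post = 1)
  releases <- numeric(8)
  for (i in 1:8) {
    x_before <- g$x
    g <- tm_on_spike(g, tm, 1)
    releases[i] <- x_before - g$x
    g <- tm_decay(g, tm, 100)
  }
  expect_true(all(diff(releases) <= 1e-12))
})

test_that("synaptic currents follow the reversal-potential form with Mg block", {
  expect_equal(synaptic_current(s_fast_exc = 2, v_post = 0), 0)
  expect_equal(synaptic_current(v_post = -55), 0)
  expect_equal(synaptic_current(s_fast_inh = 1, v_post = -50), -20)
  # slow excitatory channel is attenuated by the voltage-dependent block
  i_slow <- synaptic_current(s_slow_exc = 1, v_post = -55)
  expect_equal(i_slow, 55 * mg_block(-55))
  expect_lt(i_slow, 55)
  expect_true(all(mg_block(c(-80, -55, 0, 40)) >= 0 &
                    mg_block(c(-80, -55, 0, 40)) < 1))
})

test_that("all packaged synapse tables satisfy the model invariants", {
  cfg <- load_model_config()
  for (nm in names(cfg$connections)) {
    tm <- connection_params(cfg, nm)
    expect_true(tm$U >= 0 && tm$U <= 1, label = nm)
    expect_true(all(c(tm$tau_d_fast, tm$tau_u, tm$tau_x, tm$tau_d_slow) > 0),
                label = nm)
    expect_true(tm$g_fast >= 0 && tm$g_slow >= 0, label = nm)
  }
})
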
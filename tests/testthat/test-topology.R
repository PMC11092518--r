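test_that("preferred directions tile the sheet in balanced 2x2 blocks", {
  d40 <- assign_preferred_directions(sheet_layout(40, 40))
  expect_equal(as.numeric(table(d40$label)), rep(400, 4))
  d2 <- assign_preferred_directions(sheet_layout(2, 2))
  expect_equal(as.numeric(table(d2$label)), rep(1, 4))
  # unit vectors sum to zero over every 2x2 tile
  expect_equal(sum(d2$ex), 0)
  expect_equal(sum(d2$ey), 0)
  lay <- sheet_layout(4, 4)
  d4 <- assign_preferred_directions(lay)
  for (tr in c(0, 2)) for (tc in c(0, 2)) {
    sel <- lay$row %in% c(tr, tr + 1) & lay$col %in% c(tc, tc + 1)
    expect_equal(sum(d4$ex[sel]), 0)
    expect_equal(sum(d4$ey[sel]), 0)
  }
  expect_error(assign_preferred_directions(sheet_layout(3, 4)), "even")
})

test_that("center-surround edges equal brute-force torus enumeration", {
  lay <- sheet_layout(8, 8)
  ins <- sheet_layout(6, 6, span_rows = 8, span_cols = 8)
  dirs <- assign_preferred_directions(lay)
  preset <- list(annulus_inner = 1.2, annulus_outer = 3.1,
                 disc_radius = 1.0, xi = 1.0, name = "toy")
  cs <- build_cs_connectivity(lay, ins, preset, dirs)
  # exhaustive pairwise re-derivation with scalar loops
  tor <- function(a, b, L) { d <- abs(a - b); min(d, L - d) }
  n_in_edges <- 0L
  for (i in seq_len(ins$count)) {
    for (s in seq_len(lay$count)) {
      d <- sqrt(tor(ins$x[i], lay$x[s], 8)^2 + tor(ins$y[i], lay$y[s], 8)^2)
      if (d >= 1.2 && d < 3.1) n_in_edges <- n_in_edges + 1L
    }
  }
  expect_equal(length(cs$in_to_sc$pre), n_in_edges)
  n_out_edges <- 0L
  for (s in seq_len(lay$count)) {
    cx <- (lay$x[s] + dirs$ex[s]) %% 8
    cy <- (lay$y[s] + dirs$ey[s]) %% 8
    for (i in seq_len(ins$count)) {
      d <- sqrt(tor(cx, ins$x[i], 8)^2 + tor(cy, ins$y[i], 8)^2)
      if (d <= 1.0) n_out_edges <- n_out_edges + 1L
    }
  }
  expect_equal(length(cs$sc_to_in$pre), n_out_edges)
  expect_error(build_cs_connectivity(lay, ins,
                                     list(annulus_inner = 2, annulus_outer = 2,
                                          disc_radius = 1, xi = 1, name = "bad"),
                                     dirs), "annulus")
})

test_that("torus translation symmetry makes out-degree constant per direction class", {
  lay <- sheet_layout(12, 12)
  ins <- sheet_layout(12, 12, span_rows = 12, span_cols = 12)
  dirs <- assign_preferred_directions(lay)
  cs <- build_cs_connectivity(lay, ins, list(annulus_inner = 1.5,
                                             annulus_outer = 4, disc_radius = 1.2,
                                             xi = 1, name = "toy"), dirs)
  out_deg <- tabulate(cs$sc_to_in$pre, lay$count)
  for (lab in levels(dirs$label)) {
    expect_equal(length(unique(out_deg[dirs$label == lab])), 1, label = lab)
  }
  in_out <- tabulate(cs$in_to_sc$pre, ins$count)
  expect_equal(length(unique(in_out)), 1)  # INs are equivalent on the torus
})

test_that("one-to-one wiring is bijective and degree statistics recount exactly", {
  a <- sheet_layout(40, 40)
  g <- build_one_to_one(a, a)
  expect_equal(length(g$pre), 1600)
  expect_equal(tabulate(g$post, 1600), rep(1L, 1600))
  s <- connectivity_stats(g)
  expect_equal(s$out_mean, 1)
  expect_equal(s$out_sd, 0)
  expect_error(build_one_to_one(a, sheet_layout(40, 30)), "sizes differ")
  expect_error(connectivity_stats(synapse_group(integer(0), integer(0),
                                                n_pre = 5, n_post = 5)),
               "empty")
  # recount oracle on an arbitrary group
  set.seed(7)
  g2 <- synapse_group(sample(1:20, 60, TRUE), sample(1:15, 60, TRUE),
                      n_pre = 20, n_post = 15)
  s2 <- connectivity_stats(g2)
  cnt <- sapply(1:20, function(i) sum(g2$pre == i))
  expect_equal(s2$out_mean, mean(cnt))
  expect_equal(s2$out_sd, sd(cnt))
})

test_that("edge lists round-trip through CSV", {
  g <- synapse_group(c(1, 2, 3), c(3, 2, 1), weight = c(1, 0.5, 2),
                     n_pre = 3, n_post = 3)
  path <- tempfile(fileext = ".csv")
  write_edges_csv(g, path)
  g2 <- read_edges_csv(path, n_pre = 3, n_post = 3)
  expect_equal(g2$pre, g$pre)
  expect_equal(g2$post, g$post)
  expect_equal(g2$weight, g$weight)
  unlink(path)
})

test_that("no direct stellate-stellate or interneuron-interneuron edges exist", {
  cfg <- load_model_config()
  net <- build_network(cfg, "desk")
  pre_post <- vapply(net$groups, function(g) paste(g$pre, "->", g$post), "")
  expect_false(any(grepl("Stellate -> MEC LII Stellate", pre_post)))
  in_names <- c("EC LII AxoAxonic", "MEC LII Basket", "EC LII Basket Multipolar")
  for (g in net$groups) {
    expect_false(g$pre %in% in_names && g$post %in% in_names)
  }
})
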
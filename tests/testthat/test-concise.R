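test_that("state positions track the latent closure coordinate", {
  d <- generate_shift_dataset(quiet_config(n_residues = 40L, seed = 6L))
  res <- concise_scores(d$shifts)
  lam <- d$truth$state_lambdas
  # <PC> strictly increasing in lambda order, apo at the minimum
  expect_true(all(diff(res$mean_pc[order(lam)]) > 0))
  expect_equal(which.min(res$mean_pc), 1L, ignore_attr = TRUE)
  # every networked residue responds perfectly linearly and is admitted
  expect_true(all(d$truth$network_members %in% res$residues_used))
})

test_that("duplicated states land at identical equilibrium positions", {
  cfg <- quiet_config(n_residues = 20L, networked_fraction = 1,
                      state_lambdas = c(apo = 0, b1 = 0.5, b2 = 0.5,
                                        tern = 1),
                      seed = 8L)
  d <- generate_shift_dataset(cfg)
  res <- concise_scores(d$shifts)
  expect_equal(res$mean_pc[["b1"]], res$mean_pc[["b2"]], tolerance = 1e-9)
  expect_equal(res$density$sd[2], res$density$sd[3], tolerance = 1e-9)
})

test_that("non-linear trajectories are rejected by the linearity filter", {
  states <- c("s1", "s2", "s3", "s4")
  theta <- c(0, 0.5, 1, 1.5) * pi
  recs <- do.call(rbind, lapply(1:5, function(i)
    data.frame(residue_id = i, state = states,
               delta_H = 8 + 0.1 * cos(theta),
               delta_N = 115 + 0.1 * sin(theta) / 0.154)))
  st <- shift_table(recs, states = states)
  expect_error(concise_scores(st), "linearity")
})

test_that("scores are invariant to constant offsets of a residue's shifts", {
  d <- generate_shift_dataset(synthetic_shift_config(n_residues = 25L,
                                                     seed = 12L))
  res1 <- concise_scores(d$shifts)
  shifted <- d$shifts
  pick <- shifted$residue_id == res1$residues_used[1]
  shifted$delta_H[pick] <- shifted$delta_H[pick] + 3
  shifted$delta_N[pick] <- shifted$delta_N[pick] - 10
  res2 <- concise_scores(shift_table(as.data.frame(shifted),
                                     states = shift_states(d$shifts)))
  expect_equal(res1$scores, res2$scores, tolerance = 1e-10)
})

test_that("community-resolved runs mirror the global result on homogeneous data", {
  d <- generate_shift_dataset(quiet_config(n_residues = 30L,
                                           networked_fraction = 1,
                                           community_count = 3L, seed = 14L))
  glob <- concise_scores(d$shifts)
  per <- suppressWarnings(community_concise(d$shifts, d$communities))
  for (l in names(per)) {
    if (is.null(per[[l]])) next
    expect_equal(per[[l]]$mean_pc, glob$mean_pc, tolerance = 1e-9)
  }
})

test_that("a community that stops short of closure scores below the others", {
  # two groups generated with different ternary-state closure
  full <- generate_shift_dataset(quiet_config(n_residues = 12L,
                                              networked_fraction = 1,
                                              seed = 15L))
  partial_cfg <- quiet_config(n_residues = 12L, networked_fraction = 1,
                              state_lambdas = c(apo = 0, ADP = 0.45,
                                                ATPgN = 0.55,
                                                `ATPgN-PKI` = 0.75),
                              seed = 16L)
  partial <- generate_shift_dataset(partial_cfg)
  pt <- as.data.frame(partial$shifts)
  pt$residue_id <- pt$residue_id + 12L
  combined <- shift_table(rbind(as.data.frame(full$shifts), pt),
                          states = shift_states(full$shifts))
  map <- community_map(data.frame(residue_id = 1:24,
                                  community = rep(c("ComFull", "ComPartial"),
                                                  each = 12)))
  per <- community_concise(combined, map)
  expect_lt(per$ComPartial$mean_pc[["ATPgN-PKI"]],
            per$ComFull$mean_pc[["ATPgN-PKI"]])

  # undersized community: undefined with a warning
  map2 <- community_map(data.frame(residue_id = 1:24,
                                   community = c(rep("Big", 22), "Tiny",
                                                 "Tiny")))
  expect_warning(per2 <- community_concise(combined, map2), "fewer than 3")
  expect_null(per2$Tiny)
})

test_that("percent closed and free energy interpolate between the anchors", {
  mp <- c(apo = -1.2, ADP = -0.1, ATPgN = 0.05, tern = 1.3)
  pct <- percent_closed(mp, "apo", "tern")
  expect_equal(pct[["apo"]], 0)
  expect_equal(pct[["tern"]], 100)
  mid <- c(a = 0, b = 0.5, c = 1)
  expect_equal(percent_closed(mid, "a", "c")[["b"]], 50)
  expect_error(percent_closed(mid, "a", "a"), "differ")
  expect_error(percent_closed(c(a = 1, b = 1), "a", "b"), "degenerate")

  expect_equal(ddg_from_closure(0, ddg_closed = -15), 0)
  expect_equal(ddg_from_closure(100, ddg_closed = -15), -15)
  expect_equal(ddg_from_closure(50, ddg_closed = -15), -7.5)

  # overshoot beyond a reference is reported and flagged, not clipped
  over <- percent_closed(c(a = 0, b = 1.1, c = 1), "a", "c")
  expect_gt(over[["b"]], 100)
  expect_equal(attr(over, "outside"), "b")
})

test_that("free-energy tables anchor exactly and propagate density SDs", {
  d <- generate_shift_dataset(synthetic_shift_config(n_residues = 40L,
                                                     seed = 17L))
  res <- concise_scores(d$shifts)
  fe <- concise_free_energy(res, ddg_closed = -15)
  expect_equal(fe$pct_closed[fe$state == "apo"], 0)
  expect_equal(fe$pct_closed[fe$state == "ATPgN-PKI"], 100)
  expect_equal(fe$ddg[fe$state == "apo"], 0)
  expect_equal(fe$ddg[fe$state == "ATPgN-PKI"], -15)
  # ddg is affine in percent closed
  expect_equal(fe$ddg, -15 * fe$pct_closed / 100)
  # uncertainties scale with the density SDs
  span <- abs(res$mean_pc[["ATPgN-PKI"]] - res$mean_pc[["apo"]])
  expect_equal(fe$ddg_sd, 15 * res$density$sd / span)
})
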
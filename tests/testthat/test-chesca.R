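test_that("the linewidth inequality admits moving residues and drops static ones", {
  states <- c("apo", "ADP", "ATPgN", "tern")
  recs <- rbind(
    # residue 1: 0.10 ppm 1H excursion against 0.04 ppm linewidths -> in
    data.frame(residue_id = 1, state = states,
               delta_H = c(8.00, 8.03, 8.06, 8.10), delta_N = 115,
               lw_H = 0.04, lw_N = 0.4),
    # residue 2: static in both dimensions -> out
    data.frame(residue_id = 2, state = states,
               delta_H = 8.5, delta_N = 118, lw_H = 0.04, lw_N = 0.4),
    # residue 3: moves only in 15N, above its 15N linewidths -> in
    data.frame(residue_id = 3, state = states,
               delta_H = 7.8, delta_N = c(110, 110.2, 110.4, 110.6),
               lw_H = 0.04, lw_N = 0.4))
  st <- shift_table(recs, states = states)
  expect_equal(filter_responsive_residues(st), c(1L, 3L))

  # missing linewidths: defaults with a warning, or an error if disabled
  recs_nolw <- recs[, setdiff(names(recs), c("lw_H", "lw_N"))]
  st2 <- shift_table(recs_nolw, states = states)
  expect_warning(kept <- filter_responsive_residues(st2), "defaults")
  expect_equal(kept, c(1L, 3L))
  expect_error(
    suppressWarnings(filter_responsive_residues(st2, default_lw_H = NULL,
                                                default_lw_N = NULL)),
    "no defaults")
})

test_that("on synthetic data the filter retains exactly the networked set", {
  d <- generate_shift_dataset(quiet_config(n_residues = 80L, seed = 9L))
  expect_identical(filter_responsive_residues(d$shifts),
                   d$truth$network_members)
})

test_that("trajectory projection matches a closed-form singular-value oracle", {
  # perfectly collinear points: infinite linearity, signed distances preserved
  pts <- cbind(c(0, 1, 2, 3) * 0.1, c(0, 1, 2, 3) * 0.5)
  pr <- project_trajectory(pts)
  expect_identical(pr$linearity, Inf)
  step <- sqrt(0.1^2 + (0.154 * 0.5)^2)
  expect_equal(abs(diff(pr$trace)), rep(step, 3), tolerance = 1e-12)

  # isotropic square (after 15N weighting): linearity exactly 1
  sq <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1) / 0.154)
  expect_equal(project_trajectory(sq)$linearity, 1, tolerance = 1e-9)

  # noisy near-collinear fixture agrees with the eigenvalue oracle
  set.seed(7)
  for (k in 1:10) {
    lam <- runif(5)
    pts <- cbind(0.1 * lam + rnorm(5, 0, 0.01),
                 0.6 * lam + rnorm(5, 0, 0.05))
    pr <- project_trajectory(pts)
    sv <- singular_values_oracle(cbind(pts[, 1], 0.154 * pts[, 2]))
    expect_equal(pr$singular_values, sv, tolerance = 1e-10)
    expect_equal(pr$linearity, sv[1] / sv[2], tolerance = 1e-8)
  }
  expect_error(project_trajectory(pts[1:2, ]), "3 states")
})

test_that("correlation matrix equals the brute-force Pearson oracle", {
  # anti-collinear traces correlate at |R| = 1; orthogonal traces at 0
  st <- h_trace_table(list(c(0, 1, 2, 3) * 0.1, c(0, -2, -4, -6) * 0.05,
                           c(0, 1, 0, -1) * 0.1, c(1, 0, -1, 0) * 0.1))
  m <- correlation_matrix(st)
  expect_equal(m$R[1, 2], 1, tolerance = 1e-12)
  expect_equal(m$R[3, 4], 0, tolerance = 1e-12)
  expect_true(isSymmetric(m$R))
  expect_equal(unname(diag(m$R)), rep(1, 4))

  # oracle equivalence on random fixtures of up to 20 residues
  for (seed in 1:5) {
    d <- generate_shift_dataset(synthetic_shift_config(
      n_residues = 5L * seed, networked_fraction = 0.5, seed = seed))
    m <- correlation_matrix(d$shifts)
    expect_lt(max(abs(m$R - abs_cor_matrix_oracle(m$traces))), 1e-12)
    expect_true(all(m$R >= 0 & m$R <= 1 + 1e-15))
  }
})

test_that("zero-variance traces are dropped with a warning", {
  st <- h_trace_table(list(c(0, 1, 2, 3) * 0.1, c(0, 0, 0, 0),
                           c(0, 2, 4, 6) * 0.1))
  expect_warning(m <- correlation_matrix(st), "zero-variance")
  expect_equal(m$residues, c(1L, 3L))
})

test_that("correlation scores count partners over a fixed denominator", {
  # residue with 7 of 9 partners above cutoff, denominator 350 -> 0.02
  R <- diag(1, 10)
  R[1, 2:8] <- R[2:8, 1] <- 0.99
  m <- make_chesca_matrix(R)
  sc <- correlation_scores(m, denominator = 350)
  expect_equal(sc$score[1], 7 / 350)
  expect_equal(sc$score[1], 0.02)
  expect_equal(sc$n_partners[10], 0L)      # isolated residue
  expect_equal(sc$score[10], 0)
  expect_error(correlation_scores(m, denominator = 0), "denominator")

  # fully connected noiseless network of 10, denominator 10 -> 9/10 each
  d <- generate_shift_dataset(quiet_config(n_residues = 10L,
                                           networked_fraction = 1,
                                           seed = 2L))
  mfull <- correlation_matrix(d$shifts)
  expect_equal(correlation_scores(mfull, denominator = 10)$score,
               rep(0.9, 10))
})

test_that("raising the cutoff never increases scores (monotonicity)", {
  d <- generate_shift_dataset(synthetic_shift_config(n_residues = 40L,
                                                     seed = 13L))
  m <- correlation_matrix(d$shifts)
  map <- d$communities
  cuts <- c(0.8, 0.9, 0.95, 0.98, 0.995)
  prev_scores <- NULL; prev_comm <- NULL
  for (ct in cuts) {
    sc <- correlation_scores(m, cutoff = ct)$score
    cm <- community_correlation(m, map, r_cutoff = ct)$R_XY
    if (!is.null(prev_scores)) {
      expect_true(all(sc <= prev_scores + 1e-15))
      expect_true(all(cm <= prev_comm + 1e-15, na.rm = TRUE))
    }
    prev_scores <- sc; prev_comm <- cm
  }
})

test_that("agglomerative clustering recovers block structure", {
  # two independent noiseless networks -> exactly two clusters
  st <- h_trace_table(list(
    c(0, 1, 2, 3) * 0.1, c(0, 2, 4, 6) * 0.1, c(0, -1, -2, -3) * 0.1,
    c(3, 1, 0, 2) * 0.1, c(6, 2, 0, 4) * 0.1, c(-3, -1, 0, -2) * 0.1))
  m <- correlation_matrix(st)
  cl <- cluster_residues(m)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$clusters[[which(sapply(cl$clusters, function(x) 1 %in% x))]],
                  1:3)

  # uncorrelated residues -> all singletons
  R0 <- diag(1, 5); R0[upper.tri(R0)] <- 0.1; R0[lower.tri(R0)] <- 0.1
  expect_length(cluster_residues(make_chesca_matrix(R0))$clusters, 0L)

  # one coherent network -> one cluster
  d <- generate_shift_dataset(quiet_config(n_residues = 8L,
                                           networked_fraction = 1, seed = 4L))
  expect_length(cluster_residues(correlation_matrix(d$shifts))$clusters, 1L)
})

test_that("community scores normalize qualifying pairs by community sizes", {
  # X = {1, 2}, Y = {3, 4, 5}; exactly 3 qualifying cross pairs -> 3/6
  R <- diag(1, 5)
  R[1, 3] <- R[3, 1] <- 0.95
  R[1, 4] <- R[4, 1] <- 0.9
  R[2, 5] <- R[5, 2] <- 0.85
  R[1, 2] <- R[2, 1] <- 0.99   # one within-X pair -> 1/choose(2,2)
  m <- make_chesca_matrix(R)
  map <- community_map(data.frame(residue_id = 1:5,
                                  community = c("X", "X", "Y", "Y", "Y")))
  cm <- community_correlation(m, map, r_cutoff = 0.8)
  expect_equal(cm$R_XY["X", "Y"], 3 / 6)
  expect_equal(cm$R_XY["X", "Y"], 0.5)
  expect_equal(cm$R_XY["X", "X"], 1)       # within-community, unordered pairs
  expect_equal(cm$R_XY["Y", "Y"], 0)       # no qualifying pairs
  expect_true(isSymmetric(cm$R_XY))

  # all cross pairs above cutoff -> upper bound 1
  R1 <- matrix(0.99, 5, 5); diag(R1) <- 1
  cm1 <- community_correlation(make_chesca_matrix(R1), map, r_cutoff = 0.8)
  expect_equal(cm1$R_XY["X", "Y"], 1)

  # a community with no scored residues is undefined, not zero
  map2 <- community_map(data.frame(residue_id = c(1:5, 99),
                                   community = c("X", "X", "Y", "Y", "Y", "Z")))
  cm2 <- community_correlation(m, map2, r_cutoff = 0.8)
  expect_true(all(is.na(cm2$R_XY["Z", ])))
})

test_that("residue order never changes CHESCA outputs", {
  d <- generate_shift_dataset(synthetic_shift_config(n_residues = 30L,
                                                     seed = 21L))
  m1 <- correlation_matrix(d$shifts)
  shuf <- shift_table(d$shifts[sample.int(nrow(d$shifts)), ],
                      states = shift_states(d$shifts))
  m2 <- correlation_matrix(shuf)
  expect_equal(m1$R, m2$R, tolerance = 1e-14)
  expect_equal(correlation_scores(m1)$score, correlation_scores(m2)$score)
})
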
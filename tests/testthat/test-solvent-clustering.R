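# Solvent cluster construction and size statistics.

test_that("simple constructed geometries cluster as expected", {
  # two waters in contact -> one cluster of two
  b <- 0.09572; a <- 104.52 * pi / 180
  w <- rbind(c(0, 0, 0), c(b, 0, 0), c(b * cos(a), b * sin(a), 0))
  pos <- rbind(sweep(w, 2, c(1, 1, 1), "+"),
               sweep(w, 2, c(1.2, 1, 1), "+"))
  top <- spidrosolv:::build_topology(rep(c("OW", "HW1", "HW2"), 2),
                                     rep("SOL", 6), rep(1:2, each = 3),
                                     element = rep(c("O", "H", "H"), 2))
  f <- md_frame(pos, sim_box(3))
  cs <- build_clusters(f, top, "WATER")
  expect_equal(sort(lengths(cs$clusters)), 2L)

  # a chain of molecules, consecutive in contact: one cluster spanning all
  n <- 10
  centres <- cbind(seq(0.5, by = 0.24, length.out = n), 1, 1)
  posc <- do.call(rbind, lapply(seq_len(n), function(k) {
    sweep(w, 2, centres[k, ], "+")
  }))
  topc <- spidrosolv:::build_topology(
    rep(c("OW", "HW1", "HW2"), n), rep("SOL", 3 * n), rep(1:n, each = 3),
    element = rep(c("O", "H", "H"), n))
  fc <- md_frame(posc, sim_box(6))
  csc <- build_clusters(fc, topc, "WATER")
  expect_equal(lengths(csc$clusters), 10L)

  # all far apart: all singletons
  centres2 <- cbind(seq(0.5, by = 0.8, length.out = 5), 1, 1)
  poss <- do.call(rbind, lapply(1:5, function(k) {
    sweep(w, 2, centres2[k, ], "+")
  }))
  tops <- spidrosolv:::build_topology(
    rep(c("OW", "HW1", "HW2"), 5), rep("SOL", 15), rep(1:5, each = 3),
    element = rep(c("O", "H", "H"), 5))
  fs <- md_frame(poss, sim_box(6))
  expect_equal(lengths(build_clusters(fs, tops, "WATER")$clusters),
               rep(1L, 5))
})

test_that("clusters spanning the periodic boundary are joined", {
  # two waters touching only across the box face
  b <- 0.09572
  pos <- rbind(c(0.05, 1, 1), c(0.05 + b, 1, 1), c(0.02, 1.09, 1),
               c(1.92, 1, 1), c(1.92 - b, 1, 1), c(1.95, 1.09, 1))
  top <- spidrosolv:::build_topology(rep(c("OW", "HW1", "HW2"), 2),
                                     rep("SOL", 6), rep(1:2, each = 3),
                                     element = rep(c("O", "H", "H"), 2))
  f <- md_frame(pos, sim_box(2))
  cs <- build_clusters(f, top, "WATER")
  expect_equal(lengths(cs$clusters), 2L)
})

test_that("cluster construction equals the brute-force BFS oracle", {
  # many random periodic configurations, including dense ones
  set.seed(20)
  for (rep_i in 1:20) {
    nw <- sample(30:70, 1)
    L <- runif(1, 1.6, 2.6)
    sys <- random_mixture(seed = 100 + rep_i, n_water = nw,
                          n_ethanol = sample(0:6, 1), box_length = L)
    at <- sys$topology$atoms
    for (sp in c("WATER", "ETHANOL")) {
      mols <- species_molecules(sys$topology, sp)
      if (length(mols) == 0) next
      sel <- which(at$molecule_id %in% mols)
      got <- build_clusters(sys$frame, sys$topology, sp)
      ref <- oracle_clusters(sys$frame$positions[sel, , drop = FALSE],
                             at$molecule_id[sel], rep(L, 3), 0.25)
      key <- function(cl) sort(vapply(cl, function(x)
        paste(sort(x), collapse = ","), ""))
      expect_equal(key(got$clusters), key(ref))
    }
  }
})

test_that("cluster sizes partition the species and the cutoff is monotone", {
  sys <- random_mixture(seed = 55, n_water = 60, n_ethanol = 10,
                        box_length = 2.2)
  for (sp in c("WATER", "ETHANOL")) {
    n_mol <- length(species_molecules(sys$topology, sp))
    cs <- build_clusters(sys$frame, sys$topology, sp)
    expect_equal(sum(lengths(cs$clusters)), n_mol)
    expect_true(all(lengths(cs$clusters) > 0))
  }
  # coarsening: every cluster at the smaller cutoff is inside one at the
  # larger cutoff
  small <- build_clusters(sys$frame, sys$topology, "WATER",
                          cluster_criterion(0.22))
  big <- build_clusters(sys$frame, sys$topology, "WATER",
                        cluster_criterion(0.3))
  for (cl in small$clusters) {
    containing <- vapply(big$clusters, function(b) all(cl %in% b), logical(1))
    expect_equal(sum(containing), 1L)
  }
  expect_error(build_clusters(sys$frame, sys$topology, "WATER",
                              cluster_criterion(1.2)), "half")
})

test_that("size distributions follow the two weighting conventions", {
  # constant ensemble with clusters {3, 3, 4}
  b <- 0.09572
  w <- rbind(c(0, 0, 0), c(b, 0, 0), c(0, b, 0))
  place <- function(centres) do.call(rbind, lapply(seq_len(nrow(centres)),
    function(k) sweep(w, 2, centres[k, ], "+")))
  # three groups well separated; in-group spacing 0.2 nm chains
  grp <- function(n, origin) cbind(origin[1] + 0.2 * (seq_len(n) - 1),
                                   origin[2], origin[3])
  centres <- rbind(grp(3, c(0.5, 0.5, 0.5)), grp(3, c(0.5, 2.5, 0.5)),
                   grp(4, c(0.5, 4.5, 0.5)))
  nmol <- nrow(centres)
  top <- spidrosolv:::build_topology(
    rep(c("OW", "HW1", "HW2"), nmol), rep("SOL", 3 * nmol),
    rep(seq_len(nmol), each = 3), element = rep(c("O", "H", "H"), nmol))
  f <- md_frame(place(centres), sim_box(6), time = 0)
  traj <- trajectory(top, list(f))
  dist <- cluster_size_distribution(traj, "WATER")
  p3 <- dist$p_cluster[dist$size_lo == 3]
  p4 <- dist$p_cluster[dist$size_lo == 4]
  expect_equal(p3, 2 / 3, tolerance = 1e-12)
  expect_equal(p4, 1 / 3, tolerance = 1e-12)
  # molecule-weighted: 6/10 in 3-clusters, 4/10 in the 4-cluster
  expect_equal(dist$p_molecule[dist$size_lo == 3], 0.6, tolerance = 1e-12)
  expect_equal(dist$p_molecule[dist$size_lo == 4], 0.4, tolerance = 1e-12)
  expect_equal(sum(dist$p_cluster), 1, tolerance = 1e-12)
  expect_equal(sum(dist$p_molecule), 1, tolerance = 1e-12)

  # pooling two frames equals the brute-force tally
  f2 <- md_frame(place(centres), sim_box(6), time = 1)
  traj2 <- trajectory(top, list(f, f2))
  dist2 <- cluster_size_distribution(traj2, "WATER")
  expect_equal(dist2$p_cluster, dist$p_cluster)

  # all singletons -> P(1) = 1
  far <- cbind(seq(0.5, by = 1.1, length.out = 5), 0.5, 0.5)
  top5 <- spidrosolv:::build_topology(
    rep(c("OW", "HW1", "HW2"), 5), rep("SOL", 15), rep(1:5, each = 3),
    element = rep(c("O", "H", "H"), 5))
  traj5 <- trajectory(top5, list(md_frame(place(far), sim_box(6))))
  d5 <- cluster_size_distribution(traj5, "WATER")
  expect_equal(d5$p_cluster[d5$size_lo == 1], 1)
})

test_that("mean-size series is constant for static frames and smooths steps", {
  sys <- random_mixture(seed = 77, n_water = 30, n_ethanol = 0,
                        box_length = 2.0)
  traj <- perturb_trajectory(sys, 6, generator_config(seed = 1,
                                                      jitter_sigma = 0))
  ms <- mean_cluster_size_series(traj, "WATER")
  expect_equal(ms$mean_size, rep(ms$mean_size[1], 6))
  expect_equal(ms$mean_size_smooth, ms$mean_size)
  ms3 <- mean_cluster_size_series(traj, "WATER", window = 3)
  expect_equal(ms3$mean_size_smooth, ms$mean_size)
})

test_that("with/without-protein comparison sees adsorbed-layer clusters", {
  # identical trajectories -> all deltas zero
  sys <- random_mixture(seed = 31, n_water = 40, n_ethanol = 0,
                        box_length = 2.2)
  traj <- trajectory(sys$topology, list(sys$frame))
  cmp0 <- compare_with_without_protein(traj, traj, "WATER")
  expect_equal(cmp0$delta_small_per_frame, 0)
  expect_equal(cmp0$delta_largest, 0)
  expect_equal(cmp0$distribution$p_cluster_with,
               cmp0$distribution$p_cluster_without)

  # adsorbed-layer fixture: a bulk blob plus a ring of waters around a
  # solute, far from the blob; solvent-only system lacks the ring
  b <- 0.09572
  w <- rbind(c(0, 0, 0), c(b, 0, 0), c(0, b, 0))
  blob <- as.matrix(expand.grid(x = seq(3.0, 3.6, 0.3),
                                y = seq(3.0, 3.6, 0.3), z = 3.3))
  ring_angles <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1 + 0.45 * cos(ring_angles), 1 + 0.45 * sin(ring_angles), 1)
  mk_sys <- function(centres) {
    nmol <- nrow(centres)
    top <- spidrosolv:::build_topology(
      rep(c("OW", "HW1", "HW2"), nmol), rep("SOL", 3 * nmol),
      rep(seq_len(nmol), each = 3), element = rep(c("O", "H", "H"), nmol))
    pos <- do.call(rbind, lapply(seq_len(nmol), function(k) {
      sweep(w, 2, centres[k, ], "+")
    }))
    trajectory(top, list(md_frame(pos, sim_box(5))))
  }
  with_prot <- mk_sys(rbind(blob, ring))      # ring = adsorbed layer
  without <- mk_sys(blob)
  cmp <- compare_with_without_protein(with_prot, without, "WATER")
  expect_gt(cmp$delta_small_per_frame, 0)     # extra small clusters appear
  expect_equal(cmp$delta_largest, 0)          # bulk blob unchanged
})
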
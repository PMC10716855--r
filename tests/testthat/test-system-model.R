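# Core data model, file I/O and geometric primitives.

test_that("minimum-image distance matches explicit 27-image enumeration", {
  b <- sim_box(8.8)
  expect_equal(minimum_image_distance(c(0.1, 0, 0), c(8.7, 0, 0), b), 0.2)
  expect_equal(minimum_image_distance(c(0, 0, 0), c(4.4, 4.4, 4.4), b),
               4.4 * sqrt(3), tolerance = 1e-12)
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), b), 0)

  set.seed(42)
  bl <- c(3.1, 4.2, 2.7)
  box <- sim_box(bl)
  for (k in 1:25) {
    a <- runif(3, 0, bl)
    p <- runif(3, 0, bl)
    expect_equal(minimum_image_distance(a, p, box),
                 oracle_min_image(a, p, bl), tolerance = 1e-10)
    # symmetry and lattice-translation invariance
    expect_equal(minimum_image_distance(a, p, box),
                 minimum_image_distance(p, a, box))
    shift <- sample(-2:2, 3, replace = TRUE) * bl
    expect_equal(minimum_image_distance(a, p + shift, box),
                 minimum_image_distance(a, p, box), tolerance = 1e-10)
  }
})

test_that("neighbour-pair search equals the brute-force pair scan", {
  set.seed(7)
  for (k in 1:10) {
    n <- sample(40:120, 1)
    bl <- runif(3, 1.5, 3)
    pos <- cbind(runif(n, 0, bl[1]), runif(n, 0, bl[2]), runif(n, 0, bl[3]))
    cutoff <- runif(1, 0.2, 0.45)
    got <- neighbor_pairs(pos, sim_box(bl), cutoff)
    ref <- oracle_pairs(pos, bl, cutoff)
    key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
    expect_setequal(key(got), key(ref))
  }
})

test_that("radius of gyration follows the mass-weighted formula", {
  top1 <- spidrosolv:::build_topology(c("CA", "CA"), c("ALA", "ALA"), c(1L, 2L),
                                      element = c("C", "C"))
  f <- md_frame(rbind(c(0, 0, 0), c(1, 0, 0)), sim_box(5))
  expect_equal(radius_of_gyration(f, top1, 1:2), 0.5)
  expect_equal(radius_of_gyration(f, top1, 1L), 0)
  expect_error(radius_of_gyration(f, top1, integer()), "empty")

  # four unit masses at square corners, side 0.6 -> a / sqrt(2)
  a <- 0.6
  sq <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0))
  top4 <- spidrosolv:::build_topology(rep("CA", 4), rep("GLY", 4), 1:4,
                                      element = rep("C", 4))
  f4 <- md_frame(sq, sim_box(5))
  expect_equal(radius_of_gyration(f4, top4, 1:4), a / sqrt(2),
               tolerance = 1e-12)

  # translation invariance on a random frame
  set.seed(1)
  ch <- build_chain("GAQYAS", "random_coil", generator_config(seed = 3))
  f0 <- ch$frame
  f1 <- md_frame(f0$positions + matrix(rep(c(1, -2, 0.5), each =
                                             nrow(f0$positions)), ncol = 3),
                 f0$box)
  expect_equal(radius_of_gyration(f0, ch$topology),
               radius_of_gyration(f1, ch$topology), tolerance = 1e-10)
})

test_that("RMSD handles superposition, identity and closed-form cases", {
  ch <- build_chain("AAAAA", "ideal_helix")
  f <- ch$frame
  expect_equal(rmsd_to_reference(f, f, ch$topology), 0)

  # rigid translation vanishes under superposition
  ft <- md_frame(sweep(f$positions, 2, c(0.7, -0.3, 1.1), "+"), f$box)
  expect_lt(rmsd_to_reference(ft, f, ch$topology, superpose = TRUE), 1e-6)
  # and a rigid rotation too
  th <- 0.6
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr <- md_frame(f$positions %*% rot, f$box)
  expect_lt(rmsd_to_reference(fr, f, ch$topology, superpose = TRUE), 1e-6)

  # one of N=10 atoms displaced by 0.3 nm, no superposition: 0.3/sqrt(10)
  pos <- matrix(rnorm(30), 10, 3)
  top <- spidrosolv:::build_topology(rep("CA", 10), rep("GLY", 10), 1:10,
                                     element = rep("C", 10))
  fa <- md_frame(pos, sim_box(10))
  pos2 <- pos; pos2[4, ] <- pos2[4, ] + c(0.3, 0, 0)
  fb <- md_frame(pos2, sim_box(10))
  expect_equal(rmsd_to_reference(fb, fa, selection = 1:10, superpose = FALSE),
               0.3 / sqrt(10), tolerance = 1e-12)
})

test_that("RMSD and Rg agree with bio3d on a helix", {
  skip_if_not_installed("bio3d")
  ch <- build_chain("AAAAAAAA", "ideal_helix")
  sel <- protein_heavy_atoms(ch$topology)
  set.seed(5)
  jit <- perturb_trajectory(ch, 2, generator_config(seed = 2,
                                                    jitter_sigma = 0.05))
  a <- ch$frame$positions[sel, ] * 10          # Angstrom for bio3d
  b <- jit$frames[[2]]$positions[sel, ] * 10
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  got <- rmsd_to_reference(jit$frames[[2]], ch$frame, ch$topology,
                           superpose = TRUE) * 10
  expect_equal(got, ref, tolerance = 1e-3)

  m <- ch$topology$atoms$mass[sel]
  rg_ref <- bio3d::rgyr(bio3d::as.xyz(matrix(as.vector(t(a)), nrow = 1)),
                        mass = m)
  expect_equal(radius_of_gyration(ch$frame, ch$topology, sel) * 10,
               unname(rg_ref), tolerance = 1e-3)
})

test_that("structure files round-trip through PDB and GRO", {
  ch <- build_chain("GAQYASGPGQ", "random_coil", generator_config(seed = 11))
  for (fmt in c("pdb", "gro")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_structure(ch$topology, ch$frame, path)
    back <- read_structure(path)
    expect_equal(nrow(back$topology$atoms), nrow(ch$topology$atoms))
    expect_equal(back$topology$sequence, ch$topology$sequence)
    expect_equal(back$frame$positions, ch$frame$positions, tolerance = 1e-3)
    expect_equal(unclass(back$frame$box), unclass(ch$frame$box),
                 tolerance = 1e-3)
  }
})

test_that("PDB reading agrees with bio3d coordinates", {
  skip_if_not_installed("bio3d")
  ch <- build_chain("AAGG", "extended")
  path <- tempfile(fileext = ".pdb")
  write_structure(ch$topology, ch$frame, path)
  ref <- bio3d::read.pdb(path)
  got <- read_structure(path)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE) / 10,
               got$frame$positions, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("GRO water parses to a single 3-atom water molecule", {
  lines <- c("one water", "    3",
             "    1SOL    OW    1   0.500   0.500   0.500",
             "    1SOL   HW1    2   0.596   0.500   0.500",
             "    1SOL   HW2    3   0.476   0.593   0.500",
             "   2.00000   2.00000   2.00000")
  path <- tempfile(fileext = ".gro")
  writeLines(lines, path)
  s <- read_structure(path)
  expect_equal(nrow(s$topology$atoms), 3L)
  expect_equal(s$topology$molecules$species, "WATER")
  expect_equal(nrow(s$topology$molecules), 1L)
})

test_that("malformed and incomplete structure files raise targeted errors", {
  ch <- build_chain("AA", "extended")
  path <- tempfile(fileext = ".pdb")
  write_structure(ch$topology, ch$frame, path)
  lines <- readLines(path)
  # missing box record
  writeLines(lines[!grepl("^CRYST1", lines)], path)
  expect_error(read_structure(path), "CRYST1")
  # corrupted coordinate field
  bad <- lines
  bad[3] <- paste0(substr(bad[3], 1, 30), "  badnum", substr(bad[3], 39, 80))
  writeLines(bad, path)
  expect_error(read_structure(path), "line 3")
  # unknown residue name without a mapping
  unk <- lines
  unk <- sub("ALA", "XXZ", unk)
  writeLines(unk, path)
  expect_error(read_structure(path), "XXZ")
})

test_that("species mapping overrides are honoured", {
  lines <- c("methanolish", "    1",
             "    1MOH    O1    1   0.500   0.500   0.500",
             "   2.00000   2.00000   2.00000")
  path <- tempfile(fileext = ".gro")
  writeLines(lines, path)
  expect_error(read_structure(path), "MOH")
  s <- read_structure(path, species_map = c(MOH = "ETHANOL"))
  expect_equal(s$topology$molecules$species, "ETHANOL")

  mp <- tempfile()
  writeLines(c("# comment", "MOH = ETHANOL"), mp)
  expect_equal(read_species_map(mp), c(MOH = "ETHANOL"))
})

test_that("trajectory reading respects stride, times and truncation errors", {
  ch <- build_chain("AAAA", "extended")
  traj <- perturb_trajectory(ch, 10, generator_config(seed = 1,
                                                      jitter_sigma = 0.01))
  path <- tempfile(fileext = ".pdb")
  write_trajectory(traj, path)

  back <- read_trajectory(path, ch$topology)
  expect_length(back$frames, 10L)
  expect_equal(frame_times(back), 0:9)
  expect_equal(back$frames[[4]]$positions, traj$frames[[4]]$positions,
               tolerance = 1e-3)

  half <- read_trajectory(path, ch$topology, stride = 2)
  expect_length(half$frames, 5L)

  # truncated final frame: drop the last ENDMDL
  lines <- readLines(path)
  writeLines(lines[-max(grep("^ENDMDL", lines))], path)
  expect_error(read_trajectory(path, ch$topology), "frame 10")
})

test_that("trajectory invariants are enforced", {
  ch <- build_chain("AA", "extended")
  f1 <- ch$frame
  f2 <- md_frame(f1$positions, f1$box, time = 0)
  expect_error(trajectory(ch$topology, list(f1, f2)), "strictly increasing")
  short <- md_frame(f1$positions[-1, , drop = FALSE], f1$box, time = 1)
  expect_error(trajectory(ch$topology, list(f1, short)), "frame 2")
  expect_error(trajectory(ch$topology, list(f1), equilibration_cut = -1),
               ">= 0")
})
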
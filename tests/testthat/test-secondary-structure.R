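# DSSP-style assignment and grouped fraction statistics.

test_that("ideal helix, lone extended chain and sheet dimer assign correctly", {
  ch <- build_chain(strrep("A", 12), "ideal_helix")
  ss <- assign_secondary_structure(ch$frame, ch$topology)
  interior <- ss[2:11]
  expect_gte(mean(interior == "H"), 0.8)

  ext <- build_chain(strrep("A", 10), "extended")
  ss_ext <- assign_secondary_structure(ext$frame, ext$topology)
  expect_true(all(ss_ext %in% c("C", "S")))
  expect_equal(sum(ss_ext == "E"), 0L)

  dim2 <- build_sheet_dimer()
  ss_sheet <- assign_secondary_structure(dim2$frame, dim2$topology)
  expect_gte(sum(ss_sheet == "E"), 6L)
})

test_that("assignment matches the reference DSSP implementation", {
  # a mixed library: helices, strands+sheets, coils, a long helix, a
  # two-chain dimer; >= 20 structures in all
  structures <- list()
  for (k in 1:6) {
    structures[[length(structures) + 1L]] <-
      build_chain(strrep("A", 8 + k), "ideal_helix")
  }
  for (k in 1:4) {
    structures[[length(structures) + 1L]] <-
      build_chain(strrep("A", 6 + k), "extended")
  }
  for (seed in 1:6) {
    structures[[length(structures) + 1L]] <-
      build_chain("GAGAGSQGGYGQGAG", "random_coil",
                  generator_config(seed = seed))
  }
  for (nn in c(5, 6, 7, 8)) {
    structures[[length(structures) + 1L]] <-
      build_sheet_dimer(strrep("A", nn))
  }
  expect_gte(length(structures), 20L)

  paths <- character(length(structures))
  mine <- character(length(structures))
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    paths[s] <- tempfile(fileext = ".pdb")
    write_structure(st$topology, st$frame, paths[s])
    mine[s] <- paste(suppressWarnings(
      assign_secondary_structure(st$frame, st$topology)), collapse = "")
  }
  ref <- reference_dssp(paths)
  ref <- ref[match(paths, ref$path), ]
  total <- 0L; agree <- 0L
  for (s in seq_along(structures)) {
    a <- strsplit(mine[s], "")[[1]]
    b <- strsplit(ref$codes[s], "")[[1]]
    expect_length(a, length(b))
    total <- total + length(a)
    agree <- agree + sum(a == b)
  }
  expect_gte(agree / total, 0.95)
})

test_that("residues missing backbone atoms are forced to coil", {
  ch <- build_chain("AAAAAA", "ideal_helix")
  at <- ch$topology$atoms
  drop <- which(at$residue_index == 3 & at$name == "O")
  keep <- setdiff(seq_len(nrow(at)), drop)
  top2 <- spidrosolv:::build_topology(at$name[keep],
                                      ch$topology$residues$resname[
                                        at$residue_index[keep]],
                                      at$residue_index[keep],
                                      element = at$element[keep])
  f2 <- md_frame(ch$frame$positions[keep, ], ch$frame$box)
  expect_warning(ss <- assign_secondary_structure(f2, top2), "forced to C")
  expect_equal(ss[3], "C")
})

test_that("group fractions sum to one and follow the grouping schemes", {
  ch <- build_chain(strrep("A", 12), "ideal_helix")
  traj <- perturb_trajectory(ch, 8, generator_config(seed = 2,
                                                     jitter_sigma = 0.004))
  ss <- assign_trajectory(traj)
  for (scheme in list(grouping_scheme("four_group"),
                      grouping_scheme("three_group"))) {
    ft <- group_fractions(ss, scheme)
    pf <- attr(ft, "per_frame")
    expect_equal(unname(rowSums(pf)), rep(1, nrow(pf)))
    expect_equal(sum(ft$mean), 1, tolerance = 1e-12)
  }

  # hand-built assignment matrices against hand-computed fractions
  mk <- function(codes) structure(matrix(codes, nrow = 1),
                                  residue_index = seq_along(codes),
                                  class = "ss_assignment")
  allc <- mk(rep("C", 10))
  ft <- group_fractions(allc, grouping_scheme("four_group"))
  expect_equal(ft$mean[ft$group == "coil"], 1)
  expect_equal(sum(ft$mean), 1)

  const <- rbind(matrix(rep(c(rep("H", 3), rep("T", 2), rep("C", 5)), 4),
                        nrow = 4, byrow = TRUE))
  m <- structure(const, residue_index = 1:10, class = "ss_assignment")
  f3 <- group_fractions(m, grouping_scheme("three_group"))
  expect_equal(f3$mean[f3$group == "ordered"], 0.3)
  expect_equal(f3$mean[f3$group == "turns"], 0.2)
  expect_equal(f3$mean[f3$group == "other"], 0.5)
  expect_equal(f3$std, rep(0, 3))

  # two-frame ensemble all-H / all-C: mean 0.5, population std 0.5
  two <- structure(rbind(rep("H", 6), rep("C", 6)), residue_index = 1:6,
                   class = "ss_assignment")
  f4 <- group_fractions(two, grouping_scheme("four_group"))
  expect_equal(f4$mean[f4$group == "helical"], 0.5)
  expect_equal(f4$std[f4$group == "helical"], 0.5)
})

test_that("fraction densities integrate to one and locate the mode", {
  mk <- function(m) structure(m, residue_index = seq_len(ncol(m)),
                              class = "ss_assignment")
  # constant ensemble: sharp peak at the constant value
  const <- mk(matrix(rep(c(rep("H", 5), rep("C", 5)), 20), nrow = 20,
                     byrow = TRUE))
  d <- fraction_distribution(const, grouping_scheme("four_group"), "helical")
  expect_lt(abs(d$fraction[which.max(d$density)] - 0.5), 0.01)
  integral <- sum(d$density) * diff(d$fraction[1:2])
  expect_lt(abs(integral - 1), 0.01)

  # sampled fractions around 0.5: mode within 0.02, integral within 0.01
  set.seed(31)
  x <- pmin(pmax(rnorm(500, 0.5, 0.05), 0), 1)
  n_res <- 200
  m <- t(vapply(x, function(f) {
    c(rep("H", round(f * n_res)), rep("C", n_res - round(f * n_res)))
  }, character(n_res)))
  d2 <- fraction_distribution(mk(m), grouping_scheme("four_group"), "helical")
  expect_lt(abs(d2$fraction[which.max(d2$density)] - 0.5), 0.02)
  expect_lt(abs(sum(d2$density) * diff(d2$fraction[1:2]) - 1), 0.01)

  single <- mk(matrix("C", nrow = 1, ncol = 4))
  expect_error(fraction_distribution(single, group = "coil"),
               "perturb_trajectory")
})

test_that("per-type contributions match brute-force counting", {
  # 50/50 Gly/Ala chain, Gly all T, Ala all H
  codes <- rep(c("T", "H"), 5)
  top <- spidrosolv:::build_topology(
    rep("CA", 10), rep(c("GLY", "ALA"), 5), 1:10, element = rep("C", 10))
  m <- structure(matrix(codes, nrow = 1), residue_index = 1:10,
                 class = "ss_assignment")
  tab <- per_aatype_contributions(m, top, grouping_scheme("four_group"))
  expect_equal(tab$mean[tab$aa == "G" & tab$group == "turn_related"], 0.5)
  expect_equal(tab$mean[tab$aa == "A" & tab$group == "helical"], 0.5)
  expect_equal(sum(tab$mean), 1, tolerance = 1e-12)

  # random assignments against an independent per-frame tally
  set.seed(12)
  codes8 <- c("H", "G", "I", "E", "B", "T", "S", "C")
  nf <- 40; nr <- 12
  rnd <- matrix(sample(codes8, nf * nr, replace = TRUE), nf, nr)
  top2 <- spidrosolv:::build_topology(
    rep("CA", nr), sample(c("GLY", "ALA", "GLN"), nr, replace = TRUE),
    1:nr, element = rep("C", nr))
  m2 <- structure(rnd, residue_index = 1:nr, class = "ss_assignment")
  sch <- grouping_scheme("four_group")
  tab2 <- per_aatype_contributions(m2, top2, sch)
  aa <- spidrosolv:::aa_one(top2$residues$resname)
  for (k in seq_len(nrow(tab2))) {
    manual <- mean(vapply(seq_len(nf), function(f) {
      sum(aa == tab2$aa[k] &
            unname(sch$mapping[rnd[f, ]]) == tab2$group[k]) / nr
    }, numeric(1)))
    expect_equal(tab2$mean[k], manual, tolerance = 1e-12)
  }
  expect_equal(sum(tab2$mean), 1, tolerance = 1e-12)
})

test_that("delta tables subtract with quadrature errors and antisymmetry", {
  a <- structure(data.frame(group = c("helical", "coil"),
                            mean = c(0.18, 0.82), std = c(0.03, 0.03)),
                 class = c("fraction_table", "data.frame"))
  b <- structure(data.frame(group = c("helical", "coil"),
                            mean = c(0.20, 0.80), std = c(0.03, 0.03)),
                 class = c("fraction_table", "data.frame"))
  d <- delta_table(a, b)
  expect_equal(d$delta[d$group == "helical"], 0.02)
  expect_equal(d$std[d$group == "helical"], sqrt(2) * 0.03, tolerance = 1e-12)

  expect_equal(delta_table(a, a)$delta, c(0, 0))
  expect_equal(delta_table(a, b)$delta, -delta_table(b, a)$delta)

  bad <- b; bad$group[1] <- "bend"
  expect_error(delta_table(a, bad), "bend")
})
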
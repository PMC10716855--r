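# Synthetic test-system generators: peptide chains built from internal
# coordinates, solvated water/ethanol boxes at the published compositions,
# jittered pseudo-trajectories, and synthetic CD fraction tables. These are
# fixtures for exercising the analysis stages without MD; the random-coil
# generator is clash-rejecting, not Boltzmann-weighted.

#' Generator configuration
#'
#' @param seed integer RNG seed.
#' @param min_insertion_distance minimum allowed any-atom inter-molecular
#'   distance when packing solvent, nm (default 0.22, just below the 0.25 nm
#'   analysis cutoff so packed boxes exercise both contact regimes).
#' @param helix_dihedrals backbone (phi, psi) in degrees for `ideal_helix`
#'   chains; default the canonical alpha-helix (-57, -47).
#' @param jitter_sigma per-coordinate Gaussian displacement for
#'   [perturb_trajectory()], nm.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, min_insertion_distance = 0.22,
                             helix_dihedrals = c(-57, -47),
                             jitter_sigma = 0.02) {
  if (min_insertion_distance <= 0) stop("min_insertion_distance must be > 0")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(seed = as.integer(seed),
                 min_insertion_distance = min_insertion_distance,
                 helix_dihedrals = helix_dihedrals,
                 jitter_sigma = jitter_sigma),
            class = "generator_config")
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulated-system compositions
#'
#' The four simulated solvent compositions: ethanol volume percentage, water,
#' ethanol and NaCl pair counts, and cubic box edge (nm).
#'
#' @return data.frame of class `system_composition` rows with columns
#'   `ethanol_vv_percent`, `n_water`, `n_ethanol`, `n_nacl_pairs`,
#'   `box_length`.
#' @export
table1_compositions <- function() {
  data.frame(
    ethanol_vv_percent = c(0, 20, 80, 94),
    n_water = c(24500L, 18209L, 4445L, 1301L),
    n_ethanol = c(0L, 1408L, 5496L, 6567L),
    n_nacl_pairs = c(71L, 0L, 0L, 0L),
    box_length = c(9.1, 8.8, 8.8, 8.8)
  )
}

#' Scale a composition's molecule counts
#'
#' Divides the molecule counts of a composition row by `scale` (rounding to
#' the nearest integer) and substitutes a smaller box, preserving the mixture
#' ratio for desk-sized test systems.
#'
#' @param composition one row of [table1_compositions()] or a compatible
#'   data.frame/list.
#' @param scale divisor for all counts (default 50).
#' @param box_length new cubic box edge, nm.
#' @return a one-row composition data.frame.
#' @export
scale_composition <- function(composition, scale = 50, box_length = 3.0) {
  data.frame(
    ethanol_vv_percent = composition$ethanol_vv_percent,
    n_water = as.integer(round(composition$n_water / scale)),
    n_ethanol = as.integer(round(composition$n_ethanol / scale)),
    n_nacl_pairs = as.integer(round(composition$n_nacl_pairs / scale)),
    box_length = box_length
  )
}

# ---- internal-coordinate atom placement ------------------------------------

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D given positions a-b-c, bond |cD|, angle b-c-D (deg) and
# dihedral a-b-c-D (deg); standard natural-extension-reference-frame step
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# four-point torsion angle in degrees, IUPAC sign convention
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# direction from apex making `angle` (deg) with both unit vectors u1, u2
bisector_out_of_plane <- function(u1, u2, angle) {
  ct <- cos(angle * pi / 180)
  s <- u1 + u2
  alpha <- ct / (1 + sum(u1 * u2))
  v_in <- alpha * s
  rem <- 1 - sum(v_in * v_in)
  n <- cross3(u1, u2)
  v <- v_in + sqrt(max(rem, 0)) * unitv(n)
  unitv(v)
}

# ideal backbone geometry (nm / degrees)
.BB <- list(
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329, b_c_o = 0.1231,
  b_n_h = 0.101, b_ca_cb = 0.1521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, omega = 180
)

#' Build a peptide chain from internal coordinates
#'
#' Constructs backbone (N, H, CA, C, O) plus CB atoms for a sequence at fixed
#' or randomly drawn backbone dihedrals. `ideal_helix` uses the configured
#' (phi, psi) (default -57, -47); `extended` uses (180, 180); `random_coil`
#' draws each residue's (phi, psi) uniformly and re-draws on any heavy-atom
#' clash closer than `min_insertion_distance` against residues at least two
#' positions back. The amide hydrogen is placed by the DSSP convention, 0.101
#' nm from N opposite the preceding carbonyl; the first residue and prolines
#' carry no amide H.
#'
#' @param sequence one-letter amino-acid string.
#' @param mode `"ideal_helix"`, `"extended"` or `"random_coil"`.
#' @param config a [generator_config()].
#' @param box optional [sim_box()]; default a cube comfortably containing the
#'   chain.
#' @return list with `topology` and `frame`.
#' @export
build_chain <- function(sequence, mode = c("ideal_helix", "extended",
                                           "random_coil"),
                        config = generator_config(), box = NULL) {
  mode <- match.arg(mode)
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq1 %in% names(.AA_THREE))) {
    stop("sequence contains non-standard residue letters: ",
         paste(setdiff(seq1, names(.AA_THREE)), collapse = ", "))
  }
  n <- length(seq1)
  phi_psi <- switch(mode,
    ideal_helix = matrix(rep(config$helix_dihedrals, n), ncol = 2, byrow = TRUE),
    extended = matrix(rep(c(180, 180), n), ncol = 2, byrow = TRUE),
    random_coil = NULL)

  build <- function(pp) chain_coords(seq1, pp, config$min_insertion_distance)

  if (mode == "random_coil") {
    res <- with_seed(config$seed, random_coil_coords(seq1, config))
  } else {
    res <- build(phi_psi)
  }
  name <- res$name; resid <- res$resid; pos <- res$pos
  if (is.null(box)) {
    ext <- apply(pos, 2, function(v) diff(range(v)))
    box <- sim_box(max(ext) + 4)
  }
  pos <- sweep(pos, 2, apply(pos, 2, min) - 1)  # keep inside the box
  top <- build_topology(name, aa_three(seq1)[resid], resid)
  list(topology = top, frame = md_frame(pos, box))
}

# deterministic whole-chain build at given per-residue (phi, psi)
chain_coords <- function(seq1, phi_psi, min_dist = NULL) {
  n <- length(seq1)
  g <- .BB
  # per-residue atom storage
  Npos <- matrix(NA_real_, n, 3); CApos <- Npos; Cpos <- Npos; Opos <- Npos
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  Cpos[1, ] <- CApos[1, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    psi <- phi_psi[i, 2]
    Opos[i, ] <- place_atom(Npos[i, ], CApos[i, ], Cpos[i, ],
                            g$b_c_o, g$a_ca_c_o, psi + 180)
    if (i < n) {
      Npos[i + 1, ] <- place_atom(Npos[i, ], CApos[i, ], Cpos[i, ],
                                  g$b_c_n, g$a_ca_c_n, psi)
      CApos[i + 1, ] <- place_atom(CApos[i, ], Cpos[i, ], Npos[i + 1, ],
                                   g$b_n_ca, g$a_c_n_ca, g$omega)
      Cpos[i + 1, ] <- place_atom(Cpos[i, ], Npos[i + 1, ], CApos[i + 1, ],
                                  g$b_ca_c, g$a_n_ca_c, phi_psi[i + 1, 1])
    }
  }
  assemble_residues(seq1, Npos, CApos, Cpos, Opos)
}

assemble_residues <- function(seq1, Npos, CApos, Cpos, Opos) {
  g <- .BB
  n <- length(seq1)
  name <- character(0); resid <- integer(0); pos <- NULL
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    p <- rbind(Npos[i, ], CApos[i, ], Cpos[i, ], Opos[i, ])
    if (i > 1 && seq1[i] != "P") {
      h <- Npos[i, ] + g$b_n_h * unitv(Cpos[i - 1, ] - Opos[i - 1, ])
      nm <- c(nm, "H"); p <- rbind(p, h)
    }
    if (seq1[i] != "G") {
      u1 <- unitv(Npos[i, ] - CApos[i, ])
      u2 <- unitv(Cpos[i, ] - CApos[i, ])
      cb <- CApos[i, ] + g$b_ca_cb * bisector_out_of_plane(u1, u2, g$a_n_ca_cb)
      nm <- c(nm, "CB"); p <- rbind(p, cb)
    }
    name <- c(name, nm)
    resid <- c(resid, rep(i, length(nm)))
    pos <- rbind(pos, p)
  }
  list(name = name, resid = resid, pos = pos)
}

# incremental random-coil build with clash rejection
random_coil_coords <- function(seq1, config) {
  n <- length(seq1)
  dmin <- config$min_insertion_distance
  total_draws <- 0L
  pp <- matrix(0, n, 2)
  i <- 1L
  local_draws <- 0L
  while (i <= n) {
    total_draws <- total_draws + 1L
    if (total_draws > 1e4) {
      stop("random-coil clash rejection failed after 10000 draws")
    }
    pp[i, ] <- stats::runif(2, -180, 180)
    res <- chain_coords(seq1[seq_len(i)], pp[seq_len(i), , drop = FALSE])
    heavy <- res$name != "H"
    new_atoms <- which(res$resid == i & heavy)
    old_atoms <- which(res$resid <= i - 2L & heavy)
    ok <- TRUE
    if (length(old_atoms)) {
      d <- as.matrix(stats::dist(res$pos[c(new_atoms, old_atoms), ]))
      nn <- length(new_atoms)
      dd <- d[seq_len(nn), -seq_len(nn), drop = FALSE]
      ok <- all(dd >= dmin)
    }
    if (ok) {
      i <- i + 1L
      local_draws <- 0L
    } else {
      local_draws <- local_draws + 1L
      if (local_draws >= 50L && i > 1L) {
        # dead end: the previous residue boxed this one in; back up
        i <- i - 1L
        local_draws <- 0L
      }
    }
  }
  chain_coords(seq1, pp)
}

# ---- solvent templates -----------------------------------------------------

# 3-site rigid water, nm; O at origin
.WATER_TEMPLATE <- local({
  b <- 0.09572; a <- 104.52 * pi / 180
  pos <- rbind(c(0, 0, 0),
               c(b, 0, 0),
               c(b * cos(a), b * sin(a), 0))
  list(name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
       resname = "SOL", pos = pos)
})

# all-atom 9-site ethanol with standard bond geometry, nm
.ETHANOL_TEMPLATE <- local({
  c2 <- c(0, 0, 0)                       # methylene carbon
  c1 <- c(0.1529, 0, 0)                  # methyl carbon
  o <- place_atom(c(0, 0.1, 0), c1, c2, 0.1425, 109.5, 60)
  h21 <- place_atom(o, c1, c2, 0.1090, 109.5, 120)
  h22 <- place_atom(o, c1, c2, 0.1090, 109.5, -120)
  h11 <- place_atom(o, c2, c1, 0.1090, 110.0, 60)
  h12 <- place_atom(o, c2, c1, 0.1090, 110.0, 180)
  h13 <- place_atom(o, c2, c1, 0.1090, 110.0, -60)
  ho <- place_atom(c1, c2, o, 0.0945, 108.5, 180)
  list(name = c("C1", "H11", "H12", "H13", "C2", "H21", "H22", "OH", "HO"),
       element = c("C", "H", "H", "H", "C", "H", "H", "O", "H"),
       resname = "ETH",
       pos = rbind(c1, h11, h12, h13, c2, h21, h22, o, ho))
})

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Pack a solvent box at a given composition
#'
#' Inserts rigid 3-site waters, 9-site all-atom ethanols and Na+/Cl- ions at
#' random positions and orientations into a cubic box (optionally around a
#' solute), rejecting any insertion that places an atom closer than
#' `min_insertion_distance` to an already placed molecule under the
#' minimum-image convention. Achieved counts are exact or the function errors.
#'
#' @param composition one row of [table1_compositions()] (usually passed
#'   through [scale_composition()] for test-sized systems).
#' @param solute optional list with `topology` and `frame` (e.g. from
#'   [build_chain()]) to embed at the box centre.
#' @param config a [generator_config()].
#' @param max_attempts insertion attempts allowed per molecule (default 2000).
#' @return list with `topology` and `frame`.
#' @export
solvate_box <- function(composition, solute = NULL,
                        config = generator_config(), max_attempts = 2000L) {
  L <- composition$box_length
  box <- sim_box(L)
  dmin <- config$min_insertion_distance
  n_wat <- composition$n_water
  n_eth <- composition$n_ethanol
  n_ion <- composition$n_nacl_pairs
  # packing bound: hard spheres of diameter dmin at most ~64% of the volume
  n_atoms_req <- 3 * n_wat + 9 * n_eth + 2 * n_ion
  if (n_atoms_req * (4 / 3) * pi * (dmin / 2)^3 > 0.64 * box_volume(box)) {
    stop("requested counts cannot fit in the box at min_insertion_distance")
  }

  name <- character(0); element <- character(0); resname <- character(0)
  resid <- integer(0); pos <- NULL; next_resid <- 0L
  if (!is.null(solute)) {
    at <- solute$topology$atoms
    res <- solute$topology$residues
    name <- at$name; element <- at$element
    resname <- res$resname[at$residue_index]
    resid <- at$residue_index
    # centre the solute in the box
    p <- solute$frame$positions
    p <- sweep(p, 2, colMeans(p))
    p <- sweep(p, 2, rep(L / 2, 3), "+")
    pos <- p
    next_resid <- max(resid)
  }

  with_seed(config$seed, {
    insert_species <- function(template, count) {
      for (k in seq_len(count)) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          rot <- random_rotation()
          shift <- stats::runif(3, 0, L)
          cand <- template$pos %*% t(rot)
          cand <- sweep(cand, 2, shift, "+")
          if (is.null(pos) || min_sep_ok(cand, pos, box, dmin)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("solvent insertion failed for ", template$resname,
               " molecule ", k, " of ", count,
               " (achieved counts: ", next_resid, " residues placed)")
        }
        next_resid <<- next_resid + 1L
        name <<- c(name, template$name)
        element <<- c(element, template$element)
        resname <<- c(resname, rep(template$resname, length(template$name)))
        resid <<- c(resid, rep(next_resid, length(template$name)))
        pos <<- rbind(pos, cand)
      }
    }
    # larger molecules first: packing ethanol into pre-placed water jams at
    # much lower densities than the reverse order
    insert_species(.ETHANOL_TEMPLATE, n_eth)
    insert_species(.WATER_TEMPLATE, n_wat)
    if (n_ion > 0) {
      na_t <- list(name = "NA", element = "NA", resname = "NA",
                   pos = matrix(0, 1, 3))
      cl_t <- list(name = "CL", element = "CL", resname = "CL",
                   pos = matrix(0, 1, 3))
      insert_species(na_t, n_ion)
      insert_species(cl_t, n_ion)
    }
  })
  top <- build_topology(name, resname, resid, element = element)
  list(topology = top, frame = md_frame(wrap_positions(pos, box), box))
}

# TRUE if every candidate atom is at least dmin from every existing atom
min_sep_ok <- function(cand, existing, box, dmin) {
  L <- unclass(box)
  for (i in seq_len(nrow(cand))) {
    d <- existing - matrix(cand[i, ], nrow(existing), 3, byrow = TRUE)
    Lm <- rep(L, each = nrow(d))
    d <- d - Lm * round(d / Lm)
    if (min(rowSums(d * d)) < dmin^2) return(FALSE)
  }
  TRUE
}

#' Jittered pseudo-trajectory around a base configuration
#'
#' Each frame adds i.i.d. Gaussian displacements (sigma = `jitter_sigma`) to
#' the base positions and re-wraps solvent into the box; frame times are 0,
#' 1, ..., `n_frames - 1` ns. With `jitter_sigma = 0` all frames equal the
#' base. Deterministic under a fixed seed.
#'
#' @param base list with `topology` and `frame`.
#' @param n_frames number of frames.
#' @param config a [generator_config()] (uses `seed` and `jitter_sigma`).
#' @param equilibration_cut passed to [trajectory()] (ns, default 0).
#' @return a [trajectory()].
#' @export
perturb_trajectory <- function(base, n_frames, config = generator_config(),
                               equilibration_cut = 0) {
  sigma <- config$jitter_sigma
  top <- base$topology
  p0 <- base$frame$positions
  box <- base$frame$box
  frames <- with_seed(config$seed, {
    lapply(seq_len(n_frames), function(i) {
      p <- p0
      if (sigma > 0) {
        p <- p + matrix(stats::rnorm(length(p0), sd = sigma), nrow(p0), 3)
      }
      md_frame(p, box, time = i - 1)
    })
  })
  trajectory(top, frames, equilibration_cut = equilibration_cut)
}

#' Synthetic antiparallel beta-sheet dimer
#'
#' Places two extended strands at hydrogen-bonding register: strand A is
#' built at beta-strand dihedrals (-139, 135) and strand B is a point
#' reflection of A (which reverses the chain direction, giving antiparallel
#' pairing) shifted by `offset` from the reflected centre. The default offset
#' yields a well-formed ladder whose interior residues are assigned `E`.
#' Strand B is a mirror-image chain: a geometric fixture, not a physical
#' peptide.
#'
#' @param sequence one-letter sequence of each strand (default six alanines).
#' @param offset 3-vector displacement (nm) of the reflected strand.
#' @param box a [sim_box()] (default 8 nm cube).
#' @return list with `topology` (two protein molecules) and `frame`.
#' @export
build_sheet_dimer <- function(sequence = "AAAAAA",
                              offset = c(-0.25, -0.2, 0),
                              box = sim_box(8)) {
  cfg <- generator_config(helix_dihedrals = c(-139, 135))
  s <- build_chain(sequence, "ideal_helix", cfg)
  pos <- s$frame$positions
  at <- s$topology$atoms
  nres <- nchar(sequence)
  t <- 2 * colMeans(pos) + offset
  pb <- sweep(-pos, 2, t, "+")
  allpos <- rbind(pos, pb)
  allpos <- sweep(allpos, 2, apply(allpos, 2, min) - 1)
  name <- c(at$name, at$name)
  resid <- c(at$residue_index, at$residue_index + nres)
  resname <- s$topology$residues$resname
  brk <- c(rep(FALSE, nres), TRUE, rep(FALSE, nres - 1L))
  top <- build_topology(name, c(resname, resname)[resid], resid,
                        molecule_break = brk)
  list(topology = top, frame = md_frame(allpos, box))
}

#' Synthetic whole-protein CD fraction table from block tables
#'
#' Builds the whole-protein secondary-structure fraction table of a
#' multi-block fusion construct as the residue-length-weighted average of the
#' per-block tables, optionally corrupted by truncated Gaussian noise and
#' renormalized. Serves as the round-trip fixture for
#' [subtract_block_contribution()].
#'
#' @param block_fractions named list of per-block fraction vectors (each a
#'   named numeric vector summing to 1 over the same structure keys).
#' @param block_lengths named integer vector of residue counts per block.
#' @param noise_sigma standard deviation of the additive noise (fraction
#'   units); default 0.
#' @param seed RNG seed.
#' @return list with `whole` (named fraction vector) and `blocks` (the input
#'   list).
#' @export
synthetic_cd_table <- function(block_fractions, block_lengths,
                               noise_sigma = 0, seed = 1L) {
  if (any(block_lengths <= 0)) stop("block lengths must be positive")
  stopifnot(length(block_fractions) == length(block_lengths))
  keys <- names(block_fractions[[1]])
  for (b in block_fractions) {
    if (!identical(sort(names(b)), sort(keys))) {
      stop("all block tables must share the same structure keys")
    }
    if (abs(sum(b) - 1) > 1e-6) stop("each block's fractions must sum to 1")
  }
  w <- block_lengths / sum(block_lengths)
  whole <- Reduce(`+`, Map(function(f, wi) wi * f[keys], block_fractions, w))
  if (noise_sigma > 0) {
    whole <- with_seed(seed, {
      noisy <- whole + stats::rnorm(length(whole), sd = noise_sigma)
      pmax(noisy, 0)
    })
    whole <- whole / sum(whole)
  }
  list(whole = whole, blocks = block_fractions)
}
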
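# Per-residue solvation-shell analysis, bulk densities, region-region RDFs
# and the protein mass concentration.

#' Solvation-shell specification
#'
#' @param cutoff any-atom shell cutoff distance, nm (default 0.25).
#' @param samples Monte-Carlo samples for the shell-volume estimator
#'   (default 20000, minimum 1000).
#' @return list of class `shell_spec`.
#' @export
shell_spec <- function(cutoff = 0.25, samples = 20000L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (samples < 1000L) stop("at least 1000 volume samples are required")
  structure(list(cutoff = cutoff, samples = as.integer(samples)),
            class = "shell_spec")
}

#' Members of a residue's solvation shell
#'
#' A solvent molecule (or another protein residue) belongs to the shell of a
#' residue when any of its atoms lies within the cutoff of any atom of the
#' residue, under the minimum-image convention. For `species = "PROTEIN"`,
#' residues i-1, i and i+1 are excluded so trivially bonded contacts do not
#' count.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param residue_index the protein residue whose shell to take.
#' @param shell a [shell_spec()].
#' @param species `"WATER"`, `"ETHANOL"` or `"PROTEIN"`.
#' @return integer vector: molecule ids (solvent) or residue indices
#'   (protein).
#' @export
shell_members <- function(frame, topology, residue_index,
                          shell = shell_spec(), species = "WATER") {
  species <- match.arg(toupper(species), c("WATER", "ETHANOL", "PROTEIN"))
  at <- topology$atoms
  ratoms <- residue_atoms(topology, residue_index)
  if (species == "PROTEIN") {
    cand_res <- setdiff(protein_residues(topology),
                        (residue_index - 1L):(residue_index + 1L))
    cand_atoms <- which(at$residue_index %in% cand_res)
    label <- at$residue_index
  } else {
    mols <- species_molecules(topology, species)
    cand_atoms <- which(at$molecule_id %in% mols)
    label <- at$molecule_id
  }
  if (length(cand_atoms) == 0L) return(integer())
  hits <- atoms_within(frame$positions, ratoms, cand_atoms, frame$box,
                       shell$cutoff)
  sort(unique(label[hits]))
}

# candidate atoms within cutoff of any reference atom (vectorised per
# reference atom; candidates are typically the bigger set)
atoms_within <- function(pos, ref_atoms, cand_atoms, box, cutoff) {
  L <- unclass(box)
  cand_pos <- pos[cand_atoms, , drop = FALSE]
  hit <- rep(FALSE, length(cand_atoms))
  for (a in ref_atoms) {
    d <- cand_pos - matrix(pos[a, ], length(cand_atoms), 3, byrow = TRUE)
    Lm <- rep(L, each = nrow(d))
    d <- d - Lm * round(d / Lm)
    hit <- hit | rowSums(d * d) <= cutoff^2
  }
  cand_atoms[hit]
}

#' Monte-Carlo shell volume of a residue
#'
#' Estimates the volume of the union of spheres of radius `cutoff` centred on
#' the residue's atoms, excluding the parts claimed by the shells of other
#' protein residues (points within the cutoff of another residue's atoms).
#' Sampling is uniform over the residue's bounding box padded by the cutoff.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param residue_index residue whose shell volume to estimate.
#' @param shell a [shell_spec()].
#' @param seed RNG seed for the sampler.
#' @param exclude_other logical: subtract overlap with other protein
#'   residues' shells (default `TRUE`).
#' @return numeric volume in nm^3 with attribute `se` (standard error).
#' @export
shell_volume <- function(frame, topology, residue_index,
                         shell = shell_spec(), seed = 1L,
                         exclude_other = TRUE) {
  pos <- frame$positions
  ratoms <- residue_atoms(topology, residue_index)
  rpos <- pos[ratoms, , drop = FALSE]
  cutoff <- shell$cutoff
  lo <- apply(rpos, 2, min) - cutoff
  hi <- apply(rpos, 2, max) + cutoff
  vol_bbox <- prod(hi - lo)
  other <- NULL
  if (exclude_other) {
    at <- topology$atoms
    other_res <- setdiff(protein_residues(topology), residue_index)
    oat <- which(at$residue_index %in% other_res & !at$is_hydrogen)
    if (length(oat)) other <- pos[oat, , drop = FALSE]
  }
  n <- shell$samples
  hits <- with_seed(seed, {
    p <- cbind(stats::runif(n, lo[1], hi[1]),
               stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
    inside <- point_within(p, rpos, frame$box, cutoff)
    if (!is.null(other)) {
      inside & !point_within(p, other, frame$box, cutoff)
    } else inside
  })
  p_hat <- mean(hits)
  v <- vol_bbox * p_hat
  attr(v, "se") <- vol_bbox * sqrt(p_hat * (1 - p_hat) / n)
  v
}

# for each sample point, TRUE if within cutoff of any centre (minimum image)
point_within <- function(points, centres, box, cutoff) {
  L <- unclass(box)
  hit <- rep(FALSE, nrow(points))
  for (k in seq_len(nrow(centres))) {
    d <- points - matrix(centres[k, ], nrow(points), 3, byrow = TRUE)
    Lm <- rep(L, each = nrow(d))
    d <- d - Lm * round(d / Lm)
    hit <- hit | rowSums(d * d) <= cutoff^2
  }
  hit
}

#' Per-residue local solvent density along the chain
#'
#' rho(i) = mean shell occupancy / mean shell volume over post-equilibration
#' frames, for each protein residue, with a centred moving average along the
#' chain (window truncated at the termini).
#'
#' @param traj a [trajectory()].
#' @param shell a [shell_spec()].
#' @param species character vector of profiles to compute (default water,
#'   ethanol, protein).
#' @param window moving-average window in residues (default 5).
#' @param seed seed for the volume estimator.
#' @return data.frame of class `density_profile` with columns
#'   `residue_index`, `aa`, then per species `rho_<species>` and
#'   `rho_<species>_smooth` (nm^-3).
#' @export
local_density_profile <- function(traj, shell = shell_spec(),
                                  species = c("WATER", "ETHANOL", "PROTEIN"),
                                  window = 5L, seed = 1L) {
  top <- traj$topology
  frames <- production_frames(traj)
  res_idx <- protein_residues(top)
  resname <- top$residues$resname[match(res_idx, top$residues$residue_index)]
  out <- data.frame(residue_index = res_idx, aa = aa_one(resname))
  vols <- matrix(0, length(frames), length(res_idx))
  for (fi in seq_along(frames)) {
    for (ri in seq_along(res_idx)) {
      vols[fi, ri] <- shell_volume(frames[[fi]], top, res_idx[ri], shell,
                                   seed = seed + fi)
    }
  }
  mean_vol <- colMeans(vols)
  if (any(mean_vol <= 0)) {
    stop("zero shell volume for residue(s) ",
         paste(res_idx[mean_vol <= 0], collapse = ", "))
  }
  for (sp in toupper(species)) {
    counts <- matrix(0, length(frames), length(res_idx))
    for (fi in seq_along(frames)) {
      for (ri in seq_along(res_idx)) {
        counts[fi, ri] <- length(shell_members(frames[[fi]], top,
                                               res_idx[ri], shell, sp))
      }
    }
    rho <- colMeans(counts) / mean_vol
    col <- paste0("rho_", tolower(sp))
    out[[col]] <- rho
    out[[paste0(col, "_smooth")]] <- moving_average(rho, window)
  }
  structure(out, class = c("density_profile", "data.frame"))
}

#' Bulk number density
#'
#' Number of molecules divided by the box volume.
#'
#' @param n_molecules molecule count.
#' @param box a [sim_box()].
#' @return density in nm^-3.
#' @examples
#' bulk_density(1301, sim_box(8.8))  # water in the 94% ethanol system
#' @export
bulk_density <- function(n_molecules, box) {
  if (n_molecules < 0) stop("n_molecules must be >= 0")
  v <- box_volume(box)
  if (v <= 0) stop("box volume must be positive")
  n_molecules / v
}

#' Radial distribution function between two selections
#'
#' Pair-distance histogram between two disjoint atom groups, normalized by
#' the ideal-gas expectation at the groups' box-average pair density.
#' Supports atom-atom or centre-of-mass mode.
#'
#' @param traj a [trajectory()].
#' @param groupA,groupB disjoint selections: integer atom-index vectors
#'   (`mode = "atom"`) or lists of atom-index vectors, one per site
#'   (`mode = "com"`).
#' @param breaks bin edges in nm (strictly increasing; the last edge must not
#'   exceed half the smallest box length).
#' @param mode `"atom"` or `"com"`.
#' @param production_only use only post-equilibration frames (default TRUE).
#' @return data.frame with columns `r` (bin centre), `g`, `count`.
#' @export
region_rdf <- function(traj, groupA, groupB, breaks = seq(0, 1.2, by = 0.02),
                       mode = c("atom", "com"), production_only = TRUE) {
  mode <- match.arg(mode)
  top <- traj$topology
  frames <- if (production_only) production_frames(traj) else traj$frames
  box <- frames[[1]]$box
  if (max(breaks) > min(unclass(box)) / 2 + 1e-9) {
    stop("largest break (", max(breaks), " nm) exceeds half the smallest ",
         "box length")
  }
  if (mode == "atom") {
    if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
    nA <- length(groupA); nB <- length(groupB)
  } else {
    if (length(intersect(unlist(groupA), unlist(groupB)))) {
      stop("groups must be disjoint")
    }
    nA <- length(groupA); nB <- length(groupB)
  }
  masses <- top$atoms$mass
  site_pos <- function(frame, group) {
    if (mode == "atom") {
      frame$positions[group, , drop = FALSE]
    } else {
      t(vapply(group, function(idx) {
        m <- masses[idx]
        colSums(frame$positions[idx, , drop = FALSE] * m) / sum(m)
      }, numeric(3)))
    }
  }
  counts <- numeric(length(breaks) - 1L)
  for (f in frames) {
    pa <- site_pos(f, groupA)
    pb <- site_pos(f, groupB)
    d <- cross_distances(pa, pb, f$box)
    d <- d[d >= breaks[1] & d <= max(breaks)]
    idx <- pmin(findInterval(d, breaks), length(breaks) - 1L)
    idx <- pmax(idx, 1L)
    counts <- counts + tabulate(idx, nbins = length(breaks) - 1L)
  }
  v <- box_volume(box)
  shell_vols <- (4 / 3) * pi * diff(breaks^3)
  expected <- length(frames) * nA * nB / v * shell_vols
  r_mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(r = r_mid, g = ifelse(expected > 0, counts / expected, NA_real_),
             count = counts)
}

# all minimum-image distances between two position sets
cross_distances <- function(pa, pb, box) {
  L <- unclass(box)
  out <- numeric(nrow(pa) * nrow(pb))
  k <- 0L
  for (i in seq_len(nrow(pa))) {
    d <- pb - matrix(pa[i, ], nrow(pb), 3, byrow = TRUE)
    Lm <- rep(L, each = nrow(d))
    d <- d - Lm * round(d / Lm)
    out[k + seq_len(nrow(pb))] <- sqrt(rowSums(d * d))
    k <- k + nrow(pb)
  }
  out
}

#' Protein mass concentration of one chain in a box
#'
#' Molecular mass of the chain (standard residue masses plus one water for
#' the termini) divided by Avogadro's number and the box volume, in g/L.
#'
#' @param sequence one-letter amino-acid string (default the reconstructed
#'   AQ3 sequence [AQ3_SEQUENCE]).
#' @param box a [sim_box()].
#' @return concentration in g/L, with attribute `molecular_mass` (Da).
#' @examples
#' protein_mass_concentration(AQ3_SEQUENCE, sim_box(9.1))  # ~26 g/L
#' @export
protein_mass_concentration <- function(sequence = AQ3_SEQUENCE, box) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) == 0L) stop("empty sequence")
  unknown <- setdiff(seq1, names(.RESIDUE_MASS))
  if (length(unknown)) stop("unknown residue letter(s): ",
                            paste(unknown, collapse = ", "))
  m <- sum(.RESIDUE_MASS[seq1]) + 18.0153
  v_litre <- box_volume(box) * 1e-24
  conc <- m / (AVOGADRO * v_litre)
  attr(conc, "molecular_mass") <- m
  conc
}
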
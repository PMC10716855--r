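# Geometric hydrogen-bond detection and intra/inter classification.
#
# A donor is any N or O with a covalently attached hydrogen (attachment is
# resolved geometrically: a hydrogen belongs to the nearest N/O within 0.12 nm
# inside its own residue, so carbon-bound hydrogens are never donors); every
# N or O is a potential acceptor. A bond is recorded when the donor-acceptor
# distance and the H-D-A angle are both within the criteria, distances under
# the minimum-image convention. Pairs within the same residue are excluded.

#' Hydrogen-bond criteria
#'
#' @param max_distance donor-acceptor distance cutoff, nm (default 0.35).
#' @param max_angle hydrogen-donor-acceptor angle cutoff, degrees (default
#'   30; donor-centred convention).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 0.35, max_angle = 30) {
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (max_angle <= 0 || max_angle >= 90) stop("max_angle must be in (0, 90)")
  structure(list(max_distance = max_distance, max_angle = max_angle),
            class = "hbond_criteria")
}

# donor table: for each polar hydrogen, the heavy atom it rides on.
# Returns data.frame(h = hydrogen atom index, d = donor heavy atom index).
polar_hydrogens <- function(frame, topology) {
  at <- topology$atoms
  if (any(!nzchar(at$element))) stop("atoms lack element typing")
  hs <- which(at$is_hydrogen)
  out_h <- integer(0); out_d <- integer(0)
  if (length(hs) == 0L) {
    return(data.frame(h = out_h, d = out_d))
  }
  pos <- frame$positions
  for (h in hs) {
    sel <- residue_atoms(topology, at$residue_index[h])
    heavies <- sel[!at$is_hydrogen[sel]]
    if (length(heavies) == 0L) next
    d2 <- rowSums((pos[heavies, , drop = FALSE] -
                     matrix(pos[h, ], length(heavies), 3,
                            byrow = TRUE))^2)
    nearest <- heavies[which.min(d2)]
    if (sqrt(min(d2)) < 0.12 && at$element[nearest] %in% c("N", "O")) {
      out_h <- c(out_h, h); out_d <- c(out_d, nearest)
    }
  }
  data.frame(h = out_h, d = out_d)
}

#' Detect hydrogen bonds in a frame
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param criteria an [hbond_criteria()].
#' @return data.frame of class `hbond_records` with columns `donor`,
#'   `hydrogen`, `acceptor` (atom indices), `donor_residue`,
#'   `acceptor_residue`, `class` (one of `INTRA_PROTEIN`, `PROTEIN_SOLVENT`,
#'   `SOLVENT_SOLVENT`).
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria()) {
  at <- topology$atoms
  pos <- frame$positions
  box <- frame$box
  dh <- polar_hydrogens(frame, topology)
  acceptors <- which(at$element %in% c("N", "O"))
  donors <- unique(dh$d)
  if (length(donors) == 0L || length(acceptors) == 0L) {
    return(empty_hbond_records())
  }
  # neighbour search over the union of donor and acceptor heavy atoms
  cand <- sort(unique(c(donors, acceptors)))
  pairs <- neighbor_pairs(pos[cand, , drop = FALSE], box,
                          criteria$max_distance)
  if (nrow(pairs) == 0L) return(empty_hbond_records())
  gi <- cand[pairs$i]; gj <- cand[pairs$j]
  # orient as donor -> acceptor, keeping both directions where applicable
  da <- rbind(
    data.frame(d = gi, a = gj),
    data.frame(d = gj, a = gi)
  )
  da <- da[da$d %in% donors & da$a %in% acceptors, , drop = FALSE]
  da <- da[at$residue_index[da$d] != at$residue_index[da$a], , drop = FALSE]
  if (nrow(da) == 0L) return(empty_hbond_records())

  # expand donors to their hydrogens and apply the angle criterion
  recs <- merge(da, dh, by.x = "d", by.y = "d")
  v_dh <- min_image_disp(pos[recs$d, , drop = FALSE],
                         pos[recs$h, , drop = FALSE], box)
  v_da <- min_image_disp(pos[recs$d, , drop = FALSE],
                         pos[recs$a, , drop = FALSE], box)
  cosang <- rowSums(v_dh * v_da) /
    (sqrt(rowSums(v_dh^2)) * sqrt(rowSums(v_da^2)))
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  recs <- recs[ang <= criteria$max_angle, , drop = FALSE]
  if (nrow(recs) == 0L) return(empty_hbond_records())

  species <- topology$molecules$species[
    match(at$molecule_id, topology$molecules$molecule_id)]
  cls <- classify_pair(species[recs$d], species[recs$a])
  out <- data.frame(donor = recs$d, hydrogen = recs$h, acceptor = recs$a,
                    donor_residue = at$residue_index[recs$d],
                    acceptor_residue = at$residue_index[recs$a],
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_records", "data.frame"))
}

empty_hbond_records <- function() {
  structure(data.frame(donor = integer(), hydrogen = integer(),
                       acceptor = integer(), donor_residue = integer(),
                       acceptor_residue = integer(), class = character(),
                       stringsAsFactors = FALSE),
            class = c("hbond_records", "data.frame"))
}

classify_pair <- function(sp_d, sp_a) {
  d_prot <- sp_d == "PROTEIN"
  a_prot <- sp_a == "PROTEIN"
  ifelse(d_prot & a_prot, "INTRA_PROTEIN",
         ifelse(d_prot | a_prot, "PROTEIN_SOLVENT", "SOLVENT_SOLVENT"))
}

#' Count hydrogen bonds per class
#'
#' @param records an `hbond_records` data.frame from [detect_hbonds()].
#' @return named integer vector over the three classes; entries sum to the
#'   total number of records.
#' @export
classify_and_count <- function(records) {
  classes <- c("INTRA_PROTEIN", "PROTEIN_SOLVENT", "SOLVENT_SOLVENT")
  out <- integer(length(classes)); names(out) <- classes
  tab <- table(records$class)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Mean hydrogen bonds per residue by amino-acid type
#'
#' For each amino-acid type, the mean number of hydrogen bonds (in the chosen
#' classes) touching one residue of that type, averaged over
#' post-equilibration frames. A bond between two protein residues credits
#' both residues.
#'
#' @param traj a [trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param classes subset of the bond classes to count (default intramolecular
#'   protein bonds).
#' @return data.frame with columns `aa`, `mean` (bonds per residue per
#'   frame), `n_residues`.
#' @export
per_aatype_hbond_means <- function(traj, criteria = hbond_criteria(),
                                   classes = "INTRA_PROTEIN") {
  top <- traj$topology
  frames <- production_frames(traj)
  res_idx <- protein_residues(top)
  resname <- top$residues$resname[match(res_idx, top$residues$residue_index)]
  aa <- aa_one(resname)
  touch <- numeric(length(res_idx))
  names(touch) <- as.character(res_idx)
  for (f in frames) {
    recs <- detect_hbonds(f, top, criteria)
    recs <- recs[recs$class %in% classes, , drop = FALSE]
    for (col in c("donor_residue", "acceptor_residue")) {
      r <- recs[[col]][recs[[col]] %in% res_idx]
      if (length(r)) {
        tab <- table(r)
        touch[names(tab)] <- touch[names(tab)] + as.integer(tab)
      }
    }
  }
  per_res <- touch / length(frames)
  agg <- tapply(per_res, aa, mean)
  data.frame(aa = names(agg), mean = as.numeric(agg),
             n_residues = as.integer(table(aa)[names(agg)]),
             row.names = NULL)
}

#' Time series of intra- and intermolecular hydrogen-bond counts
#'
#' Per-frame counts of intramolecular protein bonds and protein-solvent
#' bonds over the whole trajectory (equilibration diagnostics use all
#' frames), smoothed with a centred moving average.
#'
#' @param traj a [trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param window moving-average window in frames (default 1 = raw counts).
#' @return data.frame with columns `time`, `intra`, `protein_solvent`,
#'   `intra_smooth`, `protein_solvent_smooth`.
#' @export
hbond_timeseries <- function(traj, criteria = hbond_criteria(), window = 1L) {
  counts <- t(vapply(traj$frames, function(f) {
    classify_and_count(detect_hbonds(f, traj$topology, criteria))
  }, integer(3)))
  data.frame(
    time = frame_times(traj),
    intra = counts[, "INTRA_PROTEIN"],
    protein_solvent = counts[, "PROTEIN_SOLVENT"],
    intra_smooth = moving_average(counts[, "INTRA_PROTEIN"], window),
    protein_solvent_smooth = moving_average(counts[, "PROTEIN_SOLVENT"],
                                            window)
  )
}
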
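# Core data model: topology (atoms / residues / molecules / species), single
# frames, and time-ordered trajectories. These are deliberately plain S3
# containers over data.frames so every analysis module can use vectorised
# base-R operations on them.

#' Molecular topology
#'
#' Static description of a simulated system: the atom table, the residue and
#' molecule spans over it, and the protein one-letter sequence.
#'
#' @param atoms data.frame with columns `atom_index`, `name`, `element`,
#'   `mass`, `residue_index`, `molecule_id`, `is_hydrogen`.
#' @param residues data.frame with columns `residue_index`, `resname`,
#'   `first`, `last` (atom spans; spans partition the atom table).
#' @param molecules data.frame with columns `molecule_id`, `species` (one of
#'   `"PROTEIN"`, `"WATER"`, `"ETHANOL"`, `"ION"`), `first`, `last`.
#' @param sequence one-letter string for the protein chain ("" if none).
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, residues, molecules, sequence = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(residues),
            is.data.frame(molecules))
  need <- c("atom_index", "name", "element", "mass", "residue_index",
            "molecule_id", "is_hydrogen")
  if (!all(need %in% names(atoms))) {
    stop("atoms table lacks columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  }
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0")
  if (!all(atoms$is_hydrogen == (atoms$element == "H"))) {
    stop("is_hydrogen flag inconsistent with element column")
  }
  if (!all(residues$residue_index == seq_len(nrow(residues)))) {
    stop("residue indices must be contiguous from 1")
  }
  if (!all(molecules$species %in% .SPECIES_LEVELS)) {
    stop("unknown species: ",
         paste(setdiff(molecules$species, .SPECIES_LEVELS), collapse = ", "))
  }
  # spans must partition the atom table
  span_len <- sum(residues$last - residues$first + 1L)
  if (span_len != nrow(atoms)) stop("residue spans do not partition the atoms")
  if (sum(molecules$last - molecules$first + 1L) != nrow(atoms)) {
    stop("molecule spans do not partition the atoms")
  }
  structure(list(atoms = atoms, residues = residues, molecules = molecules,
                 sequence = sequence),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  tab <- table(x$molecules$species)
  cat(sprintf("topology: %d atoms, %d residues, %d molecules\n",
              nrow(x$atoms), nrow(x$residues), nrow(x$molecules)))
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (nzchar(x$sequence)) {
    cat(sprintf("  protein sequence (%d aa): %s%s\n", nchar(x$sequence),
                substr(x$sequence, 1, 40),
                if (nchar(x$sequence) > 40) "..." else ""))
  }
  invisible(x)
}

#' Single coordinate frame
#'
#' @param positions n-by-3 matrix of atom positions in nm (topology order).
#' @param box a [sim_box()].
#' @param time frame time in ns.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(positions, box, time = 0) {
  positions <- rbind3(positions)
  dimnames(positions) <- NULL
  storage.mode(positions) <- "double"
  stopifnot(inherits(box, "sim_box"))
  structure(list(time = as.numeric(time), positions = positions, box = box),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("frame at t = %g ns: %d atoms, box %.3g x %.3g x %.3g nm\n",
              x$time, nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Trajectory container
#'
#' @param topology a [topology()].
#' @param frames list of [md_frame()]s with strictly increasing times and
#'   position counts matching the topology.
#' @param equilibration_cut initial time span (ns) discarded by ensemble
#'   analyses; default 0.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, equilibration_cut = 0) {
  stopifnot(inherits(topology, "topology"), is.list(frames))
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  nat <- vapply(frames, function(f) nrow(f$positions), integer(1))
  bad <- which(nat != nrow(topology$atoms))
  if (length(bad)) {
    stop("frame ", bad[1L], " has ", nat[bad[1L]],
         " atoms; topology has ", nrow(topology$atoms))
  }
  if (equilibration_cut < 0) stop("equilibration_cut must be >= 0")
  structure(list(topology = topology, frames = frames,
                 equilibration_cut = as.numeric(equilibration_cut)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf("trajectory: %d frames, t = %g..%g ns (equilibration cut %g ns)\n",
              length(x$frames), min(times), max(times), x$equilibration_cut))
  print(x$topology)
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj a [trajectory()].
#' @return numeric vector of times in ns.
#' @export
frame_times <- function(traj) vapply(traj$frames, function(f) f$time, numeric(1))

#' Post-equilibration frames
#'
#' Frames with `time >= equilibration_cut`, the production span used by all
#' ensemble averages.
#'
#' @param traj a [trajectory()].
#' @return list of [md_frame()]s.
#' @export
production_frames <- function(traj) {
  keep <- frame_times(traj) >= traj$equilibration_cut
  if (!any(keep)) stop("no frames after the equilibration cut")
  traj$frames[keep]
}

# ---- selections ------------------------------------------------------------

#' Atom selections by species and element
#'
#' @param topology a [topology()].
#' @return integer vector of atom indices.
#' @export
protein_atoms <- function(topology) {
  mol <- topology$molecules
  prot <- mol[mol$species == "PROTEIN", , drop = FALSE]
  if (nrow(prot) == 0L) return(integer())
  unlist(mapply(seq.int, prot$first, prot$last, SIMPLIFY = FALSE))
}

#' @rdname protein_atoms
#' @export
protein_heavy_atoms <- function(topology) {
  sel <- protein_atoms(topology)
  sel[!topology$atoms$is_hydrogen[sel]]
}

#' Atom indices of a residue
#' @param topology a [topology()].
#' @param residue_index 1-based residue index.
#' @return integer vector of atom indices.
#' @export
residue_atoms <- function(topology, residue_index) {
  r <- topology$residues[topology$residues$residue_index == residue_index, ]
  if (nrow(r) == 0L) stop("no residue with index ", residue_index)
  seq.int(r$first, r$last)
}

#' Protein residue indices
#' @param topology a [topology()].
#' @return integer vector of residue indices belonging to protein molecules.
#' @export
protein_residues <- function(topology) {
  sel <- protein_atoms(topology)
  sort(unique(topology$atoms$residue_index[sel]))
}

#' Molecule ids of one species
#' @param topology a [topology()].
#' @param species `"WATER"`, `"ETHANOL"`, `"PROTEIN"` or `"ION"`.
#' @return integer vector of molecule ids.
#' @export
species_molecules <- function(topology, species) {
  species <- match.arg(toupper(species), .SPECIES_LEVELS)
  topology$molecules$molecule_id[topology$molecules$species == species]
}

#' Atom spans of molecules
#' @param topology a [topology()].
#' @param molecule_ids integer vector of molecule ids.
#' @return list of integer atom-index vectors, one per molecule.
#' @export
molecule_atoms <- function(topology, molecule_ids) {
  mol <- topology$molecules
  idx <- match(molecule_ids, mol$molecule_id)
  if (anyNA(idx)) stop("unknown molecule id(s)")
  mapply(seq.int, mol$first[idx], mol$last[idx], SIMPLIFY = FALSE)
}

#' Assemble a topology from per-atom vectors
#'
#' Convenience constructor used by the file readers and the synthetic
#' generators: residues are delimited by changes in the raw residue id or
#' name, species are assigned from residue names, and consecutive protein
#' residues are merged into chain molecules.
#'
#' @param name atom names (length n).
#' @param resname residue name per atom.
#' @param resid_raw raw residue id per atom (only changes matter).
#' @param element optional element symbols; guessed from atom names when
#'   absent.
#' @param species_map optional named overrides for residue-name to species
#'   assignment.
#' @param sequence optional protein one-letter sequence (derived from the
#'   residue names when omitted).
#' @param molecule_break optional logical per residue; `TRUE` forces the
#'   residue to start a new molecule (e.g. to split two chains that share a
#'   continuous numbering).
#' @return a [topology()].
#' @export
build_topology <- function(name, resname, resid_raw, element = NULL,
                           species_map = NULL, sequence = NULL,
                           molecule_break = NULL) {
  n <- length(name)
  if (is.null(element)) element <- guess_element(name, resname)
  mass <- atomic_mass(element)
  # consecutive-run residue identity: new residue whenever the raw id or name
  # changes between consecutive atoms
  newres <- c(TRUE, resid_raw[-1L] != resid_raw[-n] | resname[-1L] != resname[-n])
  residue_index <- cumsum(newres)
  nres <- residue_index[n]
  res_first <- which(newres)
  res_last <- c(res_first[-1L] - 1L, n)
  res_name <- resname[res_first]

  map <- .DEFAULT_SPECIES_MAP
  if (!is.null(species_map)) map[names(species_map)] <- toupper(species_map)
  sp_res <- unname(map[toupper(res_name)])
  sp_res[is.na(sp_res)] <- "PROTEIN"
  known <- toupper(res_name) %in% c(names(map), names(.AA_ONE))
  if (any(sp_res == "PROTEIN" & !known)) {
    stop("unknown residue name(s) with no species mapping: ",
         paste(unique(res_name[sp_res == "PROTEIN" & !known]), collapse = ", "))
  }

  # molecules: each non-protein residue is one molecule; consecutive protein
  # residues form one chain molecule
  newmol <- rep(TRUE, nres)
  if (nres > 1L) {
    both_prot <- sp_res[-1L] == "PROTEIN" & sp_res[-nres] == "PROTEIN"
    newmol[-1L] <- !both_prot
  }
  if (!is.null(molecule_break)) {
    stopifnot(length(molecule_break) == nres)
    newmol <- newmol | molecule_break
  }
  mol_of_res <- cumsum(newmol)
  nmol <- mol_of_res[nres]
  mol_first <- res_first[which(newmol)]
  mol_last <- c(mol_first[-1L] - 1L, n)
  mol_species <- sp_res[which(newmol)]

  atoms <- data.frame(
    atom_index = seq_len(n), name = name, element = element, mass = mass,
    residue_index = residue_index,
    molecule_id = mol_of_res[residue_index],
    is_hydrogen = element == "H",
    stringsAsFactors = FALSE
  )
  residues <- data.frame(residue_index = seq_len(nres), resname = res_name,
                         first = res_first, last = res_last,
                         stringsAsFactors = FALSE)
  molecules <- data.frame(molecule_id = seq_len(nmol), species = mol_species,
                          first = mol_first, last = mol_last,
                          stringsAsFactors = FALSE)
  if (is.null(sequence)) {
    prot_res <- residues[sp_res == "PROTEIN", , drop = FALSE]
    sequence <- if (nrow(prot_res)) {
      paste(aa_one(prot_res$resname), collapse = "")
    } else ""
  }
  topology(atoms, residues, molecules, sequence)
}

# element from atom name (PDB/GRO conventions), with residue context for ions
guess_element <- function(name, resname) {
  up <- toupper(trimws(name))
  res <- toupper(trimws(resname))
  el <- character(length(up))
  ion <- res %in% c("NA", "CL", "K", "MG") & up == res
  el[ion] <- c("NA" = "NA", "CL" = "CL", "K" = "K", "MG" = "MG")[res[ion]]
  rest <- !ion
  stripped <- sub("^[0-9']+", "", up[rest])
  el[rest] <- substr(stripped, 1L, 1L)
  if (any(el == "" | is.na(el))) stop("cannot infer element for atom name(s): ",
                                      paste(unique(name[el == "" | is.na(el)]),
                                            collapse = ", "))
  el
}
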
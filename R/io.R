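# Structure and trajectory file I/O. PDB coordinates are Angstrom on disk and
# converted to nm in memory; GRO files are already nm. Only orthorhombic boxes
# are supported (CRYST1 angles must be 90).

#' Read a structure file
#'
#' Parses a PDB or GRO file into a topology and a coordinate frame. Species
#' are assigned from residue names through a configurable mapping; by default
#' SOL/HOH/TIP3/TIP4/WAT map to WATER, ETH/EOH/ETO to ETHANOL, NA/CL/K/MG to
#' ION, and the twenty standard amino-acid names to PROTEIN. A residue name
#' outside both sets is an error.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @param species_map optional named character vector of extra residue-name to
#'   species assignments, e.g. `c(MOH = "ETHANOL")`.
#' @return list with elements `topology` and `frame`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           species_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (format == "pdb") read_pdb_structure(path, species_map)
  else read_gro_structure(path, species_map)
}

read_pdb_structure <- function(path, species_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  parsed <- parse_pdb_model(lines, offset = 0L, path = path)
  if (is.null(parsed$box)) {
    stop("PDB file ", path, " has no CRYST1 record (required for the periodic box)")
  }
  top <- build_topology(parsed$name, parsed$resname, parsed$resid,
                        species_map = species_map)
  list(topology = top,
       frame = md_frame(parsed$pos, parsed$box, time = 0))
}

# parse one model's worth of ATOM/HETATM records from `lines`
parse_pdb_model <- function(lines, offset = 0L, path = "<pdb>") {
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  al <- lines[is_atom]
  ln <- which(is_atom) + offset
  if (length(al) == 0L) stop("no ATOM/HETATM records in ", path)
  name <- trimws(substr(al, 13L, 16L))
  resname <- trimws(substr(al, 18L, 21L))
  resid <- suppressWarnings(as.integer(trimws(substr(al, 23L, 26L))))
  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  el <- trimws(substr(al, 77L, 78L))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad)) {
    stop("malformed ATOM record at line ", ln[bad[1L]], " of ", path)
  }
  cry <- grep("^CRYST1", lines, value = TRUE)
  box <- NULL
  if (length(cry)) {
    a <- as.numeric(substr(cry[1L], 7L, 15L))
    b <- as.numeric(substr(cry[1L], 16L, 24L))
    c_ <- as.numeric(substr(cry[1L], 25L, 33L))
    ang <- c(as.numeric(substr(cry[1L], 34L, 40L)),
             as.numeric(substr(cry[1L], 41L, 47L)),
             as.numeric(substr(cry[1L], 48L, 54L)))
    if (any(abs(ang - 90) > 1e-3)) {
      stop("only orthorhombic boxes are supported (CRYST1 angles must be 90)")
    }
    box <- sim_box(c(a, b, c_) / 10)
  }
  element <- ifelse(nzchar(el), toupper(el), NA_character_)
  if (anyNA(element)) {
    element[is.na(element)] <- guess_element(name[is.na(element)],
                                             resname[is.na(element)])
  }
  list(name = name, resname = resname, resid = resid,
       pos = cbind(x, y, z) / 10, element = element, box = box)
}

read_gro_structure <- function(path, species_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file ", path, " is truncated")
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms)) stop("malformed atom count at line 2 of ", path)
  if (length(lines) < natoms + 3L) {
    stop("GRO file ", path, " is truncated: expected ", natoms,
         " atom lines, found ", length(lines) - 3L)
  }
  al <- lines[3:(natoms + 2L)]
  resid <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
  resname <- trimws(substr(al, 6L, 10L))
  name <- trimws(substr(al, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("malformed GRO atom record at line ", bad[1L] + 2L,
                        " of ", path)
  bl <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3L]),
                                             "\\s+")[[1L]]))
  if (length(bl) < 3L || anyNA(bl[1:3])) {
    stop("malformed box line at line ", natoms + 3L, " of ", path)
  }
  if (length(bl) > 3L && any(abs(bl[-(1:3)]) > 1e-9)) {
    stop("only orthorhombic boxes are supported")
  }
  top <- build_topology(name, resname, resid, species_map = species_map)
  list(topology = top, frame = md_frame(cbind(x, y, z), sim_box(bl[1:3])))
}

#' Write a structure file
#'
#' @param topology a [topology()].
#' @param frame an [md_frame()].
#' @param path output file path.
#' @param format `"pdb"` or `"gro"`; default from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frame, path,
                            format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (format == "pdb") {
    writeLines(c(pdb_cryst1(frame$box),
                 pdb_atom_lines(topology, frame), "END"), path)
  } else {
    writeLines(gro_lines(topology, frame), path)
  }
  invisible(path)
}

pdb_cryst1 <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1L] * 10, box[2L] * 10, box[3L] * 10, 90, 90, 90)
}

pdb_atom_lines <- function(topology, frame) {
  at <- topology$atoms
  res <- topology$residues
  mol <- topology$molecules
  resname <- res$resname[at$residue_index]
  pos <- frame$positions * 10
  is_aa <- toupper(resname) %in% names(.AA_ONE)
  rec <- ifelse(is_aa, "ATOM  ", "HETATM")
  nm <- at$name
  # chain letter per protein molecule (A, B, ...); solvent/ions share 'z'
  prot_ids <- mol$molecule_id[mol$species == "PROTEIN"]
  chain_of_mol <- structure(rep("z", nrow(mol)), names = mol$molecule_id)
  chain_of_mol[as.character(prot_ids)] <-
    LETTERS[pmin(seq_along(prot_ids), 26L)]
  chain <- chain_of_mol[as.character(at$molecule_id)]
  # PDB name column convention: 1-char elements start in column 14
  nm4 <- ifelse(nchar(nm) < 4L & nchar(at$element) == 1L,
                sprintf(" %-3s", nm), sprintf("%-4s", substr(nm, 1L, 4L)))
  lines <- sprintf(
    "%s%5d %s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, at$atom_index %% 100000L, nm4,
    substr(resname, 1L, 4L), chain,
    at$residue_index %% 10000L, "",
    pos[, 1L], pos[, 2L], pos[, 3L], 1, 0,
    substr(at$element, 1L, 2L))
  # TER after each protein molecule so readers split the chains
  ter_after <- sort(unique(mol$last[mol$species == "PROTEIN"]))
  if (length(ter_after)) {
    bounds <- unique(c(0L, ter_after, nrow(at)))
    out <- character(0)
    for (k in seq_len(length(bounds) - 1L)) {
      seg <- (bounds[k] + 1L):bounds[k + 1L]
      out <- c(out, lines[seg],
               if (bounds[k + 1L] %in% ter_after) "TER")
    }
    out
  } else lines
}

gro_lines <- function(topology, frame) {
  at <- topology$atoms
  res <- topology$residues
  resname <- res$resname[at$residue_index]
  pos <- frame$positions
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  at$residue_index %% 100000L, substr(resname, 1L, 5L),
                  substr(at$name, 1L, 5L), at$atom_index %% 100000L,
                  pos[, 1L], pos[, 2L], pos[, 3L])
  c("generated by spidrosolv", sprintf("%5d", nrow(at)), body,
    sprintf("%10.5f%10.5f%10.5f", frame$box[1L], frame$box[2L], frame$box[3L]))
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame. Frame times are taken as 0, 1,
#' 2, ... ns for the frames kept after applying `stride`.
#'
#' @param path multi-model PDB file.
#' @param topology a [topology()] whose atom count every model must match.
#' @param stride keep every `stride`-th model (default 1).
#' @param equilibration_cut passed through to [trajectory()] (ns, default 0).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology, stride = 1L, equilibration_cut = 0) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {
    # single-model file: treat as one frame
    s <- read_structure(path, format = "pdb")
    return(trajectory(topology, list(s$frame),
                      equilibration_cut = equilibration_cut))
  }
  if (length(ends) < length(starts)) {
    stop("truncated trajectory: frame ", length(starts),
         " has MODEL but no ENDMDL in ", path)
  }
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) == 0L) {
    stop("trajectory ", path, " has no CRYST1 record (required for the periodic box)")
  }
  nat_top <- nrow(topology$atoms)
  keep <- seq(1L, length(starts), by = as.integer(stride))
  frames <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    parsed <- parse_pdb_model(c(cry[1L], block), offset = starts[i] - 1L,
                              path = path)
    if (nrow(parsed$pos) != nat_top) {
      stop("frame ", i, " has ", nrow(parsed$pos),
           " atoms; topology has ", nat_top)
    }
    frames[[k]] <- md_frame(parsed$pos, parsed$box, time = k - 1)
  }
  trajectory(topology, frames, equilibration_cut = equilibration_cut)
}

#' Write a multi-model PDB trajectory
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- character(0)
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    out <- c(out, sprintf("MODEL     %4d", i), pdb_cryst1(f$box),
             pdb_atom_lines(traj$topology, f), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a species mapping from a key=value file
#'
#' Plain-text overrides for residue-name to species assignment, one
#' `RESNAME = SPECIES` pair per line; `#` starts a comment.
#'
#' @param path file path.
#' @return named character vector usable as `species_map` in
#'   [read_structure()].
#' @export
read_species_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed species-map line: ", lines[bad[1L]])
  out <- toupper(vapply(kv, `[`, "", 2L))
  names(out) <- toupper(vapply(kv, `[`, "", 1L))
  if (!all(out %in% .SPECIES_LEVELS)) {
    stop("unknown species in map: ",
         paste(setdiff(out, .SPECIES_LEVELS), collapse = ", "))
  }
  out
}
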
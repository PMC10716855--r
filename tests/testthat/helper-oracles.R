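# Independent brute-force oracles used to cross-check the package's
# accelerated implementations. These deliberately share no code with the
# package internals: plain double loops and direct formula evaluation.

# O(n^2) minimum-image pair scan
oracle_pairs <- function(pos, box_lengths, cutoff) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pos[j, ] - pos[i, ]
      d <- d - box_lengths * round(d / box_lengths)
      dist <- sqrt(sum(d^2))
      if (dist <= cutoff) out <- rbind(out, c(i, j, dist))
    }
  }
  if (is.null(out)) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  data.frame(i = out[, 1], j = out[, 2], d = out[, 3])
}

# minimum distance over the 27 explicit periodic images
oracle_min_image <- function(a, b, box_lengths) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    img <- b + c(ix, iy, iz) * box_lengths
    best <- min(best, sqrt(sum((img - a)^2)))
  }
  best
}

# BFS connected components of molecules under an any-atom contact cutoff
# (adjacency built one atom at a time against all later atoms, vectorised
# over the partner axis only)
oracle_clusters <- function(pos, mol_of_atom, box_lengths, cutoff) {
  mols <- sort(unique(mol_of_atom))
  nm <- length(mols)
  adj <- matrix(FALSE, nm, nm)
  n <- nrow(pos)
  midx <- match(mol_of_atom, mols)
  for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    d <- pos[jj, , drop = FALSE] -
      matrix(pos[i, ], length(jj), 3, byrow = TRUE)
    d <- d - matrix(box_lengths, length(jj), 3, byrow = TRUE) *
      round(d / matrix(box_lengths, length(jj), 3, byrow = TRUE))
    hit <- jj[rowSums(d * d) <= cutoff^2]
    hit <- hit[midx[hit] != midx[i]]
    if (length(hit)) {
      adj[cbind(midx[i], midx[hit])] <- TRUE
      adj[cbind(midx[hit], midx[i])] <- TRUE
    }
  }
  comp <- rep(0L, nm)
  cur <- 0L
  for (s in seq_len(nm)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  unname(split(mols, comp))
}

# O(n^2) hydrogen-bond scan: donors are N/O with an attached H (nearest
# in-residue heavy atom within 0.12 nm), acceptors all N/O, same-residue
# pairs excluded
oracle_hbonds <- function(pos, element, residue, box_lengths,
                          max_dist = 0.35, max_angle = 30) {
  n <- nrow(pos)
  is_h <- element == "H"
  donors <- list()
  for (h in which(is_h)) {
    in_res <- which(residue == residue[h] & !is_h)
    if (!length(in_res)) next
    dd <- sqrt(rowSums((pos[in_res, , drop = FALSE] -
                          matrix(pos[h, ], length(in_res), 3, byrow = TRUE))^2))
    near <- in_res[which.min(dd)]
    if (min(dd) < 0.12 && element[near] %in% c("N", "O")) {
      donors[[length(donors) + 1L]] <- c(d = near, h = h)
    }
  }
  acceptors <- which(element %in% c("N", "O"))
  out <- NULL
  Lm <- matrix(box_lengths, length(acceptors), 3, byrow = TRUE)
  for (dh in donors) {
    keep <- residue[acceptors] != residue[dh["d"]]
    v_da <- pos[acceptors, , drop = FALSE] -
      matrix(pos[dh["d"], ], length(acceptors), 3, byrow = TRUE)
    v_da <- v_da - Lm * round(v_da / Lm)
    dist_da <- sqrt(rowSums(v_da^2))
    v_dh <- pos[dh["h"], ] - pos[dh["d"], ]
    v_dh <- v_dh - box_lengths * round(v_dh / box_lengths)
    cosang <- as.vector(v_da %*% v_dh) / (dist_da * sqrt(sum(v_dh^2)))
    ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
    hit <- keep & dist_da <= max_dist & ang <= max_angle
    for (a in acceptors[hit]) {
      out <- rbind(out, c(dh["d"], dh["h"], a))
    }
  }
  if (is.null(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  }
  out <- data.frame(donor = out[, 1], hydrogen = out[, 2], acceptor = out[, 3])
  out[order(out$donor, out$hydrogen, out$acceptor), ]
}

# reference DSSP through mdtraj; returns a character matrix (frames x
# residues) of codes with loops as 'C'
reference_dssp <- function(pdb_paths) {
  script <- system.file("python", "dssp_reference.py", package = "spidrosolv")
  out <- system2("python", c(shQuote(script), shQuote(pdb_paths)),
                 stdout = TRUE, stderr = FALSE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(path = vapply(parts, `[`, "", 1L),
             frame = as.integer(vapply(parts, `[`, "", 2L)),
             codes = vapply(parts, `[`, "", 3L))
}

# random mixed water/ethanol box fixture (shared by several suites)
random_mixture <- function(seed, n_water = 40, n_ethanol = 8,
                           box_length = 2.4) {
  comp <- data.frame(ethanol_vv_percent = NA, n_water = n_water,
                     n_ethanol = n_ethanol, n_nacl_pairs = 0L,
                     box_length = box_length)
  solvate_box(comp, config = generator_config(seed = seed))
}
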
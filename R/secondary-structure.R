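# DSSP-style secondary-structure assignment and grouped fraction statistics.
#
# Assignment follows the Kabsch-Sander scheme: backbone amide-carbonyl
# hydrogen bonds are scored with the electrostatic energy
#   E = k (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN),   r in Angstrom,
# a bond exists when E < cutoff, and helices, strands, turns and bends are
# read off the bond pattern. Codes: H alpha-helix, G 3.10-helix, I pi-helix,
# E beta-strand, B beta-bridge, T turn, S bend, C coil.

#' DSSP parameters
#'
#' @param coupling electrostatic coupling constant, kcal*Angstrom/mol
#'   (default 27.888 = 0.42 * 0.20 * 332, the standard value).
#' @param hbond_cutoff hydrogen-bond energy cutoff, kcal/mol (default -0.5;
#'   must be negative).
#' @param bend_angle bend ('S') angle threshold in degrees (default 70).
#' @return list of class `dssp_parameters`.
#' @export
dssp_parameters <- function(coupling = 27.888, hbond_cutoff = -0.5,
                            bend_angle = 70) {
  if (hbond_cutoff >= 0) stop("hbond_cutoff must be negative")
  structure(list(coupling = coupling, hbond_cutoff = hbond_cutoff,
                 bend_angle = bend_angle),
            class = "dssp_parameters")
}

# collect per-protein-residue backbone coordinates; NA rows where atoms are
# missing. Returns list of matrices plus chain id per residue.
backbone_table <- function(frame, topology) {
  res_idx <- protein_residues(topology)
  n <- length(res_idx)
  pick <- function(nm) {
    m <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      sel <- residue_atoms(topology, res_idx[k])
      hit <- sel[topology$atoms$name[sel] == nm]
      if (length(hit)) m[k, ] <- frame$positions[hit[1L], ]
    }
    m
  }
  atoms <- topology$atoms
  chain <- integer(n)
  for (k in seq_len(n)) {
    sel <- residue_atoms(topology, res_idx[k])
    chain[k] <- atoms$molecule_id[sel[1L]]
  }
  resname <- topology$residues$resname[match(res_idx,
                                             topology$residues$residue_index)]
  list(residue_index = res_idx, chain = chain, resname = resname,
       N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
       H = pick("H"))
}

# amide H by the DSSP convention when not present in the structure:
# 1 Angstrom from N along the previous residue's O->C direction
complete_amide_h <- function(bb) {
  n <- length(bb$residue_index)
  H <- bb$H
  for (i in seq_len(n)) {
    if (!anyNA(H[i, ])) next
    if (i == 1L || bb$chain[i] != bb$chain[i - 1L]) next
    if (bb$resname[i] == "PRO") next
    c_prev <- bb$C[i - 1L, ]; o_prev <- bb$O[i - 1L, ]
    if (anyNA(c_prev) || anyNA(o_prev) || anyNA(bb$N[i, ])) next
    H[i, ] <- bb$N[i, ] + 0.101 * unitv(c_prev - o_prev)
  }
  H[bb$resname == "PRO", ] <- NA_real_  # proline never donates
  bb$H <- H
  bb
}

# Kabsch-Sander backbone H-bond matrix: bond[i, j] = NH of residue i donates
# to C=O of residue j
ks_hbond_matrix <- function(bb, params) {
  n <- length(bb$residue_index)
  energy <- matrix(Inf, n, n)
  ok_acc <- !is.na(bb$C[, 1L]) & !is.na(bb$O[, 1L])
  ok_don <- !is.na(bb$N[, 1L]) & !is.na(bb$H[, 1L])
  ca_ok <- !is.na(bb$CA[, 1L])
  k <- params$coupling
  for (i in seq_len(n)) {
    if (!ok_don[i]) next
    for (j in seq_len(n)) {
      if (i == j || !ok_acc[j]) next
      # the backward-adjacent NH(i+1) -> CO(i) bond is sterically impossible
      # and never evaluated in DSSP
      if (i == j + 1L && bb$chain[i] == bb$chain[j]) next
      if (ca_ok[i] && ca_ok[j] &&
          vnorm(bb$CA[i, ] - bb$CA[j, ]) > 0.9) next
      rON <- vnorm(bb$N[i, ] - bb$O[j, ]) * 10
      rCH <- vnorm(bb$H[i, ] - bb$C[j, ]) * 10
      rOH <- vnorm(bb$H[i, ] - bb$O[j, ]) * 10
      rCN <- vnorm(bb$N[i, ] - bb$C[j, ]) * 10
      if (min(rON, rCH, rOH, rCN) < 0.5) next
      energy[i, j] <- k * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  # Kabsch-Sander bookkeeping: each residue retains only its two
  # lowest-energy acceptors (for its NH) and two lowest-energy donors (for
  # its CO); a bond must survive both lists
  bond <- energy < params$hbond_cutoff
  for (i in seq_len(n)) {
    hit <- which(bond[i, ])
    if (length(hit) > 2L) {
      keep <- hit[order(energy[i, hit])[1:2]]
      bond[i, setdiff(hit, keep)] <- FALSE
    }
  }
  for (j in seq_len(n)) {
    hit <- which(bond[, j])
    if (length(hit) > 2L) {
      keep <- hit[order(energy[hit, j])[1:2]]
      bond[setdiff(hit, keep), j] <- FALSE
    }
  }
  bond
}

#' Assign DSSP-style secondary structure for one frame
#'
#' Backbone N, CA, C and O atoms must be present for a residue to be
#' assignable; the amide hydrogen is taken from the structure or rebuilt
#' geometrically. Residues missing backbone atoms are forced to `C` (with a
#' warning when mid-chain). Assignment priority is H > G > I > E > B > T > S,
#' remainder C.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param params a [dssp_parameters()].
#' @return character vector of per-residue codes with attribute
#'   `residue_index`.
#' @export
assign_secondary_structure <- function(frame, topology,
                                       params = dssp_parameters()) {
  bb <- backbone_table(frame, topology)
  n <- length(bb$residue_index)
  if (n == 0L) stop("topology contains no protein residues")
  bb <- complete_amide_h(bb)

  assignable <- !is.na(bb$N[, 1L]) & !is.na(bb$CA[, 1L]) &
    !is.na(bb$C[, 1L]) & !is.na(bb$O[, 1L])
  if (any(!assignable[-c(1L, n)])) {
    warning("residue(s) ", paste(bb$residue_index[-c(1L, n)][
      !assignable[-c(1L, n)]], collapse = ", "),
      " lack backbone atoms mid-chain; forced to C")
  }

  # chain breaks: consecutive residues whose peptide bond is broken
  linked <- rep(FALSE, n)  # linked[i]: residue i connected to residue i+1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      linked[i] <- bb$chain[i] == bb$chain[i + 1L] &&
        assignable[i] && assignable[i + 1L] &&
        vnorm(bb$N[i + 1L, ] - bb$C[i, ]) < 0.25
    }
  }
  contiguous <- function(i, j) {
    if (i > j) return(contiguous(j, i))
    i >= 1L && j <= n && all(linked[i:(j - 1L)])
  }

  bond <- ks_hbond_matrix(bb, params)

  # n-turns: CO of i accepts from NH of i+len
  turn <- list()
  for (len in 3:5) {
    tv <- rep(FALSE, n)
    for (i in seq_len(max(n - len, 0L))) {
      tv[i] <- bond[i + len, i] && contiguous(i, i + len)
    }
    turn[[as.character(len)]] <- tv
  }

  code <- rep("C", n)
  set_code <- function(code, idx, value) {
    idx <- idx[idx >= 1L & idx <= n]
    code[idx] <- value
    code
  }

  # bends first (lowest priority above coil)
  for (i in seq_len(n)) {
    if (i < 3L || i > n - 2L) next
    if (!contiguous(i - 2L, i + 2L)) next
    u <- bb$CA[i, ] - bb$CA[i - 2L, ]
    v <- bb$CA[i + 2L, ] - bb$CA[i, ]
    ang <- acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
    if (ang > params$bend_angle) code[i] <- "S"
  }

  # turns: interior residues of any n-turn
  for (len in 3:5) {
    tv <- turn[[as.character(len)]]
    for (i in which(tv)) code <- set_code(code, (i + 1L):(i + len - 1L), "T")
  }

  # bridges and ladders
  br <- find_bridges(bond, contiguous, n)
  lad <- bridges_to_ladders(br)
  for (l in lad) {
    value <- if (length(l$i) >= 2L) "E" else "B"
    code <- set_code(code, c(l$i, l$j), value)
  }
  code <- mark_bulges(code, lad, n)

  # helices, lowest to highest priority: I, G, H
  t5 <- turn[["5"]]
  for (i in which(t5[-1L] & t5[-n]) + 1L) {
    code <- set_code(code, i:(i + 4L), "I")
  }
  t3 <- turn[["3"]]
  for (i in which(t3[-1L] & t3[-n]) + 1L) {
    code <- set_code(code, i:(i + 2L), "G")
  }
  t4 <- turn[["4"]]
  for (i in which(t4[-1L] & t4[-n]) + 1L) {
    code <- set_code(code, i:(i + 3L), "H")
  }

  code[!assignable] <- "C"
  structure(code, residue_index = bb$residue_index)
}

# all beta bridges (i < j, |i-j| >= 3); returns data.frame(i, j, parallel)
find_bridges <- function(bond, contiguous, n) {
  out <- list(); k <- 0L
  tb <- function(a, b) a >= 1L && a <= n && b >= 1L && b <= n && bond[a, b]
  if (n < 5L) return(data.frame(i = integer(), j = integer(),
                                parallel = logical()))
  for (i in 2:(n - 1L)) {
    if (i + 3L > n - 1L) break
    for (j in (i + 3L):(n - 1L)) {
      if (!contiguous(i - 1L, i + 1L) || !contiguous(j - 1L, j + 1L)) next
      par <- (tb(i + 1L, j) && tb(j, i - 1L)) ||
             (tb(j + 1L, i) && tb(i, j - 1L))
      anti <- (tb(i, j) && tb(j, i)) ||
              (tb(i + 1L, j - 1L) && tb(j + 1L, i - 1L))
      if (par || anti) {
        k <- k + 1L
        out[[k]] <- data.frame(i = i, j = j, parallel = par && !anti)
      }
    }
  }
  if (k == 0L) return(data.frame(i = integer(), j = integer(),
                                 parallel = logical()))
  do.call(rbind, out)
}

# group consecutive bridges into ladders
bridges_to_ladders <- function(br) {
  if (nrow(br) == 0L) return(list())
  br <- br[order(br$i, br$j), ]
  used <- rep(FALSE, nrow(br))
  ladders <- list()
  for (s in seq_len(nrow(br))) {
    if (used[s]) next
    used[s] <- TRUE
    li <- br$i[s]; lj <- br$j[s]; par <- br$parallel[s]
    repeat {
      nxt_j <- if (par) lj[length(lj)] + 1L else lj[length(lj)] - 1L
      cand <- which(!used & br$i == li[length(li)] + 1L & br$j == nxt_j &
                      br$parallel == par)
      if (length(cand) == 0L) break
      used[cand[1L]] <- TRUE
      li <- c(li, br$i[cand[1L]]); lj <- c(lj, br$j[cand[1L]])
    }
    ladders[[length(ladders) + 1L]] <- list(i = li, j = lj, parallel = par)
  }
  ladders
}

# bulge-linked ladders: gap of at most 1 residue on one strand and at most 4
# on the other joins two same-type ladders into one sheet region marked E
mark_bulges <- function(code, ladders, n) {
  if (length(ladders) < 2L) return(code)
  for (a in seq_along(ladders)) {
    for (b in seq_along(ladders)) {
      if (a == b) next
      la <- ladders[[a]]; lb <- ladders[[b]]
      if (la$parallel != lb$parallel) next
      gi <- min(lb$i) - max(la$i) - 1L
      ja <- la$j[length(la$j)]; jb <- lb$j[1L]
      gj <- if (la$parallel) jb - ja - 1L else ja - jb - 1L
      if (gi < 0L || gj < 0L) next
      if ((gi <= 1L && gj <= 4L) || (gi <= 4L && gj <= 1L)) {
        span_i <- (max(la$i)):(min(lb$i))
        span_j <- if (la$parallel) ja:jb else jb:ja
        idx <- c(la$i, lb$i, la$j, lb$j, span_i, span_j)
        idx <- idx[idx >= 1L & idx <= n]
        code[idx] <- "E"
      }
    }
  }
  code
}

#' Assign secondary structure over a trajectory
#'
#' @param traj a [trajectory()].
#' @param params a [dssp_parameters()].
#' @param production_only use only frames after the equilibration cut
#'   (default `TRUE`).
#' @return an `ss_assignment`: character matrix (frames x residues) with
#'   attributes `residue_index` and `times`.
#' @export
assign_trajectory <- function(traj, params = dssp_parameters(),
                              production_only = TRUE) {
  frames <- if (production_only) production_frames(traj) else traj$frames
  rows <- lapply(frames, assign_secondary_structure, topology = traj$topology,
                 params = params)
  m <- do.call(rbind, rows)
  structure(m,
            residue_index = attr(rows[[1L]], "residue_index"),
            times = vapply(frames, function(f) f$time, numeric(1)),
            class = "ss_assignment")
}

# coerce a single-frame assignment vector to the matrix form
as_ss_matrix <- function(assignments) {
  if (inherits(assignments, "ss_assignment") || is.matrix(assignments)) {
    return(assignments)
  }
  structure(matrix(assignments, nrow = 1L,
                   dimnames = NULL),
            residue_index = attr(assignments, "residue_index"),
            class = "ss_assignment")
}

#' Grouping schemes for DSSP codes
#'
#' `"four_group"` groups codes as helical (H, G, I), turn-related (T, E, B),
#' coil (C) and bend (S); `"three_group"` groups them as ordered (H, G, I, E,
#' B), turns (T) and other (S, C). The pi-helix is mapped with the helices in
#' both schemes; isolated beta-bridges travel with the sheets.
#'
#' @param name `"four_group"` or `"three_group"`, or `"custom"` with an
#'   explicit `mapping`.
#' @param mapping named character vector over all eight DSSP codes (only for
#'   `name = "custom"`).
#' @return list of class `grouping_scheme` with elements `name`, `mapping`.
#' @export
grouping_scheme <- function(name = c("four_group", "three_group", "custom"),
                            mapping = NULL) {
  name <- match.arg(name)
  codes <- c("H", "G", "I", "E", "B", "T", "S", "C")
  if (name == "four_group") {
    mapping <- c(H = "helical", G = "helical", I = "helical",
                 E = "turn_related", B = "turn_related", T = "turn_related",
                 S = "bend", C = "coil")
  } else if (name == "three_group") {
    mapping <- c(H = "ordered", G = "ordered", I = "ordered",
                 E = "ordered", B = "ordered",
                 T = "turns", S = "other", C = "other")
  } else {
    if (is.null(mapping) || !all(codes %in% names(mapping))) {
      stop("custom scheme requires a mapping over all codes: ",
           paste(codes, collapse = " "))
    }
  }
  structure(list(name = name, mapping = mapping[codes]),
            class = "grouping_scheme")
}

scheme_groups <- function(scheme) unique(unname(scheme$mapping))

# population standard deviation (errors reported as standard deviations over
# frames)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Grouped secondary-structure fractions over frames
#'
#' Per-frame fraction of selected residues in each group, summarized as mean
#' and population standard deviation over frames. Fractions sum to 1 in every
#' frame.
#'
#' @param assignments an `ss_assignment` (or single-frame assignment).
#' @param scheme a [grouping_scheme()].
#' @param selection residue indices to include; default all assigned residues.
#' @return data.frame of class `fraction_table` with columns `group`, `mean`,
#'   `std`, plus attribute `per_frame` (frames x groups matrix).
#' @export
group_fractions <- function(assignments, scheme = grouping_scheme(),
                            selection = NULL) {
  m <- as_ss_matrix(assignments)
  res_idx <- attr(m, "residue_index")
  cols <- seq_len(ncol(m))
  if (!is.null(selection)) {
    cols <- match(selection, res_idx)
    if (anyNA(cols)) stop("selection contains residues outside the assignment")
  }
  if (length(cols) == 0L) stop("empty residue selection")
  groups <- scheme_groups(scheme)
  g <- matrix(scheme$mapping[m[, cols, drop = FALSE]], nrow = nrow(m))
  per_frame <- sapply(groups, function(gr) rowMeans(g == gr))
  per_frame <- matrix(per_frame, nrow = nrow(m),
                      dimnames = list(NULL, groups))
  out <- data.frame(group = groups,
                    mean = colMeans(per_frame),
                    std = apply(per_frame, 2L, pop_sd),
                    row.names = NULL)
  structure(out, per_frame = per_frame, class = c("fraction_table",
                                                  "data.frame"))
}

#' Kernel-density estimate of a group's per-frame fraction
#'
#' Gaussian KDE with Scott's-rule bandwidth, evaluated on a regular grid over
#' the fraction's support `[0, 1]` (clipped, no boundary correction). A
#' constant ensemble degenerates to a narrow fixed-bandwidth peak.
#'
#' @param assignments an `ss_assignment` over at least two frames.
#' @param scheme a [grouping_scheme()].
#' @param group group label to profile.
#' @param selection optional residue selection.
#' @param n grid size (default 512).
#' @return data.frame with columns `fraction`, `density`; attribute `bw`.
#' @export
fraction_distribution <- function(assignments, scheme = grouping_scheme(),
                                  group, selection = NULL, n = 512L) {
  m <- as_ss_matrix(assignments)
  if (nrow(m) < 2L) {
    stop("at least two frames are required for a density estimate; ",
         "generate an ensemble, e.g. with perturb_trajectory()")
  }
  ft <- group_fractions(m, scheme, selection)
  pf <- attr(ft, "per_frame")
  if (!group %in% colnames(pf)) {
    stop("unknown group '", group, "'; scheme has: ",
         paste(colnames(pf), collapse = ", "))
  }
  x <- pf[, group]
  s <- stats::sd(x)
  bw <- if (s < 1e-9) 0.003 else s * length(x)^(-1 / 5)
  d <- stats::density(x, bw = bw, n = n, from = 0, to = 1)
  structure(data.frame(fraction = d$x, density = d$y), bw = bw, group = group)
}

#' Per-amino-acid-type contributions to each structure group
#'
#' entry(a, g) = mean over frames of (number of residues of amino-acid type a
#' assigned to group g) / (number of residues considered); entries sum to 1.
#'
#' @param assignments an `ss_assignment`.
#' @param topology the matching [topology()] (provides residue types).
#' @param scheme a [grouping_scheme()].
#' @return data.frame of class `fraction_table` with columns `aa`, `group`,
#'   `mean`, `std`.
#' @export
per_aatype_contributions <- function(assignments, topology,
                                     scheme = grouping_scheme()) {
  m <- as_ss_matrix(assignments)
  res_idx <- attr(m, "residue_index")
  resname <- topology$residues$resname[match(res_idx,
                                             topology$residues$residue_index)]
  aa <- aa_one(resname)
  groups <- scheme_groups(scheme)
  aas <- sort(unique(aa))
  nres <- ncol(m)
  combos <- expand.grid(aa = aas, group = groups, stringsAsFactors = FALSE)
  per_frame <- matrix(0, nrow(m), nrow(combos))
  gmat <- matrix(scheme$mapping[m], nrow = nrow(m))
  for (k in seq_len(nrow(combos))) {
    sel <- aa == combos$aa[k]
    per_frame[, k] <- rowSums(gmat[, sel, drop = FALSE] ==
                                combos$group[k]) / nres
  }
  out <- data.frame(aa = combos$aa, group = combos$group,
                    mean = colMeans(per_frame),
                    std = apply(per_frame, 2L, pop_sd))
  structure(out, class = c("fraction_table", "data.frame"))
}

#' Difference between two fraction tables
#'
#' Computes `B - A` entry-wise with standard deviations propagated in
#' quadrature: a positive value is an increase from condition A to condition
#' B (e.g. with the addition of ethanol).
#'
#' @param a,b `fraction_table` data.frames with matching key columns
#'   (`group`, and `aa` when present).
#' @return data.frame with the key columns plus `delta` and `std`.
#' @export
delta_table <- function(a, b) {
  keys <- intersect(c("aa", "group"), names(a))
  if (!identical(keys, intersect(c("aa", "group"), names(b)))) {
    stop("fraction tables have different key columns")
  }
  ka <- do.call(paste, c(a[keys], sep = "|"))
  kb <- do.call(paste, c(b[keys], sep = "|"))
  if (!setequal(ka, kb)) {
    stop("key mismatch between tables; missing: ",
         paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", "))
  }
  idx <- match(ka, kb)
  out <- a[keys]
  out$delta <- b$mean[idx] - a$mean
  out$std <- sqrt(a$std^2 + b$std[idx]^2)
  out
}
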
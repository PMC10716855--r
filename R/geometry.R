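# Periodic-boundary geometry primitives. All coordinates are in nm and all
# boxes are orthorhombic; analyses therefore only ever need the component-wise
# minimum-image convention.

#' Simulation box
#'
#' Construct an orthorhombic periodic simulation box.
#'
#' @param lengths numeric vector of three positive edge lengths in nm, or a
#'   single length for a cubic box.
#' @return An object of class `sim_box`: a named numeric 3-vector.
#' @examples
#' sim_box(8.8)          # the studied cubic mixture box
#' sim_box(c(4, 5, 6))
#' @export
sim_box <- function(lengths) {
  if (length(lengths) == 1L) lengths <- rep(lengths, 3L)
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3L || anyNA(lengths) || any(lengths <= 0)) {
    stop("box lengths must be three positive numbers (nm)")
  }
  structure(c(x = lengths[1L], y = lengths[2L], z = lengths[3L]),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("orthorhombic box %.4g x %.4g x %.4g nm (V = %.4g nm^3)\n",
              x[1L], x[2L], x[3L], prod(x)))
  invisible(x)
}

#' Box volume in nm^3
#' @param box a [sim_box()].
#' @return numeric volume.
#' @export
box_volume <- function(box) prod(unclass(box))

#' Minimum-image displacement vectors
#'
#' Component-wise minimum-image displacement `b - a` for orthorhombic boxes.
#'
#' @param a,b numeric 3-vectors or n-by-3 matrices of positions (nm).
#' @param box a [sim_box()].
#' @return n-by-3 matrix of displacement vectors.
#' @keywords internal
min_image_disp <- function(a, b, box) {
  a <- rbind3(a); b <- rbind3(b)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  d <- b - a
  L <- rep(unclass(box), each = n)
  d - L * round(d / L)
}

# coerce a 3-vector or n x 3 matrix to matrix form
rbind3 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    matrix(as.numeric(x), ncol = 3L)
  }
}

#' Minimum-image distance under periodic boundaries
#'
#' Distance between points measured to the nearest periodic image. For
#' separations at most half the smallest box length the image is unique.
#'
#' @param a,b positions: 3-vectors or n-by-3 matrices (nm). If both are
#'   matrices they are paired row-wise.
#' @param box a [sim_box()].
#' @return numeric vector of distances in nm.
#' @examples
#' b <- sim_box(8.8)
#' minimum_image_distance(c(0.1, 0, 0), c(8.7, 0, 0), b)  # 0.2, not 8.6
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- min_image_disp(a, b, box)
  sqrt(rowSums(d * d))
}

#' Wrap positions into the primary box
#' @param pos n-by-3 matrix of positions (nm).
#' @param box a [sim_box()].
#' @return n-by-3 matrix with every coordinate in `[0, L)`.
#' @keywords internal
wrap_positions <- function(pos, box) {
  L <- rep(unclass(box), each = nrow(pos))
  pos - L * floor(pos / L)
}

#' All atom pairs within a cutoff under periodic boundaries
#'
#' Cell-list neighbour search over one set of positions. Falls back to the
#' direct all-pairs scan when the box is too small to tile with cells of edge
#' >= cutoff in every dimension.
#'
#' @param pos n-by-3 matrix of positions (nm).
#' @param box a [sim_box()].
#' @param cutoff pair distance cutoff (nm).
#' @return data.frame with columns `i`, `j` (1-based row indices, i < j) and
#'   `d` (minimum-image distance, nm).
#' @keywords internal
neighbor_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), d = numeric()))
  L <- unclass(box)
  ncell <- pmax(1L, as.integer(floor(L / cutoff)))
  if (any(ncell < 3L)) return(brute_pairs(pos, box, cutoff))

  w <- wrap_positions(pos, box)
  cidx <- floor(sweep(w, 2L, L / ncell, "/"))
  cidx <- pmin(cidx, matrix(rep(ncell - 1L, each = n), ncol = 3L))  # guard fp edge
  cell <- as.integer(cidx[, 1L] + ncell[1L] * (cidx[, 2L] + ncell[2L] * cidx[, 3L]))

  ord <- order(cell)
  atoms_by_cell <- split(ord, cell[ord])

  # half neighbourhood: self cell plus 13 of the 26 periodic neighbours
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- offs[, 3L] > 0 | (offs[, 3L] == 0 & (offs[, 2L] > 0 |
          (offs[, 2L] == 0 & offs[, 1L] >= 0)))
  offs <- offs[keep, , drop = FALSE]

  key <- as.integer(names(atoms_by_cell))
  kx <- key %% ncell[1L]
  ky <- (key %/% ncell[1L]) %% ncell[2L]
  kz <- key %/% (ncell[1L] * ncell[2L])

  out_i <- vector("list", length(atoms_by_cell) * nrow(offs))
  out_j <- out_i; out_d <- out_i
  slot <- 0L
  cut2 <- cutoff^2
  for (ci in seq_along(atoms_by_cell)) {
    ai <- atoms_by_cell[[ci]]
    for (oi in seq_len(nrow(offs))) {
      nx <- (kx[ci] + offs[oi, 1L]) %% ncell[1L]
      ny <- (ky[ci] + offs[oi, 2L]) %% ncell[2L]
      nz <- (kz[ci] + offs[oi, 3L]) %% ncell[3L]
      nkey <- as.character(nx + ncell[1L] * (ny + ncell[2L] * nz))
      aj <- atoms_by_cell[[nkey]]
      if (is.null(aj)) next
      same <- all(offs[oi, ] == 0L)
      if (same) {
        if (length(ai) < 2L) next
        cmb <- pair_grid(ai, ai, self = TRUE)
      } else {
        cmb <- pair_grid(ai, aj, self = FALSE)
      }
      if (nrow(cmb) == 0L) next
      dvec <- w[cmb[, 2L], , drop = FALSE] - w[cmb[, 1L], , drop = FALSE]
      Lm <- rep(L, each = nrow(dvec))
      dvec <- dvec - Lm * round(dvec / Lm)
      d2 <- rowSums(dvec * dvec)
      hit <- d2 <= cut2
      if (!any(hit)) next
      slot <- slot + 1L
      ii <- pmin(cmb[hit, 1L], cmb[hit, 2L])
      jj <- pmax(cmb[hit, 1L], cmb[hit, 2L])
      out_i[[slot]] <- ii
      out_j[[slot]] <- jj
      out_d[[slot]] <- sqrt(d2[hit])
    }
  }
  if (slot == 0L) return(data.frame(i = integer(), j = integer(), d = numeric()))
  res <- data.frame(i = unlist(out_i[seq_len(slot)]),
                    j = unlist(out_j[seq_len(slot)]),
                    d = unlist(out_d[seq_len(slot)]))
  res[!duplicated(res[c("i", "j")]), , drop = FALSE]
}

pair_grid <- function(a, b, self) {
  if (self) {
    n <- length(a)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cbind(a[idx[, 1L]], a[idx[, 2L]])
  } else {
    cbind(rep(a, times = length(b)), rep(b, each = length(a)))
  }
}

# direct O(n^2) minimum-image pair scan (small systems / small boxes)
brute_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  L <- unclass(box)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    d <- pos[jj, , drop = FALSE] -
      pos[rep(i, length(jj)), , drop = FALSE]
    Lm <- rep(L, each = length(jj))
    d <- d - Lm * round(d / Lm)
    dist <- sqrt(rowSums(d * d))
    hit <- dist <= cutoff
    out[[i]] <- if (any(hit)) data.frame(i = i, j = jj[hit], d = dist[hit]) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(i = integer(), j = integer(), d = numeric()) else res
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}} over the
#' selected atoms, without periodic wrapping (the selection is assumed whole).
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param selection integer vector of atom indices; default all protein atoms.
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(frame, topology, selection = NULL) {
  if (is.null(selection)) selection <- protein_atoms(topology)
  if (length(selection) == 0L) stop("empty atom selection")
  pos <- frame$positions[selection, , drop = FALSE]
  m <- topology$atoms$mass[selection]
  com <- colSums(pos * m) / sum(m)
  dp <- sweep(pos, 2L, com)
  sqrt(sum(m * rowSums(dp * dp)) / sum(m))
}

#' Root-mean-square deviation between two frames
#'
#' RMSD over a matched atom selection, optionally after an optimal rigid-body
#' superposition (Kabsch algorithm; degenerate covariance resolves toward the
#' identity rotation).
#'
#' @param frame,reference [md_frame()] objects over the same topology.
#' @param topology the matching [topology()]; used for the default selection.
#' @param selection integer atom indices, applied to both frames; default all
#'   protein heavy atoms.
#' @param superpose logical; fit before measuring (default `TRUE`).
#' @return RMSD in nm.
#' @export
rmsd_to_reference <- function(frame, reference, topology = NULL,
                              selection = NULL, superpose = TRUE) {
  if (is.null(selection)) {
    if (is.null(topology)) stop("either a topology or a selection is required")
    selection <- protein_heavy_atoms(topology)
  }
  x <- frame$positions[selection, , drop = FALSE]
  y <- reference$positions[selection, , drop = FALSE]
  if (nrow(x) != nrow(y)) stop("selection size mismatch between frames")
  if (superpose) x <- kabsch_superpose(x, y)
  d <- x - y
  sqrt(sum(d * d) / nrow(d))
}

# optimal superposition of x onto y (equal weights); returns transformed x
kabsch_superpose <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2L, cx); y0 <- sweep(y, 2L, cy)
  h <- crossprod(x0, y0)
  sv <- svd(h)
  s <- diag(3L)
  s[3L, 3L] <- sign(det(sv$v %*% t(sv$u)))
  if (s[3L, 3L] == 0) s[3L, 3L] <- 1  # degenerate: fall back to identity branch
  r <- sv$v %*% s %*% t(sv$u)
  sweep(x0 %*% t(r), 2L, cy, "+")
}

#' Centred moving average with truncated end windows
#'
#' @param x numeric series.
#' @param window window length in samples (>= 1). Endpoints average over the
#'   part of the window that exists.
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > length(x)) stop("window (", window, ") exceeds series length (",
                               length(x), ")")
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - ((window - 1L) %/% 2L))
  hi <- pmin(n, seq_len(n) + (window %/% 2L))
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
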
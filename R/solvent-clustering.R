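# Single-species solvent clusters under an any-atom distance criterion:
# connected components of the molecular contact graph, built from a periodic
# neighbour search and a union-find pass.

#' Cluster criterion
#'
#' @param cutoff any-atom contact distance, nm (default 0.25, the
#'   hydrogen-bond formation distance between atoms of the molecules).
#' @param include_hydrogens count hydrogen atoms as contacts (default TRUE:
#'   "any of the atoms" means any).
#' @return list of class `cluster_criterion`.
#' @export
cluster_criterion <- function(cutoff = 0.25, include_hydrogens = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, include_hydrogens = include_hydrogens),
            class = "cluster_criterion")
}

#' Build single-species solvent clusters in a frame
#'
#' Two molecules of the species are in contact when any atom of one is within
#' the cutoff of any atom of the other (minimum image); clusters are the
#' connected components of the contact graph.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param species `"WATER"` or `"ETHANOL"`.
#' @param criterion a [cluster_criterion()].
#' @return list of class `cluster_set`: `species`, `time`, `clusters` (list
#'   of integer molecule-id vectors, partitioning the species).
#' @export
build_clusters <- function(frame, topology, species = "WATER",
                           criterion = cluster_criterion()) {
  species <- match.arg(toupper(species), c("WATER", "ETHANOL"))
  if (criterion$cutoff > min(unclass(frame$box)) / 2) {
    stop("cutoff exceeds half the smallest box length")
  }
  mols <- species_molecules(topology, species)
  if (length(mols) == 0L) stop("no molecules of species ", species)
  at <- topology$atoms
  sel <- which(at$molecule_id %in% mols)
  if (!criterion$include_hydrogens) sel <- sel[!at$is_hydrogen[sel]]
  pairs <- neighbor_pairs(frame$positions[sel, , drop = FALSE], frame$box,
                          criterion$cutoff)
  mol_of <- match(at$molecule_id[sel], mols)
  parent <- seq_along(mols)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    mi <- mol_of[pairs$i]; mj <- mol_of[pairs$j]
    keep <- mi != mj
    for (k in which(keep)) {
      ri <- find(mi[k]); rj <- find(mj[k])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_along(mols), find, integer(1))
  clusters <- split(mols, root)
  names(clusters) <- NULL
  structure(list(species = species, time = frame$time, clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("%s clusters at t = %g ns: %d clusters of %d molecules (max %d)\n",
              tolower(x$species), x$time, length(sizes), sum(sizes),
              max(sizes)))
  invisible(x)
}

#' Cluster sizes of a cluster set
#' @param cluster_set a `cluster_set` from [build_clusters()].
#' @return integer vector of cluster sizes.
#' @export
cluster_sizes <- function(cluster_set) lengths(cluster_set$clusters)

#' Cluster-size distribution over a trajectory
#'
#' Pools cluster sizes over post-equilibration frames and reports, per size
#' bin, the probability that a randomly chosen cluster has that size
#' (cluster-weighted) and the probability that a randomly chosen molecule
#' sits in a cluster of that size (molecule-weighted). Sizes above 10 are
#' binned logarithmically.
#'
#' @param traj a [trajectory()].
#' @param species `"WATER"` or `"ETHANOL"`.
#' @param criterion a [cluster_criterion()].
#' @param log_bins_per_decade bins per decade above size 10 (default 8).
#' @param pooled pool sizes over frames (default TRUE; otherwise averages the
#'   per-frame distributions).
#' @return data.frame with columns `size_lo`, `size_hi`, `p_cluster`,
#'   `p_molecule`; attribute `sizes` carries the pooled size sample.
#' @export
cluster_size_distribution <- function(traj, species = "WATER",
                                      criterion = cluster_criterion(),
                                      log_bins_per_decade = 8L,
                                      pooled = TRUE) {
  frames <- production_frames(traj)
  per_frame <- lapply(frames, function(f) {
    cluster_sizes(build_clusters(f, traj$topology, species, criterion))
  })
  all_sizes <- unlist(per_frame)
  edges <- size_bin_edges(max(all_sizes), log_bins_per_decade)
  tab <- function(sizes) {
    idx <- pmin(findInterval(sizes, edges), length(edges) - 1L)
    pc <- tabulate(idx, nbins = length(edges) - 1L)
    pm <- vapply(seq_len(length(edges) - 1L), function(b) {
      sum(sizes[idx == b])
    }, numeric(1))
    cbind(p_cluster = pc / length(sizes), p_molecule = pm / sum(sizes))
  }
  probs <- if (pooled) {
    tab(all_sizes)
  } else {
    Reduce(`+`, lapply(per_frame, tab)) / length(per_frame)
  }
  out <- data.frame(size_lo = edges[-length(edges)],
                    size_hi = edges[-1] - 1,
                    p_cluster = probs[, "p_cluster"],
                    p_molecule = probs[, "p_molecule"])
  structure(out, sizes = all_sizes)
}

# integer bin edges: unit bins up to 10, log-spaced above
size_bin_edges <- function(max_size, per_decade = 8L) {
  edges <- 1:11
  if (max_size > 10) {
    lo <- log10(10); hi <- log10(max_size + 1)
    n <- max(1L, ceiling((hi - lo) * per_decade))
    more <- unique(ceiling(10^seq(lo, hi, length.out = n + 1L))[-1])
    edges <- c(edges, more[more > 11])
  }
  if (edges[length(edges)] <= max_size) {
    edges <- c(edges, max_size + 1L)
  }
  edges
}

#' Mean cluster size time series
#'
#' Per-frame mean cluster size (over the whole trajectory; an equilibration
#' diagnostic), smoothed with a centred moving average.
#'
#' @param traj a [trajectory()].
#' @param species `"WATER"` or `"ETHANOL"`.
#' @param criterion a [cluster_criterion()].
#' @param window moving-average window in frames (default 1).
#' @return data.frame with columns `time`, `mean_size`, `mean_size_smooth`.
#' @export
mean_cluster_size_series <- function(traj, species = "WATER",
                                     criterion = cluster_criterion(),
                                     window = 1L) {
  ms <- vapply(traj$frames, function(f) {
    mean(cluster_sizes(build_clusters(f, traj$topology, species, criterion)))
  }, numeric(1))
  data.frame(time = frame_times(traj), mean_size = ms,
             mean_size_smooth = moving_average(ms, window))
}

#' Compare cluster-size distributions with and without protein
#'
#' Puts the two trajectories' distributions on a shared binning and reports
#' the change in the per-frame number of small clusters (fewer than
#' `small_cutoff` molecules) and in the largest cluster size.
#'
#' @param traj_with trajectory containing the protein.
#' @param traj_without matched solvent-only trajectory.
#' @param species `"WATER"` or `"ETHANOL"`.
#' @param criterion a [cluster_criterion()].
#' @param small_cutoff size below which a cluster counts as small (default
#'   10).
#' @return list with `distribution` (shared-binning data.frame with
#'   `p_cluster_with`, `p_cluster_without`), `delta_small_per_frame` (mean
#'   with-protein minus without-protein count of small clusters per frame)
#'   and `delta_largest` (difference of mean largest sizes).
#' @export
compare_with_without_protein <- function(traj_with, traj_without,
                                         species = "WATER",
                                         criterion = cluster_criterion(),
                                         small_cutoff = 10L) {
  stats_of <- function(traj) {
    frames <- production_frames(traj)
    sizes <- lapply(frames, function(f) {
      cluster_sizes(build_clusters(f, traj$topology, species, criterion))
    })
    list(sizes = sizes, pooled = unlist(sizes))
  }
  a <- stats_of(traj_with)
  b <- stats_of(traj_without)
  edges <- size_bin_edges(max(a$pooled, b$pooled))
  binned <- function(sizes) {
    idx <- pmin(findInterval(sizes, edges), length(edges) - 1L)
    tabulate(idx, nbins = length(edges) - 1L) / length(sizes)
  }
  dist <- data.frame(size_lo = edges[-length(edges)], size_hi = edges[-1] - 1,
                     p_cluster_with = binned(a$pooled),
                     p_cluster_without = binned(b$pooled))
  small_mean <- function(s) mean(vapply(s, function(x) sum(x < small_cutoff),
                                        numeric(1)))
  largest_mean <- function(s) mean(vapply(s, max, numeric(1)))
  list(distribution = dist,
       delta_small_per_frame = small_mean(a$sizes) - small_mean(b$sizes),
       delta_largest = largest_mean(a$sizes) - largest_mean(b$sizes))
}
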
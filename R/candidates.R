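#' Extract above-threshold C-alpha voxels
#'
#' Emits every voxel whose C-alpha probability strictly exceeds the
#' threshold (default 0.3), with its center coordinate in Angstrom and its
#' backbone probability.
#'
#' @param pred a `prediction_volumes` list (fields `calpha_p`, `backbone_p`,
#'   `amino_p`).
#' @param map the paired [density_map] (supplies origin/voxel size).
#' @param threshold extraction threshold on `calpha_p` (strict inequality).
#' @return data.frame with columns x, y, z (Angstrom), ca_prob,
#'   backbone_prob, i, j, k (zero-based voxel indices). May have zero rows.
#' @export
extract_candidate_voxels <- function(pred, map, threshold = 0.3) {
  stopifnot(inherits(map, "density_map"))
  sel <- which(pred$calpha_p > threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      ca_prob = numeric(0), backbone_prob = numeric(0),
                      i = integer(0), j = integer(0), k = integer(0)))
  ijk <- sel - 1L
  xyz <- index_to_coord(ijk, map)
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             ca_prob = pred$calpha_p[sel],
             backbone_prob = pred$backbone_p[sel],
             i = ijk[, 1], j = ijk[, 2], k = ijk[, 3])
}

#' Density-based clustering of candidate voxels (DBSCAN)
#'
#' Standard DBSCAN over 3-D coordinates: points with at least `min_samples`
#' neighbors within `eps` are core points; clusters are the connected
#' components of density-reachability; border points join a reachable core
#' cluster; noise points are returned as singleton clusters so no candidate
#' is silently dropped. Defaults follow C-alpha geometry: eps = 1.9 Angstrom
#' (half the 3.8 Angstrom consecutive C-alpha spacing, so adjacent residues
#' never merge) and min_samples = 1.
#'
#' @param points data.frame with x, y, z columns (plus any extra columns).
#' @param eps neighborhood radius, Angstrom.
#' @param min_samples minimum neighborhood size (the point itself counts).
#' @return Integer vector of cluster ids (1-based), one per row of `points`.
#' @export
cluster_candidates <- function(points, eps = 1.9, min_samples = 1L) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  xyz <- as.matrix(points[, c("x", "y", "z")])
  dd <- as.matrix(stats::dist(xyz))
  nb <- dd <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)                     # 0 = unassigned
  cl <- 0L
  for (p in seq_len(n)) {
    if (labels[p] != 0L || !core[p]) next
    cl <- cl + 1L
    queue <- p; labels[p] <- cl
    while (length(queue) > 0L) {
      q <- queue[1L]; queue <- queue[-1L]
      if (!core[q]) next
      for (r in which(nb[q, ])) {
        if (labels[r] == 0L) {
          labels[r] <- cl
          queue <- c(queue, r)
        }
      }
    }
  }
  for (p in which(labels == 0L)) {         # noise -> singleton clusters
    cl <- cl + 1L
    labels[p] <- cl
  }
  labels
}

#' Filter clusters by mean backbone probability
#'
#' Scores each cluster by the mean backbone probability of its member voxels
#' and keeps only clusters whose mean exceeds 50% of the best cluster's
#' mean. The best cluster is always kept.
#'
#' @param points candidate voxel data.frame (needs `backbone_prob`).
#' @param labels integer cluster ids from [cluster_candidates()].
#' @param frac keep threshold as a fraction of the best mean (default 0.5).
#' @return Logical vector: TRUE for voxels in surviving clusters.
#' @export
filter_clusters <- function(points, labels, frac = 0.5) {
  if (nrow(points) == 0L) return(logical(0))
  means <- tapply(points$backbone_prob, labels, mean)
  keep_ids <- as.integer(names(means))[means > frac * max(means)]
  labels %in% keep_ids
}

#' Non-maximum suppression and coordinate refinement
#'
#' Candidates are selected greedily in descending C-alpha probability; any
#' voxel within `nms_radius` of an already-accepted candidate is suppressed.
#' Each accepted candidate's coordinate is refined to the probability-
#' weighted mean of same-cluster voxels within `refine_radius`, and its
#' amino-acid probability vector is read from `amino_p` at the refined
#' (rounded) voxel.
#'
#' @param points filtered candidate voxels (data.frame from
#'   [extract_candidate_voxels()], possibly subset).
#' @param labels cluster ids aligned with `points`.
#' @param pred the `prediction_volumes` (for `amino_p`).
#' @param map the paired [density_map].
#' @param nms_radius suppression radius, Angstrom (default 2.0).
#' @param refine_radius refinement averaging radius, Angstrom (default 2.0).
#' @return A `candidate_set`: data.frame with x, y, z, ca_prob,
#'   backbone_score, cluster_id and aa_1..aa_20 columns (per-type
#'   probabilities, each row summing to 1).
#' @export
nms_and_refine <- function(points, labels, pred, map, nms_radius = 2.0,
                           refine_radius = 2.0) {
  if (nrow(points) == 0L) return(empty_candidate_set())
  ord <- order(-points$ca_prob)
  acc <- integer(0)
  for (p in ord) {
    if (length(acc) > 0L) {
      dmin <- min(sqrt((points$x[acc] - points$x[p])^2 +
                       (points$y[acc] - points$y[p])^2 +
                       (points$z[acc] - points$z[p])^2))
      if (dmin < nms_radius) next
    }
    acc <- c(acc, p)
  }
  out <- lapply(acc, function(p) {
    memb <- which(labels == labels[p])
    dd <- sqrt((points$x[memb] - points$x[p])^2 +
               (points$y[memb] - points$y[p])^2 +
               (points$z[memb] - points$z[p])^2)
    memb <- memb[dd <= refine_radius]
    wts <- points$ca_prob[memb]
    coord <- c(sum(points$x[memb] * wts), sum(points$y[memb] * wts),
               sum(points$z[memb] * wts)) / sum(wts)
    ijk <- coord_to_index(coord, map)
    d <- dim(map$data)
    aa <- if (in_bounds(ijk, d))
      pred$amino_p[, ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
    else rep(1 / 20, 20L)
    s <- sum(aa); aa <- if (s > 0) aa / s else rep(1 / 20, 20L)
    c(coord, points$ca_prob[p], mean(points$backbone_prob[memb]),
      labels[p], aa)
  })
  m <- do.call(rbind, out)
  cs <- data.frame(m)
  names(cs) <- c("x", "y", "z", "ca_prob", "backbone_score", "cluster_id",
                 paste0("aa_", 1:20))
  # refinement can pull accepted candidates together; a final suppression
  # sweep on the refined coordinates restores the min-distance contract
  ord2 <- order(-cs$ca_prob)
  keep2 <- logical(nrow(cs))
  for (p in ord2) {
    prev <- which(keep2)
    if (length(prev) == 0L ||
        min(sqrt((cs$x[prev] - cs$x[p])^2 + (cs$y[prev] - cs$y[p])^2 +
                 (cs$z[prev] - cs$z[p])^2)) >= nms_radius)
      keep2[p] <- TRUE
  }
  cs <- cs[sort(which(keep2)), , drop = FALSE]
  rownames(cs) <- NULL
  class(cs) <- c("candidate_set", "data.frame")
  cs
}

empty_candidate_set <- function() {
  cs <- data.frame(matrix(numeric(0), ncol = 26))
  names(cs) <- c("x", "y", "z", "ca_prob", "backbone_score", "cluster_id",
                 paste0("aa_", 1:20))
  class(cs) <- c("candidate_set", "data.frame")
  cs
}

#' Full candidate-extraction pipeline
#'
#' Threshold extraction, DBSCAN clustering, cluster filtering and NMS +
#' refinement in one call.
#'
#' @inheritParams extract_candidate_voxels
#' @inheritParams cluster_candidates
#' @inheritParams nms_and_refine
#' @param filter_frac cluster-filter fraction (see [filter_clusters()]).
#' @return A `candidate_set` data.frame (see [nms_and_refine()]).
#' @export
extract_candidates <- function(pred, map, threshold = 0.3, eps = 1.9,
                               min_samples = 1L, filter_frac = 0.5,
                               nms_radius = 2.0, refine_radius = 2.0) {
  pts <- extract_candidate_voxels(pred, map, threshold)
  if (nrow(pts) == 0L) return(empty_candidate_set())
  labels <- cluster_candidates(pts, eps = eps, min_samples = min_samples)
  keep <- filter_clusters(pts, labels, frac = filter_frac)
  nms_and_refine(pts[keep, , drop = FALSE], labels[keep], pred, map,
                 nms_radius = nms_radius, refine_radius = refine_radius)
}

#' Amino-acid probability matrix of a candidate set
#' @param cands a `candidate_set`.
#' @return Numeric matrix (n x 20), rows on the simplex.
#' @export
aa_prob_matrix <- function(cands) {
  as.matrix(cands[, paste0("aa_", 1:20), drop = FALSE])
}
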
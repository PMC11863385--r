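# Ensemble-docking post-processing: superpose every receptor
# conformation onto a common reference over the binding site, carry the
# ligand pose along, cluster poses with a size-adaptive RMSD cutoff and
# rank clusters by their best docking score.

#' Size-adaptive pose-clustering cutoff
#'
#' d_c = 0.067 Angstrom per ligand non-hydrogenous atom, so the
#' merging radius scales with molecular size. The value is reported to
#' one decimal (the unrounded value is available via
#' `attr(, "exact")`).
#'
#' @param n_heavy ligand heavy-atom count (>= 1).
#' @return cutoff in Angstrom, rounded to 1 decimal.
#' @export
adaptive_cutoff <- function(n_heavy) {
  stopifnot(n_heavy >= 1)
  exact <- 0.067 * n_heavy
  structure(round(exact, 1), exact = exact)
}

#' Align docking poses into a common binding-site frame
#'
#' Each receptor conformation is superposed onto the reference receptor
#' over the site heavy atoms, and the same rigid transform is applied
#' to its ligand pose.
#'
#' @param poses list of ligand coordinate matrices (same atom count and
#'   order).
#' @param receptors list of `pdb` receptor conformations, one per pose.
#' @param site `site_definition` present in every receptor.
#' @param reference `pdb` reference receptor.
#' @return list of transformed ligand coordinate matrices.
#' @export
align_poses_by_site <- function(poses, receptors, site, reference) {
  stopifnot(length(poses) == length(receptors))
  ref_xyz <- atom_coords(reference,
                         atom_indices(reference, site$residues, "heavy"))
  lapply(seq_along(poses), function(i) {
    m <- .matched_site_coords(receptors[[i]], reference, site, "heavy")
    fit <- superpose(m$model, m$reference)
    apply_transform(poses[[i]], fit)
  })
}

#' Pairwise pose distance matrix
#'
#' Entry (i, j) is the coordinate RMSD between poses i and j in the
#' common aligned frame, with no further fitting (so rigid displacement
#' of a pose is fully counted).
#'
#' @param poses list of aligned ligand coordinate matrices with equal
#'   atom counts and consistent atom order.
#' @return symmetric n x n matrix in Angstrom with zero diagonal.
#' @export
pose_distance_matrix <- function(poses) {
  stopifnot(length(poses) >= 2)
  n_atoms <- vapply(poses, nrow, integer(1))
  if (length(unique(n_atoms)) != 1) {
    stop("poses differ in atom count: ",
         paste(unique(n_atoms), collapse = ", "))
  }
  n <- length(poses)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- rmsd(poses[[i]], poses[[j]])
    }
  }
  m
}

#' Cluster poses at the adaptive cutoff and rank by best score
#'
#' Average-linkage agglomerative clustering of the pose distance
#' matrix, cut at height `d_c`; clusters are ordered by ascending best
#' member score (lower = better binding), members within a cluster by
#' score.
#'
#' @param dmat symmetric pose distance matrix.
#' @param d_c merging cutoff in Angstrom (see [adaptive_cutoff()]).
#' @param scores docking score per pose (lower = better).
#' @param linkage linkage criterion (default "average").
#' @return object of class `pose_cluster_set`: data.frame `clusters`
#'   (rank, size, best_score, best_pose), `membership` (pose -> rank),
#'   `d_c`.
#' @export
cluster_and_rank_poses <- function(dmat, d_c, scores,
                                   linkage = "average") {
  dmat <- as.matrix(dmat)
  stopifnot(isSymmetric(unname(dmat), tol = 1e-8),
            length(scores) == nrow(dmat))
  n <- nrow(dmat)
  raw <- if (n == 1) rep(1L, 1) else {
    hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
    stats::cutree(hc, h = d_c)
  }
  best <- vapply(seq_len(max(raw)), function(k) {
    min(scores[raw == k])
  }, numeric(1))
  ord <- order(best, seq_along(best))  # ascending best score, stable
  rank_of_raw <- match(seq_along(best), ord)
  membership <- rank_of_raw[raw]
  clusters <- data.frame(
    rank = seq_along(ord),
    size = as.integer(table(factor(membership,
                                   levels = seq_along(ord)))),
    best_score = best[ord],
    best_pose = vapply(ord, function(k) {
      cand <- which(raw == k)
      cand[which.min(scores[cand])]
    }, integer(1)))
  structure(list(clusters = clusters, membership = membership,
                 d_c = as.numeric(d_c)),
            class = "pose_cluster_set")
}

#' @export
print.pose_cluster_set <- function(x, ...) {
  cat("Pose clusters (d_c =", x$d_c, "A):", nrow(x$clusters),
      "clusters\n")
  print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Write a ranked pose-cluster report (tab-separated)
#' @param set `pose_cluster_set`.
#' @param path output path.
#' @export
write_pose_report <- function(set, path) {
  rep <- cbind(set$clusters, d_c = set$d_c)
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
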
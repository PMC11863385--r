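# Two-stage clustering of trajectories in collective-variable space:
# the pocket-gyration axis is cut into equal-width slices, cluster
# counts are allocated proportionally (with a minimum of two per
# populated slice, enforced by inflating the total), hierarchical
# agglomerative clustering seeds each slice, and a deterministic
# k-means refinement polishes the whole partition. Representatives are
# the frames nearest their centroid. The procedure is deterministic:
# there is no randomized initialization anywhere.

#' Slice frames by the pocket gyration radius
#'
#' Equal-width bins spanning the observed range of the given CV column;
#' intervals are half-open on the right except the last, so boundary
#' values fall in the higher slice and the maximum is kept.
#'
#' @param series `cv_series`.
#' @param rog_col name or index of the gyration column (default 1).
#' @param n_slices number of slices (default 30).
#' @return list with `slice` (per-frame index in `1..n_slices`) and
#'   `breaks` (slice boundaries, length `n_slices + 1`).
#' @export
slice_by_rog <- function(series, rog_col = 1, n_slices = 30) {
  stopifnot(n_slices >= 1)
  v <- series$values[, rog_col]
  rng <- range(v)
  if (diff(rng) == 0) stop("constant gyration column cannot be sliced")
  breaks <- seq(rng[1], rng[2], length.out = n_slices + 1)
  # half-open on the right: index of the last break <= v
  idx <- pmin(findInterval(v, breaks, rightmost.closed = FALSE), n_slices)
  list(slice = idx, breaks = breaks)
}

.round_half_away <- function(x) floor(x + 0.5)

#' Allocate per-slice cluster counts
#'
#' Proportional allocation x_i = round((N_i / N_tot) * N_c), clipped to
#' the slice size. Any populated slice (>= 2 frames) must receive at
#' least two clusters; while one does not, the total is inflated by
#' `increment` and the allocation recomputed. Slices with fewer than 2
#' frames are exempt (they keep one cluster per frame), otherwise the
#' iteration could not terminate.
#'
#' @param sizes frames per slice (N_i), zeros allowed.
#' @param base starting total cluster count N_c (default 100).
#' @param increment inflation step (default 10).
#' @return list with `x` (per-slice counts), `n_c` (final total
#'   target), `base`, `sizes`, `exempt` (logical per slice).
#' @export
allocate_cluster_counts <- function(sizes, base = 100, increment = 10) {
  sizes <- as.numeric(sizes)
  n_tot <- sum(sizes)
  stopifnot(n_tot >= 1, base >= 1, increment >= 1)
  exempt <- sizes < 2
  n_c <- base
  repeat {
    x <- pmin(.round_half_away(sizes / n_tot * n_c), sizes)
    x[exempt] <- sizes[exempt]
    if (all(x[!exempt] >= 2)) break
    n_c <- n_c + increment
  }
  if (any(exempt & sizes > 0)) {
    message("slice(s) with a single frame are exempt from the ",
            ">=2-clusters rule: ", sum(exempt & sizes > 0), " singleton(s)")
  }
  list(x = x, n_c = n_c, base = base, sizes = sizes, exempt = exempt)
}

# standardize CV columns to zero mean / unit variance over all frames;
# constant columns are left centered only
.standardize <- function(values) {
  mu <- colMeans(values)
  sd <- apply(values, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  scale(values, center = mu, scale = sd)
}

#' Hierarchical seeding stage
#'
#' Complete-linkage agglomerative clustering of the frames of each
#' slice in standardized CV space, cut at the allocated count; labels
#' are globally unique across slices.
#'
#' @param series `cv_series`.
#' @param slices result of [slice_by_rog()].
#' @param allocation result of [allocate_cluster_counts()].
#' @param linkage linkage criterion for `stats::hclust`
#'   (default "complete").
#' @return object of class `cluster_result`: `labels` (per frame),
#'   `centroids` (clusters x CVs, standardized space), `stage`.
#' @export
hierarchical_seed_clusters <- function(series, slices, allocation,
                                       linkage = "complete") {
  z <- .standardize(series$values)
  labels <- integer(nrow(z))
  offset <- 0L
  for (s in seq_along(allocation$sizes)) {
    idx <- which(slices$slice == s)
    if (length(idx) == 0) next
    k <- allocation$x[s]
    if (k > length(idx)) {
      warning("slice ", s, ": allocation ", k, " clipped to ",
              length(idx), " frames")
      k <- length(idx)
    }
    if (length(idx) == 1 || k == length(idx)) {
      labels[idx] <- offset + seq_along(idx)
      offset <- offset + length(idx)
    } else {
      hc <- stats::hclust(stats::dist(z[idx, , drop = FALSE]),
                          method = linkage)
      cl <- stats::cutree(hc, k = k)
      labels[idx] <- offset + cl
      offset <- offset + max(cl)
    }
  }
  .cluster_result(labels, z, stage = "hierarchical-seed")
}

.cluster_result <- function(labels, z, stage) {
  ids <- sort(unique(labels))
  cent <- t(vapply(ids, function(k) {
    colMeans(z[labels == k, , drop = FALSE])
  }, numeric(ncol(z))))
  # relabel 1..K in centroid order
  labels <- match(labels, ids)
  structure(list(labels = labels, centroids = cent, stage = stage),
            class = "cluster_result")
}

#' Deterministic k-means refinement from given seeds
#'
#' Lloyd iterations in the same standardized CV space as the seeding
#' stage, started from the seed centroids. The cluster count is
#' preserved: a cluster that empties is re-seeded with the frame
#' farthest from its current centroid. Ties in assignment go to the
#' lower cluster index, so the result is deterministic.
#'
#' @param series `cv_series`.
#' @param seed `cluster_result` from the seeding stage (its centroids
#'   are the starting points).
#' @param max_iter iteration cap (default 10000).
#' @return `cluster_result` (stage "kmeans-refined") with an extra
#'   `iterations` element.
#' @export
kmeans_refine <- function(series, seed, max_iter = 10000) {
  z <- .standardize(series$values)
  cent <- seed$centroids
  k <- nrow(cent)
  labels_prev <- integer(nrow(z))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(z^2), rowSums(cent^2), "+") - 2 * z %*% t(cent)
    labels <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(labels))
    for (e in empty) {
      far <- which.max(d2[cbind(seq_len(nrow(z)), labels)])
      labels[far] <- e
    }
    for (j in seq_len(k)) {
      cent[j, ] <- colMeans(z[labels == j, , drop = FALSE])
    }
    if (identical(labels, labels_prev) || iter >= max_iter) break
    labels_prev <- labels
  }
  out <- .cluster_result(labels, z, stage = "kmeans-refined")
  out$iterations <- iter
  out
}

#' Run the full two-stage clustering pipeline
#'
#' @param series `cv_series`.
#' @param rog_col gyration column (default 1).
#' @param n_slices slices along the gyration axis (default 30).
#' @param base target total cluster count N_c (default 100).
#' @param increment inflation step for the >=2-per-slice rule.
#' @param linkage hierarchical linkage (default "complete").
#' @param max_iter k-means iteration cap (default 10000).
#' @return `cluster_result` with `slices` and `allocation` attached.
#' @export
cluster_cv_series <- function(series, rog_col = 1, n_slices = 30,
                              base = 100, increment = 10,
                              linkage = "complete", max_iter = 10000) {
  slices <- slice_by_rog(series, rog_col, n_slices)
  alloc <- allocate_cluster_counts(tabulate(slices$slice, n_slices),
                                   base, increment)
  seed <- hierarchical_seed_clusters(series, slices, alloc, linkage)
  out <- kmeans_refine(series, seed, max_iter)
  out$slices <- slices
  out$allocation <- alloc
  out
}

#' Extract representative frames per cluster
#'
#' The representative of a cluster is its member frame closest to the
#' cluster centroid in standardized CV space (earliest frame on ties).
#'
#' @param result `cluster_result`.
#' @param series `cv_series` the clustering was run on.
#' @param traj optional `trajectory` aligned with the series rows; when
#'   given, the representative structures are returned too.
#' @return list with `manifest` (data.frame: cluster, frame, size, one
#'   column per CV) and, if `traj` given, `structures` (list of `pdb`).
#' @export
extract_representatives <- function(result, series, traj = NULL) {
  z <- .standardize(series$values)
  if (!is.null(traj) && n_frames(traj) != nrow(z)) {
    stop("trajectory frames do not align with series rows")
  }
  k <- nrow(result$centroids)
  rep_frame <- vapply(seq_len(k), function(j) {
    members <- which(result$labels == j)
    d2 <- rowSums((z[members, , drop = FALSE] -
                     matrix(result$centroids[j, ], length(members),
                            ncol(z), byrow = TRUE))^2)
    members[which.min(d2)]  # which.min returns the first minimum
  }, integer(1))
  manifest <- data.frame(cluster = seq_len(k), frame = rep_frame,
                         size = tabulate(result$labels, k),
                         series$values[rep_frame, , drop = FALSE],
                         check.names = FALSE)
  out <- list(manifest = manifest)
  if (!is.null(traj)) {
    out$structures <- lapply(rep_frame, function(i) {
      set_coords(traj$topology, frame_coords(traj, i))
    })
  }
  out
}

#' Write a cluster manifest as a tab-separated table
#' @param reps result of [extract_representatives()].
#' @param path output path.
#' @export
write_cluster_manifest <- function(reps, path) {
  utils::write.table(reps$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
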
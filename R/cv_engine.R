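# Binding-site shape collective variables: pocket radius of gyration,
# contacts across inertia planes (CIP) and inter-domain contacts (cRD),
# evaluated on single structures or trajectories.

#' Rational switching-function parameters
#'
#' The contact CVs count pairs through the rational switching function
#' s(r) = (1 - x^n) / (1 - x^m) with x = (r - d0)/r0, the form used by
#' the `coordination` facility of metadynamics engines.
#'
#' @param r0 switching radius in Angstrom (default 4.5, a standard
#'   heavy-atom contact radius).
#' @param n,m integer exponents, `m > n > 0` (defaults 6/12).
#' @param d0 offset in Angstrom (default 0).
#' @return object of class `switching_params`.
#' @export
switching_params <- function(r0 = 4.5, n = 6, m = 12, d0 = 0) {
  stopifnot(r0 > 0, m > n, n > 0, d0 >= 0)
  structure(list(r0 = r0, n = n, m = m, d0 = d0), class = "switching_params")
}

#' Evaluate the rational switching function
#'
#' Monotone non-increasing in r; equals 1 for r <= d0, tends to 0 as
#' r grows; the removable singularity at x = 1 is filled with n/m.
#'
#' @param r distance(s) in Angstrom, `r >= 0`.
#' @param params `switching_params`.
#' @return values in `[0, 1]`, vectorized over `r`.
#' @export
switching_value <- function(r, params = switching_params()) {
  x <- (r - params$d0) / params$r0
  x <- pmax(x, 0)  # s = 1 inside the offset
  s <- ifelse(abs(x - 1) < 1e-9,
              params$n / params$m,
              (1 - x^params$n) / (1 - x^params$m))
  pmin(pmax(s, 0), 1)
}

#' Mass-weighted radius of gyration
#'
#' sqrt( sum_i w_i |r_i - r_center|^2 / sum_i w_i ) with the center
#' being the weighted centroid.
#'
#' @param xyz coordinate matrix (n x 3), Angstrom.
#' @param weights atom weights (masses by default usage); positive.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("empty coordinate set")
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  stopifnot(all(weights > 0), length(weights) == nrow(xyz))
  ctr <- colSums(xyz * weights) / sum(weights)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(weights * d2) / sum(weights))
}

#' Principal inertia frame of a point set
#'
#' Center is the unweighted geometric center; axes are the eigenvectors
#' of the (weighted) inertia tensor, sorted by ascending moment. Each
#' axis is flipped so its largest-magnitude component is positive,
#' giving a deterministic sign convention, and the third axis is set to
#' the cross product of the first two so the frame is right-handed.
#'
#' @param xyz coordinate matrix (n x 3), at least 3 non-collinear rows.
#' @param weights per-point weights (default unit).
#' @return list with `center`, `axes` (3x3, one axis per column) and
#'   `moments` (ascending).
#' @export
principal_inertia_frame <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("need at least 3 points for an inertia frame")
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  center <- colMeans(xyz)
  rel <- sweep(xyz, 2, colSums(xyz * weights) / sum(weights))
  r2 <- rowSums(rel^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(weights * ((a == b) * r2 - rel[, a] * rel[, b]))
  }
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  moments <- e$values[ord]
  axes <- e$vectors[, ord, drop = FALSE]
  if (moments[3] < 1e-9 * max(1, moments[1]) || qr(rel)$rank < 2) {
    stop("degenerate point set: points are collinear or coincident")
  }
  for (k in 1:3) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  cross <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
             axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
             axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  axes[, 3] <- cross  # right-handed; may override the flip convention
  list(center = center, axes = axes, moments = moments)
}

#' Partition site residues across an inertia plane
#'
#' Residues are assigned by the sign of the projection of their
#' heavy-atom geometric center onto the plane normal; zero projections
#' go to group A.
#'
#' @param pdb structure.
#' @param site `site_definition`.
#' @param axis plane normal (unit 3-vector).
#' @param center point on the plane (3-vector).
#' @return list with `group_a` and `group_b` residue id vectors.
#' @export
partition_residues_across_plane <- function(pdb, site, axis, center) {
  stopifnot(abs(sqrt(sum(axis^2)) - 1) < 1e-6)
  ctrs <- .residue_centers(pdb, site$residues)
  proj <- as.numeric(sweep(ctrs, 2, center) %*% axis)
  ga <- site$residues[proj <= 0]
  gb <- site$residues[proj > 0]
  if (length(ga) == 0 || length(gb) == 0) {
    warning("plane does not separate the site: one group is empty")
  }
  list(group_a = ga, group_b = gb)
}

#' Switching-function coordination number between two atom groups
#'
#' Sum of the switching value over all cross pairs; a smooth count of
#' contacts between the groups, bounded by `nrow(a) * nrow(b)`.
#'
#' @param a,b coordinate matrices of the two (disjoint) groups.
#' @param params `switching_params`.
#' @export
coordination_number <- function(a, b, params = switching_params()) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("empty group in coordination number")
    return(0)
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sum(switching_value(sqrt(pmax(d2, 0)), params))
}

# ---- CV definitions --------------------------------------------------------

#' Define a collective variable over fixed atom groups
#'
#' @param name CV label.
#' @param kind "ROG" (radius of gyration of group A), "CIP" (contacts
#'   across an inertia plane) or "CRD" (contacts between quasi-rigid
#'   domains); CIP/CRD need two disjoint groups and switching params.
#' @param group_a,group_b atom row indices into the structure.
#' @param weights per-atom weights for ROG (masses or unit).
#' @param switching `switching_params` for CIP/CRD.
#' @param meta free-form list (residue lists, plane normal, ...) kept
#'   for the audit log.
#' @return object of class `cv_definition`.
#' @export
cv_definition <- function(name, kind, group_a, group_b = integer(0),
                          weights = NULL, switching = NULL, meta = list()) {
  kind <- match.arg(kind, c("ROG", "CIP", "CRD"))
  stopifnot(length(group_a) > 0)
  if (kind != "ROG") {
    stopifnot(length(group_b) > 0)
    if (length(intersect(group_a, group_b))) {
      stop("CV groups must be disjoint")
    }
    if (is.null(switching)) switching <- switching_params()
  }
  structure(list(name = name, kind = kind, group_a = group_a,
                 group_b = group_b, weights = weights,
                 switching = switching, meta = meta),
            class = "cv_definition")
}

#' Evaluate one CV on a coordinate matrix
#' @param cv `cv_definition`.
#' @param xyz full-structure coordinate matrix (all atoms).
#' @export
evaluate_cv <- function(cv, xyz) {
  switch(cv$kind,
    ROG = radius_of_gyration(xyz[cv$group_a, , drop = FALSE], cv$weights),
    CIP = ,
    CRD = coordination_number(xyz[cv$group_a, , drop = FALSE],
                              xyz[cv$group_b, , drop = FALSE],
                              cv$switching))
}

#' Evaluate a set of CVs along a trajectory
#'
#' @param traj `trajectory` whose atom order matches the CV atom
#'   indices (checked before any frame is processed).
#' @param cvs list of `cv_definition` objects.
#' @return object of class `cv_series`: list with `values` (frames x
#'   CVs matrix, CV names as column names) and `times` (ps).
#' @export
evaluate_cv_series <- function(traj, cvs) {
  stopifnot(inherits(traj, "trajectory"))
  n_atoms <- dim(traj$coords)[2]
  max_idx <- max(unlist(lapply(cvs, function(cv) c(cv$group_a, cv$group_b))))
  if (max_idx > n_atoms) {
    stop("CV atom indices exceed trajectory atom count (", n_atoms, ")")
  }
  vals <- t(vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    vapply(cvs, evaluate_cv, numeric(1), xyz = xyz)
  }, numeric(length(cvs))))
  colnames(vals) <- vapply(cvs, `[[`, character(1), "name")
  cv_series(vals, traj$times)
}

#' Construct a CV series container
#' @param values frames x CVs numeric matrix with column names.
#' @param times frame times in ps.
#' @export
cv_series <- function(values, times = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("CV series contains missing values")
  if (is.null(times)) times <- (seq_len(nrow(values)) - 1) * 10
  stopifnot(length(times) == nrow(values))
  structure(list(values = values, times = times), class = "cv_series")
}

#' Write a CV series as a COLVAR-style tab-separated file
#' @param series `cv_series`.
#' @param path output path.
#' @export
write_cv_series <- function(series, path) {
  tab <- data.frame(time = series$times, series$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a COLVAR-style tab-separated CV series
#' @param path input path (header row: time + one column per CV).
#' @export
read_cv_series <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  cv_series(as.matrix(tab[, -1, drop = FALSE]), tab[[1]])
}
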
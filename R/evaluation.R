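# Holo-likeness evaluation: binding-site RMSD after selection
# alignment, per-residue bound-like flags, binned/spline RMSD
# distributions, ensemble summary tables, and fraction of native
# contacts for docking poses.

# coordinates of the site selection, matched atom-by-atom between two
# structures (error listing any atoms missing on either side)
.matched_site_coords <- function(model, reference, site, subset) {
  key <- function(p) {
    idx <- atom_indices(p, site$residues, subset)
    stats::setNames(idx, paste(p$atoms$resid[idx], p$atoms$name[idx]))
  }
  km <- key(model); kr <- key(reference)
  miss <- c(setdiff(names(kr), names(km)), setdiff(names(km), names(kr)))
  if (length(miss)) {
    stop("atoms missing from one structure: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ..." else "")
  }
  common <- names(kr)
  list(model = atom_coords(model, km[common]),
       reference = atom_coords(reference, kr[common]),
       names = common)
}

#' Binding-site RMSD after site superposition
#'
#' Superposes the site selection of the model onto the same selection
#' of the reference and returns the RMSD over that selection.
#'
#' @param model,reference `pdb` structures sharing residue/atom naming
#'   over the site.
#' @param site `site_definition`.
#' @param subset "heavy" (non-hydrogenous, default) or "CA".
#' @return RMSD in Angstrom.
#' @export
binding_site_rmsd <- function(model, reference, site,
                              subset = c("heavy", "CA")) {
  subset <- match.arg(subset)
  m <- .matched_site_coords(model, reference, site, subset)
  superpose(m$model, m$reference)$rmsd
}

#' Holo-like criteria
#' @param default_threshold heavy-atom RMSD threshold in Angstrom under
#'   which a residue counts as bound-like (default 2.0).
#' @param per_residue optional named vector of per-residue overrides
#'   (names are residue ids).
#' @export
holo_criteria <- function(default_threshold = 2.0, per_residue = NULL) {
  stopifnot(default_threshold > 0, all(per_residue > 0))
  structure(list(default_threshold = default_threshold,
                 per_residue = per_residue), class = "holo_criteria")
}

#' Per-residue bound-like flags after whole-site alignment
#'
#' One global superposition of the site heavy atoms; in that frame each
#' residue's heavy-atom RMSD is compared to its threshold. Whole-site
#' (not per-residue) alignment makes the flags sensitive to residue
#' placement, not just internal geometry.
#'
#' @param model,reference `pdb` structures.
#' @param site `site_definition`.
#' @param criteria `holo_criteria`.
#' @param charged_set residue names counted as charged for the split
#'   counts.
#' @return list with `flags` (named logical), `rmsd` (named numeric),
#'   `n_holo`, `n_site`, `n_holo_charged`, `n_charged`.
#' @export
per_residue_holo_flags <- function(model, reference, site,
                                   criteria = holo_criteria(),
                                   charged_set = CHARGED_RESIDUES) {
  m <- .matched_site_coords(model, reference, site, "heavy")
  fit <- superpose(m$model, m$reference)
  fitted <- apply_transform(m$model, fit)
  res_of_atom <- sub(" [^ ]+$", "", m$names)
  res_rmsd <- vapply(site$residues, function(r) {
    rows <- which(res_of_atom == r)
    rmsd(fitted[rows, , drop = FALSE], m$reference[rows, , drop = FALSE])
  }, numeric(1))
  thr <- rep(criteria$default_threshold, length(site$residues))
  names(thr) <- site$residues
  if (!is.null(criteria$per_residue)) {
    thr[names(criteria$per_residue)] <- criteria$per_residue
  }
  flags <- res_rmsd <= thr
  charge <- classify_residue_charge(reference, site, charged_set)
  list(flags = flags, rmsd = res_rmsd,
       n_holo = sum(flags), n_site = length(flags),
       n_holo_charged = sum(flags[charge$charged]),
       n_charged = length(charge$charged))
}

#' Binned and spline-smoothed RMSD distribution
#'
#' Histogram with fixed-width bins normalized to unit area, then
#' interpolated with a cubic spline on a regular grid; negative
#' overshoot is clipped to zero and the curve renormalized to unit
#' area on its grid.
#'
#' @param values RMSD values (>= 2 distinct).
#' @param bin_width bin width in Angstrom (default 0.2).
#' @param points_per_angstrom spline grid density (default 20, i.e.
#'   0.05 A spacing).
#' @return data.frame with `x` (Angstrom) and `density`.
#' @export
rmsd_distribution <- function(values, bin_width = 0.2,
                              points_per_angstrom = 20) {
  if (length(values) == 0) stop("empty input")
  if (length(unique(values)) < 2) {
    # single occupied bin: return it without a spline
    lo <- floor(min(values) / bin_width) * bin_width
    return(data.frame(x = lo + bin_width / 2, density = 1 / bin_width))
  }
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  sp <- stats::splinefun(h$mids, h$density, method = "natural")
  grid <- seq(lo, hi, by = 1 / points_per_angstrom)
  d <- pmax(sp(grid), 0)
  area <- sum((d[-1] + d[-length(d)]) / 2) / points_per_angstrom
  if (area > 0) d <- d / area
  data.frame(x = grid, density = d)
}

#' Native ligand-protein contact set of a reference complex
#'
#' All (ligand heavy atom, protein heavy atom) pairs within the cutoff
#' shell in the reference complex.
#'
#' @param reference `pdb` holding both protein and ligand.
#' @param ligand ligand residue identifier.
#' @param cutoff shell radius in Angstrom (default 5).
#' @return object of class `contact_set`: data.frame of pairs
#'   (`ligand_atom`, `protein_atom` as "resid|name" keys) plus the
#'   `cutoff` attribute.
#' @export
native_contact_set <- function(reference, ligand, cutoff = 5) {
  if (!ligand %in% reference$resids) stop("ligand not found: ", ligand)
  lig_idx <- atom_indices(reference, ligand, "heavy")
  prot_res <- setdiff(residue_ids(reference, protein_only = TRUE), ligand)
  prot_idx <- atom_indices(reference, prot_res, "heavy")
  a <- reference$atoms
  lx <- atom_coords(reference, lig_idx)
  px <- atom_coords(reference, prot_idx)
  d2 <- outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * lx %*% t(px)
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) warning("no contacts within ", cutoff, " A")
  key <- function(i) paste(a$resid[i], a$name[i], sep = "|")
  pairs <- data.frame(
    ligand_atom = key(lig_idx[hits[, 1]]),
    protein_atom = key(prot_idx[hits[, 2]]),
    stringsAsFactors = FALSE)
  structure(pairs[order(pairs$ligand_atom, pairs$protein_atom), ,
                  drop = FALSE],
            cutoff = cutoff, class = c("contact_set", "data.frame"))
}

#' Fraction of native contacts recovered by a model complex
#'
#' Fraction of the reference contact pairs whose distance in the model
#' is within the contact set's cutoff. Distance-based, hence invariant
#' to rigid transforms of the model.
#'
#' @param model `pdb` model complex with the same atom identities.
#' @param contacts `contact_set` from [native_contact_set()].
#' @return F_nat in `[0, 1]` (0 with a warning for an empty set).
#' @export
fraction_native_contacts <- function(model, contacts) {
  if (nrow(contacts) == 0) {
    warning("empty contact set: F_nat defined as 0")
    return(0)
  }
  cutoff <- attr(contacts, "cutoff")
  a <- model$atoms
  akey <- paste(a$resid, a$name, sep = "|")
  i <- match(contacts$ligand_atom, akey)
  j <- match(contacts$protein_atom, akey)
  if (anyNA(i) || anyNA(j)) {
    miss <- unique(c(contacts$ligand_atom[is.na(i)],
                     contacts$protein_atom[is.na(j)]))
    stop("model is missing contact atoms: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
  mean(d <= cutoff)
}

#' Ensemble summary percentages
#'
#' For each metric (a vector of per-frame RMSD values), the percentage
#' of frames below each threshold and the minimum, reported to one
#' decimal as in standard ensemble-quality tables.
#'
#' @param metrics named list of numeric vectors (per-frame RMSD per
#'   metric, e.g. protein CA, each binding site's heavy atoms).
#' @param thresholds thresholds in Angstrom (default `c(2, 2.5)`).
#' @return data.frame: metric, one `pct_below_*` column per threshold,
#'   `min`.
#' @export
ensemble_summary <- function(metrics, thresholds = c(2, 2.5)) {
  stopifnot(length(metrics) >= 1)
  rows <- lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]
    stopifnot(length(v) >= 1)
    pct <- vapply(thresholds, function(thr) {
      round(100 * mean(v < thr), 1)
    }, numeric(1))
    out <- data.frame(metric = nm, t(pct), min = round(min(v), 1))
    names(out)[2:(1 + length(thresholds))] <-
      paste0("pct_below_", thresholds)
    out
  })
  do.call(rbind, rows)
}

#' Write an ensemble summary table (tab-separated)
#' @param summary data.frame from [ensemble_summary()].
#' @param path output path.
#' @export
write_summary_table <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
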
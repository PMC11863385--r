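# Structure input/output, residue selections and rigid-body superposition.
#
# Structures are stored as an S3 object of class "pdb": a list with an
# `atoms` data.frame (one row per atom) and a `resids` character vector
# giving the unique residue identifiers ("chain:resno[icode]") in file
# order. No installed package reads PDB files, so the fixed-width
# ATOM/HETATM parser lives here.

.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  "NA" = 22.99, K = 39.098, CL = 35.45, CA = 40.078, MN = 54.938
)

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Charged residue names used by default throughout the package
#'
#' Titratable side chains at neutral pH, excluding the ambiguous
#' histidine. Override via the `charged_set` argument of
#' [classify_residue_charge()].
#' @export
CHARGED_RESIDUES <- c("ASP", "GLU", "LYS", "ARG")

.infer_element <- function(name) {
  # strip leading digits (e.g. "1HG1"), take leading alpha run
  core <- sub("^[0-9]+", "", trimws(name))
  two <- toupper(substr(core, 1, 2))
  one <- toupper(substr(core, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "SE", "CL", "MN"), two, one)
}

.mass_of <- function(element) {
  m <- .ATOMIC_MASSES[toupper(element)]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon-like
  unname(m)
}

.make_resid <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  ch <- ifelse(is.na(chain) | chain == " ", "_", chain)
  paste0(ch, ":", resno, ins)
}

.new_pdb <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  atoms$resid <- .make_resid(atoms$chain, atoms$resno, atoms$insert)
  structure(list(atoms = atoms, resids = unique(atoms$resid)),
            class = "pdb")
}

#' Build a structure from an atom table
#'
#' Programmatic constructor used by the synthetic fixtures and by tests.
#'
#' @param name,resname,chain,resno atom name, residue name, chain id and
#'   residue number vectors (recycled against the coordinate rows).
#' @param xyz numeric matrix (n x 3), coordinates in Angstrom.
#' @param element optional element symbols; inferred from atom names if
#'   missing.
#' @param record "ATOM" or "HETATM" per atom.
#' @return an object of class `pdb`.
#' @export
make_structure <- function(name, resname, chain, resno, xyz,
                           element = NULL, record = "ATOM") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  n <- nrow(xyz)
  if (is.null(element)) element <- .infer_element(name)
  atoms <- data.frame(
    record = rep_len(record, n),
    serial = seq_len(n),
    name = rep_len(name, n),
    altloc = "",
    resname = rep_len(resname, n),
    chain = rep_len(chain, n),
    resno = rep_len(resno, n),
    insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1,
    element = rep_len(element, n),
    stringsAsFactors = FALSE
  )
  atoms$mass <- .mass_of(atoms$element)
  atoms$is_hydrogen <- toupper(atoms$element) == "H"
  atoms$is_backbone <- atoms$name %in% .BACKBONE_NAMES & atoms$record == "ATOM"
  .new_pdb(atoms)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM and HETATM records of the first model; ligands are kept
#' as distinct residues. Alternate locations are resolved by keeping the
#' highest-occupancy conformer of each atom.
#'
#' @param path path to a PDB file.
#' @param model model number to read from a multi-model file (default 1).
#' @return an object of class `pdb`.
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- .split_models(lines)
  if (model > length(models)) {
    stop("model ", model, " requested but file has ", length(models))
  }
  atoms <- .parse_atom_lines(models[[model]], path)
  if (nrow(atoms) == 0) stop("no ATOM/HETATM records in ", path)
  atoms <- .resolve_altloc(atoms)
  .new_pdb(atoms)
}

.split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends[seq_along(starts)],
         SIMPLIFY = FALSE)
}

.parse_atom_lines <- function(lines, path = "<text>") {
  keep <- grepl("^(ATOM  |HETATM)", lines)
  rec <- lines[keep]
  if (length(rec) == 0) {
    return(data.frame())
  }
  rec <- formatC(rec, width = 80, flag = "-")  # pad short lines
  f <- function(a, b) substr(rec, a, b)
  xyz <- suppressWarnings(cbind(as.numeric(f(31, 38)),
                                as.numeric(f(39, 46)),
                                as.numeric(f(47, 54))))
  if (anyNA(xyz)) {
    bad <- which(apply(is.na(xyz), 1, any))[1]
    stop("cannot parse coordinates in ", path, " at record: ",
         trimws(rec[bad]))
  }
  resno <- suppressWarnings(as.integer(f(23, 26)))
  if (anyNA(resno)) {
    stop("cannot parse residue number in ", path, " at record: ",
         trimws(rec[which(is.na(resno))[1]]))
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  element <- trimws(f(77, 78))
  name <- trimws(f(13, 16))
  element <- ifelse(element == "", .infer_element(name), element)
  atoms <- data.frame(
    record = trimws(f(1, 6)),
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = name,
    altloc = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    resno = resno,
    insert = trimws(f(27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    element = element,
    stringsAsFactors = FALSE
  )
  atoms$mass <- .mass_of(atoms$element)
  atoms$is_hydrogen <- toupper(atoms$element) == "H"
  atoms$is_backbone <- atoms$name %in% .BACKBONE_NAMES & atoms$record == "ATOM"
  atoms
}

.resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c("", " "))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    i[which.max(atoms$occupancy[i])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure to a PDB file
#' @param pdb object of class `pdb`.
#' @param path output path.
#' @export
write_structure <- function(pdb, path) {
  stopifnot(inherits(pdb, "pdb"))
  writeLines(c(.format_atom_records(pdb$atoms), "END"), path)
  invisible(path)
}

.format_atom_records <- function(a) {
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, a$serial %% 100000, name4, " ",
          a$resname, substr(paste0(a$chain, " "), 1, 1),
          a$resno, substr(paste0(a$insert, " "), 1, 1),
          a$x, a$y, a$z, a$occupancy, 0,
          toupper(a$element))
}

#' @export
print.pdb <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,", length(x$resids),
      "residues,", sum(!x$atoms$is_hydrogen), "heavy atoms\n")
  invisible(x)
}

# ---- residue-level helpers -------------------------------------------------

#' Residue identifiers of a structure
#' @param pdb object of class `pdb`.
#' @param protein_only drop HETATM-only residues (ligands, waters).
#' @return character vector of "chain:resno" identifiers in file order.
#' @export
residue_ids <- function(pdb, protein_only = FALSE) {
  if (!protein_only) return(pdb$resids)
  unique(pdb$atoms$resid[pdb$atoms$record == "ATOM"])
}

#' Atom row indices for a set of residues
#'
#' @param pdb object of class `pdb`.
#' @param resids residue identifiers.
#' @param subset one of "all", "heavy", "backbone", "CA".
#' @return integer vector of row indices into `pdb$atoms`.
#' @export
atom_indices <- function(pdb, resids = NULL,
                         subset = c("all", "heavy", "backbone", "CA")) {
  subset <- match.arg(subset)
  a <- pdb$atoms
  sel <- if (is.null(resids)) rep(TRUE, nrow(a)) else a$resid %in% resids
  sel <- sel & switch(subset,
    all = TRUE,
    heavy = !a$is_hydrogen,
    backbone = a$is_backbone,
    CA = a$name == "CA" & a$record == "ATOM")
  which(sel)
}

#' Coordinates of selected atoms
#' @param pdb object of class `pdb`.
#' @param idx atom row indices (default: all atoms).
#' @return numeric matrix (n x 3).
#' @export
atom_coords <- function(pdb, idx = NULL) {
  a <- pdb$atoms
  if (is.null(idx)) idx <- seq_len(nrow(a))
  cbind(x = a$x[idx], y = a$y[idx], z = a$z[idx])
}

#' Replace all atom coordinates
#' @param pdb object of class `pdb`.
#' @param xyz numeric matrix, one row per atom.
#' @return the modified `pdb`.
#' @export
set_coords <- function(pdb, xyz) {
  stopifnot(nrow(xyz) == nrow(pdb$atoms))
  pdb$atoms$x <- xyz[, 1]; pdb$atoms$y <- xyz[, 2]; pdb$atoms$z <- xyz[, 3]
  pdb
}

# geometric center of the heavy atoms of each residue
.residue_centers <- function(pdb, resids) {
  t(vapply(resids, function(r) {
    idx <- atom_indices(pdb, r, "heavy")
    colMeans(atom_coords(pdb, idx))
  }, numeric(3)))
}

# minimum heavy-atom distance from each residue in `from` to the residue
# set `to`
.min_dist_to_set <- function(pdb, from, to) {
  to_xyz <- atom_coords(pdb, atom_indices(pdb, to, "heavy"))
  vapply(from, function(r) {
    xyz <- atom_coords(pdb, atom_indices(pdb, r, "heavy"))
    d2 <- outer(rowSums(xyz^2), rowSums(to_xyz^2), "+") -
      2 * xyz %*% t(to_xyz)
    sqrt(max(0, min(d2)))
  }, numeric(1))
}

# ---- site definitions ------------------------------------------------------

#' Construct a binding-site definition
#' @param residues residue identifiers, order preserved, no duplicates.
#' @param provenance "user", "ligand-derived" or "merged-prediction".
#' @param pdb optional structure to validate residues against.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(residues, provenance = "user", pdb = NULL) {
  if (anyDuplicated(residues)) stop("duplicate residues in site definition")
  if (!is.null(pdb)) {
    missing <- setdiff(residues, pdb$resids)
    if (length(missing)) {
      stop("site residues absent from structure: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(residues = as.character(residues), provenance = provenance),
            class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("Binding site (", x$provenance, "): ", length(x$residues),
      " residues\n", sep = "")
  invisible(x)
}

#' Read a residue list file (one "chain:resnum" per line)
#' @param path input path; lines starting with `#` ignored.
#' @param provenance provenance tag for the returned site.
#' @export
read_site <- function(path, provenance = "user") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  site_definition(lines, provenance)
}

#' Write a residue list file
#' @param site `site_definition`.
#' @param path output path.
#' @export
write_site <- function(site, path) {
  writeLines(site$residues, path)
  invisible(path)
}

#' Define a binding site as the residue shell around a bound ligand
#'
#' Selects every protein residue having at least one non-hydrogenous
#' atom within `cutoff` of any non-hydrogenous ligand atom -- the
#' standard crystallographic definition of a ligand-binding region.
#'
#' @param pdb structure containing both protein and ligand.
#' @param ligand residue identifier of the ligand (e.g. `"A:215"`).
#' @param cutoff shell radius in Angstrom (default 3.5).
#' @return `site_definition` with provenance "ligand-derived".
#' @export
select_site_by_ligand <- function(pdb, ligand, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  if (!ligand %in% pdb$resids) stop("ligand residue not found: ", ligand)
  prot <- setdiff(residue_ids(pdb, protein_only = TRUE), ligand)
  d <- .min_dist_to_set(pdb, prot, ligand)
  hits <- prot[d <= cutoff]
  if (length(hits) == 0) {
    warning("no residues within ", cutoff, " A of ", ligand)
  }
  site_definition(hits, "ligand-derived")
}

#' Merge pocket-predictor sites into a consensus binding site
#'
#' Union of the residues of all predicted sites whose confidence score
#' passes `score_floor`; low-confidence predictions are discarded.
#'
#' @param sites list of `site_definition` objects.
#' @param scores numeric confidence scores in `[0, 1]`, one per site.
#' @param score_floor minimum score to retain a site (default 0.01).
#' @return `site_definition` with provenance "merged-prediction",
#'   residues ordered by residue number.
#' @export
merge_site_predictions <- function(sites, scores, score_floor = 0.01) {
  stopifnot(length(sites) == length(scores))
  keep <- scores >= score_floor
  if (!any(keep)) stop("no reliable site: all scores below ", score_floor)
  res <- unique(unlist(lapply(sites[keep], `[[`, "residues")))
  num <- as.integer(sub("^.*:", "", gsub("[A-Za-z]+$", "", res)))
  site_definition(res[order(num, res)], "merged-prediction")
}

#' Partition site residues into charged and other
#'
#' @param pdb structure.
#' @param site `site_definition`.
#' @param charged_set residue names considered charged
#'   (default [CHARGED_RESIDUES]: ASP/GLU/LYS/ARG).
#' @return list with `charged`, `other` (residue id vectors) and
#'   `fraction` (charged fraction of the site).
#' @export
classify_residue_charge <- function(pdb, site,
                                    charged_set = CHARGED_RESIDUES) {
  res <- site$residues
  if (length(res) == 0) {
    return(list(charged = character(0), other = character(0), fraction = NaN))
  }
  a <- pdb$atoms
  rn <- vapply(res, function(r) a$resname[match(r, a$resid)], character(1))
  known <- c(charged_set, "ALA", "GLY", "SER", "THR", "VAL", "LEU", "ILE",
             "PRO", "PHE", "TRP", "TYR", "MET", "CYS", "ASN", "GLN", "HIS")
  if (any(!rn %in% known)) {
    warning("unknown residue name(s) classified as 'other': ",
            paste(unique(rn[!rn %in% known]), collapse = ", "))
  }
  charged <- res[rn %in% charged_set]
  list(charged = charged, other = setdiff(res, charged),
       fraction = length(charged) / length(res))
}

# ---- domain maps -----------------------------------------------------------

#' Construct a quasi-rigid domain map
#' @param resids residue identifiers.
#' @param domains domain label per residue (e.g. CORE/LID/NMP).
#' @return named character vector (class `domain_map`).
#' @export
domain_map <- function(resids, domains) {
  stopifnot(length(resids) == length(domains))
  if (anyDuplicated(resids)) stop("residue mapped to more than one domain")
  structure(stats::setNames(as.character(domains), resids),
            class = "domain_map")
}

#' Read a domain map file (lines "chain:resnum<TAB>DOMAIN")
#' @param path input path.
#' @export
read_domain_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("resid", "domain"),
                           stringsAsFactors = FALSE)
  domain_map(tab$resid, tab$domain)
}

#' Write a domain map file
#' @param dm `domain_map`.
#' @param path output path.
#' @export
write_domain_map <- function(dm, path) {
  writeLines(paste(names(dm), unclass(dm), sep = "\t"), path)
  invisible(path)
}

# ---- superposition ---------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over corresponding
#' rows; reflections are corrected so the rotation is proper.
#'
#' @param mobile,reference numeric matrices (n x 3), corresponding rows.
#' @return list with `rotation` (3x3, det +1), `translation`
#'   (length-3) and `rmsd` (Angstrom). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    stop("coordinate sets differ in size")
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2) stop("degenerate (collinear) point set")
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param xyz numeric matrix (n x 3).
#' @param fit result of [superpose()].
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' RMSD between two coordinate sets without fitting
#' @param a,b corresponding coordinate matrices.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(sum((a - b)^2) / nrow(a))
}

# ---- trajectories ----------------------------------------------------------

#' Construct a trajectory object
#' @param coords 3D array `[frame, atom, xyz]` or list of coordinate
#'   matrices.
#' @param topology `pdb` structure with matching atom order.
#' @param times frame times in ps (default `0, 10, 20, ...` matching a
#'   10 ps save stride).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, topology, times = NULL) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(topology$atoms)) {
    stop("trajectory atom count (", dim(coords)[2],
         ") does not match topology (", nrow(topology$atoms), ")")
  }
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * 10
  structure(list(coords = coords, topology = topology, times = times),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj `trajectory`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) traj$coords[i, , , drop = TRUE]

#' Read a multi-model PDB file as a trajectory
#' @param path multi-model PDB path.
#' @param dt frame spacing in ps for the time axis (default 10).
#' @export
read_trajectory <- function(path, dt = 10) {
  lines <- readLines(path, warn = FALSE)
  models <- .split_models(lines)
  top <- read_structure(path, model = 1)
  coords <- lapply(models, function(m) {
    a <- .resolve_altloc(.parse_atom_lines(m, path))
    if (nrow(a) != nrow(top$atoms)) {
      stop("model atom count mismatch in ", path)
    }
    cbind(a$x, a$y, a$z)
  })
  trajectory(coords, top, times = (seq_along(models) - 1) * dt)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj `trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pdb <- traj$topology
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.format_atom_records(set_coords(pdb, frame_coords(traj, i))$atoms),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
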
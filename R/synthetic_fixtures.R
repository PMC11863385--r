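# Deterministic toy systems for testing every stage of the pipeline
# without downloads: a hinged three-domain protein whose two arms close
# over a central core (shrinking the binding-site gyration radius and
# raising interface contacts), open->closed trajectories, labeled CV
# mixtures and perturbed docking-pose bundles.
#
# Toy residues carry a minimal atom set (N, CA, C, O backbone plus one
# CB pseudo side-chain heavy atom) so heavy/backbone/CA selections are
# all distinct without full chemistry. There is no physical realism.

# run `expr` under a seed without touching the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification of the hinged toy protein
#'
#' Three quasi-rigid domains: a CORE (a 10-residue floor along x plus
#' two 4-residue walls) and two 10-residue arms (labels NMP and LID)
#' hinged at pivots beyond the floor ends. The hinge angle sweeps the
#' arms from raised (open) to folded over the core (closed); the
#' default geometry shrinks the site gyration radius by more than 20%
#' on closing.
#'
#' @param arm_length residues per arm (default 10).
#' @param open_deg,closed_deg hinge angle from vertical, degrees
#'   (defaults 15 and 75).
#' @param charged_fraction fraction of site residues given charged
#'   names (default 11/32, realized exactly for the default site).
#' @return object of class `toy_protein_spec`.
#' @export
toy_protein_spec <- function(arm_length = 10, open_deg = 15,
                             closed_deg = 75,
                             charged_fraction = 11 / 32) {
  stopifnot(arm_length >= 6, closed_deg > open_deg,
            charged_fraction >= 0, charged_fraction <= 1)
  structure(list(arm_length = arm_length, open_deg = open_deg,
                 closed_deg = closed_deg,
                 charged_fraction = charged_fraction),
            class = "toy_protein_spec")
}

# CA positions and local chain directions for a closure fraction in
# [0, 1]; returns list of per-residue (resno, domain, ca, u = chain
# direction, z offset)
.toy_layout <- function(spec, closure = 0) {
  phi <- (spec$open_deg +
            closure * (spec$closed_deg - spec$open_deg)) * pi / 180
  n_arm <- spec$arm_length
  res <- list()
  add <- function(resno, domain, ca, u) {
    res[[length(res) + 1]] <<- list(resno = resno, domain = domain,
                                    ca = ca, u = u)
  }
  # arms: pivot at (-19, 0, +2.5) for NMP (inward = +x) and
  # (+19, 0, -2.5) for LID (inward = -x); direction from vertical by phi
  arm <- function(first_resno, domain, pivot, inward, zoff) {
    d <- c(inward * sin(phi), cos(phi), 0)
    for (j in seq_len(n_arm)) {
      add(first_resno + j - 1, domain,
          pivot + 3.8 * j * d + c(0, 0, zoff), d)
    }
  }
  arm(1, "NMP", c(-19, 0, 0), +1, +2.5)
  # floor: 10 CORE residues along x
  for (i in 1:10) {
    add(10 + i, "CORE", c(-17.1 + 3.8 * (i - 1), 0, 0), c(1, 0, 0))
  }
  # walls: 4 CORE residues flanking each arm on its closing side
  for (k in 1:4) add(20 + k, "CORE", c(-12.5, 2.6 * k, 0), c(0, 1, 0))
  for (k in 1:4) add(24 + k, "CORE", c(12.5, 2.6 * k, 0), c(0, 1, 0))
  arm(29, "LID", c(19, 0, 0), -1, -2.5)
  res
}

.toy_site_resnos <- function(spec) {
  n <- spec$arm_length
  c(1:n,                    # NMP arm
    21:28,                  # both walls
    14:17,                  # central floor
    28 + seq_len(n))        # LID arm
}

# charged resnos: chosen so each interface side keeps >= 2 nonadjacent
# charged and >= 2 nonadjacent uncharged residues
.toy_charged_resnos <- function(spec, n_charged) {
  pref <- c(1, 3, 29, 31, 21, 23, 25, 27, 6, 34, 15, 8, 36, 17, 22, 26)
  site <- .toy_site_resnos(spec)
  pref <- pref[pref %in% site]
  utils::head(unique(c(pref, setdiff(site, pref))), n_charged)
}

#' Build the hinged toy protein
#'
#' @param spec `toy_protein_spec`.
#' @param closure hinge closure fraction in `[0, 1]` (0 = open).
#' @return list with `structure` (`pdb`), `domains` (`domain_map`) and
#'   `site` (`site_definition`, 32 residues for the default spec,
#'   spanning both arm-core interfaces).
#' @export
make_hinged_toy_protein <- function(spec = toy_protein_spec(),
                                    closure = 0) {
  stopifnot(inherits(spec, "toy_protein_spec"),
            closure >= 0, closure <= 1)
  layout <- .toy_layout(spec, closure)
  site_resnos <- .toy_site_resnos(spec)
  n_charged <- round(spec$charged_fraction * length(site_resnos))
  charged <- .toy_charged_resnos(spec, n_charged)
  charged_names <- c("ASP", "LYS", "GLU", "ARG")
  other_names <- c("ALA", "GLY", "SER", "VAL", "LEU", "THR")
  name <- resname <- character(0)
  resno <- integer(0)
  xyz <- NULL
  for (r in layout) {
    rn <- if (r$resno %in% charged) {
      charged_names[(r$resno %% length(charged_names)) + 1]
    } else {
      other_names[(r$resno %% length(other_names)) + 1]
    }
    at <- rbind(N = r$ca - 1.2 * r$u,
                CA = r$ca,
                C = r$ca + 1.2 * r$u,
                O = r$ca + 1.2 * r$u + c(0, 0, 0.6),
                CB = r$ca + c(0, 0, 1.0))
    name <- c(name, rownames(at))
    resname <- c(resname, rep(rn, 5))
    resno <- c(resno, rep(r$resno, 5))
    xyz <- rbind(xyz, at)
  }
  pdb <- make_structure(name, resname, "A", resno, xyz,
                        element = substr(name, 1, 1))
  dm <- domain_map(paste0("A:", vapply(layout, `[[`, numeric(1), "resno")),
                   vapply(layout, `[[`, character(1), "domain"))
  site <- site_definition(paste0("A:", site_resnos), "user", pdb)
  list(structure = pdb, domains = dm, site = site)
}

#' Generate an open-to-closed trajectory of the toy protein
#'
#' Frame t is the toy at hinge closure `schedule[t]` plus seeded
#' Gaussian coordinate noise. Identical arguments give a byte-identical
#' trajectory; the caller's RNG state is untouched.
#'
#' @param spec `toy_protein_spec`.
#' @param n_frames number of frames (default 60).
#' @param schedule per-frame closure fractions in `[0, 1]` (default:
#'   linear 0 to 1).
#' @param sigma Gaussian coordinate noise, Angstrom (default 0.1).
#' @param seed RNG seed (mandatory).
#' @param dt frame spacing in ps (default 10, a typical save stride).
#' @return `trajectory`.
#' @export
make_open_close_trajectory <- function(spec = toy_protein_spec(),
                                       n_frames = 60, schedule = NULL,
                                       sigma = 0.1, seed, dt = 10) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(schedule)) {
    schedule <- seq(0, 1, length.out = n_frames)
  }
  stopifnot(length(schedule) == n_frames,
            all(schedule >= 0 & schedule <= 1), sigma >= 0)
  top <- make_hinged_toy_protein(spec, closure = 0)$structure
  n_atoms <- nrow(top$atoms)
  coords <- .with_seed(seed, {
    lapply(schedule, function(f) {
      xyz <- atom_coords(make_hinged_toy_protein(spec, f)$structure)
      xyz + matrix(stats::rnorm(n_atoms * 3, 0, sigma), n_atoms, 3)
    })
  })
  trajectory(coords, top, times = (seq_len(n_frames) - 1) * dt)
}

#' Generate a labeled CV series from a Gaussian mixture
#'
#' Ground truth for clustering parameter recovery: frames are drawn
#' from planted modes with recorded component labels.
#'
#' @param n_frames frames to draw.
#' @param means modes x CVs matrix of component means.
#' @param sds per-component scalar (or per-CV vector) standard
#'   deviations; recycled.
#' @param weights component weights, summing to 1.
#' @param seed RNG seed (mandatory).
#' @param cv_names CV column names (default `cv1..cvd`).
#' @return list with `series` (`cv_series`) and `labels` (true
#'   component per frame).
#' @export
make_labeled_cv_series <- function(n_frames, means, sds = 0.1,
                                   weights = NULL, seed,
                                   cv_names = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(abs(sum(weights) - 1) < 1e-8, length(weights) == k)
  sds <- matrix(rep_len(sds, k * d), k, d, byrow = FALSE)
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  out <- .with_seed(seed, {
    labels <- sample.int(k, n_frames, replace = TRUE, prob = weights)
    vals <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_frames * d), n_frames, d) *
        sds[labels, , drop = FALSE]
    list(labels = labels, vals = vals)
  })
  colnames(out$vals) <- cv_names
  list(series = cv_series(out$vals), labels = out$labels)
}

#' Generate bundles of perturbed docking poses with synthetic scores
#'
#' Bundle b is the reference pose displaced by `(b - 1) * separation`
#' along x, each member jittered by Gaussian noise of the bundle's
#' scale, so within-bundle RMSD is far below between-bundle RMSD by
#' construction. Scores are drawn so `best_bundle` holds the global
#' best (lowest) score.
#'
#' @param reference_pose ligand heavy-atom coordinate matrix (n x 3).
#' @param counts poses per bundle.
#' @param scales per-bundle jitter scale, Angstrom.
#' @param separation bundle spacing along x, Angstrom (default 10).
#' @param best_bundle bundle holding the best score (default 1).
#' @param seed RNG seed (mandatory).
#' @return list with `poses` (list of coordinate matrices), `labels`
#'   (true bundle per pose) and `scores`.
#' @export
make_perturbed_pose_set <- function(reference_pose, counts, scales,
                                    separation = 10, best_bundle = 1,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(counts) == length(scales), best_bundle <= length(counts))
  ref <- as.matrix(reference_pose)
  n_at <- nrow(ref)
  .with_seed(seed, {
    poses <- list(); labels <- integer(0); scores <- numeric(0)
    for (b in seq_along(counts)) {
      for (i in seq_len(counts[b])) {
        jitter <- matrix(stats::rnorm(n_at * 3, 0, scales[b]), n_at, 3)
        poses[[length(poses) + 1]] <-
          sweep(ref + jitter, 2, c((b - 1) * separation, 0, 0), "+")
        labels <- c(labels, b)
        # bundle scores live in disjoint unit bands; the designated
        # bundle is shifted below all others
        base <- if (b == best_bundle) -10 else b
        scores <- c(scores, base + stats::runif(1))
      }
    }
    list(poses = poses, labels = labels, scores = scores)
  })
}
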
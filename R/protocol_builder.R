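# Automated enhanced-sampling setup: build the binding-site CV set from
# structure + site + quasi-rigid domain map, apply the charged-split
# rule, estimate hill widths from a short unbiased run, build the
# pocket-contraction restraint schedule and emit a complete
# well-tempered metadynamics input deck.

#' Build the pocket-shape CV set (RoG + three CIPs)
#'
#' One radius-of-gyration CV over the site backbone atoms
#' (mass-weighted) plus three contact CVs, one per inertia plane of the
#' site's heavy atoms; each plane partitions the site residues into the
#' two contact groups. The inertia frame is computed once on the input
#' (apo) structure and frozen, since biasing requires fixed atom groups.
#'
#' @param pdb apo structure.
#' @param site `site_definition` with at least 3 residues.
#' @param switching `switching_params` shared by the CIP CVs.
#' @param mass_weighted_rog mass-weight the gyration CV (default TRUE).
#' @return list with `cvs` (list of 4 `cv_definition`) and `audit`
#'   (character log of the partition decisions).
#' @export
build_binding_site_cvs <- function(pdb, site,
                                   switching = switching_params(),
                                   mass_weighted_rog = TRUE) {
  stopifnot(length(site$residues) >= 3)
  bb <- atom_indices(pdb, site$residues, "backbone")
  heavy <- atom_indices(pdb, site$residues, "heavy")
  w <- if (mass_weighted_rog) pdb$atoms$mass[bb] else rep(1, length(bb))
  rog <- cv_definition("rog_bs", "ROG", bb, weights = w,
                       meta = list(residues = site$residues))
  frame <- principal_inertia_frame(atom_coords(pdb, heavy),
                                   pdb$atoms$mass[heavy])
  audit <- character(0)
  cips <- lapply(1:3, function(k) {
    ax <- frame$axes[, k]
    part <- partition_residues_across_plane(pdb, site, ax, frame$center)
    audit <<- c(audit, sprintf(
      "cip_%d: normal=(%.3f,%.3f,%.3f) groups %d/%d residues", k,
      ax[1], ax[2], ax[3], length(part$group_a), length(part$group_b)))
    cv_definition(paste0("cip_", k), "CIP",
                  atom_indices(pdb, part$group_a, "heavy"),
                  atom_indices(pdb, part$group_b, "heavy"),
                  switching = switching,
                  meta = list(plane = k, normal = ax, center = frame$center,
                              group_a = part$group_a, group_b = part$group_b))
  })
  list(cvs = c(list(rog), cips), audit = audit)
}

#' Interface residues between a mobile domain and the core
#'
#' Union of (i) site residues of the mobile domain within `cutoff` of
#' any core residue and (ii) the specular selection of site residues of
#' the core within `cutoff` of any mobile-domain residue. Distances are
#' heavy-atom minima; the whole domains (not just their site residues)
#' serve as the distance targets.
#'
#' @param pdb structure.
#' @param site `site_definition`.
#' @param domains `domain_map`.
#' @param mobile,core domain labels.
#' @param cutoff interface cutoff in Angstrom (default 8).
#' @return list with `mobile` and `core` residue id vectors (both
#'   subsets of the site).
#' @export
select_interface_residues <- function(pdb, site, domains, mobile, core,
                                      cutoff = 8) {
  labs <- unclass(domains)
  if (!mobile %in% labs || !core %in% labs) {
    stop("domain label(s) absent from map: ",
         paste(setdiff(c(mobile, core), labs), collapse = ", "))
  }
  mob_all <- names(labs)[labs == mobile]
  core_all <- names(labs)[labs == core]
  site_mob <- intersect(site$residues, mob_all)
  site_core <- intersect(site$residues, core_all)
  sel_mob <- site_mob[.min_dist_to_set(pdb, site_mob, core_all) <= cutoff]
  sel_core <- site_core[.min_dist_to_set(pdb, site_core, mob_all) <= cutoff]
  if (length(sel_mob) + length(sel_core) == 0) {
    stop("no interface residues between ", mobile, " and ", core,
         " at ", cutoff, " A; try a larger cutoff")
  }
  list(mobile = sel_mob, core = sel_core)
}

#' Build inter-domain contact CVs (one per mobile-core interface)
#'
#' For every non-core domain, the site residues at its interface with
#' the core define a contact CV: group A = mobile-side heavy atoms,
#' group B = core-side heavy atoms. Two validity conditions are
#' enforced: no site residue may belong to more than one interface, and
#' each domain side must contribute at least `min_side` residues
#' (guarding against distortion of secondary-structure elements).
#'
#' @param pdb structure.
#' @param site `site_definition`.
#' @param domains `domain_map`.
#' @param core label of the core domain (default "CORE").
#' @param cutoff interface cutoff in Angstrom (default 8).
#' @param switching `switching_params`.
#' @param min_side minimum residues per domain side (default 4).
#' @return list with `cvs` (list of `cv_definition`, possibly empty)
#'   and `audit` log.
#' @export
build_crd_cvs <- function(pdb, site, domains, core = "CORE", cutoff = 8,
                          switching = switching_params(), min_side = 4) {
  labs <- unclass(domains)
  if (!core %in% labs) stop("core domain '", core, "' absent from map")
  mobiles <- setdiff(unique(labs), core)
  audit <- character(0)
  if (length(mobiles) == 0) {
    warning("single-domain protein: no inter-domain CVs")
    return(list(cvs = list(), audit = "no mobile domains"))
  }
  ifaces <- lapply(mobiles, function(m) {
    select_interface_residues(pdb, site, domains, m, core, cutoff)
  })
  names(ifaces) <- mobiles
  all_res <- unlist(lapply(ifaces, function(f) c(f$mobile, f$core)))
  dup <- unique(all_res[duplicated(all_res)])
  if (length(dup)) {
    stop("site residue(s) assigned to more than one interface CV: ",
         paste(dup, collapse = ", "),
         "; reduce the interface cutoff (currently ", cutoff, " A)")
  }
  cvs <- lapply(mobiles, function(m) {
    f <- ifaces[[m]]
    if (length(f$mobile) < min_side || length(f$core) < min_side) {
      stop("interface ", m, "-", core, " has ", length(f$mobile), "/",
           length(f$core), " residues per side; at least ", min_side,
           " required on each")
    }
    audit <<- c(audit, sprintf("crd_%s: %d %s + %d %s residues",
                               tolower(m), length(f$mobile), m,
                               length(f$core), core))
    cv_definition(paste0("crd_", tolower(m)), "CRD",
                  atom_indices(pdb, f$mobile, "heavy"),
                  atom_indices(pdb, f$core, "heavy"),
                  switching = switching,
                  meta = list(mobile = m, core = core,
                              mobile_residues = f$mobile,
                              core_residues = f$core))
  })
  list(cvs = cvs, audit = audit)
}

# residues with >= `k` members pairwise non-adjacent in sequence
# (sequence numbers differing by >= 2 within a chain)
.has_nonadjacent <- function(resids, k = 2) {
  if (length(resids) < k) return(FALSE)
  chain <- sub(":.*$", "", resids)
  num <- as.integer(sub("^[^:]*:", "", gsub("[A-Za-z]+$", "", resids)))
  # greedy: within each chain, count residues keeping gaps >= 2
  total <- sum(vapply(split(num, chain), function(v) {
    v <- sort(v)
    kept <- v[1]; cnt <- 1L
    for (x in v[-1]) if (x - kept >= 2) { kept <- x; cnt <- cnt + 1L }
    cnt
  }, integer(1)))
  total >= k
}

#' Split an inter-domain contact CV by residue charge
#'
#' When the binding site holds more than `threshold` charged residues,
#' each inter-domain CV is split into a charged-residue CV (suffix "c")
#' and an other-residue CV (suffix "o"), provided every resulting group
#' on both sides contains at least `min_nonadjacent` residues that are
#' not sequence-adjacent. Otherwise the CV is returned unchanged.
#'
#' @param cv a "CRD" `cv_definition` from [build_crd_cvs()].
#' @param charge charge partition of the site from
#'   [classify_residue_charge()].
#' @param pdb structure (to map residues back to atoms).
#' @param threshold charged fraction that triggers the split
#'   (default 0.25).
#' @param min_nonadjacent minimum non-adjacent residues per group
#'   (default 2).
#' @return list with `cvs` (one or two `cv_definition`) and `audit`
#'   (the decision and its reason).
#' @export
apply_charged_split <- function(cv, charge, pdb, threshold = 0.25,
                                min_nonadjacent = 2) {
  stopifnot(cv$kind == "CRD")
  if (!(charge$fraction > threshold)) {
    return(list(cvs = list(cv), audit = sprintf(
      "%s: not split (charged fraction %.0f%% <= %.0f%%)",
      cv$name, 100 * charge$fraction, 100 * threshold)))
  }
  sides <- list(mobile = cv$meta$mobile_residues,
                core = cv$meta$core_residues)
  groups <- list()
  for (s in names(sides)) {
    groups[[paste0(s, "_c")]] <- intersect(sides[[s]], charge$charged)
    groups[[paste0(s, "_o")]] <- intersect(sides[[s]], charge$other)
  }
  ok <- all(vapply(groups, .has_nonadjacent, logical(1),
                   k = min_nonadjacent))
  if (!ok) {
    return(list(cvs = list(cv), audit = sprintf(
      "%s: not split (a charge group lacks %d nonadjacent residues)",
      cv$name, min_nonadjacent)))
  }
  mk <- function(suffix, mob, core_res) {
    cv_definition(paste0(cv$name, suffix), "CRD",
                  atom_indices(pdb, mob, "heavy"),
                  atom_indices(pdb, core_res, "heavy"),
                  switching = cv$switching,
                  meta = utils::modifyList(cv$meta, list(
                    mobile_residues = mob, core_residues = core_res,
                    charge_class = suffix)))
  }
  list(cvs = list(mk("c", groups$mobile_c, groups$core_c),
                  mk("o", groups$mobile_o, groups$core_o)),
       audit = sprintf(
         "%s: split into c/o (charged fraction %.0f%% > %.0f%%)",
         cv$name, 100 * charge$fraction, 100 * threshold))
}

#' Estimate Gaussian hill widths from a short unbiased run
#'
#' Width of CV k = `scale` times the sample standard deviation of that
#' CV over the trailing `window` ps of the series.
#'
#' @param series `cv_series` from an unbiased run spanning at least
#'   `window` ps.
#' @param window window length in ps (default 200).
#' @param scale multiplier on the sample sigma (default 1).
#' @return named numeric vector of widths, one per CV.
#' @export
estimate_hill_widths <- function(series, window = 200, scale = 1) {
  span <- diff(range(series$times))
  if (span < window) {
    stop("series spans ", span, " ps, shorter than the ", window,
         " ps window")
  }
  keep <- series$times >= max(series$times) - window
  sd_k <- apply(series$values[keep, , drop = FALSE], 2, stats::sd)
  if (any(sd_k == 0)) {
    stop("constant CV column(s): ",
         paste(colnames(series$values)[sd_k == 0], collapse = ", "),
         " (zero width is unusable)")
  }
  scale * sd_k
}

#' Well-tempered metadynamics parameters
#' @param height Gaussian hill height, kcal/mol (default 0.6).
#' @param bias_factor well-tempered bias factor (default 10).
#' @param deposition_ps hill deposition period, ps (default 2.5).
#' @param exchange_ps bias-exchange period, ps (default 50).
#' @param widths named per-CV hill widths (from
#'   [estimate_hill_widths()]).
#' @export
metad_params <- function(height = 0.6, bias_factor = 10,
                         deposition_ps = 2.5, exchange_ps = 50,
                         widths = NULL) {
  stopifnot(height > 0, bias_factor > 0, deposition_ps > 0,
            exchange_ps > 0)
  structure(list(height = height, bias_factor = bias_factor,
                 deposition_ps = deposition_ps, exchange_ps = exchange_ps,
                 widths = widths),
            class = "metad_params")
}

#' Pocket-contraction restraint schedule
#'
#' Four phases acting on the site gyration CV: (1) unrestrained; (2)
#' upper wall at the apo value with force constant ramping linearly
#' between `k_range`; (3) wall center lowered stepwise (every ns,
#' linear envelope) to `target_fraction` of the apo value at constant
#' final force constant; (4) hold.
#'
#' @param rog_apo apo-structure site radius of gyration, Angstrom.
#' @param durations_ns phase durations in ns
#'   (default `c(10, 40, 400, 150)`).
#' @param k_range force-constant ramp (kcal/mol/A^2),
#'   default `c(10, 25)`.
#' @param target_fraction final center as a fraction of `rog_apo`
#'   (default 0.85).
#' @return object of class `restraint_schedule`; query with
#'   [schedule_at()].
#' @export
build_restraint_schedule <- function(rog_apo,
                                     durations_ns = c(10, 40, 400, 150),
                                     k_range = c(10, 25),
                                     target_fraction = 0.85) {
  stopifnot(rog_apo > 0, all(durations_ns > 0), length(durations_ns) == 4)
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target fraction must be in (0, 1]")
  }
  structure(list(rog_apo = rog_apo, durations_ns = durations_ns,
                 k_range = k_range, target_fraction = target_fraction,
                 boundaries = cumsum(durations_ns)),
            class = "restraint_schedule")
}

#' Query a restraint schedule at a time point
#' @param schedule `restraint_schedule`.
#' @param t_ns time in ns from the start of the run.
#' @return list with `wall` ("none"/"upper"), `center` (Angstrom, NA in
#'   phase 1) and `k` (kcal/mol/A^2, 0 in phase 1).
#' @export
schedule_at <- function(schedule, t_ns) {
  b <- schedule$boundaries
  rog <- schedule$rog_apo
  kr <- schedule$k_range
  if (t_ns < 0) stop("negative time")
  t_ns <- min(t_ns, b[4])
  if (t_ns < b[1]) {
    return(list(wall = "none", center = NA_real_, k = 0))
  }
  if (t_ns <= b[2]) {
    frac <- (t_ns - b[1]) / schedule$durations_ns[2]
    return(list(wall = "upper", center = rog,
                k = kr[1] + frac * (kr[2] - kr[1])))
  }
  if (t_ns <= b[3]) {
    # center updated every ns along a linear envelope to the target
    step <- floor(t_ns - b[2])
    frac <- step / schedule$durations_ns[3]
    center <- rog * (1 - frac * (1 - schedule$target_fraction))
    return(list(wall = "upper", center = center, k = kr[2]))
  }
  list(wall = "upper", center = rog * schedule$target_fraction, k = kr[2])
}

#' Assemble a complete setup bundle
#'
#' Runs the full CV construction on a structure, site and domain map:
#' pocket-shape CVs, inter-domain CVs, the charged-split rule, and the
#' restraint schedule anchored at the apo pocket gyration radius.
#'
#' @param pdb apo structure.
#' @param site `site_definition`.
#' @param domains `domain_map` (NULL to skip inter-domain CVs).
#' @param params `metad_params`; widths may be attached later.
#' @param switching `switching_params` shared by contact CVs.
#' @param core core domain label.
#' @param cutoff interface cutoff, Angstrom.
#' @param charged_threshold charged-fraction trigger for the split.
#' @param charged_set residue names counted as charged.
#' @param schedule optional `restraint_schedule` (default: built from
#'   the apo site gyration radius with default phases).
#' @return object of class `protocol_bundle`: list with `cvs`,
#'   `params`, `schedule`, `audit`.
#' @export
build_protocol <- function(pdb, site, domains = NULL,
                           params = metad_params(),
                           switching = switching_params(),
                           core = "CORE", cutoff = 8,
                           charged_threshold = 0.25,
                           charged_set = CHARGED_RESIDUES,
                           schedule = NULL) {
  bs <- build_binding_site_cvs(pdb, site, switching)
  audit <- bs$audit
  cvs <- bs$cvs
  if (!is.null(domains)) {
    crd <- build_crd_cvs(pdb, site, domains, core, cutoff, switching)
    audit <- c(audit, crd$audit)
    charge <- classify_residue_charge(pdb, site, charged_set)
    audit <- c(audit, sprintf("site charged fraction: %d/%d (%.0f%%)",
                              length(charge$charged),
                              length(site$residues),
                              100 * charge$fraction))
    for (cv in crd$cvs) {
      sp <- apply_charged_split(cv, charge, pdb,
                                threshold = charged_threshold)
      audit <- c(audit, sp$audit)
      cvs <- c(cvs, sp$cvs)
    }
  }
  if (is.null(schedule)) {
    rog_cv <- cvs[[1]]
    rog_apo <- evaluate_cv(rog_cv, atom_coords(pdb))
    schedule <- build_restraint_schedule(rog_apo)
  }
  total <- sum(schedule$durations_ns)
  audit <- c(audit, sprintf(
    "schedule phases %s ns (total %g ns)",
    paste(schedule$durations_ns, collapse = "+"), total))
  structure(list(cvs = cvs, params = params, schedule = schedule,
                 audit = audit),
            class = "protocol_bundle")
}

#' @export
print.protocol_bundle <- function(x, ...) {
  cat("Protocol bundle:", length(x$cvs), "CVs\n")
  for (line in x$audit) cat(" -", line, "\n")
  invisible(x)
}

# ---- deck emission ---------------------------------------------------------

.fmt_num <- function(x) {
  # deterministic, trailing-zero-free numeric formatting
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 6))
}

#' Emit a metadynamics input deck
#'
#' Serializes the bundle into a deterministic PLUMED-dialect text:
#' atom-group definitions by serial list, gyration and coordination CV
#' lines, the well-tempered metadynamics directive and moving-restraint
#' directives realizing the schedule. Units are Angstrom and kcal/mol
#' as configured; the deposition pace is converted to integer MD steps.
#'
#' @param bundle `protocol_bundle` with hill widths present in
#'   `bundle$params$widths`.
#' @param timestep_fs integrator timestep in fs (default 2).
#' @return character vector of deck lines.
#' @export
emit_metadynamics_input <- function(bundle, timestep_fs = 2) {
  p <- bundle$params
  if (is.null(p$widths)) stop("bundle has no hill widths; run estimate_hill_widths first")
  if (length(p$widths) != length(bundle$cvs)) {
    stop("need one width per CV (", length(bundle$cvs), "), got ",
         length(p$widths))
  }
  pace <- p$deposition_ps * 1000 / timestep_fs
  if (abs(pace - round(pace)) > 1e-9) {
    stop("deposition period ", p$deposition_ps,
         " ps is not an integer number of ", timestep_fs,
         " fs steps; choose a compatible timestep")
  }
  sch <- bundle$schedule
  lines <- c("# metadynamics input deck (units: Angstrom, kcal/mol, ps)",
             sprintf("#TIMESTEP_FS %s", .fmt_num(timestep_fs)))
  cv_names <- vapply(bundle$cvs, `[[`, character(1), "name")
  for (cv in bundle$cvs) {
    ga <- paste(cv$group_a, collapse = ",")
    if (cv$kind == "ROG") {
      lines <- c(lines,
        sprintf("%s_grp: GROUP ATOMS=%s", cv$name, ga),
        sprintf("%s: GYRATION TYPE=RADIUS ATOMS=%s_grp", cv$name, cv$name))
    } else {
      s <- cv$switching
      lines <- c(lines,
        sprintf("%s_grpa: GROUP ATOMS=%s", cv$name, ga),
        sprintf("%s_grpb: GROUP ATOMS=%s", cv$name,
                paste(cv$group_b, collapse = ",")),
        sprintf(
          "%s: COORDINATION GROUPA=%s_grpa GROUPB=%s_grpb R_0=%s D_0=%s NN=%d MM=%d",
          cv$name, cv$name, cv$name, .fmt_num(s$r0), .fmt_num(s$d0),
          s$n, s$m))
    }
  }
  lines <- c(lines, sprintf(
    "metad: METAD ARG=%s SIGMA=%s HEIGHT=%s PACE=%d BIASFACTOR=%s",
    paste(cv_names, collapse = ","),
    paste(vapply(unname(p$widths), .fmt_num, character(1)), collapse = ","),
    .fmt_num(p$height), as.integer(round(pace)), .fmt_num(p$bias_factor)))
  lines <- c(lines, sprintf("#EXCHANGE_PS %s", .fmt_num(p$exchange_ps)))
  step_ns <- 1000 * 1000 / timestep_fs  # MD steps per ns
  b <- sch$boundaries
  steps <- as.integer(round(c(b[1], b[2], b[3], b[4]) * step_ns))
  lines <- c(lines, sprintf(paste0(
    "restraint: MOVINGRESTRAINT ARG=%s VERSE=U",
    " STEP0=%d AT0=%s KAPPA0=%s",
    " STEP1=%d AT1=%s KAPPA1=%s",
    " STEP2=%d AT2=%s KAPPA2=%s",
    " STEP3=%d AT3=%s KAPPA3=%s"),
    cv_names[1],
    steps[1], .fmt_num(sch$rog_apo), .fmt_num(sch$k_range[1]),
    steps[2], .fmt_num(sch$rog_apo), .fmt_num(sch$k_range[2]),
    steps[3], .fmt_num(sch$rog_apo * sch$target_fraction),
    .fmt_num(sch$k_range[2]),
    steps[4], .fmt_num(sch$rog_apo * sch$target_fraction),
    .fmt_num(sch$k_range[2])))
  lines <- c(lines, sprintf("PRINT ARG=%s STRIDE=%d FILE=COLVAR",
                            paste(cv_names, collapse = ","),
                            as.integer(round(pace))))
  lines
}

#' Parse an emitted metadynamics deck back into its parameters
#'
#' Inverse of [emit_metadynamics_input()] for round-trip checks and for
#' recovering a deck's settings: returns the CV definitions (kind,
#' groups, switching), metadynamics parameters, and the restraint
#' schedule breakpoints.
#'
#' @param lines character vector as returned by
#'   [emit_metadynamics_input()].
#' @return list with `cvs`, `params`, `schedule`, `timestep_fs`.
#' @export
parse_metadynamics_input <- function(lines) {
  grab <- function(pattern, line) {
    m <- regmatches(line, regexec(pattern, line))[[1]]
    if (length(m) < 2) stop("cannot parse deck line: ", line)
    m[2]
  }
  ts <- as.numeric(grab("^#TIMESTEP_FS ([0-9.]+)",
                        grep("^#TIMESTEP_FS", lines, value = TRUE)))
  groups <- list()
  for (line in grep(": GROUP ATOMS=", lines, value = TRUE)) {
    lab <- sub(":.*$", "", line)
    groups[[lab]] <- as.integer(strsplit(grab("ATOMS=([0-9,]+)", line),
                                         ",")[[1]])
  }
  cvs <- list()
  for (line in grep(": GYRATION ", lines, value = TRUE)) {
    name <- sub(":.*$", "", line)
    cvs[[name]] <- cv_definition(name, "ROG",
                                 groups[[paste0(name, "_grp")]])
  }
  for (line in grep(": COORDINATION ", lines, value = TRUE)) {
    name <- sub(":.*$", "", line)
    sw <- switching_params(
      r0 = as.numeric(grab("R_0=([0-9.]+)", line)),
      n = as.integer(grab("NN=([0-9]+)", line)),
      m = as.integer(grab("MM=([0-9]+)", line)),
      d0 = as.numeric(grab("D_0=([0-9.]+)", line)))
    kind <- if (grepl("^cip", name)) "CIP" else "CRD"
    cvs[[name]] <- cv_definition(name, kind,
                                 groups[[paste0(name, "_grpa")]],
                                 groups[[paste0(name, "_grpb")]],
                                 switching = sw)
  }
  metad <- grep(": METAD ", lines, value = TRUE)
  arg_order <- strsplit(grab("ARG=([^ ]+)", metad), ",")[[1]]
  cvs <- cvs[arg_order]
  widths <- as.numeric(strsplit(grab("SIGMA=([^ ]+)", metad), ",")[[1]])
  names(widths) <- arg_order
  pace <- as.integer(grab("PACE=([0-9]+)", metad))
  params <- metad_params(
    height = as.numeric(grab("HEIGHT=([0-9.]+)", metad)),
    bias_factor = as.numeric(grab("BIASFACTOR=([0-9.]+)", metad)),
    deposition_ps = pace * ts / 1000,
    exchange_ps = as.numeric(grab("^#EXCHANGE_PS ([0-9.]+)",
                                  grep("^#EXCHANGE_PS", lines,
                                       value = TRUE))),
    widths = widths)
  res <- grep(": MOVINGRESTRAINT ", lines, value = TRUE)
  step_ns <- 1000 * 1000 / ts
  steps <- vapply(0:3, function(i) {
    as.numeric(grab(sprintf("STEP%d=([0-9]+)", i), res))
  }, numeric(1))
  at <- vapply(0:3, function(i) {
    as.numeric(grab(sprintf("AT%d=([0-9.]+)", i), res))
  }, numeric(1))
  kap <- vapply(0:3, function(i) {
    as.numeric(grab(sprintf("KAPPA%d=([0-9.]+)", i), res))
  }, numeric(1))
  rog_apo <- at[1]
  schedule <- build_restraint_schedule(
    rog_apo,
    durations_ns = diff(c(0, steps)) / step_ns,
    k_range = c(kap[1], kap[2]),
    target_fraction = at[3] / rog_apo)
  list(cvs = cvs, params = params, schedule = schedule, timestep_fs = ts)
}
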
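test_that("pocket CV construction yields one gyration plus three planes", {
  bs <- build_binding_site_cvs(toy$structure, toy$site)
  expect_length(bs$cvs, 4)
  expect_equal(vapply(bs$cvs, `[[`, character(1), "kind"),
               c("ROG", "CIP", "CIP", "CIP"))
  # each plane partitions the site
  for (cv in bs$cvs[2:4]) {
    expect_setequal(c(cv$meta$group_a, cv$meta$group_b),
                    toy$site$residues)
    expect_length(intersect(cv$group_a, cv$group_b), 0)
  }
  # audit records the plane normals
  expect_length(bs$audit, 3)
  expect_match(bs$audit[1], "normal=")
})

test_that("interface selection applies the 8 A rule on both sides", {
  # toy scan: mobile residues at 7 and 9 A from a core residue
  pdb <- make_structure(
    name = "CA", resname = "ALA", chain = "A", resno = 1:3,
    xyz = rbind(c(0, 0, 0), c(7, 0, 0), c(9, 0, 0)))
  dm <- domain_map(paste0("A:", 1:3), c("CORE", "NMP", "NMP"))
  site <- site_definition(paste0("A:", 1:3))
  sel <- select_interface_residues(pdb, site, dm, "NMP", "CORE")
  expect_equal(sel$mobile, "A:2")  # 7 A in, 9 A out
  expect_equal(sel$core, "A:1")
  # infinite cutoff: every site residue of the two domains
  sel_inf <- select_interface_residues(pdb, site, dm, "NMP", "CORE",
                                       cutoff = Inf)
  expect_setequal(c(sel_inf$mobile, sel_inf$core), site$residues)
  expect_error(select_interface_residues(pdb, site, dm, "LID", "CORE"),
               "absent")
})

test_that("the two toy interfaces are disjoint and subsets of the site", {
  nc <- select_interface_residues(toy$structure, toy$site, toy$domains,
                                  "NMP", "CORE")
  lc <- select_interface_residues(toy$structure, toy$site, toy$domains,
                                  "LID", "CORE")
  nc_all <- c(nc$mobile, nc$core)
  lc_all <- c(lc$mobile, lc$core)
  expect_length(intersect(nc_all, lc_all), 0)
  expect_true(all(c(nc_all, lc_all) %in% toy$site$residues))
})

test_that("inter-domain CV construction enforces its validity checks", {
  crd <- build_crd_cvs(toy$structure, toy$site, toy$domains)
  expect_length(crd$cvs, 2)
  for (cv in crd$cvs) {
    expect_gte(length(cv$meta$mobile_residues), 4)
    expect_gte(length(cv$meta$core_residues), 4)
  }
  # single-domain protein: empty list with a warning
  one_dom <- domain_map(names(unclass(toy$domains)),
                        rep("CORE", length(toy$domains)))
  expect_warning(out <- build_crd_cvs(toy$structure, toy$site, one_dom),
                 "single-domain")
  expect_length(out$cvs, 0)
  # fewer than 4 residues on one side is an error
  pdb <- make_structure(
    name = "CA", resname = "ALA", chain = "A", resno = 1:8,
    xyz = rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0),
                c(0, 4, 0), c(3.8, 4, 0), c(7.6, 4, 0), c(11.4, 4, 0)))
  dm <- domain_map(paste0("A:", 1:8),
                   c(rep("CORE", 4), rep("LID", 4)))
  site <- site_definition(paste0("A:", c(1:4, 5:7)))  # 3 LID residues
  expect_error(build_crd_cvs(pdb, site, dm), "at least 4")
})

test_that("the charged-split rule needs both the fraction and the groups", {
  crd <- build_crd_cvs(toy$structure, toy$site, toy$domains)
  charge <- classify_residue_charge(toy$structure, toy$site)
  # toy site: 11/32 charged (~34%) -> split applies
  expect_equal(charge$fraction, 11 / 32)
  sp <- apply_charged_split(crd$cvs[[1]], charge, toy$structure)
  expect_length(sp$cvs, 2)
  expect_equal(vapply(sp$cvs, `[[`, character(1), "name"),
               c("crd_nmpc", "crd_nmpo"))
  # splitting never changes the union of covered atoms
  expect_setequal(c(sp$cvs[[1]]$group_a, sp$cvs[[2]]$group_a),
                  crd$cvs[[1]]$group_a)
  expect_setequal(c(sp$cvs[[1]]$group_b, sp$cvs[[2]]$group_b),
                  crd$cvs[[1]]$group_b)
  # below the 25% threshold: no split
  low <- charge
  low$fraction <- 2 / 32
  sp2 <- apply_charged_split(crd$cvs[[1]], low, toy$structure)
  expect_length(sp2$cvs, 1)
  expect_match(sp2$audit, "not split")
  # 28% charged but the charged residues are one adjacent pair: no split
  adj <- list(charged = c("A:1", "A:2"),
              other = setdiff(toy$site$residues, c("A:1", "A:2")),
              fraction = 0.28)
  sp3 <- apply_charged_split(crd$cvs[[1]], adj, toy$structure)
  expect_length(sp3$cvs, 1)
  expect_match(sp3$audit, "nonadjacent")
})

test_that("hill widths are the sample sigma over the window", {
  set.seed(23)
  n <- 400  # 10 ps stride -> ~4 ns, window is the trailing 200 ps
  vals <- cbind(a = rnorm(n, 10, 0.3), b = rnorm(n, 5, 0.15))
  series <- cv_series(vals, times = (seq_len(n) - 1) * 1)  # 1 ps stride
  w <- estimate_hill_widths(series, window = 200)
  keep <- series$times >= max(series$times) - 200
  expect_equal(unname(w["a"]), sd(vals[keep, "a"]))
  expect_equal(unname(w["a"]), 0.3, tolerance = 0.15)
  # two CVs with sigma ratio 2:1 give width ratio ~2:1
  expect_equal(unname(w["a"] / w["b"]), 2, tolerance = 0.3)
  # scale factor
  expect_equal(estimate_hill_widths(series, window = 200, scale = 0.5),
               w / 2)
  # constant column is an error
  const <- cv_series(cbind(a = rep(1, n)), times = seq_len(n) - 1)
  expect_error(estimate_hill_widths(const, window = 200), "constant")
  expect_error(estimate_hill_widths(series, window = 1e6), "shorter")
})

test_that("the restraint schedule realizes the contraction protocol", {
  rog <- 12
  sch <- build_restraint_schedule(rog)
  # phase 1: unrestrained
  expect_equal(schedule_at(sch, 5)$wall, "none")
  # phase 2 start and end: force constant ramps 10 -> 25
  expect_equal(schedule_at(sch, 10)$k, 10)
  expect_equal(schedule_at(sch, 50)$k, 25)
  expect_equal(schedule_at(sch, 50)$center, rog)
  # phase 3 midpoint: center at 92.5% of the apo value
  expect_equal(schedule_at(sch, 250)$center, 0.925 * rog)
  # phase 3 end and phase 4: 85% of the apo value, k stays 25
  expect_equal(schedule_at(sch, 450)$center, 0.85 * rog)
  expect_equal(schedule_at(sch, 600)$center, 0.85 * rog)
  expect_equal(schedule_at(sch, 600)$k, 25)
  # center is non-increasing after phase 2 and continuous at boundaries
  t_grid <- seq(10, 600, by = 0.25)
  centers <- vapply(t_grid, function(t) schedule_at(sch, t)$center,
                    numeric(1))
  expect_true(all(diff(centers) <= 1e-12))
  expect_lt(max(abs(diff(centers))), 0.01 * rog)  # 1 ns steps are small
  expect_error(build_restraint_schedule(rog, target_fraction = 1.5),
               "target fraction")
})

test_that("the emitted deck carries the stated defaults and round trips", {
  bundle <- build_protocol(toy$structure, toy$site, toy$domains)
  traj <- make_open_close_trajectory(n_frames = 40, sigma = 0.1, seed = 9,
                                     dt = 10)
  series <- evaluate_cv_series(traj, bundle$cvs)
  bundle$params$widths <- estimate_hill_widths(series, window = 200)
  deck <- emit_metadynamics_input(bundle, timestep_fs = 2)
  # 2.5 ps deposition at 2 fs -> pace 1250 steps
  expect_match(deck[grepl("METAD", deck)], "PACE=1250")
  expect_match(deck[grepl("METAD", deck)], "HEIGHT=0.6")
  expect_match(deck[grepl("METAD", deck)], "BIASFACTOR=10")
  # non-integer pace is rejected
  expect_error(emit_metadynamics_input(bundle, timestep_fs = 3),
               "not an integer")
  # parse recovers the parameters; emit o parse o emit is byte-identical
  parsed <- parse_metadynamics_input(deck)
  expect_equal(parsed$params$height, 0.6)
  expect_equal(parsed$params$bias_factor, 10)
  expect_equal(parsed$params$deposition_ps, 2.5)
  expect_equal(parsed$params$exchange_ps, 50)
  expect_equal(names(parsed$cvs),
               vapply(bundle$cvs, `[[`, character(1), "name"))
  bundle2 <- structure(list(cvs = parsed$cvs, params = parsed$params,
                            schedule = parsed$schedule),
                       class = "protocol_bundle")
  expect_identical(emit_metadynamics_input(bundle2, parsed$timestep_fs),
                   deck)
  # same inputs -> byte-identical output (determinism)
  expect_identical(emit_metadynamics_input(bundle, 2), deck)
})

test_that("the full setup bundle logs every rule decision", {
  bundle <- build_protocol(toy$structure, toy$site, toy$domains)
  # 4 pocket CVs + 2 interfaces split into 2 each = 8 CVs
  expect_length(bundle$cvs, 8)
  expect_true(any(grepl("split into c/o", bundle$audit)))
  expect_true(any(grepl("charged fraction", bundle$audit)))
  expect_true(any(grepl("schedule phases", bundle$audit)))
})
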
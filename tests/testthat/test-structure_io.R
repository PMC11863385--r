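test_that("minimal PDB text parses into atoms and residues", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(lines = lines, fileext = ".pdb")
  pdb <- read_structure(path)
  expect_equal(nrow(pdb$atoms), 2)
  expect_equal(length(pdb$resids), 1)
  expect_equal(pdb$atoms$name, c("N", "CA"))
  expect_equal(pdb$atoms$mass, c(14.007, 12.011))
  expect_true(all(pdb$atoms$is_backbone))
})

test_that("read-write-read round trip preserves the structure exactly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, path)
  back <- read_structure(path)
  expect_equal(back$atoms$name, toy$structure$atoms$name)
  expect_equal(back$atoms$resno, toy$structure$atoms$resno)
  expect_equal(back$atoms$resname, toy$structure$atoms$resname)
  # coordinates to fixed-width PDB precision (3 decimals)
  expect_lt(max(abs(atom_coords(back) - atom_coords(toy$structure))),
            5.1e-4)
  # second round trip is bit-identical
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("unparseable and empty files raise informative errors", {
  bad <- withr::local_tempfile(
    lines = "ATOM      1  N   ALA A   1      bad coords", fileext = ".pdb")
  expect_error(read_structure(bad), "cannot parse coordinates")
  empty <- withr::local_tempfile(lines = "REMARK nothing", fileext = ".pdb")
  expect_error(read_structure(empty), "no ATOM/HETATM")
})

test_that("ligand shell selection applies the distance cutoff strictly", {
  # one ligand atom at origin; residue nearest atoms at 3.4 and 3.6 A
  pdb <- make_structure(
    name = c("C1", "CA", "CB", "CA", "CB"),
    resname = c("LIG", "ALA", "ALA", "GLY", "GLY"),
    chain = "A", resno = c(99, 1, 1, 2, 2),
    xyz = rbind(c(0, 0, 0),
                c(3.4, 0, 0), c(6, 0, 0),
                c(0, 3.6, 0), c(0, 6, 0)),
    record = c("HETATM", rep("ATOM", 4)))
  site <- select_site_by_ligand(pdb, "A:99", cutoff = 3.5)
  expect_equal(site$residues, "A:1")
  expect_equal(site$provenance, "ligand-derived")
  # oracle: brute-force scan agrees at several cutoffs
  for (cutoff in c(0.5, 3.45, 3.65, 10)) {
    got <- suppressWarnings(select_site_by_ligand(pdb, "A:99", cutoff))$residues
    want <- c("A:1", "A:2")[c(3.4, 3.6) <= cutoff]
    expect_equal(got, want, info = paste("cutoff", cutoff))
  }
  expect_error(select_site_by_ligand(pdb, "A:77"), "not found")
})

test_that("ligand shell selection is monotone in the cutoff", {
  pdb <- toy$structure
  # graft a fake ligand next to the site for the monotonicity scan
  lig <- make_structure("C1", "LIG", "A", 99, rbind(c(-15, 5, 1)),
                        record = "HETATM")
  both <- make_structure(c(pdb$atoms$name, "C1"),
                         c(pdb$atoms$resname, "LIG"),
                         "A", c(pdb$atoms$resno, 99),
                         rbind(atom_coords(pdb), c(-15, 5, 1)),
                         record = c(pdb$atoms$record, "HETATM"))
  prev <- character(0)
  for (cutoff in c(2, 4, 6, 9, 14)) {
    cur <- suppressWarnings(
      select_site_by_ligand(both, "A:99", cutoff)$residues)
    expect_true(all(prev %in% cur), info = paste("cutoff", cutoff))
    prev <- cur
  }
})

test_that("site prediction merging unions residues above the score floor", {
  s <- function(r) site_definition(r)
  merged <- merge_site_predictions(
    list(s(c("A:1", "A:2")), s(c("A:2", "A:3"))), c(0.99, 0.89))
  expect_equal(merged$residues, c("A:1", "A:2", "A:3"))
  expect_equal(merged$provenance, "merged-prediction")
  # low scorers excluded
  merged2 <- merge_site_predictions(
    list(s(c("A:1", "A:2")), s("A:3"), s("A:9")), c(0.99, 0.67, 0.005))
  expect_false("A:9" %in% merged2$residues)
  # single site returned unchanged
  expect_equal(merge_site_predictions(list(s(c("A:5", "A:7"))), 0.5)$residues,
               c("A:5", "A:7"))
  expect_error(merge_site_predictions(list(s("A:1")), 0.001),
               "no reliable site")
})

test_that("charge classification partitions the site", {
  pdb <- make_structure(
    name = "CA", resname = c("ASP", "GLY", "LYS", "ALA"),
    chain = "A", resno = 1:4, xyz = matrix(rnorm(12), 4, 3))
  site <- site_definition(paste0("A:", 1:4))
  cls <- classify_residue_charge(pdb, site)
  expect_setequal(cls$charged, c("A:1", "A:3"))
  expect_setequal(cls$other, c("A:2", "A:4"))
  expect_equal(cls$fraction, 0.5)
  expect_setequal(c(cls$charged, cls$other), site$residues)
  # empty site -> empty partition
  empty <- classify_residue_charge(pdb, site_definition(character(0)))
  expect_length(empty$charged, 0)
  expect_length(empty$other, 0)
})

test_that("superposition recovers known rigid transforms", {
  set.seed(42)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  # identity
  same <- superpose(xyz, xyz)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  # known rotation about z by 90 degrees plus translation
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- xyz %*% t(R90) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit <- superpose(xyz, moved)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, R90, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_transform(xyz, fit), moved, tolerance = 1e-9)
})

test_that("superposition is symmetric and never worse than no fit", {
  set.seed(7)
  for (i in 1:20) {
    a <- matrix(rnorm(24, sd = 3), 8, 3)
    b <- a + matrix(rnorm(24, sd = 1), 8, 3)
    expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd,
                 tolerance = 1e-9)
    expect_lte(superpose(a, b)$rmsd, rmsd(a, b) + 1e-12)
  }
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  collinear <- cbind(1:5, 0, 0)
  expect_error(superpose(collinear, collinear), "collinear")
})

test_that("domain map and site files round trip through disk", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "site.txt")
  write_site(toy$site, p1)
  expect_equal(read_site(p1)$residues, toy$site$residues)
  p2 <- file.path(d, "domains.tsv")
  write_domain_map(toy$domains, p2)
  expect_equal(unclass(read_domain_map(p2)), unclass(toy$domains))
})

test_that("multi-model PDB trajectories round trip through disk", {
  traj <- make_open_close_trajectory(n_frames = 4, sigma = 0.05, seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(n_frames(back), 4)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("altloc conformers resolve to the highest occupancy", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "END")
  path <- withr::local_tempfile(lines = lines, fileext = ".pdb")
  pdb <- read_structure(path)
  expect_equal(nrow(pdb$atoms), 1)
  expect_equal(pdb$atoms$x, 5)
})
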
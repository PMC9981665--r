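test_that("build_system packs the requested composition at net charge zero", {
  sys <- build_system(15, 35, box_spec(30), min_separation = 3, seed = 42)
  tab <- table(sys$residues$species)
  expect_identical(as.integer(tab[c("IM1H", "OAC", "IM1", "HOAC")]),
                   c(15L, 15L, 35L, 35L))
  expect_identical(total_charge(sys), 0L)
  expect_identical(nrow(sys$residues), 100L)
  # min separation respected under minimum image
  hits <- protonhop:::self_pairs_cpp(sys$positions, as.numeric(sys$box), 3)
  expect_identical(nrow(hits), 0L)
})

test_that("build_system is deterministic given the seed", {
  a <- build_system(5, 5, box_spec(25), min_separation = 4, seed = 9)
  b <- build_system(5, 5, box_spec(25), min_separation = 4, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$residues$species, b$residues$species)
  d <- build_system(5, 5, box_spec(25), min_separation = 4, seed = 10)
  expect_false(identical(a$positions, d$positions))
})

test_that("empty and infeasible packings are handled", {
  sys <- build_system(0, 0, box_spec(20), min_separation = 3, seed = 1)
  expect_identical(nrow(sys$residues), 0L)
  expect_identical(total_charge(sys), 0L)
  expect_error(build_system(200, 200, box_spec(10), min_separation = 3,
                            seed = 1, max_attempts = 50),
               "packing failure")
})

test_that("state swap turns the acidic hydrogen into a chargeless dummy", {
  cfg <- default_templates()
  n_at <- nrow(cfg$templates$IM1H$atoms_protonated)
  pos <- matrix(seq_len(3 * n_at), n_at, 3)  # arbitrary finite positions
  sys <- md_system("IM1H", cfg$templates, pos, box = box_spec(40))
  expect_identical(sys$residues$charge, 1L)
  sw <- apply_residue_state(sys, 1, "IM1")
  expect_identical(sw$residues$species, "IM1")
  expect_identical(sw$residues$charge, 0L)
  i <- match("H7", sw$atoms$name)
  expect_identical(sw$atoms$type[i], "DUMH")
  expect_identical(sw$atoms$charge[i], 0)
  expect_true(sw$atoms$dummy[i])
  expect_identical(nrow(sw$atoms), nrow(sys$atoms))
  expect_identical(sw$atoms$name, sys$atoms$name)  # ordering preserved
})

test_that("state swaps are idempotent and invertible", {
  cfg <- default_templates()
  n_at <- nrow(cfg$templates$IM1H$atoms_protonated)
  sys <- md_system("IM1H", cfg$templates, matrix(1, n_at, 3),
                   box = box_spec(40))
  same <- apply_residue_state(sys, 1, "IM1H")
  expect_identical(same$atoms, sys$atoms)
  back <- apply_residue_state(apply_residue_state(sys, 1, "IM1"), 1, "IM1H")
  expect_identical(back$atoms, sys$atoms)
  expect_identical(back$residues, sys$residues)
  expect_error(apply_residue_state(sys, 1, "OAC"), "unknown")
})

test_that("charges-only mode changes charges but not LJ parameters", {
  cfg <- default_templates()
  n_at <- nrow(cfg$templates$IM1H$atoms_protonated)
  sys <- md_system("IM1H", cfg$templates, matrix(1, n_at, 3),
                   box = box_spec(40))
  sw <- apply_residue_state(sys, 1, "IM1", mode = "charges_only")
  expect_identical(sw$atoms$lj_epsilon, sys$atoms$lj_epsilon)
  expect_identical(sw$atoms$type, sys$atoms$type)
  expect_false(identical(sw$atoms$charge, sys$atoms$charge))
  expect_identical(sw$residues$charge, 0L)
})

test_that("PSF write/read round-trips composition and parameters", {
  sys <- build_system(4, 6, box_spec(25), min_separation = 3, seed = 3)
  path <- withr::local_tempfile(fileext = ".psf")
  write_psf(sys, path)
  back <- read_psf(path, bead_templates(), box = sys$box)
  expect_identical(back$residues$species, sys$residues$species)
  expect_identical(back$atoms$name, sys$atoms$name)
  expect_identical(back$atoms$type, sys$atoms$type)
  expect_equal(back$atoms$charge, sys$atoms$charge, tolerance = 1e-6)
  expect_equal(back$atoms$mass, sys$atoms$mass, tolerance = 1e-6)
})

test_that("PSF reader rejects unknown residues and accepts empty files", {
  sys <- two_bead_system()
  path <- withr::local_tempfile(fileext = ".psf")
  write_psf(sys, path)
  txt <- gsub("IM1H", "ZZZZ", readLines(path))
  writeLines(txt, path)
  expect_error(read_psf(path, bead_templates()), "ZZZZ")

  empty <- md_system(character(), bead_templates(), matrix(0, 0, 3),
                     box = box_spec(20))
  p2 <- withr::local_tempfile(fileext = ".psf")
  write_psf(empty, p2)
  back <- read_psf(p2, bead_templates())
  expect_identical(nrow(back$residues), 0L)
})

test_that("XYZ trajectories round-trip with box metadata", {
  coords <- array(runif(3 * 5 * 3) * 20, c(3, 5, 3))
  traj <- xyz_trajectory(coords, times = c(0, 1, 2), box = box_spec(20),
                         atom_names = paste0("A", 1:5))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  back <- read_xyz(path)
  expect_equal(back$coords, traj$coords, tolerance = 1e-7)
  expect_equal(back$times, traj$times, tolerance = 1e-7)
  expect_equal(as.numeric(back$box), as.numeric(traj$box), tolerance = 1e-7)
  expect_identical(back$atom_names, traj$atom_names)
})

test_that("XYZ reader demands box metadata and consistent atom counts", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "no metadata here", "A 0 0 0", "B 1 1 1"), path)
  expect_error(read_xyz(path), "box")
  writeLines(c("1", "time= 0 box= 10 10 10", "A 0 0 0",
               "2", "time= 1 box= 10 10 10", "A 0 0 0", "B 1 1 1"), path)
  expect_error(read_xyz(path), "atoms")
  # single-atom frames are valid
  writeLines(c("1", "time= 0 box= 10 10 10", "A 0.5 0.25 0.125",
               "1", "time= 1 box= 10 10 10", "A 1 1 1"), path)
  tr <- read_xyz(path)
  expect_identical(dim(tr$coords), c(2L, 1L, 3L))
  expect_equal(tr$coords[1, 1, ], c(0.5, 0.25, 0.125))
})

test_that("charge reporter counts states and sums to the system charge", {
  sys <- build_system(15, 35, box_spec(30), min_separation = 3, seed = 5)
  rep <- report_charges(sys)
  expect_identical(nrow(rep), 100L)
  expect_identical(sum(rep$charge_e), 0L)
  expect_identical(sum(rep$charge_e == 1), 15L)
  expect_identical(sum(rep$charge_e == -1), 15L)
  expect_identical(sum(rep$charge_e == 0), 70L)
  empty <- md_system(character(), bead_templates(), matrix(0, 0, 3),
                     box = box_spec(20))
  expect_identical(nrow(report_charges(empty)), 0L)
})

test_that("charge report reflects a cation+anion -> neutral transfer", {
  sys <- build_system(15, 35, box_spec(30), min_separation = 3, seed = 5)
  rx <- bead_reactions(6)
  don <- which(sys$residues$species == "IM1H")[1]
  acc <- which(sys$residues$species == "OAC")[1]
  acc_pair <- data.frame(donor_res = don, acceptor_res = acc,
                         donor_atom = "BD", acceptor_atom = "BD",
                         distance = 1, reaction = rx[[1]]$name,
                         stringsAsFactors = FALSE)
  upd <- execute_update(sys, acc_pair, rx)
  rep <- report_charges(upd$system)
  expect_identical(sum(rep$charge_e == 1), 14L)
  expect_identical(sum(rep$charge_e == -1), 14L)
  expect_identical(sum(rep$charge_e == 0), 72L)
  expect_identical(sum(rep$charge_e), 0L)
})

test_that("energy reporter matches Coulomb's law and is additive", {
  # +1/-1 beads at 10 A, unscreened, unshifted, no LJ overlap
  sys <- two_bead_system(c("IM1H", "OAC"), d = 10, box_edge = 50)
  ff <- toy_forcefield(epsilon = 0.2, sigma = 5, screening_length = Inf,
                       cutoff = 20, dielectric = 1, shift = FALSE)
  en <- report_energies(sys, ff)
  coul <- en$energy_kcal_mol[en$component == "coulomb"]
  expect_equal(coul, -332.0716 / 10, tolerance = 1e-10)
  expect_equal(en$energy_kcal_mol[en$component == "total"],
               sum(en$energy_kcal_mol[en$component != "total"]),
               tolerance = 1e-12)
  # neutral beads beyond every interaction range: all components zero
  far <- two_bead_system(c("IM1", "HOAC"), d = 22, box_edge = 50)
  en2 <- report_energies(far, ff)
  expect_equal(en2$energy_kcal_mol, c(0, 0, 0))
  # reporters are pure: system unchanged
  expect_identical(report_charges(sys), report_charges(sys))
})
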
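# Kabsch-Sander H-bond energies, DSSP class assignment and helicity
# occupancy maps.

test_that("hydrogen-bond energy follows the electrostatic model", {
  # ideal alpha-helix i -> i+4 geometry is well below the -0.5 cutoff
  h <- build_ideal_helix(10)
  xyz <- h$frame$coordinates
  atom <- function(i, nm) xyz[(i - 1) * 4 + match(nm, c("N", "CA", "C", "O")), ]
  # reconstruct donor H of residue 6 from the preceding carbonyl
  u <- atom(5, "C") - atom(5, "O")
  hpos <- atom(6, "N") + u / sqrt(sum(u^2))
  e <- backbone_hbond_energy(atom(6, "N"), hpos, atom(2, "C"), atom(2, "O"))
  expect_lt(e, -0.5)
  # distant donor/acceptor: negligible energy
  far <- backbone_hbond_energy(c(20, 0, 0), c(20, 1, 0), c(0, 0, 0), c(0, 1, 0))
  expect_lt(abs(far), 0.1)
  # the formula depends only on the four distances
  e1 <- backbone_hbond_energy(c(0, 3, 0), c(0, 2, 0), c(0, 0, 0), c(0, 1, 0))
  e2 <- backbone_hbond_energy(c(3, 0, 0), c(2, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(e1, e2, tolerance = 1e-12)
  # overlapping atoms clamp and flag
  cl <- backbone_hbond_energy(c(0, 0.2, 0), c(0, 0.1, 0), c(0, 0, 0), c(0, 0.05, 0))
  expect_true(isTRUE(attr(cl, "flagged")))
  expect_equal(as.numeric(cl), -9.9)
})

test_that("ideal helices and short peptides are classified correctly", {
  h <- build_ideal_helix(14)
  ss <- assign_secstruct(h$frame, h$topology)
  expect_equal(length(ss), 14L)
  expect_true(all(ss[3:12] == "H"))
  # every residue gets exactly one label from the DSSP alphabet
  expect_true(all(ss %in% c("H", "G", "I", "E", "B", "T", "S", "-")))
  # 3-10-like torsions yield G
  g <- build_ideal_helix(12, phi = -49, psi = -26)
  ssg <- assign_secstruct(g$frame, g$topology)
  expect_true(all(ssg[3:10] == "G"))
  # isolated extended strand: no E without a bridge partner
  e <- build_peptide(rep(-140, 10), rep(135, 10))
  sse <- assign_secstruct(e$frame, e$topology)
  expect_false(any(sse %in% c("E", "B")))
  # 3-residue peptide is too short for any n-turn
  p3 <- build_peptide(rep(-57, 3), rep(-47, 3))
  expect_true(all(assign_secstruct(p3$frame, p3$topology) == "-"))
})

test_that("assignment agrees with the mdtraj reference implementation", {
  dir <- tempfile(); dir.create(dir)
  structures <- list(
    helix20 = build_ideal_helix(20),
    helix310 = build_ideal_helix(12, phi = -49, psi = -26),
    strand = build_peptide(rep(-140, 12), rep(135, 12)))
  m <- spb_model()
  total <- 0L; agree <- 0L
  for (nm in names(structures)) {
    s <- structures[[nm]]
    path <- file.path(dir, paste0(nm, ".pdb"))
    write_pdb_models(one_frame_traj(s$frame, s$topology), path)
    ref <- strsplit(mdtraj_dssp(path), "")[[1]]
    ours <- unname(assign_secstruct(s$frame, s$topology))
    expect_equal(length(ref), length(ours))
    total <- total + length(ours); agree <- agree + sum(ours == ref)
  }
  for (conf in c("closed", "open")) {
    path <- file.path(dir, paste0("spb_", conf, ".pdb"))
    write_pdb_models(one_frame_traj(m[[conf]], m$topology), path)
    ref <- strsplit(mdtraj_dssp(path), "")[[1]]
    ours <- unname(assign_secstruct(m[[conf]], m$topology))
    total <- total + length(ours); agree <- agree + sum(ours == ref)
  }
  expect_gte(agree / total, 0.95)
})

test_that("helical binarization and occupancy maps average correctly", {
  expect_equal(is_helical(c("H", "G", "I", "E", "T", "-")),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # all replicates helical -> occupancy 1 everywhere
  all_h <- matrix(TRUE, 20, 5)
  occ <- helicity_occupancy(list(all_h, all_h), time_bins = 4)
  expect_true(all(occ == 1))
  # 3 of 5 replicates helical at a residue-bin -> 0.6
  maps <- c(replicate(3, matrix(TRUE, 10, 2), simplify = FALSE),
            replicate(2, matrix(FALSE, 10, 2), simplify = FALSE))
  occ2 <- helicity_occupancy(maps, time_bins = 5)
  expect_true(all(abs(occ2 - 0.6) < 1e-12))
  # single replicate: occupancy equals its own binarized map
  m1 <- matrix(c(TRUE, FALSE), 6, 2)
  expect_equal(unname(helicity_occupancy(list(m1), time_bins = 6)),
               unname(m1) * 1)
  # replicate order does not matter
  expect_equal(helicity_occupancy(maps, 5), helicity_occupancy(rev(maps), 5))
  # unequal replicate lengths map onto the common fraction axis
  occ3 <- helicity_occupancy(list(matrix(TRUE, 30, 2), matrix(FALSE, 50, 2)),
                             time_bins = 10)
  expect_true(all(abs(occ3 - 0.5) < 0.2))
  expect_error(helicity_occupancy(list(matrix(TRUE, 5, 2), matrix(TRUE, 5, 3))),
               "mismatched")
})

test_that("per-frame classes partition the residues of a trajectory", {
  # low thermal noise: i.i.d. displacements beyond ~0.2 A disrupt the
  # sharply distance-dependent H-bond energies, as documented
  sim <- simulate_hinge_trajectory(hinge_params(n_frames = 5, seed = 50,
                                                noise_sigma = 0.1))
  ss <- secstruct_series(sim$trajectory)
  expect_equal(dim(ss), c(5L, 79L))
  expect_true(all(ss %in% c("H", "G", "I", "E", "B", "T", "S", "-")))
  # helical segments of the generator show up as helix classes
  hel <- is_helical(ss)
  expect_gt(mean(hel[, 10:18]), 0.9)   # helix 1 core
  expect_gt(mean(hel[, 47:60]), 0.9)   # helix 3 core
  expect_lt(mean(hel[, 75:79]), 0.1)   # C-terminal tail is coil
})
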
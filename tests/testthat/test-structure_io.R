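# Multi-model PDB parsing contracts, sequence/charge bookkeeping,
# disulfide detection and centers of mass.

test_that("multi-model PDB parsing honors the frame/topology contract", {
  xyz1 <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE)
  p <- write_mini_pdb(tempfile(fileext = ".pdb"),
                      list(mini_model(xyz1)))
  tr <- read_pdb_models(p)
  expect_equal(n_frames(tr), 1L)
  expect_equal(dim(tr$coords)[2], 3L)
  expect_equal(tr$coords[1, , ], xyz1, tolerance = 1e-6)

  # second model dropping an atom must be named in the error
  p2 <- write_mini_pdb(tempfile(fileext = ".pdb"),
                       list(mini_model(xyz1), mini_model(xyz1[1:2, ])))
  expect_error(read_pdb_models(p2), "model 2")

  # unknown residue code: warning, atoms retained
  bad <- mini_model(xyz1, resname = "XYZ")
  p3 <- write_mini_pdb(tempfile(fileext = ".pdb"), list(bad))
  expect_warning(tr3 <- read_pdb_models(p3), "XYZ")
  expect_equal(dim(tr3$coords)[2], 3L)
})

test_that("write/read round-trip preserves coordinates and topology", {
  sim <- simulate_hinge_trajectory(hinge_params(n_frames = 3, seed = 11))
  tr <- sim$trajectory
  path <- tempfile(fileext = ".pdb")
  write_pdb_models(tr, path)
  back <- read_pdb_models(path)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$topology$atoms$name, tr$topology$atoms$name)
  expect_equal(back$topology$atoms$residue_index, tr$topology$atoms$residue_index)
  expect_equal(back$topology$atoms$residue_name, tr$topology$atoms$residue_name)
  # PDB precision is 3 decimals
  expect_equal(back$coords, tr$coords, tolerance = 1e-3)
})

test_that("coordinate-table round-trip preserves frames, box and timestep", {
  sim <- simulate_hinge_trajectory(hinge_params(n_frames = 2, seed = 5))
  s <- add_uniform_solvent(get_frame(sim$trajectory, 1), sim$trajectory$topology,
                           box_edge = 60, n_solvent = 20, seed = 2)
  tr <- trajectory(s$topology, list(s$frame, s$frame), timestep = 0.5)
  path <- tempfile(fileext = ".dat")
  write_coord_table(tr, path)
  back <- read_coord_table(path, s$topology)
  expect_equal(back$coords, tr$coords, tolerance = 1e-6)
  expect_equal(back$box[1, ], c(60, 60, 60))
  expect_equal(back$timestep, 0.5)
})

test_that("sequence extraction maps residues and flags nonstandard codes", {
  top <- topology(data.frame(name = c("CA", "CA"),
                             residue_index = 1:2,
                             residue_name = c("ALA", "GLY")))
  expect_equal(extract_sequence(top), "AG")
  top2 <- topology(data.frame(name = c("CA", "CA", "CA"),
                              residue_index = 1:3,
                              residue_name = c("ALA", "XXX", "GLY")))
  suppressWarnings(expect_equal(extract_sequence(top2), "AXG"))
  # synthetic SP-B reference model carries the full 79-residue chain
  m <- spb_model()
  expect_equal(nchar(extract_sequence(m$topology)), 79L)
  expect_equal(extract_sequence(m$topology), spb_mature_sequence())
})

test_that("charge census follows pH 7.4 rules and is order-invariant", {
  cs <- count_charged_residues("KRDE")
  expect_equal(cs$n_positive, 2L)
  expect_equal(cs$n_negative, 2L)
  expect_equal(cs$net_charge, 0L)
  expect_equal(count_charged_residues("GGGG")$net_charge, 0L)
  # His neutral at pH 7.4
  expect_equal(count_charged_residues("HHH")$net_charge, 0L)
  # mature SP-B: 9 positive, 2 negative, net +7
  cs2 <- count_charged_residues(spb_mature_sequence())
  expect_equal(cs2$n_positive, 9L)
  expect_equal(cs2$n_negative, 2L)
  expect_equal(cs2$net_charge, 7L)
  # permutation invariance
  set.seed(4)
  perm <- paste(sample(strsplit(spb_mature_sequence(), "")[[1]]), collapse = "")
  expect_equal(count_charged_residues(perm)$net_charge, 7L)
  expect_error(count_charged_residues(""), "non-empty")
})

test_that("neutralizing ion count mirrors the net charge", {
  expect_equal(neutralizing_ion_count(count_charged_residues(spb_mature_sequence())),
               list(species = "anion", count = 7L))
  expect_equal(neutralizing_ion_count(0L), list(species = "none", count = 0L))
  expect_equal(neutralizing_ion_count(-3L), list(species = "cation", count = 3L))
})

test_that("disulfide detection pairs sulfurs greedily and symmetrically", {
  # no cysteines -> empty
  m0 <- toy_topology(3)
  fr0 <- frame(diag(3))
  expect_equal(nrow(detect_disulfides(fr0, m0)), 0L)
  # two SG atoms 2.05 A apart -> one pair
  at <- data.frame(name = c("CA", "SG", "CA", "SG"),
                   residue_index = c(1, 1, 2, 2),
                   residue_name = "CYS")
  top <- topology(at)
  fr <- frame(rbind(c(0, 0, 0), c(0, 0, 1), c(5, 0, 0), c(0, 0, 3.05)))
  got <- detect_disulfides(fr, top)
  expect_equal(unname(got), matrix(c(1L, 2L), 1))
  # beyond cutoff -> none
  fr2 <- frame(rbind(c(0, 0, 0), c(0, 0, 1), c(5, 0, 0), c(0, 0, 4)))
  expect_equal(nrow(detect_disulfides(fr2, top)), 0L)
  # CYS without SG warns and is skipped
  top3 <- topology(data.frame(name = c("CA", "CA", "SG"),
                              residue_index = c(1, 2, 2),
                              residue_name = "CYS"))
  expect_warning(detect_disulfides(frame(diag(3)), top3), "skipped")
  # synthetic closed SP-B model: exactly the saposin pattern, both frames
  m <- spb_model()
  expected <- matrix(c(8L, 77L, 11L, 71L, 35L, 46L), 3, 2, byrow = TRUE)
  expected <- expected[order(expected[, 1]), ]
  for (fr in list(m$closed, m$open)) {
    got <- detect_disulfides(fr, m$topology)
    expect_equal(unname(got), expected)
  }
})

test_that("center of mass is mass-weighted and validated", {
  top1 <- toy_topology(1)
  expect_equal(center_of_mass(frame(matrix(c(1, 2, 3), 1)), top1, c(1, 1)),
               c(1, 2, 3))
  # two equal masses at +/- x -> origin
  top2 <- toy_topology(2)
  expect_equal(center_of_mass(frame(rbind(c(-2, 0, 0), c(2, 0, 0))), top2, c(1, 2)),
               c(0, 0, 0))
  # 4-atom mixed-mass toy vs direct arithmetic
  masses <- c(1, 2, 3, 10)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 4))
  top4 <- toy_topology(4, mass = masses)
  expect_equal(center_of_mass(frame(xyz), top4, c(1, 4)),
               colSums(xyz * masses) / sum(masses))
  expect_error(center_of_mass(frame(xyz), top4, c(9, 10)), "empty selection")
})
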
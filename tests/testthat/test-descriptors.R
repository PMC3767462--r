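fix <- generate_fixture_molecules()

test_that("molecular weight sums standard atomic masses incl. implicit H", {
  expect_equal(molecular_weight(fix$atom_H), 1.008)
  expect_equal(molecular_weight(fix$benzene), 78.114, tolerance = 1e-4)
  expect_equal(molecular_weight(fix$water), 18.015, tolerance = 1e-4)
  # SMILES-derived ethanol has implicit hydrogens only
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines("CCO ethanol", smi)
  mol <- read_structures(smi, "smiles")[[1]]
  expect_equal(molecular_weight(mol), molecular_weight(fix$ethanol),
               tolerance = 1e-6)
  xx <- molecule_record("bad", tibble::tibble(element = "Xx",
                                              x = 0, y = 0, z = 0))
  expect_error(molecular_weight(xx), "Xx")
})

test_that("hydrogen-bond counts follow the shipped pattern set", {
  expect_equal(count_hba(fix$methane), 0L)
  expect_equal(count_hbd(fix$methane), 0L)
  # heavy-atom donor convention: water's two O-H hydrogens count once
  expect_equal(count_hbd(fix$water), 1L)
  # hand application of the shipped rules to ethanol: one O acceptor, one
  # H-bearing O donor
  expect_equal(count_hba(fix$ethanol), 1L)
  expect_equal(count_hbd(fix$ethanol), 1L)
  # configurable pattern set
  wide <- hbond_patterns(acceptor_elements = c("N", "O", "F"))
  expect_equal(count_hba(fix$ethanol, wide), 1L)
})

test_that("rotatable bonds: single, acyclic, non-terminal, amide excluded", {
  expect_equal(count_rotatable_bonds(fix$cc_dimer), 0L)  # terminal (ethane-like)
  expect_equal(count_rotatable_bonds(fix$benzene), 0L)   # all ring bonds
  # n-butane: enumerate bonds against the definition -> exactly C2-C3
  butane <- molecule_record("butane", tibble::tibble(
    element = rep("C", 4), x = c(0, 1.54, 3.08, 4.62),
    y = 0, z = 0), bonds = tibble::tibble(from = 1:3, to = 2:4, order = 1L))
  expect_equal(count_rotatable_bonds(butane), 1L)
  # N-methylacetamide: both methyl C-C/N-C bonds are terminal; the only
  # non-terminal single bond is the amide C-N, excluded by default
  nma <- molecule_record("nma", tibble::tibble(
    element = c("C", "C", "O", "N", "C"),
    x = c(0, 1.5, 2.1, 2.2, 3.6), y = c(0, 0, 1.1, -1.1, -1.2), z = 0),
    bonds = tibble::tibble(from = c(1L, 2L, 2L, 4L),
                           to = c(2L, 3L, 4L, 5L),
                           order = c(1L, 2L, 1L, 1L)))
  expect_equal(count_rotatable_bonds(nma), 0L)
  expect_equal(count_rotatable_bonds(nma, exclude_amide = FALSE), 1L)
})

test_that("globularity follows its closed form and spots bad input", {
  r <- 2.5
  expect_equal(globularity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  # two disjoint equal spheres: v = 2v0, s = 2s0 -> 2^(-1/3)
  expect_equal(globularity(2 * 4 / 3 * pi * r^3, 2 * 4 * pi * r^2),
               2^(-1 / 3))
  expect_error(globularity(-1, 10), "positive")
  expect_error(globularity(10, 0), "positive")
})

test_that("cohesion index is the exact ratio HBA*HBD/S_mol", {
  expect_equal(cohesion_index(0, 5, 400), 0)
  expect_equal(cohesion_index(4, 2, 500), 0.016)
  expect_equal(cohesion_index(4, 2, 1000), 0.008)  # doubling S_mol halves it
  expect_error(cohesion_index(1, 1, 0), "positive")
})

test_that("logP backends are pluggable, deterministic and auditable", {
  expect_equal(estimate_logp(fix$benzene, "zero"), 0)
  expect_error(estimate_logp(fix$benzene, "no_such_backend"), "unregistered")
  expect_identical(estimate_logp(fix$ethanol), estimate_logp(fix$ethanol))
  # hand summation from the shipped contribution table
  tab <- logp_atom_contributions()
  co <- stats::setNames(tab$contribution, tab$element)
  expect_equal(estimate_logp(fix$ethanol, "atomic"),
               2 * co[["C"]] + 6 * co[["H"]] + co[["O"]])
  register_logp_backend("const7", function(mol) 7)
  expect_equal(estimate_logp(fix$water, "const7"), 7)
})

test_that("compute_descriptors assembles a computed-provenance profile table", {
  prof <- compute_descriptors(list(fix$methane, fix$water))
  expect_equal(prof$id, c("methane", "water"))
  expect_true(all(c("MW", "HBA", "HBD", "NRB", "S_mol", "S_mol_hfob",
                    "V_mol", "Glob", "Ind_coh", "logP") %in% names(prof)))
  expect_true(all(provenance(prof) == "computed"))
  expect_equal(prof$Ind_coh[1], 0)
  expect_gt(prof$Ind_coh[2], 0)
})
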
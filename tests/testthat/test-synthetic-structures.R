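test_that("toy dimer honours requested counts and all structural invariants", {
  dim <- generate_toy_dimer(30, 6, 0.5, c(11, 62), seed = 1)
  expect_equal(nrow(dim), 60)
  ann <- structure_annotations(dim)
  expect_equal(nrow(ann$interface_pairs), 6)
  expect_equal(nrow(ann$domain_swap_pairs), 3)
  # out-of-range calcium residue 62 dropped, 11 kept on both chains
  expect_equal(sort(ann$calcium_sites), c(11, 41))
  expect_true(validate_structure(dim))

  # domain-swap pairs lie in both chains' N-terminal strands
  h <- 15
  expect_true(all(dim$residue_index[ann$domain_swap_pairs[, 1]] <= h))
  expect_true(all(dim$residue_index[ann$domain_swap_pairs[, 2]] <= h))

  # invariants hold across seeds and sizes
  for (seed in 1:5) {
    expect_true(validate_structure(
      generate_toy_dimer(24, 8, 0.25, c(3, 7), seed = seed)
    ))
  }
})

test_that("generators are bitwise reproducible and seeds differ", {
  a <- generate_toy_dimer(10, 1, 0, seed = 7)
  b <- generate_toy_dimer(10, 1, 0, seed = 7)
  expect_identical(a, b)
  c <- generate_toy_dimer(10, 1, 0, seed = 8)
  expect_false(identical(a$x, c$x))

  for (kind in c("monomer", "oligomer", "seed")) {
    s1 <- generate_ligand(ligand_spec(kind, 12, seed = 3))
    s2 <- generate_ligand(ligand_spec(kind, 12, seed = 3))
    expect_identical(s1, s2)
  }
})

test_that("infeasible interface contact counts fail with a named constraint", {
  expect_error(generate_toy_dimer(10, 30, 1, seed = 1), "domain-swap")
  expect_error(generate_toy_dimer(10, 30, 0, seed = 1), "non-swap")
})

test_that("ligand classes realize the intended contact architecture", {
  mono <- generate_ligand(ligand_spec("monomer", 15, seed = 3))
  expect_equal(nrow(mono), 15)
  expect_equal(nrow(find_native_contacts(mono)), 0)

  sd <- generate_ligand(ligand_spec("seed", 10, n_chains = 4, seed = 2))
  expect_equal(nrow(sd), 40)
  pairs <- structure_annotations(sd)$inter_peptide_pairs
  chain_of <- function(b) sd$chain_id[b]
  link <- unique(paste(chain_of(pairs[, 1]), chain_of(pairs[, 2])))
  expect_setequal(link, c("L1 L2", "L2 L3", "L3 L4"))

  # oligomer realized density within 20% of target (brute-force scan)
  spec <- ligand_spec("oligomer", 20, intra_contact_density = 0.5, seed = 5)
  olig <- generate_ligand(spec)
  pos <- cbind(olig$x, olig$y, olig$z)
  cnt <- 0
  for (i in 1:19) {
    for (j in (i + 1):20) {
      if (j - i >= 3 && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 6.5) {
        cnt <- cnt + 1
      }
    }
  }
  expect_gte(cnt, 8)
  expect_lte(cnt, 12)
})

test_that("rigidity ordering monomer < oligomer < seed is realized structurally", {
  per_residue <- function(s) {
    topo <- build_topology(s)
    nrow(topo$contacts) / nrow(s)
  }
  m <- per_residue(generate_ligand(ligand_spec("monomer", 15, seed = 1)))
  o <- per_residue(generate_ligand(ligand_spec("oligomer", 15, seed = 1)))
  s <- per_residue(generate_ligand(ligand_spec("seed", 10, 4, seed = 1)))
  expect_lt(m, o)
  expect_lt(o, s)
})

test_that("ligand net charge sign follows the specification", {
  net <- function(kind, sign) {
    lig <- generate_ligand(ligand_spec(kind, 15, net_charge_sign = sign))
    sum(assign_bead_properties(lig)$charge)
  }
  expect_lt(net("monomer", "negative"), 0)
  expect_gt(net("oligomer", "positive"), 0)
  expect_equal(net("monomer", "neutral"), 0)
})

test_that("placement respects separation, box and determinism", {
  dimer <- generate_toy_dimer(20, 4, 0.5, seed = 1)
  lig <- generate_ligand(ligand_spec("monomer", 10, seed = 2))
  centroids <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    sys <- place_components(dimer, lig, min_separation = 12,
                            box_edge = 90, seed = s)
    ann <- structure_annotations(sys)
    pa <- cbind(sys$x, sys$y, sys$z)[ann$component_1, ]
    pb <- cbind(sys$x, sys$y, sys$z)[ann$component_2, ]
    dmin <- min(as.matrix(stats::dist(rbind(pa, pb)))[
      seq_len(nrow(pa)), nrow(pa) + seq_len(nrow(pb))])
    expect_gte(dmin, 12)
    expect_true(all(sys$x >= 0 & sys$x <= 90))
    centroids[s, ] <- colMeans(pb)
  }
  expect_equal(nrow(unique(round(centroids, 6))), 20)

  s1 <- place_components(dimer, lig, 12, 90, seed = 4)
  s2 <- place_components(dimer, lig, 12, 90, seed = 4)
  expect_identical(s1$x, s2$x)

  # degenerate bound: components may touch but never overlap hard
  s0 <- place_components(dimer, lig, 0, 90, seed = 1)
  expect_true(validate_structure(s0))

  expect_error(place_components(dimer, lig, 12, 20, seed = 1), "box")
})

test_that("peptide masses match the printed molecular weights", {
  expect_equal(peptide_average_mass(amyloid_sequence("abeta42")),
               4514, tolerance = 0.5 / 4514)
  expect_equal(peptide_average_mass(amyloid_sequence("asyn")),
               14460, tolerance = 0.5 / 14460)
  expect_equal(peptide_average_mass("G"), 75.07, tolerance = 1e-3)
  expect_error(peptide_average_mass("AXZ"), "position 2")
})

test_that("peptide mass is additive up to one water", {
  w <- 18.0153
  set.seed(1)
  aa <- residue_properties()$code
  for (k in 1:5) {
    a <- paste(sample(aa, 8, TRUE), collapse = "")
    b <- paste(sample(aa, 5, TRUE), collapse = "")
    expect_equal(
      peptide_average_mass(paste0(a, b)),
      peptide_average_mass(a) + peptide_average_mass(b) - w,
      tolerance = 1e-9
    )
  }
})

test_that("PDB coarse-graining follows the CA/CB and altLoc rules", {
  txt <- toy_pdb_text()
  s <- read_pdb_coarse(txt, "backbone")
  expect_equal(nrow(s), 3)
  expect_equal(s$residue_name, c("A", "G", "S"))
  expect_equal(s$x, c(1.458, 5.100, 8.700))

  # backbone+sidechain: GLY contributes no CB -> 5 beads
  s2 <- read_pdb_coarse(txt, "backbone+sidechain")
  expect_equal(nrow(s2), 5)
  expect_equal(sum(s2$bead_kind == "sidechain"), 2)

  # altLoc: first occurrence wins
  alt <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  sa <- read_pdb_coarse(alt, "backbone")
  expect_equal(sa$x, 1.0)

  # missing CA and malformed lines produce named errors
  expect_error(read_pdb_coarse(c(
    "ATOM      1  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C"
  )), "no CA")
  bad <- txt
  bad[3] <- "ATOM      2  CA  ALA A   1       xxx"
  expect_error(read_pdb_coarse(bad), "line 3")

  # insertion codes rejected
  ins <- c(
    "ATOM      1  CA  ALA A   1A      1.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  expect_error(read_pdb_coarse(ins), "insertion")
})

test_that("structure XYZ writer round-trips counts and coordinates", {
  dim <- generate_toy_dimer(12, 2, 0.5, seed = 1)
  f <- tempfile(fileext = ".xyz")
  write_structure_xyz(dim, f)
  lines <- readLines(f)
  expect_equal(as.integer(lines[1]), 24)
  expect_equal(length(lines), 26)
  expect_true(file.exists(paste0(f, ".json")))
  third <- strsplit(lines[3], " ")[[1]]
  expect_equal(as.numeric(third[2]), dim$x[1], tolerance = 1e-5)
})
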
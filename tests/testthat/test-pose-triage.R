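# A hand-built minimal scene: one ligand atom vs one receptor atom at a
# controlled distance, with controllable roles/charges.
two_atom_scene <- function(dist, lig_role = "donor", rec_role = "acceptor",
                           lig_charge = 0, rec_charge = 0) {
  lig <- data.frame(element = if (lig_role == "donor") "N" else "O",
                    x = 0, y = 0, z = 0, formal_charge = lig_charge,
                    is_donor = lig_role == "donor",
                    is_acceptor = lig_role == "acceptor")
  rec <- data.frame(resname = "GLU", resno = 1948L, atom = "OE1", element = "O",
                    x = dist, y = 0, z = 0, formal_charge = rec_charge,
                    is_donor = rec_role == "donor",
                    is_acceptor = rec_role == "acceptor",
                    is_sidechain = TRUE)
  pose_scene(lig, rec)
}

test_that("polar contacts require complementarity and strict distance", {
  expect_equal(nrow(detect_polar_contacts(two_atom_scene(2.8))), 1L)
  expect_equal(nrow(detect_polar_contacts(two_atom_scene(3.5))), 0L)   # boundary
  expect_equal(nrow(detect_polar_contacts(two_atom_scene(3.4999))), 1L)
  expect_equal(nrow(detect_polar_contacts(
    two_atom_scene(2.8, lig_role = "donor", rec_role = "donor"))), 0L)
})

test_that("contacts are typed salt bridge only for opposite formal charges", {
  hb <- detect_polar_contacts(two_atom_scene(2.8))
  expect_equal(hb$kind, "hydrogen_bond")
  sb <- detect_polar_contacts(two_atom_scene(2.8, lig_charge = 1, rec_charge = -1))
  expect_equal(sb$kind, "salt_bridge")
  same <- detect_polar_contacts(two_atom_scene(2.8, lig_charge = -1, rec_charge = -1))
  expect_equal(same$kind, "hydrogen_bond")
  expect_equal(sb$chain_part, "side_chain")
})

test_that("scene validation rejects inconsistent atoms", {
  lig <- data.frame(element = "C", x = 0, y = 0, z = 0, formal_charge = 0,
                    is_donor = TRUE, is_acceptor = FALSE)
  rec <- two_atom_scene(3)$receptor
  expect_error(pose_scene(lig, rec), "N, O, S")
  lig2 <- data.frame(element = "N", x = NaN, y = 0, z = 0, formal_charge = 0,
                     is_donor = TRUE, is_acceptor = FALSE)
  expect_error(pose_scene(lig2, rec), "finite")
  expect_error(detect_polar_contacts(pose_scene(two_atom_scene(3)$ligand[0, ], rec)),
               "ligand and receptor")
})

test_that("contact detection matches the all-pairs oracle on generated scenes", {
  set.seed(31)
  for (k in 1:40) {
    sc <- gen_pose_scene(sample(0:5, 1), seed = 1000 + k,
                         n_unsat_donors = sample(0:1, 1))
    got <- detect_polar_contacts(sc)
    want <- contact_pairs_oracle(sc)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_setequal(paste(got$ligand_atom, got$resno, got$receptor_atom),
                      paste(want$ligand_atom, want$resno, want$receptor_atom))
    }
  }
})

test_that("contacts are invariant under rigid rotation and translation", {
  set.seed(17)
  sc <- gen_pose_scene(3, seed = 77)
  base <- detect_polar_contacts(sc)
  for (k in 1:5) {
    moved <- transform_scene(sc, random_rotation(), rnorm(3, 0, 20))
    got <- detect_polar_contacts(moved)
    expect_equal(got$resno, base$resno)
    expect_equal(got$distance, base$distance, tolerance = 1e-9)
  }
})

test_that("key-residue filter counts distinct residues and is monotone", {
  contacts <- data.frame(resname = c("GLU", "ALA"), resno = c(1948L, 1950L),
                         ligand_atom = 1:2, receptor_atom = c("OE1", "O"),
                         distance = c(2.9, 3.0), kind = "hydrogen_bond",
                         chain_part = c("side_chain", "main_chain"))
  v <- key_residue_filter(contacts)
  expect_true(as.logical(v)); expect_equal(attr(v, "count"), 2L)
  # two contacts to the same residue count once and fail
  dup <- contacts; dup$resno <- c(1948L, 1948L); dup$resname <- "GLU"
  v2 <- key_residue_filter(dup)
  expect_false(as.logical(v2)); expect_equal(attr(v2, "count"), 1L)
  expect_true(as.logical(key_residue_filter(dup, count = "pairs")))
  # non-key residues never count
  alien <- contacts; alien$resno <- c(1L, 2L)
  expect_equal(attr(key_residue_filter(alien), "count"), 0L)
  # monotonicity: appending contacts never flips pass to fail
  set.seed(4)
  for (k in 1:20) {
    n <- sample(1:6, 1)
    base <- contacts[sample(1:2, n, replace = TRUE), ]
    more <- rbind(base, data.frame(resname = "LYS", resno = 1906L,
                                   ligand_atom = 9L, receptor_atom = "NZ",
                                   distance = 3.1, kind = "hydrogen_bond",
                                   chain_part = "side_chain"))
    expect_gte(attr(key_residue_filter(more), "count"),
               attr(key_residue_filter(base), "count"))
    if (as.logical(key_residue_filter(base))) {
      expect_true(as.logical(key_residue_filter(more)))
    }
  }
})

test_that("unsatisfied-polar counting distinguishes burial and satisfaction", {
  exposed <- gen_pose_scene(0, seed = 2)
  expect_equal(count_unsatisfied_polar(exposed), c(donors = 0L, acceptors = 0L))
  one_donor <- gen_pose_scene(0, seed = 3, n_unsat_donors = 1)
  expect_equal(count_unsatisfied_polar(one_donor), c(donors = 1L, acceptors = 0L))
  mixed <- gen_pose_scene(2, seed = 4, n_unsat_donors = 1, n_unsat_acceptors = 2)
  expect_equal(count_unsatisfied_polar(mixed), c(donors = 1L, acceptors = 2L))
  # a buried donor with a partner at 3.0 A is satisfied
  sat <- gen_pose_scene(0, seed = 5, n_unsat_donors = 1)
  donor_idx <- which(sat$ligand$is_donor)
  partner <- data.frame(resname = "SER", resno = 2200L, atom = "OG", element = "O",
                        x = sat$ligand$x[donor_idx] + 3.0,
                        y = sat$ligand$y[donor_idx],
                        z = sat$ligand$z[donor_idx],
                        formal_charge = 0, is_donor = FALSE, is_acceptor = TRUE,
                        is_sidechain = TRUE)
  sat2 <- pose_scene(sat$ligand, rbind(sat$receptor, partner))
  expect_equal(count_unsatisfied_polar(sat2), c(donors = 0L, acceptors = 0L))
})

test_that("unsatisfied filter applies the printed conjunction and the or-variant", {
  expect_true(unsatisfied_filter(c(donors = 0L, acceptors = 3L), combine = "and"))
  expect_false(unsatisfied_filter(c(donors = 1L, acceptors = 3L), combine = "and"))
  expect_false(unsatisfied_filter(c(donors = 1L, acceptors = 0L), combine = "or"))
  expect_true(unsatisfied_filter(c(donors = 0L, acceptors = 2L), combine = "or"))
})

test_that("strain flag honors the table and passes unknown molecules with a warning", {
  tab <- data.frame(molecule_id = c("a", "b"), strain = c(7.0, 2.0))
  expect_false(as.logical(strain_flag("a", tab, threshold = 6.0)))
  expect_true(as.logical(strain_flag("b", tab, threshold = 6.0)))
  expect_true(as.logical(strain_flag("a", tab, threshold = Inf)))
  expect_warning(v <- strain_flag("zzz", tab, threshold = 6.0), "no strain")
  expect_true(as.logical(v))
})

test_that("grid specification centers on the key-residue heavy-atom centroid", {
  one <- data.frame(resname = "LYS", resno = 1906L, atom = "NZ", element = "N",
                    x = 1, y = 2, z = 3, formal_charge = 1,
                    is_donor = TRUE, is_acceptor = FALSE, is_sidechain = TRUE)
  g1 <- make_grid_spec(one, key_residue_set(data.frame(name = "LYS", number = 1906L)))
  expect_equal(unname(g1$center), c(1, 2, 3))
  a0 <- one; a0$x <- 0; a0$y <- 0; a0$z <- 0
  a2 <- one; a2$x <- 2; a2$y <- 0; a2$z <- 0; a2$atom <- "CB"; a2$element <- "C"
  g2 <- make_grid_spec(rbind(a0, a2),
                       key_residue_set(data.frame(name = "LYS", number = 1906L)))
  expect_equal(unname(g2$center), c(1, 0, 0))

  rec <- gen_pose_scene(3, seed = 6)$receptor
  g <- make_grid_spec(rec)
  keys <- key_residue_set()
  sel <- rec[rec$resno %in% keys$number & rec$element != "H", ]
  expect_equal(unname(g$center), c(mean(sel$x), mean(sel$y), mean(sel$z)))
  expect_equal(g$inner_box, rep(10, 3))
  expect_equal(g$outer_box, rep(30, 3))
  expect_error(make_grid_spec(rec[rec$resno != 1906, ]), "1906")
  f <- withr::local_tempfile(fileext = ".txt")
  write_grid_spec(g, f)
  expect_true(any(grepl("inner_box = 10 10 10", readLines(f))))
})

test_that("receptor PDB round trip preserves geometry and polar typing", {
  sc <- gen_pose_scene(2, seed = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(sc$receptor, f)
  back <- read_receptor_pdb(f)
  expect_equal(nrow(back), nrow(sc$receptor))
  expect_equal(back$resno, sc$receptor$resno)
  expect_equal(back$x, sc$receptor$x, tolerance = 1e-3)  # PDB 3-decimal fields
  # typing rules recover the generator's donor/acceptor flags for these atoms
  expect_equal(back$is_donor, sc$receptor$is_donor)
  expect_equal(back$is_acceptor, sc$receptor$is_acceptor)
  # grid built from the file matches the in-memory one
  g_file <- make_grid_spec(back)
  g_mem <- make_grid_spec(sc$receptor)
  expect_equal(g_file$center, g_mem$center, tolerance = 1e-3)
})

test_that("ligand SDF round trip preserves coordinates, charges and typing", {
  sc <- gen_pose_scene(3, seed = 9)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(sc$ligand, f, id = "POSE1")
  back <- read_pose_sdf(f)
  expect_named(back, "POSE1")
  lig <- back[["POSE1"]]
  expect_equal(nrow(lig), nrow(sc$ligand))
  expect_equal(lig$x, sc$ligand$x, tolerance = 1e-4)
  expect_equal(lig$element, sc$ligand$element)
  # isolated N atoms type as donors, isolated O as donor+acceptor
  expect_true(all(lig$is_donor[lig$element == "N"]))
  expect_true(all(lig$is_acceptor[lig$element == "O"]))
})
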
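test_that("benchmark curation filters, sorts, and deduplicates by potency", {
  ms <- fixture_cluster_set()
  kept_all <- select_benchmark_actives(ms, n_top = 60, mw_max = 500, dedup_tc = 0.99)
  expect_equal(nrow(kept_all), nrow(ms))    # nothing reaches TC 0.99
  expect_false(is.unsorted(-kept_all$pchembl))

  # one representative per planted scaffold once the cutoff bites
  reps <- select_benchmark_actives(ms, n_top = 60, mw_max = 500, dedup_tc = 0.5)
  expect_equal(nrow(reps), 3L)
  expect_setequal(reps$scaffold, 1:3)
  # the survivor of each scaffold is its most potent member
  for (s in 1:3) {
    expect_equal(reps$pchembl[reps$scaffold == s],
                 max(ms$pchembl[ms$scaffold == s]))
  }
  # kept set is pairwise below the threshold (exhaustive)
  tm <- tanimoto_matrix(reps$fp, reps$fp); diag(tm) <- 0
  expect_lt(max(tm), 0.5)
})

test_that("identical structures collapse to the more potent copy", {
  mt <- molecule_table(c(hi = "OCCc1ccccc1", lo = "c1ccccc1CCO"),
                       pchembl = c(9, 8))
  kept <- select_benchmark_actives(mt, n_top = 10, mw_max = 500, dedup_tc = 0.6)
  expect_equal(kept$id, "hi")
})

test_that("molecules without potency are skipped with a warning", {
  mt <- molecule_table(c(a = "CCO", b = "CCN"), pchembl = c(6, NA))
  expect_warning(kept <- select_benchmark_actives(mt, n_top = 10), "pChEMBL")
  expect_equal(kept$id, "a")
})

test_that("decoy matching enforces property windows and topological dissimilarity", {
  pool <- fixture_pool()
  active <- pool[1, ]
  # a pool of copies of the active itself can never supply decoys
  copies <- pool[rep(1, 5), ]; copies$id <- sprintf("cp%d", 1:5)
  expect_warning(none <- match_decoys(active, copies, n = 3), "shortfall")
  expect_equal(nrow(none), 0L)
  # zero tolerances against a distinct pool is empty too
  expect_warning(
    zero <- match_decoys(active, pool[-1, ], n = 3,
                         property_tolerances = list(mw = 0, clogp = 0, hbd = 0,
                                                    hba = 0, rotatable_bonds = 0)),
    "shortfall")
  expect_equal(nrow(zero), 0L)

  got <- suppressWarnings(match_decoys(active, pool[-1, ], n = 15,
                                       property_tolerances = list(mw = 60, clogp = 2,
                                                                  hbd = 2, hba = 3,
                                                                  rotatable_bonds = 4),
                                       tc_max_to_active = 0.35))
  expect_gt(nrow(got), 0L)
  # verify every window by direct comparison
  expect_true(all(abs(got$mw - active$mw) <= 60))
  expect_true(all(abs(got$clogp - active$clogp) <= 2))
  expect_true(all(abs(got$hbd - active$hbd) <= 2))
  expect_true(all(abs(got$hba - active$hba) <= 3))
  expect_true(all(abs(got$rotatable_bonds - active$rotatable_bonds) <= 4))
  expect_true(all(got$net_charge == active$net_charge))
  expect_true(all(got$tc_to_active < 0.35))
  expect_false(is.unsorted(got$tc_to_active))
})

test_that("novelty filter excludes strictly above the threshold with closest-reference audit", {
  ms <- fixture_cluster_set()
  refs <- ms[c(1, 6), ]; refs$id <- c("ref1", "ref2")
  out <- novelty_filter(ms, refs, tc_exclude_above = 0.35)
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(ms))
  # identical to a reference: excluded at TC 1
  self_row <- out$excluded[out$excluded$id == "SYN0001", ]
  expect_equal(self_row$closest_tc, 1.0)
  expect_equal(self_row$closest_ref_id, "ref1")
  # closest-reference report matches brute-force all-pairs computation
  for (i in seq_len(nrow(ms))) {
    tcs <- vapply(refs$fp, tanimoto, numeric(1), b = ms$fp[[i]])
    row <- rbind(out$kept, out$excluded)
    row <- row[row$id == ms$id[i], ]
    expect_equal(row$closest_tc, max(tcs))
    expect_equal(row$closest_ref_id, refs$id[which.max(tcs)])
  }
})

test_that("novelty threshold is strict: a molecule at exactly 0.35 is kept", {
  ms <- fixture_cluster_set()[1:2, ]
  # plant synthetic fingerprints with TC exactly 7/20 = 0.35
  ms$fp <- list(chem_fp(1:13), chem_fp(c(1:7, 100:106)))
  refs <- ms[2, ]; refs$id <- "ref"
  out <- novelty_filter(ms[1, ], refs, tc_exclude_above = 0.35)
  expect_equal(out$kept$id, ms$id[1])
  expect_equal(out$kept$closest_tc, 0.35)
})

test_that("empty reference set keeps everything with a warning", {
  ms <- fixture_cluster_set()[1:3, ]
  expect_warning(out <- novelty_filter(ms, ms[0, ]), "empty reference")
  expect_equal(nrow(out$kept), 3L)
})

test_that("property filter keeps the closed window and excludes beyond it", {
  ms <- fixture_cluster_set()[1:4, ]
  ms$mw <- c(399, 401, 300, 400)
  ms$clogp <- c(1.6, 1.0, 4.5, 4.0)
  kept <- property_filter(ms)
  expect_setequal(kept$id, ms$id[c(1, 4)])   # 399/1.6 kept; caps inclusive
})

test_that("leader clustering recovers planted clusters and satisfies its contract", {
  ms <- fixture_cluster_set()
  cl <- cluster_leader(ms, tc_cut = 0.5)
  expect_length(cl, 3L)
  assignment <- attr(cl, "assignment")
  # partition: every molecule appears exactly once
  all_members <- unlist(lapply(cl, function(c) c$members$id))
  expect_setequal(all_members, ms$id)
  expect_equal(length(all_members), nrow(ms))
  # clusters coincide with the planted scaffolds
  expect_true(all(tapply(assignment, ms$scaffold,
                         function(x) length(unique(x)) == 1)))
  for (c in cl) {
    rep_fp <- c$representative$fp[[1]]
    expect_equal(c$representative$energy, min(c$members$energy))
    for (k in seq_len(nrow(c$members))) {
      expect_gte(tanimoto(c$members$fp[[k]], rep_fp), 0.5)
    }
  }
  reps <- cluster_representatives(cl)
  tm <- tanimoto_matrix(reps$fp, reps$fp); diag(tm) <- 0
  expect_lt(max(tm), 0.5)
})

test_that("leader clustering degenerate cases", {
  ms <- fixture_cluster_set()[c(1, 6, 11), ]   # one per scaffold: all dissimilar
  cl <- cluster_leader(ms, tc_cut = 0.5)
  expect_length(cl, 3L)

  twins <- molecule_table(c(a = "OCCc1ccccc1", b = "c1ccccc1CCO"),
                          energy = c(-9, -8))
  cl2 <- cluster_leader(twins, tc_cut = 0.5)
  expect_length(cl2, 1L)
  expect_equal(cl2[[1]]$representative$energy, -9)

  noe <- fixture_cluster_set()[1:2, ]; noe$energy <- NA_real_
  expect_error(cluster_leader(noe), "energy")
})

test_that("substructure search retrieves exactly the planted scaffold family", {
  ms <- fixture_cluster_set()
  hits <- substructure_search(ms, "c1ccc2[nH]ccc2c1")   # indole core
  expect_setequal(hits$id, ms$id[ms$scaffold == 2])
  # a full member SMILES matches at least that member
  self <- substructure_search(ms, ms$smiles[1])
  expect_true(ms$id[1] %in% self$id)
  none <- substructure_search(molecule_table(c(x = "CCCCCC")), "c1ccccc1")
  expect_equal(nrow(none), 0L)
})
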
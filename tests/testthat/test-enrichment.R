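records <- function(labels, energies) {
  data.frame(molecule_id = sprintf("m%02d", seq_along(labels)),
             label = labels, energy = energies, stringsAsFactors = FALSE)
}

test_that("ROC curve geometry matches the step/tie conventions", {
  perfect <- compute_roc(records(c("active", "active", "decoy", "decoy"),
                                 c(-9, -8.5, -7, -6)))
  expect_equal(perfect$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(perfect$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(auc_percent(perfect), 100)

  alternating <- compute_roc(records(c("active", "decoy", "active", "decoy"),
                                     c(-9, -8, -7, -6)))
  expect_equal(auc_percent(alternating), 75)  # 3 of 4 ordered pairs

  tied <- compute_roc(records(c("active", "active", "decoy", "decoy"),
                              rep(-7, 4)))
  expect_equal(tied$fpr, c(0, 1))
  expect_equal(tied$tpr, c(0, 1))
  expect_equal(auc_percent(tied), 50)
})

test_that("single-class input signals undefined enrichment", {
  expect_error(compute_roc(records(rep("active", 3), c(-9, -8, -7))),
               "at least one active and one decoy")
  expect_error(compute_roc(records(c("active", "decoy"), c(-9, Inf))), "finite")
})

test_that("trapezoidal AUC equals pair counting with tie credit on random instances", {
  set.seed(101)
  for (k in 1:200) {
    rec <- random_tied_records()
    expect_equal(auc_percent(compute_roc(rec)), auc_pair_oracle(rec),
                 tolerance = 1e-12)
  }
})

test_that("LogAUC hits its closed-form limits", {
  perfect <- compute_roc(records(c("active", "active", "decoy", "decoy"),
                                 c(-9, -8.5, -7, -6)))
  expect_equal(logauc_percent(perfect), 100 * (1 - 0.145), tolerance = 1e-12)

  diagonal <- compute_roc(records(c("active", "active", "decoy", "decoy"),
                                  rep(-7, 4)))
  # analytic diagonal area is (1 - lambda)/(3 ln 10) = 0.14462, so the
  # baseline-corrected score sits within 0.05 of zero
  expect_lt(abs(logauc_percent(diagonal)), 0.05)

  worst <- compute_roc(records(c("decoy", "decoy", "active", "active"),
                               c(-9, -8.5, -7, -6)))
  expect_equal(logauc_percent(worst), -14.5, tolerance = 1e-12)
  expect_error(logauc_percent(perfect, lambda = 1.5), "lambda")
  expect_error(logauc_percent(perfect, lambda = 0), "lambda")
})

test_that("LogAUC is invariant under strictly monotone energy transforms", {
  set.seed(5)
  rec <- records(sample(c(rep("active", 8), rep("decoy", 30))),
                 rnorm(38, -8))
  base <- logauc_percent(compute_roc(rec))
  for (f in list(function(e) 2 * e + 3, function(e) -1 / (e - 10),
                 function(e) exp(e / 4))) {
    rec2 <- rec; rec2$energy <- f(rec$energy)
    expect_equal(logauc_percent(compute_roc(rec2)), base, tolerance = 1e-12)
  }
})

test_that("degrading a perfect ranking monotonically lowers LogAUC", {
  n_act <- 10; n_dec <- 90
  lab <- c(rep("active", n_act), rep("decoy", n_dec))
  vals <- c()
  for (shift in 0:5) {
    # push the actives progressively deeper into the decoy block
    energy <- c(seq_len(n_act) + shift * 6, (n_act + 1):(n_act + n_dec))
    vals <- c(vals, logauc_percent(compute_roc(records(lab, energy))))
  }
  expect_true(all(diff(vals) < 0))
})

test_that("Gaussian score tables reproduce the closed-form expected AUC", {
  delta <- 1.5; sdev <- 1
  spec <- score_matrix_spec(1, 2000, 2000, active_mean_energy = -8 - delta,
                            decoy_mean_energy = -8, sd = sdev, seed = 99)
  tab <- gen_score_tables(spec)[[1]]
  expected <- 100 * pnorm(delta / (sdev * sqrt(2)))
  expect_equal(auc_percent(compute_roc(tab)), expected, tolerance = 0.02)
})

test_that("conformer ranking fills consistent ranks and breaks ties by id", {
  one <- list(only = records(c("active", "decoy"), c(-9, -8)))
  rep1 <- rank_conformers(one)
  expect_equal(rep1$rank_by_logauc, 1L)
  expect_equal(rep1$rank_by_mean_active_energy, 1L)
  expect_equal(rep1$rank_by_separation, 1L)

  same <- records(c("active", "decoy", "active", "decoy"), c(-9, -8, -7.5, -6))
  twins <- rank_conformers(list(b = same, a = same))
  expect_equal(twins$conformer_id, c("a", "b"))   # tie broken lexicographically
  expect_setequal(twins$rank_by_logauc, 1:2)

  spec <- score_matrix_spec(4, 30, 300,
                            active_mean_energy = c(-8.5, -10, -8.5, -8.5),
                            decoy_mean_energy = -8, sd = 1, seed = 3)
  reports <- rank_conformers(gen_score_tables(spec))
  expect_equal(reports$conformer_id[1], "conf02")  # planted high-separation
  for (col in c("rank_by_logauc", "rank_by_mean_active_energy", "rank_by_separation")) {
    expect_setequal(reports[[col]], seq_len(nrow(reports)))
  }
  expect_equal(reports$separation,
               with(reports, vapply(reports$conformer_id, function(cid) {
                 t <- gen_score_tables(spec)[[cid]]
                 mean(t$energy[t$label == "decoy"]) - mean(t$energy[t$label == "active"])
               }, numeric(1), USE.NAMES = FALSE)))
})

test_that("conformer ranking rejects mismatched molecule sets", {
  a <- records(c("active", "decoy"), c(-9, -8))
  b <- a; b$molecule_id <- c("zz1", "zz2")
  expect_error(rank_conformers(list(c1 = a, c2 = b)), "different molecule set")
  expect_error(rank_conformers(stats::setNames(list(a, a), c("x", "x"))),
               "duplicate")
})

test_that("score tables and ROC curves round-trip through CSV", {
  tab <- records(c("active", "decoy", "decoy"), c(-9.25, -8, -7.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, f)
  back <- read_score_table(f)
  expect_equal(back$energy, tab$energy)
  expect_equal(back$label, tab$label)
  roc_f <- withr::local_tempfile(fileext = ".csv")
  write_roc_csv(compute_roc(tab), roc_f)
  curve <- utils::read.csv(roc_f)
  expect_equal(names(curve), c("fpr", "tpr"))
  expect_false(is.unsorted(curve$fpr))
})
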
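# Independent oracles and shared fixtures.

# Mann-Whitney pair-counting AUC oracle: fraction of (active, decoy) pairs
# ranked correctly by energy (lower wins), half credit for ties, in percent.
auc_pair_oracle <- function(records) {
  ae <- records$energy[records$label == "active"]
  de <- records$energy[records$label == "decoy"]
  total <- 0
  for (a in ae) total <- total + sum(a < de) + 0.5 * sum(a == de)
  100 * total / (length(ae) * length(de))
}

# Exhaustive all-pairs polar-contact oracle over a pose scene.
contact_pairs_oracle <- function(scene, cutoff = 3.5) {
  lig <- scene$ligand; rec <- scene$receptor
  hits <- data.frame(ligand_atom = integer(), resno = integer(),
                     receptor_atom = character())
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(rec))) {
      compl <- (lig$is_donor[i] && rec$is_acceptor[j]) ||
               (lig$is_acceptor[i] && rec$is_donor[j])
      if (!compl) next
      d <- sqrt(sum((c(lig$x[i], lig$y[i], lig$z[i]) -
                     c(rec$x[j], rec$y[j], rec$z[j]))^2))
      if (d < cutoff) {
        hits <- rbind(hits, data.frame(ligand_atom = i, resno = rec$resno[j],
                                       receptor_atom = rec$atom[j]))
      }
    }
  }
  hits
}

# Apply a rigid rotation + translation to every atom of a scene.
transform_scene <- function(scene, rotation, translation) {
  rot_df <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
    df$x <- xyz[, 1] + translation[1]
    df$y <- xyz[, 2] + translation[2]
    df$z <- xyz[, 3] + translation[3]
    df
  }
  pose_scene(rot_df(scene$ligand), rot_df(scene$receptor),
             ligand_id = scene$ligand_id)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal donor(ligand)/acceptor(receptor) pair at a controlled distance.
donor_acceptor_pair_scene <- function(dist) {
  pose_scene(
    data.frame(element = "N", x = 0, y = 0, z = 0, formal_charge = 0,
               is_donor = TRUE, is_acceptor = FALSE),
    data.frame(resname = "GLU", resno = 1948L, atom = "OE1", element = "O",
               x = dist, y = 0, z = 0, formal_charge = 0,
               is_donor = FALSE, is_acceptor = TRUE, is_sidechain = TRUE))
}

# Random small score tables with ties, for AUC oracle equivalence tests.
random_tied_records <- function(n_max = 20L) {
  n <- sample(2:n_max, 1)
  n_act <- sample(seq_len(n - 1L), 1)
  energies <- round(rnorm(n, -8, 1), sample(0:2, 1))  # coarse rounding forces ties
  data.frame(molecule_id = sprintf("m%02d", seq_len(n)),
             label = c(rep("active", n_act), rep("decoy", n - n_act)),
             energy = energies, stringsAsFactors = FALSE)
}

# Memoized chemistry fixtures (molecule construction goes through OpenBabel;
# build each fixture once per test run).
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# 3 planted scaffold clusters x 5 variants, with energies and potencies.
fixture_cluster_set <- function() {
  memo("cluster_set", {
    ms <- gen_molecule_set(n_per_scaffold = 5L, seed = 42L)
    ms$energy <- seq(-10, -8, length.out = nrow(ms))
    ms$pchembl <- seq(9, 7, length.out = nrow(ms))
    ms
  })
}

# A diverse background pool (several scaffolds, many substituents).
fixture_pool <- function() {
  memo("pool", {
    gen_molecule_set(vstriage:::SCAFFOLD_LIBRARY[1:6], gen_substituents(40),
                     n_per_scaffold = 25L, seed = 5L)
  })
}
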
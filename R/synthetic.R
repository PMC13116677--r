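#' Specification for synthetic docking score tables
#'
#' Describes a Gaussian two-class energy model per receptor conformer:
#' actives and decoys draw docking energies from normal distributions with
#' conformer-specific means and a common standard deviation. Only the rank
#' structure matters for enrichment metrics, and the Gaussian model gives a
#' closed-form expected AUC, `pnorm(delta_mu / (sd * sqrt(2)))`, usable as an
#' oracle in tests.
#'
#' @param n_conformers,n_actives,n_decoys Positive integers.
#' @param active_mean_energy Numeric, length `n_conformers` (kcal/mol);
#'   recycled when scalar.
#' @param decoy_mean_energy Numeric, scalar or length `n_conformers`.
#' @param sd Common standard deviation (kcal/mol, > 0).
#' @param seed Integer seed.
#' @return A validated list of class `score_matrix_spec`.
#' @export
score_matrix_spec <- function(n_conformers, n_actives, n_decoys,
                              active_mean_energy, decoy_mean_energy,
                              sd = 1, seed = 1L) {
  stopifnot(n_conformers >= 1, n_actives >= 1, n_decoys >= 1)
  if (length(active_mean_energy) == 1L) {
    active_mean_energy <- rep(active_mean_energy, n_conformers)
  }
  if (length(decoy_mean_energy) == 1L) {
    decoy_mean_energy <- rep(decoy_mean_energy, n_conformers)
  }
  if (length(active_mean_energy) != n_conformers ||
      length(decoy_mean_energy) != n_conformers) {
    stop("per-conformer mean lists must have length n_conformers")
  }
  if (!is.numeric(sd) || sd <= 0) stop("sd must be strictly positive")
  structure(list(n_conformers = as.integer(n_conformers),
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 active_mean_energy = active_mean_energy,
                 decoy_mean_energy = decoy_mean_energy,
                 sd = sd, seed = as.integer(seed)),
            class = "score_matrix_spec")
}

#' Generate synthetic per-conformer docking score tables
#'
#' Emulates the score tables of a benchmark docking run of actives and
#' decoys against each conformer of a receptor ensemble. Active and decoy
#' ids are shared across conformers (as in a real ensemble benchmark);
#' energies are drawn independently per conformer from the Gaussian model in
#' the spec. Identical seeds give bit-identical tables.
#'
#' @param spec A [score_matrix_spec()].
#' @return Named list (`conf01`, `conf02`, ...) of score tables with columns
#'   `molecule_id`, `label`, `energy`.
#' @export
gen_score_tables <- function(spec) {
  stopifnot(inherits(spec, "score_matrix_spec"))
  set.seed(spec$seed)
  ids <- c(sprintf("ACT%04d", seq_len(spec$n_actives)),
           sprintf("DEC%05d", seq_len(spec$n_decoys)))
  labels <- c(rep("active", spec$n_actives), rep("decoy", spec$n_decoys))
  out <- lapply(seq_len(spec$n_conformers), function(k) {
    energy <- c(stats::rnorm(spec$n_actives, spec$active_mean_energy[k], spec$sd),
                stats::rnorm(spec$n_decoys, spec$decoy_mean_energy[k], spec$sd))
    data.frame(molecule_id = ids, label = labels, energy = energy,
               stringsAsFactors = FALSE)
  })
  names(out) <- sprintf("conf%02d", seq_len(spec$n_conformers))
  out
}

# Built-in fragment vocabularies for the molecule-set generator.
SCAFFOLD_LIBRARY <- c(
  benzene        = "c1ccc(*)cc1",
  pyridine       = "c1ccnc(*)c1",
  pyrimidine     = "c1cnc(*)nc1",
  pyrazole       = "c1cc(*)[nH]n1",
  imidazole      = "c1nc(*)c[nH]1",
  thiophene      = "c1ccc(*)s1",
  furan          = "c1ccc(*)o1",
  oxazole        = "c1occ(*)n1",
  indole         = "c1ccc2[nH]cc(*)c2c1",
  quinoline      = "c1ccc2ncc(*)cc2c1",
  piperidine     = "C1CCN(*)CC1",
  morpholine     = "O1CCN(*)CC1",
  pyrrolopyridine = "c1cc2c(*)c[nH]c2nc1",
  pyrazolopyridine = "c1cc2c(*)n[nH]c2nc1"
)

SUBSTITUENT_LIBRARY <- c(
  "C", "CC", "CCC", "CCO", "CCN", "COC", "CC(C)C", "CC(=O)N", "CC(=O)OC",
  "CCOC", "CCNC", "CN(C)C", "CCS", "CC#N", "CCF", "C(F)(F)F", "Cc1ccccc1",
  "CCc1ccco1", "CC(=O)NC", "CCOCC"
)

# Large phenyl-fused bicyclic scaffolds whose ECFP4 signal dominates small
# substituent edits: with single-atom substituents, intra-scaffold TC stays
# above 0.5 while inter-scaffold TC stays below it, giving clean planted
# clusters for similarity/clustering fixtures.
CLUSTER_SCAFFOLDS <- c(
  phenylpyrazolopyridine = "c1ccc(-c2n[nH]c3ncccc23)c(*)c1",
  phenylindole           = "c1ccc(-c2c[nH]c3ccccc23)c(*)c1",
  phenylquinoline        = "c1ccc(-c2cnc3ccccc3c2)c(*)c1"
)
CLUSTER_SUBSTITUENTS <- c("C", "CC", "O", "N", "F")

#' Enumerate substituent fragments
#'
#' Deterministically enumerates linear substituent SMILES by chaining
#' two-atom units (`C`, `CO`, `CN`, `CS`, methyl-branched `C(C)`) and
#' appending an optional terminal group. Used to feed [gen_molecule_set()]
#' when more variants are needed than the built-in fragment list offers.
#'
#' @param n Number of fragments to return.
#' @return Character vector of `n` distinct substituent SMILES.
#' @export
gen_substituents <- function(n) {
  units <- c("C", "CO", "CN", "CS", "C(C)")
  terminals <- c("", "C", "O", "N", "F", "C(F)(F)F", "C#N", "C(=O)N", "OC")
  frags <- character(0)
  for (len in 1:3) {
    idx <- rep(list(seq_along(units)), len)
    combos <- do.call(expand.grid, idx)
    chains <- apply(combos, 1, function(r) paste0(units[r], collapse = ""))
    for (t in terminals) frags <- c(frags, paste0(chains, t))
    frags <- unique(frags)
    if (length(frags) >= n) break
  }
  if (length(frags) < n) stop("substituent enumeration exhausted at ", length(frags))
  frags[seq_len(n)]
}

#' Generate a molecule set with planted similarity clusters
#'
#' Enumerates scaffold-substituent combinations: each scaffold SMILES must
#' contain a single `*` attachment atom, textually replaced by a substituent
#' fragment. Molecules sharing a scaffold form a planted high-similarity
#' cluster; the scaffold index is emitted as ground truth in the `scaffold`
#' column. Duplicate structures (identical canonical SMILES) are collapsed
#' and the removed count reported via attribute `n_duplicates`.
#'
#' @param scaffold_smiles Character vector of scaffold SMILES, each carrying
#'   one parenthesised `(*)` attachment point; defaults drawn from a built-in
#'   ring library.
#' @param substituents Character vector of substituent fragments.
#' @param n_per_scaffold Variants per scaffold; substituents are sampled
#'   without replacement when enough are available, with replacement
#'   otherwise (duplicates then collapse).
#' @param seed Integer seed for substituent sampling.
#' @return A [molecule_table] with ground-truth columns `scaffold` (integer)
#'   and `scaffold_smiles`.
#' @export
gen_molecule_set <- function(scaffold_smiles = CLUSTER_SCAFFOLDS,
                             substituents = CLUSTER_SUBSTITUENTS,
                             n_per_scaffold = 5L, seed = 1L) {
  stopifnot(length(scaffold_smiles) >= 1L, n_per_scaffold >= 1L)
  if (any(!grepl("(*)", scaffold_smiles, fixed = TRUE))) {
    stop("every scaffold must contain a '(*)' attachment point")
  }
  # validate scaffolds parse (with a methyl cap on the attachment)
  invisible(tryCatch(
    canonical_smiles(sub("(*)", "(C)", scaffold_smiles, fixed = TRUE)),
    error = function(e) stop("unparseable scaffold SMILES: ", conditionMessage(e))
  ))
  set.seed(seed)
  smi <- character(0); scaf <- integer(0)
  for (s in seq_along(scaffold_smiles)) {
    subs <- if (n_per_scaffold <= length(substituents)) {
      sample(substituents, n_per_scaffold)
    } else {
      sample(substituents, n_per_scaffold, replace = TRUE)
    }
    smi <- c(smi, vapply(subs, function(r) {
      sub("(*)", paste0("(", r, ")"), scaffold_smiles[s], fixed = TRUE)
    }, character(1), USE.NAMES = FALSE))
    scaf <- c(scaf, rep.int(s, n_per_scaffold))
  }
  mols <- molecule_table(smi, id = sprintf("SYN%04d", seq_along(smi)))
  mols$scaffold <- scaf
  mols$scaffold_smiles <- scaffold_smiles[scaf]
  dup <- duplicated(mols$smiles)
  out <- mols[!dup, ]
  attr(out, "n_duplicates") <- sum(dup)
  out
}

# Geometry of the toy binding site: polar atom of each key residue sits on a
# circle of this radius around the origin; the ligand occupies the center.
TOY_SITE_RADIUS <- 6.0
TOY_CONTACT_DIST <- 2.9

#' Generate a toy pose scene with planted key-residue contacts
#'
#' Builds an idealized binding site containing the five key residues, each
#' reduced to a single polar side-chain (or hinge carbonyl) heavy atom plus
#' two aliphatic carbons, arranged on a circle around the ligand. The ligand
#' is placed so that exactly `n_key_contacts` complementary donor-acceptor
#' pairs lie below 3.5 A (at ~2.9 A); all other polar pairs are beyond 4.5 A.
#' Optionally plants buried unsatisfied ligand donors/acceptors inside a
#' hydrophobic carbon cage for testing the unsatisfied-polar filter. The
#' planted truth is attached as attributes `planted_contacts` (data.frame of
#' residue numbers and distances) and `planted_unsat` (named counts).
#'
#' @param n_key_contacts Number of key residues contacted, 0..5.
#' @param seed Integer seed (controls sub-Angstrom coordinate jitter).
#' @param n_unsat_donors,n_unsat_acceptors Buried unsatisfied ligand donors /
#'   acceptors to plant (default 0).
#' @param ligand_id Molecule id stamped on the scene.
#' @return A [pose_scene()] with ground-truth attributes.
#' @export
gen_pose_scene <- function(n_key_contacts, seed = 1L,
                           n_unsat_donors = 0L, n_unsat_acceptors = 0L,
                           ligand_id = "LIG") {
  keys <- key_residue_set()
  if (n_key_contacts < 0L || n_key_contacts > nrow(keys)) {
    stop("n_key_contacts must be between 0 and ", nrow(keys))
  }
  set.seed(seed)
  # one polar atom per key residue: name, role, charge
  polar_info <- data.frame(
    atom = c("NZ", "OE1", "O", "ND2", "OD1"),
    donor = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    acceptor = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    charge = c(1, -1, 0, 0, -1),
    sidechain = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  ang <- seq(0, length.out = nrow(keys), by = 2 * pi / nrow(keys))
  jit <- function(n) stats::runif(n, -0.08, 0.08)
  rec <- NULL
  for (i in seq_len(nrow(keys))) {
    px <- TOY_SITE_RADIUS * cos(ang[i]) + jit(1)
    py <- TOY_SITE_RADIUS * sin(ang[i]) + jit(1)
    pz <- jit(1)
    res <- data.frame(
      resname = rep(keys$name[i], 3), resno = rep(keys$number[i], 3),
      atom = c(polar_info$atom[i], "CA", "CB"),
      element = c(substr(polar_info$atom[i], 1, 1), "C", "C"),
      x = c(px, px * 1.35, px * 1.2),
      y = c(py, py * 1.35, py * 1.2),
      z = c(pz, pz + 1.2, pz - 1.2),
      formal_charge = c(polar_info$charge[i], 0, 0),
      is_donor = c(polar_info$donor[i], FALSE, FALSE),
      is_acceptor = c(polar_info$acceptor[i], FALSE, FALSE),
      is_sidechain = c(polar_info$sidechain[i], FALSE, TRUE),
      stringsAsFactors = FALSE)
    rec <- rbind(rec, res)
  }
  # ligand core: three carbons near the origin
  lig <- data.frame(element = c("C", "C", "C"),
                    x = c(0, 1.4, -1.4) + jit(3), y = c(0, 0.4, 0.4) + jit(3),
                    z = jit(3), formal_charge = 0,
                    is_donor = FALSE, is_acceptor = FALSE,
                    stringsAsFactors = FALSE)
  truth <- data.frame(resno = integer(0), distance = numeric(0))
  for (i in seq_len(n_key_contacts)) {
    rp <- rec[rec$resno == keys$number[i] & rec$atom == polar_info$atom[i], ]
    u <- c(rp$x, rp$y, rp$z)
    pos <- u * (1 - TOY_CONTACT_DIST / sqrt(sum(u^2)))  # step toward origin
    lig <- rbind(lig, data.frame(
      element = if (polar_info$donor[i]) "O" else "N",
      x = pos[1], y = pos[2], z = pos[3], formal_charge = 0,
      is_donor = !polar_info$donor[i], is_acceptor = polar_info$donor[i],
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(resno = keys$number[i],
                                     distance = TOY_CONTACT_DIST))
  }
  # buried unsatisfied polar atoms inside a carbon cage below the site
  n_unsat <- c(donors = as.integer(n_unsat_donors),
               acceptors = as.integer(n_unsat_acceptors))
  cage_center_z <- -8
  total_unsat <- n_unsat[["donors"]] + n_unsat[["acceptors"]]
  if (total_unsat > 0L) {
    for (k in seq_len(total_unsat)) {
      as_donor <- k <= n_unsat[["donors"]]
      cx <- (k - 1) * 12
      lig <- rbind(lig, data.frame(
        element = if (as_donor) "N" else "O",
        x = cx, y = 0, z = cage_center_z, formal_charge = 0,
        is_donor = as_donor, is_acceptor = !as_donor,
        stringsAsFactors = FALSE))
      # 14 carbons on a sphere of radius 4.0 around the atom
      phi <- seq(0, 2 * pi, length.out = 8)[-8]
      cage <- rbind(
        cbind(cx + 4 * cos(phi), 4 * sin(phi), cage_center_z),
        cbind(cx + 3 * cos(phi), 3 * sin(phi), cage_center_z + 2.6))
      rec <- rbind(rec, data.frame(
        resname = "LEU", resno = 2100L + k, atom = "CD1", element = "C",
        x = cage[, 1], y = cage[, 2], z = cage[, 3],
        formal_charge = 0, is_donor = FALSE, is_acceptor = FALSE,
        is_sidechain = TRUE, stringsAsFactors = FALSE))
    }
  }
  scene <- pose_scene(lig, rec, ligand_id = ligand_id)
  attr(scene, "planted_contacts") <- truth
  attr(scene, "planted_unsat") <- n_unsat
  scene
}

#' Specification for a simulated inhibition assay
#'
#' Encodes the competitive-inhibition ground truth of a simulated kinase
#' assay: the inhibitor's true Ki, the ATP Michaelis constant Km, the assay
#' ATP concentration, and a Hill slope. The noiseless dose-response midpoint
#' then falls at IC50 = Ki (1 + S/Km), the Cheng-Prusoff relation.
#'
#' @param true_ki True inhibition constant (uM, > 0).
#' @param km ATP Michaelis constant (uM, > 0).
#' @param substrate_conc Assay ATP concentration (uM, >= 0; default 50).
#' @param hill Hill slope (default 1).
#' @param concentrations Inhibitor concentrations tested (uM, >= 0).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (>= 0).
#' @param seed Integer seed.
#' @return A validated list of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(true_ki, km, substrate_conc = 50, hill = 1,
                           concentrations = 10^seq(-2, 2, length.out = 8),
                           noise_cv = 0, seed = 1L) {
  stopifnot(true_ki > 0, km > 0, substrate_conc >= 0,
            all(concentrations >= 0), noise_cv >= 0, hill > 0)
  structure(list(true_ki = true_ki, km = km, substrate_conc = substrate_conc,
                 hill = hill, concentrations = sort(concentrations),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "assay_sim_spec")
}

#' Generate a simulated dose-response table
#'
#' Noiseless activities follow `1 / (1 + (c / IC50)^hill)` with
#' `IC50 = true_ki * (1 + S/Km)`; at zero inhibitor the activity is exactly 1
#' and at `c = IC50` exactly 0.5. Noise is multiplicative lognormal with unit
#' mean and coefficient of variation `noise_cv` (luminescence-style noise:
#' scatter proportional to signal).
#'
#' @param spec An [assay_sim_spec()].
#' @param compound_id Identifier stamped on the table.
#' @return A data.frame (`compound_id`, `concentration_uM`, `activity`) with
#'   the true IC50 attached as attribute `true_ic50`.
#' @export
gen_assay_data <- function(spec, compound_id = "CPD1") {
  stopifnot(inherits(spec, "assay_sim_spec"))
  set.seed(spec$seed)
  ic50 <- spec$true_ki * (1 + spec$substrate_conc / spec$km)
  act <- 1 / (1 + (spec$concentrations / ic50)^spec$hill)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    act <- act * stats::rlnorm(length(act), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out <- data.frame(compound_id = compound_id,
                    concentration_uM = spec$concentrations,
                    activity = act, stringsAsFactors = FALSE)
  attr(out, "true_ic50") <- ic50
  out
}

#' Generate a full synthetic triage scenario with planted survivors
#'
#' Assembles everything [run_triage()] consumes — a docked library with
#' energies, a reference set of known inhibitors, and one pose scene per
#' molecule — with `n_planted` molecules planted to pass every stage of the
#' cascade: they carry the lowest docking energies, are mutually dissimilar
#' (pairwise TC < 0.5), novel against the references (TC <= 0.35), inside
#' the property window (MW <= 400, clogP <= 4), and their poses contact
#' three key residues with no buried unsatisfied polar atoms. All other
#' molecules receive energies above the planted block.
#'
#' @param n_molecules Library size (default 1000).
#' @param n_planted Number of pass-all candidates (default 5).
#' @param seed Integer seed.
#' @return List with `molecules` ([molecule_table] with energies),
#'   `references` ([molecule_table]), `scenes` (named list of
#'   [pose_scene()]), `planted_ids` (character ground truth), and `config`
#'   (a [pipeline_config()] whose energy cut keeps exactly `n_planted`
#'   molecules of this library size).
#' @export
gen_triage_scenario <- function(n_molecules = 1000L, n_planted = 5L, seed = 1L) {
  stopifnot(n_planted >= 1L, n_molecules >= 20 * n_planted)
  set.seed(seed)
  lib_scaffolds <- SCAFFOLD_LIBRARY[seq_len(10)]
  ref_scaffolds <- SCAFFOLD_LIBRARY[11:14]
  n_per <- ceiling(n_molecules / length(lib_scaffolds)) + 8L
  mols <- gen_molecule_set(lib_scaffolds, gen_substituents(n_per + 30L),
                           n_per_scaffold = n_per, seed = seed)
  if (nrow(mols) < n_molecules) stop("library generator underproduced; raise n_per_scaffold")
  mols <- mols[seq_len(n_molecules), ]
  refs <- gen_molecule_set(ref_scaffolds, SUBSTITUENT_LIBRARY[1:6],
                           n_per_scaffold = 4L, seed = seed + 1L)
  refs$id <- sprintf("REF%03d", seq_len(nrow(refs)))
  # deterministic greedy pick of planted pass-all candidates
  planted <- integer(0)
  for (i in seq_len(nrow(mols))) {
    if (length(planted) == n_planted) break
    if (mols$scaffold[i] %in% mols$scaffold[planted]) next
    if (mols$mw[i] > 400 || mols$clogp[i] > 4) next
    tc_ref <- max(vapply(refs$fp, tanimoto, numeric(1), b = mols$fp[[i]]))
    if (tc_ref > 0.35) next
    if (length(planted) &&
        any(vapply(planted, function(j) tanimoto(mols$fp[[i]], mols$fp[[j]]),
                   numeric(1)) >= 0.5)) next
    planted <- c(planted, i)
  }
  if (length(planted) < n_planted) stop("could not plant enough pass-all candidates")
  energy <- -8 + stats::rnorm(n_molecules, 0, 1)
  energy <- pmax(energy, -10.5)                   # keep the bulk above the block
  energy[planted] <- -12 + 0.1 * seq_len(n_planted)
  mols$energy <- energy
  scenes <- vector("list", n_molecules)
  names(scenes) <- mols$id
  n_contacts_bg <- sample(0:1, n_molecules, replace = TRUE)
  for (i in seq_len(n_molecules)) {
    k <- if (i %in% planted) 3L else n_contacts_bg[i]
    scenes[[i]] <- gen_pose_scene(k, seed = seed + i, ligand_id = mols$id[i])
  }
  list(molecules = mols, references = refs, scenes = scenes,
       planted_ids = mols$id[planted],
       config = pipeline_config(energy_top_fraction = n_planted / n_molecules,
                                seed = as.integer(seed)))
}
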
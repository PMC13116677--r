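#' Default key-residue set of the LRRK2 ATP pocket
#'
#' The five putative inhibitor-contact residues of the LRRK2 kinase domain:
#' the catalytic lysine (Lys1906), the hinge residues Glu1948 and Ala1950,
#' Asn1999, and the DFG aspartate Asp2017 (kinase-domain numbering
#' 1879-2138).
#'
#' @param residues A data.frame with columns `name` (3-letter residue name)
#'   and `number`; defaults to the LRRK2 set.
#' @return A data.frame of class `key_residue_set`.
#' @export
key_residue_set <- function(residues = data.frame(
                              name = c("LYS", "GLU", "ALA", "ASN", "ASP"),
                              number = c(1906L, 1948L, 1950L, 1999L, 2017L),
                              stringsAsFactors = FALSE)) {
  stopifnot(is.data.frame(residues), all(c("name", "number") %in% names(residues)),
            nrow(residues) >= 1L, !anyDuplicated(residues$number))
  residues$name <- toupper(residues$name)
  class(residues) <- c("key_residue_set", "data.frame")
  residues
}

#' Construct a pose scene
#'
#' A pose scene pairs one docked ligand pose with the receptor environment,
#' both as explicit heavy-atom records carrying hydrogen-bond donor/acceptor
#' typing. Hydrogens are not represented: the geometric criteria downstream
#' are heavy-atom distance cutoffs.
#'
#' @param ligand_atoms data.frame: `element`, `x`, `y`, `z` (Angstrom),
#'   `formal_charge`, `is_donor`, `is_acceptor`.
#' @param receptor_atoms data.frame: `resname`, `resno`, `atom` (atom name),
#'   `element`, `x`, `y`, `z`, `formal_charge`, `is_donor`, `is_acceptor`,
#'   `is_sidechain`.
#' @param ligand_id Optional molecule identifier.
#' @return A list of class `pose_scene`.
#' @export
pose_scene <- function(ligand_atoms, receptor_atoms, ligand_id = NA_character_) {
  lig <- as.data.frame(ligand_atoms, stringsAsFactors = FALSE)
  rec <- as.data.frame(receptor_atoms, stringsAsFactors = FALSE)
  need_l <- c("element", "x", "y", "z", "formal_charge", "is_donor", "is_acceptor")
  need_r <- c("resname", "resno", "atom", "element", "x", "y", "z",
              "formal_charge", "is_donor", "is_acceptor", "is_sidechain")
  stopifnot(all(need_l %in% names(lig)), all(need_r %in% names(rec)))
  for (d in list(lig, rec)) {
    if (!all(is.finite(d$x) & is.finite(d$y) & is.finite(d$z))) {
      stop("pose scene coordinates must be finite")
    }
    polar <- d$is_donor | d$is_acceptor
    if (any(polar & !(toupper(d$element) %in% c("N", "O", "S")))) {
      stop("donor/acceptor flags are only allowed on N, O, S atoms")
    }
  }
  structure(list(ligand = lig, receptor = rec, ligand_id = ligand_id),
            class = "pose_scene")
}

#' @export
print.pose_scene <- function(x, ...) {
  cat(sprintf("<pose_scene%s: %d ligand atoms, %d receptor atoms (%d residues)>\n",
              if (is.na(x$ligand_id)) "" else paste0(" ", x$ligand_id),
              nrow(x$ligand), nrow(x$receptor), length(unique(x$receptor$resno))))
  invisible(x)
}

#' Detect intermolecular polar contacts in a docked pose
#'
#' Scans every (ligand polar atom, receptor polar atom) pair for
#' donor-acceptor complementarity with a heavy-atom distance strictly below
#' `cutoff`. Contacts between atoms with opposite formal charges are typed
#' salt bridges; all others are hydrogen bonds. The receptor partner's
#' main-chain/side-chain classification is carried on each contact.
#'
#' @param scene A [pose_scene].
#' @param cutoff Heavy-atom distance cutoff in Angstrom, strict (default 3.5).
#' @return A data.frame of class `contact_table`: `resname`, `resno`,
#'   `ligand_atom`, `receptor_atom`, `distance`, `kind`
#'   (`hydrogen_bond`/`salt_bridge`), `chain_part` (`main_chain`/`side_chain`).
#' @export
detect_polar_contacts <- function(scene, cutoff = 3.5) {
  stopifnot(inherits(scene, "pose_scene"))
  lig <- scene$ligand; rec <- scene$receptor
  if (nrow(lig) == 0L || nrow(rec) == 0L) {
    stop("contact detection needs both ligand and receptor atoms")
  }
  li <- which(lig$is_donor | lig$is_acceptor)
  ri <- which(rec$is_donor | rec$is_acceptor)
  rows <- list()
  for (i in li) {
    for (j in ri) {
      compl <- (lig$is_donor[i] && rec$is_acceptor[j]) ||
               (lig$is_acceptor[i] && rec$is_donor[j])
      if (!compl) next
      d <- sqrt((lig$x[i] - rec$x[j])^2 + (lig$y[i] - rec$y[j])^2 +
                (lig$z[i] - rec$z[j])^2)
      if (d >= cutoff) next
      salt <- lig$formal_charge[i] * rec$formal_charge[j] < 0
      rows[[length(rows) + 1L]] <- data.frame(
        resname = rec$resname[j], resno = rec$resno[j],
        ligand_atom = i, receptor_atom = rec$atom[j],
        distance = d,
        kind = if (salt) "salt_bridge" else "hydrogen_bond",
        chain_part = if (rec$is_sidechain[j]) "side_chain" else "main_chain",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resname = character(), resno = integer(), ligand_atom = integer(),
               receptor_atom = character(), distance = numeric(), kind = character(),
               chain_part = character(), stringsAsFactors = FALSE)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Key-residue contact filter
#'
#' Counts the distinct key residues contacted by a pose and passes it iff the
#' count reaches `min_contacts`. The default counts residues, not raw
#' contact pairs (two hydrogen bonds to the same hinge residue count once);
#' `count = "pairs"` switches to raw-pair counting.
#'
#' @param contacts A `contact_table` from [detect_polar_contacts()].
#' @param keys A [key_residue_set()].
#' @param min_contacts Minimum count to pass (default 2).
#' @param count `"residues"` (default) or `"pairs"`.
#' @return Logical pass verdict with attribute `count`.
#' @export
key_residue_filter <- function(contacts, keys = key_residue_set(),
                               min_contacts = 2L, count = c("residues", "pairs")) {
  count <- match.arg(count)
  hit <- contacts$resno %in% keys$number
  n <- if (count == "residues") length(unique(contacts$resno[hit])) else sum(hit)
  structure(n >= min_contacts, count = n)
}

#' Count buried, unsatisfied polar atoms of a ligand pose
#'
#' A ligand donor or acceptor is unsatisfied when it is buried in the
#' receptor — at least `burial_min_neighbors` receptor heavy atoms within
#' `burial_radius` — yet has no complementary receptor polar atom within
#' `contact_cutoff`. Buried unpaired polar atoms are an implausibility
#' signal: the desolvation penalty is paid without a compensating hydrogen
#' bond.
#'
#' @param scene A [pose_scene].
#' @param contact_cutoff Polar-partner distance cutoff (Angstrom, strict;
#'   default 3.5).
#' @param burial_radius Neighbor-count radius (default 4.5).
#' @param burial_min_neighbors Receptor heavy atoms within `burial_radius`
#'   required to call an atom buried (default 12).
#' @return Named integer vector `c(donors = , acceptors = )`.
#' @export
count_unsatisfied_polar <- function(scene, contact_cutoff = 3.5,
                                    burial_radius = 4.5, burial_min_neighbors = 12L) {
  stopifnot(inherits(scene, "pose_scene"))
  lig <- scene$ligand; rec <- scene$receptor
  n_unsat <- c(donors = 0L, acceptors = 0L)
  polar <- which(lig$is_donor | lig$is_acceptor)
  if (!length(polar) || !nrow(rec)) return(n_unsat)
  rx <- rec$x; ry <- rec$y; rz <- rec$z
  for (i in polar) {
    d <- sqrt((lig$x[i] - rx)^2 + (lig$y[i] - ry)^2 + (lig$z[i] - rz)^2)
    if (sum(d <= burial_radius) < burial_min_neighbors) next  # solvent-exposed
    satisfied <- FALSE
    if (lig$is_donor[i]) {
      satisfied <- satisfied || any(rec$is_acceptor & d < contact_cutoff)
    }
    if (lig$is_acceptor[i]) {
      satisfied <- satisfied || any(rec$is_donor & d < contact_cutoff)
    }
    if (!satisfied) {
      if (lig$is_donor[i]) n_unsat["donors"] <- n_unsat["donors"] + 1L
      if (lig$is_acceptor[i] && !lig$is_donor[i]) {
        n_unsat["acceptors"] <- n_unsat["acceptors"] + 1L
      }
    }
  }
  n_unsat
}

#' Unsatisfied-polar-atom exclusion filter
#'
#' Applies the screening exclusion rule on the counts from
#' [count_unsatisfied_polar()]. With `combine = "and"` (the rule as printed:
#' acceptors > `max_unsat_acceptors` AND donors > `max_unsat_donors`) a pose
#' is excluded only when both bounds are violated; `combine = "or"` excludes
#' on either violation.
#'
#' @param counts Named vector `c(donors=, acceptors=)`.
#' @param max_unsat_acceptors Acceptor bound (default 2).
#' @param max_unsat_donors Donor bound (default 0).
#' @param combine `"and"` (default) or `"or"`.
#' @return Logical pass verdict (TRUE = keep).
#' @export
unsatisfied_filter <- function(counts, max_unsat_acceptors = 2L,
                               max_unsat_donors = 0L, combine = c("and", "or")) {
  combine <- match.arg(combine)
  acc_bad <- counts[["acceptors"]] > max_unsat_acceptors
  don_bad <- counts[["donors"]] > max_unsat_donors
  excluded <- if (combine == "and") acc_bad && don_bad else acc_bad || don_bad
  !excluded
}

#' Torsion-strain flag from an externally computed strain table
#'
#' Integration hook for external torsion-strain estimators: poses whose
#' tabulated strain energy exceeds `threshold` fail; molecules absent from
#' the table pass with a warning (strain unknown is not evidence of strain).
#'
#' @param molecule_id Molecule identifier.
#' @param strain_table Named numeric vector or data.frame
#'   (`molecule_id`, `strain`) mapping ids to strain energies; or a CSV path.
#' @param threshold Maximum tolerated strain energy.
#' @return Logical pass verdict with attribute `strain` (NA when missing).
#' @export
strain_flag <- function(molecule_id, strain_table, threshold) {
  if (is.character(strain_table) && length(strain_table) == 1L && file.exists(strain_table)) {
    strain_table <- utils::read.csv(strain_table, stringsAsFactors = FALSE)
  }
  if (is.data.frame(strain_table)) {
    strain_table <- stats::setNames(strain_table$strain, strain_table$molecule_id)
  }
  s <- strain_table[as.character(molecule_id)]
  s <- if (length(s)) unname(s) else NA_real_
  if (is.na(s)) {
    warning("no strain energy for '", molecule_id, "': passing unflagged")
    return(structure(TRUE, strain = NA_real_))
  }
  structure(s <= threshold, strain = s)
}

#' Docking-grid specification centered on the key residues
#'
#' Centers the grid on the unweighted centroid of all heavy atoms of the key
#' residues and attaches the standard inner (ligand-center) and outer
#' (ligand-extent) box sizes.
#'
#' @param receptor_atoms Receptor atom data.frame (as in [pose_scene()]).
#' @param keys A [key_residue_set()].
#' @param inner_box,outer_box Cubic box edge lengths in Angstrom
#'   (defaults 10 and 30).
#' @return A list of class `grid_spec`: `center` (xyz), `inner_box`,
#'   `outer_box`.
#' @export
make_grid_spec <- function(receptor_atoms, keys = key_residue_set(),
                           inner_box = 10, outer_box = 30) {
  stopifnot(inner_box <= outer_box)
  missing <- setdiff(keys$number, receptor_atoms$resno)
  if (length(missing)) {
    stop("key residue(s) absent from receptor: ",
         paste(keys$name[match(missing, keys$number)], missing, sep = "", collapse = ", "))
  }
  sel <- receptor_atoms[receptor_atoms$resno %in% keys$number &
                          toupper(receptor_atoms$element) != "H", ]
  center <- c(x = mean(sel$x), y = mean(sel$y), z = mean(sel$z))
  structure(list(center = center, inner_box = rep(inner_box, 3),
                 outer_box = rep(outer_box, 3)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  c(sprintf("grid_center_x = %.3f", x$center[["x"]]),
    sprintf("grid_center_y = %.3f", x$center[["y"]]),
    sprintf("grid_center_z = %.3f", x$center[["z"]]),
    sprintf("inner_box = %g %g %g", x$inner_box[1], x$inner_box[2], x$inner_box[3]),
    sprintf("outer_box = %g %g %g", x$outer_box[1], x$outer_box[2], x$outer_box[3]))
}

#' Write a grid specification as a key=value text block
#'
#' @param grid A `grid_spec`.
#' @param path Output path.
#' @export
write_grid_spec <- function(grid, path) {
  writeLines(format(grid), path)
  invisible(path)
}

#' Write per-pose contacts to CSV
#'
#' @param contacts A `contact_table`.
#' @param path Output CSV path.
#' @export
write_contacts_csv <- function(contacts, path) {
  utils::write.csv(as.data.frame(contacts), path, row.names = FALSE)
  invisible(path)
}
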
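# Donor/acceptor typing of standard protein residues by atom name.
# Backbone: N is a donor (except proline), O an acceptor. Side chains follow
# the usual chemistry at pH 7.4: Lys NZ protonated donor (+1), Arg guanidinium
# donors (+1 on NH1/NH2), Asp/Glu carboxylates acceptors (-1), His ND1/NE2
# treated as donor+acceptor, hydroxyls (Ser/Thr/Tyr) donor+acceptor,
# amides (Asn/Gln) split into NH2 donor and C=O acceptor, Trp NE1 donor,
# Cys SG donor, Met SD acceptor.
RECEPTOR_POLAR_TYPES <- local({
  rows <- rbind(
    c("LYS", "NZ",  "donor",  1),
    c("ARG", "NE",  "donor",  0), c("ARG", "NH1", "donor", 1), c("ARG", "NH2", "donor", 1),
    c("ASP", "OD1", "acceptor", -1), c("ASP", "OD2", "acceptor", -1),
    c("GLU", "OE1", "acceptor", -1), c("GLU", "OE2", "acceptor", -1),
    c("ASN", "ND2", "donor", 0), c("ASN", "OD1", "acceptor", 0),
    c("GLN", "NE2", "donor", 0), c("GLN", "OE1", "acceptor", 0),
    c("HIS", "ND1", "both", 0), c("HIS", "NE2", "both", 0),
    c("SER", "OG",  "both", 0), c("THR", "OG1", "both", 0), c("TYR", "OH", "both", 0),
    c("TRP", "NE1", "donor", 0), c("CYS", "SG", "donor", 0), c("MET", "SD", "acceptor", 0)
  )
  data.frame(resname = rows[, 1], atom = rows[, 2], role = rows[, 3],
             charge = as.numeric(rows[, 4]), stringsAsFactors = FALSE)
})

# Assign is_donor / is_acceptor / formal_charge to receptor atoms by residue
# and atom name; backbone rule plus the side-chain lookup above.
type_receptor_atoms <- function(rec) {
  n <- nrow(rec)
  rec$is_donor <- rep(FALSE, n)
  rec$is_acceptor <- rep(FALSE, n)
  if (is.null(rec$formal_charge)) rec$formal_charge <- rep(0, n)
  bb_n <- rec$atom == "N" & rec$resname != "PRO"
  bb_o <- rec$atom %in% c("O", "OXT")
  rec$is_donor[bb_n] <- TRUE
  rec$is_acceptor[bb_o] <- TRUE
  key <- paste(rec$resname, rec$atom)
  idx <- match(key, paste(RECEPTOR_POLAR_TYPES$resname, RECEPTOR_POLAR_TYPES$atom))
  hit <- !is.na(idx)
  role <- RECEPTOR_POLAR_TYPES$role[idx[hit]]
  rec$is_donor[hit] <- rec$is_donor[hit] | role %in% c("donor", "both")
  rec$is_acceptor[hit] <- rec$is_acceptor[hit] | role %in% c("acceptor", "both")
  rec$formal_charge[hit] <- RECEPTOR_POLAR_TYPES$charge[idx[hit]]
  rec$is_sidechain <- !(rec$atom %in% c("N", "CA", "C", "O", "OXT"))
  rec
}

#' Read a receptor from a PDB file
#'
#' Parses ATOM records (chain and residue numbering honored), drops
#' hydrogens, and assigns hydrogen-bond donor/acceptor roles and formal
#' charges from residue/atom-name rules (backbone N donor / O acceptor;
#' standard side-chain chemistry at pH 7.4). The assignment can be
#' overridden downstream by editing the returned data.frame.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier to restrict to.
#' @return A receptor atom data.frame suitable for [pose_scene()] and
#'   [make_grid_spec()].
#' @export
read_receptor_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  elem <- ifelse(nzchar(trimws(at$elesy)), trimws(at$elesy),
                 substr(trimws(at$elety), 1, 1))
  rec <- data.frame(resname = toupper(at$resid), resno = at$resno,
                    atom = trimws(at$elety), element = toupper(elem),
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  rec <- rec[rec$element != "H", ]
  type_receptor_atoms(rec)
}

#' Write a receptor atom table to a PDB file
#'
#' @param receptor_atoms Receptor data.frame (as in [pose_scene()]).
#' @param path Output path.
#' @export
write_receptor_pdb <- function(receptor_atoms, path) {
  r <- receptor_atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(r[, c("x", "y", "z")]))),
                   resno = r$resno, resid = r$resname, eleno = seq_len(nrow(r)),
                   elety = r$atom, chain = rep("A", nrow(r)),
                   elesy = r$element)
  invisible(path)
}

# Donor/acceptor typing for ligand atoms from element, formal charge and
# heavy-atom bond count (hydrogens implicit): O with one heavy neighbor and
# no negative charge is hydroxyl-like (donor+acceptor); other O acceptor;
# neutral N with < 3 heavy neighbors has implicit H (donor), and is also an
# acceptor unless positively charged; S with <= 1 heavy neighbor thiol-like.
type_ligand_atom <- function(element, formal_charge, n_heavy_neighbors) {
  el <- toupper(element)
  don <- FALSE; acc <- FALSE
  if (el == "O") {
    acc <- formal_charge <= 0
    don <- formal_charge == 0 && n_heavy_neighbors <= 1
  } else if (el == "N") {
    don <- n_heavy_neighbors < 3 || formal_charge > 0
    acc <- formal_charge <= 0 && n_heavy_neighbors < 4
  } else if (el == "S") {
    don <- n_heavy_neighbors <= 1 && formal_charge == 0
    acc <- formal_charge <= 0 && n_heavy_neighbors <= 2
  }
  c(don = don, acc = acc)
}

#' Read docked ligand poses from an SDF file
#'
#' One pose per SDF record, molecule id from the title line. Atoms are typed
#' as hydrogen-bond donors/acceptors from element, formal charge and bond
#' count; explicit hydrogens are dropped.
#'
#' @param path SDF path (multi-record).
#' @return Named list of ligand atom data.frames keyed by molecule id.
#' @export
read_pose_sdf <- function(path) {
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  ids <- ChemmineR::sdfid(sdf)
  out <- vector("list", length(sdf))
  for (k in seq_along(sdf)) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    bb <- ChemmineR::bondblock(sdf[[k]])
    elem <- toupper(gsub("_.*$", "", rownames(ab)))
    deg <- integer(nrow(ab))
    chg <- numeric(nrow(ab))
    if (!is.null(bb) && nrow(bb)) {
      for (b in seq_len(nrow(bb))) {
        a1 <- bb[b, 1]; a2 <- bb[b, 2]
        if (a1 < 1 || a2 < 1) next   # placeholder row of a bond-less record
        if (elem[a1] != "H") deg[a2] <- deg[a2] + 1L
        if (elem[a2] != "H") deg[a1] <- deg[a1] + 1L
      }
    }
    # ctab charge code: 0 none, 3 = +1, 5 = -1, generally charge = 4 - code
    if (ncol(ab) >= 5) {
      ctab <- ab[, 5]
      chg <- ifelse(ctab == 0 | ctab == 4, 0, 4 - ctab)
    }
    keep <- elem != "H"
    typing <- t(vapply(which(keep), function(i) {
      type_ligand_atom(elem[i], chg[i], deg[i])
    }, logical(2)))
    out[[k]] <- data.frame(element = elem[keep],
                           x = ab[keep, 1], y = ab[keep, 2], z = ab[keep, 3],
                           formal_charge = chg[keep],
                           is_donor = typing[, 1], is_acceptor = typing[, 2],
                           stringsAsFactors = FALSE)
  }
  names(out) <- ids
  out
}

#' Assemble pose scenes from a poses SDF and a receptor PDB
#'
#' Convenience loader for the triage pipeline: reads one receptor and a
#' multi-record SDF of docked poses (molecule id in the title line) and
#' returns one [pose_scene()] per pose against that receptor.
#'
#' @param poses_sdf Path to a multi-record SDF of docked ligand poses.
#' @param receptor_pdb Path to the receptor PDB file.
#' @param chain Optional receptor chain restriction.
#' @return Named list of [pose_scene()] keyed by molecule id.
#' @export
load_pose_scenes <- function(poses_sdf, receptor_pdb, chain = NULL) {
  receptor <- read_receptor_pdb(receptor_pdb, chain = chain)
  ligands <- read_pose_sdf(poses_sdf)
  out <- lapply(names(ligands), function(id) {
    pose_scene(ligands[[id]], receptor, ligand_id = id)
  })
  names(out) <- names(ligands)
  out
}

#' Write a ligand atom table as a minimal SDF record
#'
#' Coordinates and elements only (no bond block): sufficient for the
#' distance-based triage this package performs and for round-tripping
#' generated scenes.
#'
#' @param ligand_atoms Ligand data.frame (as in [pose_scene()]).
#' @param path Output path.
#' @param id Title-line molecule id.
#' @param append Append to an existing multi-record file.
#' @export
write_ligand_sdf <- function(ligand_atoms, path, id = "LIG", append = FALSE) {
  n <- nrow(ligand_atoms)
  lines <- c(id, "  vstriage", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L))
  for (i in seq_len(n)) {
    q <- as.integer(ligand_atoms$formal_charge[i])
    code <- if (q == 0) 0L else 4L - q            # ctab charge code
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                              ligand_atoms$x[i], ligand_atoms$y[i], ligand_atoms$z[i],
                              ligand_atoms$element[i], code))
  }
  chg <- which(ligand_atoms$formal_charge != 0)
  for (i in chg) {
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i, as.integer(ligand_atoms$formal_charge[i])))
  }
  lines <- c(lines, "M  END", "$$$$")
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}
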
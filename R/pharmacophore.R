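# Pharmacophore atom typing.
#
# Eight-class vocabulary in a fixed canonical order; the typing table maps
# (res_name, atom_name) to one or more classes, with element fallbacks for
# atoms outside the 20 canonical residues (ligands, modified residues).

#' The eight pharmacophore classes, in canonical order
#'
#' The order fixes the class-pair enumeration used to lay out signature
#' vectors, so it must never change between releases.
#' @export
PHARMACOPHORE_CLASSES <- c("hydrophobic", "positive", "negative",
                           "acceptor", "donor", "aromatic",
                           "sulfur", "neutral")

# Heavy side-chain atoms per canonical residue (backbone handled separately).
SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

POSITIVE_ATOMS <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)

NEGATIVE_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

# Side-chain N/O hydrogen-bonding roles (backbone N donor / O acceptor are
# added for every residue; PRO backbone N has no H and is typed neutral).
DONOR_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1",
  SER = "OG", THR = "OG1", TYR = "OH"
)

ACCEPTOR_ATOMS <- list(
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)

SULFUR_ATOMS <- list(CYS = "SG", MET = "SD")

#' Default pharmacophore typing table
#'
#' Builds the shipped typing table covering every heavy atom of the 20
#' canonical residues plus element fallbacks (rows with `res_name = "*"`)
#' and the C-terminal `OXT` rule. The rules: aromatic = ring atoms of
#' PHE/TYR/TRP/HIS; positive = LYS NZ, ARG NE/NH1/NH2, HIS ND1/NE2;
#' negative = ASP OD1/OD2, GLU OE1/OE2, OXT; donor/acceptor follow the
#' standard N/O hydrogen-bonding roles (backbone N donor except PRO,
#' backbone O acceptor); sulfur = CYS SG, MET SD; hydrophobic = every
#' carbon not classified aromatic; neutral = any atom left classless
#' (e.g. the proline backbone nitrogen). Atoms may carry several classes.
#'
#' @return Data frame with columns `res_name`, `atom_name`, `classes`
#'   (comma-separated, ordered by [PHARMACOPHORE_CLASSES]).
#' @export
default_pharmacophore_table <- function() {
  rows <- list()
  add <- function(res, atom, classes) {
    classes <- PHARMACOPHORE_CLASSES[PHARMACOPHORE_CLASSES %in% classes]
    if (!length(classes)) classes <- "neutral"
    rows[[length(rows) + 1L]] <<- data.frame(
      res_name = res, atom_name = atom,
      classes = paste(classes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (res in names(SIDECHAIN_ATOMS)) {
    add(res, "N", if (res == "PRO") "neutral" else "donor")
    add(res, "CA", "hydrophobic")
    add(res, "C", "hydrophobic")
    add(res, "O", "acceptor")
    add(res, "OXT", c("negative", "acceptor"))
    for (atom in SIDECHAIN_ATOMS[[res]]) {
      cls <- character(0)
      if (atom %in% AROMATIC_RING_ATOMS[[res]]) cls <- c(cls, "aromatic")
      if (atom %in% POSITIVE_ATOMS[[res]])      cls <- c(cls, "positive")
      if (atom %in% NEGATIVE_ATOMS[[res]])      cls <- c(cls, "negative")
      if (atom %in% DONOR_ATOMS[[res]])         cls <- c(cls, "donor")
      if (atom %in% ACCEPTOR_ATOMS[[res]])      cls <- c(cls, "acceptor")
      if (atom %in% SULFUR_ATOMS[[res]])        cls <- c(cls, "sulfur")
      el <- substr(atom, 1, 1)
      if (el == "C" && !("aromatic" %in% cls)) cls <- c(cls, "hydrophobic")
      add(res, atom, cls)
    }
  }
  # element fallbacks for ligands / unknown residues
  add("*", "C", "hydrophobic")
  add("*", "N", "donor")
  add("*", "O", "acceptor")
  add("*", "S", "sulfur")
  add("*", "P", "neutral")
  do.call(rbind, rows)
}

#' Read a pharmacophore typing table from TSV
#'
#' @param path TSV with columns `res_name`, `atom_name`, `classes`
#'   (comma-separated class names from the 8-class vocabulary).
#' @return Validated typing table data frame.
#' @export
read_pharmacophore_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("res_name", "atom_name", "classes")
  if (!all(need %in% names(tab)))
    stop_format(paste0("pharmacophore table needs columns: ",
                       paste(need, collapse = ", ")))
  cls <- unique(unlist(strsplit(tab$classes, ",", fixed = TRUE)))
  unknown <- setdiff(trimws(cls), PHARMACOPHORE_CLASSES)
  if (length(unknown))
    stop_format(paste0("unknown pharmacophore classes: ",
                       paste(unknown, collapse = ", ")))
  tab[, need]
}

#' Assign pharmacophore classes to every atom of a structure
#'
#' Lookup order per atom: exact (res_name, atom_name) entry, then the
#' global `OXT` entry, then the element fallback row. Ligand atoms are
#' typed by element only. The result is deterministic and independent of
#' atom order.
#'
#' @param structure an `ssv_structure`.
#' @param table typing table; default [default_pharmacophore_table()].
#' @return List (length = number of atoms) of character vectors of
#'   classes, each non-empty and ordered by [PHARMACOPHORE_CLASSES].
#' @export
assign_pharmacophores <- function(structure,
                                  table = default_pharmacophore_table()) {
  at <- structure$atoms
  key <- paste(table$res_name, table$atom_name, sep = "|")
  lut <- setNames(table$classes, key)
  exact <- lut[paste(at$res_name, at$name, sep = "|")]
  # hetero atoms never use residue-specific typing
  exact[at$is_hetero] <- NA_character_
  oxt <- !at$is_hetero & at$name == "OXT" & is.na(exact)
  exact[oxt] <- lut[paste("*", "OXT", sep = "|")] %||% NA_character_
  exact[oxt & is.na(exact)] <- "negative,acceptor"
  fb <- is.na(exact)
  exact[fb] <- lut[paste("*", at$element[fb], sep = "|")]
  bad <- which(is.na(exact))
  if (length(bad)) {
    b <- bad[1L]
    stop_typing(sprintf(
      "no pharmacophore typing for atom '%s' of %s %s%d%s (element '%s')",
      at$name[b], at$res_name[b], at$chain_id[b], at$seq_num[b],
      at$icode[b], at$element[b]))
  }
  lapply(strsplit(unname(exact), ",", fixed = TRUE), function(cl) {
    PHARMACOPHORE_CLASSES[PHARMACOPHORE_CLASSES %in% trimws(cl)]
  })
}
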
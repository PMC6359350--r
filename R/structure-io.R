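# PDB structure input/output.
#
# A structure is represented the way bio3d represents one: a flat atom
# table (one row per heavy atom) carrying residue identity, plus an id.
# Hetero residues (ligands) stay in the same table, flagged by is_hetero,
# so residue order and file order are preserved.

ATOM_COLS <- c("serial", "name", "alt_loc", "res_name", "chain_id",
               "seq_num", "icode", "x", "y", "z", "occupancy",
               "element", "is_hetero")

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR",
                         "SE", "CA", "NI", "CO", "CD", "HG", "AS")

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the fixture generators.
#' Most users never call it directly.
#'
#' @param atoms data frame with columns `serial`, `name`, `alt_loc`,
#'   `res_name`, `chain_id`, `seq_num`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `element`, `is_hetero`.
#' @param id structure identifier string.
#' @return An object of class `ssv_structure`.
#' @export
new_structure <- function(atoms, id = "structure") {
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop_input(paste0("atom table lacks columns: ",
                      paste(missing_cols, collapse = ", ")))
  atoms <- as.data.frame(atoms)[, ATOM_COLS]
  rownames(atoms) <- NULL
  if (nrow(atoms) && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_input("non-finite atom coordinates")
  structure(list(id = as.character(id), atoms = atoms),
            class = "ssv_structure")
}

#' @export
print.ssv_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<ssv_structure '%s': %d atoms, %d residues (%d hetero)>\n",
              x$id, nrow(x$atoms), nrow(rt), sum(rt$is_hetero)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `ssv_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Heavy-atom coordinate matrix
#' @param structure an `ssv_structure`.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Residue-level view of a structure
#'
#' @param structure an `ssv_structure`.
#' @param hetero if `FALSE` (default) protein residues only; if `TRUE`
#'   hetero (ligand) residues only; if `NA` all residues.
#' @return Data frame with one row per residue: `chain_id`, `seq_num`,
#'   `icode`, `res_name`, `is_hetero`, `n_atoms`, in structure order.
#' @export
residue_table <- function(structure, hetero = NA) {
  at <- structure$atoms
  key <- residue_key(at)
  first <- !duplicated(key)
  rt <- at[first, c("chain_id", "seq_num", "icode", "res_name", "is_hetero")]
  rt$n_atoms <- as.integer(table(factor(key, levels = key[first])))
  rownames(rt) <- NULL
  if (!is.na(hetero)) rt <- rt[rt$is_hetero == hetero, , drop = FALSE]
  rownames(rt) <- NULL
  rt
}

# Residue identity key: chain + number + insertion code.
residue_key <- function(df) {
  paste(df$chain_id, df$seq_num, df$icode, sep = "|")
}

infer_element <- function(name) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(stripped, 1, 2)
  ifelse(nchar(stripped) >= 2 & two %in% TWO_LETTER_ELEMENTS,
         two, substr(stripped, 1, 1))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 fixed-width layout) from the
#' first model of a PDB file. Hydrogens (and deuteriums) and waters are
#' dropped. Alternate locations are resolved per atom: the
#' highest-occupancy record wins, ties go to alt-loc `A`, then first seen.
#'
#' @param path path to a PDB file.
#' @param keep_ligands keep HETATM (non-water) residues as flagged ligand
#'   residues? If `FALSE` they are dropped.
#' @return An `ssv_structure`.
#' @export
read_pdb <- function(path, keep_ligands = TRUE) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(sel))
    stop_input(paste0("no ATOM/HETATM records in ", path))
  ln <- lines[sel]

  num <- function(from, to, what) {
    txt <- trimws(substr(ln, from, to))
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & txt != "")
    if (length(bad))
      stop_format(sprintf("unparsable %s in %s at line %d: '%s'",
                          what, path, sel[bad[1L]], ln[bad[1L]]))
    out
  }

  atoms <- data.frame(
    serial    = num(7, 11, "atom serial"),
    name      = trimws(substr(ln, 13, 16)),
    alt_loc   = trimws(substr(ln, 17, 17)),
    res_name  = trimws(substr(ln, 18, 20)),
    chain_id  = substr(ln, 22, 22),
    seq_num   = num(23, 26, "residue number"),
    icode     = trimws(substr(ln, 27, 27)),
    x         = num(31, 38, "x coordinate"),
    y         = num(39, 46, "y coordinate"),
    z         = num(47, 54, "z coordinate"),
    occupancy = num(55, 60, "occupancy"),
    element   = toupper(trimws(substr(ln, 77, 78))),
    is_hetero = rec[sel] == "HETATM",
    stringsAsFactors = FALSE
  )
  bad_xyz <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))
  if (length(bad_xyz))
    stop_format(sprintf("missing coordinates in %s at line %d",
                        path, sel[bad_xyz[1L]]))
  atoms$seq_num <- as.integer(atoms$seq_num)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  noel <- atoms$element == ""
  atoms$element[noel] <- infer_element(atoms$name[noel])

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$res_name %in% WATER_NAMES), , drop = FALSE]
  if (!keep_ligands) atoms <- atoms[!atoms$is_hetero, , drop = FALSE]
  if (!nrow(atoms))
    stop_input(paste0("structure is empty after filtering: ", path))

  # alt-loc resolution per (residue, atom name)
  akey <- paste(residue_key(atoms), atoms$name, sep = "|")
  if (anyDuplicated(akey)) {
    pref <- order(akey,
                  -atoms$occupancy,
                  atoms$alt_loc != "A",
                  seq_len(nrow(atoms)))
    keep_idx <- pref[!duplicated(akey[pref])]
    atoms <- atoms[sort(keep_idx), , drop = FALSE]
  }
  atoms$alt_loc <- ""

  id <- tools::file_path_sans_ext(basename(path))
  new_structure(atoms, id = id)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (coordinates to 3 decimals,
#' occupancy to 2) with TER records at chain breaks and a final END.
#' Round-trips through [read_pdb()] on the retained fields.
#'
#' @param structure a non-empty `ssv_structure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "ssv_structure"))
  if (!n_atoms(structure)) stop_input("refusing to write an empty structure")
  at <- structure$atoms
  at$serial <- seq_len(nrow(at))
  # PDB atom-name column convention: 1/2-letter elements with short names
  # start in column 14
  fmt_name <- ifelse(nchar(at$name) >= 4L | nchar(at$element) >= 2L,
                     sprintf("%-4s", at$name),
                     sprintf(" %-3s", at$name))
  recs <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$is_hetero, "HETATM", "ATOM"),
    at$serial, fmt_name, at$alt_loc, at$res_name, at$chain_id,
    at$seq_num, at$icode, at$x, at$y, at$z, at$occupancy, 0,
    at$element)
  # TER after each protein chain
  prot <- which(!at$is_hetero)
  out <- character(0)
  if (length(prot)) {
    chains <- at$chain_id[prot]
    breaks <- c(which(chains[-1] != chains[-length(chains)]), length(chains))
    prev <- 0L
    for (b in breaks) {
      out <- c(out, recs[prot[(prev + 1L):b]], "TER")
      prev <- b
    }
  }
  out <- c(out, recs[at$is_hetero], "END")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_input(paste0("cannot open for writing: ", path)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
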
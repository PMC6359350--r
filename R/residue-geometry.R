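# Idealized side-chain geometry for the graft-mode mutant builder.
#
# Missing side-chain atoms are placed one at a time from an internal
# coordinate (Z-matrix) template: each atom is defined by a bond length
# to atom `b`, a bond angle through `a` and a dihedral through `d`, all
# of which are already placed (backbone or earlier side-chain atoms).
# Acyclic chains use trans (180 deg) chain dihedrals with branches offset
# by roughly a staggered rotamer; rings carry fixed dihedrals that close
# them approximately planar. Standard bond lengths/angles; no clash
# resolution and no rotamer search (documented limitation).

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Canonical heavy-atom set of a residue type
#'
#' @param res_name 3-letter residue code.
#' @return Character vector of backbone + side-chain heavy atom names.
#' @export
canonical_atoms <- function(res_name) {
  sc <- SIDECHAIN_ATOMS[[res_name]]
  if (is.null(sc))
    stop_typing(paste0("not a canonical residue type: ", res_name))
  c(BACKBONE_ATOMS, sc)
}

# res, atom, b (bond ref), a (angle ref), d (dihedral ref), bond A,
# angle deg, dihedral deg. "CB" row applies to all residues.
zmatrix_rows <- function() {
  z <- function(res, atom, b, a, d, bond, angle, dihedral)
    data.frame(res = res, atom = atom, b = b, a = a, d = d,
               bond = bond, angle = angle, dihedral = dihedral,
               stringsAsFactors = FALSE)
  rbind(
    # CB from the backbone frame; -122.7 deg improper gives L chirality
    z("*",   "CB",  "CA", "N",  "C",   1.53, 110.5, -122.7),
    z("SER", "OG",  "CB", "CA", "N",   1.42, 110.8, 180),
    z("CYS", "SG",  "CB", "CA", "N",   1.81, 114.0, 180),
    z("THR", "OG1", "CB", "CA", "N",   1.43, 109.5, 180),
    z("THR", "CG2", "CB", "CA", "N",   1.52, 110.5, -60),
    z("VAL", "CG1", "CB", "CA", "N",   1.52, 110.5, 180),
    z("VAL", "CG2", "CB", "CA", "N",   1.52, 110.5, -60),
    z("ILE", "CG1", "CB", "CA", "N",   1.53, 110.4, 180),
    z("ILE", "CG2", "CB", "CA", "N",   1.53, 110.5, -60),
    z("ILE", "CD1", "CG1", "CB", "CA", 1.52, 113.1, 180),
    z("LEU", "CG",  "CB", "CA", "N",   1.53, 116.3, 180),
    z("LEU", "CD1", "CG", "CB", "CA",  1.52, 110.7, 180),
    z("LEU", "CD2", "CG", "CB", "CA",  1.52, 110.7, 60),
    z("ASN", "CG",  "CB", "CA", "N",   1.52, 112.6, 180),
    z("ASN", "OD1", "CG", "CB", "CA",  1.23, 120.8, 0),
    z("ASN", "ND2", "CG", "CB", "CA",  1.33, 116.5, 180),
    z("ASP", "CG",  "CB", "CA", "N",   1.52, 112.6, 180),
    z("ASP", "OD1", "CG", "CB", "CA",  1.25, 118.5, 0),
    z("ASP", "OD2", "CG", "CB", "CA",  1.25, 118.5, 180),
    z("GLN", "CG",  "CB", "CA", "N",   1.52, 114.1, 180),
    z("GLN", "CD",  "CG", "CB", "CA",  1.52, 112.6, 180),
    z("GLN", "OE1", "CD", "CG", "CB",  1.23, 120.8, 0),
    z("GLN", "NE2", "CD", "CG", "CB",  1.33, 116.5, 180),
    z("GLU", "CG",  "CB", "CA", "N",   1.52, 114.1, 180),
    z("GLU", "CD",  "CG", "CB", "CA",  1.52, 112.6, 180),
    z("GLU", "OE1", "CD", "CG", "CB",  1.25, 118.5, 0),
    z("GLU", "OE2", "CD", "CG", "CB",  1.25, 118.5, 180),
    z("MET", "CG",  "CB", "CA", "N",   1.52, 114.1, 180),
    z("MET", "SD",  "CG", "CB", "CA",  1.81, 112.7, 180),
    z("MET", "CE",  "SD", "CG", "CB",  1.79, 100.2, 180),
    z("LYS", "CG",  "CB", "CA", "N",   1.52, 114.1, 180),
    z("LYS", "CD",  "CG", "CB", "CA",  1.52, 111.3, 180),
    z("LYS", "CE",  "CD", "CG", "CB",  1.52, 111.3, 180),
    z("LYS", "NZ",  "CE", "CD", "CG",  1.49, 111.9, 180),
    z("ARG", "CG",  "CB", "CA", "N",   1.52, 114.1, 180),
    z("ARG", "CD",  "CG", "CB", "CA",  1.52, 111.3, 180),
    z("ARG", "NE",  "CD", "CG", "CB",  1.46, 112.0, 180),
    z("ARG", "CZ",  "NE", "CD", "CG",  1.33, 124.2, 180),
    z("ARG", "NH1", "CZ", "NE", "CD",  1.33, 120.0, 0),
    z("ARG", "NH2", "CZ", "NE", "CD",  1.33, 120.0, 180),
    z("PRO", "CG",  "CB", "CA", "N",   1.50, 104.5, 30),
    z("PRO", "CD",  "CG", "CB", "CA",  1.50, 106.1, -35),
    z("PHE", "CG",  "CB", "CA", "N",   1.50, 113.8, 180),
    z("PHE", "CD1", "CG", "CB", "CA",  1.39, 120.8, 90),
    z("PHE", "CD2", "CG", "CB", "CA",  1.39, 120.8, -90),
    z("PHE", "CE1", "CD1", "CG", "CD2", 1.39, 120.3, 0),
    z("PHE", "CE2", "CD2", "CG", "CD1", 1.39, 120.3, 0),
    z("PHE", "CZ",  "CE1", "CD1", "CG", 1.39, 119.8, 0),
    z("TYR", "CG",  "CB", "CA", "N",   1.51, 113.9, 180),
    z("TYR", "CD1", "CG", "CB", "CA",  1.39, 120.8, 90),
    z("TYR", "CD2", "CG", "CB", "CA",  1.39, 120.8, -90),
    z("TYR", "CE1", "CD1", "CG", "CD2", 1.39, 121.1, 0),
    z("TYR", "CE2", "CD2", "CG", "CD1", 1.39, 121.1, 0),
    z("TYR", "CZ",  "CE1", "CD1", "CG", 1.38, 119.5, 0),
    z("TYR", "OH",  "CZ", "CE1", "CD1", 1.38, 119.7, 180),
    z("HIS", "CG",  "CB", "CA", "N",   1.50, 113.8, 180),
    z("HIS", "ND1", "CG", "CB", "CA",  1.38, 122.7, 90),
    z("HIS", "CD2", "CG", "CB", "CA",  1.36, 129.1, -90),
    z("HIS", "CE1", "ND1", "CG", "CD2", 1.32, 108.2, 0),
    z("HIS", "NE2", "CD2", "CG", "ND1", 1.37, 107.2, 0),
    z("TRP", "CG",  "CB", "CA", "N",   1.50, 113.6, 180),
    z("TRP", "CD1", "CG", "CB", "CA",  1.37, 126.9, 90),
    z("TRP", "CD2", "CG", "CB", "CA",  1.43, 126.8, -90),
    z("TRP", "NE1", "CD1", "CG", "CD2", 1.38, 110.2, 0),
    z("TRP", "CE2", "CD2", "CG", "CD1", 1.41, 107.2, 0),
    z("TRP", "CE3", "CD2", "CG", "CD1", 1.40, 133.9, 180),
    z("TRP", "CZ2", "CE2", "CD2", "CG", 1.40, 122.4, 180),
    z("TRP", "CZ3", "CE3", "CD2", "CE2", 1.39, 118.6, 0),
    z("TRP", "CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0)
  )
}

get_zmatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- zmatrix_rows()
    cache
  }
})

# Place atom X given positions of b (bonded), a (angle ref), d (dihedral
# ref) and internal coordinates: |X-b| = bond, angle X-b-a, dihedral
# X-b-a-d. Natural extension reference frame construction.
place_atom <- function(b, a, d, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  ab <- b - a
  da <- a - d
  n1 <- ab / sqrt(sum(ab^2))
  # orthonormal frame at b
  nv <- pracma_cross(da, ab)
  if (sqrt(sum(nv^2)) < 1e-8) {
    # colinear references: pick any perpendicular
    alt <- if (abs(n1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    nv <- pracma_cross(alt, ab)
  }
  n2 <- nv / sqrt(sum(nv^2))
  n3 <- pracma_cross(n2, n1)
  local_dir <- -cos(ang) * n1 +
    sin(ang) * (cos(dih) * n3 + sin(dih) * n2)
  b + bond * local_dir
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Build the missing heavy atoms of `res_name` for one residue's atom
# table (data frame subset of a structure's atoms). Returns added rows.
graft_sidechain <- function(res_atoms, res_name) {
  have <- setNames(lapply(seq_len(nrow(res_atoms)), function(i)
    as.numeric(res_atoms[i, c("x", "y", "z")])), res_atoms$name)
  for (bb in c("N", "CA", "C"))
    if (is.null(have[[bb]]))
      stop_input(paste0("graft mode needs backbone atom ", bb))
  want <- setdiff(canonical_atoms(res_name), names(have))
  want <- setdiff(want, "O")  # never fabricate backbone carbonyl O
  if (!length(want)) return(res_atoms[0, , drop = FALSE])
  zm <- get_zmatrix()
  added <- list()
  for (atom in intersect(c("CB", SIDECHAIN_ATOMS[[res_name]]), want)) {
    row <- zm[(zm$res == res_name | zm$res == "*") & zm$atom == atom, ]
    if (!nrow(row))
      stop_typing(paste0("no geometry template for ", res_name, " ", atom))
    row <- row[1L, ]
    for (ref in c(row$b, row$a, row$d))
      if (is.null(have[[ref]]))
        stop_input(sprintf("graft reference atom %s missing for %s %s",
                           ref, res_name, atom))
    xyz <- place_atom(have[[row$b]], have[[row$a]], have[[row$d]],
                      row$bond, row$angle, row$dihedral)
    have[[atom]] <- xyz
    tmpl <- res_atoms[1L, , drop = FALSE]
    tmpl$name <- atom
    tmpl$element <- substr(atom, 1, 1)
    tmpl$x <- xyz[1]; tmpl$y <- xyz[2]; tmpl$z <- xyz[3]
    tmpl$occupancy <- 1.0
    added[[length(added) + 1L]] <- tmpl
  }
  if (!length(added)) return(res_atoms[0, , drop = FALSE])
  do.call(rbind, added)
}
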
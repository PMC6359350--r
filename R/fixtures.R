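# Deterministic synthetic fixtures.
#
# Everything the test suite and examples need is generated in code: toy
# structures whose atoms are named so the shipped typing table reproduces
# requested class sets exactly, toy proteins with grafted side chains,
# jittered template databases standing in for a curated template set, and
# planted-benefit wild/mutant/template triples. The module also houses
# the independent brute-force signature oracle.

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# class-set -> (res_name, atom_name) realizations under the default table;
# keys are class sets in canonical order, comma-joined
CLASS_SET_ATOMS <- list(
  "hydrophobic"                      = c("ALA", "CB"),
  "donor"                            = c("ALA", "N"),
  "acceptor"                         = c("ALA", "O"),
  "aromatic"                         = c("PHE", "CG"),
  "sulfur"                           = c("CYS", "SG"),
  "neutral"                          = c("PRO", "N"),
  "positive,donor"                   = c("LYS", "NZ"),
  "negative,acceptor"                = c("ASP", "OD1"),
  "acceptor,donor"                   = c("SER", "OG"),
  "donor,aromatic"                   = c("TRP", "NE1"),
  "positive,acceptor,donor,aromatic" = c("HIS", "ND1")
)

canonical_class_key <- function(classes) {
  paste(PHARMACOPHORE_CLASSES[PHARMACOPHORE_CLASSES %in% classes],
        collapse = ",")
}

#' Build a toy structure realizing requested pharmacophore class sets
#'
#' Each atom is emitted as its own one-atom residue whose residue/atom
#' names are chosen so that [assign_pharmacophores()] with the default
#' table reproduces the requested class set exactly. Only class sets a
#' canonical atom can realize are accepted (e.g. `"hydrophobic"`,
#' `"sulfur"`, `c("negative", "acceptor")`, ...).
#'
#' @param classes list of character vectors, one class set per atom.
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param id structure id.
#' @return An `ssv_structure`.
#' @export
make_toy_structure <- function(classes, coords, id = "toy") {
  if (!length(classes)) stop_input("toy spec has no atoms")
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(classes))
    stop_input("one coordinate row per class set is required")
  if (any(!is.finite(coords))) stop_input("non-finite toy coordinates")
  rows <- lapply(seq_along(classes), function(i) {
    key <- canonical_class_key(classes[[i]])
    hit <- CLASS_SET_ATOMS[[key]]
    if (is.null(hit))
      stop_input(paste0("no canonical atom realizes class set {", key, "}"))
    data.frame(serial = i, name = hit[2L], alt_loc = "",
               res_name = hit[1L], chain_id = "A", seq_num = i,
               icode = "", x = coords[i, 1], y = coords[i, 2],
               z = coords[i, 3], occupancy = 1.0,
               element = substr(hit[2L], 1, 1), is_hetero = FALSE,
               stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows), id = id)
}

#' Build a toy protein with full residues and grafted side chains
#'
#' Residues are laid out along an extended zig-zag backbone (roughly
#' 3.8 Angstrom CA-CA spacing) and side chains are grown with the
#' idealized internal-coordinate templates, so the result is a
#' well-formed multi-residue structure suitable for pocket extraction,
#' mutation and signature tests. Not a physically refined model.
#'
#' @param sequence one-letter amino-acid string, or an integer length
#'   (sequence then drawn uniformly from the 20 canonical letters under
#'   `seed`).
#' @param seed RNG seed used only when `sequence` is a length.
#' @param chain_id chain identifier.
#' @param id structure id.
#' @param start_seq_num numbering of the first residue.
#' @return An `ssv_structure`.
#' @export
make_toy_protein <- function(sequence = 8, seed = 1, chain_id = "A",
                             id = "toyprot", start_seq_num = 1L) {
  if (is.numeric(sequence)) {
    n <- as.integer(sequence)
    if (n < 1L) stop_input("toy protein needs at least one residue")
    sequence <- with_seed(seed,
                          paste(sample(AA_ONE, n, replace = TRUE),
                                collapse = ""))
  }
  letters1 <- strsplit(sequence, "")[[1L]]
  res3 <- one_to_three(letters1)
  rows <- list()
  serial <- 0L
  for (i in seq_along(res3)) {
    base <- c(3.8 * (i - 1L), 1.4 * (i %% 2), 0.4 * ((i %/% 2) %% 2))
    bb <- rbind(N  = base,
                CA = base + c(1.20, 0.90, 0.30),
                C  = base + c(2.50, 0.60, 0.10),
                O  = base + c(3.05, -0.45, 0.35))
    res_rows <- data.frame(
      serial = serial + seq_len(4L), name = rownames(bb), alt_loc = "",
      res_name = res3[i], chain_id = chain_id,
      seq_num = start_seq_num + i - 1L, icode = "",
      x = bb[, 1], y = bb[, 2], z = bb[, 3], occupancy = 1.0,
      element = substr(rownames(bb), 1, 1), is_hetero = FALSE,
      stringsAsFactors = FALSE)
    side <- graft_sidechain(res_rows, res3[i])
    if (nrow(side)) side$serial <- max(res_rows$serial) + seq_len(nrow(side))
    res_rows <- rbind(res_rows, side)
    serial <- serial + nrow(res_rows)
    rows[[i]] <- res_rows
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  new_structure(at, id = id)
}

#' Add a toy ligand to a structure
#'
#' Appends a small hetero residue (carbon/oxygen atoms) centered at
#' `center`, e.g. to exercise ligand-distance pocket extraction.
#'
#' @param structure an `ssv_structure`.
#' @param center ligand centroid (length-3).
#' @param res_name hetero residue name (default `"LIG"`).
#' @param seq_num hetero residue number (default 900).
#' @return The structure with the ligand appended.
#' @export
add_toy_ligand <- function(structure, center, res_name = "LIG",
                           seq_num = 900L) {
  offs <- rbind(C1 = c(0, 0, 0), C2 = c(1.4, 0, 0), O1 = c(0, 1.3, 0),
                O2 = c(1.4, 1.3, 0.6))
  lig <- data.frame(
    serial = n_atoms(structure) + seq_len(nrow(offs)),
    name = rownames(offs), alt_loc = "", res_name = res_name,
    chain_id = "A", seq_num = as.integer(seq_num), icode = "",
    x = center[1] + offs[, 1], y = center[2] + offs[, 2],
    z = center[3] + offs[, 3], occupancy = 1.0,
    element = substr(rownames(offs), 1, 1), is_hetero = TRUE,
    stringsAsFactors = FALSE)
  new_structure(rbind(structure$atoms, lig), id = structure$id)
}

#' Jittered template database from a base structure
#'
#' Emulates a curated template set: `n` copies of `base` with every
#' coordinate perturbed by independent uniform noise in
#' `[-jitter, jitter]`. With `jitter = 0` every template signature equals
#' the base signature.
#'
#' @param base an `ssv_structure`.
#' @param n number of templates (>= 1).
#' @param jitter noise amplitude in Angstrom (>= 0).
#' @param seed RNG seed.
#' @param grid cutoff grid for the signatures.
#' @return An `ssv_template_db` with ids `T01`, `T02`, ...
#' @export
make_template_db <- function(base, n = 23, jitter = 0.3, seed = 1,
                             grid = cutoff_grid()) {
  if (n < 1L) stop_config("template database needs n >= 1")
  if (jitter < 0) stop_config("jitter must be >= 0")
  sigs <- with_seed(seed, lapply(seq_len(n), function(i) {
    at <- base$atoms
    m <- nrow(at)
    at$x <- at$x + runif(m, -jitter, jitter)
    at$y <- at$y + runif(m, -jitter, jitter)
    at$z <- at$z + runif(m, -jitter, jitter)
    structure_signature(new_structure(at, id = sprintf("T%02d", i)),
                        grid = grid)
  }))
  names(sigs) <- sprintf("T%02d", seq_len(n))
  new_template_db(sigs, grid = grid)
}

#' Plant a beneficial-mutation scenario
#'
#' Derives wild and mutant structures from a template by displacing every
#' atom along a fixed random direction, the wild farther than the mutant,
#' so that the mutant signature is strictly closer to the template
#' signature (checked at construction; the direction set is redrawn
#' deterministically in the rare event the displacement ordering does not
#' carry over to signature space). The returned database contains the
#' template alone, so a beneficial (negative) ddSSV is guaranteed.
#'
#' @param template an `ssv_structure`.
#' @param wild_displacement,mutant_displacement per-atom displacement
#'   magnitudes in Angstrom; the mutant displacement must not exceed the
#'   wild one.
#' @param seed RNG seed.
#' @param grid cutoff grid.
#' @return List with `wild`, `mutant` (structures), `db` (single-entry
#'   `ssv_template_db`) and the realized `wild_sig`/`mutant_sig`.
#' @export
plant_beneficial_case <- function(template, wild_displacement = 2.0,
                                  mutant_displacement = 0.5, seed = 1,
                                  grid = cutoff_grid()) {
  if (mutant_displacement > wild_displacement)
    stop_input("mutant displacement must not exceed wild displacement")
  tpl_sig <- structure_signature(template, grid = grid)
  n <- n_atoms(template)
  for (attempt in 0:19) {
    u <- with_seed(seed + attempt, {
      v <- matrix(runif(3 * n, -1, 1), ncol = 3)
      v / sqrt(rowSums(v^2))
    })
    displace <- function(amount, id) {
      at <- template$atoms
      at$x <- at$x + amount * u[, 1]
      at$y <- at$y + amount * u[, 2]
      at$z <- at$z + amount * u[, 3]
      new_structure(at, id = id)
    }
    wild <- displace(wild_displacement, "wild")
    mutant <- displace(mutant_displacement, "mutant")
    wild_sig <- structure_signature(wild, grid = grid)
    mutant_sig <- structure_signature(mutant, grid = grid)
    d_w <- signature_distance(wild_sig, tpl_sig)
    d_m <- signature_distance(mutant_sig, tpl_sig)
    ok <- if (wild_displacement == mutant_displacement) d_w == d_m else
      d_m < d_w
    if (ok) break
  }
  if (!ok)
    stop_input("could not realize the requested displacement ordering")
  db <- new_template_db(list(T1 = tpl_sig), grid = grid)
  list(wild = wild, mutant = mutant, db = db,
       wild_sig = wild_sig, mutant_sig = mutant_sig)
}

#' Independent brute-force signature oracle
#'
#' A literal double loop over all unordered atom pairs and all cutoff
#' points, with its own class-pair enumeration and its own inclusive
#' distance comparison -- no shared code with [compute_signature()]
#' beyond the canonical class order. Intended for testing only.
#'
#' @param classes list of per-atom class sets.
#' @param coords numeric n x 3 coordinate matrix.
#' @param grid cutoff grid.
#' @return Numeric vector laid out exactly like an `ssv_signature`.
#' @export
brute_force_signature <- function(classes, coords, grid = cutoff_grid()) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(classes)
  ncut <- length(grid$points)
  cls <- PHARMACOPHORE_CLASSES
  npair <- length(cls) * (length(cls) + 1) / 2
  out <- numeric(npair * ncut)
  pair_ordinal <- function(a, b) {
    # independent enumeration: count unordered pairs before (min, max)
    i <- min(match(a, cls), match(b, cls))
    j <- max(match(a, cls), match(b, cls))
    ord <- 0L
    for (p in seq_along(cls)) {
      for (q in p:length(cls)) {
        ord <- ord + 1L
        if (p == i && q == j) return(ord)
      }
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        seen <- integer(0)
        for (a in classes[[i]]) {
          for (b in classes[[j]]) {
            r <- pair_ordinal(a, b)
            if (r %in% seen) next
            seen <- c(seen, r)
            for (k in seq_len(ncut)) {
              if (d <= grid$points[k] + 1e-9) {
                cell <- (r - 1L) * ncut + k
                out[cell] <- out[cell] + 1
              }
            }
          }
        }
      }
    }
  }
  out
}

#' Engineered saturation-screen filter fixture
#'
#' A deterministic candidate set and filter chain shaped like a realistic
#' pocket screen: 86 single-site candidates over a 22-residue pocket, of
#' which 9 sit at fully conserved positions, 58 of the rest are not
#' tolerated by the substitution table, and 4 of the remainder are
#' predicted highly destabilizing -- leaving 15 survivors.
#'
#' @return List with `candidates` (list of specs), `stages` (named stage
#'   list for [apply_filter_chain()]), plus the underlying `profile`,
#'   `sift` map and `mcsm` table.
#' @export
make_screen_filter_fixture <- function() {
  positions <- 101:122
  conserved_idx <- c(3, 5, 8, 13, 17, 20)
  conserved_pos <- positions[conserved_idx]
  counts <- integer(22)
  counts[conserved_idx] <- c(2, 2, 2, 1, 1, 1)              # 9 candidates
  other_idx <- setdiff(seq_along(positions), conserved_idx)
  counts[other_idx] <- c(rep(5L, 13L), rep(4L, 3L))         # 77 candidates
  wild <- "A"
  targets <- setdiff(AA_ALPHABET, wild)
  candidates <- list()
  for (i in seq_along(positions)) {
    for (t in targets[seq_len(counts[i])]) {
      candidates[[length(candidates) + 1L]] <-
        parse_mutation(sprintf("%s%d%s", wild, positions[i], t))
    }
  }
  profile <- setNames(ifelse(positions %in% conserved_pos, 1.0, 0.5),
                      positions)
  # tolerated sets: 19 of the 77 non-conserved candidates survive
  tolerate_n <- setNames(integer(length(positions)), positions)
  tolerate_n[as.character(positions[other_idx])] <-
    c(rep(2L, 7L), rep(1L, 5L), rep(0L, 4L))                # sums to 19
  sift <- list()
  for (i in seq_along(positions)) {
    p <- as.character(positions[i])
    sift[[p]] <- targets[seq_len(tolerate_n[[p]])]
  }
  # stability: first 4 tolerated candidates highly destabilizing
  tolerated_keys <- vapply(
    Filter(function(sp) {
      p <- as.character(sp$position)
      !(sp$position %in% conserved_pos) && sp$mutant_aa %in% sift[[p]]
    }, candidates),
    format_mutation, "")
  ddg <- setNames(rep(-0.5, length(candidates)),
                  vapply(candidates, format_mutation, ""))
  ddg[tolerated_keys[1:4]] <- -3.0
  stages <- list(
    conservation = stage_conservation(profile, threshold = 1.0),
    sift = stage_sift(sift),
    mcsm = stage_mcsm(ddg, cutoff = -2.0)
  )
  list(candidates = candidates, stages = stages,
       profile = profile, sift = sift, mcsm = ddg)
}

#' Synthetic pocket-residue alignment fixture
#'
#' An alignment of a 22-column query pocket against `n_templates`
#' template rows in which exactly the requested query positions are
#' fully conserved across the template rows; all other columns disagree
#' with the query in at least one row. Deterministic.
#'
#' @param conserved_positions query positions (1-based) to conserve.
#' @param n_templates number of template rows (default 23).
#' @param width alignment width (default 22).
#' @return Named character vector of aligned sequences; the query row is
#'   named `"query"`.
#' @export
make_conservation_alignment <- function(conserved_positions = c(3, 5, 8, 13, 17, 20),
                                        n_templates = 23, width = 22) {
  query <- strsplit(paste(rep(c("A", "G", "E", "H", "W", "Y"),
                              length.out = width), collapse = ""), "")[[1L]]
  rows <- matrix(rep(query, n_templates), nrow = n_templates, byrow = TRUE)
  swap <- setdiff(seq_len(width), conserved_positions)
  for (j in swap) {
    # break conservation in one template row per column, cycling rows
    r <- ((j - 1L) %% n_templates) + 1L
    rows[r, j] <- if (query[j] == "S") "T" else "S"
  }
  aln <- c(paste(query, collapse = ""),
           apply(rows, 1, paste, collapse = ""))
  names(aln) <- c("query", sprintf("T%02d", seq_len(n_templates)))
  aln
}
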
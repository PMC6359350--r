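# Cutoff-scanning signature computation.
#
# The signature of a structure is the flat vector of cumulative heavy-atom
# pair counts per unordered pharmacophore class pair (36 pairs of the 8
# classes) per distance cutoff (101 points from 0 to 10 Angstrom in 0.1
# steps by default), giving 36 x 101 = 3636 components. Layout is
# row-major: component index = class_pair_index * n_cutoffs + cutoff_index.

#' Distance cutoff grid
#'
#' @param d_min,d_max grid range in Angstrom (defaults 0 and 10).
#' @param step cutoff step in Angstrom (default 0.1).
#' @return An object of class `ssv_grid` with the ordered cutoff `points`
#'   (101 points at the defaults).
#' @export
cutoff_grid <- function(d_min = 0, d_max = 10, step = 0.1) {
  if (!(d_max > d_min) || step <= 0)
    stop_config("cutoff grid requires d_max > d_min and step > 0")
  n <- round((d_max - d_min) / step)
  points <- d_min + (0:n) * step
  structure(list(d_min = d_min, d_max = d_max, step = step, points = points),
            class = "ssv_grid")
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$points, b$points, tolerance = 1e-9))
}

# 1-based symmetric lookup matrix for unordered class pairs, enumerated
# lexicographically in the canonical class order:
# (1,1),(1,2),...,(1,8),(2,2),...,(8,8).
.pair_index_matrix <- local({
  k <- length(PHARMACOPHORE_CLASSES)
  m <- matrix(0L, k, k, dimnames = list(PHARMACOPHORE_CLASSES,
                                        PHARMACOPHORE_CLASSES))
  idx <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    idx <- idx + 1L
    m[i, j] <- idx
    m[j, i] <- idx
  }
  m
})

N_CLASS_PAIRS <- max(.pair_index_matrix)

#' Canonical index of an unordered pharmacophore class pair
#'
#' Enumerates the 36 unordered pairs (with repetition) of the 8 classes
#' lexicographically in the canonical class order, 0-based:
#' (hydrophobic, hydrophobic) is 0, (hydrophobic, positive) is 1, ...,
#' (neutral, neutral) is 35. Symmetric in its arguments.
#'
#' @param c1,c2 class names from [PHARMACOPHORE_CLASSES].
#' @return Integer in `[0, 36)`.
#' @export
class_pair_index <- function(c1, c2) {
  i <- match(c1, PHARMACOPHORE_CLASSES)
  j <- match(c2, PHARMACOPHORE_CLASSES)
  if (anyNA(i) || anyNA(j))
    stop_typing(paste0("unknown pharmacophore class: ",
                       paste(unique(c(c1[is.na(i)], c2[is.na(j)])),
                             collapse = ", ")))
  .pair_index_matrix[cbind(i, j)] - 1L
}

signature_names <- function(grid) {
  k <- length(PHARMACOPHORE_CLASSES)
  pairs <- character(N_CLASS_PAIRS)
  idx <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    idx <- idx + 1L
    pairs[idx] <- paste(PHARMACOPHORE_CLASSES[i],
                        PHARMACOPHORE_CLASSES[j], sep = ":")
  }
  as.vector(t(outer(pairs, format_cutoff(grid$points), paste, sep = ":")))
}

format_cutoff <- function(x) formatC(x, format = "f", digits = 1)

# First cumulative cell a distance contributes to: the smallest grid index
# whose cutoff point is >= d (inclusive comparison, 1e-9 float guard).
first_bin <- function(d, grid) {
  t <- (d - grid$d_min) / grid$step
  as.integer(ceiling(t - 1e-9)) + 1L
}

new_signature <- function(values, grid, id = "") {
  structure(as.numeric(values),
            names = signature_names(grid),
            grid = grid, id = id, class = "ssv_signature")
}

#' Compute the cutoff-scanning signature of a structure
#'
#' For every unordered pair of distinct heavy atoms at Euclidean distance
#' `d <= d_max`, and every unordered class pair derivable from the two
#' atoms' class sets (each distinct derived pair counted once), the
#' cumulative count is incremented at every cutoff point `>= d`.
#' Intra-residue pairs are included; self-pairs are not. The result is
#' invariant to atom order and to rigid motion of the structure.
#'
#' @param pocket_structure an `ssv_structure` (normally an extracted
#'   pocket); hetero/ligand atoms must already be excluded by the caller
#'   if they are not to be counted.
#' @param assignments per-atom class sets from [assign_pharmacophores()];
#'   computed with the default table when omitted.
#' @param grid a [cutoff_grid()].
#' @return An `ssv_signature`: named numeric vector of length
#'   `36 * length(grid$points)` (3636 at the default grid) with attributes
#'   `grid` and `id`. An empty structure yields the zero vector.
#' @export
compute_signature <- function(pocket_structure,
                              assignments = NULL,
                              grid = cutoff_grid()) {
  stopifnot(inherits(pocket_structure, "ssv_structure"))
  n <- n_atoms(pocket_structure)
  ncut <- length(grid$points)
  out <- numeric(N_CLASS_PAIRS * ncut)
  if (n == 0L)
    return(new_signature(out, grid, id = pocket_structure$id))
  if (is.null(assignments))
    assignments <- assign_pharmacophores(pocket_structure)
  if (length(assignments) != n)
    stop_typing("one class assignment per atom is required")
  if (any(lengths(assignments) == 0L))
    stop_typing("empty pharmacophore class set encountered")

  if (n > 1L) {
    # group atoms by identical class sets; count per group pair
    setkey <- vapply(assignments, paste, "", collapse = ",")
    groups <- split(seq_len(n), setkey)
    gsets <- lapply(groups, function(ix) assignments[[ix[1L]]])
    D <- as.matrix(dist(coords(pocket_structure)))
    ng <- length(groups)
    for (gi in seq_len(ng)) {
      for (gj in gi:ng) {
        rows <- unique(as.vector(outer(gsets[[gi]], gsets[[gj]],
                                       class_pair_index))) + 1L
        d <- if (gi == gj) {
          ix <- groups[[gi]]
          if (length(ix) < 2L) next
          D[ix, ix][upper.tri(diag(length(ix)))]
        } else {
          as.vector(D[groups[[gi]], groups[[gj]], drop = FALSE])
        }
        bins <- first_bin(d, grid)
        bins <- bins[bins >= 1L & bins <= ncut]
        if (!length(bins)) next
        row_counts <- cumsum(tabulate(bins, nbins = ncut))
        for (r in rows) {
          off <- (r - 1L) * ncut
          out[(off + 1L):(off + ncut)] <- out[(off + 1L):(off + ncut)] +
            row_counts
        }
      }
    }
  }
  new_signature(out, grid, id = pocket_structure$id)
}

#' Euclidean distance between two signatures
#'
#' @param a,b `ssv_signature` vectors (or plain numeric vectors of equal
#'   length); grids must match when both carry one.
#' @return Non-negative Euclidean (L2) distance.
#' @export
signature_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_shape(sprintf("signature dimension mismatch: %d vs %d",
                       length(a), length(b)))
  ga <- attr(a, "grid"); gb <- attr(b, "grid")
  if (!is.null(ga) && !is.null(gb) && !grids_equal(ga, gb))
    stop_shape("signatures computed on different cutoff grids")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Convenience: pocket signature straight from a structure
#'
#' Drops hetero (ligand) atoms, assigns pharmacophore classes with the
#' supplied table and computes the signature.
#'
#' @inheritParams compute_signature
#' @param structure an `ssv_structure`.
#' @param table typing table for [assign_pharmacophores()].
#' @return An `ssv_signature`.
#' @export
structure_signature <- function(structure, grid = cutoff_grid(),
                                table = default_pharmacophore_table()) {
  at <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  prot <- new_structure(at, id = structure$id)
  compute_signature(prot, assign_pharmacophores(prot, table), grid)
}

#' Write a signature matrix to TSV
#'
#' One row per structure: first column `id`, then one column per
#' signature component named `<classA>:<classB>:<cutoff>`.
#'
#' @param signatures a single `ssv_signature` or a list of them.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_signature_tsv <- function(signatures, path) {
  if (inherits(signatures, "ssv_signature")) signatures <- list(signatures)
  ids <- vapply(signatures, function(s) attr(s, "id"), "")
  mat <- do.call(rbind, lapply(signatures, as.numeric))
  df <- data.frame(id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", names(signatures[[1L]]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix from TSV
#'
#' @param path TSV written by [write_signature_tsv()].
#' @param grid grid the signatures are expected to live on.
#' @return Named list of `ssv_signature` vectors.
#' @export
read_signature_tsv <- function(path, grid = cutoff_grid()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "id")
    stop_format("signature TSV must start with an 'id' column")
  if (ncol(df) - 1L != N_CLASS_PAIRS * length(grid$points))
    stop_shape(sprintf(
      "signature TSV has %d components but the grid implies %d",
      ncol(df) - 1L, N_CLASS_PAIRS * length(grid$points)))
  sigs <- lapply(seq_len(nrow(df)), function(i)
    new_signature(as.numeric(df[i, -1L]), grid, id = df$id[i]))
  setNames(sigs, df$id)
}
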
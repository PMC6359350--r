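# Catalytic pocket definition and transfer.
#
# A pocket is defined on a reference structure by ligand distance
# (every protein residue with a heavy atom within the cutoff of a ligand
# heavy atom) and transferred to homologous structures by global sequence
# alignment; Kabsch superposition is provided for QC/visualization.

#' Create a pocket definition
#'
#' @param residues data frame with columns `chain_id`, `seq_num`, `icode`,
#'   `res_name` (ordered).
#' @param reference_id id of the structure the pocket was defined on.
#' @param cutoff the ligand-distance cutoff used, in Angstrom (or `NA`).
#' @return An object of class `ssv_pocket`.
#' @export
new_pocket <- function(residues, reference_id = "", cutoff = NA_real_) {
  need <- c("chain_id", "seq_num", "icode", "res_name")
  if (!all(need %in% names(residues)))
    stop_input(paste0("pocket residues need columns: ",
                      paste(need, collapse = ", ")))
  residues <- as.data.frame(residues)[, need]
  if (!nrow(residues)) stop_input("empty pocket definition")
  if (anyDuplicated(residue_key(residues)))
    stop_input("duplicate residue keys in pocket definition")
  rownames(residues) <- NULL
  structure(list(reference_id = reference_id, residues = residues,
                 cutoff = cutoff),
            class = "ssv_pocket")
}

#' @export
print.ssv_pocket <- function(x, ...) {
  cat(sprintf("<ssv_pocket: %d residues, reference '%s', cutoff %s A>\n",
              nrow(x$residues), x$reference_id,
              format(x$cutoff)))
  invisible(x)
}

#' Residues within a distance cutoff of a ligand
#'
#' Selects every protein residue having at least one heavy atom within
#' `cutoff` (inclusive) of at least one heavy atom of the named ligand,
#' in chain/sequence order of the structure.
#'
#' @param structure an `ssv_structure` read with `keep_ligands = TRUE`.
#' @param ligand_key residue key of the ligand as `"chain:seq_num"` or
#'   `"chain:seq_num:res_name"`.
#' @param cutoff distance cutoff in Angstrom (default 6.5).
#' @return An `ssv_pocket`.
#' @export
residues_near_ligand <- function(structure, ligand_key, cutoff = 6.5) {
  if (!is.numeric(cutoff) || cutoff < 0)
    stop_config("cutoff must be a non-negative number")
  at <- structure$atoms
  parts <- strsplit(ligand_key, ":", fixed = TRUE)[[1L]]
  if (length(parts) < 2L)
    stop_lookup("ligand key must be 'chain:seq_num[:res_name]'")
  lig <- at$is_hetero & at$chain_id == parts[1L] &
    at$seq_num == as.integer(parts[2L])
  if (length(parts) >= 3L) lig <- lig & at$res_name == parts[3L]
  if (!any(lig))
    stop_lookup(paste0("ligand not found: ", ligand_key))
  lig_xyz <- as.matrix(at[lig, c("x", "y", "z")])
  prot <- !at$is_hetero
  if (!any(prot)) stop_input("structure has no protein atoms")
  prot_xyz <- as.matrix(at[prot, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  d2 <- vapply(seq_len(nrow(lig_xyz)), function(i) {
    rowSums(sweep(prot_xyz, 2, lig_xyz[i, ])^2)
  }, numeric(nrow(prot_xyz)))
  mind <- sqrt(if (is.matrix(d2)) apply(d2, 1, min) else d2)
  hit_atoms <- mind <= cutoff + 1e-9
  if (!any(hit_atoms))
    stop_lookup(sprintf("no residue within %.2f A of ligand %s",
                        cutoff, ligand_key))
  pa <- at[prot, , drop = FALSE]
  hit_keys <- unique(residue_key(pa[hit_atoms, , drop = FALSE]))
  rt <- residue_table(structure, hetero = FALSE)
  sel <- rt[residue_key(rt) %in% hit_keys,
            c("chain_id", "seq_num", "icode", "res_name")]
  # chain/sequence order
  sel <- sel[order(sel$chain_id, sel$seq_num, sel$icode), , drop = FALSE]
  new_pocket(sel, reference_id = structure$id, cutoff = cutoff)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping `mobile_coords`
#' onto `target_coords`, via SVD of the cross-covariance of the centered
#' point sets with the usual reflection correction.
#'
#' @param mobile_coords,target_coords numeric n x 3 matrices, n >= 3, in
#'   one-to-one correspondence.
#' @return List with `rotation` (3 x 3), `translation` (length 3) such
#'   that `mobile %*% t(rotation) + translation` approximates the target,
#'   and the resulting `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(mobile_coords, target_coords) {
  M <- as.matrix(mobile_coords)
  T <- as.matrix(target_coords)
  if (!all(dim(M) == dim(T)) || ncol(M) != 3L)
    stop_input("coordinate sets must be equal-size n x 3 matrices")
  if (nrow(M) < 3L)
    stop_input("superposition needs at least 3 points")
  cm <- colMeans(M); ct <- colMeans(T)
  M0 <- sweep(M, 2, cm); T0 <- sweep(T, 2, ct)
  H <- crossprod(M0, T0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- M0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - T0)^2)))
  translation <- as.numeric(ct - cm %*% t(R))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# One-letter sequence and residue bookkeeping for one chain.
chain_sequence <- function(structure, chain) {
  rt <- residue_table(structure, hetero = FALSE)
  rt <- rt[rt$chain_id == chain, , drop = FALSE]
  list(seq = paste(three_to_one(rt$res_name), collapse = ""), residues = rt)
}

#' Transfer a pocket definition to a homologous structure
#'
#' Aligns each reference chain appearing in the pocket against the target
#' chains (global Needleman-Wunsch, BLOSUM62, affine gap open 10 /
#' extend 0.5, via Biostrings) and maps every pocket residue to its
#' aligned target residue. Pocket residues that fall in alignment gaps
#' are reported as unmapped and omitted from the result.
#'
#' @param reference structure the pocket was defined on.
#' @param pocket an `ssv_pocket` on `reference`.
#' @param target structure to transfer the pocket to.
#' @param min_identity minimum percent sequence identity (0-100) required
#'   of the chain alignment; default 20.
#' @return An `ssv_pocket` on `target`, with attribute `unmapped` (data
#'   frame of reference pocket residues that could not be mapped).
#' @export
map_pocket <- function(reference, pocket, target, min_identity = 20) {
  mapped <- list()
  unmapped <- list()
  target_chains <- unique(residue_table(target, hetero = FALSE)$chain_id)
  for (chain in unique(pocket$residues$chain_id)) {
    ref <- chain_sequence(reference, chain)
    if (!nrow(ref$residues))
      stop_lookup(paste0("pocket chain absent from reference: ", chain))
    # align against every target chain, keep the best-scoring one
    best <- NULL
    for (tc in target_chains) {
      tgt <- chain_sequence(target, tc)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(ref$seq), Biostrings::AAString(tgt$seq),
        substitutionMatrix = "BLOSUM62", gapOpening = 10,
        gapExtension = 0.5, type = "global")
      if (is.null(best) || Biostrings::score(aln) > best$score)
        best <- list(aln = aln, score = Biostrings::score(aln), tgt = tgt)
    }
    pid <- Biostrings::pid(best$aln)
    if (pid < min_identity)
      stop_input(sprintf(
        "alignment identity %.1f%% below floor %.1f%% for chain %s",
        pid, min_identity, chain))
    # position-to-position correspondence from the alignment
    ref_pos <- ref_target_map(best$aln)
    pr <- pocket$residues[pocket$residues$chain_id == chain, , drop = FALSE]
    ref_keys <- residue_key(ref$residues)
    for (i in seq_len(nrow(pr))) {
      ridx <- match(residue_key(pr[i, , drop = FALSE]), ref_keys)
      if (is.na(ridx))
        stop_lookup(sprintf("pocket residue %s%d%s not in reference chain",
                            pr$chain_id[i], pr$seq_num[i], pr$icode[i]))
      tidx <- ref_pos[ridx]
      if (is.na(tidx)) {
        unmapped[[length(unmapped) + 1L]] <- pr[i, , drop = FALSE]
      } else {
        tr <- best$tgt$residues[tidx, , drop = FALSE]
        mapped[[length(mapped) + 1L]] <-
          tr[, c("chain_id", "seq_num", "icode", "res_name")]
      }
    }
  }
  unmapped_df <- if (length(unmapped)) do.call(rbind, unmapped) else
    pocket$residues[0, ]
  if (!length(mapped))
    stop_lookup("no pocket residue could be mapped onto the target")
  out <- new_pocket(do.call(rbind, mapped), reference_id = target$id,
                    cutoff = pocket$cutoff)
  attr(out, "unmapped") <- unmapped_df
  out
}

# For a global pairwise alignment, the target residue index aligned to
# each reference residue index (NA where the reference sits in a gap).
ref_target_map <- function(aln) {
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  ref_i <- cumsum(pc != "-")
  tgt_i <- cumsum(sc != "-")
  keep <- pc != "-"
  out <- ifelse(sc[keep] != "-", tgt_i[keep], NA_integer_)
  as.integer(out)
}

#' Extract the pocket residues of a structure
#'
#' Residues are matched by identity key (chain, number, insertion code);
#' `res_name` in the pocket definition is informational so that mutated
#' copies of a structure can be extracted with the same definition.
#'
#' @param structure an `ssv_structure`.
#' @param pocket an `ssv_pocket`.
#' @return An `ssv_structure` containing exactly the pocket residues with
#'   all their heavy atoms, in pocket order.
#' @export
extract_pocket <- function(structure, pocket) {
  at <- structure$atoms
  akey <- residue_key(at)
  pkeys <- residue_key(pocket$residues)
  missing <- setdiff(pkeys, unique(akey))
  if (length(missing))
    stop_lookup(paste0("pocket residues absent from structure: ",
                       paste(missing, collapse = ", ")))
  rows <- unlist(lapply(pkeys, function(k) which(akey == k)),
                 use.names = FALSE)
  new_structure(at[rows, , drop = FALSE],
                id = paste0(structure$id, "_pocket"))
}

#' Pocket spanning every protein residue
#'
#' The whole-protein alternative to ligand-distance extraction.
#'
#' @param structure an `ssv_structure`.
#' @return An `ssv_pocket` listing all protein residues.
#' @export
whole_protein_pocket <- function(structure) {
  rt <- residue_table(structure, hetero = FALSE)
  new_pocket(rt[, c("chain_id", "seq_num", "icode", "res_name")],
             reference_id = structure$id, cutoff = NA_real_)
}

#' Write a pocket definition as TSV
#' @param pocket an `ssv_pocket`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pocket_tsv <- function(pocket, path) {
  write.table(pocket$residues, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a pocket definition from TSV
#' @param path TSV with columns `chain_id`, `seq_num`, `icode`, `res_name`.
#' @param reference_id,cutoff metadata to attach.
#' @return An `ssv_pocket`.
#' @export
read_pocket_tsv <- function(path, reference_id = "", cutoff = NA_real_) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(icode = "character"))
  df$icode[is.na(df$icode)] <- ""
  new_pocket(df, reference_id = reference_id, cutoff = cutoff)
}
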
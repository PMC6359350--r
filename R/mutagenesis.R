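# Mutation notation, saturation enumeration and the geometric mutant
# builder (a lightweight stand-in for homology modeling: externally
# modeled mutant PDBs remain first-class input to the scoring layer).

AA_ALPHABET <- sort(AA_ONE)

#' Parse point-mutation notation
#'
#' Accepts single- or multi-site specs in the usual `X123Y` notation,
#' multi-site joined with `/` (e.g. `"V174C/A404V/L441F"`). Wild and
#' mutant letters must differ at every site and positions must be unique
#' within a spec.
#'
#' @param text a mutation string.
#' @return An `ssv_mutation`: data frame with columns `wild_aa`,
#'   `position`, `mutant_aa`, one row per site.
#' @export
parse_mutation <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop_parse("mutation text must be a single non-empty string")
  tokens <- strsplit(text, "/", fixed = TRUE)[[1L]]
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop_parse(paste0("malformed mutation token: '", tokens[bad[1L]], "'"))
  sites <- data.frame(
    wild_aa = vapply(m, `[`, "", 2L),
    position = as.integer(vapply(m, `[`, "", 3L)),
    mutant_aa = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE)
  letters_used <- c(sites$wild_aa, sites$mutant_aa)
  if (!all(letters_used %in% AA_ONE))
    stop_parse(paste0("non-canonical amino acid letter in '", text, "'"))
  if (any(sites$wild_aa == sites$mutant_aa))
    stop_parse(paste0("identity substitution in '", text, "'"))
  if (anyDuplicated(sites$position))
    stop_parse(paste0("duplicate positions in '", text, "'"))
  structure(sites, class = c("ssv_mutation", "data.frame"))
}

#' Canonical string form of a mutation spec
#' @param spec an `ssv_mutation`.
#' @return The `X123Y[/X456Z...]` string.
#' @export
format_mutation <- function(spec) {
  paste(sprintf("%s%d%s", spec$wild_aa, spec$position, spec$mutant_aa),
        collapse = "/")
}

#' Enumerate in-silico saturation mutagenesis over pocket residues
#'
#' For every pocket residue, proposes all 19 substitutions to the other
#' canonical amino acids, ordered by position then target letter.
#'
#' @param pocket_residues data frame with columns `seq_num` and
#'   `res_name` (3-letter codes), e.g. the `residues` field of an
#'   `ssv_pocket`.
#' @return List of single-site `ssv_mutation` specs, `19 * nrow` long.
#' @export
enumerate_saturation <- function(pocket_residues) {
  if (!nrow(pocket_residues)) return(list())
  if (!all(pocket_residues$res_name %in% AA_THREE))
    stop_typing(paste0("non-canonical pocket residue: ",
                       paste(setdiff(pocket_residues$res_name, AA_THREE),
                             collapse = ", ")))
  ord <- order(pocket_residues$seq_num)
  specs <- list()
  for (i in ord) {
    wild <- three_to_one(pocket_residues$res_name[i])
    for (target in setdiff(AA_ALPHABET, wild)) {
      specs[[length(specs) + 1L]] <- parse_mutation(
        sprintf("%s%d%s", wild, pocket_residues$seq_num[i], target))
    }
  }
  specs
}

#' Apply a point mutation to a structure
#'
#' `truncate` mode renames the residue and keeps only atoms the mutant
#' type also has (backbone N/CA/C/O always kept), never adding atoms.
#' `graft` mode additionally places the mutant type's missing side-chain
#' atoms from an idealized internal-coordinate template built off the
#' existing backbone (standard bond lengths/angles, fixed rotamer, no
#' clash resolution). Residues not named in the spec are untouched.
#'
#' @param structure an `ssv_structure`.
#' @param spec an `ssv_mutation` or a mutation string.
#' @param mode `"truncate"` or `"graft"`.
#' @param chain restrict position lookup to this chain; by default the
#'   position must be unambiguous across chains.
#' @return The mutated `ssv_structure`; its id gains a `_<spec>` suffix.
#' @export
apply_mutation <- function(structure, spec, mode = c("truncate", "graft"),
                           chain = NULL) {
  mode <- match.arg(mode)
  if (is.character(spec)) spec <- parse_mutation(spec)
  at <- structure$atoms
  for (s in seq_len(nrow(spec))) {
    pos <- spec$position[s]
    sel <- !at$is_hetero & at$seq_num == pos
    if (!is.null(chain)) sel <- sel & at$chain_id == chain
    if (!any(sel))
      stop_lookup(sprintf("position %d not found in structure", pos))
    chains_hit <- unique(at$chain_id[sel])
    if (length(chains_hit) > 1L)
      stop_lookup(sprintf(
        "position %d is ambiguous across chains (%s); pass `chain`",
        pos, paste(chains_hit, collapse = ", ")))
    found <- unique(at$res_name[sel])
    if (three_to_one(found[1L]) != spec$wild_aa[s])
      stop_input(sprintf(
        "wild-type mismatch at position %d: spec says %s, structure has %s",
        pos, spec$wild_aa[s], found[1L]))
    new_res <- one_to_three(spec$mutant_aa[s])
    keep_names <- canonical_atoms(new_res)
    drop <- sel & !(at$name %in% keep_names)
    renamed <- at[sel & !drop, , drop = FALSE]
    renamed$res_name <- new_res
    before <- at[seq_len(nrow(at)) < which(sel)[1L] & !sel, , drop = FALSE]
    after <- at[seq_len(nrow(at)) > which(sel)[1L] & !sel, , drop = FALSE]
    if (mode == "graft") {
      grafted <- graft_sidechain(renamed, new_res)
      renamed <- rbind(renamed, grafted)
    }
    at <- rbind(before, renamed, after)
  }
  new_structure(at, id = paste0(structure$id, "_", format_mutation(spec)))
}
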
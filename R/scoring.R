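# Template database, nearest-template selection and the ddSSV score.
#
# A template database holds the signatures of curated reference enzymes
# (e.g. glucose-tolerant beta-glucosidases). The signature variation
# dSSV of a protein is the Euclidean distance to its nearest template;
# ddSSV = dSSV(mutant) - dSSV(wild). Negative values mean the mutation
# moved the pocket signature closer to the template set (predicted
# beneficial), positive values further away (predicted not beneficial).

#' Construct a template database
#'
#' @param signatures named list of `ssv_signature` vectors (names are the
#'   template ids) or a numeric matrix with one row per template and
#'   rownames as ids.
#' @param grid the common cutoff grid.
#' @return An object of class `ssv_template_db` with fields `ids`,
#'   `signatures` (matrix, one row per template) and `grid`.
#' @export
new_template_db <- function(signatures, grid = cutoff_grid()) {
  if (is.list(signatures)) {
    if (!length(signatures)) stop_config("template database is empty")
    ids <- names(signatures) %||%
      vapply(signatures, function(s) attr(s, "id"), "")
    for (s in signatures) {
      g <- attr(s, "grid")
      if (!is.null(g) && !grids_equal(g, grid))
        stop_shape("template signatures computed on different grids")
    }
    mat <- do.call(rbind, lapply(signatures, as.numeric))
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(signatures)
    ids <- rownames(mat)
  }
  if (is.null(ids) || any(!nzchar(ids)))
    stop_config("every template needs a non-empty id")
  if (anyDuplicated(ids))
    stop_config(paste0("duplicate template ids: ",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!nrow(mat)) stop_config("template database is empty")
  if (ncol(mat) != N_CLASS_PAIRS * length(grid$points))
    stop_shape(sprintf("template signatures have %d components, grid implies %d",
                       ncol(mat), N_CLASS_PAIRS * length(grid$points)))
  structure(list(ids = ids, signatures = mat, grid = grid),
            class = "ssv_template_db")
}

#' @export
print.ssv_template_db <- function(x, ...) {
  cat(sprintf("<ssv_template_db: %d templates x %d signature components>\n",
              nrow(x$signatures), ncol(x$signatures)))
  invisible(x)
}

#' Load a template database from PDB files or a signature TSV
#'
#' @param paths character vector of template PDB paths, or a single path
#'   to a signature TSV written by [write_signature_tsv()].
#' @param pocket optional `ssv_pocket`; when supplied each template PDB is
#'   reduced to the pocket residues (matched by key) before its signature
#'   is computed. Ignored for TSV input.
#' @param grid the cutoff grid.
#' @param table pharmacophore typing table for PDB input.
#' @return An `ssv_template_db`.
#' @export
load_template_db <- function(paths, pocket = NULL, grid = cutoff_grid(),
                             table = default_pharmacophore_table()) {
  if (!length(paths)) stop_config("no template inputs supplied")
  if (length(paths) == 1L && grepl("\\.(tsv|txt)$", paths, ignore.case = TRUE)) {
    sigs <- read_signature_tsv(paths, grid = grid)
    return(new_template_db(sigs, grid = grid))
  }
  sigs <- lapply(paths, function(p) {
    s <- read_pdb(p, keep_ligands = FALSE)
    if (!is.null(pocket)) s <- extract_pocket(s, pocket)
    sig <- structure_signature(s, grid = grid, table = table)
    attr(sig, "id") <- tools::file_path_sans_ext(basename(p))
    sig
  })
  names(sigs) <- vapply(sigs, function(s) attr(s, "id"), "")
  new_template_db(sigs, grid = grid)
}

#' Nearest template by Euclidean signature distance
#'
#' Ties are broken by lexicographically smallest template id so results
#' are deterministic across platforms.
#'
#' @param sig an `ssv_signature` (or numeric vector of matching length).
#' @param db an `ssv_template_db`.
#' @return List with `template_id` and `distance`.
#' @export
nearest_template <- function(sig, db) {
  stopifnot(inherits(db, "ssv_template_db"))
  if (length(sig) != ncol(db$signatures))
    stop_shape(sprintf("query signature has %d components, database %d",
                       length(sig), ncol(db$signatures)))
  dists <- sqrt(rowSums(sweep(db$signatures, 2, as.numeric(sig))^2))
  dmin <- min(dists)
  cand <- db$ids[dists <= dmin + 0e0]
  winner <- sort(cand)[1L]
  list(template_id = winner, distance = unname(dists[match(winner, db$ids)]))
}

#' Sign-based label from a ddSSV score
#'
#' @param ddssv the ddSSV score (dSSV mutant minus dSSV wild).
#' @param neutral_tol non-negative half-width of the neutral band around
#'   zero (default 0: only an exact 0 is neutral).
#' @return `"beneficial"`, `"not_beneficial"` or `"neutral"`.
#' @export
classify <- function(ddssv, neutral_tol = 0) {
  if (neutral_tol < 0) stop_config("neutral_tol must be >= 0")
  ifelse(ddssv < -neutral_tol, "beneficial",
         ifelse(ddssv > neutral_tol, "not_beneficial", "neutral"))
}

#' Score a mutation by signature variation against a template database
#'
#' Wild and mutant templates are selected independently (they may
#' differ); dSSV_wt and dSSV_mt are the respective minimal Euclidean
#' distances; ddSSV = dSSV_mt - dSSV_wt; the label follows the sign rule
#' of [classify()].
#'
#' @param wild_sig,mutant_sig signatures of the wild and mutant pockets.
#' @param db an `ssv_template_db`.
#' @param neutral_tol see [classify()].
#' @param wild_id,mutant_id identifiers for the report (defaults taken
#'   from the signatures).
#' @return An `ssv_result` list: `wild_id`, `mutant_id`,
#'   `wild_template_id`, `mutant_template_id`, `dssv_wt`, `dssv_mt`,
#'   `ddssv`, `label`.
#' @export
score_mutation <- function(wild_sig, mutant_sig, db, neutral_tol = 0,
                           wild_id = NULL, mutant_id = NULL) {
  wt <- nearest_template(wild_sig, db)
  mt <- nearest_template(mutant_sig, db)
  ddssv <- mt$distance - wt$distance
  structure(list(
    wild_id = wild_id %||% (attr(wild_sig, "id") %||% "wild"),
    mutant_id = mutant_id %||% (attr(mutant_sig, "id") %||% "mutant"),
    wild_template_id = wt$template_id,
    mutant_template_id = mt$template_id,
    dssv_wt = wt$distance,
    dssv_mt = mt$distance,
    ddssv = ddssv,
    label = classify(ddssv, neutral_tol)
  ), class = "ssv_result")
}

#' @export
print.ssv_result <- function(x, ...) {
  cat(sprintf(
    "<ssv_result %s -> %s: dSSV_wt %.2f (%s), dSSV_mt %.2f (%s), ddSSV %.2f [%s]>\n",
    x$wild_id, x$mutant_id, x$dssv_wt, x$wild_template_id,
    x$dssv_mt, x$mutant_template_id, x$ddssv, x$label))
  invisible(x)
}

result_row <- function(x, mutation = "") {
  data.frame(wild_id = x$wild_id, mutant_id = x$mutant_id,
             mutation = mutation,
             wild_template = x$wild_template_id,
             mutant_template = x$mutant_template_id,
             dssv_wt = x$dssv_wt, dssv_mt = x$dssv_mt,
             ddssv = x$ddssv, label = x$label,
             stringsAsFactors = FALSE)
}
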
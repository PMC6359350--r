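# Post-score candidate triage.
#
# After the saturation screen, candidates with negative ddSSV are thinned
# by an ordered chain of pure predicates: an in-repo conservation filter
# plus readers for externally produced tolerated-substitution (SIFT-style)
# and predicted-stability (mCSM-style) tables. Each stage's removals are
# recorded in an audit trail.

#' Per-position conservation profile of a multiple alignment
#'
#' For every ungapped position of the target row, the fraction of the
#' other rows whose residue in that column matches the target residue.
#' Gapped rows in a column are excluded from both numerator and
#' denominator.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (or a `Biostrings::AAStringSet`).
#' @param target_row name of the row whose positions index the profile.
#' @param exclude_target drop the target row itself from the fraction
#'   (default `TRUE`, i.e. conservation among the template sequences).
#' @return Named numeric vector in `[0, 1]`; names are target positions
#'   (ungapped numbering).
#' @export
conservation_profile <- function(alignment, target_row,
                                 exclude_target = TRUE) {
  if (inherits(alignment, "AAStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (length(unique(nchar(alignment))) != 1L)
    stop_format("alignment rows have unequal lengths")
  if (!target_row %in% names(alignment))
    stop_lookup(paste0("target row not in alignment: ", target_row))
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  tgt <- mat[target_row, ]
  others <- mat[if (exclude_target) rownames(mat) != target_row else
    rep(TRUE, nrow(mat)), , drop = FALSE]
  cols <- which(tgt != "-")
  prof <- vapply(cols, function(j) {
    col <- others[, j]
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    mean(col == tgt[j])
  }, numeric(1))
  setNames(prof, seq_along(cols))
}

#' Remove candidates at conserved positions
#'
#' @param candidates list of `ssv_mutation` specs.
#' @param profile conservation profile from [conservation_profile()],
#'   named by position.
#' @param threshold conservation fraction in `(0, 1]` at or above which a
#'   position is protected (default 1: only fully conserved positions).
#' @return List with `survivors` and `removed` (an exact partition of
#'   the input).
#' @export
filter_conserved <- function(candidates, profile, threshold = 1.0) {
  if (threshold <= 0 || threshold > 1)
    stop_config("conservation threshold must be in (0, 1]")
  keep <- vapply(candidates, function(spec) {
    pos <- as.character(spec$position)
    miss <- setdiff(pos, names(profile))
    if (length(miss))
      stop_lookup(paste0("candidate position absent from profile: ",
                         paste(miss, collapse = ", ")))
    all(profile[pos] < threshold - 1e-12)
  }, logical(1))
  list(survivors = candidates[keep], removed = candidates[!keep])
}

#' Read a tolerated-substitution (SIFT-style) table
#'
#' Two TSV layouts are accepted: `position`, `aa`, `tolerated`
#' (logical/yes/no), or `position`, `aa`, `score` with substitutions
#' scoring below `cutoff` deemed not tolerated.
#'
#' @param path TSV path.
#' @param cutoff score cutoff for the score layout (default 0.05).
#' @return List keyed by position (as character) of tolerated amino-acid
#'   sets. Positions absent from the table are unconstrained (callers
#'   should treat missing keys as "allow all"); an empty file yields an
#'   empty map with a warning.
#' @export
read_sift_table <- function(path, cutoff = 0.05) {
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format(paste0(
                   "cannot parse substitution table ", path, ": ",
                   conditionMessage(e))))
  if (!nrow(df)) {
    warning("empty substitution table: ", path)
    return(list())
  }
  if (!all(c("position", "aa") %in% names(df)))
    stop_format("substitution table needs 'position' and 'aa' columns")
  if ("tolerated" %in% names(df)) {
    tol <- tolower(as.character(df$tolerated)) %in%
      c("true", "yes", "1", "tolerated", "t")
  } else if ("score" %in% names(df)) {
    score <- suppressWarnings(as.numeric(df$score))
    bad <- which(is.na(score))
    if (length(bad))
      stop_format(sprintf("unparsable score at line %d of %s",
                          bad[1L] + 1L, path))
    tol <- score >= cutoff
  } else {
    stop_format("substitution table needs a 'tolerated' or 'score' column")
  }
  allowed <- lapply(split(df$aa[tol], as.character(df$position[tol])),
                    unique)
  # positions listed but with nothing tolerated must still constrain
  for (p in setdiff(unique(as.character(df$position)), names(allowed)))
    allowed[[p]] <- character(0)
  allowed
}

#' Read an mCSM-style predicted stability-change table
#'
#' @param path TSV with columns `mutation` (single-site `X123Y` strings)
#'   and `ddg` (predicted stability change, kcal/mol).
#' @return Named numeric vector of ddG keyed by canonical mutation string.
#' @export
read_mcsm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mutation", "ddg") %in% names(df)))
    stop_format("stability table needs 'mutation' and 'ddg' columns")
  keys <- vapply(df$mutation, function(m) format_mutation(parse_mutation(m)),
                 "")
  if (anyDuplicated(keys))
    stop_format(paste0("duplicate mutation keys: ",
                       paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  ddg <- suppressWarnings(as.numeric(df$ddg))
  if (anyNA(ddg)) stop_format("non-numeric ddg values in stability table")
  setNames(ddg, keys)
}

#' Filter stage: conserved positions
#' @param profile,threshold see [filter_conserved()].
#' @return A predicate stage for [apply_filter_chain()].
#' @export
stage_conservation <- function(profile, threshold = 1.0) {
  force(profile); force(threshold)
  function(spec) {
    length(filter_conserved(list(spec), profile, threshold)$survivors) == 1L
  }
}

#' Filter stage: substitutions not tolerated in the family
#'
#' A candidate survives if every site's mutant amino acid is in the
#' tolerated set for its position; positions missing from the map are
#' unconstrained.
#' @param allowed map from [read_sift_table()].
#' @return A predicate stage for [apply_filter_chain()].
#' @export
stage_sift <- function(allowed) {
  force(allowed)
  function(spec) {
    all(vapply(seq_len(nrow(spec)), function(i) {
      p <- as.character(spec$position[i])
      if (!p %in% names(allowed)) return(TRUE)
      spec$mutant_aa[i] %in% allowed[[p]]
    }, logical(1)))
  }
}

#' Filter stage: highly destabilizing mutations
#'
#' Removes candidates whose predicted stability change is at or below the
#' cutoff. Candidates missing from the table are unconstrained.
#' @param ddg_map named ddG vector from [read_mcsm_table()].
#' @param cutoff ddG (kcal/mol) at or below which a mutation counts as
#'   highly destabilizing; default -2.0.
#' @return A predicate stage for [apply_filter_chain()].
#' @export
stage_mcsm <- function(ddg_map, cutoff = -2.0) {
  force(ddg_map); force(cutoff)
  function(spec) {
    key <- format_mutation(spec)
    if (!key %in% names(ddg_map)) return(TRUE)
    ddg_map[[key]] > cutoff
  }
}

#' Apply an ordered chain of candidate filters
#'
#' @param candidates list of `ssv_mutation` specs.
#' @param stages named list of predicate functions; each takes one spec
#'   and returns `TRUE` to keep it. Applied in order.
#' @return List with `survivors` and `audit`, the latter an
#'   `ssv_filter_audit` data frame (`stage`, `removed`, `remaining`) with
#'   attribute `initial`.
#' @export
apply_filter_chain <- function(candidates, stages = list()) {
  initial <- length(candidates)
  if (length(stages) && is.null(names(stages)))
    names(stages) <- paste0("stage", seq_along(stages))
  remaining <- candidates
  rows <- list()
  for (nm in names(stages)) {
    keep <- vapply(remaining, stages[[nm]], logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      stage = nm, removed = sum(!keep), remaining = sum(keep),
      stringsAsFactors = FALSE)
    remaining <- remaining[keep]
  }
  audit <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), removed = integer(0),
               remaining = integer(0))
  attr(audit, "initial") <- initial
  class(audit) <- c("ssv_filter_audit", "data.frame")
  list(survivors = remaining, audit = audit)
}

#' @export
print.ssv_filter_audit <- function(x, ...) {
  cat(sprintf("<filter audit: %d candidates in>\n", attr(x, "initial")))
  print.data.frame(x)
  invisible(x)
}
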
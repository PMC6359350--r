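# Benchmark evaluation of sign-based predictions.
#
# A labeled benchmark pairs observed ddSSV scores with expected binary
# labels; the sign rule is applied per record and the usual confusion
# metric panel is computed. The package ships a 27-mutation
# beta-glucosidase benchmark as a TSV fixture (see
# `system.file("extdata", "benchmark_bglucosidase.tsv", package = "ssv")`).

BENCHMARK_LABELS <- c("beneficial", "not_beneficial")

#' Read a labeled mutation benchmark
#'
#' @param path TSV with columns `mutation`, `expected_label`
#'   (`beneficial` / `not_beneficial`), `ddssv`, and optionally `source`.
#' @return Data frame of validated records (mutation strings parsed and
#'   canonicalized).
#' @export
read_benchmark <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mutation", "expected_label", "ddssv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format(paste0("benchmark TSV lacks columns: ",
                       paste(miss, collapse = ", ")))
  bad <- setdiff(unique(df$expected_label), BENCHMARK_LABELS)
  if (length(bad))
    stop_parse(paste0("unknown expected_label values: ",
                      paste(bad, collapse = ", ")))
  df$ddssv <- as.numeric(df$ddssv)
  if (anyNA(df$ddssv)) stop_format("non-numeric ddssv values in benchmark")
  df$mutation <- vapply(df$mutation,
                        function(m) format_mutation(parse_mutation(m)), "")
  if (!"source" %in% names(df)) df$source <- ""
  df[, c("mutation", "expected_label", "ddssv", "source")]
}

#' Evaluate sign-rule predictions against a labeled benchmark
#'
#' Each record is predicted with the sign rule ([classify()]); a record
#' is a hit when the prediction equals its expected label. Neutral
#' predictions (|ddssv| <= `neutral_tol`) never match a binary
#' expectation and are flagged. Confusion counts treat `positive_class`
#' as the positive; metrics with zero denominators are `NA`, never 0.
#'
#' @param records data frame from [read_benchmark()].
#' @param positive_class `"beneficial"` (default) or `"not_beneficial"`.
#' @param neutral_tol see [classify()].
#' @return An `ssv_metrics` list: `counts` (tp/fp/tn/fn), `metrics`
#'   (precision, accuracy, specificity, sensitivity, f_measure),
#'   `n_correct`, `n`, and `records` with `predicted` and `hit` columns.
#' @export
evaluate_benchmark <- function(records, positive_class = "beneficial",
                               neutral_tol = 0) {
  if (!nrow(records)) stop_config("benchmark has no records")
  if (!positive_class %in% BENCHMARK_LABELS)
    stop_config("positive_class must be 'beneficial' or 'not_beneficial'")
  records$predicted <- classify(records$ddssv, neutral_tol)
  records$hit <- records$predicted == records$expected_label
  pos <- positive_class
  neg <- setdiff(BENCHMARK_LABELS, pos)
  tp <- sum(records$expected_label == pos & records$predicted == pos)
  fn <- sum(records$expected_label == pos & records$predicted != pos)
  tn <- sum(records$expected_label == neg & records$predicted == neg)
  fp <- sum(records$expected_label == neg & records$predicted == pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  sensitivity <- ratio(tp, tp + fn)
  f_measure <- if (is.na(precision) || is.na(sensitivity) ||
                   precision + sensitivity == 0) NA_real_ else
    2 * precision * sensitivity / (precision + sensitivity)
  structure(list(
    positive_class = pos,
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    metrics = c(precision = precision,
                accuracy = ratio(tp + tn, nrow(records)),
                specificity = ratio(tn, tn + fp),
                sensitivity = sensitivity,
                f_measure = f_measure),
    n_correct = sum(records$hit),
    n = nrow(records),
    records = records
  ), class = "ssv_metrics")
}

#' @export
print.ssv_metrics <- function(x, ...) {
  cat(sprintf("<ssv_metrics (positive = %s): %d/%d correct>\n",
              x$positive_class, x$n_correct, x$n))
  print(round(x$metrics, 3))
  invisible(x)
}
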
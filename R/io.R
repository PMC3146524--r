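#' Write ranked predictions as a five-column TSV
#'
#' One row per (query, order): `query`, `order`, `fluid`, `name`, `score`,
#' rows grouped by query with ascending order, scores rendered with six
#' decimals. An empty prediction set writes a header-only file.
#'
#' @param preds a `fluidvote_predictions` data frame from
#'   [predict.fluidvote()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(preds, path) {
  stopifnot(is.data.frame(preds))
  lines <- c("query\torder\tfluid\tname\tscore",
             sprintf("%s\t%d\t%d\t%s\t%.6f", preds$query, preds$order,
                     preds$fluid, preds$name, preds$score))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' All fields of a [jackknife_evaluate()] report are written at full
#' precision, so [read_report()] round-trips losslessly. An empty
#' evaluation (`n_evaluated = 0`) is invalid and refuses to serialize.
#'
#' @param report a `fluidvote_eval` object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fluidvote_eval"))
  if (is.null(report$n_evaluated) || report$n_evaluated < 1L)
    stop("refusing to write an empty evaluation report (n_evaluated = 0)")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path path written by [write_report()].
#' @return A `fluidvote_eval` object.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_evaluated", "n_unpredictable", "k"))
    raw[[f]] <- as.integer(raw[[f]])
  # JSON arrays carry no names; restore the conventional labels
  Fn <- length(raw$order_accuracy)
  names(raw$order_accuracy) <- paste0("ACC", seq_len(Fn))
  names(raw$coverage_curve) <- paste0("L", seq_len(Fn))
  structure(raw, class = "fluidvote_eval")
}
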
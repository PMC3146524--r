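#' Construct a protein body-fluid annotation table
#'
#' Maps each protein to the non-empty set of body fluids it is known to be
#' secreted into, validated against a vocabulary. Duplicate protein entries
#' are merged by set union.
#'
#' @param labels named list: protein id -> vector of fluid type numbers (or
#'   names resolvable through `vocab`).
#' @param vocab a [fluid_vocabulary()]; defaults to [body_fluids()].
#' @return An object of class `fluid_annotations`: a named list of sorted
#'   integer fluid-type vectors, with the vocabulary attached as attribute
#'   `vocab`.
#' @export
#' @examples
#' ann <- fluid_annotations(list(O75594 = c(6, 7, 11), P05231 = 6))
#' label_count(ann)
fluid_annotations <- function(labels, vocab = body_fluids()) {
  stopifnot(inherits(vocab, "fluid_vocabulary"))
  if (length(labels) == 0L)
    return(structure(stats::setNames(list(), character()),
                     vocab = vocab, class = "fluid_annotations"))
  ids <- names(labels)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'labels' must be a named list keyed by protein id")
  sets <- lapply(seq_along(labels), function(i) {
    fl <- match_fluid_tokens(as.character(labels[[i]]), vocab,
                             context = paste0(" for protein '", ids[i], "'"))
    sort(unique(fl))
  })
  # union-merge duplicate protein rows
  merged <- lapply(split(sets, ids), function(s) sort(unique(unlist(s))))
  out <- merged[sort(unique(ids))]
  empty <- lengths(out) == 0L
  if (any(empty))
    stop("empty fluid set for protein '", names(out)[empty][1L], "'")
  structure(out, vocab = vocab, class = "fluid_annotations")
}

#' @export
print.fluid_annotations <- function(x, ...) {
  cat("Fluid annotations: ", length(x), " proteins, ",
      sum(lengths(x)), " protein-fluid assignments, F = ",
      nrow(attr(x, "vocab")), " fluids\n", sep = "")
  invisible(x)
}

#' Number of annotated fluids per protein
#'
#' @param ann a [fluid_annotations()].
#' @param proteins optional id subset (defaults to all annotated proteins).
#' @return Named integer vector of label counts `m(p)`.
#' @export
label_count <- function(ann, proteins = names(ann)) {
  stopifnot(inherits(ann, "fluid_annotations"))
  missing <- setdiff(proteins, names(ann))
  if (length(missing))
    stop("protein(s) not annotated: ", paste(utils::head(missing, 3L),
                                             collapse = ", "))
  lengths(ann[proteins])
}

#' Read a protein -> body-fluid annotation table
#'
#' Each row holds a protein id followed by its fluids, separated from the id
#' by whitespace; the fluid list itself is comma- or semicolon-separated and
#' may mix type numbers and names (e.g. `O75594  6, 7, 11` or
#' `X  Plasma/Serum`). An optional header is detected by an unresolvable
#' fluid field. Duplicate protein rows are merged by union.
#'
#' @param path path to the annotation TSV.
#' @param vocab a [fluid_vocabulary()]; defaults to [body_fluids()].
#' @return A [fluid_annotations()].
#' @export
read_annotations <- function(path, vocab = body_fluids()) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  m <- regexpr("[\t ]", lines)
  if (any(m < 0L))
    stop("malformed annotation row at line ", line_no[m < 0L][1L],
         ": expected a protein id followed by fluids")
  ids <- substr(lines, 1L, m - 1L)
  rest <- trimws(substring(lines, m + 1L))
  tokens <- strsplit(rest, "[,;]")
  # header line: first row whose fluid field resolves to nothing
  first_ok <- tryCatch({
    match_fluid_tokens(tokens[[1L]], vocab)
    TRUE
  }, error = function(e) FALSE)
  if (!first_ok && length(lines) > 1L) {
    ids <- ids[-1L]; tokens <- tokens[-1L]; line_no <- line_no[-1L]
  }
  sets <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (!length(tokens[[i]]) || all(!nzchar(trimws(tokens[[i]]))))
      stop("empty fluid set at line ", line_no[i])
    sets[[i]] <- match_fluid_tokens(tokens[[i]], vocab,
                                    context = paste0(" at line ", line_no[i]))
  }
  fluid_annotations(stats::setNames(sets, ids), vocab)
}

#' Write an annotation table as a two-column TSV
#'
#' @param ann a [fluid_annotations()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "fluid_annotations"))
  lines <- c("protein\tfluids",
             sprintf("%s\t%s", names(ann),
                     vapply(ann, function(s) paste(s, collapse = ","), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Binary fluid-indicator matrix
#'
#' The n-by-F 0/1 matrix with entry `(i, j) = 1` exactly when protein `i` is
#' annotated to the `j`-th fluid of the vocabulary; row sums equal the label
#' counts `m(p)`. This is the annotation side of the weighted-vote score
#' product.
#'
#' @param ann a [fluid_annotations()].
#' @param proteins ordered protein ids to include (all must be annotated).
#' @param vocab vocabulary (defaults to the one attached to `ann`).
#' @return Integer matrix with `proteins` as rownames and fluid type numbers
#'   as colnames.
#' @export
annotation_matrix <- function(ann, proteins = names(ann),
                              vocab = attr(ann, "vocab")) {
  counts <- label_count(ann, proteins)  # validates coverage
  A <- matrix(0L, nrow = length(proteins), ncol = nrow(vocab),
              dimnames = list(proteins, vocab$type))
  if (length(proteins)) {
    j <- match(unlist(ann[proteins], use.names = FALSE), vocab$type)
    A[cbind(rep(seq_along(proteins), counts), j)] <- 1L
  }
  A
}

#' Average number of fluids per protein
#'
#' The mean label count over a set of proteins. Accepts either a
#' [fluid_annotations()] table (counting each protein's fluid set) or a
#' per-fluid census data frame such as [body_fluid_census()] (summing the
#' per-fluid protein counts and dividing by the number of distinct
#' proteins).
#'
#' @param x a `fluid_annotations` object or a census data frame with an
#'   `n_proteins` column and attribute.
#' @param proteins protein subset for the annotation form.
#' @return The average label count (>= 1).
#' @export
#' @examples
#' round(average_label_count(body_fluid_census()), 2)  # 3.23
average_label_count <- function(x, proteins = NULL) {
  if (inherits(x, "fluid_annotations")) {
    if (is.null(proteins)) proteins <- names(x)
    if (length(proteins) == 0L)
      stop("cannot average over an empty protein list")
    return(sum(label_count(x, proteins)) / length(proteins))
  }
  if (is.data.frame(x) && "n_proteins" %in% names(x)) {
    n <- attr(x, "n_proteins")
    if (is.null(n) || n <= 0L)
      stop("census must carry a positive 'n_proteins' attribute")
    return(sum(x$n_proteins) / n)
  }
  stop("'x' must be a fluid_annotations object or a census data frame")
}
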
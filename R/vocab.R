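#' Build a body-fluid vocabulary
#'
#' A vocabulary is the ordered set of fluid labels the predictor can assign:
#' a table of `(type, name)` pairs with unique, strictly increasing positive
#' type numbers and unique names. All scoring and evaluation is indexed by
#' position in this table; `F = nrow(vocab)` is the number of candidate
#' fluids.
#'
#' @param type integer vector of fluid type numbers (unique, positive,
#'   ascending).
#' @param name character vector of fluid names (unique, same length).
#' @return A data frame of class `fluid_vocabulary` with columns `type` and
#'   `name`.
#' @seealso [body_fluids()] for the default 11-fluid human vocabulary.
#' @export
#' @examples
#' fluid_vocabulary(1:3, c("CSF", "Plasma", "Urine"))
fluid_vocabulary <- function(type, name) {
  type <- as.integer(type)
  name <- trimws(as.character(name))
  if (length(type) == 0L)
    stop("vocabulary must contain at least one fluid")
  if (length(type) != length(name))
    stop("'type' and 'name' must have the same length")
  if (anyNA(type) || any(type <= 0L))
    stop("fluid type numbers must be positive integers")
  if (anyDuplicated(type))
    stop("duplicate fluid type number: ", type[duplicated(type)][1L])
  if (anyDuplicated(name))
    stop("duplicate fluid name: ", name[duplicated(name)][1L])
  if (is.unsorted(type, strictly = TRUE))
    stop("fluid type numbers must be sorted in ascending order")
  out <- data.frame(type = type, name = name, stringsAsFactors = FALSE)
  class(out) <- c("fluid_vocabulary", "data.frame")
  out
}

#' The canonical 11 human body fluids
#'
#' The default label vocabulary: amniotic fluid (1), bronchoalveolar lavage
#' fluid (2), cerebrospinal fluid (3), milk (4), nipple aspiration fluid (5),
#' plasma/serum (6), saliva (7), seminal fluid (8), synovial fluid (9),
#' tear (10) and urine (11).
#'
#' @return A `fluid_vocabulary` with 11 rows.
#' @export
#' @examples
#' body_fluids()
body_fluids <- function() {
  census <- body_fluid_census()
  fluid_vocabulary(census$type, census$name)
}

#' Census of the reference training compendium
#'
#' Per-fluid protein counts of the 529-protein human secreted-protein
#' compendium used to calibrate the method's evaluation constants: 1708
#' protein-fluid annotations across the 11 fluids (most proteins occur in
#' more than one fluid). The compendium size is attached as attribute
#' `n_proteins`; [average_label_count()] on this census gives the average
#' number of fluids per protein.
#'
#' @return A data frame with columns `type`, `name`, `n_proteins` and
#'   attribute `n_proteins` (the number of distinct proteins, 529).
#' @export
#' @examples
#' census <- body_fluid_census()
#' sum(census$n_proteins)        # total annotations
#' attr(census, "n_proteins")    # distinct proteins
body_fluid_census <- function() {
  path <- system.file("extdata", "body_fluids.tsv", package = "fluidvote",
                      mustWork = TRUE)
  census <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(census, "n_proteins") <- 529L
  census
}

#' Read a fluid vocabulary from a two-column TSV
#'
#' The file holds one fluid per row: type number, then name, tab-separated,
#' with an optional header (detected by a non-numeric first field). With
#' `path = NULL` the default human vocabulary [body_fluids()] is returned.
#'
#' @param path path to a TSV file, or `NULL` for the built-in default.
#' @return A [fluid_vocabulary()].
#' @export
read_fluid_vocab <- function(path = NULL) {
  if (is.null(path)) return(body_fluids())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty vocabulary file: ", path)
  fields <- strsplit(lines, "\t")
  if (suppressWarnings(is.na(as.numeric(trimws(fields[[1L]][1L]))))) {
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("vocabulary file has a header but no rows")
  }
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("malformed vocabulary row at line ", bad[1L], ": expected 2 columns")
  type <- suppressWarnings(as.integer(trimws(vapply(fields, `[`, "", 1L))))
  if (anyNA(type))
    stop("non-numeric fluid type number at line ", which(is.na(type))[1L])
  ord <- order(type)
  fluid_vocabulary(type[ord], vapply(fields, `[`, "", 2L)[ord])
}

#' @export
print.fluid_vocabulary <- function(x, ...) {
  cat("Body-fluid vocabulary (", nrow(x), " fluids)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Map fluid tokens (type numbers or names, possibly mixed) to type numbers.
# Names match case-insensitively after whitespace trimming.
match_fluid_tokens <- function(tokens, vocab, context = "") {
  tokens <- trimws(tokens)
  out <- integer(length(tokens))
  nums <- suppressWarnings(as.integer(tokens))
  is_num <- !is.na(nums) & grepl("^[0-9]+$", tokens)
  out[is_num] <- nums[is_num]
  idx <- match(tolower(tokens[!is_num]), tolower(vocab$name))
  out[!is_num] <- vocab$type[idx]
  bad <- is.na(out) | !(out %in% vocab$type)
  if (any(bad))
    stop("unknown fluid token '", tokens[bad][1L], "'", context)
  out
}
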
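#' Construct a weighted protein-protein interaction network
#'
#' An undirected simple graph weighted by interaction confidence in `(0, 1]`
#' (the STRING combined-score convention on the unit scale). Self-loops are
#' dropped with a warning — a protein carries no self-interaction, so its own
#' annotation can never vote for itself — and duplicate or antiparallel edges
#' are merged keeping the maximum confidence, with a warning. A protein pair
#' without a stored edge has implicit confidence 0.
#'
#' @param protein_a,protein_b character vectors of interacting protein ids.
#' @param confidence numeric vector of confidences in `(0, 1]`.
#' @param nodes optional character vector of additional isolated nodes to
#'   retain (e.g. the endpoints of dropped self-loops).
#' @return An object of class `ppi_network`: a list with `nodes` (sorted
#'   character vector) and `edges` (data frame `a`, `b`, `confidence` with
#'   `a < b`).
#' @export
#' @examples
#' net <- ppi_network(c("P1", "P1"), c("P2", "P3"), c(0.9, 0.4))
#' net$edges
ppi_network <- function(protein_a = character(), protein_b = character(),
                        confidence = numeric(), nodes = character()) {
  protein_a <- as.character(protein_a)
  protein_b <- as.character(protein_b)
  confidence <- as.numeric(confidence)
  if (length(protein_a) != length(protein_b) ||
      length(protein_a) != length(confidence))
    stop("'protein_a', 'protein_b' and 'confidence' must have equal length")
  if (anyNA(confidence) || any(confidence <= 0) || any(confidence > 1))
    stop("interaction confidences must lie in (0, 1]")

  all_nodes <- c(protein_a, protein_b, as.character(nodes))
  loop <- protein_a == protein_b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped (no self-interaction in a PPI network)")
    protein_a <- protein_a[!loop]
    protein_b <- protein_b[!loop]
    confidence <- confidence[!loop]
  }
  a <- pmin(protein_a, protein_b)
  b <- pmax(protein_a, protein_b)
  key <- paste0(a, "\r", b)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate edge(s) merged, keeping the maximum confidence")
    confidence <- as.numeric(tapply(confidence, key, max)[unique(key)])
    keep <- !duplicated(key)
    a <- a[keep]
    b <- b[keep]
  }
  ord <- order(a, b)
  structure(list(
    nodes = sort(unique(all_nodes)),
    edges = data.frame(a = a[ord], b = b[ord], confidence = confidence[ord],
                       stringsAsFactors = FALSE)
  ), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network: ", length(x$nodes), " proteins, ", nrow(x$edges),
      " weighted interactions\n", sep = "")
  if (nrow(x$edges)) {
    cat("Confidence range: [", format(min(x$edges$confidence)), ", ",
        format(max(x$edges$confidence)), "]\n", sep = "")
  }
  invisible(x)
}

# Long (both-direction) incidence table: one row per (protein, neighbour, w).
incidence_table <- function(net) {
  e <- net$edges
  data.frame(protein = c(e$a, e$b), neighbour = c(e$b, e$a),
             confidence = c(e$confidence, e$confidence),
             stringsAsFactors = FALSE)
}

#' Neighbours of a protein in the interaction network
#'
#' @param net a [ppi_network()].
#' @param protein a single protein id.
#' @return Named numeric vector of interaction confidences, named by
#'   neighbouring protein id; empty for an isolated or unknown protein.
#' @export
network_neighbors <- function(net, protein) {
  stopifnot(inherits(net, "ppi_network"), length(protein) == 1L)
  e <- net$edges
  hit_a <- e$a == protein
  hit_b <- e$b == protein
  stats::setNames(c(e$confidence[hit_a], e$confidence[hit_b]),
                  c(e$b[hit_a], e$a[hit_b]))
}

#' Read a weighted PPI edge list
#'
#' Reads a whitespace/tab-separated edge list with columns protein A,
#' protein B, confidence (the STRING `protein.links` dialect). An optional
#' header line is detected by a non-numeric third field. Confidences are
#' canonicalized to the unit scale: `score_scale = "string1000"` divides raw
#' STRING integer scores (1–1000) by 1000, `"unit"` takes them as-is, and
#' `"auto"` (default) infers `string1000` when any value exceeds 1.
#'
#' @param path path to the edge-list file.
#' @param score_scale one of `"auto"`, `"unit"`, `"string1000"`.
#' @return A [ppi_network()].
#' @export
read_network <- function(path, score_scale = c("auto", "unit", "string1000")) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  if (length(fields) == 0L)
    return(ppi_network())
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][3L])))) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L)
    return(ppi_network())
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("malformed network row at line ", line_no[nf < 3L][1L],
         ": expected at least 3 columns")
  conf <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(conf))
    stop("non-numeric confidence at line ", line_no[is.na(conf)][1L])
  if (score_scale == "auto")
    score_scale <- if (any(conf > 1)) "string1000" else "unit"
  max_allowed <- if (score_scale == "string1000") 1000 else 1
  bad <- conf <= 0 | conf > max_allowed
  if (any(bad))
    stop("confidence out of (0, ", max_allowed, "] at line ",
         line_no[bad][1L])
  if (score_scale == "string1000") conf <- conf / 1000
  ppi_network(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L), conf)
}

#' Write a PPI network as a three-column TSV
#'
#' @param net a [ppi_network()]; isolated nodes are not representable in an
#'   edge list and are omitted.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges
  lines <- c("protein_a\tprotein_b\tconfidence",
             sprintf("%s\t%s\t%.15g", e$a, e$b, e$confidence))
  writeLines(lines, path)
  invisible(path)
}
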
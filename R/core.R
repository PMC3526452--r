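#' Construct an adjacency matrix (weighted binary matrix of degree 2 or 3)
#'
#' The central input object: a weighted binary matrix whose columns are
#' genetic markers (genes, or gene families when copy numbers exceed one)
#' and whose rows are intervals of markers. A row of degree 2 is an
#' *adjacency* -- an unordered pair of markers believed to be neighbours in
#' the ancestral genome, weighted by the confidence in that adjacency.
#' Degree-3 rows are accepted only for the brute-force oracles; the
#' polynomial linearizer requires degree 2.
#'
#' @param rows data frame with columns `row_id` (character, unique; if
#'   missing ids `r000001...` are generated in order), `cols` (list column
#'   of character vectors, each of length 2 or 3), and `weight` (positive
#'   numeric).
#' @param markers character vector of marker ids. Markers referenced by
#'   rows are added automatically; markers with no incident row (isolated
#'   columns) may be declared here.
#' @return object of class `adj_matrix` with elements `markers` (sorted
#'   character vector) and `rows` (data frame as above).
#' @examples
#' am <- adj_matrix(data.frame(row_id = c("r1", "r2"),
#'                             cols = I(list(c("a", "b"), c("b", "c"))),
#'                             weight = c(1, 2)))
#' adj_degree(am)
#' @export
adj_matrix <- function(rows = NULL, markers = character()) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- data.frame(row_id = character(), cols = I(list()),
                       weight = numeric())
  }
  if (!"row_id" %in% names(rows)) {
    rows$row_id <- sprintf("r%06d", seq_len(nrow(rows)))
  }
  stopifnot(is.list(rows$cols), is.numeric(rows$weight))
  rows$cols <- lapply(rows$cols, as.character)
  referenced <- unique(unlist(rows$cols, use.names = FALSE))
  markers <- sort(unique(c(as.character(markers), referenced)))
  obj <- structure(
    list(markers = markers,
         rows = data.frame(row_id = as.character(rows$row_id),
                           cols = I(rows$cols),
                           weight = as.numeric(rows$weight))),
    class = "adj_matrix")
  obj
}

#' Degree of an adjacency matrix (maximum row degree)
#' @param matrix an [adj_matrix()].
#' @return integer; 0 for a matrix with no rows.
#' @export
adj_degree <- function(matrix) {
  if (nrow(matrix$rows) == 0L) return(0L)
  max(lengths(matrix$rows$cols))
}

#' @export
print.adj_matrix <- function(x, ...) {
  cat(sprintf("<adj_matrix> %d markers, %d rows, degree %d, total weight %g\n",
              length(x$markers), nrow(x$rows), adj_degree(x),
              sum(x$rows$weight)))
  invisible(x)
}

#' Construct a multiplicity map (maximum copy number per marker)
#'
#' `m(c)` bounds how many times marker `c` may occur in the reconstructed
#' genome; markers not listed default to single copy.
#'
#' @param values named integer vector (names are marker ids, values >= 1),
#'   or NULL for all-default.
#' @return object of class `mult_map`.
#' @examples
#' mm <- mult_map(c(dupgene = 2))
#' multiplicity(mm, c("dupgene", "other"))
#' @export
mult_map <- function(values = NULL) {
  if (is.null(values)) values <- integer()
  values <- setNames(as.integer(values), names(values))
  if (length(values) > 0 && (is.null(names(values)) || any(names(values) == "")))
    stop("multiplicity values must be named by marker id")
  structure(list(values = values), class = "mult_map")
}

#' Look up maximum copy numbers
#' @param mult a [mult_map()].
#' @param marker_ids character vector.
#' @return integer vector of m(c) values (default 1).
#' @export
multiplicity <- function(mult, marker_ids) {
  out <- rep(1L, length(marker_ids))
  hit <- match(marker_ids, names(mult$values))
  out[!is.na(hit)] <- mult$values[hit[!is.na(hit)]]
  out
}

#' @export
print.mult_map <- function(x, ...) {
  cat(sprintf("<mult_map> %d markers with m > 1 declared (default 1)\n",
              sum(x$values > 1L)))
  invisible(x)
}

#' Validate an instance (matrix plus multiplicities)
#'
#' Reports, without aborting, every violation of the input contract:
#' duplicate row column-sets, rows whose degree is not 2 or 3,
#' self-adjacencies (repeated marker within one row), non-positive weights,
#' and copy-number bounds below 1. Callers decide whether to abort.
#'
#' @param matrix an [adj_matrix()].
#' @param mult a [mult_map()].
#' @return character vector of violation messages; empty means valid.
#' @examples
#' bad <- adj_matrix(data.frame(cols = I(list(c("a", "a"))), weight = 1))
#' validate_instance(bad, mult_map())
#' @export
validate_instance <- function(matrix, mult = mult_map()) {
  report <- character()
  rows <- matrix$rows
  for (k in seq_len(nrow(rows))) {
    cset <- rows$cols[[k]]
    if (length(unique(cset)) < length(cset)) {
      report <- c(report, sprintf(
        "row %s: self-adjacency (marker repeated within the row)",
        rows$row_id[k]))
    } else if (!length(cset) %in% c(2L, 3L)) {
      report <- c(report, sprintf(
        "row %s: degree %d not in {2, 3}", rows$row_id[k], length(cset)))
    }
    if (!is.finite(rows$weight[k]) || rows$weight[k] <= 0) {
      report <- c(report, sprintf(
        "row %s: weight %s is not positive", rows$row_id[k],
        format(rows$weight[k])))
    }
  }
  keys <- vapply(rows$cols, function(cs) paste(sort(cs), collapse = "\t"), "")
  dup <- duplicated(keys)
  for (k in which(dup)) {
    report <- c(report, sprintf("row %s: duplicate row column set {%s}",
                                rows$row_id[k],
                                paste(sort(rows$cols[[k]]), collapse = ",")))
  }
  if (anyDuplicated(rows$row_id)) {
    report <- c(report, "row ids are not unique")
  }
  bad_m <- mult$values[mult$values < 1L | is.na(mult$values)]
  for (nm in names(bad_m)) {
    report <- c(report, sprintf("marker %s: multiplicity %s < 1", nm,
                                format(bad_m[[nm]])))
  }
  undeclared <- setdiff(names(mult$values), matrix$markers)
  # multiplicities for unknown markers are tolerated (harmless defaults),
  # but whitespace in marker ids is not
  badid <- grepl("[\t ]", matrix$markers)
  for (nm in matrix$markers[badid]) {
    report <- c(report, sprintf("marker '%s': id contains whitespace", nm))
  }
  report
}

#' Identify a degree-2 matrix with its graph
#'
#' A degree-2 matrix is the same object as a simple weighted graph: the
#' vertices are the marker columns and each adjacency row is an edge
#' weighted by the row weight. Isolated markers become isolated vertices.
#'
#' @param matrix a valid degree-2 [adj_matrix()].
#' @return an [igraph][igraph::make_graph] undirected graph with vertex
#'   attribute `name` (marker ids), edge attributes `weight` and `row_id`.
#' @examples
#' am <- adj_matrix(data.frame(cols = I(list(c("a","b"), c("b","c"))),
#'                             weight = c(1, 2)))
#' matrix_to_graph(am)
#' @export
matrix_to_graph <- function(matrix) {
  if (adj_degree(matrix) > 2L) {
    stop("degree>2 not supported by linearizer")
  }
  viol <- validate_instance(matrix)
  if (length(viol) > 0) {
    stop("invalid instance: ", paste(viol, collapse = "; "))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(matrix$markers),
                            name = matrix$markers)
  if (nrow(matrix$rows) > 0) {
    ends <- t(vapply(matrix$rows$cols, function(cs) sort(cs), character(2)))
    g <- igraph::add_edges(
      g, t(cbind(match(ends[, 1], matrix$markers),
                 match(ends[, 2], matrix$markers))),
      weight = matrix$rows$weight, row_id = matrix$rows$row_id)
  }
  g
}

#' Rebuild the adjacency matrix of a weighted graph
#'
#' Inverse of [matrix_to_graph()]: each edge becomes a degree-2 row. The
#' round trip graph -> matrix -> graph is the identity on simple weighted
#' graphs with named vertices.
#'
#' @param g an igraph undirected simple graph with `name` vertex attribute,
#'   `weight` and optionally `row_id` edge attributes.
#' @return an [adj_matrix()].
#' @export
graph_to_matrix <- function(g) {
  nm <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  ids <- igraph::E(g)$row_id
  if (is.null(ids)) ids <- sprintf("r%06d", seq_len(nrow(el)))
  w <- igraph::E(g)$weight
  if (nrow(el) == 0L) {
    return(adj_matrix(markers = nm))
  }
  adj_matrix(data.frame(row_id = ids,
                        cols = I(lapply(seq_len(nrow(el)),
                                        function(k) as.character(el[k, ]))),
                        weight = w),
             markers = nm)
}

#' Construct a genome: an ordered collection of chromosomes
#'
#' Each chromosome is a sequence of marker occurrences, flagged linear or
#' circular. Circular chromosomes model plasmid-like replicons; a marker
#' may occur several times (up to its copy-number bound) in total.
#'
#' @param chromosomes list of lists, each with elements `kind` ("linear" or
#'   "circular") and `seq` (character vector of marker ids, length >= 1).
#' @return object of class `genome`.
#' @examples
#' genome(list(list(kind = "circular", seq = c("a", "b", "c"))))
#' @export
genome <- function(chromosomes = list()) {
  for (ch in chromosomes) {
    if (!is.list(ch) || !all(c("kind", "seq") %in% names(ch)))
      stop("each chromosome needs 'kind' and 'seq'")
    if (!ch$kind %in% c("linear", "circular"))
      stop("chromosome kind must be 'linear' or 'circular'")
    if (length(ch$seq) < 1L) stop("empty chromosome")
  }
  structure(list(chromosomes = chromosomes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  kinds <- vapply(x$chromosomes, `[[`, "", "kind")
  cat(sprintf("<genome> %d chromosomes (%d linear, %d circular)\n",
              length(kinds), sum(kinds == "linear"),
              sum(kinds == "circular")))
  for (ch in head(x$chromosomes, 20)) {
    cat(sprintf("  %s %s\n", if (ch$kind == "circular") "C" else "L",
                paste(ch$seq, collapse = " ")))
  }
  if (length(x$chromosomes) > 20) cat("  ...\n")
  invisible(x)
}

#' Marker occurrence counts of a genome
#' @param genome a [genome()].
#' @return named integer vector (marker -> number of occurrences).
#' @export
genome_occurrences <- function(genome) {
  occ <- table(unlist(lapply(genome$chromosomes, `[[`, "seq"),
                      use.names = FALSE))
  setNames(as.integer(occ), names(occ))
}

#' A selected row subset of a degree-2 matrix (candidate 2m-matching)
#'
#' @param matrix the parent degree-2 [adj_matrix()].
#' @param row_ids character vector of selected row ids (subset of the
#'   parent's row ids).
#' @return object of class `selected_rows` with the induced spanning
#'   subgraph semantics: the vertex set is always all markers.
#' @export
selected_rows <- function(matrix, row_ids) {
  stopifnot(all(row_ids %in% matrix$rows$row_id))
  idx <- match(row_ids, matrix$rows$row_id)
  structure(list(matrix = matrix,
                 row_ids = as.character(row_ids),
                 weight = sum(matrix$rows$weight[idx])),
            class = "selected_rows")
}

#' @export
print.selected_rows <- function(x, ...) {
  cat(sprintf("<selected_rows> %d of %d rows, weight %g\n",
              length(x$row_ids), nrow(x$matrix$rows), x$weight))
  invisible(x)
}

#' Degrees of markers in the subgraph induced by selected rows
#' @param selected a [selected_rows()].
#' @return named integer vector over all markers (0 for untouched markers).
#' @export
selected_degrees <- function(selected) {
  mk <- selected$matrix$markers
  deg <- setNames(rep(0L, length(mk)), mk)
  idx <- match(selected$row_ids, selected$matrix$rows$row_id)
  for (k in idx) {
    for (cc in selected$matrix$rows$cols[[k]]) {
      deg[cc] <- deg[cc] + 1L
    }
  }
  deg
}
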
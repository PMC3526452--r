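#' Read a weighted adjacency TSV
#'
#' One row per line: `marker_a<TAB>marker_b<TAB>weight`. Lines starting
#' with `#` and blank lines are ignored. With `allow_degree3 = TRUE` (for
#' the brute-force oracles) a four-column dialect
#' `a<TAB>b<TAB>c<TAB>weight` is also accepted. Row ids `r000001...` are
#' assigned in file order. Malformed lines (wrong column count,
#' non-numeric or non-positive weight, repeated marker within a row) are
#' errors reporting the line number; readers reject rather than repair.
#'
#' @param path file path.
#' @param allow_degree3 accept degree-3 rows.
#' @return an [adj_matrix()].
#' @export
read_adjacencies <- function(path, allow_degree3 = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  cols <- list(); wts <- numeric()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (grepl("^\\s*(#|$)", raw)) next
    parts <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    nmk <- length(parts) - 1L
    if (!(nmk == 2L || (allow_degree3 && nmk == 3L))) {
      stop(sprintf("line %d: expected %s tab-separated fields, got %d",
                   ln, if (allow_degree3) "3 or 4" else "3",
                   length(parts)))
    }
    mk <- parts[seq_len(nmk)]
    if (any(mk == "")) stop(sprintf("line %d: empty marker id", ln))
    if (anyDuplicated(mk))
      stop(sprintf("line %d: marker repeated within the row (self-adjacency)",
                   ln))
    w <- suppressWarnings(as.numeric(parts[nmk + 1L]))
    if (is.na(w)) stop(sprintf("line %d: non-numeric weight '%s'", ln,
                               parts[nmk + 1L]))
    if (w <= 0) stop(sprintf("line %d: weight %g is not positive", ln, w))
    cols[[length(cols) + 1L]] <- mk
    wts <- c(wts, w)
  }
  if (length(cols) == 0L) return(adj_matrix())
  mat <- adj_matrix(data.frame(row_id = sprintf("r%06d", seq_along(cols)),
                               cols = I(cols), weight = wts))
  viol <- grep("duplicate row column set", validate_instance(mat),
               value = TRUE)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "))
  mat
}

#' @rdname read_adjacencies
#' @param matrix an [adj_matrix()] to write.
#' @export
write_adjacencies <- function(matrix, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# adjacency rows: markers... <TAB> weight", con)
  for (k in seq_len(nrow(matrix$rows))) {
    writeLines(paste(c(matrix$rows$cols[[k]],
                       format(matrix$rows$weight[k], digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a maximum copy-number TSV
#'
#' Format `marker<TAB>max_copies`; unlisted markers default to 1. A
#' non-integer or sub-1 copy number is an error with its line number.
#'
#' @param path file path.
#' @return a [mult_map()].
#' @export
read_multiplicities <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  vals <- integer(); nms <- character()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (grepl("^\\s*(#|$)", raw)) next
    parts <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: expected 2 tab-separated fields", ln))
    m <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(m) || m != round(m))
      stop(sprintf("line %d: max_copies '%s' is not an integer", ln,
                   parts[2]))
    if (m < 1) stop(sprintf("line %d: max_copies %d < 1", ln, as.integer(m)))
    nms <- c(nms, parts[1]); vals <- c(vals, as.integer(m))
  }
  if (anyDuplicated(nms)) stop("duplicate marker in multiplicity table")
  mult_map(setNames(vals, nms))
}

#' @rdname read_multiplicities
#' @param mult a [mult_map()] to write.
#' @export
write_multiplicities <- function(mult, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# marker <TAB> max_copies", con)
  for (nm in sort(names(mult$values))) {
    writeLines(paste(nm, mult$values[[nm]], sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write a genome file
#'
#' One chromosome per line, a kind flag then the marker sequence:
#' `C m1 m2 m3` (circular) or `L m1 m2` (linear), after a header line
#' `#linchrom-genome v1`. Circular chromosomes are written in canonical
#' form: rotated to start at an occurrence of their lexicographically
#' smallest marker, direction chosen to make the whole sequence
#' lexicographically minimal, so write/read round-trips are stable.
#'
#' @param path file path.
#' @return a [genome()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  chroms <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (grepl("^\\s*(#|$)", raw)) next
    parts <- strsplit(trimws(raw), "[ \t]+")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("line %d: empty chromosome", ln))
    kind <- switch(parts[1], C = "circular", L = "linear",
                   stop(sprintf("line %d: unknown chromosome flag '%s'",
                                ln, parts[1])))
    chroms[[length(chroms) + 1L]] <- list(kind = kind, seq = parts[-1])
  }
  genome(chroms)
}

#' @rdname read_genome
#' @param genome a [genome()] to write.
#' @export
write_genome <- function(genome, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#linchrom-genome v1", con)
  for (ch in genome$chromosomes) {
    s <- if (ch$kind == "circular") canonical_rotation(ch$seq) else ch$seq
    writeLines(paste(c(if (ch$kind == "circular") "C" else "L", s),
                     collapse = " "), con)
  }
  invisible(path)
}

# lexicographically minimal rotation/reflection of a circular sequence,
# starting at an occurrence of the smallest marker
canonical_rotation <- function(s) {
  n <- length(s)
  if (n == 1L) return(s)
  best <- NULL
  for (dir in list(s, rev(s))) {
    starts <- which(dir == min(dir))
    for (st in starts) {
      cand <- dir[((st - 1L + 0:(n - 1L)) %% n) + 1L]
      if (is.null(best) || seq_less(cand, best)) best <- cand
    }
  }
  best
}

seq_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Read / write a 2,3-uniform hypergraph
#'
#' One hyperedge per line: 2 or 3 whitespace-separated vertex labels;
#' `#` comments and blank lines ignored.
#'
#' @param path file path.
#' @return a [hypergraph23()].
#' @export
read_hypergraph <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  edges <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (grepl("^\\s*(#|$)", raw)) next
    parts <- strsplit(trimws(raw), "[ \t]+")[[1]]
    if (!length(parts) %in% c(2L, 3L))
      stop(sprintf("line %d: hyperedge must have 2 or 3 vertices", ln))
    if (anyDuplicated(parts))
      stop(sprintf("line %d: repeated vertex in hyperedge", ln))
    edges[[length(edges) + 1L]] <- parts
  }
  hypergraph23(edges = edges)
}

#' @rdname read_hypergraph
#' @param h a [hypergraph23()] to write.
#' @export
write_hypergraph <- function(h, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# one hyperedge per line: 2 or 3 vertex labels", con)
  for (e in c(h$e2, h$e3)) writeLines(paste(e, collapse = " "), con)
  invisible(path)
}

#' Write run statistics as JSON
#' @param stats the `stats` element of a [linearize()] result.
#' @param path output path.
#' @export
write_stats_json <- function(stats, path) {
  stats$occurrences <- as.list(stats$occurrences)
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a planted instance to a directory
#'
#' Emits the adjacency TSV, multiplicity TSV, planted genome and a JSON
#' truth sidecar (`planted row ids`, weight, parameters, seed); file
#' content is byte-identical for identical parameters and seed. Planted
#' rows are written before decoy rows, so after [read_adjacencies()]
#' (which assigns fresh ids in file order) the planted rows are
#' `r000001` through `r00000N` for `N` planted ids in the sidecar.
#'
#' @param inst a [generate_planted()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_instance <- function(inst, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(adjacencies = file.path(dir, "adjacencies.tsv"),
             multiplicities = file.path(dir, "multiplicities.tsv"),
             genome = file.path(dir, "genome.txt"),
             truth = file.path(dir, "truth.json"))
  write_adjacencies(inst$matrix, paths[["adjacencies"]])
  write_multiplicities(inst$mult, paths[["multiplicities"]])
  write_genome(inst$genome, paths[["genome"]])
  tr <- inst$truth
  jsonlite::write_json(
    list(planted_row_ids = tr$planted_row_ids,
         planted_weight = tr$planted_weight,
         params = unclass(tr$params)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
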
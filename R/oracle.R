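#' Is a selected row subset a 2m-matching?
#'
#' A spanning subgraph of the adjacency graph is realizable as a genome of
#' linear/circular chromosomes respecting copy numbers (component-mCi1P)
#' exactly when every marker's degree is at most `2 m(marker)`: each of
#' the at most `m(v)` occurrences of a marker in the chromosomes has two
#' neighbouring positions.
#'
#' @param selected a [selected_rows()] on a degree-2 matrix.
#' @param mult a [mult_map()].
#' @return TRUE/FALSE.
#' @examples
#' am <- adj_matrix(data.frame(row_id = c("r1","r2","r3"),
#'                             cols = I(list(c("a","b"), c("b","c"), c("a","c"))),
#'                             weight = c(1,1,1)))
#' is_2m_matching(selected_rows(am, c("r1","r2","r3")), mult_map())
#' @export
is_2m_matching <- function(selected, mult) {
  if (adj_degree(selected$matrix) > 2L) stop("degree-2 instance required")
  deg <- selected_degrees(selected)
  all(deg <= 2L * multiplicity(mult, names(deg)))
}

#' Consecutive-ones checks for degree-2 matrices, via graph shape
#'
#' A degree-2 matrix has the consecutive-ones property (one linear order
#' of the columns realizing every row) iff its graph is a disjoint union
#' of paths; it has the circular variant iff the graph is a single cycle
#' through all columns, or a disjoint union of paths.
#'
#' @param selected a [selected_rows()] on a degree-2 matrix.
#' @return TRUE/FALSE.
#' @export
is_c1p_degree2 <- function(selected) {
  g <- selected_graph(selected)
  all(igraph::degree(g) <= 2L) && !has_cycle(g)
}

#' @rdname is_c1p_degree2
#' @export
is_ci1p_degree2 <- function(selected) {
  g <- selected_graph(selected)
  if (all(igraph::degree(g) <= 2L) && !has_cycle(g)) return(TRUE)
  # single cycle spanning every column
  igraph::vcount(g) > 0 && all(igraph::degree(g) == 2L) &&
    igraph::components(g)$no == 1L
}

has_cycle <- function(g) {
  igraph::ecount(g) > igraph::vcount(g) - igraph::components(g)$no
}

selected_graph <- function(selected) {
  matrix <- selected$matrix
  idx <- match(selected$row_ids, matrix$rows$row_id)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(matrix$markers), name = matrix$markers)
  if (length(idx) > 0) {
    em <- do.call(rbind, lapply(idx, function(k) sort(matrix$rows$cols[[k]])))
    g <- igraph::add_edges(g, t(cbind(match(em[, 1], matrix$markers),
                                      match(em[, 2], matrix$markers))))
  }
  g
}

#' Does a genome realize a selected row set?
#'
#' TRUE iff (i) every selected row's marker pair occurs as a consecutive
#' pair -- including the wrap-around pair of a circular chromosome -- in
#' some chromosome, exactly once in total across the genome; and (ii)
#' every marker of the parent matrix occurs at least once and at most
#' `m(marker)` times in total.
#'
#' @param genome a [genome()].
#' @param selected a [selected_rows()].
#' @param mult a [mult_map()].
#' @return TRUE/FALSE.
#' @export
check_genome_realizes <- function(genome, selected, mult) {
  matrix <- selected$matrix
  occ <- setNames(rep(0L, length(matrix$markers)), matrix$markers)
  gocc <- genome_occurrences(genome)
  known <- names(gocc) %in% matrix$markers
  if (!all(known)) return(FALSE)
  occ[names(gocc)] <- gocc
  if (any(occ < 1L) || any(occ > multiplicity(mult, names(occ))))
    return(FALSE)
  # multiset of consecutive pairs across all chromosomes
  pair_keys <- character()
  for (ch in genome$chromosomes) {
    s <- ch$seq
    n <- length(s)
    if (n >= 2L) {
      a <- s[-n]; b <- s[-1]
      pair_keys <- c(pair_keys, paste(pmin(a, b), pmax(a, b)))
    }
    if (ch$kind == "circular" && n >= 2L) {
      pair_keys <- c(pair_keys, paste(min(s[n], s[1]), max(s[n], s[1])))
    }
    if (ch$kind == "circular" && n == 1L) {
      pair_keys <- c(pair_keys, paste(s, s))  # a length-1 cycle is a self-pair
    }
  }
  counts <- table(pair_keys)
  idx <- match(selected$row_ids, matrix$rows$row_id)
  for (k in idx) {
    cs <- sort(matrix$rows$cols[[k]])
    if (length(cs) != 2L) return(FALSE)
    key <- paste(cs[1], cs[2])
    if (is.na(match(key, names(counts))) || counts[[key]] != 1L)
      return(FALSE)
  }
  TRUE
}

#' Exact maximum-weight 2m-matching by exhaustive enumeration
#'
#' Independent ground-truth oracle for [linearize()]: enumerates all
#' `2^rows` row subsets and keeps the best one satisfying
#' [is_2m_matching()]. Intended for instances with at most ~20 rows.
#'
#' @param matrix a degree-2 [adj_matrix()].
#' @param mult a [mult_map()].
#' @return list with `weight` and `row_ids` (lexicographically smallest
#'   optimum among ties).
#' @export
brute_force_max_2m_matching <- function(matrix, mult = mult_map()) {
  nr <- nrow(matrix$rows)
  if (nr > 20L) stop("instance too large for brute force (max 20 rows)")
  if (adj_degree(matrix) > 2L) stop("degree-2 instance required")
  mk <- matrix$markers
  bound <- 2L * multiplicity(mult, mk)
  # incidence matrix markers x rows
  inc <- matrix(0L, nrow = length(mk), ncol = nr)
  for (k in seq_len(nr)) {
    inc[match(matrix$rows$cols[[k]], mk), k] <- 1L
  }
  best_w <- 0; best <- integer()
  for (code in 0:(2^nr - 1)) {
    sel <- which(bitwAnd(code, bitwShiftL(1L, 0:(max(nr, 1) - 1))) > 0)
    if (nr == 0L) sel <- integer()
    w <- sum(matrix$rows$weight[sel])
    if (w <= best_w) next
    deg <- if (length(sel)) rowSums(inc[, sel, drop = FALSE]) else
      rep(0L, length(mk))
    if (all(deg <= bound)) {
      best_w <- w; best <- sel
    }
  }
  list(weight = best_w, row_ids = matrix$rows$row_id[best])
}

#' 2,3-uniform hypergraph
#'
#' @param vertices character vector of vertex ids.
#' @param edges list of character vectors, each of 2 or 3 distinct
#'   vertices; all hyperedges distinct as sets.
#' @return object of class `hypergraph23` with `vertices`, `e2`, `e3`.
#' @examples
#' hypergraph23(c("a","b","c","d"), list(c("a","b"), c("b","c","d")))
#' @export
hypergraph23 <- function(vertices = character(), edges = list()) {
  edges <- lapply(edges, function(h) sort(as.character(h)))
  sizes <- lengths(edges)
  if (any(vapply(edges, anyDuplicated, 0L) > 0))
    stop("hyperedge with repeated vertex")
  if (!all(sizes %in% c(2L, 3L)))
    stop("hyperedges must have 2 or 3 vertices")
  keys <- vapply(edges, paste, "", collapse = "\t")
  if (anyDuplicated(keys)) stop("duplicate hyperedge")
  vertices <- sort(unique(c(as.character(vertices),
                            unlist(edges, use.names = FALSE))))
  structure(list(vertices = vertices,
                 e2 = edges[sizes == 2L],
                 e3 = edges[sizes == 3L]),
            class = "hypergraph23")
}

#' @export
print.hypergraph23 <- function(x, ...) {
  cat(sprintf("<hypergraph23> %d vertices, %d 2-edges, %d 3-edges\n",
              length(x$vertices), length(x$e2), length(x$e3)))
  invisible(x)
}

#' Convert between degree-2/3 matrices and 2,3-uniform hypergraphs
#'
#' Rows of degree 2 (resp. 3) correspond one-to-one to 2-edges (resp.
#' 3-edges); the round trip is the identity (up to row ids and weights,
#' which hypergraphs do not carry).
#'
#' @param matrix an [adj_matrix()] with rows of degree 2 or 3.
#' @return a [hypergraph23()].
#' @export
matrix_to_hypergraph <- function(matrix) {
  if (nrow(matrix$rows) > 0 && !all(lengths(matrix$rows$cols) %in% c(2L, 3L)))
    stop("rows must have degree 2 or 3")
  hypergraph23(matrix$markers, matrix$rows$cols)
}

#' @rdname matrix_to_hypergraph
#' @param h a [hypergraph23()].
#' @export
hypergraph_to_matrix <- function(h) {
  edges <- c(h$e2, h$e3)
  if (length(edges) == 0L) return(adj_matrix(markers = h$vertices))
  adj_matrix(data.frame(row_id = sprintf("r%06d", seq_along(edges)),
                        cols = I(edges),
                        weight = rep(1, length(edges))),
             markers = h$vertices)
}

#' Brute-force solver for covering a 2,3-uniform hypergraph by cycles and
#' paths after hyperedge removal
#'
#' A graph covering picks the one pair from each kept 2-edge and exactly
#' two of the three pairs from each kept 3-edge; the union of picked pairs
#' must form a graph of maximum degree at most 2 (a disjoint union of
#' paths and cycles). Decides whether removing at most `k` hyperedges
#' admits such a covering, by exhaustive enumeration of removal subsets
#' and covering choices; intended for at most ~10 hyperedges.
#'
#' @param h a [hypergraph23()].
#' @param k maximum number of hyperedges that may be removed.
#' @return list with `feasible` (TRUE/FALSE) and, when feasible, `witness`
#'   = list(`removed` = hyperedges removed, `covering` = list of picked
#'   pairs per kept hyperedge), the lexicographically first one found.
#' @export
solve_23ucr_brute <- function(h, k) {
  edges <- c(h$e2, h$e3)
  ne <- length(edges)
  if (ne > 12L) stop("instance too large for brute force (max 12 hyperedges)")
  if (ne == 0L) return(list(feasible = TRUE,
                            witness = list(removed = list(),
                                           covering = list())))
  # removal subsets in order of increasing size, lexicographic within size
  for (r in 0:min(k, ne)) {
    removal_sets <- if (r == 0L) list(integer()) else
      asplit(combn(ne, r), 2)
    for (rem in removal_sets) {
      kept <- setdiff(seq_len(ne), rem)
      cov <- cover_search(edges[kept], h$vertices)
      if (!is.null(cov)) {
        covering <- setNames(cov, vapply(edges[kept], paste, "",
                                         collapse = ","))
        return(list(feasible = TRUE,
                    witness = list(removed = edges[rem],
                                   covering = covering)))
      }
    }
  }
  list(feasible = FALSE, witness = NULL)
}

# enumerate covering choices for the kept hyperedges: the single pair of a
# 2-edge, one of the 3 pair-pairs of a 3-edge; E' is the *set* union of the
# choices; feasible iff max degree of E' is <= 2. Returns the first
# (lexicographic in choice order) feasible covering or NULL.
cover_search <- function(kept_edges, vertices) {
  choices <- lapply(kept_edges, function(hh) {
    if (length(hh) == 2L) {
      list(list(hh))
    } else {
      prs <- list(c(hh[1], hh[2]), c(hh[1], hh[3]), c(hh[2], hh[3]))
      # the 3 ways to pick 2 of the 3 pairs
      list(list(prs[[1]], prs[[2]]), list(prs[[1]], prs[[3]]),
           list(prs[[2]], prs[[3]]))
    }
  })
  nch <- lengths(choices)
  idx <- rep(1L, length(choices))
  repeat {
    picked <- mapply(function(ch, i) ch[[i]], choices, idx,
                     SIMPLIFY = FALSE)
    eprime <- unique(unlist(lapply(picked, function(prs)
      vapply(prs, function(p) paste(sort(p), collapse = "\t"), "")),
      use.names = FALSE))
    degs <- table(unlist(strsplit(eprime, "\t"), use.names = FALSE))
    if (length(degs) == 0L || max(degs) <= 2L) return(picked)
    # advance mixed-radix counter
    pos <- length(idx)
    while (pos >= 1L) {
      if (idx[pos] < nch[pos]) {
        idx[pos] <- idx[pos] + 1L
        idx[seq_len(length(idx))[-seq_len(pos)]] <- 1L
        break
      }
      pos <- pos - 1L
    }
    if (pos < 1L) return(NULL)
    if (length(idx) == 0L) return(NULL)
  }
}

#' Row-removal decision for component-realizability, brute force
#'
#' Can at most `k` rows be removed from a degree-2/3 matrix with unit
#' multiplicities so that the remaining rows are simultaneously realizable
#' consecutively on a collection of circular orders (component-Ci1P)? The
#' decision delegates to the hypergraph covering solver through the
#' matrix/hypergraph correspondence.
#'
#' @param matrix an [adj_matrix()] with rows of degree 2 or 3.
#' @param k maximum rows removed.
#' @return TRUE/FALSE.
#' @export
brute_force_row_removal <- function(matrix, k) {
  solve_23ucr_brute(matrix_to_hypergraph(matrix), k)$feasible
}
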
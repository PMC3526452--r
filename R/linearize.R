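#' Build the gadget graph reducing f-matching to matching
#'
#' For each marker `x` the gadget contains copy vertices
#' `x#1 ... x#f(x)` with `f(x) = 2 m(x)`; for each adjacency row
#' `e = {x, y}` it contains two port vertices `e@x`, `e@y` and the edges
#' `{x#i, e@x}` (all i), `{e@x, e@y}`, `{y#j, e@y}` (all j), every one of
#' them carrying the weight of `e`. A maximum-weight matching of this
#' auxiliary graph encodes a maximum-weight degree-constrained subgraph
#' (2m-matching) of the original adjacency graph: matching both ports of a
#' gadget to copy vertices earns twice the row weight (row selected), while
#' matching the two ports to each other earns it once (row excluded).
#'
#' @param g the adjacency graph from [matrix_to_graph()].
#' @param mult a [mult_map()].
#' @param cap_at_degree if TRUE, the number of copy vertices of `x` is
#'   capped at `deg(x)`; degree constraints beyond the actual degree are
#'   slack so the encoded feasible set is unchanged, but the gadget is
#'   smaller. The default FALSE keeps the full `2 m(x)` copies.
#' @return object of class `gadget_graph`: list with `vertices` (names),
#'   `vkind` ("copy"/"port"), `vmarker` (marker of a copy vertex, NA for
#'   ports), `vrow` (row id of a port vertex, NA for copies), `edges`
#'   (data frame `i`, `j`, `w`, `row_id`), and `port_index` (matrix of the
#'   two port vertex indices per row).
#' @examples
#' am <- adj_matrix(data.frame(row_id = "e", cols = I(list(c("x", "y"))),
#'                             weight = 5))
#' gg <- build_gadget(matrix_to_graph(am), mult_map())
#' gg$vertices
#' @export
build_gadget <- function(g, mult, cap_at_degree = FALSE) {
  markers <- igraph::V(g)$name
  stopifnot(!is.unsorted(markers))
  deg <- igraph::degree(g)
  f <- 2L * multiplicity(mult, markers)
  if (any(f < 2L)) stop("multiplicities must be >= 1")
  if (cap_at_degree) f <- pmin(f, as.integer(deg))
  el <- igraph::as_edgelist(g, names = TRUE)
  nr <- nrow(el)
  w <- igraph::E(g)$weight
  row_id <- igraph::E(g)$row_id

  copy_names <- unlist(lapply(seq_along(markers), function(k) {
    if (f[k] == 0L) character() else paste0(markers[k], "#", seq_len(f[k]))
  }), use.names = FALSE)
  copy_marker <- rep(markers, f)
  port_names <- if (nr > 0)
    c(rbind(paste0(row_id, "@", el[, 1]), paste0(row_id, "@", el[, 2])))
  else character()
  vertices <- c(copy_names, port_names)
  nv_copy <- length(copy_names)
  vkind <- c(rep("copy", nv_copy), rep("port", length(port_names)))
  vmarker <- c(copy_marker, rep(NA_character_, length(port_names)))
  vrow <- c(rep(NA_character_, nv_copy), rep(row_id, each = 2))

  # copy index ranges per marker
  cstart <- cumsum(c(0L, f))[seq_along(markers)]
  ei <- integer(); ej <- integer(); ew <- numeric(); erow <- character()
  port_index <- matrix(integer(), nrow = nr, ncol = 2)
  for (k in seq_len(nr)) {
    x <- el[k, 1]; y <- el[k, 2]
    px <- nv_copy + 2L * (k - 1L) + 1L
    py <- nv_copy + 2L * (k - 1L) + 2L
    port_index[k, ] <- c(px, py)
    kx <- match(x, markers); ky <- match(y, markers)
    xi <- if (f[kx] > 0L) cstart[kx] + seq_len(f[kx]) else integer()
    yj <- if (f[ky] > 0L) cstart[ky] + seq_len(f[ky]) else integer()
    ei <- c(ei, xi, px, yj)
    ej <- c(ej, rep(px, length(xi)), py, rep(py, length(yj)))
    ew <- c(ew, rep(w[k], length(xi) + 1L + length(yj)))
    erow <- c(erow, rep(row_id[k], length(xi) + 1L + length(yj)))
  }
  structure(list(vertices = vertices, vkind = vkind, vmarker = vmarker,
                 vrow = vrow,
                 edges = data.frame(i = ei, j = ej, w = ew,
                                    row_id = erow),
                 port_index = port_index, row_id = row_id,
                 row_weight = if (nr > 0) setNames(w, row_id) else
                   setNames(numeric(), character())),
            class = "gadget_graph")
}

#' @export
print.gadget_graph <- function(x, ...) {
  cat(sprintf("<gadget_graph> %d vertices (%d copies, %d ports), %d edges\n",
              length(x$vertices), sum(x$vkind == "copy"),
              sum(x$vkind == "port"), nrow(x$edges)))
  invisible(x)
}

#' Maximum-weight matching of a gadget graph
#'
#' Delegates to the general-graph blossom solver
#' ([max_weight_matching()]); the gadget contains odd cycles, so a
#' bipartite solver would not do.
#'
#' @param gadget a [build_gadget()] result.
#' @return object of class `gadget_matching`: list with `mate` (integer
#'   vector over gadget vertices) and `weight` (total matched weight, in
#'   the original weight units).
#' @export
solve_max_weight_matching <- function(gadget) {
  mate <- max_weight_matching(gadget$edges, length(gadget$vertices))
  structure(list(mate = mate,
                 weight = matching_weight(mate, gadget$edges)),
            class = "gadget_matching")
}

#' @export
print.gadget_matching <- function(x, ...) {
  cat(sprintf("<gadget_matching> weight %g, %d matched vertices\n",
              x$weight, sum(!is.na(x$mate))))
  invisible(x)
}

#' Recover the selected rows (2m-matching) from a gadget matching
#'
#' A row is selected if and only if *both* of its port vertices are matched
#' to copy vertices; a port matched across the gadget bridge, or left
#' unmatched, excludes the row. For a maximum-weight matching the recovered
#' row set is a maximum-weight 2m-matching of the adjacency graph.
#'
#' @param matching a [solve_max_weight_matching()] result.
#' @param gadget the gadget it was computed on.
#' @param matrix the parent [adj_matrix()].
#' @return a [selected_rows()] object.
#' @export
recover_f_matching <- function(matching, gadget, matrix) {
  mate <- matching$mate
  nr <- nrow(gadget$port_index)
  keep <- logical(nr)
  for (k in seq_len(nr)) {
    p <- gadget$port_index[k, ]
    keep[k] <- !is.na(mate[p[1]]) && !is.na(mate[p[2]]) &&
      gadget$vkind[mate[p[1]]] == "copy" &&
      gadget$vkind[mate[p[2]]] == "copy"
  }
  selected_rows(matrix, gadget$row_id[keep])
}

#' Check the weight conservation identity of the gadget reduction
#'
#' For every instance, the weight of a maximum matching of the gadget must
#' equal `W + w(selected)`, where `W` is the total weight of all rows.
#' This identity is run as a mandatory self-check after every solve: a
#' violation means a solver or gadget construction defect.
#'
#' @param matching a [solve_max_weight_matching()] result.
#' @param selected the [recover_f_matching()] output.
#' @param matrix the parent [adj_matrix()].
#' @return TRUE if the identity holds (exactly for integer-scalable
#'   weights, within 1e-9 relative otherwise), FALSE if not.
#' @export
verify_weight_relation <- function(matching, selected, matrix) {
  W <- sum(matrix$rows$weight)
  s <- scale_weights(matrix$rows$weight)
  lhs <- matching$weight
  rhs <- W + selected$weight
  if (s$exact) {
    isTRUE(all.equal(round(lhs * s$factor), round(rhs * s$factor),
                     tolerance = 0))
  } else {
    abs(lhs - rhs) <= 1e-9 * max(1, abs(W))
  }
}

#' Decompose a 2m-matching into chromosomes (Eulerian trails)
#'
#' Every connected component of the selected spanning subgraph whose
#' vertices all have even degree carries a closed Eulerian trail and
#' becomes exactly one circular chromosome; a component with `2k > 0`
#' odd-degree vertices is decomposed into `k` edge-disjoint open trails
#' (the minimum possible) and becomes `k` linear chromosomes. Isolated
#' markers become length-1 linear chromosomes, so every declared marker
#' occurs at least once. Marker occurrences are the minimum the trails
#' require, never exceeding the copy-number bound `m(c)`.
#'
#' @param selected a [selected_rows()] object satisfying the 2m-matching
#'   degree bounds (checked).
#' @param mult a [mult_map()].
#' @return a [genome()].
#' @examples
#' am <- adj_matrix(data.frame(row_id = c("r1","r2","r3"),
#'                             cols = I(list(c("a","b"), c("b","c"), c("a","c"))),
#'                             weight = c(1, 1, 1)))
#' decompose_to_chromosomes(selected_rows(am, c("r1","r2","r3")), mult_map())
#' @export
decompose_to_chromosomes <- function(selected, mult) {
  matrix <- selected$matrix
  if (adj_degree(matrix) > 2L) stop("degree-2 instance required")
  deg <- selected_degrees(selected)
  bound <- 2L * multiplicity(mult, names(deg))
  if (any(deg > bound)) {
    stop("selected rows violate the 2m-matching degree bounds for: ",
         paste(names(deg)[deg > bound], collapse = ", "))
  }
  idx <- match(selected$row_ids, matrix$rows$row_id)
  ends <- lapply(idx, function(k) sort(matrix$rows$cols[[k]]))

  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(matrix$markers), name = matrix$markers)
  if (length(ends) > 0) {
    em <- do.call(rbind, ends)
    g <- igraph::add_edges(g, t(cbind(match(em[, 1], matrix$markers),
                                      match(em[, 2], matrix$markers))),
                           virtual = FALSE)
  }
  comp <- igraph::components(g)
  chroms <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    vnames <- sort(matrix$markers[vids])
    sub <- igraph::induced_subgraph(g, vids)
    if (igraph::ecount(sub) == 0L) {
      chroms[[length(chroms) + 1L]] <-
        list(kind = "linear", seq = vnames[1])
      next
    }
    dsub <- igraph::degree(sub)
    odd <- sort(igraph::V(sub)$name[dsub %% 2L == 1L])
    if (length(odd) == 0L) {
      walk <- igraph::eulerian_cycle(sub)
      vpath <- igraph::as_ids(walk$vpath)
      chroms[[length(chroms) + 1L]] <-
        list(kind = "circular", seq = vpath[-length(vpath)])
    } else {
      # pair odd-degree vertices lexicographically with virtual edges,
      # close the component into an Eulerian multigraph, then cut the
      # closed trail back open at the virtual edges
      pairs <- matrix(match(odd, igraph::V(sub)$name),
                      ncol = 2, byrow = TRUE)
      aug <- igraph::add_edges(sub, t(pairs), virtual = TRUE)
      walk <- igraph::eulerian_cycle(aug)
      vpath <- igraph::as_ids(walk$vpath)
      epath <- as.integer(walk$epath)
      isvirt <- igraph::E(aug)$virtual[epath]
      ne <- length(epath)
      cut <- which(isvirt)
      for (t in seq_along(cut)) {
        from <- cut[t]
        to <- if (t < length(cut)) cut[t + 1L] else cut[1L] + ne
        # edges (from+1) .. (to-1) form one open trail; vertex sequence is
        # vpath positions (from+1) .. to, wrapping modulo ne
        pos <- ((from + 1L):to - 1L) %% ne + 1L
        chroms[[length(chroms) + 1L]] <-
          list(kind = "linear", seq = vpath[pos])
      }
    }
  }
  gen <- genome(chroms)
  occ <- genome_occurrences(gen)
  mocc <- multiplicity(mult, names(occ))
  stopifnot(all(occ <= mocc))
  gen
}

#' Linearize a weighted adjacency matrix into an ancestral genome
#'
#' End-to-end pipeline: validates the degree-2 instance, builds the
#' adjacency graph and its matching gadget, solves a maximum-weight
#' matching, recovers the maximum-weight row subset realizable as a genome
#' with linear/circular chromosomes (a 2m-matching), checks the weight
#' conservation identity, and decomposes the selection into chromosomes.
#'
#' @param matrix a degree-2 [adj_matrix()].
#' @param mult a [mult_map()] of maximum copy numbers (default all 1).
#' @param self_check if TRUE (default), abort unless the weight identity
#'   and the genome realization checks pass.
#' @return object of class `linchrom_result`: list with `selected` (a
#'   [selected_rows()]), `genome` (a [genome()]), and `stats` (a list with
#'   total input weight `W`, `optimum`, row and chromosome counts, and the
#'   marker occurrence histogram).
#' @examples
#' am <- adj_matrix(data.frame(
#'   cols = I(list(c("a","b"), c("b","c"), c("c","d"), c("d","a"),
#'                 c("a","c"), c("b","d"))),
#'   weight = rep(1, 6)))
#' res <- linearize(am, mult_map())
#' res$stats$optimum
#' @export
linearize <- function(matrix, mult = mult_map(), self_check = TRUE) {
  viol <- validate_instance(matrix, mult)
  if (length(viol) > 0) {
    stop("invalid instance: ", paste(viol, collapse = "; "))
  }
  t0 <- proc.time()[["elapsed"]]
  g <- matrix_to_graph(matrix)
  gadget <- build_gadget(g, mult, cap_at_degree = TRUE)
  matching <- solve_max_weight_matching(gadget)
  selected <- recover_f_matching(matching, gadget, matrix)
  if (!verify_weight_relation(matching, selected, matrix)) {
    stop("internal invariant failure: gadget weight identity violated ",
         "(matching weight != W + selected weight)")
  }
  gen <- decompose_to_chromosomes(selected, mult)
  if (self_check && !check_genome_realizes(gen, selected, mult)) {
    stop("internal invariant failure: genome does not realize the ",
         "selected rows")
  }
  kinds <- vapply(gen$chromosomes, `[[`, "", "kind")
  stats <- list(
    W = sum(matrix$rows$weight),
    optimum = selected$weight,
    rows_total = nrow(matrix$rows),
    rows_kept = length(selected$row_ids),
    rows_discarded = nrow(matrix$rows) - length(selected$row_ids),
    n_linear = sum(kinds == "linear"),
    n_circular = sum(kinds == "circular"),
    occurrences = genome_occurrences(gen),
    exact_arithmetic = scale_weights(matrix$rows$weight)$exact,
    elapsed_seconds = proc.time()[["elapsed"]] - t0)
  structure(list(selected = selected, genome = gen, stats = stats),
            class = "linchrom_result")
}

#' @export
print.linchrom_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0(
    "<linchrom_result> optimum %g of total %g; kept %d/%d rows; ",
    "%d linear + %d circular chromosomes\n"),
    s$optimum, s$W, s$rows_kept, s$rows_total, s$n_linear, s$n_circular))
  invisible(x)
}
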
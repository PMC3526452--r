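#' Maximum-weight matching in a general weighted graph
#'
#' Computes a matching (a set of vertex-disjoint edges) of maximum total
#' weight, using a primal-dual blossom method implemented in C++. This is
#' *maximum weight*, not maximum cardinality: with positive weights, edges
#' are matched only when they increase the total weight, and the returned
#' matching need not be perfect.
#'
#' Edge weights that are exactly representable as scaled integers are solved
#' in exact (integer-valued double) arithmetic; see [scale_weights()].
#'
#' @param edges data frame with columns `i`, `j` (1-based vertex indices)
#'   and `w` (positive weights).
#' @param n_vertices number of vertices.
#' @return integer vector `mate` of length `n_vertices`; `mate[v]` is the
#'   vertex matched to `v`, or `NA` if `v` is unmatched.
#' @examples
#' edges <- data.frame(i = c(1, 2, 3), j = c(2, 3, 1), w = c(1, 1, 1))
#' max_weight_matching(edges, 3)
#' @export
max_weight_matching <- function(edges, n_vertices) {
  stopifnot(is.data.frame(edges), all(c("i", "j", "w") %in% names(edges)))
  if (nrow(edges) == 0L) {
    return(rep(NA_integer_, n_vertices))
  }
  if (any(edges$w <= 0)) {
    stop("edge weights must be positive")
  }
  w <- scale_weights(edges$w)$scaled
  .mwm_cpp(as.integer(edges$i), as.integer(edges$j), as.numeric(w),
           as.integer(n_vertices))
}

#' Scale rational weights to exact integers where possible
#'
#' Tries successive powers of ten up to `10^max_digits`; if some scaling
#' makes every weight integral (within 1e-9 relative), returns the scaled
#' integer weights so downstream arithmetic is exact. Otherwise weights are
#' passed through unchanged and comparisons fall back to a 1e-9 tolerance.
#'
#' @param w numeric vector of weights.
#' @param max_digits largest power of ten tried.
#' @return list with `scaled` (numeric), `factor` (the multiplier used) and
#'   `exact` (logical: TRUE if integral scaling succeeded).
#' @export
scale_weights <- function(w, max_digits = 6L) {
  for (d in 0:max_digits) {
    s <- w * 10^d
    if (all(abs(s - round(s)) <= 1e-9 * pmax(1, abs(s)))) {
      return(list(scaled = round(s), factor = 10^d, exact = TRUE))
    }
  }
  list(scaled = w, factor = 1, exact = FALSE)
}

#' Total weight of a matching returned by [max_weight_matching()]
#' @param mate mate vector.
#' @param edges the edge data frame the matching was computed from.
#' @return numeric scalar.
#' @export
matching_weight <- function(mate, edges) {
  if (nrow(edges) == 0L) return(0)
  inm <- !is.na(mate[edges$i]) & mate[edges$i] == edges$j
  sum(edges$w[inm])
}

#' Exhaustive maximum-weight matching (reference oracle)
#'
#' Enumerates all matchings by branching on edges; exponential, intended for
#' graphs with at most ~20 edges, as an independent check of the blossom
#' solver.
#'
#' @inheritParams max_weight_matching
#' @return list with `weight` and `mate` (as in [max_weight_matching()]).
#' @export
brute_force_matching <- function(edges, n_vertices) {
  m <- nrow(edges)
  if (m > 22L) stop("instance too large for brute-force matching")
  best <- list(weight = 0, mate = rep(NA_integer_, n_vertices))
  used <- rep(FALSE, n_vertices)
  mate <- rep(NA_integer_, n_vertices)
  recurse <- function(k, acc) {
    if (k > m) {
      if (acc > best$weight) best <<- list(weight = acc, mate = mate)
      return(invisible(NULL))
    }
    i <- edges$i[k]; j <- edges$j[k]
    if (!used[i] && !used[j]) {
      used[i] <<- TRUE; used[j] <<- TRUE
      mate[i] <<- j; mate[j] <<- i
      recurse(k + 1L, acc + edges$w[k])
      used[i] <<- FALSE; used[j] <<- FALSE
      mate[i] <<- NA_integer_; mate[j] <<- NA_integer_
    }
    recurse(k + 1L, acc)
  }
  recurse(1L, 0)
  best
}
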
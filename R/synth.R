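#' Parameters for the planted-genome instance generator
#'
#' @param n_markers number of markers (>= 1).
#' @param n_chromosomes number of chromosomes in the planted genome.
#' @param circular_fraction fraction of chromosomes that are circular.
#' @param duplicated_fraction fraction of markers given copy number 2.
#' @param true_weight_range `c(lo, hi)`: planted row weights are drawn
#'   uniformly from the rationals with denominator 10^4 in `(lo, hi]`.
#' @param noise_edge_count number of decoy rows appended.
#' @param noise_weight_range `c(lo', hi')` for decoy weights; strict mode
#'   requires `hi' < lo` so every decoy is lighter than every planted row.
#' @param strict if TRUE, decoy rows only connect markers whose planted
#'   degree already equals `2 m`, so each decoy conflicts with the planted
#'   solution and the planted row set is the unique optimum.
#' @param seed integer seed; the generator is deterministic given
#'   identical parameters and seed.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(n_markers = 8, n_chromosomes = 1,
                         circular_fraction = 0.5,
                         duplicated_fraction = 0,
                         true_weight_range = c(1, 2),
                         noise_edge_count = 0,
                         noise_weight_range = c(0.1, 0.5),
                         strict = TRUE, seed = 1L) {
  stopifnot(n_markers >= 1, n_chromosomes >= 1,
            circular_fraction >= 0, circular_fraction <= 1,
            duplicated_fraction >= 0, duplicated_fraction <= 1,
            true_weight_range[1] > 0,
            true_weight_range[1] <= true_weight_range[2],
            noise_edge_count >= 0,
            noise_weight_range[1] >= 0,
            noise_weight_range[1] <= noise_weight_range[2])
  if (strict && noise_weight_range[2] >= true_weight_range[1]) {
    stop("strict mode requires every noise weight below every true weight")
  }
  structure(list(n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 circular_fraction = circular_fraction,
                 duplicated_fraction = duplicated_fraction,
                 true_weight_range = true_weight_range,
                 noise_edge_count = as.integer(noise_edge_count),
                 noise_weight_range = noise_weight_range,
                 strict = isTRUE(strict), seed = as.integer(seed)),
            class = "synth_params")
}

#' Evaluate code under a fixed RNG seed, restoring the session RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rational_weights <- function(n, lo, hi) {
  # uniform on the rationals k/10^4 in (lo, hi]
  klo <- floor(lo * 1e4) + 1
  khi <- floor(hi * 1e4)
  if (khi < klo) khi <- klo
  sample(seq(klo, khi), n, replace = TRUE) / 1e4
}

#' Generate a planted-genome instance with known optimum
#'
#' Builds a random genome respecting the copy-number bounds, takes its
#' adjacency set as the planted rows, and optionally appends lighter decoy
#' rows. A genome's adjacency set always satisfies the degree bounds
#' (every occurrence of a marker has at most two neighbours), so the
#' planted rows are always feasible; in strict mode they are the unique
#' optimum, because every decoy joins two markers whose planted degree is
#' already maximal, so including any decoy forces dropping at least as
#' many strictly heavier planted rows.
#'
#' @param params a [synth_params()].
#' @return list with `matrix` (an [adj_matrix()]), `mult` (a
#'   [mult_map()]), `genome` (the planted [genome()]), and `truth` (list:
#'   planted row ids, their total weight, params echo).
#' @export
generate_planted <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  with_rng_seed(params$seed, {
    markers <- sprintf("m%03d", seq_len(params$n_markers))
    n_dup <- round(params$duplicated_fraction * params$n_markers)
    dup <- sort(sample(markers, n_dup))
    mult <- mult_map(setNames(rep(2L, length(dup)), dup))

    occurrences <- c(markers, dup)  # each duplicated marker twice
    if (length(occurrences) < params$n_chromosomes) {
      stop("impossible request: more chromosomes than marker occurrences")
    }
    n_circ <- round(params$circular_fraction * params$n_chromosomes)

    gen <- NULL
    for (attempt in 1:200) {
      occ <- sample(occurrences)
      # split occurrences into n_chromosomes non-empty chunks; circular
      # chromosomes need length >= 3 to avoid self-pairs and repeats
      sizes <- random_composition(length(occ), params$n_chromosomes)
      kinds <- rep("linear", params$n_chromosomes)
      if (n_circ > 0) {
        big <- order(sizes, decreasing = TRUE)
        kinds[big[seq_len(n_circ)]] <- "circular"
      }
      if (any(sizes[kinds == "circular"] < 3L)) next
      chroms <- list(); at <- 0L; ok <- TRUE
      for (ci in seq_len(params$n_chromosomes)) {
        s <- occ[at + seq_len(sizes[ci])]; at <- at + sizes[ci]
        chroms[[ci]] <- list(kind = kinds[ci], seq = s)
      }
      cand <- genome(chroms)
      adjs <- genome_adjacencies(cand)
      if (length(adjs) > 0) {
        keys <- vapply(adjs, paste, "", collapse = "\t")
        selfp <- vapply(adjs, function(p) p[1] == p[2], TRUE)
        if (anyDuplicated(keys) || any(selfp)) next  # repeated/self pair
      }
      gen <- cand
      break
    }
    if (is.null(gen)) {
      stop("impossible request: could not arrange a genome without ",
           "repeated or self adjacencies (e.g. circular chromosome of ",
           "length < 3 needed)")
    }
    adjs <- genome_adjacencies(gen)
    wts <- rational_weights(length(adjs), params$true_weight_range[1],
                            params$true_weight_range[2])
    planted_ids <- sprintf("p%05d", seq_along(adjs))

    # decoy rows among non-planted pairs; strict mode restricts the pool
    # to saturated markers (planted degree == 2m)
    deg <- setNames(rep(0L, length(markers)), markers)
    for (p in adjs) {
      deg[p[1]] <- deg[p[1]] + 1L
      deg[p[2]] <- deg[p[2]] + 1L
    }
    pool_markers <- if (params$strict) {
      names(deg)[deg == 2L * multiplicity(mult, names(deg))]
    } else markers
    cand_pairs <- if (length(pool_markers) >= 2)
      combn(sort(pool_markers), 2, simplify = FALSE) else list()
    planted_keys <- vapply(adjs, paste, "", collapse = "\t")
    cand_pairs <- Filter(function(p)
      !(paste(p, collapse = "\t") %in% planted_keys), cand_pairs)
    n_noise <- min(params$noise_edge_count, length(cand_pairs))
    if (n_noise < params$noise_edge_count) {
      message(sprintf(
        "noise pool exhausted: %d of %d requested decoy rows generated",
        n_noise, params$noise_edge_count))
    }
    noise <- if (n_noise > 0) cand_pairs[sort(sample(length(cand_pairs),
                                                     n_noise))] else list()
    nwts <- if (n_noise > 0)
      rational_weights(n_noise, params$noise_weight_range[1],
                       params$noise_weight_range[2]) else numeric()
    noise_ids <- if (n_noise > 0) sprintf("n%05d", seq_len(n_noise)) else
      character()

    rows <- data.frame(row_id = c(planted_ids, noise_ids),
                       cols = I(c(adjs, noise)),
                       weight = c(wts, nwts))
    mat <- adj_matrix(rows, markers = markers)
    list(matrix = mat, mult = mult, genome = gen,
         truth = list(planted_row_ids = planted_ids,
                      planted_weight = sum(wts),
                      params = params))
  })
}

# adjacency multiset of a genome, as sorted pairs
genome_adjacencies <- function(genome) {
  out <- list()
  for (ch in genome$chromosomes) {
    s <- ch$seq; n <- length(s)
    if (n >= 2L) {
      for (k in seq_len(n - 1L))
        out[[length(out) + 1L]] <- sort(c(s[k], s[k + 1L]))
    }
    if (ch$kind == "circular" && n >= 2L)
      out[[length(out) + 1L]] <- sort(c(s[n], s[1L]))
    if (ch$kind == "circular" && n == 1L)
      out[[length(out) + 1L]] <- c(s, s)
  }
  out
}

# random composition of n into k positive parts
random_composition <- function(n, k) {
  if (k == 1L) return(n)
  cuts <- sort(sample(n - 1L, k - 1L))
  diff(c(0L, cuts, n))
}

#' Generate a uniform random degree-2 instance for oracle fuzzing
#'
#' @param n_vertices number of markers.
#' @param n_edges number of adjacency rows (at most `choose(n, 2)`).
#' @param max_mult multiplicities drawn uniformly from `1:max_mult`.
#' @param seed integer seed.
#' @return list with `matrix` and `mult`.
#' @export
generate_random_graph <- function(n_vertices, n_edges, max_mult = 2L,
                                  seed = 1L) {
  if (n_edges > choose(n_vertices, 2)) {
    stop("n_edges exceeds the number of marker pairs")
  }
  with_rng_seed(seed, {
    width <- max(3L, nchar(as.character(n_vertices)))
    markers <- sprintf(paste0("m%0", width, "d"), seq_len(n_vertices))
    # sample pair indices and unrank, so large vertex counts never
    # materialize all choose(n, 2) pairs
    n_pairs <- choose(n_vertices, 2)
    sel <- if (n_edges > 0) sort(sample(n_pairs, n_edges)) else integer()
    pairs <- lapply(sel, function(k) {
      # pairs (i < j) ordered by j then i; cumulative count up to j is
      # (j - 1) j / 2
      j <- floor((1 + sqrt(8 * k - 7)) / 2) + 1
      while ((j - 2) * (j - 1) / 2 >= k) j <- j - 1
      while ((j - 1) * j / 2 < k) j <- j + 1
      i <- k - (j - 2) * (j - 1) / 2
      c(markers[i], markers[j])
    })
    wts <- if (n_edges > 0) rational_weights(n_edges, 0, 1) else numeric()
    mat <- adj_matrix(
      if (n_edges > 0)
        data.frame(row_id = sprintf("r%06d", seq_len(n_edges)),
                   cols = I(pairs), weight = wts)
      else NULL,
      markers = markers)
    mv <- sample(seq_len(max_mult), n_vertices, replace = TRUE)
    mult <- mult_map(setNames(as.integer(mv), markers))
    list(matrix = mat, mult = mult)
  })
}
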
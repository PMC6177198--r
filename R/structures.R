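#' Population structures
#'
#' A population structure fixes who can be a coplayer of whom. In well-mixed
#' mode the focal individual draws its `d - 1` coplayers uniformly without
#' replacement from the whole rest of the population; in network mode it
#' draws them from its neighbourhood on a simple undirected graph. Every node
#' must have at least `d - 1` neighbours so that each individual can fill a
#' d-player game.
#'
#' @param n Population size.
#' @param mode `"well_mixed"` or `"network"`.
#' @param adj For network mode, a list of integer neighbour vectors
#'   (1-based), one per node.
#' @param kind Label: one of `"complete"`, `"ring"`, `"k_regular"`,
#'   `"erdos_renyi"`, `"barabasi_albert"`, `"custom"`, `"well_mixed"`.
#' @return An object of class `population_structure` with fields `n`, `mode`,
#'   `adj` (NULL in well-mixed mode), `kind`, `degrees`.
#' @export
population_structure <- function(n, mode = c("well_mixed", "network"),
                                 adj = NULL, kind = "custom") {
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(n >= 2L)
  if (mode == "well_mixed") {
    return(structure(list(n = n, mode = mode, adj = NULL, kind = kind,
                          degrees = rep(n - 1L, n)),
                     class = "population_structure"))
  }
  if (!is.list(adj) || length(adj) != n) {
    stop("network mode needs an adjacency list of length n", call. = FALSE)
  }
  adj <- lapply(adj, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    v <- adj[[i]]
    if (any(v < 1L) || any(v > n)) stop("neighbour id out of range", call. = FALSE)
    if (i %in% v) stop("self-loops are not allowed", call. = FALSE)
    if (!all(vapply(v, function(j) i %in% adj[[j]], logical(1)))) {
      stop("adjacency must be symmetric (undirected graph)", call. = FALSE)
    }
  }
  structure(list(n = n, mode = "network", adj = adj, kind = kind,
                 degrees = vapply(adj, length, integer(1))),
            class = "population_structure")
}

#' @export
print.population_structure <- function(x, ...) {
  if (x$mode == "well_mixed") {
    cat(sprintf("well-mixed population, N = %d\n", x$n))
  } else {
    cat(sprintf("%s network, N = %d, degrees in [%d, %d], %d edges\n",
                x$kind, x$n, min(x$degrees), max(x$degrees),
                sum(x$degrees) %/% 2L))
  }
  invisible(x)
}

#' Well-mixed (structureless) population
#'
#' Coplayers are drawn uniformly without replacement from all other `n - 1`
#' individuals, afresh at every game.
#'
#' @param n Population size.
#' @return A `population_structure` in well-mixed mode.
#' @export
make_well_mixed <- function(n) {
  population_structure(n, mode = "well_mixed", kind = "well_mixed")
}

#' Ring (cycle) population
#'
#' Each individual's neighbourhood is exactly its two nearest neighbours on
#' the cycle, the canonical regular structure of degree 2 for three-player
#' games.
#'
#' @param n Population size, at least 3.
#' @return A `population_structure` with every degree equal to 2.
#' @export
make_ring <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("a ring needs at least 3 individuals", call. = FALSE)
  adj <- lapply(seq_len(n), function(i) {
    c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)
  })
  population_structure(n, mode = "network", adj = adj, kind = "ring")
}

#' Complete network
#'
#' Everyone is everyone else's neighbour (degree `n - 1`). Differs from
#' [make_well_mixed()] only in that coplayers come from a stored
#' neighbourhood rather than being defined implicitly.
#'
#' @param n Population size.
#' @return A `population_structure` of kind `"complete"`.
#' @export
make_complete <- function(n) {
  n <- as.integer(n)
  adj <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  population_structure(n, mode = "network", adj = adj, kind = "complete")
}

#' Random network generators with a degree floor
#'
#' Generates a simple connected graph of one of three kinds and enforces a
#' minimum degree so that every individual has enough neighbours for the
#' d-player game:
#' \describe{
#'   \item{`k_regular`}{random k-regular graph (every degree exactly `k`).}
#'   \item{`erdos_renyi`}{G(n, p); default `p = 4/n` (mean degree 4).}
#'   \item{`barabasi_albert`}{preferential attachment with `m` edges per new
#'     node (default 2).}
#' }
#' Generation is retried up to `max_tries` times until the sample is
#' connected; nodes still below the degree floor are then repaired by adding
#' edges to uniformly chosen non-neighbours.
#'
#' @param n Population size.
#' @param kind Generator name.
#' @param k Degree for `k_regular`.
#' @param p Edge probability for `erdos_renyi` (default `4/n`).
#' @param m Attachment count for `barabasi_albert`.
#' @param min_degree Degree floor, at least `d - 1` for d-player games.
#' @param seed Optional integer seed.
#' @param max_tries Resampling budget.
#' @return A `population_structure` whose every degree is `>= min_degree`.
#' @export
make_random_graph <- function(n,
                              kind = c("k_regular", "erdos_renyi",
                                       "barabasi_albert"),
                              k = 2L, p = NULL, m = 2L, min_degree = 2L,
                              seed = NULL, max_tries = 100L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  min_degree <- as.integer(min_degree)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "k_regular" && k < min_degree) {
    stop("k below the requested degree floor", call. = FALSE)
  }
  if (is.null(p)) p <- 4 / n
  for (try in seq_len(max_tries)) {
    gr <- switch(kind,
                 k_regular = igraph::sample_k_regular(n, k),
                 erdos_renyi = igraph::sample_gnp(n, p),
                 barabasi_albert = igraph::sample_pa(n, power = 1, m = m,
                                                     directed = FALSE))
    gr <- igraph::simplify(gr)
    if (!igraph::is_connected(gr)) next
    deg <- igraph::degree(gr)
    if (any(deg < min_degree)) {
      if (kind == "k_regular") next  # regularity must not be broken by repair
      gr <- repair_min_degree(gr, min_degree)
      if (is.null(gr)) next
    }
    adj <- igraph::as_adj_list(gr)
    adj <- lapply(adj, as.integer)
    return(population_structure(n, mode = "network", adj = adj, kind = kind))
  }
  stop(sprintf("could not generate a connected %s graph with min degree %d in %d tries",
               kind, min_degree, max_tries), call. = FALSE)
}

# Add edges from deficient nodes to random non-neighbours until the floor
# holds; returns NULL if impossible (should not happen for n > min_degree).
repair_min_degree <- function(gr, min_degree) {
  n <- igraph::vcount(gr)
  for (pass in seq_len(n)) {
    deg <- igraph::degree(gr)
    low <- which(deg < min_degree)
    if (length(low) == 0L) return(gr)
    v <- low[1L]
    cand <- setdiff(seq_len(n), c(v, as.integer(igraph::neighbors(gr, v))))
    if (length(cand) == 0L) return(NULL)
    u <- if (length(cand) == 1L) cand else sample(cand, 1L)
    gr <- igraph::add_edges(gr, c(v, u))
  }
  NULL
}

#' Read a population structure from a whitespace-delimited edge list
#'
#' Each line holds one undirected edge as two 0-based node ids. The node
#' count is inferred as `max(id) + 1` unless given.
#'
#' @param path Edge-list file.
#' @param n Optional population size (to include isolated trailing ids).
#' @return A `population_structure` of kind `"custom"`.
#' @export
read_edgelist <- function(path, n = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) < 2L) stop("edge list needs two columns", call. = FALSE)
  m <- m[, 1:2, drop = FALSE] + 1L  # to 1-based
  if (is.null(n)) n <- max(m)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(m))) {
    a <- m[r, 1L]; b <- m[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  population_structure(n, mode = "network", adj = adj, kind = "custom")
}

#' Write a population structure as a 0-based edge list
#'
#' @param structure A network-mode `population_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(structure, path) {
  stopifnot(inherits(structure, "population_structure"),
            structure$mode == "network")
  edges <- do.call(rbind, lapply(seq_len(structure$n), function(i) {
    js <- structure$adj[[i]]
    js <- js[js > i]
    if (length(js)) cbind(i - 1L, js - 1L) else NULL
  }))
  write.table(edges, path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Sample the coplayers of a focal individual
#'
#' Draws `d - 1` distinct coplayers uniformly without replacement: from the
#' focal's neighbourhood in network mode, or from all other individuals in
#' well-mixed mode. On a regular structure of degree exactly `d - 1` the
#' draw is deterministic (the whole neighbourhood).
#'
#' @param structure A `population_structure`.
#' @param focal Focal individual id (1-based).
#' @param d Group size of the game.
#' @return Integer vector of `d - 1` coplayer ids.
#' @export
sample_coplayers <- function(structure, focal, d) {
  stopifnot(inherits(structure, "population_structure"))
  need <- d - 1L
  if (structure$mode == "well_mixed") {
    if (structure$n < d) stop("population smaller than the game", call. = FALSE)
    pool <- setdiff(seq_len(structure$n), focal)
  } else {
    pool <- structure$adj[[focal]]
    if (length(pool) < need) {
      stop(sprintf("individual %d has only %d neighbours but needs %d",
                   focal, length(pool), need), call. = FALSE)
    }
  }
  if (length(pool) == need) return(pool)
  sample(pool, need)
}
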
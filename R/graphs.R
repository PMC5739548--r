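#' Construct a network for Moran invasion dynamics
#'
#' Builds one of the network families used in the incubation-period model and
#' returns it with a uniform adjacency interface. All networks are simple
#' (no self-loops or duplicate edges), undirected and connected; random
#' families are resampled (up to `max_retries` fresh draws) until a connected
#' graph is obtained. Lattices are periodic (toroidal) in every dimension, so
#' the 1D lattice is a ring and every node of a d-dimensional lattice has
#' degree 2d.
#'
#' @param family One of `"complete"`, `"star"`, `"ring_1d"`, `"lattice_2d"`,
#'   `"lattice_3d"`, `"erdos_renyi"`, `"small_world"`, `"k_regular"`,
#'   `"scale_free"`.
#' @param n Number of nodes. For `"star"` give `spokes` instead (a star with
#'   S spokes has S + 1 nodes in total); for 2D/3D lattices give `dims`.
#' @param spokes Spoke count for the star family.
#' @param dims Integer vector of side lengths for lattice families (length 2
#'   for `"lattice_2d"`, length 3 for `"lattice_3d"`).
#' @param p Edge probability (Erdos-Renyi) or per-edge shortcut probability
#'   (Newman-Watts-Strogatz small-world), in (0, 1].
#' @param k Degree for the random k-regular family.
#' @param m Number of edges each new node attaches with (minimum degree) for
#'   the Barabasi-Albert scale-free family.
#' @param nei Neighbourhood radius of the small-world ring backbone: each node
#'   is joined to its `nei` nearest neighbours on each side (backbone degree
#'   `2 * nei`).
#' @param seed Optional integer seed; when given, construction is
#'   reproducible bit-for-bit.
#' @param max_retries Maximum number of fresh draws for random families that
#'   come out disconnected.
#'
#' @return An object of class `"moran_network"`: a list with elements
#'   `n_nodes`, `family`, `params`, and `adjacency` (a list of 1-based
#'   integer neighbour vectors, one per node).
#'
#' @examples
#' net <- make_network("star", spokes = 5)
#' network_degrees(net) # hub degree 5, spokes degree 1
#' net2 <- make_network("erdos_renyi", n = 30, p = 0.5, seed = 1)
#' @export
make_network <- function(family,
                         n = NULL,
                         spokes = NULL,
                         dims = NULL,
                         p = NULL,
                         k = NULL,
                         m = NULL,
                         nei = 2L,
                         seed = NULL,
                         max_retries = 100L) {
  family <- match.arg(family, c(
    "complete", "star", "ring_1d", "lattice_2d", "lattice_3d",
    "erdos_renyi", "small_world", "k_regular", "scale_free"
  ))
  if (!is.null(seed)) set.seed(seed)

  chk_n <- function(n, min = 2L) {
    if (is.null(n) || length(n) != 1L || !is.finite(n) || n < min || n != round(n)) {
      stop("'n' must be a single integer >= ", min, call. = FALSE)
    }
    as.integer(n)
  }
  chk_p <- function(p) {
    if (is.null(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
      stop("'p' must be a probability in (0, 1]", call. = FALSE)
    }
    p
  }

  params <- list()
  build <- switch(family,
    complete = {
      n <- chk_n(n)
      params <- list(n = n)
      function() igraph::make_full_graph(n, directed = FALSE)
    },
    star = {
      if (is.null(spokes) && !is.null(n)) spokes <- n - 1L
      spokes <- chk_n(spokes, min = 1L)
      params <- list(spokes = spokes, n = spokes + 1L)
      function() igraph::make_star(spokes + 1L, mode = "undirected", center = 1L)
    },
    ring_1d = {
      n <- chk_n(n, min = 3L)
      params <- list(n = n)
      function() igraph::make_ring(n, directed = FALSE, circular = TRUE)
    },
    lattice_2d = ,
    lattice_3d = {
      d <- if (family == "lattice_2d") 2L else 3L
      if (is.null(dims) && !is.null(n)) {
        side <- round(n^(1 / d))
        if (side^d != n) stop("'n' is not a perfect ", d, "-dimensional cube; give 'dims'", call. = FALSE)
        dims <- rep(side, d)
      }
      if (length(dims) != d || any(dims < 3L) || any(dims != round(dims))) {
        stop("'dims' must be ", d, " integer side lengths >= 3 (periodic boundaries)", call. = FALSE)
      }
      dims <- as.integer(dims)
      params <- list(dims = dims, n = prod(dims))
      function() igraph::make_lattice(dimvector = dims, periodic = TRUE)
    },
    erdos_renyi = {
      n <- chk_n(n)
      p <- chk_p(p)
      params <- list(n = n, p = p)
      function() igraph::sample_gnp(n, p, directed = FALSE)
    },
    small_world = {
      # Newman-Watts-Strogatz: periodic ring backbone (each node joined to its
      # `nei` nearest neighbours per side) plus, for each backbone edge, an
      # extra shortcut with probability p between two uniform random nodes.
      n <- chk_n(n, min = 4L)
      p <- chk_p(p)
      nei <- chk_n(nei, min = 1L)
      params <- list(n = n, p = p, nei = nei)
      function() {
        g <- igraph::make_lattice(length = n, dim = 1, nei = nei, periodic = TRUE)
        n_backbone <- igraph::ecount(g)
        n_short <- stats::rbinom(1L, n_backbone, p)
        if (n_short > 0) {
          ends <- matrix(sample.int(n, 2L * n_short, replace = TRUE), ncol = 2L)
          ends <- ends[ends[, 1L] != ends[, 2L], , drop = FALSE]
          if (nrow(ends) > 0) {
            g <- igraph::add_edges(g, t(ends))
            g <- igraph::simplify(g)
          }
        }
        g
      }
    },
    k_regular = {
      n <- chk_n(n)
      if (is.null(k) || k < 1L || k >= n || k != round(k)) {
        stop("'k' must be an integer in [1, n)", call. = FALSE)
      }
      if ((n * k) %% 2L != 0L) {
        stop("infeasible k-regular graph: n * k must be even", call. = FALSE)
      }
      params <- list(n = n, k = as.integer(k))
      function() igraph::sample_k_regular(n, k)
    },
    scale_free = {
      n <- chk_n(n)
      if (is.null(m) || m < 1L || m >= n || m != round(m)) {
        stop("'m' (attachment/minimum degree) must be an integer in [1, n)", call. = FALSE)
      }
      params <- list(n = n, m = as.integer(m))
      function() igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
    }
  )

  g <- build()
  tries <- 0L
  while (!igraph::is_connected(g)) {
    tries <- tries + 1L
    if (tries > max_retries) {
      stop("failed to draw a connected '", family, "' graph in ",
        max_retries, " retries",
        call. = FALSE
      )
    }
    g <- build()
  }

  adjacency <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  structure(
    list(
      n_nodes = igraph::vcount(g),
      family = family,
      params = params,
      adjacency = adjacency
    ),
    class = "moran_network"
  )
}

#' @export
print.moran_network <- function(x, ...) {
  degs <- network_degrees(x)
  cat(
    sprintf(
      "<moran_network> family=%s  nodes=%d  edges=%d  degree range [%d, %d]\n",
      x$family, x$n_nodes, sum(degs) %/% 2L, min(degs), max(degs)
    )
  )
  invisible(x)
}

#' Node degrees of a network
#'
#' @param network A [make_network()] object.
#' @return Integer vector of node degrees.
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "moran_network"))
  lengths(network$adjacency)
}

#' Export a network as a plain edge list
#'
#' Writes one edge per line as two whitespace-separated 0-based node indices,
#' each undirected edge appearing once (smaller index first).
#'
#' @param network A [make_network()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "moran_network"))
  edges <- edge_matrix(network)
  writeLines(paste(edges[, 1L] - 1L, edges[, 2L] - 1L), path)
  invisible(path)
}

# all edges as a 2-column matrix of 1-based indices, i < j
edge_matrix <- function(network) {
  adj <- network$adjacency
  from <- rep.int(seq_along(adj), lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  keep <- from < to
  cbind(from[keep], to[keep])
}

# flat compressed adjacency (0-based) for the C++ engine
flat_adjacency <- function(network) {
  adj <- network$adjacency
  list(
    offsets = c(0L, cumsum(lengths(adj))),
    neighbors = as.integer(unlist(adj, use.names = FALSE)) - 1L
  )
}
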
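# Generators for ground-truth connectivity graphs. The edge count is fixed
# at round(density * n(n-1)/2) (round-half-even, base R `round`) so tests
# can assert exact counts.

# column-major upper-triangle index table for n nodes: row k -> (i, j), i < j
pair_table <- function(n) {
  which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
}

edges_to_adjacency <- function(edges, n) {
  a <- matrix(0L, n, n)
  a[edges] <- 1L
  a[edges[, c(2L, 1L), drop = FALSE]] <- 1L
  a
}

adjacency_to_edges <- function(adjacency) {
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  colnames(idx) <- NULL
  idx
}

# Ring-lattice edge list with m edges: complete nearest-neighbour rings are
# filled first; leftover edges go to the next ring, either at the positions
# sampled uniformly (random = TRUE) or at the first positions (deterministic).
ring_lattice_edges <- function(n, m, random_leftover = FALSE) {
  max_m <- (n * (n - 1L)) %/% 2L
  stopifnot(m <= max_m)
  full <- m %/% n
  leftover <- m %% n
  # ring at distance d has n edges, except d = n/2 (n even) which has n/2
  ring <- function(d) {
    i <- seq_len(n)
    j <- ((i - 1L + d) %% n) + 1L
    e <- cbind(pmin(i, j), pmax(i, j))
    unique(e)
  }
  d <- 1L
  edges <- vector("list", 0L)
  m_placed <- 0L
  while (m_placed < m) {
    e <- ring(d)
    take <- m - m_placed
    if (nrow(e) <= take) {
      edges[[d]] <- e
      m_placed <- m_placed + nrow(e)
    } else {
      pick <- if (random_leftover) sample.int(nrow(e), take) else seq_len(take)
      edges[[d]] <- e[pick, , drop = FALSE]
      m_placed <- m
    }
    d <- d + 1L
  }
  do.call(rbind, edges)
}

#' Generate a planted connectivity network
#'
#' Creates the ground-truth electrode graph that
#' [synthesize_coupled_recording()] realizes as band-limited, phase-lagged
#' coupling. Three stock topologies span the regular-to-random axis used by
#' the small-world analysis: `ring_lattice` (each node tied to its nearest
#' neighbours), `watts_strogatz` (the lattice with each edge rewired to a
#' random vacant pair with probability `rewire_p`) and `erdos_renyi`
#' (uniformly random placement). All three place exactly
#' `round(density * n(n-1)/2)` edges.
#'
#' @param topology One of `"ring_lattice"`, `"watts_strogatz"`,
#'   `"erdos_renyi"`, `"custom"`.
#' @param n_nodes Number of nodes (>= 4).
#' @param density Fraction of possible edges present, in (0, 1).
#' @param rewire_p Rewiring probability for `watts_strogatz`.
#' @param adjacency Binary symmetric matrix for `topology = "custom"`.
#' @param lag_ms Phase lag of the shared source on each edge, ms. Must be
#'   non-zero: zero-lag coupling is invisible to imaginary coherency by
#'   construction.
#' @param band Frequency interval (Hz) of the planted coupling.
#' @param seed Integer seed.
#' @return Object of class `planted_network`: `adjacency`, `n_nodes`,
#'   `n_edges`, `density` (achieved), `topology`, `lag_ms`, `band`.
#' @examples
#' net <- generate_planted_network("erdos_renyi", n_nodes = 60,
#'                                 density = 0.15, seed = 1)
#' net$n_edges  # round(0.15 * 1770) = 266
#' @export
generate_planted_network <- function(topology = c("ring_lattice",
                                                  "watts_strogatz",
                                                  "erdos_renyi", "custom"),
                                     n_nodes = 60L, density = 0.15,
                                     rewire_p = 0.1, adjacency = NULL,
                                     lag_ms = 20, band = c(4, 7),
                                     seed = NULL) {
  topology <- match.arg(topology)
  if (topology == "custom") {
    stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
    if (!isSymmetric(unname(adjacency * 1)) || any(diag(adjacency) != 0) ||
        !all(adjacency %in% c(0, 1))) {
      stop("custom `adjacency` must be binary, symmetric, zero-diagonal",
           call. = FALSE)
    }
    n_nodes <- nrow(adjacency)
    a <- adjacency * 1L
  } else {
    n_nodes <- assert_count(n_nodes, "n_nodes", min = 4L)
    density <- assert_number(density, "density")
    if (density <= 0 || density >= 1) {
      stop("`density` must lie strictly between 0 and 1", call. = FALSE)
    }
    npairs <- (n_nodes * (n_nodes - 1L)) %/% 2L
    m <- as.integer(round(density * npairs))
    if (2 * m / n_nodes < 2) {
      warning("mean degree below 2; disconnected graphs are likely",
              call. = FALSE)
    }
    a <- with_seed(seed, {
      edges <- switch(
        topology,
        ring_lattice = ring_lattice_edges(n_nodes, m, random_leftover = TRUE),
        watts_strogatz = rewire_edges(
          ring_lattice_edges(n_nodes, m, random_leftover = TRUE),
          n_nodes, rewire_p
        ),
        erdos_renyi = pair_table(n_nodes)[sample.int(npairs, m), ,
                                          drop = FALSE]
      )
      edges_to_adjacency(edges, n_nodes)
    })
  }
  m <- sum(a) %/% 2L
  structure(
    list(adjacency = a,
         n_nodes = n_nodes,
         n_edges = m,
         density = m / (n_nodes * (n_nodes - 1L) / 2),
         topology = topology,
         rewire_p = if (topology == "watts_strogatz") rewire_p else NULL,
         lag_ms = assert_number(lag_ms, "lag_ms"),
         band = band,
         seed = seed),
    class = "planted_network"
  )
}

# Watts-Strogatz style rewiring that preserves the edge count: each edge is,
# with probability p, replaced by a uniformly chosen vacant pair.
rewire_edges <- function(edges, n, p) {
  p <- assert_number(p, "rewire_p", 0, 1)
  if (p == 0) {
    return(edges)
  }
  a <- edges_to_adjacency(edges, n)
  flip <- stats::runif(nrow(edges)) < p
  for (k in which(flip)) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    a[i, j] <- a[j, i] <- 0L
    repeat {
      u <- sample.int(n, 1L)
      v <- sample.int(n, 1L)
      if (u != v && a[u, v] == 0L) break
    }
    a[u, v] <- a[v, u] <- 1L
    edges[k, ] <- c(min(u, v), max(u, v))
  }
  adjacency_to_edges(a)
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("planted network: %s, %d nodes, %d edges (density %.3f)\n",
              x$topology, x$n_nodes, x$n_edges, x$density))
  cat(sprintf("  coupling: lag %.1f ms in band [%g, %g] Hz\n",
              x$lag_ms, x$band[1], x$band[2]))
  invisible(x)
}
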
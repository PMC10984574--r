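complete_graph <- function(n) {
  m <- matrix(1L, n, n)
  diag(m) <- 0L
  m
}

cycle_graph <- function(n) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    m[i, j] <- m[j, i] <- 1L
  }
  m
}

test_that("percentile thresholding keeps 265 of 1770 distinct values at the 85th percentile", {
  set.seed(1)
  v <- matrix(0, 60, 60)
  v[upper.tri(v)] <- runif(1770)
  v <- v + t(v)
  adj <- threshold_adjacency(v, 85)
  expect_equal(adj$n_edges, 265L)
  # brute-force count: strictly above the type-5 percentile
  q <- quantile(v[upper.tri(v)], 0.85, type = 5)
  expect_equal(adj$n_edges, sum(v[upper.tri(v)] > q))
})

test_that("a constant matrix thresholds to the empty graph", {
  v <- matrix(0.5, 10, 10)
  diag(v) <- 0
  expect_warning(adj <- threshold_adjacency(v, 85), "empty")
  expect_equal(adj$n_edges, 0L)
})

test_that("thresholding is invariant to rank-preserving transforms", {
  set.seed(2)
  v <- matrix(0, 20, 20)
  v[upper.tri(v)] <- runif(190)
  v <- v + t(v)
  a1 <- threshold_adjacency(v, 85)
  a2 <- threshold_adjacency(sqrt(v), 85)
  expect_identical(a1$matrix, a2$matrix)
})

test_that("degree matches hand counts on canonical graphs", {
  k5 <- network_degree(as_adjacency_network(complete_graph(5)))
  expect_equal(k5$degree, rep(4, 5))
  expect_equal(k5$mean_degree_2k, 4)
  c6 <- network_degree(as_adjacency_network(cycle_graph(6)))
  expect_equal(c6$degree, rep(2, 6))
})

test_that("path length matches hand counts on canonical graphs", {
  expect_equal(path_length(as_adjacency_network(complete_graph(5)))$L, 1)
  p3 <- matrix(0L, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1L
  expect_equal(path_length(as_adjacency_network(p3))$L, 4 / 3)
  expect_equal(path_length(as_adjacency_network(cycle_graph(6)))$L, 1.8)
})

test_that("clustering matches hand counts on canonical graphs", {
  expect_equal(clustering_coefficient(
    as_adjacency_network(complete_graph(5)))$C, 1)
  expect_equal(clustering_coefficient(
    as_adjacency_network(cycle_graph(6)))$C, 0)
  tri_pendant <- matrix(0L, 4, 4)
  tri_pendant[1, 2] <- tri_pendant[2, 1] <- 1L
  tri_pendant[1, 3] <- tri_pendant[3, 1] <- 1L
  tri_pendant[2, 3] <- tri_pendant[3, 2] <- 1L
  tri_pendant[3, 4] <- tri_pendant[4, 3] <- 1L
  # nodes: 1, 1, 1/3 (one of three neighbour pairs linked), 0 -> 7/12
  expect_equal(clustering_coefficient(
    as_adjacency_network(tri_pendant))$C, 7 / 12)
  expect_equal(clustering_coefficient(
    as_adjacency_network(tri_pendant))$C_local, c(1, 1, 1 / 3, 0))
})

test_that("disconnected graphs use the finite-pairs rule and set the flag", {
  m <- matrix(0L, 5, 5)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 1L
  pl <- path_length(as_adjacency_network(m))
  expect_true(pl$disconnected)
  expect_equal(pl$L, 1)  # only the two connected pairs count
  empty <- as_adjacency_network(matrix(0L, 4, 4))
  expect_true(is.na(path_length(empty)$L))
})

test_that("metrics are invariant under node relabeling", {
  set.seed(3)
  a <- random_adjacency(15, 30)
  perm <- sample(15)
  b <- a[perm, perm]
  na <- as_adjacency_network(a)
  nb <- as_adjacency_network(b)
  expect_equal(path_length(na)$L, path_length(nb)$L)
  expect_equal(clustering_coefficient(na)$C,
               clustering_coefficient(nb)$C)
  expect_equal(sort(network_degree(na)$degree),
               sort(network_degree(nb)$degree))
})

test_that("omega identities: matched references and complete graphs give zero", {
  expect_equal(small_world_omega(2, 0.5, 2, 0.5), 0)
  expect_equal(small_world_omega(1, 1, 1, 1), 0)
  expect_error(small_world_omega(0, 1, 1, 1), "L_real")
  expect_error(small_world_omega(1, 1, 1, 0), "C_latt")
})

test_that("the complete-graph null ensemble is exactly (1, 1)", {
  nul <- null_ensemble(8, 28, reps = 5, seed = 1, cache = FALSE)
  expect_equal(nul$L_rand, 1)
  expect_equal(nul$C_latt, 1)
})

test_that("a lattice with integer rings has zero ensemble variance", {
  # n = 12, m = 24 -> two complete rings, no leftover edges
  nul <- null_ensemble(12, 24, reps = 10, seed = 2, cache = FALSE)
  expect_equal(nul$C_latt_sd, 0)
})

test_that("null ensemble matches a same-stream brute-force re-implementation", {
  n <- 16
  m <- 40
  reps <- 25
  seed <- 7
  got <- null_ensemble(n, m, reps = reps, seed = seed, cache = FALSE)
  # oracle: identical RNG consumption, naive metric computation
  pt <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ring <- function(d) {
    i <- seq_len(n)
    j <- ((i - 1 + d) %% n) + 1
    unique(cbind(pmin(i, j), pmax(i, j)))
  }
  set.seed(seed)
  L <- C <- numeric(reps)
  for (r in seq_len(reps)) {
    e <- pt[sample.int(nrow(pt), m), , drop = FALSE]
    a <- matrix(0L, n, n)
    a[e] <- 1L
    a[e[, c(2, 1)]] <- 1L
    L[r] <- brute_path_length(a)
    # lattice: full rings then a sampled partial next ring
    full <- m %/% n
    leftover <- m %% n
    edges <- do.call(rbind, lapply(seq_len(full), ring))
    if (leftover > 0) {
      nxt <- ring(full + 1)
      edges <- rbind(edges, nxt[sample.int(nrow(nxt), leftover), ,
                                drop = FALSE])
    }
    al <- matrix(0L, n, n)
    al[edges] <- 1L
    al[edges[, c(2, 1)]] <- 1L
    C[r] <- mean(brute_clustering(al))
  }
  expect_equal(got$L_rand, mean(L), tolerance = 1e-12)
  expect_equal(got$C_latt, mean(C), tolerance = 1e-12)
})

test_that("null ensembles are cached per (n, m, reps, seed)", {
  a <- null_ensemble(20, 60, reps = 8, seed = 3)
  t0 <- Sys.time()
  b <- null_ensemble(20, 60, reps = 8, seed = 3)
  expect_identical(a, b)
  expect_lt(as.numeric(Sys.time() - t0), 0.5)
  expect_error(null_ensemble(10, 60, reps = 5), "exceeds")
})

test_that("subject-level metrics average per-segment omega", {
  set.seed(4)
  v <- matrix(0, 20, 20)
  v[upper.tri(v)] <- runif(190)
  v <- v + t(v)
  one <- subject_condition_metrics(list(v), null_reps = 30, seed = 5)
  rep3 <- subject_condition_metrics(list(v, v, v), null_reps = 30,
                                    seed = 5)
  expect_equal(one$omega, rep3$omega)
  expect_equal(rep3$n_segments, 3L)
  # permuting segment order changes nothing
  set.seed(6)
  vs <- replicate(4, {
    w <- matrix(0, 20, 20)
    w[upper.tri(w)] <- runif(190)
    w + t(w)
  }, simplify = FALSE)
  m1 <- subject_condition_metrics(vs, null_reps = 30, seed = 7)
  m2 <- subject_condition_metrics(rev(vs), null_reps = 30, seed = 7)
  expect_equal(m1$omega, m2$omega)
})

test_that("averaging-first mode thresholds the segment-mean matrix once", {
  set.seed(8)
  vs <- replicate(3, {
    w <- matrix(0, 15, 15)
    w[upper.tri(w)] <- runif(105)
    w + t(w)
  }, simplify = FALSE)
  avg <- Reduce(`+`, vs) / 3
  direct <- subject_condition_metrics(list(avg), null_reps = 30, seed = 9)
  via_flag <- subject_condition_metrics(vs, null_reps = 30, seed = 9,
                                        average_first = TRUE)
  expect_equal(via_flag$omega, direct$omega)
  expect_equal(via_flag$n_segments, 1L)
})

test_that("the degree-preserving random reference keeps the degree sequence", {
  set.seed(10)
  a <- random_adjacency(14, 30)
  adj <- as_adjacency_network(a)
  nul <- null_ensemble(14, 30, reps = 5, seed = 11, cache = FALSE,
                       method = "degree_preserving", real_graph = adj)
  expect_true(is.finite(nul$L_rand))
  expect_gt(nul$L_rand, 1)
})
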
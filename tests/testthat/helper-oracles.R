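# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# Moving-window triplet categorizer: enumerates every window explicitly.
brute_categorize <- function(block, position, direction, trial_class,
                             pattern) {
  succ <- integer(4)
  succ[pattern] <- pattern[c(2, 3, 4, 1)]
  n <- length(direction)
  prob <- rep(NA_character_, n)
  trill <- rep(FALSE, n)
  for (t in seq_len(n)) {
    if (t >= 3 && block[t] == block[t - 1] && block[t] == block[t - 2]) {
      d1 <- direction[t - 2]
      d3 <- direction[t]
      if (trial_class[t] == "pattern" || d3 == succ[d1]) {
        prob[t] <- "high"
      } else {
        prob[t] <- "low"
      }
      trill[t] <- d1 == d3
    }
  }
  list(probability = prob, trill = trill)
}

# Local clustering by explicit triangle enumeration.
brute_clustering <- function(m) {
  n <- nrow(m)
  cl <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(m[i, ] == 1)
    k <- length(nb)
    if (k < 2) {
      cl[i] <- 0
      next
    }
    links <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (b > a && m[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    cl[i] <- 2 * links / (k * (k - 1))
  }
  cl
}

# All-pairs shortest paths by Floyd-Warshall.
brute_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  d[m == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Mean shortest path over ordered pairs with finite distance.
brute_path_length <- function(m) {
  d <- brute_distances(m)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# Random binary graph with exactly m edges.
random_adjacency <- function(n, m) {
  pt <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  e <- pt[sample.int(nrow(pt), m), , drop = FALSE]
  a <- matrix(0L, n, n)
  a[e] <- 1L
  a[e[, c(2, 1), drop = FALSE]] <- 1L
  a
}

# Rank-based AUC of values for a positive/negative labelling.
rank_auc <- function(values, positive) {
  r <- rank(values)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Balanced split-plot (one between, one within factor) ANOVA from the
# textbook sums-of-squares decomposition. y[s, w], group: factor over s.
brute_split_plot <- function(y, group) {
  a <- nlevels(group)
  b <- ncol(y)
  n <- unname(table(group)[1])
  stopifnot(all(table(group) == n))
  grand <- mean(y)
  subj_means <- rowMeans(y)
  cell_ab <- matrix(0, a, b)
  for (g in seq_len(a)) {
    cell_ab[g, ] <- colMeans(y[group == levels(group)[g], , drop = FALSE])
  }
  grp_means <- rowMeans(cell_ab)
  w_means <- colMeans(cell_ab)
  ss_A <- n * b * sum((grp_means - grand)^2)
  ss_SwA <- b * sum((subj_means - grp_means[as.integer(group)])^2)
  ss_B <- a * n * sum((w_means - grand)^2)
  ss_AB <- n * sum((cell_ab - outer(grp_means, rep(1, b)) -
                      outer(rep(1, a), w_means) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_BS <- ss_tot - ss_A - ss_SwA - ss_B - ss_AB
  df_A <- a - 1
  df_SwA <- a * (n - 1)
  df_B <- b - 1
  df_AB <- (a - 1) * (b - 1)
  df_BS <- (b - 1) * a * (n - 1)
  list(
    F_A = (ss_A / df_A) / (ss_SwA / df_SwA),
    F_B = (ss_B / df_B) / (ss_BS / df_BS),
    F_AB = (ss_AB / df_AB) / (ss_BS / df_BS),
    df = c(A = df_A, SwA = df_SwA, B = df_B, AB = df_AB, BS = df_BS),
    eta_A = ss_A / (ss_A + ss_SwA),
    eta_B = ss_B / (ss_B + ss_BS),
    eta_AB = ss_AB / (ss_AB + ss_BS)
  )
}

# A tiny hand-written ASRT stream used across behaviour tests:
# pattern (1,2,3,4), one block of 20 trials.
hand_stream <- function() {
  pos <- 1:20
  is_pattern <- pos >= 6 & pos %% 2 == 0
  data.frame(
    block = rep(1L, 20),
    position = pos,
    trial = pos,
    direction = c(3L, 1L, 4L, 2L, 2L,
                  1L, 3L, 2L, 2L, 3L, 1L, 4L, 4L, 1L, 1L, 2L, 4L, 3L, 3L,
                  4L),
    trial_class = factor(ifelse(is_pattern, "pattern", "random"),
                         levels = c("pattern", "random")),
    cue = ifelse(is_pattern, "black", "red")
  )
}
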
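toy_mixed_data <- function(y, n_per_group = 2) {
  # y: subjects x within-levels matrix, groups in blocks
  n <- nrow(y)
  data.frame(
    subject = rep(seq_len(n), each = ncol(y)),
    group = rep(rep(c("GTS", "HC"), each = n_per_group), each = ncol(y)),
    w = rep(paste0("w", seq_len(ncol(y))), n),
    dv = as.numeric(t(y))
  )
}

test_that("mixed ANOVA matches the textbook split-plot decomposition exactly", {
  y <- matrix(c(12, 15,
                14, 19,
                10, 9,
                11, 12), 4, 2, byrow = TRUE)
  df <- toy_mixed_data(y)
  got <- mixed_anova(df, "dv", "subject", "group", "w")
  ref <- brute_split_plot(y, factor(rep(c("GTS", "HC"), each = 2)))
  expect_equal(got$F[got$effect == "group"], ref$F_A, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "w"], ref$F_B, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "group x w"], ref$F_AB,
               tolerance = 1e-10)
  expect_equal(got$df_num, c(1, 1, 1))
  expect_equal(got$df_den, c(2, 2, 2))
  expect_equal(got$eta_p2[got$effect == "group"], ref$eta_A,
               tolerance = 1e-10)
  expect_equal(got$eta_p2[got$effect == "group x w"], ref$eta_AB,
               tolerance = 1e-10)
})

test_that("mixed ANOVA agrees with the split-plot oracle on random data", {
  set.seed(11)
  for (r in 1:5) {
    y <- matrix(rnorm(10 * 4), 10, 4)
    df <- toy_mixed_data(y, n_per_group = 5)
    got <- mixed_anova(df, "dv", "subject", "group", "w")
    ref <- brute_split_plot(y, factor(rep(c("GTS", "HC"), each = 5)))
    expect_equal(got$F[got$effect == "group"], ref$F_A, tolerance = 1e-8)
    expect_equal(got$F[got$effect == "w"], ref$F_B, tolerance = 1e-8)
    expect_equal(got$F[got$effect == "group x w"], ref$F_AB,
                 tolerance = 1e-8)
  }
})

test_that("constant responses give zero F everywhere", {
  y <- matrix(5, 6, 2)
  df <- toy_mixed_data(y, n_per_group = 3)
  got <- mixed_anova(df, "dv", "subject", "group", "w")
  expect_true(all(got$F == 0))
  expect_true(all(got$P == 1))
})

test_that("partial eta squared satisfies its F/df identity", {
  set.seed(12)
  y <- matrix(rnorm(8 * 4, sd = 2), 8, 4)
  df <- toy_mixed_data(y, n_per_group = 4)
  got <- mixed_anova(df, "dv", "subject", "group", "w")
  expect_equal(got$eta_p2,
               got$F * got$df_num / (got$F * got$df_num + got$df_den),
               tolerance = 1e-10)
})

test_that("between-only designs reduce to the one-way ANOVA", {
  set.seed(13)
  df <- data.frame(subject = 1:12,
                   group = rep(c("GTS", "HC"), each = 6),
                   dv = rnorm(12))
  got <- mixed_anova(df, "dv", "subject", "group")
  tt <- t.test(dv ~ group, data = df, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$P, tt$p.value, tolerance = 1e-10)
  expect_equal(got$df_den, 10)
})

test_that("subjects with missing within cells are dropped with a message", {
  set.seed(14)
  y <- matrix(rnorm(6 * 2), 6, 2)
  df <- toy_mixed_data(y, n_per_group = 3)
  df <- df[!(df$subject == 1 & df$w == "w2"), ]
  expect_message(got <- mixed_anova(df, "dv", "subject", "group", "w"),
                 "dropping 1 subject")
  expect_equal(attr(got, "n_subjects"), 5L)
})

test_that("two within factors reproduce the 2x(2x4) behavioural design shape", {
  set.seed(15)
  df <- expand.grid(subject = 1:10, probability = c("high", "low"),
                    unit = 1:4)
  df$group <- rep(c("GTS", "HC"), each = 5)[df$subject]
  df$dv <- rnorm(nrow(df))
  got <- mixed_anova(df, "dv", "subject", "group",
                     c("probability", "unit"))
  expect_setequal(got$effect,
                  c("group", "probability", "group x probability", "unit",
                    "group x unit", "probability x unit",
                    "group x probability x unit"))
  expect_equal(got$df_den[got$effect == "group x probability"], 8)
  expect_equal(got$df_num[got$effect == "unit"], 3)
  expect_equal(got$df_den[got$effect == "unit"], 24)
})

test_that("post hoc contrasts: identical cells give zero difference, P = 1", {
  df <- expand.grid(subject = 1:6, w = c("a", "b"))
  df$group <- rep(c("GTS", "HC"), each = 3)[df$subject]
  df$dv <- 4
  ph <- posthoc_pairwise(df, "dv", "subject", "group", c("group", "w"))
  expect_true(all(ph$diff == 0))
  expect_true(all(ph$P == 1))
})

test_that("post hoc contrasts recover hand-computed cell means and pairing", {
  df <- expand.grid(subject = 1:6, w = c("a", "b"))
  df$group <- rep(c("GTS", "HC"), each = 3)[df$subject]
  df$dv <- c(1, 2, 3, 10, 11, 12,   # w = a
             4, 5, 6, 10, 11, 12)   # w = b
  ph <- posthoc_pairwise(df, "dv", "subject", "group", c("group", "w"))
  row <- ph[ph$cell_a == "GTS:a" & ph$cell_b == "GTS:b", ]
  expect_equal(row$mean_a, 2)
  expect_equal(row$mean_b, 5)
  expect_equal(row$diff, -3)
  expect_true(row$paired)  # same subjects across within levels
  btw <- ph[ph$cell_a == "GTS:a" & ph$cell_b == "HC:a", ]
  expect_false(btw$paired)
  expect_equal(btw$diff, 2 - 11)
})

test_that("severity correlation matches a rank-based oracle and its t approximation", {
  set.seed(16)
  x <- rnorm(25)
  y <- 0.4 * x + rnorm(25)
  got <- severity_correlation(x, y, "spearman")
  r_oracle <- cor(rank(x), rank(y))
  expect_equal(got$estimate, r_oracle, tolerance = 1e-12)
  expect_equal(got$df, 23L)
  t_oracle <- r_oracle * sqrt(23 / (1 - r_oracle^2))
  expect_equal(got$P, 2 * pt(-abs(t_oracle), 23), tolerance = 1e-12)
  mono <- severity_correlation(1:10, (1:10)^3, "spearman")
  expect_equal(mono$estimate, 1)
  expect_warning(cst <- severity_correlation(rep(1, 10), rnorm(10)),
                 "constant")
  expect_true(is.na(cst$estimate))
  expect_error(severity_correlation(1:3, 1:3), "at least 4")
})

test_that("clinical table has the documented shape and missingness", {
  clin <- gts_clinical_table()
  expect_equal(nrow(clin), 25L)
  expect_equal(sum(!is.na(clin$rush)), 20L)
  expect_equal(sum(!is.na(clin$disease_duration_years)), 24L)
  expect_equal(sum(nzchar(clin$medication)), 13L)
})

test_that("sensitivity rerun with no medicated subjects reproduces the full analysis", {
  set.seed(17)
  df <- expand.grid(subject = 1:10, w = c("a", "b"))
  df$group <- rep(c("GTS", "HC"), each = 5)[df$subject]
  df$dv <- rnorm(nrow(df))
  info <- data.frame(subject = 1:10,
                     group = rep(c("GTS", "HC"), each = 5),
                     medicated = FALSE)
  fn <- function(d) mixed_anova(d, "dv", "subject", "group", "w")
  out <- sensitivity_rerun(df, info, fn)
  expect_equal(out$full, out$reduced)
  expect_length(out$excluded, 0)
})

test_that("an effect carried by medicated subjects attenuates in the rerun", {
  set.seed(18)
  n <- 16
  df <- expand.grid(subject = seq_len(n), w = c("a", "b"))
  df$group <- rep(c("GTS", "HC"), each = n / 2)[df$subject]
  medicated <- df$subject <= 4  # first four GTS subjects
  df$dv <- rnorm(nrow(df), sd = 0.3) +
    ifelse(medicated & df$group == "GTS" & df$w == "b", 3, 0)
  info <- data.frame(subject = seq_len(n),
                     group = rep(c("GTS", "HC"), each = n / 2),
                     medicated = seq_len(n) <= 4,
                     matched_to = c(rep(NA, n / 2), seq_len(n / 2)))
  fn <- function(d) mixed_anova(d, "dv", "subject", "group", "w")
  out <- sensitivity_rerun(df, info, fn)
  expect_setequal(out$excluded, c(1:4, 9:12))
  F_full <- out$full$F[out$full$effect == "group x w"]
  F_red <- out$reduced$F[out$reduced$effect == "group x w"]
  expect_gt(F_full, F_red)
  # deterministic under fixed input
  expect_equal(out$reduced, sensitivity_rerun(df, info, fn)$reduced)
})

test_that("sensitivity rerun refuses too-small reduced samples", {
  df <- expand.grid(subject = 1:6, w = c("a", "b"))
  df$group <- rep(c("GTS", "HC"), each = 3)[df$subject]
  df$dv <- rnorm(nrow(df))
  info <- data.frame(subject = 1:6,
                     group = rep(c("GTS", "HC"), each = 3),
                     medicated = c(TRUE, TRUE, FALSE, rep(FALSE, 3)),
                     matched_to = c(NA, NA, NA, 1, 2, 3))
  fn <- function(d) mixed_anova(d, "dv", "subject", "group", "w")
  expect_error(sensitivity_rerun(df, info, fn), "min_per_group")
})
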
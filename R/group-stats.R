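# Mixed-design ANOVAs with partial eta squared, post hoc contrasts,
# severity correlations, the medication-free sensitivity rerun and the
# clinical characteristics fixture.

#' Mixed-design ANOVA with partial eta squared
#'
#' Fits a mixed-design (split-plot) ANOVA with one between-subjects factor
#' and any number of fully crossed within-subjects factors, using Type-III
#' sums of squares and the univariate (sphericity-assumed) mixed-model
#' tables, as is conventional for these designs. Supports the 2x(2x4)
#' behavioural design, the 2x2 resting design and the 2x(2x2) task design.
#' Subjects with missing within-subject cells are dropped with a message.
#' Replicated observations within a subject/cell are averaged first.
#'
#' Partial eta squared is computed as `SS_effect / (SS_effect + SS_error)`,
#' identical to `F * df_num / (F * df_num + df_den)`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param between Name of the between-subjects factor (or `NULL` for a
#'   within-only design).
#' @param within Character vector of within-subjects factor names (possibly
#'   empty).
#' @return A data frame of class `anova_result` with columns `effect`, `F`,
#'   `df_num`, `df_den`, `P` and `eta_p2`.
#' @examples
#' df <- expand.grid(subject = 1:8, probability = c("high", "low"))
#' df$group <- rep(c("GTS", "HC"), each = 4)[df$subject]
#' set.seed(1); df$score <- rnorm(nrow(df))
#' mixed_anova(df, "score", "subject", "group", "probability")
#' @export
mixed_anova <- function(data, dv, subject, between = NULL,
                        within = character()) {
  data <- as.data.frame(data)
  for (v in c(dv, subject, between, within)) {
    if (!v %in% names(data)) {
      stop(sprintf("column '%s' not found in `data`", v), call. = FALSE)
    }
  }
  data[[subject]] <- factor(data[[subject]])
  if (!is.null(between)) {
    data[[between]] <- factor(data[[between]])
    if (min(table(unique(data[, c(subject, between)])[[between]])) < 2) {
      stop("need at least 2 subjects per group", call. = FALSE)
    }
  }
  for (w in within) {
    data[[w]] <- factor(data[[w]])
  }
  constant <- vapply(within, function(w) nlevels(data[[w]]) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant within-subject factor(s): ",
            paste(within[constant], collapse = ", "))
    within <- within[!constant]
  }

  if (length(within) == 0L) {
    return(between_only_anova(data, dv, subject, between))
  }

  # cell means per subject x within combination
  cells <- do.call(expand.grid, c(lapply(within, function(w)
    levels(data[[w]])), list(KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = TRUE)))
  names(cells) <- within
  cell_key <- interaction(cells, drop = FALSE, lex.order = FALSE)
  data_key <- interaction(data[within], drop = FALSE, lex.order = FALSE)
  agg <- tapply(data[[dv]], list(data[[subject]], data_key), mean)
  agg <- agg[, as.character(cell_key), drop = FALSE]
  complete <- stats::complete.cases(agg)
  if (any(!complete)) {
    message(sprintf("dropping %d subject(s) with missing cells: %s",
                    sum(!complete),
                    paste(rownames(agg)[!complete], collapse = ", ")))
    agg <- agg[complete, , drop = FALSE]
  }
  subj_tab <- unique(data[, c(subject, between), drop = FALSE])
  rownames(subj_tab) <- as.character(subj_tab[[subject]])
  subj_tab <- subj_tab[rownames(agg), , drop = FALSE]

  rhs <- if (is.null(between)) "1" else between
  contr <- if (is.null(between)) NULL else {
    stats::setNames(list("contr.sum"), between)
  }
  mod <- stats::lm(stats::as.formula(paste("agg ~", rhs)), data = subj_tab,
                   contrasts = contr)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = cells, idesign = idesign, type = 3)
  # sphericity epsilons are not consumed here; silence HF eps > 1 notes
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  tab <- s$univariate.tests
  eff <- rownames(tab)
  keep <- eff != "(Intercept)"
  res <- data.frame(
    effect = pretty_effect(eff[keep]),
    F = as.numeric(tab[keep, "F value"]),
    df_num = as.numeric(tab[keep, "num Df"]),
    df_den = as.numeric(tab[keep, "den Df"]),
    P = as.numeric(tab[keep, "Pr(>F)"]),
    eta_p2 = as.numeric(tab[keep, "Sum Sq"] /
                          (tab[keep, "Sum Sq"] + tab[keep, "Error SS"])),
    row.names = NULL
  )
  res <- zero_variance_effects(
    res, ss = as.numeric(tab[keep, "Sum Sq"] + tab[keep, "Error SS"]),
    scale = mean(agg)^2
  )
  class(res) <- c("anova_result", "data.frame")
  attr(res, "n_subjects") <- nrow(agg)
  res
}

# an all-constant dv gives 0/0 sums of squares (up to rounding noise);
# such effects are reported as F = 0, P = 1
zero_variance_effects <- function(res, ss = NULL, scale = 1) {
  degen <- !is.finite(res$F)
  if (!is.null(ss)) {
    degen <- degen | ss < 1e-10 * max(1, scale)
  }
  res$F[degen] <- 0
  res$P[degen] <- 1
  res$eta_p2[degen] <- 0
  res
}

between_only_anova <- function(data, dv, subject, between) {
  agg <- tapply(data[[dv]], data[[subject]], mean)
  subj_tab <- unique(data[, c(subject, between), drop = FALSE])
  rownames(subj_tab) <- as.character(subj_tab[[subject]])
  subj_tab <- subj_tab[names(agg), , drop = FALSE]
  y <- as.numeric(agg)
  g <- subj_tab[[between]]
  fit <- stats::lm(y ~ g, contrasts = list(g = "contr.sum"))
  an <- stats::anova(fit)
  res <- data.frame(
    effect = between,
    F = an[1, "F value"],
    df_num = an[1, "Df"],
    df_den = an[2, "Df"],
    P = an[1, "Pr(>F)"],
    eta_p2 = an[1, "Sum Sq"] / (an[1, "Sum Sq"] + an[2, "Sum Sq"]),
    row.names = NULL
  )
  res <- zero_variance_effects(res, ss = an[1, "Sum Sq"] + an[2, "Sum Sq"],
                               scale = mean(y)^2)
  class(res) <- c("anova_result", "data.frame")
  attr(res, "n_subjects") <- length(y)
  res
}

pretty_effect <- function(x) {
  gsub(":", " x ", x, fixed = TRUE)
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed-design ANOVA (Type III, univariate)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s F(%g,%g) = %.3f, P = %.4g, eta_p2 = %.3f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$P[i],
                x$eta_p2[i]))
  }
  invisible(x)
}

#' Post hoc pairwise contrasts for an interaction
#'
#' Cell-wise pairwise comparisons following a significant interaction:
#' within-subject contrasts use paired t-tests over the common subjects,
#' between-group contrasts independent-sample t-tests on the subject cell
#' means. P values are uncorrected (Fisher-LSD convention); pass a
#' `p.adjust` method to correct them.
#'
#' @param data Long-format data frame (as for [mixed_anova()]).
#' @param dv,subject,between Column names.
#' @param factors Character vector of factor names (between and/or within)
#'   whose crossing defines the cells to compare.
#' @param adjust Multiple-comparison correction passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return Data frame with one row per cell pair: cell labels, cell means,
#'   difference, `t`, `df`, `P` and `paired`.
#' @export
posthoc_pairwise <- function(data, dv, subject, between = NULL,
                             factors, adjust = "none") {
  data <- as.data.frame(data)
  data[[subject]] <- factor(data[[subject]])
  cell <- interaction(data[factors], drop = TRUE, sep = ":")
  agg <- tapply(data[[dv]], list(data[[subject]], cell), mean)
  cells <- colnames(agg)
  if (!is.null(between)) {
    subj_group <- unique(data[, c(subject, between)])
    grp <- stats::setNames(as.character(subj_group[[between]]),
                           as.character(subj_group[[subject]]))[rownames(agg)]
  }
  rows <- list()
  for (i in seq_along(cells)) {
    for (j in seq_along(cells)) {
      if (j <= i) next
      a <- agg[, i]
      b <- agg[, j]
      both <- !is.na(a) & !is.na(b)
      if (sum(both) >= 3) {
        # subjects observed in both cells: paired (within-subject) contrast
        tt <- safe_t_test(a[both], b[both], paired = TRUE)
        paired <- TRUE
      } else if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
        tt <- safe_t_test(a[!is.na(a)], b[!is.na(b)], paired = FALSE)
        paired <- FALSE
      } else {
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_a = cells[i], cell_b = cells[j],
        mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
        diff = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
        t = unname(tt$statistic), df = unname(tt$parameter),
        P = tt$p.value, paired = paired
      )
    }
  }
  out <- do.call(rbind, rows)
  out$P <- stats::p.adjust(out$P, method = adjust)
  rownames(out) <- NULL
  out
}

# t.test that degrades gracefully on zero-variance cells: identical cells
# give t = 0, P = 1 instead of an error.
safe_t_test <- function(a, b, paired) {
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    d <- mean(a) - mean(b)
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    return(list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
                parameter = c(df = df),
                p.value = if (d == 0) 1 else 0))
  }
  if (paired) {
    stats::t.test(a, b, paired = TRUE)
  } else {
    stats::t.test(a, b, var.equal = TRUE)
  }
}

#' Correlation of learning scores with symptom severity
#'
#' Spearman (default) or Pearson correlation with `df = n - 2`; the P value
#' of the Spearman coefficient uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`, the convention of the statistics
#' packages this analysis mirrors.
#'
#' @param scores Numeric vector of per-subject scores.
#' @param severity Numeric vector of severity values, aligned with
#'   `scores`.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `estimate`, `df`, `P`, `n` and `method`.
#' @export
severity_correlation <- function(scores, severity,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(scores) & is.finite(severity)
  x <- scores[ok]
  y <- severity[ok]
  n <- length(x)
  if (n < 4) {
    stop("need at least 4 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(list(estimate = NA_real_, df = n - 2L, P = NA_real_, n = n,
                method = method))
  }
  r <- if (method == "spearman") {
    stats::cor(rank(x), rank(y))
  } else {
    stats::cor(x, y)
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(estimate = r, df = n - 2L, P = p, n = n, method = method)
}

#' Medication-free sensitivity rerun
#'
#' Re-executes an analysis after excluding medicated patients and their
#' matched controls, and reports which effects changed significance class
#' (significant at `alpha`, trend below `trend`, or neither).
#'
#' @param data Long-format data frame with a subject column.
#' @param subject_info Data frame with one row per subject: the subject
#'   column, `medicated` (logical) and optionally `matched_to` (subject id
#'   of the case a control is matched to; controls matched to a medicated
#'   case are excluded with them).
#' @param analysis_fn Function taking a (reduced) data frame and returning
#'   an `anova_result`.
#' @param subject Name of the subject column.
#' @param min_per_group Smallest admissible group size after exclusion.
#' @param group Name of the group column in `subject_info` (used for the
#'   size check when present).
#' @param alpha,trend Significance and trend thresholds.
#' @return List with `full`, `reduced`, `excluded` (subject ids) and
#'   `changed` (effects whose significance class differs).
#' @export
sensitivity_rerun <- function(data, subject_info, analysis_fn,
                              subject = "subject", min_per_group = 3L,
                              group = "group", alpha = 0.05, trend = 0.10) {
  stopifnot(subject %in% names(subject_info),
            "medicated" %in% names(subject_info))
  med_ids <- subject_info[[subject]][subject_info$medicated %in% TRUE]
  excl <- med_ids
  if ("matched_to" %in% names(subject_info)) {
    excl <- union(excl, subject_info[[subject]][
      subject_info$matched_to %in% med_ids])
  }
  keep_info <- subject_info[!subject_info[[subject]] %in% excl, ,
                            drop = FALSE]
  if (group %in% names(keep_info)) {
    if (any(table(keep_info[[group]]) < min_per_group)) {
      stop("fewer than `min_per_group` subjects per group after exclusion",
           call. = FALSE)
    }
  }
  full <- analysis_fn(data)
  reduced_data <- data[!data[[subject]] %in% excl, , drop = FALSE]
  reduced <- analysis_fn(reduced_data)
  cls <- function(p) ifelse(p < alpha, "significant",
                            ifelse(p < trend, "trend", "ns"))
  changed <- full$effect[cls(full$P) != cls(reduced$P)]
  list(full = full, reduced = reduced, excluded = excl, changed = changed)
}

#' Clinical characteristics of the patient group
#'
#' Loads the packaged per-patient clinical table (age, sex, disease
#' duration, diagnostic confidence index, tic severity on the YGTSS and
#' modified Rush scales, comorbidities, medication). One disease-duration
#' entry is approximate in the source and is stored as missing; the Rush
#' score is available for 20 of the 25 patients.
#'
#' @return Data frame with 25 rows.
#' @export
gts_clinical_table <- function() {
  path <- system.file("extdata", "gts_clinical_table.csv",
                      package = "asrtnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Column means of a clinical table
#'
#' Means over available (non-missing) values for every numeric column.
#'
#' @param clinical A data frame such as [gts_clinical_table()].
#' @return Named numeric vector of column means.
#' @export
clinical_descriptives <- function(clinical) {
  num <- vapply(clinical, is.numeric, logical(1))
  if (!any(num)) {
    stop("no numeric columns", call. = FALSE)
  }
  vapply(clinical[num], function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}
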
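# Group-comparison statistics for the cohort demographics table:
# Pearson chi-square on categorical counts, one-way ANOVA (raw data or
# published summary statistics), and Kruskal-Wallis. These reproduce the
# printed table statistics from a subjects table or from the published
# group summaries alone.

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic without continuity correction (the convention that
#' reproduces published multi-group demographic tables; Yates' correction
#' applies only to 2x2 tables and is not used here).
#'
#' @param counts Integer matrix of non-negative counts, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' sex <- rbind(m = c(5, 7, 8, 3), f = c(11, 28, 10, 4))
#' chi_square(sex)$statistic  # ~ 3.996
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("chi_square: table must be at least 2x2", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("chi_square: counts must be non-negative and finite", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi_square: zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' One-way ANOVA from raw group data
#'
#' @param groups List of numeric vectors, one per group (each length >= 2).
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("anova_oneway: need a list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("anova_oneway: every group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (all(vapply(groups, stats::var, 1) == 0))
    stop("anova_oneway: zero within-group variance in all groups", call. = FALSE)
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df1 = unname(fit$parameter[1L]), df2 = unname(fit$parameter[2L]),
       p_value = unname(fit$p.value))
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the F test from per-group sample sizes, means, and SDs — the
#' only inputs a published demographics table provides. Algebraically
#' identical to [anova_oneway()] on any raw data with the same summaries.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param means Numeric vector of group means.
#' @param sds Numeric vector of group standard deviations.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' anova_from_summary(c(16, 35, 18, 7),
#'                    c(66.63, 65.91, 66.22, 64.57),
#'                    c(4.559, 4.161, 5.264, 5.192))$F  # ~ 0.34
anova_from_summary <- function(n, means, sds) {
  k <- length(n)
  if (k < 2L || length(means) != k || length(sds) != k)
    stop("anova_from_summary: n, means, sds must have equal length >= 2",
         call. = FALSE)
  if (any(n < 2L)) stop("anova_from_summary: every group needs n >= 2", call. = FALSE)
  if (any(sds < 0)) stop("anova_from_summary: negative SD", call. = FALSE)
  N <- sum(n)
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum((n - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, df1 = df1, df2 = df2,
       p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square approximation on k - 1 df. If all
#' pooled values are identical, H is defined as 0 with a warning.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis: need a list of >= 2 groups", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  if (length(y) < 5L)
    stop("kruskal_wallis: total n must be >= 5", call. = FALSE)
  k <- length(groups)
  if (length(unique(y)) == 1L) {
    warning("kruskal_wallis: all observations identical; H defined as 0")
    return(list(H = 0, df = k - 1L, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(y, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value))
}

#' Demographics summary table for a synthetic cohort
#'
#' Builds a demographics-and-cognition comparison table across groups:
#' chi-square for sex/hypertension/diabetes counts, one-way ANOVA for age,
#' and Kruskal-Wallis for education and each cognitive score.
#'
#' @param subjects Data frame with columns `group`, `sex`, `hypertension`,
#'   `diabetes`, `age`, `education`, and cognitive score columns.
#' @param scores Character vector of cognitive score column names.
#' @return Data frame with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p_value`.
#' @export
cohort_stats_table <- function(subjects,
                               scores = c("MMSE", "MoCA", "BNT", "CDT",
                                          "BDST", "TMT_A", "TMT_B")) {
  need <- c("group", "sex", "hypertension", "diabetes", "age", "education")
  missing_cols <- setdiff(c(need, scores), names(subjects))
  if (length(missing_cols))
    stop("cohort_stats_table: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  grp <- factor(subjects$group, levels = unique(subjects$group))
  rows <- list()
  for (v in c("sex", "hypertension", "diabetes")) {
    tab <- table(factor(subjects[[v]], levels = c(1, 0)), grp)
    cs <- chi_square(as.matrix(tab))
    rows[[v]] <- data.frame(variable = v, test = "chi-square",
                            statistic = cs$statistic, df = cs$df,
                            p_value = cs$p_value)
  }
  ag <- anova_oneway(split(subjects$age, grp))
  rows$age <- data.frame(variable = "age", test = "anova",
                         statistic = ag$F, df = ag$df1, p_value = ag$p_value)
  for (v in c("education", scores)) {
    kw <- kruskal_wallis(split(subjects[[v]], grp))
    rows[[v]] <- data.frame(variable = v, test = "kruskal-wallis",
                            statistic = kw$H, df = kw$df, p_value = kw$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
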
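#' Two-group one-way ANOVA F test
#'
#' One-way ANOVA for exactly two groups: `F = MS_between / MS_within`
#' with degrees of freedom `(1, n1 + n2 - 2)` and an upper-tail p-value.
#' Degenerate fragments are clamped: when the within-group mean square
#' is zero, `F = 0, p = 1` if the group means are equal, else `p = 0`
#' (an infinitely strong separation).
#'
#' For two groups the F statistic equals the square of the pooled
#' two-sample t statistic.
#'
#' @param values_group1,values_group2 Numeric methylation values (each
#'   of length >= 2 after filtering).
#' @return List with `f_statistic`, `df` (between, within), `p_value`.
#' @export
anova_f <- function(values_group1, values_group2) {
  g1 <- values_group1[!is.na(values_group1)]
  g2 <- values_group2[!is.na(values_group2)]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least two values")
  }
  n1 <- length(g1); n2 <- length(g2)
  m1 <- mean(g1); m2 <- mean(g2)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ss_b <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ss_w <- sum((g1 - m1)^2) + sum((g2 - m2)^2)
  df_b <- 1L
  df_w <- n1 + n2 - 2L
  ms_w <- ss_w / df_w
  if (ms_w == 0) {
    # means compared with a tolerance: 0.1 etc. are not exact in binary
    if (abs(m1 - m2) < 1e-9 * (1 + abs(grand))) {
      return(list(f_statistic = 0, df = c(df_b, df_w), p_value = 1))
    }
    return(list(f_statistic = Inf, df = c(df_b, df_w), p_value = 0))
  }
  f <- (ss_b / df_b) / ms_w
  list(
    f_statistic = f, df = c(df_b, df_w),
    p_value = pf(f, df_b, df_w, lower.tail = FALSE)
  )
}

# Row-vectorised two-group ANOVA over a fragments x samples matrix.
# NA cells are missing observations; rows with < 2 values in either
# group get NA statistics.
.row_anova <- function(meth, is_g1, is_g2) {
  x1 <- meth[, is_g1, drop = FALSE]
  x2 <- meth[, is_g2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ss_b <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  df_w <- n1 + n2 - 2
  ms_w <- (ss1 + ss2) / df_w
  f <- (ss_b / 1) / ms_w
  p <- pf(f, 1, df_w, lower.tail = FALSE)
  # clamps for zero within-group variance (mean equality with tolerance)
  zero_w <- ms_w == 0
  eq <- abs(m1 - m2) < 1e-9 * (1 + abs(grand))
  f[zero_w & eq] <- 0
  p[zero_w & eq] <- 1
  f[zero_w & !eq] <- Inf
  p[zero_w & !eq] <- 0
  bad <- n1 < 2 | n2 < 2
  f[bad] <- NA_real_
  p[bad] <- NA_real_
  data.frame(
    n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
    f_statistic = f, df_within = df_w, p_value = p
  )
}

#' Bonferroni-adjusted p-value cutoff
#'
#' @param family_alpha Family-wise error level (default 0.05).
#' @param n_tests Number of tests in the family (>= 1).
#' @return The adjusted per-test cutoff `family_alpha / n_tests`.
#' @examples
#' bonferroni_cutoff(0.05, 32163)  # ~1.55e-6
#' @export
bonferroni_cutoff <- function(family_alpha = 0.05, n_tests) {
  if (n_tests < 1L) {
    stop("`n_tests` must be >= 1")
  }
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("`family_alpha` must lie in (0, 1)")
  }
  family_alpha / n_tests
}

#' Call differentially methylated fragments (DMFs)
#'
#' For each comparison fragment, a two-group one-way ANOVA is computed
#' from the contributing (coverage-filter-passing) samples.  A fragment
#' is a DMF when its p-value is at or below the Bonferroni-adjusted
#' cutoff (`family_alpha` over the number of comparison fragments) AND
#' the absolute difference in group mean methylation is at least
#' `min_diff`.  Direction is relative to the test group: `hypo` when the
#' test group's mean is lower than the reference group's.
#'
#' @param cs A [build_comparison_set()] object.
#' @param fmm The [fragment_meth_matrix()] the set was built from.
#' @param test_group,reference_group Group labels; default: the second
#'   and first group of the comparison set.
#' @param min_diff Minimum absolute group-mean difference (in (0, 1\]).
#' @param family_alpha Family-wise error level for Bonferroni control.
#' @return An object of class `"dmf_result"`: list with `table` (one row
#'   per comparison fragment: fragment_id, mean_reference, mean_test,
#'   difference = test - reference, f_statistic, p_value, passes_alpha,
#'   is_dmf, direction) and `summary` (n_tests, adjusted_cutoff,
#'   n_passed_alpha, n_dmf, n_hypo, n_hyper, group labels).
#' @export
call_dmfs <- function(cs, fmm, test_group = NULL, reference_group = NULL,
                      min_diff = 0.25, family_alpha = 0.05) {
  if (length(cs$fragment_ids) == 0L) {
    stop("comparison set is empty")
  }
  if (min_diff <= 0 || min_diff > 1) {
    stop("`min_diff` must lie in (0, 1]")
  }
  if (is.null(test_group)) test_group <- cs$groups[2]
  if (is.null(reference_group)) {
    reference_group <- setdiff(cs$groups, test_group)
  }
  stopifnot(
    test_group %in% cs$groups, reference_group %in% cs$groups,
    test_group != reference_group
  )
  meth <- fmm$meth[cs$fragment_ids, names(cs$design), drop = FALSE]
  meth[!cs$contributing] <- NA_real_
  av <- .row_anova(meth, cs$design == reference_group,
                   cs$design == test_group)
  n_tests <- length(cs$fragment_ids)
  cutoff <- bonferroni_cutoff(family_alpha, n_tests)
  difference <- av$mean2 - av$mean1
  passes_alpha <- !is.na(av$p_value) & av$p_value <= cutoff
  is_dmf <- passes_alpha & abs(difference) >= min_diff
  direction <- ifelse(!is_dmf, "none",
                      ifelse(difference < 0, "hypo", "hyper"))
  tab <- data.frame(
    fragment_id = cs$fragment_ids,
    n_reference = av$n1, n_test = av$n2,
    mean_reference = av$mean1, mean_test = av$mean2,
    difference = difference,
    f_statistic = av$f_statistic, p_value = av$p_value,
    passes_alpha = passes_alpha, is_dmf = is_dmf,
    direction = direction,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      table = tab,
      summary = list(
        reference_group = reference_group, test_group = test_group,
        n_tests = n_tests, family_alpha = family_alpha,
        adjusted_cutoff = cutoff,
        n_passed_alpha = sum(passes_alpha),
        n_dmf = sum(is_dmf),
        n_hypo = sum(direction == "hypo"),
        n_hyper = sum(direction == "hyper"),
        min_diff = min_diff
      )
    ),
    class = "dmf_result"
  )
}

#' @export
print.dmf_result <- function(x, ...) {
  s <- x$summary
  cat("DMF calling:", s$test_group, "vs", s$reference_group, "\n")
  cat(sprintf("  %d comparison fragments; adjusted cutoff %.3g\n",
              s$n_tests, s$adjusted_cutoff))
  cat(sprintf("  %d passed alpha; %d DMFs (|diff| >= %.2f): %d hypo, %d hyper\n",
              s$n_passed_alpha, s$n_dmf, s$min_diff, s$n_hypo, s$n_hyper))
  invisible(x)
}
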
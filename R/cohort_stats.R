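#' Nonparametric cohort statistics
#'
#' Thin, contract-checked wrappers around the classical nonparametric tests
#' used to relate imaging metrics to clinical covariates: Spearman rank
#' correlation, Wilcoxon rank-sum and signed-rank tests, Kruskal-Wallis,
#' Pearson chi-square association and Cohen's kappa. Every function returns
#' a one-row `stat_result` data.frame with a common column layout so results
#' can be stacked into panels. Ties are handled by midranks; exact p-values
#' are used for the rank tests up to n = 25 (without ties), the tie-corrected
#' normal/chi-square approximation otherwise. Missing values are removed
#' pairwise, and the n actually used is reported.
#'
#' @name cohort_stats
NULL

stat_result <- function(test, statistic, estimate = NA_real_, p_value, n,
                        groups = NA_character_, note = NA_character_,
                        alpha = 0.05) {
  data.frame(test = test, statistic = as.numeric(statistic),
             estimate = as.numeric(estimate), p_value = as.numeric(p_value),
             n = as.integer(n), groups = groups,
             significant = !is.na(p_value) && p_value < alpha,
             note = note, stringsAsFactors = FALSE)
}

drop_pairwise_na <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep])
}

#' @rdname cohort_stats
#' @param x,y Paired numeric vectors.
#' @return A one-row `stat_result` data.frame: `test`, `statistic`,
#'   `estimate` (r, kappa, median difference... as applicable), `p_value`,
#'   `n`, `groups`, `significant` (at alpha = 0.05), `note`.
#' @export
spearman <- function(x, y) {
  d <- drop_pairwise_na(x, y)
  if (length(d$x) < 3L)
    stop("Spearman correlation needs at least 3 complete pairs",
         call. = FALSE)
  if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0)
    stop("undefined correlation: constant input vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(d$x, d$y, method = "spearman",
                                         alternative = "two.sided"))
  stat_result("spearman", ct$statistic, ct$estimate, ct$p.value,
              length(d$x))
}

#' @rdname cohort_stats
#' @param values Numeric outcomes.
#' @param group Two-level grouping vector parallel to `values`.
#' @export
two_group_compare <- function(values, group) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group)[keep]
  lv <- sort(unique(group))
  if (length(lv) != 2L)
    stop(sprintf("two_group_compare needs exactly 2 groups, got %d",
                 length(lv)), call. = FALSE)
  a <- values[group == lv[1]]; b <- values[group == lv[2]]
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact(a, b),
                                            correct = FALSE))
  stat_result("wilcoxon_rank_sum", wt$statistic,
              stats::median(a) - stats::median(b), wt$p.value,
              length(values),
              groups = sprintf("%s (n=%d, med=%g) vs %s (n=%d, med=%g)",
                               lv[1], length(a), stats::median(a),
                               lv[2], length(b), stats::median(b)))
}

use_exact <- function(a, b = NULL) {
  vals <- c(a, b)
  length(vals) <= 25L && !any(duplicated(vals))
}

#' @rdname cohort_stats
#' @param before,after Paired numeric vectors (same patients, two
#'   timepoints). Zero differences are dropped, as in the classical
#'   signed-rank procedure.
#' @export
paired_compare <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must be paired (equal length)",
         call. = FALSE)
  keep <- is.finite(before) & is.finite(after)
  before <- before[keep]; after <- after[keep]
  diffs <- after - before
  if (all(diffs == 0))
    stop("degenerate paired comparison: all differences are zero",
         call. = FALSE)
  nz <- diffs[diffs != 0]
  if (length(nz) <= 25L) {
    # exact sign-flip null with midranks (handles tied |differences|,
    # which wilcox.test's exact path refuses)
    rk2 <- round(2 * rank(abs(nz)))            # doubled midranks: integers
    v_obs <- sum(rk2[nz > 0])
    tot <- sum(rk2)
    pmf <- c(1, numeric(tot))                  # P(V2 = 0..tot), start at 0
    for (r in rk2) {
      shifted <- c(numeric(r), pmf[seq_len(tot + 1L - r)])
      pmf <- (pmf + shifted) / 2
    }
    dev <- abs(seq(0L, tot) - tot / 2)
    p <- min(1, sum(pmf[dev >= abs(v_obs - tot / 2) - 1e-9]))
    stat <- sum(rank(abs(nz))[nz > 0])
  } else {
    wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                              correct = FALSE,
                                              exact = FALSE))
    p <- wt$p.value
    stat <- unname(wt$statistic)
  }
  stat_result("wilcoxon_signed_rank", stat, stats::median(diffs),
              p, length(diffs),
              note = sprintf("%d zero differences dropped",
                             sum(diffs == 0)))
}

#' @rdname cohort_stats
#' @export
kruskal_wallis <- function(values, group) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- factor(as.character(group)[keep])
  if (nlevels(group) < 2L)
    stop("Kruskal-Wallis needs at least 2 groups", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate Kruskal-Wallis: all values identical", call. = FALSE)
  kt <- stats::kruskal.test(values, group)
  stat_result("kruskal_wallis", kt$statistic, NA_real_, kt$p.value,
              length(values),
              groups = paste(levels(group), collapse = " | "))
}

#' @rdname cohort_stats
#' @param table 2-D contingency table of nonnegative counts.
#' @param correct Apply Yates continuity correction (default `FALSE`,
#'   plain Pearson statistic).
#' @export
chi_square_association <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (length(dim(table)) != 2L || any(table < 0) || any(!is.finite(table)))
    stop("`table` must be a 2-D matrix of nonnegative counts",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero-margin row or column",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  res <- stat_result("chi_square", ct$statistic, NA_real_, ct$p.value,
                     sum(table),
                     note = sprintf("df = %d", ct$parameter))
  attr(res, "expected") <- ct$expected
  res
}

#' @rdname cohort_stats
#' @param ratings_a,ratings_b Equal-length categorical vectors from two
#'   raters over a shared category set.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length", call. = FALSE)
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- as.character(ratings_a)[keep]; b <- as.character(ratings_b)[keep]
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  if (n == 0L) stop("no complete rating pairs", call. = FALSE)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-12)
    stop("degenerate kappa: both raters constant on the same category",
         call. = FALSE)
  kappa <- (p_o - p_e) / (1 - p_e)
  # large-sample SE (Cohen 1960) for a normal-approximation p against 0
  se0 <- sqrt(p_e / (n * (1 - p_e)))
  z <- kappa / se0
  stat_result("cohens_kappa", z, kappa,
              2 * stats::pnorm(-abs(z)), n,
              note = sprintf("%d categories", length(lev)))
}

#' Run a panel of pairwise association tests over a cohort table
#'
#' Evaluates one test per requested variable pair on a long-format cohort
#' table. Duplicate pairs are deduplicated with a warning. Significance is
#' flagged at the stated alpha without any multiplicity adjustment (the
#' descriptive-analysis convention this pipeline mirrors).
#'
#' @param cohort Data.frame with the named variables as columns.
#' @param panel Data.frame with columns `var1`, `var2`, `test`; `test` is
#'   one of "spearman", "wilcoxon_rank_sum" (var2 = 2-level group),
#'   "kruskal_wallis" (var2 = group) or "chi_square" (both categorical).
#' @param alpha Significance level, default 0.05.
#' @return `stat_result` rows stacked into one data.frame, with `var1`,
#'   `var2` prepended; empty panel gives an empty data.frame.
#' @export
run_panel <- function(cohort, panel, alpha = 0.05) {
  cols <- c("var1", "var2", "test")
  if (!all(cols %in% names(panel)))
    stop("panel must have columns var1, var2, test", call. = FALSE)
  if (nrow(panel) == 0L)
    return(data.frame(var1 = character(), var2 = character(),
                      test = character(), statistic = numeric(),
                      estimate = numeric(), p_value = numeric(),
                      n = integer(), groups = character(),
                      significant = logical(), note = character(),
                      stringsAsFactors = FALSE))
  dup <- duplicated(panel[cols])
  if (any(dup)) {
    warning(sprintf("%d duplicate panel entries removed", sum(dup)),
            call. = FALSE)
    panel <- panel[!dup, , drop = FALSE]
  }
  missing_vars <- setdiff(unique(c(panel$var1, panel$var2)), names(cohort))
  if (length(missing_vars))
    stop("unknown cohort variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    v1 <- cohort[[panel$var1[i]]]; v2 <- cohort[[panel$var2[i]]]
    res <- switch(panel$test[i],
      spearman = spearman(v1, v2),
      wilcoxon_rank_sum = two_group_compare(v1, v2),
      kruskal_wallis = kruskal_wallis(v1, v2),
      chi_square = chi_square_association(table(v1, v2)),
      stop("unknown test in panel: ", panel$test[i], call. = FALSE))
    res$significant <- !is.na(res$p_value) && res$p_value < alpha
    cbind(data.frame(var1 = panel$var1[i], var2 = panel$var2[i],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
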
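#' One-way ANOVA across named groups
#'
#' Classical fixed-effects one-way analysis of variance:
#' `F = MS_between / MS_within` with the p-value from the F distribution
#' on (groups - 1, N - groups) degrees of freedom (equal variances
#' assumed, as in the standard textbook procedure).
#'
#' @param groups Named list of numeric vectors, one per group; at least
#'   two groups with at least two values each.
#' @return A list of class `anova_result`: `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, `group_means`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  ssb <- sum(lengths(groups) *
               (vapply(groups, mean, numeric(1)) - mean(values))^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0 && ssb == 0)
    stop("zero variance within and between groups; F undefined")
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  structure(list(f_statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 df_between = as.integer(ht$parameter[["num df"]]),
                 df_within = as.integer(ht$parameter[["denom df"]]),
                 group_means = vapply(groups, mean, numeric(1))),
            class = "anova_result")
}

check_groups <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  if (any(vapply(groups, anyNA, logical(1)))) stop("NA values in groups")
  invisible(TRUE)
}

#' Tukey HSD pairwise comparisons
#'
#' Simultaneous confidence intervals for all pairwise mean differences
#' using the studentized-range distribution with the Tukey-Kramer
#' adjustment for unequal group sizes (as implemented by
#' [stats::TukeyHSD()]); a pair rejects the null when its interval
#' excludes 0.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param alpha Family-wise error rate in (0, 1); default 0.05.
#' @return A data frame with one row per unordered pair: `group_a`,
#'   `group_b`, `mean_difference` (a - b), `ci_low`, `ci_high`,
#'   `p_adjusted`, `reject_null`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_groups(groups)
  stopifnot(alpha > 0, alpha < 1)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  tk <- TukeyHSD(aov(values ~ g), conf.level = 1 - alpha)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(pairs, `[`, character(1), 1L),
             group_b = vapply(pairs, `[`, character(1), 2L),
             mean_difference = unname(tk[, "diff"]),
             ci_low = unname(tk[, "lwr"]), ci_high = unname(tk[, "upr"]),
             p_adjusted = unname(tk[, "p adj"]),
             reject_null = unname(tk[, "lwr"] > 0 | tk[, "upr"] < 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson chi-squared test of independence
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the product of the margins over the grand total; no continuity
#' correction. Degrees of freedom are `(rows - 1) * (columns - 1)`.
#'
#' @param table Matrix of non-negative integer counts, at least 2x2, with
#'   all row and column sums positive.
#' @return A list of class `chi_squared_result`: `statistic`, `dof`,
#'   `p_value`, `expected` (matrix of expected counts), `observed`.
#' @export
chi_squared_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be >= 2x2")
  if (anyNA(table) || any(table < 0)) stop("counts must be non-negative")
  if (any(table != round(table))) stop("counts must be integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 dof = as.integer(unname(ht$parameter)),
                 p_value = unname(ht$p.value),
                 expected = ht$expected, observed = table),
            class = "chi_squared_result")
}

#' Expression-weighted normalized pool disorder score
#'
#' The disorder score of a pool is the abundance-weighted mean of its
#' proteins' MDP average disorder scores, normalized by the total
#' expression: `score = sum(abundance_i * ads_i) / sum(abundance_i)`.
#' It lies between the smallest and largest ADS in the pool and is
#' invariant to rescaling all abundances.
#'
#' @param expression An [expression_table()].
#' @param mdp_ads Named numeric vector mapping protein id to its MDP ADS
#'   in \[0, 1\]; every protein with positive abundance must be covered.
#' @return A list of class `pool_disorder_score`: `pool_id`, `mean_age`,
#'   `score`.
#' @export
normalized_pool_disorder <- function(expression, mdp_ads) {
  stopifnot(inherits(expression, "expression_table"))
  ab <- expression$abundance[expression$abundance > 0]
  missing_ads <- setdiff(names(ab), names(mdp_ads))
  if (length(missing_ads))
    stop("positive-abundance protein(s) missing an MDP ADS: ",
         paste(missing_ads, collapse = ", "))
  a <- mdp_ads[names(ab)]
  if (anyNA(a) || any(a < 0) || any(a > 1))
    stop("MDP ADS values must lie in [0,1]")
  structure(list(pool_id = expression$pool_id,
                 mean_age = expression$mean_age,
                 score = sum(ab * a) / sum(ab)),
            class = "pool_disorder_score")
}
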
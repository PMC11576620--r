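# Per-protein residue count matrix (rows = proteins, cols = the fixed
# order->disorder residue ranking). The bootstrap resamples rows.
residue_count_matrix <- function(group) {
  stopifnot(inherits(group, "proteome_group"))
  aas <- Biostrings::AAStringSet(group$sequences)
  m <- Biostrings::letterFrequency(aas, letters = AA_RANKED)
  colnames(m) <- AA_RANKED
  rownames(m) <- names(group$sequences)
  m
}

#' Pooled residue composition of a proteome group
#'
#' Counts every residue across all sequences in the group and divides by
#' the total residue count, i.e. proteins contribute in proportion to
#' their length.
#'
#' @param group A [proteome_group()].
#' @return A `composition_vector`: named numeric vector of relative
#'   frequencies over the 20 canonical residues (order-promoting residues
#'   C, W, I, Y, F, L, H, V, N, M first, then disorder-promoting
#'   R, T, D, G, A, K, Q, S, E, P), summing to 1.
#' @export
residue_composition <- function(group) {
  counts <- colSums(residue_count_matrix(group))
  total <- sum(counts)
  if (total == 0) stop("group '", group$name, "' has no residues")
  structure(counts / total, class = "composition_vector")
}

#' Construct a composition vector from frequencies
#'
#' @param frequency Named numeric vector over the 20 canonical residues;
#'   non-negative, summing to 1 (tolerance 1e-9). Missing residues are
#'   taken as frequency 0.
#' @return A `composition_vector` in the fixed order->disorder ranking.
#' @export
composition_vector <- function(frequency) {
  if (is.null(names(frequency)))
    stop("frequencies must be named by residue letter")
  extra <- setdiff(names(frequency), AA_RANKED)
  if (length(extra))
    stop("unknown residue letters: ", paste(extra, collapse = ", "))
  out <- setNames(numeric(20L), AA_RANKED)
  out[names(frequency)] <- frequency
  if (any(out < 0)) stop("negative frequency")
  if (abs(sum(out) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(out)), ")")
  structure(out, class = "composition_vector")
}

#' Fractional enrichment/depletion of a query composition vs a background
#'
#' For each residue the statistic is `(C_x - C_bg) / C_bg`, where `C_x` is
#' the residue's relative frequency in the query set and `C_bg` its
#' frequency in the background set. Positive values indicate enrichment,
#' negative values depletion; the value is bounded below by -1.
#'
#' @param query,background `composition_vector` objects (or named
#'   frequency vectors accepted by [composition_vector()]).
#' @param zero_background How to treat residues with background frequency
#'   0: `"undefined"` (default) reports `Inf` when the query frequency is
#'   positive and `NaN` when it is also 0; `"strict"` raises an error for
#'   a positive query frequency.
#' @return Named numeric vector over the ranked residues.
#' @export
fractional_difference <- function(query, background,
                                  zero_background = c("undefined",
                                                      "strict")) {
  zero_background <- match.arg(zero_background)
  q <- composition_vector(unclass(query))
  b <- composition_vector(unclass(background))
  if (zero_background == "strict" && any(b == 0 & q > 0))
    stop("background frequency 0 with positive query frequency for: ",
         paste(AA_RANKED[b == 0 & q > 0], collapse = ", "))
  fd <- (unclass(q) - unclass(b)) / unclass(b)
  setNames(as.numeric(fd), AA_RANKED)
}

#' Bootstrap composition enrichment test
#'
#' Resamples whole proteins with replacement, independently within the
#' query and background groups (keeping each group's original size),
#' recomputes the per-residue fractional difference each iteration, and
#' reports the bootstrap mean, standard deviation and a two-sided
#' sign-crossing p-value per residue. The p-value is
#' `min(1, 2 * (k + 1) / (n + 1))` where `k` is the smaller of the counts
#' of non-positive and non-negative resampled fractional differences over
#' the `n` finite iterations; the add-one correction avoids exact zeros at
#' finite iteration counts.
#'
#' @param query,background [proteome_group()] objects.
#' @param iterations Number of bootstrap iterations (>= 1; default 10000).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param zero_background Passed to [fractional_difference()].
#' @return A data frame of class `composition_profile` with one row per
#'   residue in the fixed order->disorder ranking: `residue`,
#'   `fractional_difference` (full-data point estimate), `bootstrap_mean`,
#'   `bootstrap_sd`, `p_value`, `significant`, `undefined`. Residues whose
#'   point estimate is undefined (zero background frequency) carry `NA`
#'   statistics and `undefined = TRUE`.
#' @export
bootstrap_composition_test <- function(query, background,
                                       iterations = 10000L, alpha = 0.05,
                                       seed,
                                       zero_background = c("undefined",
                                                           "strict")) {
  zero_background <- match.arg(zero_background)
  stopifnot(inherits(query, "proteome_group"),
            inherits(background, "proteome_group"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (missing(seed)) stop("a seed is required for the bootstrap")

  qm <- residue_count_matrix(query)
  bm <- residue_count_matrix(background)
  point <- fractional_difference(residue_composition(query),
                                 residue_composition(background),
                                 zero_background)

  fd_boot <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = iterations, ncol = 20L,
                  dimnames = list(NULL, AA_RANKED))
    nq <- nrow(qm); nb <- nrow(bm)
    for (it in seq_len(iterations)) {
      cq <- colSums(qm[sample.int(nq, nq, replace = TRUE), , drop = FALSE])
      cb <- colSums(bm[sample.int(nb, nb, replace = TRUE), , drop = FALSE])
      fq <- cq / sum(cq)
      fb <- cb / sum(cb)
      out[it, ] <- (fq - fb) / fb
    }
    out
  })

  res <- data.frame(residue = AA_RANKED,
                    fractional_difference = as.numeric(point),
                    bootstrap_mean = NA_real_, bootstrap_sd = NA_real_,
                    p_value = NA_real_, significant = NA,
                    undefined = !is.finite(point),
                    stringsAsFactors = FALSE)
  for (j in seq_len(20L)) {
    if (res$undefined[j]) next
    draws <- fd_boot[, j]
    draws <- draws[is.finite(draws)]
    n <- length(draws)
    if (n == 0L) { res$undefined[j] <- TRUE; next }
    res$bootstrap_mean[j] <- mean(draws)
    res$bootstrap_sd[j] <- if (n > 1L) stats::sd(draws) else 0
    k <- min(sum(draws <= 0), sum(draws >= 0))
    res$p_value[j] <- min(1, 2 * (k + 1) / (n + 1))
    res$significant[j] <- res$p_value[j] < alpha
  }
  class(res) <- c("composition_profile", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "iterations") <- iterations
  res
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
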
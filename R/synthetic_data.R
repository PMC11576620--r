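#' Specification for a synthetic disorder-analysis corpus
#'
#' Describes a full synthetic study: proteome groups with controlled
#' amino-acid composition bias, pseudo-predictor disorder tracks with
#' controlled protein-level ADS structure, and expression pools with
#' specified mean donor ages and (optionally) target normalized disorder
#' scores. The whole corpus is a pure function of the spec and its seed.
#'
#' The defaults emulate the study conditions the pipeline is built for:
#' three proteome groups of 926, 261 and 279 proteins; six
#' pseudo-predictors whose per-group target mean ADS values follow the
#' published per-predictor group means; and four expression pools (A-D)
#' with mean donor ages 39, 51.5, 60 and 38.5 years and target normalized
#' disorder scores 0.323, 0.310, 0.353 and 0.310.
#'
#' @param group_sizes Named integer vector: proteins per group.
#' @param length_range Length-2 integer vector, uniform sequence length
#'   range (min >= 30).
#' @param composition_bias Named positive multiplicative weights on the
#'   baseline composition (missing residues default to 1).
#' @param baseline_composition Named frequency vector (default uniform
#'   1/20).
#' @param predictor_models Named list; each element a list with
#'   `target_ads` (named per group), `protein_sd` (between-protein SD of
#'   the ADS mean), `noise_sd` (residue-level noise SD) and
#'   `autocorrelation` (noise correlation length in residues).
#' @param pools List of pool descriptions: `pool_id`, `mean_age`,
#'   `meanlog`/`sdlog` (log-normal abundance parameters) and optional
#'   `target_score` for construction of a pool with a known normalized
#'   disorder score.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    group_sizes = c(younger_lens = 926L, older_lens = 261L,
                    zonules = 279L),
    length_range = c(60L, 400L),
    composition_bias = NULL,
    baseline_composition = setNames(rep(1 / 20, 20), AA_RANKED),
    predictor_models = default_predictor_models(),
    pools = default_pool_specs(),
    seed = 1234L) {
  stopifnot(length(group_sizes) >= 1L, !is.null(names(group_sizes)),
            all(group_sizes >= 1L),
            length(length_range) == 2L, length_range[1] >= 30L,
            length_range[1] <= length_range[2])
  bias <- setNames(rep(1, 20), AA_RANKED)
  if (!is.null(composition_bias)) {
    stopifnot(all(names(composition_bias) %in% AA_RANKED),
              all(composition_bias > 0))
    bias[names(composition_bias)] <- composition_bias
  }
  base <- composition_vector(baseline_composition)
  for (pm in predictor_models)
    stopifnot(pm$noise_sd >= 0, pm$protein_sd > 0, pm$autocorrelation >= 1)
  structure(list(group_sizes = group_sizes,
                 length_range = as.integer(length_range),
                 composition_bias = bias,
                 baseline_composition = base,
                 predictor_models = predictor_models,
                 pools = pools, seed = as.integer(seed)),
            class = "synthetic_spec")
}

default_predictor_models <- function() {
  mk <- function(y, o, z)
    list(target_ads = c(younger_lens = y, older_lens = o, zonules = z),
         protein_sd = 0.15, noise_sd = 0.1, autocorrelation = 5L)
  list(vlxt = mk(0.33, 0.30, 0.35),
       vsl2b = mk(0.42, 0.39, 0.47),
       vl3 = mk(0.34, 0.31, 0.40),
       iupred_short = mk(0.25, 0.24, 0.28),
       iupred_long = mk(0.27, 0.26, 0.32),
       pfit = mk(0.30, 0.27, 0.33))
}

default_pool_specs <- function() {
  mk <- function(id, age, target)
    list(pool_id = id, mean_age = age, meanlog = 0, sdlog = 1,
         target_score = target)
  list(mk("A", 39, 0.323), mk("B", 51.5, 0.310),
       mk("C", 60, 0.353), mk("D", 38.5, 0.310))
}

# Deterministic sub-seed for one generation task, kept inside 32-bit range.
sub_seed <- function(seed, stage, index) {
  (seed + 97003L * match(stage, c("proteome", "tracks", "pools")) +
     1009L * index) %% .Machine$integer.max
}

#' Generate a synthetic proteome group
#'
#' Sequence lengths are uniform over the spec's range; residues are drawn
#' i.i.d. from the bias-reweighted baseline composition. Deterministic
#' given spec and group.
#'
#' @param spec A [synthetic_spec()].
#' @param group Group name (must be in `spec$group_sizes`).
#' @return A [proteome_group()] with ids `<group>_0001`, ...
#' @export
generate_proteome <- function(spec, group) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gi <- match(group, names(spec$group_sizes))
  if (is.na(gi)) stop("unknown group: ", group)
  n <- spec$group_sizes[[gi]]
  probs <- unclass(spec$baseline_composition) * spec$composition_bias
  probs <- probs / sum(probs)
  seqs <- with_seed(sub_seed(spec$seed, "proteome", gi), {
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n,
                   replace = TRUE)
    vapply(lens, function(L)
      paste(sample(AA_RANKED, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
  })
  names(seqs) <- sprintf("%s_%04d", group, seq_len(n))
  proteome_group(group, seqs)
}

#' Generate synthetic disorder tracks for a group under one predictor
#'
#' Each protein draws its mean disorder level from a Beta distribution
#' re-parameterized by (mean = the group's target ADS, concentration set
#' from `protein_sd`); per-residue noise is a moving average of white
#' noise over the configured autocorrelation length, scaled to
#' `noise_sd`, added to the protein mean and clipped to \[0, 1\].
#'
#' @param group A [proteome_group()].
#' @param spec A [synthetic_spec()].
#' @param predictor Predictor name (must be in `spec$predictor_models`).
#' @return A list of [disorder_track()] objects, one per protein.
#' @export
generate_tracks <- function(group, spec, predictor) {
  stopifnot(inherits(group, "proteome_group"),
            inherits(spec, "synthetic_spec"))
  pi_ <- match(predictor, names(spec$predictor_models))
  if (is.na(pi_)) stop("unknown predictor: ", predictor)
  pm <- spec$predictor_models[[pi_]]
  if (!group$name %in% names(pm$target_ads))
    stop("no target ADS for group '", group$name, "'")
  target <- pm$target_ads[[group$name]]
  gi <- match(group$name, names(spec$group_sizes), nomatch = 0L)
  with_seed(sub_seed(spec$seed, "tracks", 131L * pi_ + gi), {
    lapply(names(group$sequences), function(id) {
      L <- nchar(group$sequences[[id]])
      m <- sample_protein_ads(1L, target, pm$protein_sd)
      noise <- if (pm$noise_sd > 0) {
        k <- as.integer(pm$autocorrelation)
        w <- rnorm(L + k - 1L)
        ma <- vapply(seq_len(L), function(i) mean(w[i:(i + k - 1L)]),
                     numeric(1))
        ma * sqrt(k) * pm$noise_sd  # MA of k iid N(0,1) has sd 1/sqrt(k)
      } else 0
      disorder_track(id, predictor, pmin(1, pmax(0, m + noise)))
    })
  })
}

#' Sample protein-level mean disorder scores
#'
#' Draws per-protein ADS means from a Beta distribution re-parameterized
#' by mean and standard deviation (`shape1 = m * c`,
#' `shape2 = (1 - m) * c` with concentration
#' `c = m (1 - m) / sd^2 - 1`), the protein-level model underlying
#' [generate_tracks()]. The Beta keeps draws on \[0, 1\].
#'
#' @param n Number of proteins.
#' @param mean Target mean ADS in (0, 1).
#' @param sd Between-protein standard deviation (must satisfy
#'   `sd^2 < mean * (1 - mean)`).
#' @return Numeric vector of length `n`. Uses the current RNG stream (seed
#'   externally for reproducibility).
#' @export
sample_protein_ads <- function(n, mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  conc <- mean * (1 - mean) / sd^2 - 1
  if (conc <= 0)
    stop("sd too large for a Beta distribution with mean ", mean)
  rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Generate synthetic expression pools
#'
#' Abundances are drawn log-normally per pool. When a pool carries a
#' `target_score`, the abundances of proteins with ADS above the target
#' are rescaled by the unique positive factor that makes the
#' expression-weighted mean ADS equal the target exactly, so the pool's
#' normalized disorder score is known by construction.
#'
#' @param spec A [synthetic_spec()].
#' @param mdp_ads Named numeric vector of per-protein MDP ADS values; the
#'   proteins over which every pool is built.
#' @return A list of [expression_table()] objects.
#' @export
generate_pools <- function(spec, mdp_ads) {
  stopifnot(inherits(spec, "synthetic_spec"), length(spec$pools) >= 1L,
            length(mdp_ads) >= 2L, !is.null(names(mdp_ads)))
  lapply(seq_along(spec$pools), function(k) {
    p <- spec$pools[[k]]
    ab <- with_seed(sub_seed(spec$seed, "pools", k),
                    rlnorm(length(mdp_ads), p$meanlog, p$sdlog))
    names(ab) <- names(mdp_ads)
    if (!is.null(p$target_score))
      ab <- tilt_to_target(ab, mdp_ads, p$target_score)
    expression_table(p$pool_id, p$mean_age, ab)
  })
}

# Rescale the above-target side of the pool so the weighted mean ADS hits
# the target exactly: alpha = S_lo (t - m_lo) / (S_hi (m_hi - t)).
tilt_to_target <- function(abundance, ads, target) {
  lo <- ads[names(abundance)] <= target
  s_lo <- sum(abundance[lo]); s_hi <- sum(abundance[!lo])
  if (s_lo == 0 || s_hi == 0)
    stop("cannot construct target score ", target,
         ": all ADS values on one side of it")
  m_lo <- sum(abundance[lo] * ads[names(abundance)][lo]) / s_lo
  m_hi <- sum(abundance[!lo] * ads[names(abundance)][!lo]) / s_hi
  alpha <- s_lo * (target - m_lo) / (s_hi * (m_hi - target))
  if (!is.finite(alpha) || alpha <= 0)
    stop("cannot construct target score ", target)
  abundance[!lo] <- abundance[!lo] * alpha
  abundance
}
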
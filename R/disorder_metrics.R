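#' Average disorder score (ADS) of a track
#'
#' The arithmetic mean of a protein's per-residue disorder scores under
#' one predictor.
#'
#' @param track A [disorder_track()].
#' @return A number in \[0, 1\].
#' @export
ads <- function(track) {
  stopifnot(inherits(track, "disorder_track"))
  mean(track$scores)
}

#' Percentage of predicted disordered residues (PPDR)
#'
#' The fraction of residues whose disorder score is strictly above the
#' threshold (scores exactly at the threshold do not count, matching the
#' "above 0.5" convention). Returned as a fraction in \[0, 1\], not a
#' percentage.
#'
#' @param track A [disorder_track()].
#' @param threshold Residue-level disorder threshold (default 0.5).
#' @param inclusive If `TRUE`, count scores `>= threshold` instead; off by
#'   default, available for sensitivity checks.
#' @return A fraction k/L in \[0, 1\].
#' @export
ppdr <- function(track, threshold = 0.5, inclusive = FALSE) {
  stopifnot(inherits(track, "disorder_track"))
  if (inclusive) mean(track$scores >= threshold)
  else mean(track$scores > threshold)
}

#' Mean disorder profile (MDP) across predictors
#'
#' Per-residue arithmetic mean of several predictors' tracks for the same
#' protein, yielding a consensus track named `"MDP"`.
#'
#' @param tracks List of [disorder_track()] objects for one protein, all
#'   of the same length.
#' @return A [disorder_track()] with predictor `"MDP"`.
#' @export
mean_disorder_profile <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  ids <- vapply(tracks, function(t) t$protein_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("tracks belong to different proteins: ",
         paste(unique(ids), collapse = ", "))
  lens <- vapply(tracks, function(t) length(t$scores), integer(1))
  if (length(unique(lens)) != 1L)
    stop("track length mismatch for ", ids[1], ": ",
         paste(unique(lens), collapse = " vs "))
  m <- vapply(tracks, function(t) t$scores, numeric(lens[1]))
  scores <- if (lens[1] == 1L) mean(unlist(m)) else rowMeans(as.matrix(m))
  disorder_track(ids[1], "MDP", scores)
}

# Bin a value on the three-level cutoff grid. Lower bins are half-open,
# the top bin is closed below ("30% or more", "0.5 or more").
cutoff_bin <- function(x, low, high) {
  ifelse(x < low, DISORDER_CLASS_LEVELS[1],
         ifelse(x < high, DISORDER_CLASS_LEVELS[2], DISORDER_CLASS_LEVELS[3]))
}

#' Classify a protein on the ADS/PPDR cutoff grid
#'
#' ADS bins: highly ordered below 0.15, moderately disordered in
#' \[0.15, 0.5), highly disordered at 0.5 or more. PPDR bins (as a
#' fraction): highly ordered below 0.10, moderately disordered in
#' \[0.10, 0.30), highly disordered at 0.30 or more. The two axes are
#' combined either conservatively (`strict_and`: the less disordered of
#' the two axes, so "highly disordered" requires both) or permissively
#' (`lenient_or`: the more disordered of the two axes). The default is
#' `lenient_or`.
#'
#' @param ads ADS value in \[0, 1\] (scalar or vector).
#' @param ppdr PPDR fraction in \[0, 1\] (same length as `ads`).
#' @param mode Combination mode, `"lenient_or"` or `"strict_and"`.
#' @param ads_cutoffs,ppdr_cutoffs Length-2 numeric cutoffs
#'   (lower, upper) for the two axes.
#' @return A data frame with columns `ads_class`, `ppdr_class`,
#'   `combined`, `agreement`.
#' @export
classify_disorder <- function(ads, ppdr,
                              mode = c("lenient_or", "strict_and"),
                              ads_cutoffs = c(0.15, 0.5),
                              ppdr_cutoffs = c(0.10, 0.30)) {
  mode <- match.arg(mode)
  stopifnot(length(ads) == length(ppdr),
            all(ads >= 0 & ads <= 1), all(ppdr >= 0 & ppdr <= 1))
  a <- match(cutoff_bin(ads, ads_cutoffs[1], ads_cutoffs[2]),
             DISORDER_CLASS_LEVELS)
  p <- match(cutoff_bin(ppdr, ppdr_cutoffs[1], ppdr_cutoffs[2]),
             DISORDER_CLASS_LEVELS)
  combined <- if (mode == "lenient_or") pmax(a, p) else pmin(a, p)
  data.frame(ads_class = DISORDER_CLASS_LEVELS[a],
             ppdr_class = DISORDER_CLASS_LEVELS[p],
             combined = DISORDER_CLASS_LEVELS[combined],
             agreement = a == p,
             stringsAsFactors = FALSE)
}

#' Summarize disorder tracks into a per-protein table
#'
#' Computes ADS and PPDR for every supplied track, adds an MDP track per
#' protein (mean across that protein's predictors), and classifies every
#' row on the cutoff grid.
#'
#' @param tracks List of [disorder_track()] objects (possibly several
#'   predictors per protein).
#' @param threshold PPDR residue threshold, passed to [ppdr()].
#' @param mode Classification combination mode, see [classify_disorder()].
#' @param add_mdp Add an MDP row per protein (default `TRUE`); requires
#'   equal track lengths within a protein.
#' @return A data frame with columns `protein_id`, `predictor`, `ads`,
#'   `ppdr`, `ads_class`, `ppdr_class`, `combined`, `agreement`.
#' @export
summarize_disorder <- function(tracks, threshold = 0.5,
                               mode = c("lenient_or", "strict_and"),
                               add_mdp = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(tracks) >= 1L)
  if (add_mdp) {
    by_protein <- split(tracks,
                        vapply(tracks, function(t) t$protein_id,
                               character(1)))
    mdp <- lapply(by_protein, mean_disorder_profile)
    tracks <- c(tracks, unname(mdp))
  }
  out <- data.frame(
    protein_id = vapply(tracks, function(t) t$protein_id, character(1)),
    predictor = vapply(tracks, function(t) t$predictor, character(1)),
    ads = vapply(tracks, ads, numeric(1)),
    ppdr = vapply(tracks, ppdr, numeric(1), threshold = threshold),
    stringsAsFactors = FALSE)
  cbind(out, classify_disorder(out$ads, out$ppdr, mode = mode))
}

#' Group-level predictor summary (mean ADS and PPDR per predictor)
#'
#' @param summaries Named list of per-group data frames from
#'   [summarize_disorder()]; names are group names.
#' @return A data frame with one row per (predictor, group): `predictor`,
#'   `group`, `n`, `mean_ads`, `mean_ppdr`.
#' @export
predictor_group_summary <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 1L,
            !is.null(names(summaries)))
  rows <- lapply(names(summaries), function(g) {
    s <- summaries[[g]]
    agg <- aggregate(cbind(ads, ppdr) ~ predictor, data = s, FUN = mean)
    n <- aggregate(protein_id ~ predictor, data = s, FUN = length)
    data.frame(predictor = agg$predictor, group = g,
               n = n$protein_id[match(agg$predictor, n$predictor)],
               mean_ads = agg$ads, mean_ppdr = agg$ppdr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @importFrom stats aggregate sd
NULL
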
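#' Boundary configuration for CH-CDF analysis
#'
#' Holds the charge-hydropathy boundary line, the CDF boundary points, the
#' hydropathy scale and the sliding-window width. The defaults use the
#' literature-standard CH line `R = 2.785 H - 1.151` (mean net charge vs
#' mean scaled hydropathy), the Kyte-Doolittle hydropathy scale min-max
#' rescaled to \[0, 1\], a window of 5 residues, and a 7-point CDF
#' boundary; all are overridable here or via a YAML file
#' ([read_boundary_config()]).
#'
#' @param ch_slope,ch_intercept CH boundary line coefficients.
#' @param cdf_boundary Two-column matrix or data frame of boundary points
#'   (`x` = score threshold in \[0, 1\], strictly increasing; `y` =
#'   cumulative fraction in \[0, 1\]); at least 2 points.
#' @param hydropathy_scale Named numeric vector over the 20 residues (raw
#'   scale; it is min-max rescaled internally).
#' @param hydropathy_window Odd positive integer window width.
#' @return An object of class `boundary_config`.
#' @export
boundary_config <- function(ch_slope = 2.785, ch_intercept = -1.151,
                            cdf_boundary = default_cdf_boundary(),
                            hydropathy_scale = KYTE_DOOLITTLE,
                            hydropathy_window = 5L) {
  cdf_boundary <- as.matrix(cdf_boundary)
  colnames(cdf_boundary) <- c("x", "y")
  if (nrow(cdf_boundary) < 2L) stop("need >= 2 CDF boundary points")
  if (any(diff(cdf_boundary[, "x"]) <= 0))
    stop("CDF boundary x-coordinates must be strictly increasing")
  if (any(cdf_boundary < 0) || any(cdf_boundary > 1))
    stop("CDF boundary points must lie in [0,1]")
  if (!all(AA_CANONICAL %in% names(hydropathy_scale)))
    stop("hydropathy scale must cover all 20 canonical residues")
  hydropathy_window <- as.integer(hydropathy_window)
  if (hydropathy_window < 1L || hydropathy_window %% 2L == 0L)
    stop("hydropathy_window must be an odd positive integer")
  structure(list(ch_slope = ch_slope, ch_intercept = ch_intercept,
                 cdf_boundary = cdf_boundary,
                 hydropathy_scale = hydropathy_scale,
                 hydropathy_window = hydropathy_window),
            class = "boundary_config")
}

default_cdf_boundary <- function() {
  cbind(x = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
        y = c(0.25, 0.35, 0.45, 0.54, 0.63, 0.72, 0.80))
}

#' Read a boundary configuration from a YAML file
#'
#' Recognized keys: `ch_slope`, `ch_intercept`, `hydropathy_window`
#' (scalars) and `cdf_boundary` (list of `[x, y]` pairs). Missing keys
#' fall back to the defaults of [boundary_config()]. The packaged default
#' is at `system.file("extdata", "ch_cdf_boundary.yaml",
#' package = "idproteome")`.
#'
#' @param path Path to the YAML file.
#' @return A [boundary_config()].
#' @export
read_boundary_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("ch_slope", "ch_intercept", "hydropathy_window"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$cdf_boundary))
    args$cdf_boundary <- do.call(rbind, y$cdf_boundary)
  do.call(boundary_config, args)
}

# Scale a hydropathy table to [0, 1] by min-max over the 20 residues.
scaled_hydropathy_values <- function(config) {
  h <- config$hydropathy_scale[AA_CANONICAL]
  (h - min(h)) / (max(h) - min(h))
}

per_residue_charge <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  (chars %in% c("K", "R")) - (chars %in% c("D", "E"))
}

#' Mean scaled hydropathy of a sequence
#'
#' Per-residue hydropathy from the configured scale is min-max rescaled to
#' \[0, 1\], averaged over every full sliding window of the configured
#' width, and those window means are averaged over the protein.
#'
#' @param sequence Amino-acid string (length >= window width).
#' @param config A [boundary_config()].
#' @return A number in \[0, 1\].
#' @export
mean_scaled_hydropathy <- function(sequence, config = boundary_config()) {
  w <- config$hydropathy_window
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < w) stop("sequence shorter than hydropathy window (", w, ")")
  h <- scaled_hydropathy_values(config)[chars]
  if (anyNA(h)) stop("non-canonical residue in sequence")
  cs <- cumsum(c(0, h))
  win_means <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  mean(win_means)
}

#' Mean absolute net charge per residue
#'
#' `|#(K) + #(R) - #(D) - #(E)| / L`; histidine is treated as neutral and
#' no pH model is applied.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @return A non-negative number.
#' @export
mean_net_charge <- function(sequence) {
  if (nchar(sequence) < 1L) stop("empty sequence")
  q <- per_residue_charge(toupper(sequence))
  abs(sum(q)) / length(q)
}

#' Signed distance from the charge-hydropathy boundary
#'
#' `delta_ch = <R> - (ch_slope * <H> + ch_intercept)` where `<R>` is the
#' mean absolute net charge and `<H>` the mean scaled hydropathy. Positive
#' values put the protein on the disordered side of the CH line (highly
#' charged, hydrophilic); negative values on the ordered side.
#'
#' @inheritParams mean_scaled_hydropathy
#' @return A signed real number.
#' @export
delta_ch <- function(sequence, config = boundary_config()) {
  mean_net_charge(sequence) -
    (config$ch_slope * mean_scaled_hydropathy(sequence, config) +
       config$ch_intercept)
}

#' Cumulative distribution curve of a disorder track
#'
#' At each threshold `x`, the fraction of residues whose disorder score is
#' `<= x`. The curve is non-decreasing and reaches 1 at `x = 1`. Curves
#' lying above the CDF boundary indicate order (most residues at low
#' scores).
#'
#' @param track A [disorder_track()].
#' @param thresholds Increasing numeric vector of thresholds in \[0, 1\].
#' @return Numeric vector of cumulative fractions, one per threshold.
#' @export
cdf_curve <- function(track, thresholds) {
  stopifnot(inherits(track, "disorder_track"), length(thresholds) >= 1L)
  if (any(diff(thresholds) < 0)) stop("thresholds must be non-decreasing")
  vapply(thresholds, function(x) mean(track$scores <= x), numeric(1))
}

#' Signed distance of a CDF curve from the boundary
#'
#' The mean, over the configured boundary points, of
#' `curve_y - boundary_y`. Positive values mean the curve runs above the
#' boundary, i.e. the protein is predicted ordered by the CDF analysis.
#'
#' @param curve Either a [disorder_track()] (its CDF is evaluated at the
#'   boundary x-coordinates) or a numeric vector of curve values already
#'   evaluated exactly at those x-coordinates.
#' @param config A [boundary_config()].
#' @return A signed real number.
#' @export
delta_cdf <- function(curve, config = boundary_config()) {
  bx <- config$cdf_boundary[, "x"]
  by <- config$cdf_boundary[, "y"]
  if (inherits(curve, "disorder_track")) {
    curve <- cdf_curve(curve, bx)
  } else {
    if (length(curve) != length(bx))
      stop("curve has ", length(curve), " values but the boundary has ",
           length(bx), " points; evaluate the curve at the boundary x's")
  }
  mean(curve - by)
}

#' Assign a CH-CDF quadrant
#'
#' Quadrants follow the sign table: Q1 (ordered by both; ΔCH < 0,
#' ΔCDF > 0), Q2 (molten-globule-like; ΔCH < 0, ΔCDF < 0), Q3 (disordered
#' by both; ΔCH > 0, ΔCDF < 0), Q4 (mixed; ΔCH > 0, ΔCDF > 0). Exact
#' zeros are resolved by treating ΔCH >= 0 as the disordered side and
#' ΔCDF >= 0 as the ordered side; such ties are reported via a message.
#'
#' @param delta_ch,delta_cdf Finite numeric vectors of equal length.
#' @return Character vector of `"Q1"`..`"Q4"`.
#' @export
assign_quadrant <- function(delta_ch, delta_cdf) {
  stopifnot(length(delta_ch) == length(delta_cdf))
  if (any(!is.finite(delta_ch)) || any(!is.finite(delta_cdf)))
    stop("non-finite delta_ch/delta_cdf")
  if (any(delta_ch == 0) || any(delta_cdf == 0))
    message(sum(delta_ch == 0 | delta_cdf == 0),
            " exact boundary tie(s) resolved by the >= 0 rule")
  ch_dis <- delta_ch >= 0    # disordered side of the CH line
  cdf_ord <- delta_cdf >= 0  # ordered side of the CDF boundary
  ifelse(!ch_dis & cdf_ord, "Q1",
         ifelse(!ch_dis & !cdf_ord, "Q2",
                ifelse(ch_dis & !cdf_ord, "Q3", "Q4")))
}

#' CH-CDF coordinates and quadrants for a proteome group
#'
#' @param group A [proteome_group()].
#' @param tracks List of [disorder_track()] objects supplying the CDF
#'   axis; one track per protein (e.g. a chosen predictor or MDP).
#'   Proteins without a track are dropped with a message.
#' @param config A [boundary_config()].
#' @return A data frame `protein_id`, `delta_ch`, `delta_cdf`, `quadrant`.
#' @export
ch_cdf_points <- function(group, tracks, config = boundary_config()) {
  stopifnot(inherits(group, "proteome_group"))
  by_id <- setNames(tracks, vapply(tracks, function(t) t$protein_id,
                                   character(1)))
  ids <- names(group$sequences)
  missing_ids <- setdiff(ids, names(by_id))
  if (length(missing_ids))
    message(length(missing_ids), " protein(s) without a track dropped ",
            "from CH-CDF analysis in group '", group$name, "'")
  ids <- setdiff(ids, missing_ids)
  dch <- vapply(ids, function(i) delta_ch(group$sequences[[i]], config),
                numeric(1))
  dcdf <- vapply(ids, function(i) delta_cdf(by_id[[i]], config), numeric(1))
  data.frame(protein_id = ids, delta_ch = as.numeric(dch),
             delta_cdf = as.numeric(dcdf),
             quadrant = assign_quadrant(dch, dcdf),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quadrant count table across groups
#'
#' @param points_by_group Named list of data frames from
#'   [ch_cdf_points()].
#' @return Integer matrix, rows = groups, columns = Q1..Q4.
#' @export
quadrant_counts <- function(points_by_group) {
  qs <- paste0("Q", 1:4)
  t(vapply(points_by_group, function(p)
    vapply(qs, function(q) sum(p$quadrant == q), integer(1)),
    integer(4)))
}

#' Baseline sliding-window disorder predictor
#'
#' A self-contained per-residue disorder index built from the CH boundary
#' geometry, so the pipeline can run with no external predictor output.
#' For each residue, the windowed mean scaled hydropathy `h` and windowed
#' mean absolute net charge `q` are computed over a centered window
#' (shrunk at the termini); the raw index `(ch_slope * h + ch_intercept)
#' - q` (positive = ordered side) is negated and squashed through a
#' logistic map, so scores lie in (0, 1) with higher = more disordered.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @param protein_id Identifier for the resulting track.
#' @param config A [boundary_config()]; supplies the window width, scale
#'   and CH line.
#' @param steepness Logistic steepness of the squashing map (default 3).
#' @return A [disorder_track()] with predictor `"baseline"`.
#' @export
baseline_disorder_track <- function(sequence, protein_id = "protein",
                                    config = boundary_config(),
                                    steepness = 3) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  h <- scaled_hydropathy_values(config)[chars]
  if (anyNA(h)) stop("non-canonical residue in sequence")
  q <- per_residue_charge(sequence)
  hw <- config$hydropathy_window %/% 2L
  scores <- vapply(seq_len(L), function(i) {
    lo <- max(1L, i - hw); hi <- min(L, i + hw)
    hbar <- mean(h[lo:hi])
    qbar <- abs(sum(q[lo:hi])) / (hi - lo + 1L)
    raw <- (config$ch_slope * hbar + config$ch_intercept) - qbar
    plogis(-steepness * raw)
  }, numeric(1))
  disorder_track(protein_id, "baseline", scores)
}
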
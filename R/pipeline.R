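write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Attach the stage name to any error raised while running it.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full disorder-comparison pipeline
#'
#' Executes the stages in order — load, composition profiles, disorder
#' summaries and MDP, cutoff-grid classification, CH-CDF analysis, group
#' statistics, pool scores — and writes every output table plus a
#' machine-readable run manifest to `config$output_dir`. Optional stages
#' with missing inputs (e.g. no expression tables) are skipped with a
#' logged notice.
#'
#' @param config A list with elements:
#'   * `groups`: named list; per group a list with `fasta` (path) and
#'     `tracks` (path to the score-track TSV).
#'   * `background`: FASTA path for the composition background set
#'     (optional; composition stage skipped when absent).
#'   * `pools`: character vector of expression-table paths (optional).
#'   * `boundary`: path to a boundary YAML (optional; defaults used).
#'   * `output_dir`: output directory (created if needed).
#'   * `seed`: integer seed for the bootstrap.
#'   * `iterations`: bootstrap iterations (default 10000).
#'   * `alpha`: significance level (default 0.05).
#'   * `mode`: classification combination mode (default `"lenient_or"`).
#'   * `cdf_predictor`: predictor feeding the CDF axis and the cutoff-grid
#'     classification (default `"MDP"`).
#'   * `policy`: FASTA ambiguity policy (default `"drop_ambiguous"`).
#' @return Invisibly, a list with the written file paths and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$groups),
            length(config$groups) >= 2L, !is.null(config$output_dir),
            !is.null(config$seed))
  iterations <- config$iterations %||% 10000L
  alpha <- config$alpha %||% 0.05
  mode <- config$mode %||% "lenient_or"
  cdf_predictor <- config$cdf_predictor %||% "MDP"
  policy <- config$policy %||% "drop_ambiguous"
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  bcfg <- if (!is.null(config$boundary)) read_boundary_config(config$boundary)
          else boundary_config()
  notices <- character()
  note <- function(msg) {
    message(msg)
    notices <<- c(notices, msg)
  }
  files <- character()
  results <- list()

  groups <- run_stage("load", lapply(names(config$groups), function(g) {
    read_fasta(config$groups[[g]]$fasta, name = g, policy = policy)
  }))
  names(groups) <- names(config$groups)
  tracks <- run_stage("load", lapply(names(config$groups), function(g) {
    read_score_tracks(config$groups[[g]]$tracks)
  }))
  names(tracks) <- names(config$groups)

  # Proteins with sequence but no track are dropped explicitly, not
  # silently: they are listed in a sidecar and excluded downstream.
  no_track <- do.call(rbind, lapply(names(groups), function(g) {
    with_track <- unique(vapply(tracks[[g]], function(t) t$protein_id,
                                character(1)))
    miss <- setdiff(names(groups[[g]]$sequences), with_track)
    if (length(miss))
      data.frame(group = g, protein_id = miss, stringsAsFactors = FALSE)
  }))
  if (!is.null(no_track) && nrow(no_track)) {
    note(sprintf("%d protein(s) have no disorder track; see %s",
                 nrow(no_track), "no_track_proteins.tsv"))
    files["no_track"] <- write_tsv(no_track,
                                   file.path(out, "no_track_proteins.tsv"))
  }

  if (!is.null(config$background)) {
    bg <- run_stage("composition",
                    read_fasta(config$background, name = "background",
                               policy = policy))
    comp <- run_stage("composition", do.call(rbind, lapply(
      names(groups), function(g) {
        pr <- bootstrap_composition_test(groups[[g]], bg,
                                         iterations = iterations,
                                         alpha = alpha,
                                         seed = config$seed)
        cbind(group = g, as.data.frame(pr))
      })))
    results$composition <- comp
    files["composition"] <- write_tsv(comp,
                                      file.path(out,
                                                "composition_profile.tsv"))
  } else {
    note("no background set configured; composition stage skipped")
  }

  summaries <- run_stage("summaries", lapply(names(groups), function(g) {
    summarize_disorder(tracks[[g]], mode = mode)
  }))
  names(summaries) <- names(groups)
  summary_df <- do.call(rbind, lapply(names(summaries), function(g)
    cbind(group = g, summaries[[g]])))
  results$summaries <- summary_df
  files["summary"] <- write_tsv(summary_df,
                                file.path(out, "disorder_summary.tsv"))

  stats_rows <- run_stage("group_stats", {
    preds <- unique(summary_df$predictor)
    do.call(rbind, lapply(preds, function(p) {
      do.call(rbind, lapply(c("ads", "ppdr"), function(metric) {
        vals <- lapply(summaries, function(s) s[[metric]][s$predictor == p])
        an <- one_way_anova(vals)
        means <- vapply(vals, mean, numeric(1))
        df <- data.frame(predictor = p, metric = metric,
                         f_statistic = an$f_statistic,
                         p_value = an$p_value,
                         stringsAsFactors = FALSE)
        for (g in names(means)) df[[paste0("mean_", g)]] <- means[[g]]
        df
      }))
    }))
  })
  results$predictor_summary <- stats_rows
  files["predictor_summary"] <- write_tsv(stats_rows,
                                          file.path(out,
                                                    "predictor_summary.tsv"))

  tukey_rows <- run_stage("group_stats", {
    preds <- unique(summary_df$predictor)
    do.call(rbind, lapply(preds, function(p) {
      do.call(rbind, lapply(c("ads", "ppdr"), function(metric) {
        vals <- lapply(summaries, function(s) s[[metric]][s$predictor == p])
        cbind(predictor = p, metric = metric,
              tukey_hsd(vals, alpha = alpha))
      }))
    }))
  })
  results$tukey <- tukey_rows
  files["tukey"] <- write_tsv(tukey_rows, file.path(out, "tukey.tsv"))

  chisq_rows <- list()
  class_counts <- run_stage("classification", {
    sel <- summary_df[summary_df$predictor == cdf_predictor, ]
    if (!nrow(sel)) stop("no rows for classification predictor '",
                         cdf_predictor, "'")
    tab <- table(factor(sel$group, levels = names(groups)),
                 factor(sel$combined, levels = DISORDER_CLASS_LEVELS))
    matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  })
  results$class_counts <- class_counts
  files["class_counts"] <- write_tsv(
    data.frame(group = rownames(class_counts), class_counts,
               check.names = FALSE, stringsAsFactors = FALSE),
    file.path(out, "classification_counts.tsv"))
  chisq_rows$classification <- chisq_on_counts(class_counts,
                                               "classification", note)

  chcdf <- run_stage("ch_cdf", {
    by_id_tracks <- lapply(names(groups), function(g) {
      sel <- tracks[[g]]
      sel <- sel[vapply(sel, function(t) t$predictor == cdf_predictor,
                        logical(1))]
      if (!length(sel) && cdf_predictor == "MDP") {
        by_protein <- split(tracks[[g]],
                            vapply(tracks[[g]], function(t) t$protein_id,
                                   character(1)))
        sel <- unname(lapply(by_protein, mean_disorder_profile))
      }
      if (!length(sel)) stop("no '", cdf_predictor,
                             "' tracks for group '", g, "'")
      ch_cdf_points(groups[[g]], sel, bcfg)
    })
    names(by_id_tracks) <- names(groups)
    by_id_tracks
  })
  chcdf_df <- do.call(rbind, lapply(names(chcdf), function(g)
    cbind(group = g, chcdf[[g]])))
  results$chcdf <- chcdf_df
  files["chcdf"] <- write_tsv(chcdf_df, file.path(out, "chcdf_points.tsv"))
  qcounts <- quadrant_counts(chcdf)
  results$quadrant_counts <- qcounts
  files["quadrants"] <- write_tsv(
    data.frame(group = rownames(qcounts), qcounts, check.names = FALSE),
    file.path(out, "quadrant_counts.tsv"))
  chisq_rows$quadrants <- chisq_on_counts(qcounts, "quadrants", note)

  chisq_df <- do.call(rbind, Filter(Negate(is.null), chisq_rows))
  if (!is.null(chisq_df) && nrow(chisq_df)) {
    results$chisq <- chisq_df
    files["chisq"] <- write_tsv(chisq_df, file.path(out, "chisq_tests.tsv"))
  }

  if (!is.null(config$pools) && length(config$pools)) {
    pool_df <- run_stage("pools", {
      mdp_ads <- with(summary_df[summary_df$predictor == "MDP", ],
                      setNames(ads, protein_id))
      do.call(rbind, lapply(config$pools, function(path) {
        et <- read_expression_table(path)
        ps <- normalized_pool_disorder(et, mdp_ads)
        data.frame(pool_id = ps$pool_id, mean_age = ps$mean_age,
                   score = ps$score, stringsAsFactors = FALSE)
      }))
    })
    results$pool_scores <- pool_df
    files["pools"] <- write_tsv(pool_df, file.path(out, "pool_scores.tsv"))
  } else {
    note("no expression pools configured; pool-score stage skipped")
  }

  manifest <- list(package = "idproteome",
                   version = as.character(packageVersion("idproteome")),
                   seed = config$seed,
                   iterations = iterations, alpha = alpha, mode = mode,
                   cdf_predictor = cdf_predictor,
                   config_hash = config_hash(config),
                   outputs = basename(unname(files)),
                   notices = notices)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- file.path(out, "manifest.json")
  invisible(list(files = files, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chi-squared on a count table, dropping all-zero columns first; returns
# NULL (with a notice) when fewer than two informative columns remain.
chisq_on_counts <- function(counts, label, note) {
  keep <- colSums(counts) > 0
  if (sum(keep) < 2L || nrow(counts) < 2L) {
    note(sprintf("%s count table too degenerate for chi-squared", label))
    return(NULL)
  }
  if (any(!keep))
    note(sprintf("%s chi-squared: dropped empty column(s) %s", label,
                 paste(colnames(counts)[!keep], collapse = ", ")))
  cs <- chi_squared_independence(counts[, keep, drop = FALSE])
  data.frame(test = label, statistic = cs$statistic, dof = cs$dof,
             p_value = cs$p_value, stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a complete synthetic corpus to disk
#'
#' Generates every input the pipeline reads — one FASTA and one
#' score-track TSV per group (all configured pseudo-predictors), a
#' background FASTA drawn from the unbiased baseline composition, and one
#' expression TSV per pool (built over the proteins of `pool_group`) —
#' in the dialects of the reader functions. Deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param output_dir Directory to write into (created if needed).
#' @param background_size Number of background proteins (default 300).
#' @param pool_group Group whose proteins the pools are built over;
#'   defaults to the last group in the spec.
#' @return Invisibly, a [run_pipeline()]-ready config list pointing at the
#'   written files.
#' @export
synthesize_corpus <- function(spec, output_dir, background_size = 300L,
                              pool_group = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(pool_group))
    pool_group <- names(spec$group_sizes)[length(spec$group_sizes)]
  cfg <- list(groups = list(), output_dir = file.path(output_dir, "results"),
              seed = spec$seed)
  mdp_ads_pool <- NULL
  for (g in names(spec$group_sizes)) {
    pg <- generate_proteome(spec, g)
    fasta <- file.path(output_dir, paste0(g, ".fasta"))
    write_fasta(pg, fasta)
    all_tracks <- unlist(lapply(names(spec$predictor_models), function(p)
      generate_tracks(pg, spec, p)), recursive = FALSE)
    tsv <- file.path(output_dir, paste0(g, "_tracks.tsv"))
    write_score_tracks(all_tracks, tsv)
    cfg$groups[[g]] <- list(fasta = fasta, tracks = tsv)
    if (g == pool_group) {
      by_protein <- split(all_tracks,
                          vapply(all_tracks, function(t) t$protein_id,
                                 character(1)))
      mdp_ads_pool <- vapply(by_protein,
                             function(ts) ads(mean_disorder_profile(ts)),
                             numeric(1))
    }
  }
  bg_spec <- synthetic_spec(
    group_sizes = setNames(as.integer(background_size), "background"),
    length_range = spec$length_range,
    baseline_composition = unclass(spec$baseline_composition),
    predictor_models = list(unused = list(
      target_ads = c(background = 0.3), protein_sd = 0.1,
      noise_sd = 0.1, autocorrelation = 1L)),
    pools = list(),
    seed = spec$seed + 1L)
  bg_path <- file.path(output_dir, "background.fasta")
  write_fasta(generate_proteome(bg_spec, "background"), bg_path)
  cfg$background <- bg_path
  if (length(spec$pools) && !is.null(mdp_ads_pool)) {
    pools <- generate_pools(spec, mdp_ads_pool)
    cfg$pools <- vapply(pools, function(et) {
      path <- file.path(output_dir, paste0("pool_", et$pool_id, ".tsv"))
      write_expression_table(et, path)
      path
    }, character(1))
  }
  invisible(cfg)
}
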
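test_that("unbiased proteomes recover the baseline composition", {
  spec <- synthetic_spec(group_sizes = c(g = 120L),
                         length_range = c(80L, 120L), seed = 51L)
  pg <- generate_proteome(spec, "g")
  expect_gte(sum(nchar(pg$sequences)), 10000)
  f <- residue_composition(pg)
  expect_true(all(abs(f - 1 / 20) <= 0.01))
  expect_error(generate_proteome(spec, "nope"), "unknown group")
})

test_that("proteome generation is byte-deterministic under the seed", {
  spec <- synthetic_spec(group_sizes = c(g = 10L),
                         length_range = c(40L, 60L), seed = 52L)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(generate_proteome(spec, "g"), f1)
  write_fasta(generate_proteome(spec, "g"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a composition bias is recovered by the bootstrap test", {
  spec_q <- synthetic_spec(group_sizes = c(q = 150L),
                           length_range = c(80L, 120L),
                           composition_bias = c(P = 3.0), seed = 53L)
  spec_b <- synthetic_spec(group_sizes = c(b = 150L),
                           length_range = c(80L, 120L), seed = 54L)
  pr <- bootstrap_composition_test(generate_proteome(spec_q, "q"),
                                   generate_proteome(spec_b, "b"),
                                   iterations = 300, seed = 55L)
  p_row <- pr[pr$residue == "P", ]
  expect_gt(p_row$fractional_difference, 0)
  expect_true(p_row$significant)
})

test_that("zero residue noise reproduces the protein mean exactly", {
  spec <- synthetic_spec(
    group_sizes = c(g = 5L), length_range = c(40L, 60L),
    predictor_models = list(p1 = list(target_ads = c(g = 0.4),
                                      protein_sd = 0.1, noise_sd = 0,
                                      autocorrelation = 1L)),
    seed = 56L)
  pg <- generate_proteome(spec, "g")
  trs <- generate_tracks(pg, spec, "p1")
  for (tr in trs) {
    expect_equal(length(unique(tr$scores)), 1L)
    expect_equal(ads(tr), tr$scores[1])
  }
  expect_error(generate_tracks(pg, spec, "p9"), "unknown predictor")
})

test_that("group mean ADS recovers the target at moderate sizes", {
  spec <- synthetic_spec(
    group_sizes = c(g = 250L), length_range = c(60L, 120L),
    predictor_models = list(p1 = list(target_ads = c(g = 0.42),
                                      protein_sd = 0.05, noise_sd = 0.15,
                                      autocorrelation = 5L)),
    seed = 57L)
  pg <- generate_proteome(spec, "g")
  trs <- generate_tracks(pg, spec, "p1")
  expect_lt(abs(mean(vapply(trs, ads, numeric(1))) - 0.42), 0.01)
})

test_that("separated target ADS means yield a detectable group effect", {
  mk <- function(g, target, seed) {
    spec <- synthetic_spec(
      group_sizes = setNames(200L, g), length_range = c(60L, 100L),
      predictor_models = list(p1 = list(
        target_ads = setNames(target, g), protein_sd = 0.15,
        noise_sd = 0.1, autocorrelation = 5L)),
      seed = seed)
    trs <- generate_tracks(generate_proteome(spec, g), spec, "p1")
    vapply(trs, ads, numeric(1))
  }
  an <- one_way_anova(list(a = mk("a", 0.47, 58L), b = mk("b", 0.39, 59L)))
  expect_lt(an$p_value, 0.01)
})

test_that("the autocorrelation length controls residual lag-1 correlation", {
  mk_spec <- function(k, seed) synthetic_spec(
    group_sizes = c(g = 50L), length_range = c(120L, 160L),
    predictor_models = list(p1 = list(target_ads = c(g = 0.5),
                                      protein_sd = 0.05, noise_sd = 0.1,
                                      autocorrelation = k)),
    seed = seed)
  lag1 <- function(k) {
    spec <- mk_spec(k, 60L)
    pg <- generate_proteome(spec, "g")
    trs <- generate_tracks(pg, spec, "p1")
    mean(vapply(trs, function(tr) {
      r <- tr$scores - mean(tr$scores)
      sum(r[-1] * r[-length(r)]) / sum(r^2)
    }, numeric(1)))
  }
  expect_gt(lag1(15L), lag1(1L))
})

test_that("pool generation recovers degenerate and constructed scores", {
  adsv <- setNames(seq(0.05, 0.95, length.out = 30), sprintf("P%02d", 1:30))

  # degenerate distribution: all abundances equal -> unweighted mean
  spec_flat <- synthetic_spec(
    pools = list(list(pool_id = "X", mean_age = 40, meanlog = 0,
                      sdlog = 0, target_score = NULL)),
    seed = 61L)
  pools <- generate_pools(spec_flat, adsv)
  expect_equal(normalized_pool_disorder(pools[[1]], adsv)$score,
               mean(adsv), tolerance = 1e-9)

  # abundance concentrated on one protein -> that protein's ADS
  one <- expression_table("Y", 40, setNames(c(1e9, rep(1e-9, 29)),
                                            names(adsv)))
  expect_equal(normalized_pool_disorder(one, adsv)$score,
               unname(adsv[1]), tolerance = 1e-6)

  # construction to the published pool targets is exact
  spec_t <- synthetic_spec(seed = 62L)
  pools_t <- generate_pools(spec_t, adsv)
  targets <- c(A = 0.323, B = 0.310, C = 0.353, D = 0.310)
  for (et in pools_t)
    expect_equal(normalized_pool_disorder(et, adsv)$score,
                 unname(targets[et$pool_id]), tolerance = 1e-9)
})

test_that("generate_pools is deterministic under the spec seed", {
  adsv <- setNames(runif(20, 0.1, 0.9), sprintf("P%02d", 1:20))
  spec <- synthetic_spec(seed = 63L)
  p1 <- generate_pools(spec, adsv)
  p2 <- generate_pools(spec, adsv)
  for (i in seq_along(p1))
    expect_identical(p1[[i]]$abundance, p2[[i]]$abundance)
})

test_that("up-weighted residues are sign-recovered at large corpus size", {
  bias <- c(P = 3.0, E = 1.5)
  spec_q <- synthetic_spec(group_sizes = c(q = 400L),
                           length_range = c(120L, 180L),
                           composition_bias = bias, seed = 64L)
  spec_b <- synthetic_spec(group_sizes = c(b = 400L),
                           length_range = c(120L, 180L), seed = 65L)
  q <- generate_proteome(spec_q, "q")
  b <- generate_proteome(spec_b, "b")
  expect_gte(sum(nchar(q$sequences)) + sum(nchar(b$sequences)), 1e5)
  fd <- fractional_difference(residue_composition(q),
                              residue_composition(b))
  expect_true(all(fd[names(bias)] > 0))
})
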
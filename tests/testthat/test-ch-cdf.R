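test_that("mean_scaled_hydropathy hits the min-max extremes", {
  cfg <- boundary_config()
  expect_equal(mean_scaled_hydropathy(strrep("I", 20), cfg), 1.0)  # most hydrophobic
  expect_equal(mean_scaled_hydropathy(strrep("R", 20), cfg), 0.0)  # least
  expect_error(mean_scaled_hydropathy("ACD", cfg), "shorter")
})

test_that("mean_scaled_hydropathy matches a brute-force two-loop oracle", {
  cfg <- boundary_config()
  set.seed(21)
  seq25 <- paste(sample(c("A", "C", "D", "E", "I", "K", "L", "R"), 25,
                        replace = TRUE), collapse = "")
  chars <- strsplit(seq25, "")[[1]]
  sc <- (cfg$hydropathy_scale - min(cfg$hydropathy_scale)) /
    diff(range(cfg$hydropathy_scale))
  h <- sc[chars]
  w <- cfg$hydropathy_window
  wins <- numeric(0)
  for (j in 1:(25 - w + 1)) {
    acc <- 0
    for (k in j:(j + w - 1)) acc <- acc + h[k]
    wins <- c(wins, acc / w)
  }
  expect_equal(mean_scaled_hydropathy(seq25, cfg), mean(wins),
               tolerance = 1e-12)
})

test_that("mean_net_charge counts K,R vs D,E with His neutral", {
  expect_equal(mean_net_charge("KKKK"), 1.0)
  expect_equal(mean_net_charge("KDKD"), 0.0)
  expect_equal(mean_net_charge("KKDAA"), 0.2)
  expect_equal(mean_net_charge("HHHH"), 0.0)
  expect_error(mean_net_charge(""), "empty")
})

test_that("delta_ch sign is forced for charged vs hydrophobic polymers", {
  cfg <- boundary_config()
  expect_gt(delta_ch(strrep("E", 30), cfg), 0)  # charged, hydrophilic
  expect_lt(delta_ch(strrep("I", 30), cfg), 0)  # uncharged, hydrophobic
})

test_that("a sequence on the CH boundary gives delta_ch of exactly zero", {
  seq <- "ACDKLMENPQRSTVKA"
  h <- mean_scaled_hydropathy(seq, boundary_config())
  r <- mean_net_charge(seq)
  # solve <R> = slope * <H> + intercept for the slope
  cfg <- boundary_config(ch_slope = (r - (-1.151)) / h,
                         ch_intercept = -1.151)
  expect_equal(delta_ch(seq, cfg), 0, tolerance = 1e-12)
})

test_that("cdf_curve counts residues at or below each threshold", {
  expect_equal(cdf_curve(make_track(c(0.2, 0.8)), c(0.5, 1.0)), c(0.5, 1.0))
  expect_equal(cdf_curve(make_track(rep(0, 4)), c(0.1, 0.5, 1)), c(1, 1, 1))

  set.seed(22)
  s <- runif(50)
  th <- c(0.1, 0.2, 0.35, 0.5, 0.6, 0.75, 0.9)
  expect_equal(cdf_curve(make_track(s), th),
               vapply(th, function(x) sum(s <= x) / 50, numeric(1)),
               tolerance = 1e-12)
})

test_that("delta_cdf measures signed distance from the boundary", {
  cfg <- boundary_config()
  by <- cfg$cdf_boundary[, "y"]
  expect_equal(delta_cdf(by, cfg), 0)
  # fully ordered track: curve is 1 everywhere
  expect_equal(delta_cdf(make_track(rep(0, 10)), cfg), mean(1 - by),
               tolerance = 1e-12)

  set.seed(23)
  tr <- make_track(runif(40))
  curve <- cdf_curve(tr, cfg$cdf_boundary[, "x"])
  acc <- 0
  for (i in seq_along(by)) acc <- acc + (curve[i] - by[i])
  expect_equal(delta_cdf(tr, cfg), acc / length(by), tolerance = 1e-12)

  expect_error(delta_cdf(c(0.5, 0.5), cfg), "boundary")
})

test_that("quadrants follow the sign table with the >= 0 tie rule", {
  expect_equal(assign_quadrant(-0.1, 0.1), "Q1")
  expect_equal(assign_quadrant(-0.1, -0.1), "Q2")
  expect_equal(assign_quadrant(0.1, -0.1), "Q3")
  expect_equal(assign_quadrant(0.1, 0.1), "Q4")
  # zeros: CH >= 0 is the disordered side, CDF >= 0 the ordered side
  expect_message(expect_equal(assign_quadrant(0, 0.1), "Q4"), "tie")
  expect_message(expect_equal(assign_quadrant(0, -0.1), "Q3"), "tie")
  expect_message(expect_equal(assign_quadrant(-0.1, 0), "Q1"), "tie")
  expect_message(expect_equal(assign_quadrant(0, 0), "Q4"), "tie")
  expect_error(assign_quadrant(NA_real_, 1), "finite")
  expect_error(assign_quadrant(Inf, 1), "finite")
})

test_that("quadrant assignment is invariant to positive rescaling", {
  set.seed(24)
  dch <- rnorm(100)
  dcdf <- rnorm(100)
  q1 <- assign_quadrant(dch, dcdf)
  for (s in c(0.01, 7))
    expect_equal(assign_quadrant(s * dch, s * dcdf), q1)
})

test_that("cdf curves are non-decreasing for random tracks", {
  set.seed(25)
  th <- sort(runif(9))
  for (i in 1:50) {
    tr <- make_track(runif(sample(5:80, 1)))
    expect_true(all(diff(cdf_curve(tr, th)) >= 0))
  }
})

test_that("baseline predictor places charged vs hydrophobic regions", {
  cfg <- boundary_config()
  expect_true(all(baseline_disorder_track(strrep("E", 20))$scores > 0.5))
  expect_true(all(baseline_disorder_track(strrep("I", 20))$scores < 0.5))

  chim <- paste0(strrep("I", 30), strrep("E", 30))
  tr <- baseline_disorder_track(chim, "chimera", cfg)
  expect_equal(tr$predictor, "baseline")
  expect_true(all(diff(tr$scores) >= -1e-12))  # monotone I -> E transition
  expect_lt(tr$scores[1], 0.5)
  expect_gt(tr$scores[60], 0.5)
})

test_that("baseline predictor is symmetric under sequence reversal", {
  tr <- baseline_disorder_track(strrep("Q", 15))
  rev_tr <- baseline_disorder_track(paste(rev(strsplit(strrep("Q", 15),
                                                       "")[[1]]),
                                          collapse = ""))
  expect_equal(tr$scores, rev_tr$scores)

  set.seed(26)
  s <- paste(sample(c("A", "E", "I", "K", "R"), 40, replace = TRUE),
             collapse = "")
  srev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(baseline_disorder_track(srev)$scores,
               rev(baseline_disorder_track(s)$scores), tolerance = 1e-12)
})

test_that("boundary configs validate and load from YAML", {
  expect_error(boundary_config(cdf_boundary = cbind(c(0.5, 0.2), c(0.3, 0.4))),
               "increasing")
  expect_error(boundary_config(cdf_boundary = cbind(0.5, 0.3)), ">= 2")
  expect_error(boundary_config(hydropathy_window = 4L), "odd")

  path <- system.file("extdata", "ch_cdf_boundary.yaml",
                      package = "idproteome")
  cfg <- read_boundary_config(path)
  expect_equal(cfg$ch_slope, 2.785)
  expect_equal(cfg$ch_intercept, -1.151)
  expect_equal(nrow(cfg$cdf_boundary), 7L)
})

test_that("ch_cdf_points assembles coordinates and counts per group", {
  set.seed(27)
  g <- random_group(6, len = 40)
  trs <- lapply(names(g$sequences), function(id)
    baseline_disorder_track(g$sequences[[id]], id))
  pts <- ch_cdf_points(g, trs)
  expect_equal(nrow(pts), 6L)
  expect_true(all(pts$quadrant %in% paste0("Q", 1:4)))
  counts <- quadrant_counts(list(grp = pts))
  expect_equal(sum(counts), 6L)
  # proteins without a track are dropped with a message
  expect_message(pts2 <- ch_cdf_points(g, trs[-1]), "without a track")
  expect_equal(nrow(pts2), 5L)
})
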
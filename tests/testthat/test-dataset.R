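test_that("conservation closure is exact and rejection respects the ranges", {
  ## worked closure: W 1.0 in, S 0.3 in, N 0.4 out drawn, E the remainder
  q <- c(W = 1.0, N = -0.4, S = 0.3)
  expect_equal(-(q[["W"]] + q[["N"]] + q[["S"]]), -0.9)  # qE = 0.9 outflow
  set.seed(101)
  for (i in 1:2000) {
    cs <- sample_case()
    r <- cs$rates
    stopifnot(abs(r$qW + r$qN + r$qE + r$qS) < 1e-12,
              r$qW >= 0, r$qW <= 2,
              all(abs(c(r$qN, r$qE, r$qS)) <= 2),
              cs$geometry$width >= 50, cs$geometry$width <= 200,
              cs$particle$diameter >= 1, cs$particle$diameter <= 20,
              sum(c(r$qN, r$qE, r$qS) < 0) >= 1)
  }
  succeed()
})

test_that("segmentation yields 3 x 10 points with exact junction crossings", {
  g <- std_geom()
  tr <- straight_traj(5)
  seg <- segment_trajectory(tr, g)
  expect_equal(dim(seg$entrance), c(10, 2))
  expect_equal(dim(seg$middle), c(10, 2))
  expect_equal(dim(seg$exit), c(10, 2))
  expect_equal(length(crossflow:::.segments_to_targets(seg)), 60)
  ## straight path: all y equal, entrance points at equal arc fractions
  expect_true(all(abs(rbind(seg$entrance, seg$middle, seg$exit)[, 2] - 5) < 1e-9))
  expect_equal(seg$entrance[, 1], seq(-250, -50, length.out = 10))
  expect_equal(seg$middle[, 1], seq(-50, 50, length.out = 10))
  expect_equal(seg$exit[, 1], seq(50, 250, length.out = 10))
  ## first entrance point is the seed; segments join at the square boundary
  expect_equal(seg$entrance[1, ], unname(tr$seed))
  expect_equal(seg$entrance[10, ], seg$middle[1, ])
  expect_equal(seg$middle[10, ], seg$exit[1, ])
})

test_that("resampling a path already at the target fractions returns it exactly", {
  ## unevenly sampled straight path: the 10 resampled points are evenly
  ## spaced chords, so a second resampling is an exact fixed point
  s <- seq(0, 1, length.out = 23)^2
  pts <- cbind(-250 + 500 * s, -50 + 100 * s)
  r1 <- crossflow:::.resample_polyline(pts, 10)
  expect_equal(r1, cbind(seq(-250, 250, length.out = 10),
                         seq(-50, 50, length.out = 10)), tolerance = 1e-12)
  r2 <- crossflow:::.resample_polyline(r1, 10)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("segmentation refuses frozen trajectories", {
  tr <- straight_traj()
  tr$status <- "FROZEN"
  expect_error(segment_trajectory(tr, std_geom()), "FROZEN")
})

test_that("dataset records carry 7 features and 60 targets, reproducibly", {
  ds1 <- build_dataset(n_cases = 4, seeds_per_case = 10, seed = 99)
  ds2 <- build_dataset(n_cases = 4, seeds_per_case = 10, seed = 99)
  expect_identical(ds1, ds2)
  expect_equal(sum(grepl("^feat_", names(ds1))), 7)
  expect_equal(sum(grepl("^tgt_", names(ds1))), 60)
  expect_true(all(stats::complete.cases(ds1)))
  ## records per case cannot exceed inlets x seeds
  counts <- table(ds1$case_seed)
  expect_true(all(counts <= 3 * 10))
  expect_gte(attr(ds1, "n_frozen"), 0)
  ## every record: entrance starts at the seed (features 3:4), exit ends on
  ## the exit-port segment
  for (i in seq_len(nrow(ds1))) {
    expect_equal(ds1$tgt_1[i], ds1$feat_3[i], tolerance = 1e-9)
    expect_equal(ds1$tgt_2[i], ds1$feat_4[i], tolerance = 1e-9)
    w <- ds1$feat_2[i]; ext <- 2.5 * w
    last <- c(ds1$tgt_59[i], ds1$tgt_60[i])
    expect_equal(max(abs(last)), ext, tolerance = 1e-6)
  }
  ## qS is recoverable from the three stored rates
  ## (conservation: qS = -(qW + qN + qE)); check against the flow case
  qS <- -(ds1$feat_5 + ds1$feat_6 + ds1$feat_7)
  expect_true(all(abs(qS) <= 2 + 1e-12))
})

test_that("fixed-range normalization hits its endpoints and inverts exactly", {
  sc <- range_scaler()
  expect_equal(normalize_features(sc, matrix(c(1, 50, -500, -500, -2, -2, -2), 1)),
               matrix(0, 1, 7))
  expect_equal(normalize_features(sc, matrix(c(20, 200, 500, 500, 2, 2, 2), 1)),
               matrix(1, 1, 7))
  set.seed(8)
  X <- cbind(runif(50, 1, 20), runif(50, 50, 200), runif(50, -500, 500),
             runif(50, -500, 500), runif(50, 0, 2), runif(50, -2, 2),
             runif(50, -2, 2))
  expect_equal(denormalize_features(sc, normalize_features(sc, X)), X,
               tolerance = 1e-12)
  Y <- matrix(runif(300, -500, 500), 5)
  expect_equal(denormalize_targets(sc, normalize_targets(sc, Y)), Y,
               tolerance = 1e-12)
})

test_that("normalized datasets live in the unit interval", {
  ds <- build_dataset(n_cases = 6, seed = 7)
  nd <- normalize_records(ds)
  F <- as.matrix(nd$data[paste0("feat_", 1:7)])
  T <- as.matrix(nd$data[paste0("tgt_", 1:60)])
  expect_true(all(F >= 0 & F <= 1))
  expect_true(all(T >= 0 & T <= 1))
  expect_error(normalize_records(ds[0, ]), "empty")
  ## scaler JSON sidecar round-trip
  tmp <- tempfile(fileext = ".json")
  write_scaler_json(nd$scaler, tmp)
  sc2 <- read_scaler_json(tmp)
  expect_equal(sc2$feat_lo, nd$scaler$feat_lo)
})

test_that("the case-level split keeps cases intact and near the 70/30 ratio", {
  ds <- build_dataset(n_cases = 12, seed = 13)
  sp <- split_dataset(ds, 0.7, seed = 1)
  expect_length(intersect(ds$case_seed[sp$train], ds$case_seed[sp$test]), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_len(nrow(ds)))
  frac <- length(unique(ds$case_seed[sp$train])) / length(unique(ds$case_seed))
  expect_gt(frac, 0.5); expect_lt(frac, 0.9)
})
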
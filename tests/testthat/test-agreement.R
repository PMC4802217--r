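test_that("Dice equals brute-force voxel counting on shifted cubes", {
  # 10x10x10 cubes, the second shifted 5 voxels along one axis
  mk <- function(xs) {
    arr <- array(0L, dim = c(20, 20, 20))
    arr[xs, 1:10, 1:10] <- 4L
    LabelVolume(arr)
  }
  a <- mk(1:10); a@rater <- "R1"
  b <- mk(6:15); b@rater <- "R2"
  # brute-force oracle on the raw arrays
  ia <- labelData(a) == 4L
  ib <- labelData(b) == 4L
  oracle <- 2 * sum(ia & ib) / (sum(ia) + sum(ib))
  expect_equal(oracle, 0.5)  # 500 shared voxels of 1000 each
  expect_equal(diceCoefficient(a, b, "CET")$dice, oracle)

  expect_equal(diceCoefficient(a, a, "CET")$dice, 1)

  disj <- mk(11:20); disj@rater <- "R2"
  expect_equal(diceCoefficient(a, disj, "CET")$dice, 0)

  # growing the intersection with fixed set sizes never decreases Dice
  prev <- -1
  for (shift in c(8, 6, 4, 2, 0)) {
    sh <- mk((1:10) + shift); sh@rater <- "R2"
    d <- diceCoefficient(a, sh, "CET")$dice
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("the small-volume gate excludes comparisons below 90 mm^3", {
  small <- blockVolume(4L, block = 1:4, spacing = c(1, 1, 1.2))  # 76.8 mm^3
  big <- blockVolume(4L, block = 1:6, spacing = c(1, 1, 1.2))
  r <- diceCoefficient(small, small, "CET")
  expect_true(r$excluded)
  expect_true(is.na(r$dice))
  # either-rater rule: one small volume suffices
  expect_true(diceCoefficient(small, big, "CET")$excluded)
  expect_false(diceCoefficient(small, big, "CET", rule = "both")$excluded)
  expect_false(diceCoefficient(big, big, "CET")$excluded)
  # the gate is physical volume, not voxel count: same voxels, finer grid
  fine <- blockVolume(4L, block = 1:6, spacing = c(0.5, 0.5, 0.5))
  expect_true(diceCoefficient(fine, fine, "CET")$excluded)  # 27 mm^3

  a <- blockVolume(4L); b <- blockVolume(2L)
  b@spacing <- c(2, 2, 2)
  expect_error(diceCoefficient(a, b, "CET"), "grid")
})

test_that("Dice is symmetric, bounded, and monotone in the intersection", {
  set.seed(7)
  for (i in 1:10) {
    arr1 <- array(sample(c(0L, 4L), 7^3, TRUE), dim = c(7, 7, 7))
    arr2 <- array(sample(c(0L, 4L), 7^3, TRUE), dim = c(7, 7, 7))
    a <- LabelVolume(arr1, rater = "A"); b <- LabelVolume(arr2, rater = "B")
    dab <- diceCoefficient(a, b, "CET", minVolume = 0)$dice
    dba <- diceCoefficient(b, a, "CET", minVolume = 0)$dice
    expect_equal(dab, dba)
    expect_gte(dab, 0); expect_lte(dab, 1)
  }
})

test_that("Dice summaries report (median, max - min, n) over included patients", {
  mkRes <- function(dice, excluded = FALSE, patient = "p") {
    data.frame(patient = patient, time_point = "PRE", rater_a = "B",
               rater_b = "R1", compartment = "CET", dice = dice,
               vol_a = 1000, vol_b = 1000, excluded = excluded)
  }
  res <- rbind(mkRes(0.6), mkRes(0.7), mkRes(0.9))
  s <- summarizeDice(res)
  expect_equal(s$median, 0.7)
  expect_equal(s$range, 0.3, tolerance = 1e-12)
  expect_equal(s$n, 3)

  s1 <- summarizeDice(mkRes(0.5))
  expect_equal(s1$median, 0.5)
  expect_equal(s1$range, 0)

  res <- rbind(mkRes(0.6), mkRes(0.7), mkRes(0.9),
               mkRes(NA, excluded = TRUE), mkRes(NA, excluded = TRUE))
  expect_equal(summarizeDice(res)$n, 3)
  expect_equal(summarizeDice(res)$n_scheduled, 5)

  allout <- summarizeDice(mkRes(NA, excluded = TRUE))
  expect_equal(allout$n, 0)
  expect_true(is.na(allout$median))
})

test_that("Pearson correlation matches the direct covariance formula and its affine invariance", {
  recs <- data.frame(patient = rep(sprintf("p%d", 1:8), 2),
                     time_point = "PRE",
                     rater = rep(c("B", "R1"), each = 8),
                     compartment = "CET",
                     volume_mm3 = c(12, 35, 7, 80, 44, 21, 63, 18,
                                    15, 30, 11, 70, 50, 25, 55, 16))
  out <- volumeCorrelation(recs, "B", "R1", compartments = "CET")
  x <- recs$volume_mm3[1:8]; y <- recs$volume_mm3[9:16]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, oracle, tolerance = 1e-12)
  tstat <- oracle * sqrt((8 - 2) / (1 - oracle^2))
  expect_equal(out$p, 2 * stats::pt(-abs(tstat), df = 6), tolerance = 1e-12)
  expect_equal(out$n, 8)

  # affine rescaling with positive slope leaves r unchanged
  recs2 <- recs
  recs2$volume_mm3[recs2$rater == "B"] <- 3.2 * x + 40
  expect_equal(volumeCorrelation(recs2, "B", "R1", compartments = "CET")$r,
               out$r, tolerance = 1e-12)

  # perfect linearity
  recs$volume_mm3[9:16] <- 2 * x
  expect_equal(volumeCorrelation(recs, "B", "R1", compartments = "CET")$r, 1)
  recs$volume_mm3[9:16] <- -x
  expect_equal(volumeCorrelation(recs, "B", "R1", compartments = "CET")$r, -1)

  recs$volume_mm3[9:16] <- 5
  expect_true(volumeCorrelation(recs, "B", "R1",
                                compartments = "CET")$degenerate)
  expect_error(volumeCorrelation(recs[c(1, 9), ], "B", "R1",
                                 compartments = "CET"), "3 pairs")
})

test_that("difference-mode correlation pairs each rater's own consecutive transitions", {
  tps <- c("PRE", "POST", "M1", "M3")
  recs <- seriesRecords(list(B = c(100, 40, 70, 90),
                             R1 = c(90, 30, 80, 85)), tps)
  out <- volumeCorrelation(recs, "B", "R1", compartments = "CET",
                           mode = "difference")
  dx <- diff(c(100, 40, 70, 90)); dy <- diff(c(90, 30, 80, 85))
  expect_equal(out$n, 3)
  expect_equal(out$r, stats::cor(dx, dy), tolerance = 1e-12)
})

test_that("estimation ratios recover identity, constant factors and the sorted median", {
  tps <- c("PRE", "POST")
  recs <- do.call(rbind, lapply(1:5, function(i)
    seriesRecords(list(B = c(10 * i, 5 * i), R1 = c(10 * i, 5 * i)), tps,
                  patient = paste0("p", i))))
  for (tp in tps)
    expect_equal(estimationRatio(recs, "B", "R1", "CET", tp)$ratio, 1)

  recs2 <- recs
  recs2$volume_mm3[recs2$rater == "B"] <- 2 * recs2$volume_mm3[recs2$rater == "B"]
  expect_equal(estimationRatio(recs2, "B", "R1", "CET", "POST")$ratio, 2)

  recs3 <- recs[recs$time_point == "PRE", ]
  recs3$volume_mm3[recs3$rater == "B"] <-
    recs3$volume_mm3[recs3$rater == "B"] * c(0.8, 1.2, 1.6, 0.8, 1.6)
  # ratios {0.8, 1.2, 1.6, 0.8, 1.6}: median by sort-and-pick is 1.2
  expect_equal(estimationRatio(recs3, "B", "R1", "CET", "PRE")$ratio, 1.2)

  # zero denominators are excluded and counted
  recs4 <- recs
  recs4$volume_mm3[recs4$rater == "R1" & recs4$patient == "p1"] <- 0
  out <- estimationRatio(recs4, "B", "R1", "CET", "POST")
  expect_equal(out$n, 4)
  expect_equal(out$nExcluded, 1)
  recs5 <- recs
  recs5$volume_mm3[recs5$rater == "R1"] <- 0
  expect_true(is.na(estimationRatio(recs5, "B", "R1", "CET", "POST")$ratio))
})
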
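diskMask <- function(nr, nc, centers, radii) {
  m <- matrix(0L, nr, nc)
  ri <- matrix(rep(seq_len(nr), nc), nr)
  ci <- matrix(rep(seq_len(nc), each = nr), nr)
  for (i in seq_len(nrow(centers)))
    m[(ri - centers[i, 1])^2 + (ci - centers[i, 2])^2 <= radii[i]^2] <-
      i
  m
}

test_that("segmentation recovers disk geometry", {
  one <- diskMask(128, 128, matrix(c(64, 64), 1), 50)
  seg <- segmentEnteroids(one)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$diameter, 100, tolerance = 0.01)
  expect_equal(seg$area, pi * 50^2, tolerance = 0.01)
  expect_gt(seg$circularity, 0.9)
  expect_warning(empty <- segmentEnteroids(matrix(0L, 32, 32)),
                 "no objects")
  expect_equal(nrow(empty), 0)
  two <- diskMask(128, 200, rbind(c(40, 50), c(90, 150)), c(20, 30))
  seg2 <- segmentEnteroids(two)
  expect_equal(nrow(seg2), 2)
  expect_equal(sort(seg2$area), sort(c(sum(two == 1), sum(two == 2))))
})

test_that("tracking keeps static objects and gates large jumps", {
  f1 <- diskMask(128, 128, rbind(c(40, 40), c(90, 90)), c(15, 15))
  ts <- trackObjects(list(f1, f1, f1))
  tr <- ts@tracks
  expect_equal(length(unique(tr$id)), 2)
  expect_true(all(table(tr$id) == 3))
  for (id in unique(tr$id))
    expect_equal(diff(range(tr$row[tr$id == id])), 0)
  # displacement beyond the gate opens a new track
  f2 <- diskMask(128, 128, matrix(c(40, 80), 1), 15)
  ts2 <- trackObjects(list(diskMask(128, 128, matrix(c(40, 40), 1), 15),
                           f2), maxDisplacement = 15)
  expect_equal(length(unique(ts2@tracks$id)), 2)
  # within the gate the track continues
  f3 <- diskMask(128, 128, matrix(c(40, 50), 1), 15)
  ts3 <- trackObjects(list(diskMask(128, 128, matrix(c(40, 40), 1), 15),
                           f3), maxDisplacement = 15)
  expect_equal(length(unique(ts3@tracks$id)), 1)
  expect_error(trackObjects(list(f1)), "2 frames")
})

test_that("diameter ratio follows sqrt of area growth and is 1 at t0", {
  r0 <- 30
  f1 <- diskMask(160, 160, matrix(c(80, 80), 1), r0)
  f2 <- diskMask(160, 160, matrix(c(80, 80), 1), r0 * 1.2)  # area x1.44
  sm <- diameterRatio(trackObjects(list(f1, f2), times = c(0, 3600)))
  expect_equal(sm@ratios$ratio[sm@ratios$time == 0], 1)
  expect_equal(sm@ratios$ratio[sm@ratios$time == 3600], 1.2,
               tolerance = 0.01)
  same <- diameterRatio(trackObjects(list(f1, f1), times = c(0, 1)))
  expect_equal(same@ratios$ratio, c(1, 1))
  expect_error(diameterRatio(trackObjects(list(f1, f2)), times = 99),
               "requested time")
})

test_that("diameter ratio is invariant to translation and 90-degree rotation", {
  f1 <- diskMask(160, 160, matrix(c(60, 60), 1), 25)
  f2 <- diskMask(160, 160, matrix(c(60, 60), 1), 30)
  base <- diameterRatio(trackObjects(list(f1, f2)))@ratios$ratio[2]
  sh1 <- diskMask(160, 160, matrix(c(90, 100), 1), 25)
  sh2 <- diskMask(160, 160, matrix(c(90, 100), 1), 30)
  expect_equal(diameterRatio(trackObjects(list(sh1, sh2)))@ratios$ratio[2],
               base)
  rot <- function(m) t(m)[ncol(m):1, ]
  expect_equal(
    diameterRatio(trackObjects(list(rot(f1), rot(f2))))@ratios$ratio[2],
    base)
})

test_that("swelling inhibition follows the increment formula", {
  expect_equal(swellingInhibition(c(1.5, 1.5), c(1.25, 1.25)), 50)
  expect_equal(swellingInhibition(c(1.4, 1.6), c(1.4, 1.6)), 0)
  expect_equal(swellingInhibition(c(1.4, 1.4), c(1.0, 1.0)), 100)
  expect_error(swellingInhibition(c(1.0, 1.0), c(1.0, 1.0)),
               "no swelling")
  expect_error(swellingInhibition(numeric(0), c(1.2)), "non-empty")
})

test_that("planted inhibition is recovered from noise-free masks", {
  ag <- genSwellingSeries(syntheticSwellingConfig("mvid", "agonist",
                                                  nObjects = 10, seed = 21))
  inh <- genSwellingSeries(syntheticSwellingConfig("mvid",
                                                   "agonist_inhibitor",
                                                   nObjects = 10,
                                                   seed = 22))
  ra <- diameterRatio(trackObjects(ag$masks, times = ag$times))
  ri <- diameterRatio(trackObjects(inh$masks, times = inh$times))
  expect_equal(swellingInhibition(ra, ri), 50, tolerance = 5 / 50)
})
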
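test_that("a dilated straight segment thins to one unpruned component", {
  img <- matrix(0, 64, 128)
  img[29:31, 21:80] <- 100   # 60 px long, 3 px thick
  sk <- skeletonizeMarker(img, method = "fixed", threshold = 50)
  comps <- skeletonComponents(sk)
  expect_length(comps, 1)
  # skeleton stays on the ribbon and spans essentially its full length
  expect_true(all(comps[[1]][, 1] %in% 29:31))
  cal <- feretTable(feretDistances(sk))$caliper_px
  expect_gt(cal, 55)
  expect_lte(cal, 60)
})

test_that("side branches shorter than the minimum are pruned", {
  img <- matrix(0, 64, 100)
  img[30, 11:70] <- 100          # main curve, 60 px
  img[31:38, 40] <- 100          # 8 px spur
  sk <- skeletonizeMarker(img, method = "fixed", threshold = 50,
                          minBranchLength = 10)
  comps <- skeletonComponents(sk)
  expect_length(comps, 1)
  expect_true(all(comps[[1]][, 1] == 30))
  # with a permissive minimum the spur survives
  sk2 <- skeletonizeMarker(img, method = "fixed", threshold = 50,
                           minBranchLength = 5)
  expect_true(any(skeletonComponents(sk2)[[1]][, 1] > 30))
})

test_that("short components are discarded and empty input warns", {
  img <- matrix(0, 40, 40)
  img[20, 10:14] <- 100          # 5 px, below the 10 px floor
  expect_warning(sk <- skeletonizeMarker(img, method = "fixed",
                                         threshold = 50), "pruning")
  expect_length(skeletonComponents(sk), 0)
  expect_warning(e <- skeletonizeMarker(matrix(0, 20, 20),
                                        method = "fixed", threshold = 10),
                 "empty foreground")
  expect_length(skeletonComponents(e), 0)
  expect_error(feretDistances(e), "empty")
  expect_error(skeletonizeMarker(matrix(5, 10, 10)), "constant")
})

test_that("Feret calipers match hand-computed and brute-force values", {
  line <- cbind(rep(10L, 50), 1:50 + 0L)
  fs <- feretDistances(skeleton_from_points(line))
  expect_equal(feretTable(fs)$caliper_px, 49)
  # right angle: endpoints (1, 40) and (30, 1)
  elbow <- unique(rbind(cbind(1L, 40:1), cbind(1:30, 1L)))
  fe <- feretDistances(skeleton_from_points(elbow))
  expect_equal(feretTable(fe)$caliper_px, sqrt(29^2 + 39^2))
  expect_equal(feretTable(fe)$caliper_px, oracle_feret(elbow))
  # mean over two components
  two <- new("SkeletonSet",
             components = list(cbind(rep(1L, 21), 1:21),
                               cbind(rep(5L, 41), 1:41)),
             channel = "t", threshold = 0, minBranchLength = 0,
             dim = c(10L, 50L))
  expect_equal(mean(feretTable(feretDistances(two))$caliper_px), 30)
  # micrometre conversion
  um <- feretTable(feretDistances(skeleton_from_points(line),
                                  pixelSize = 0.5))
  expect_equal(um$caliper_um, 24.5)
})

test_that("convex-hull caliper agrees with all-pairs brute force", {
  for (s in 1:10) {
    pts <- random_walk_component(s)
    impl <- feretTable(feretDistances(skeleton_from_points(pts)))$caliper_px
    expect_equal(impl, oracle_feret(pts), info = paste("seed", s))
  }
})

test_that("mean Feret distance grows with planted fragment length", {
  lens <- c(20, 40, 60)
  means <- vapply(lens, function(L) {
    mean(vapply(1:3, function(s) {
      mx <- genMxifImage(syntheticImageConfig(
        channels = list(ribbonChannel("CD10", 4, L)), seed = s))
      sk <- skeletonizeMarker(mx$image, channel = "CD10")
      mean(feretTable(feretDistances(sk))$caliper_px)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
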
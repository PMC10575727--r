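test_that("histogram normalization stretches to [0, 255] preserving order", {
  two <- matrix(c(0, 10), 20, 20)
  out <- normalizeHistogram(two)
  expect_setequal(unique(as.vector(out)), c(0, 255))
  ramp <- matrix(seq(3, 90, length.out = 400), 20, 20)
  r <- normalizeHistogram(ramp, 0, 100)
  expect_equal(min(r), 0)
  expect_equal(max(r), 255)
  expect_true(all(diff(as.vector(r)) >= 0))
  expect_warning(out2 <- normalizeHistogram(matrix(7, 5, 5)), "constant")
  expect_equal(out2, matrix(7, 5, 5))
})

test_that("cell-type fractions divide marker maxima by nuclei maxima", {
  nuc <- matrix(0, 64, 64)
  centers <- expand.grid(r = c(10, 25, 40, 55), c = c(10, 25, 40, 55))
  for (i in seq_len(16)) {
    for (dr in -3:3) for (dc in -3:3)
      nuc[centers$r[i] + dr, centers$c[i] + dc] <-
        nuc[centers$r[i] + dr, centers$c[i] + dc] +
        100 * exp(-(dr^2 + dc^2) / 2)
  }
  marker <- matrix(0, 64, 64)
  marker[10, 10] <- 200
  marker[40, 40] <- 200
  img <- MultichannelImage(list(DAPI = nuc, CHGA = marker,
                                flat = matrix(0, 64, 64)))
  fr <- cellTypeFractions(img, "DAPI", c(CHGA = 100, flat = 100))
  expect_equal(fr$nuclei, c(16L, 16L))
  expect_equal(fr$fraction[fr$marker == "CHGA"], 2 / 16)
  expect_equal(fr$fraction[fr$marker == "flat"], 0)
  expect_false(any(fr$flag))
  blank <- MultichannelImage(list(DAPI = matrix(0, 16, 16),
                                  CHGA = matrix(0, 16, 16)))
  expect_error(suppressWarnings(
    cellTypeFractions(blank, "DAPI", c(CHGA = 100))), "no nuclei")
})

test_that("marker fractions recover generator truth", {
  mx <- genMxifImage(syntheticImageConfig(
    channels = list(spotChannel("DAPI", 50, 100, 2),
                    spotChannel("CHGA", 10, 150, 2)),
    seed = 42))
  fr <- cellTypeFractions(mx$image, "DAPI", c(CHGA = 100))
  expect_equal(fr$fraction, 10 / 50, tolerance = 0.05)
})

test_that("channel correlations match closed-form cases", {
  set.seed(11)
  a <- matrix(runif(100 * 100, 0, 50), 100)
  img <- MultichannelImage(list(a = a, self = a, inv = max(a) - a,
                                noise = matrix(runif(1e4, 0, 50), 100)))
  r <- correlationMatrix(channelCrossCorrelation(img))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["a", "self"], 1)
  expect_equal(r["a", "inv"], -1)
  expect_lt(abs(r["a", "noise"]), 0.05)
  expect_equal(r, t(r))
})

test_that("correlation is invariant to affine rescaling of a channel", {
  set.seed(3)
  x <- matrix(rnorm(2500, 50, 10), 50)
  y <- matrix(rnorm(2500, 50, 10), 50)
  r1 <- correlationMatrix(channelCrossCorrelation(
    MultichannelImage(list(x = x, y = y))))
  r2 <- correlationMatrix(channelCrossCorrelation(
    MultichannelImage(list(x = 3 * x + 20, y = y))))
  expect_equal(r1, r2)
})

test_that("constant channels are flagged NA and must be dropped", {
  img <- MultichannelImage(list(a = matrix(runif(100), 10),
                                b = matrix(runif(100), 10),
                                k = matrix(2, 10, 10)))
  expect_warning(cc <- channelCrossCorrelation(img), "constant")
  r <- correlationMatrix(cc)
  expect_true(is.na(r["k", "a"]))
  expect_equal(r["k", "k"], 1)
  expect_error(clusterCorrelation(cc), "undefined")
  dropped <- clusterCorrelation(cc, dropUndefined = TRUE)
  expect_equal(nrow(correlationMatrix(dropped)), 2)
})

test_that("clustering places correlated blocks adjacently", {
  set.seed(5)
  x <- matrix(rnorm(900), 30)
  y <- matrix(rnorm(900), 30)
  img <- MultichannelImage(list(
    a1 = abs(x) + 10, b1 = abs(y) + 10,
    a2 = abs(2 * x + 0.01 * matrix(rnorm(900), 30)) + 10,
    b2 = abs(0.5 * y + 0.01 * matrix(rnorm(900), 30)) + 10))
  cc <- clusterCorrelation(channelCrossCorrelation(img))
  ord <- rownames(correlationMatrix(cc))
  posA <- which(ord %in% c("a1", "a2"))
  posB <- which(ord %in% c("b1", "b2"))
  expect_equal(abs(diff(posA)), 1)
  expect_equal(abs(diff(posB)), 1)
  # two channels: one merge, order preserved
  two <- clusterCorrelation(channelCrossCorrelation(
    MultichannelImage(list(a = abs(x) + 1, b = abs(y) + 1))))
  expect_equal(length(two@tree$height), 1L)
  # uncorrelated identity-like matrix: all merges at equal heights
  ident <- new("ChannelCorrelationMatrix",
               r = diag(1, 3, 3) |>
                 (\(m) { dimnames(m) <- list(letters[1:3], letters[1:3]); m })())
  tr <- clusterCorrelation(ident)@tree
  expect_equal(diff(range(tr$height)), 0)
})
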
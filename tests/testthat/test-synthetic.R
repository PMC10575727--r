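test_that("image generation is seeded-deterministic with exact truth", {
  cfg <- syntheticImageConfig(
    channels = list(spotChannel("DAPI", 10, 100, 2),
                    ribbonChannel("CD10", 5, 60),
                    correlatedChannel("copy", "DAPI", 0.8)),
    noiseSd = 0, seed = 31)
  a <- genMxifImage(cfg)
  b <- genMxifImage(cfg)
  expect_identical(lapply(channelNames(a$image),
                          function(n) getChannel(a$image, n)),
                   lapply(channelNames(b$image),
                          function(n) getChannel(b$image, n)))
  expect_identical(truthOf(a$truth), truthOf(b$truth))
  expect_equal(nrow(truthOf(a$truth)$DAPI$centers), 10)
  expect_equal(truthOf(a$truth)$CD10$lengths, rep(60, 5))
  # planted endpoints really are that far apart
  ep <- truthOf(a$truth)$CD10$endpoints
  expect_equal(sqrt((ep[, 3] - ep[, 1])^2 + (ep[, 4] - ep[, 2])^2),
               rep(60, 5))
})

test_that("invalid image configs are rejected", {
  expect_error(syntheticImageConfig(list(spotChannel("a", 5, 10)),
                                    noiseSd = -1), "noise")
  expect_error(syntheticImageConfig(list(spotChannel("a", 5, 10)),
                                    size = c(0, 10)), "positive")
  expect_error(correlatedChannel("c", "a", 1.5), "\\[-1, 1\\]")
  expect_error(genMxifImage(syntheticImageConfig(
    list(ribbonChannel("r", 40, 200)), size = c(256, 256), seed = 1)),
    "overlap|fit")
})

test_that("correlated channels hit their Pearson target", {
  mx <- genMxifImage(syntheticImageConfig(
    channels = list(spotChannel("base", 30, 100, 3),
                    correlatedChannel("pos", "base", 0.8),
                    correlatedChannel("neg", "base", -0.6)),
    noiseSd = 0.5, seed = 17))
  r <- correlationMatrix(channelCrossCorrelation(mx$image))
  expect_equal(r["base", "pos"], 0.8, tolerance = 0.05)
  expect_equal(r["base", "neg"], -0.6, tolerance = 0.05)
})

test_that("Isc traces realize their event schedule", {
  flat <- genIscTrace(syntheticAssayConfig(duration = 300, baseline = 5,
                                           noiseSd = 0, seed = 1))$trace
  expect_equal(traceValue(flat), rep(5, 301))
  sus <- genIscTrace(syntheticAssayConfig(
    duration = 600, baseline = 5,
    events = data.frame(time = 100, agent = "fsk", amplitude = 20,
                        shape = "sustained"),
    noiseSd = 0, seed = 1))$trace
  expect_equal(max(traceValue(sus)) - 5, 20, tolerance = 1e-6)
  expect_equal(deltaIsc(sus, "fsk", "plateau", c(-30, 0), c(0, 300)), 20,
               tolerance = 1e-3)
  expect_error(syntheticAssayConfig(events = data.frame(
    time = c(50, 50), agent = c("a", "b"), amplitude = c(1, 2),
    shape = c("peak", "sustained"))), "incompatible")
  expect_error(syntheticAssayConfig(events = data.frame(
    time = 700, agent = "a", amplitude = 1, shape = "peak"),
    duration = 600), "within")
})

test_that("noiseless dose-inhibition responses equal the 4PL closed form", {
  cfg <- syntheticCrofelemerConfig(seed = 2, noiseSd = 0)
  run <- genDoseInhibitionRun(cfg)
  dr <- measureDoseInhibition(run$control, run$traces, run$doses)
  truth <- 0 + (80 - 0) / (1 + (30 / run$doses)^1)
  expect_equal(dr$inhibition, truth, tolerance = 1e-6)
  expect_equal(unname(unlist(truthOf(run$truth)$inhibition)), truth)
})

test_that("dose and 4PL invariants are enforced", {
  expect_error(syntheticAssayConfig(doses = c(3, 1, 10),
                                    pl4 = list(floor = 0, ceiling = 80,
                                               ic50 = 30, slope = 1)),
               "increasing")
  expect_error(syntheticAssayConfig(doses = c(1, 3),
                                    pl4 = list(floor = 0, ceiling = 80,
                                               ic50 = -1, slope = 1)),
               "IC50")
  expect_error(syntheticAssayConfig(doses = c(1, 3),
                                    pl4 = list(floor = 90, ceiling = 80,
                                               ic50 = 30, slope = 1)),
               "floor")
})

test_that("pH traces encode recovery, inhibitor scaling and clamp map", {
  zero <- genPhTrace(syntheticPhConfig(deltaPh = 0, noiseSd = 0,
                                       seed = 1))
  tt <- traceTime(zero$trace)
  post <- traceValue(zero$trace)[tt > 130 & tt < 590]
  expect_equal(diff(range(post)), 0)
  inh <- genPhTrace(syntheticPhConfig(deltaPh = 0.5, inhibitor = TRUE,
                                      inhibitorScale = 0.1, seed = 1))
  expect_equal(truthOf(inh$truth)$deltaPh, 0.05)
  cl <- genPhTrace(syntheticPhConfig(noiseSd = 0, seed = 1))
  seg <- clampSegments(cl$trace)
  expect_equal(mean(seg[["8"]]) - mean(seg[["7"]]), 0.3, tolerance = 1e-10)
  expect_error(syntheticPhConfig(clampPh = c(6, 7)), "distinct")
  expect_error(syntheticPhConfig(deltaPh = -0.1), ">= 0")
})

test_that("swelling truth matches configured growth and placement order", {
  cfg <- syntheticSwellingConfig("healthy", "agonist", nObjects = 3,
                                 areaGrowthFactors = c(1, 1.44),
                                 objectSd = 0, seed = 7)
  out <- genSwellingSeries(cfg)
  expect_equal(unname(truthOf(out$truth)$diameterRatios[, 2]),
               rep(1.2, 3))
  same <- genSwellingSeries(syntheticSwellingConfig(
    "healthy", "agonist", nObjects = 3, diameterRatios = c(1, 1),
    objectSd = 0, seed = 7))
  expect_equal(unname(truthOf(same$truth)$diameterRatios[, 2]), rep(1, 3))
  # distinct growth per object: measured mask areas match truth order
  cfg3 <- syntheticSwellingConfig("healthy", "agonist", nObjects = 3,
                                  diameterRatios = c(1, 1.3),
                                  objectSd = 0.2, seed = 8)
  out3 <- genSwellingSeries(cfg3)
  for (i in 1:3) {
    a0 <- sum(out3$masks[[1]] == i)
    a1 <- sum(out3$masks[[2]] == i)
    expect_equal(sqrt(a1 / a0),
                 unname(truthOf(out3$truth)$diameterRatios[i, 2]),
                 tolerance = 0.02)
  }
  expect_error(genSwellingSeries(syntheticSwellingConfig(
    "healthy", "agonist", nObjects = 2, radiusRange = c(200, 250),
    size = c(256, 256), seed = 1)), "overflow|bounds")
})

test_that("DE tables plant rescue genes exactly and nulls at chance rate", {
  cfg <- syntheticDeConfig(seed = 5)
  a <- genDeTables(cfg)
  b <- genDeTables(cfg)
  expect_identical(contrastData(a$baseline), contrastData(b$baseline))
  expect_identical(contrastData(a$treatment), contrastData(b$treatment))
  planted <- truthOf(a$truth)$rescueGenes
  expect_length(planted, 50)
  hits <- rescueGenes(oppositeDirectionFilter(a$baseline, a$treatment))
  expect_true(all(planted %in% hits$gene))
  # no planted genes: filter passes only nulls, ~ n * 0.05^2 / 2 expected
  none <- genDeTables(syntheticDeConfig(nRescue = 0, seed = 6))
  nullHits <- nrow(rescueGenes(
    oppositeDirectionFilter(none$baseline, none$treatment)))
  expect_lte(nullHits, qbinom(0.999, 2000, 0.05^2 / 2))
  expect_error(syntheticDeConfig(nGenes = 10, nRescue = 20), "<=")
})
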
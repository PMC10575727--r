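mkTrace <- function(values, eventTime = 100, agent = "forskolin") {
  AssayTrace(seq_along(values) - 1, values,
             data.frame(time = eventTime, agent = agent))
}

test_that("delta Isc measures baseline-subtracted responses", {
  flat <- mkTrace(rep(5, 301))
  expect_equal(deltaIsc(flat, "forskolin", "plateau", c(-30, 0), c(0, 120)),
               0)
  step <- mkTrace(c(rep(5, 101), rep(25, 200)))  # step after t = 100
  expect_equal(deltaIsc(step, "forskolin", "plateau", c(-30, 0), c(0, 120)),
               20)
  expect_equal(deltaIsc(step, "forskolin", "peak", c(-30, 0), c(0, 120)),
               20)
  expect_error(deltaIsc(step, "carbachol"), "not found")
  expect_error(deltaIsc(step, "forskolin", "plateau", c(-30, 10)),
               "precede")
  expect_error(deltaIsc(step, "forskolin", "plateau", c(-300, 0)),
               "beyond")
})

test_that("delta Isc is invariant to adding a constant to the trace", {
  g <- genIscTrace(syntheticAssayConfig(
    duration = 400, baseline = 5,
    events = data.frame(time = 100, agent = "cch", amplitude = 15,
                        shape = "peak"),
    noiseSd = 1, seed = 9))$trace
  d1 <- deltaIsc(g, "cch", "peak", c(-30, 0), c(0, 150))
  shifted <- AssayTrace(traceTime(g), traceValue(g) + 123,
                        traceEvents(g))
  expect_equal(deltaIsc(shifted, "cch", "peak", c(-30, 0), c(0, 150)), d1)
})

test_that("peak mode recovers a planted transient amplitude", {
  g <- genIscTrace(syntheticAssayConfig(
    duration = 400, baseline = 5,
    events = data.frame(time = 100, agent = "cch", amplitude = 15,
                        shape = "peak"),
    noiseSd = 0, seed = 1))$trace
  expect_equal(deltaIsc(g, "cch", "peak", c(-30, 0), c(0, 200)), 15,
               tolerance = 1e-3)
})

test_that("sensitive fraction and percent change follow their formulas", {
  expect_equal(as.numeric(sensitiveFraction(100, 20)), 80)
  expect_equal(as.numeric(sensitiveFraction(50, 50)), 0)
  over <- sensitiveFraction(40, -2)
  expect_equal(as.numeric(over), 105)
  expect_equal(attr(over, "flag"), "exceeds_100")
  expect_equal(as.numeric(sensitiveFraction(7, 0)), 100)
  expect_error(sensitiveFraction(0, 5), "zero")
  expect_equal(percentChange(10, 4), 60)
  expect_equal(percentChange(10, 10), 0)
  expect_equal(percentChange(10, 13), -30)
  expect_error(percentChange(0, 1), "zero")
})

test_that("4PL fit recovers noiseless parameters to < 1% relative error", {
  d <- c(1, 3, 10, 30, 100, 300)
  y <- 0 + (80 - 0) / (1 + (30 / d)^1)
  fit <- fitDoseResponse(d, y)
  expect_true(fit@converged)
  expect_lt(abs(fit@ic50 - 30) / 30, 0.01)
  expect_lt(abs(fit@ceiling - 80) / 80, 0.01)
  expect_lt(abs(fit@floor), 0.5)
  expect_lt(abs(fit@slope - 1), 0.01)
  expect_error(fitDoseResponse(d, rep(0, 6)), "degenerate")
  expect_error(fitDoseResponse(c(1, 3, 10), c(1, 2, 3)), "4 distinct")
  expect_error(fitDoseResponse(c(-1, 3, 10, 30), c(1, 2, 3, 4)),
               "positive")
})

test_that("median IC50 recovery stays within 15% at 5% trace noise", {
  ic50s <- vapply(1:20, function(s) {
    run <- genDoseInhibitionRun(syntheticCrofelemerConfig(seed = s))
    dr <- measureDoseInhibition(run$control, run$traces, run$doses)
    fitDoseResponse(dr$dose, dr$inhibition)@ic50
  }, numeric(1))
  expect_lt(abs(median(ic50s) - 30) / 30, 0.15)
})
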
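test_that("calibration fits collinear clamps exactly", {
  cal <- fitCalibration(data.frame(pH = c(6, 7, 8),
                                   signal = c(0.2, 0.5, 0.8)))
  expect_equal(cal@slope, 10 / 3, tolerance = 1e-10)
  expect_equal(cal@intercept + cal@slope * 0.5, 7, tolerance = 1e-10)
  expect_equal(cal@residuals, rep(0, 3), tolerance = 1e-10)
  expect_error(fitCalibration(data.frame(pH = c(6, 7),
                                         signal = c(0.2, 0.5))),
               "3 distinct")
  expect_error(fitCalibration(data.frame(pH = c(6, 7, 8),
                                         signal = c(0.5, 0.2, 0.8))),
               "monotone")
})

test_that("calibration recovers a noisy affine truth within 5%", {
  for (s in 1:5) {
    g <- genPhTrace(syntheticPhConfig(seed = s))
    cal <- fitCalibration(clampSegments(g$trace))
    # trace stores signal = 0.3 * pH - 1.5, so pH = (signal + 1.5) / 0.3
    expect_equal(cal@slope, 1 / 0.3, tolerance = 0.05)
  }
})

test_that("signal-to-pH mapping is exact on calibrated signals", {
  cal <- fitCalibration(data.frame(pH = c(6, 7, 8),
                                   signal = c(0.3, 0.6, 0.9)))
  tr <- AssayTrace(0:10, rep(0.6, 11), unit = "au")
  ph <- signalToPh(tr, cal)
  expect_equal(traceValue(ph), rep(7, 11), tolerance = 1e-10)
  expect_false(any(attr(ph, "extrapolated")))
  out <- AssayTrace(0:10, rep(0.99, 11), unit = "au")
  expect_warning(ph2 <- signalToPh(out, cal), "extrapolated")
  expect_true(all(attr(ph2, "extrapolated")))
  expect_equal(traceValue(ph2)[1], cal@intercept + cal@slope * 0.99)
})

test_that("NHE activity quantifies recovery magnitude and rate", {
  flat <- AssayTrace(seq(0, 600, 2), rep(7, 301), unit = "pH")
  act <- nheActivity(flat, 100, 400)
  expect_equal(act@deltaPh, 0)
  expect_equal(act@rate, 0)
  # linear rise 6.8 -> 7.2 over 200 s then stable plateau
  tt <- seq(0, 600, 2)
  ph <- ifelse(tt < 100, 6.8,
               ifelse(tt < 300, 6.8 + 0.4 * (tt - 100) / 200, 7.2))
  act2 <- nheActivity(AssayTrace(tt, ph, unit = "pH"), 100, 400)
  expect_equal(act2@deltaPh, 0.4, tolerance = 1e-10)
  expect_equal(act2@rate, 0.002, tolerance = 1e-10)
  expect_error(nheActivity(flat, 700, 100), "outside")
  expect_error(nheActivity(flat, 100, 1000), "beyond")
  expect_error(nheActivity(AssayTrace(seq(0, 600, 50), rep(7, 13),
                                      unit = "pH"), 100, 400),
               "too short")
})

test_that("NHE activity is invariant to time-axis origin shifts", {
  g <- genPhTrace(syntheticPhConfig(seed = 3))
  cal <- fitCalibration(clampSegments(g$trace))
  ph <- suppressWarnings(signalToPh(g$trace, cal))
  a <- nheActivity(ph, 120, 480)
  shifted <- AssayTrace(traceTime(ph) + 1000, traceValue(ph), unit = "pH")
  b <- nheActivity(shifted, 1120, 480)
  expect_equal(a@deltaPh, b@deltaPh)
  expect_equal(a@rate, b@rate)
})

test_that("full synthetic round trip recovers the planted delta pH", {
  errs <- vapply(1:10, function(s) {
    g <- genPhTrace(syntheticPhConfig(noiseSd = 0.02, seed = s))
    cal <- fitCalibration(clampSegments(g$trace))
    ph <- suppressWarnings(signalToPh(g$trace, cal))
    act <- nheActivity(ph, truthOf(g$truth)$readditionTime,
                       truthOf(g$truth)$recoveryWindow)
    act@deltaPh - truthOf(g$truth)$deltaPh
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(max(abs(errs)), 0.05)
})

test_that("inhibitor correction subtracts, floors at zero and flags", {
  mk <- function(d) new("NheActivityResult", deltaPh = d, rate = 0.01,
                        nRate = 10L, flags = character())
  expect_equal(inhibitorCorrected(mk(0.45), mk(0.05)), 0.40)
  expect_equal(inhibitorCorrected(mk(0.05), mk(0.05)), 0)
  neg <- inhibitorCorrected(mk(0.04), mk(0.06))
  expect_equal(as.numeric(neg), 0)
  expect_equal(attr(neg, "flag"), "negative_difference")
})
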
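test_that("Debye intensity reproduces the one- and two-bead closed forms", {
  s <- seq(0, 2, by = 0.1)
  one <- debyeIntensity(matrix(0, 1, 3), s)
  expect_equal(one@intensity, rep(1, length(s)))
  d <- 15  # Angstrom -> 1.5 nm
  two <- debyeIntensity(rbind(c(0, 0, 0), c(d, 0, 0)), s)
  want <- ifelse(s == 0, 4, 2 * (1 + sin(s * 1.5) / (s * 1.5)) )
  expect_equal(two@intensity, want, tolerance = 1e-12)
  # symmetric in bead order, non-negative for positive form factors
  two2 <- debyeIntensity(rbind(c(d, 0, 0), c(0, 0, 0)), s)
  expect_equal(two2@intensity, two@intensity)
  expect_true(all(two@intensity >= -1e-9))
  expect_error(debyeIntensity(matrix(0, 1, 3), -0.1), "non-negative")
})

test_that("Guinier fit of a Debye bead curve matches the coordinate Rg", {
  hc <- makeHollowCylinder(30, 10, 10, 400, seed = 5)
  curve <- debyeIntensity(coords(hc), seq(0.01, 0.6, by = 0.01))
  fit <- guinierFit(curve)
  expect_equal(fit@rg, radiusOfGyration(coords(hc)), tolerance = 0.01)
})

test_that("noiseless Guinier curves are recovered to machine precision", {
  cv <- makeGuinierCurve(5.28, i0 = 3.7, sGrid = seq(0.02, 0.5, by = 0.005))
  fit <- guinierFit(cv)
  expect_equal(fit@rg, 5.28, tolerance = 1e-10)
  expect_equal(fit@i0, 3.7, tolerance = 1e-10)
  expect_true(fit@converged)
  # window rule: ceiling at s.Rg <= 1.3 reproduces ~0.246 nm^-1 at Rg 5.28
  expect_lte(fit@sRgMax, 1.3 + 1e-9)
  expect_equal(fit@window[2], 0.245, tolerance = 1e-9)  # grid point below 1.3/5.28
})

test_that("scale invariance: scaling I scales I0 but not Rg", {
  cv <- makeGuinierCurve(4.1, sGrid = seq(0.02, 0.6, by = 0.01))
  f1 <- guinierFit(cv)
  f2 <- guinierFit(scatteringCurve(cv@s, 100 * cv@intensity))
  expect_equal(f2@rg, f1@rg, tolerance = 1e-12)
  expect_equal(f2@i0, 100 * f1@i0, tolerance = 1e-9)
})

test_that("sphere curves recover sqrt(3/5) R within 1% on a tight window", {
  sc <- makeSphereCurve(10)
  fit <- guinierFit(sc, sRgLimit = 0.8)
  expect_equal(fit@rg, sqrt(3 / 5) * 10, tolerance = 0.01)
  # first form-factor minimum near s R = 4.493 (tan x = x root)
  wide <- makeSphereCurve(10, sGrid = seq(0.005, 0.55, by = 0.001))
  i <- which.min(wide@intensity[wide@s * 10 < 5.5])
  expect_equal(wide@s[i] * 10, 4.493, tolerance = 0.002)
})

test_that("2%-noise ensembles recover Rg within 2% on average with honest errors", {
  rgs <- ses <- numeric(100)
  for (i in 1:100) {
    cv <- makeGuinierCurve(5.28, sGrid = seq(0.02, 0.5, by = 0.005),
                           noiseFraction = 0.02, seed = i)
    f <- guinierFit(cv)
    rgs[i] <- f@rg; ses[i] <- f@rgStderr
  }
  expect_equal(mean(rgs), 5.28, tolerance = 0.02)
  # ~95% interval from the propagated slope stderr covers the truth
  expect_gte(sum(abs(rgs - 5.28) <= 2 * ses), 90)
})

test_that("guinier window diagnostics and error paths behave", {
  cv <- makeGuinierCurve(5.28, sGrid = seq(0.02, 0.5, by = 0.005))
  expect_error(guinierFit(cv, sMin = 0.496), "at least 3 points")
  bad <- scatteringCurve(c(0.01, 0.02, 0.03, 0.04),
                         c(1, 0.999, -0.5, 0.997))
  expect_error(suppressWarnings(guinierFit(bad)), "non-positive intensity")
  flat <- scatteringCurve(seq(0.01, 0.1, by = 0.01), rep(1, 10))
  expect_error(guinierFit(flat), "non-negative")
})

test_that("DAT curve files round-trip", {
  cv <- makeGuinierCurve(5.28, sGrid = seq(0.02, 0.3, by = 0.01),
                         noiseFraction = 0.02, seed = 3)
  tf <- tempfile(fileext = ".dat")
  writeScatteringCurve(cv, tf)
  cv2 <- readScatteringCurve(tf)
  expect_equal(cv2@s, cv@s, tolerance = 1e-7)
  expect_equal(cv2@intensity, cv@intensity, tolerance = 1e-6)
  expect_equal(cv2@sigma, cv@sigma, tolerance = 1e-6)
})
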
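test_that("hollow-cylinder fixture is measured at its generating dimensions", {
  hc <- makeHollowCylinder(100, 35, 25, 20000, seed = 2)
  g <- measureRingGeometry(hc, uniformMass = TRUE)
  expect_equal(g@outerDiameter, 20, tolerance = 0.01)
  # the cavity edge is measured from the sampled centroid, whose sampling
  # error (~Rg/sqrt(n) per axis) dominates the bead-grid resolution
  expect_equal(g@cavityDiameter, 7, tolerance = 0.05)
  expect_equal(g@height, 2.5, tolerance = 0.01)
  expect_equal(g@ringWidth, (g@outerDiameter - g@cavityDiameter) / 2)
})

test_that("geometry measurement is invariant to rigid motion (axis recovery)", {
  hc <- makeHollowCylinder(100, 35, 25, 5000, seed = 2)
  g0 <- measureRingGeometry(hc, uniformMass = TRUE)
  R <- ringswap:::.rotationAbout(c(1, 2, 0.5), 1.1)
  a <- atoms(hc)
  a[, c("x", "y", "z")] <- ringswap:::.applyTransform(
    as.matrix(a[, c("x", "y", "z")]), R, c(30, -12, 7))
  moved <- new("MonomerStructure", atoms = a, annotations = list())
  g1 <- measureRingGeometry(moved, uniformMass = TRUE)
  expect_equal(g1@outerDiameter, g0@outerDiameter, tolerance = 1e-3)
  expect_equal(g1@cavityDiameter, g0@cavityDiameter, tolerance = 1e-3)
  expect_equal(g1@height, g0@height, tolerance = 1e-3)
  expect_equal(g1@rg, g0@rg, tolerance = 1e-9)
})

test_that("a single point has degenerate geometry", {
  g <- measureRingGeometry(pointSubunit(), uniformMass = TRUE)
  expect_equal(c(g@outerDiameter, g@cavityDiameter, g@height, g@rg),
               rep(0, 4))
})

test_that("radius of gyration: symmetry, hoop limit, rigid invariance", {
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radiusOfGyration(two), 0.1)  # 1 A in nm
  th <- 2 * pi * seq_len(5000) / 5000
  hoop <- cbind(25 * cos(th), 25 * sin(th), 0)
  expect_equal(radiusOfGyration(hoop), 2.5, tolerance = 1e-6)
  set.seed(31)
  x <- matrix(rnorm(60), 20, 3)
  R <- ringswap:::.rotationAbout(c(1, 1, 1), 0.8)
  moved <- ringswap:::.applyTransform(x, R, c(5, 6, 7))
  expect_equal(radiusOfGyration(moved), radiusOfGyration(x),
               tolerance = 1e-12)
  expect_error(radiusOfGyration(x[0, , drop = FALSE]), "empty")
  expect_error(radiusOfGyration(x, masses = rep(-1, 20)), "positive")
})

test_that("mass weighting changes Rg when masses are uneven", {
  x <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  expect_lt(radiusOfGyration(x, masses = c(10, 1)),
            radiusOfGyration(x, masses = c(1, 1)))
})

test_that("annular closed form hits hoop and disc limits", {
  expect_equal(annulusRg(7, 7, 0), 7)
  expect_equal(annulusRg(1, 0, 0), 1 / sqrt(2))
  expect_error(annulusRg(1, 2, 0), "outerRadius >= innerRadius")
})

test_that("annulusRg matches Monte-Carlo volume integration within 0.5%", {
  grid <- expand.grid(rOut = c(1, 10.75, 12), rIn = c(0, 3.25),
                      h = c(0, 2.5, 6))
  grid <- grid[grid$rOut >= grid$rIn, ]
  mc <- function(rOut, rIn, h, n = 4e5) {
    x <- runif(n, -rOut, rOut); y <- runif(n, -rOut, rOut)
    keep <- x^2 + y^2 <= rOut^2 & x^2 + y^2 >= rIn^2
    z <- if (h > 0) runif(sum(keep), -h / 2, h / 2) else 0
    sqrt(mean(x[keep]^2 + y[keep]^2 + z^2))
  }
  set.seed(99)
  for (i in seq_len(nrow(grid))) {
    cf <- annulusRg(grid$rOut[i], grid$rIn[i], grid$h[i])
    expect_equal(cf, mc(grid$rOut[i], grid$rIn[i], grid$h[i]),
                 tolerance = 0.005)
  }
})

test_that("bead-model Rg agrees with the closed form within 2%", {
  hc <- makeHollowCylinder(100, 35, 25, 30000, seed = 12)
  expect_equal(radiusOfGyration(hc, masses = rep(1, 30000)),
               annulusRg(10, 3.5, 2.5), tolerance = 0.02)
})

test_that("constraint filtering is inclusive and lists every violation", {
  g <- new("RingGeometry", outerDiameter = 21, cavityDiameter = 10,
           ringWidth = 5.5, height = 2.0, rg = 7.5)
  expect_true(filterByConstraints(g, table1Constraints(c("TEM", "AFM")))@pass)
  expect_true(filterByConstraints(g, constraintSet())@pass)  # vacuous
  gEdge <- new("RingGeometry", outerDiameter = 16, cavityDiameter = 5,
               ringWidth = 5.5, height = 2.0, rg = 7.5)
  expect_true(filterByConstraints(
    gEdge, constraintSet(outerDiameter = c(16, 24)))@pass)  # boundary is in
  v <- filterByConstraints(g, constraintSet(outerDiameter = c(0, 1),
                                            height = c(3, 4)))
  expect_false(v@pass)
  expect_setequal(v@failed$parameter, c("outerDiameter", "height"))
})

test_that("the reference constraint rows intersect where they overlap", {
  cs <- table1Constraints(c("TEM", "AFM"))
  expect_equal(cs@bounds$outerDiameter, c(16, 24))
  expect_equal(cs@bounds$ringWidth, c(5, 6))
  expect_equal(cs@bounds$height, c(1.6, 2.5))
  # TEM and SAXS report incompatible annulus widths (5-6 vs 7-8 nm); asking
  # for their intersection is an empty interval and fails loudly
  expect_error(table1Constraints(c("TEM", "SAXS")), "min exceeds max")
  expect_error(table1Constraints("XRD"))
})
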
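test_that("generators are pure functions of their seed", {
  m1 <- makeToyMonomer(seed = 42)
  m2 <- makeToyMonomer(seed = 42)
  expect_identical(atoms(m1), atoms(m2))
  expect_false(identical(coords(m1), coords(makeToyMonomer(seed = 43))))
  h1 <- makeHollowCylinder(50, 20, 10, 500, seed = 9)
  h2 <- makeHollowCylinder(50, 20, 10, 500, seed = 9)
  expect_identical(atoms(h1), atoms(h2))
  c1 <- makeGuinierCurve(5, noiseFraction = 0.02, seed = 3)
  c2 <- makeGuinierCurve(5, noiseFraction = 0.02, seed = 3)
  expect_identical(c1@intensity, c2@intensity)
  t1 <- makeTrajectory(m1, 3, noiseSigma = 0.2, seed = 5)
  t2 <- makeTrajectory(m1, 3, noiseSigma = 0.2, seed = 5)
  expect_identical(t1@frames, t2@frames)
})

test_that("seed streams are independent per generator", {
  expect_false(generatorSeed(1, "toy_monomer") ==
                 generatorSeed(1, "hollow_cylinder"))
  expect_false(generatorSeed(1, "toy_monomer") ==
                 generatorSeed(2, "toy_monomer"))
  expect_lt(generatorSeed(.Machine$integer.max, "trajectory"), 2^31)
})

test_that("toy monomer has the designed size, numbering and shape", {
  m <- makeToyMonomer()
  a <- atoms(m)
  expect_equal(sort(unique(a$resno)), 1:120)
  expect_equal(nchar(sequenceOf(m)), 120L)
  expect_true(all(c("N", "CA", "C", "O") %in% a$name[a$resno == 60]))
  # compact, flat, elongated subunit
  rg <- radiusOfGyration(m)
  expect_gt(rg, 1.0); expect_lt(rg, 1.8)
  ext <- apply(coords(m), 2, function(v) diff(range(v)))
  expect_gt(ext[1], 50); expect_lt(ext[1], 60)   # radial span: ring width 5-6 nm
  expect_lt(ext[3], 25)                          # flat: height under 2.5 nm
  expect_error(makeToyMonomer(nResidues = 10), ">= 20")
  m80 <- makeToyMonomer(nResidues = 80, seed = 2)
  expect_equal(length(unique(atoms(m80)$resno)), 80L)
})

test_that("toy monomer truth labels agree with the assigner", {
  m <- makeToyMonomer(seed = 1)
  truth <- annotations(m)$ssTruth
  expect_equal(length(truth), 120L)
  lab <- assignSecondaryStructure(m)
  keep <- interiorMask(truth)
  expect_gte(mean(lab[keep] == truth[keep]), 0.9)
})

test_that("hollow cylinder respects its bounds and closed-form Rg", {
  hc <- makeHollowCylinder(100, 35, 25, 20000, seed = 4)
  xyz <- coords(hc)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  expect_true(all(r >= 35 - 1e-9 & r <= 100 + 1e-9))
  expect_true(all(abs(xyz[, 3]) <= 12.5 + 1e-9))
  expect_equal(radiusOfGyration(xyz), annulusRg(10, 3.5, 2.5),
               tolerance = 0.01)
  expect_error(makeHollowCylinder(10, 20, 5, 10), "outerRadius")
  expect_error(makeHollowCylinder(10, 2, 5, 0), "nBeads")
})

test_that("trajectory generator honours motion, noise and schedules", {
  m <- makeToyMonomer(seed = 8)
  tr <- makeTrajectory(m, 4, seed = 2)
  expect_equal(nFrames(tr), 4L)
  expect_equal(tr@frames[[4]], coords(m))
  expect_error(makeTrajectory(m, 0), "nFrames")
  expect_error(
    makeTrajectory(m, 5, hbondSchedule = list(
      list(donor = c("A", 110), acceptor = c("A", 5), onFrames = 1:9)),
      seed = 1),
    "beyond nFrames")
  tr2 <- makeTrajectory(m, 10, hbondSchedule = list(
    list(donor = c("A", 110), acceptor = c("A", 5), onFrames = c(2L, 7L))),
    seed = 1)
  a <- atoms(m)
  nIdx <- which(a$resno == 110 & a$name == "N")
  oIdx <- which(a$resno == 5 & a$name == "O")
  dists <- vapply(tr2@frames, function(f)
    sqrt(sum((f[nIdx, ] - f[oIdx, ])^2)), numeric(1))
  expect_true(all(dists[c(2, 7)] < 3.5))
  expect_true(all(dists[-c(2, 7)] >= 8))
})

test_that("synthetic scattering curves match their stated models", {
  sg <- seq(0.01, 0.4, by = 0.01)
  cv <- makeGuinierCurve(5.28, i0 = 2, sGrid = sg)
  expect_equal(cv@intensity, 2 * exp(-sg^2 * 5.28^2 / 3))
  sc <- makeSphereCurve(10, sGrid = c(1e-9, sg))
  expect_equal(sc@intensity[1], 1, tolerance = 1e-9)
  x <- sg * 10
  expect_equal(sc@intensity[-1], (3 * (sin(x) - x * cos(x)) / x^3)^2)
  expect_error(makeGuinierCurve(-1), "rg")
  expect_error(makeSphereCurve(0), "radius")
})

test_that("synthetic crystal-structure stand-ins carry their design labels", {
  mono <- makeSyntheticCystatinMonomer(seed = 1)
  expect_equal(length(annotations(mono)$ssTruth), 120L)
  dim <- makeSyntheticCystatinDimer(seed = 1)
  expect_equal(length(chainIds(dim)), 2L)
  expect_equal(length(annotations(dim)$ssTruth), 240L)
  expect_identical(sequenceOf(dim, "A"), sequenceOf(dim, "B"))
})
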
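test_that("kabsch recovers a known rigid transform exactly", {
  set.seed(21)
  ref <- matrix(rnorm(45, sd = 8), 15, 3)
  expect_equal(kabschSuperpose(ref, ref)@rmsd, 0, tolerance = 1e-12)
  expect_equal(kabschSuperpose(ref, ref)@rotation, diag(3), tolerance = 1e-9)
  R <- ringswap:::.rotationAbout(c(0.2, -1, 0.4), 1.3)
  t <- c(12, -3, 8)
  mob <- ringswap:::.applyTransform(ref, R, t)
  s <- kabschSuperpose(mob, ref)
  expect_lt(s@rmsd, 1e-9)
  expect_lt(max(abs(s@rotation %*% R - diag(3))), 1e-9)
  expect_error(kabschSuperpose(mob[1:4, ], ref), "point counts differ")
  expect_error(kabschSuperpose(mob[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("kabsch matches brute-force rotation-grid minimization", {
  set.seed(22)
  ref <- matrix(rnorm(12, sd = 5), 4, 3)
  mob <- ref + matrix(rnorm(12, sd = 0.8), 4, 3)
  got <- kabschSuperpose(mob, ref)@rmsd
  best <- bruteForceRMSD(mob, ref)
  expect_lt(abs(got - best), 1e-3)
  expect_lte(got, best + 1e-9)  # closed form is never worse than the search
})

test_that("rmsd series: static, rigid-motion and noisy trajectories", {
  m <- makeToyMonomer(seed = 13)
  static <- makeTrajectory(m, 5, seed = 1)
  expect_equal(rmsdSeries(static), rep(0, 5), tolerance = 1e-12)
  rot <- function(i) list(rotation = ringswap:::.rotZ(0.15 * i),
                          translation = c(2 * i, -i, 0.5 * i))
  moving <- makeTrajectory(m, 6, rigidMotion = rot, seed = 1)
  expect_lt(max(rmsdSeries(moving, reference = coords(m))), 1e-9)
  sigma <- 0.5
  noisy <- makeTrajectory(m, 20, noiseSigma = sigma, seed = 9)
  series <- rmsdSeries(noisy, reference = coords(m), selection = "all")
  expect_equal(mean(series), sigma * sqrt(3), tolerance = 0.15)
  expect_error(rmsdSeries(static, selection = "ZZ"), "empty")
})

test_that("TM-score: identity, d0 formula, displacement family", {
  set.seed(33)
  ref <- matrix(rnorm(360, sd = 10), 120, 3)
  tm <- tmScore(ref, ref)
  expect_equal(tm@score, 1.0, tolerance = 1e-12)
  expect_equal(tm@d0, 1.24 * 105^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm@d0, 4.05, tolerance = 1e-3)
  d0 <- tm@d0
  pair <- circleDisplacementPair(120, d0)
  # the least-squares superposition leaves the displacements unchanged ...
  sup <- kabschSuperpose(pair$mob, pair$ref)
  expect_equal(sup@rmsd, d0, tolerance = 1e-9)
  expect_lt(max(abs(sup@rotation - diag(3))), 1e-9)
  # ... so the plug-in score at that superposition is exactly 1/2
  expect_equal(tmScore(pair$mob, pair$ref, optimize = FALSE)@score, 0.5,
               tolerance = 1e-9)
  # maximizing over superpositions can only help
  expect_gte(tmScore(pair$mob, pair$ref)@score, 0.5)
  expect_error(tmScore(ref[1:10, ], ref[1:10, ]), "L > 15")
})

test_that("TM-score is rigid-motion invariant and decays with displacement", {
  set.seed(34)
  ref <- matrix(rnorm(240, sd = 9), 80, 3)
  mob <- ref + matrix(rnorm(240, sd = 1.5), 80, 3)
  base <- tmScore(mob, ref)@score
  R <- ringswap:::.rotationAbout(c(1, 0, 2), 2.1)
  moved <- ringswap:::.applyTransform(mob, R, c(-4, 9, 1))
  expect_equal(tmScore(moved, ref)@score, base, tolerance = 1e-6)
  d0 <- ringswap:::.tmD0(120)
  scores <- vapply(c(0.5, 1, 2, 4), function(f) {
    pair <- circleDisplacementPair(120, f * d0)
    tmScore(pair$mob, pair$ref, optimize = FALSE)@score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("hydrogen-bond occupancy reproduces scheduled fractions exactly", {
  m <- makeToyMonomer(seed = 13)
  sched <- list(list(donor = c("A", 110), acceptor = c("A", 5),
                     onFrames = 1:42),
                list(donor = c("A", 90), acceptor = c("A", 20),
                     onFrames = seq_len(50)))  # always bonded
  tr <- makeTrajectory(m, 50, hbondSchedule = sched, seed = 14)
  pairs <- data.frame(
    donorChain = "A", donorResno = c(110, 90), donorAtom = "N",
    acceptorChain = "A", acceptorResno = c(5, 20), acceptorAtom = "O",
    stringsAsFactors = FALSE)
  occ <- hbondOccupancy(tr, pairs)
  expect_equal(occ$occupancy, c(42 / 50, 1.0))
  # a pair held ~10 A apart never bonds
  far <- data.frame(donorChain = "A", donorResno = 110, donorAtom = "N",
                    acceptorChain = "A", acceptorResno = 5,
                    acceptorAtom = "O", stringsAsFactors = FALSE)
  trFar <- makeTrajectory(m, 10, hbondSchedule = list(
    list(donor = c("A", 110), acceptor = c("A", 5),
         onFrames = integer(0))), seed = 15)
  expect_equal(hbondOccupancy(trFar, far)$occupancy, 0)
  bad <- far; bad$donorResno <- 999
  expect_error(hbondOccupancy(trFar, bad), "unknown donor")
})
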
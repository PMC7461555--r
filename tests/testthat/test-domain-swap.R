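test_that("two-subunit swap exchanges the tail segments", {
  m <- makeToyMonomer(seed = 4)
  ring <- buildRing(m, 2, placementParams(60))
  sw <- applyCyclicSwap(ring)
  a <- atoms(sw)
  expect_setequal(unique(a$origChain[a$chain == "A" & a$resno <= 58]), "A")
  expect_setequal(unique(a$origChain[a$chain == "A" & a$resno >= 59]), "B")
  expect_setequal(unique(a$origChain[a$chain == "B" & a$resno >= 59]), "A")
})

test_that("the swap is a pure relabeling: coordinates conserved bitwise", {
  m <- makeToyMonomer(seed = 4)
  for (n in c(10L, 12L)) {
    ring <- buildRing(m, n, placementParams(74))
    sw <- applyCyclicSwap(ring)
    expect_equal(nAtoms(sw), nAtoms(ring))
    expect_equal(length(chainIds(sw)), n)
    keyOf <- function(s) sort(apply(atoms(s)[, c("x", "y", "z")], 1,
                                    paste, collapse = "|"))
    expect_identical(keyOf(sw), keyOf(ring))
  }
})

test_that("every swapped chain has the monomer sequence", {
  m <- makeToyMonomer(seed = 4)
  sw <- applyCyclicSwap(buildRing(m, 12, placementParams(74)))
  for (ch in chainIds(sw))
    expect_equal(sequenceOf(sw, ch), sequenceOf(m))
})

test_that("the swap is an n-cycle: its n-th power is the identity", {
  m <- makeToyMonomer(seed = 4)
  for (n in c(3L, 10L)) {
    ring <- buildRing(m, n, placementParams(74))
    cur <- ring
    partition <- function(s) {
      a <- atoms(s)
      sort(paste(a$chain, round(a$x, 3), round(a$y, 3), round(a$z, 3)))
    }
    for (i in seq_len(n)) {
      cur <- applyCyclicSwap(cur)
      if (i < n) expect_false(identical(partition(cur), partition(ring)))
    }
    a0 <- atoms(ring); an <- atoms(cur)
    ord0 <- order(a0$chain, a0$resno, a0$name)
    ordn <- order(an$chain, an$resno, an$name)
    expect_equal(a0[ord0, c("chain", "resno", "name", "x", "y", "z")],
                 an[ordn, c("chain", "resno", "name", "x", "y", "z")],
                 ignore_attr = TRUE)
  }
})

test_that("swap preconditions are enforced", {
  m <- makeToyMonomer(seed = 4)
  expect_error(applyCyclicSwap(buildRing(m, 1, placementParams(40))),
               "single-chain")
  ring <- buildRing(m, 3, placementParams(74))
  a <- atoms(ring)
  a <- a[!(a$chain == "B" & a$resno == 58L), ]
  a$serial <- seq_len(nrow(a))
  broken <- new("RingAssembly", atoms = a, annotations = list(),
                nSubunits = 3L, transforms = ring@transforms,
                symmetryAxis = c(0, 0, 1), placement = ring@placement)
  expect_error(applyCyclicSwap(broken), "residue 58 missing in chain B")
})

test_that("junction report measures C(58)-N(59) distances per chain", {
  m <- makeToyMonomer(seed = 4)
  jr <- junctionReport(m)
  expect_equal(nrow(jr$junctions), 1L)
  expect_equal(jr$junctions$distance, 1.33, tolerance = 0.06)
  sw <- applyCyclicSwap(buildRing(m, 12, placementParams(74)))
  jr12 <- junctionReport(sw)
  expect_equal(nrow(jr12$junctions), 12L)
  expect_equal(unname(jr12$summary["mean"]), mean(jr12$junctions$distance))
  expect_true(all(jr12$junctions$donorChain != jr12$junctions$acceptorChain))
})

test_that("missing internal segments are rebuilt with physical CA steps", {
  m <- makeToyMonomer(seed = 6)
  expect_identical(rebuildMissingSegment(m), m)  # no gaps -> unchanged
  a <- atoms(m)
  # delete two helix residues (the spec's short-anchor regime)
  a <- a[!(a$resno %in% c(14L, 15L)), ]
  a$serial <- seq_len(nrow(a))
  gappy <- new("MonomerStructure", atoms = a,
               annotations = list(missingSegments =
                                    ringswap:::.detectMissingSegments(a)))
  fixed <- rebuildMissingSegment(gappy)
  expect_length(missingSegments(fixed), 0L)
  expect_equal(sort(unique(atoms(fixed)$resno)), 1:120)
  ins <- atoms(fixed)
  ins14 <- ins[ins$resno == 14L, "name"]
  expect_true(all(c("N", "CA", "C", "O", "CB") %in% ins14))
  ca <- ins[ins$name == "CA" & ins$resno %in% 12:17, ]
  steps <- sqrt(rowSums(diff(as.matrix(ca[, c("x", "y", "z")]))^2))
  expect_true(all(steps >= 2.8 & steps <= 4.2))
})

test_that("terminal gaps are rejected explicitly", {
  m <- makeToyMonomer(seed = 6)
  expect_error(rebuildMissingSegment(m, gap = c(121L, 123L)),
               "not flanked")
})
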
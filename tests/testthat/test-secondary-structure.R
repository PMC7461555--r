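# Kabsch-Sander assignment on constructed geometries with known answers.

test_that("an ideal poly-Ala alpha-helix is assigned mostly helix", {
  bb <- ringswap:::.buildBackboneFromTorsions(rep(-57, 20), rep(-47, 20))
  res <- ringswap:::.residueAtomsFromBackbone(bb, rep(-47, 20))
  tab <- ringswap:::.atomTableFromResidues(res, resno = 1:20)
  s <- new("MonomerStructure", atoms = tab, annotations = list())
  lab <- assignSecondaryStructure(s)
  expect_gte(mean(lab == "H"), 0.8)   # termini excluded by the bond pattern
  expect_equal(sum(lab == "E"), 0L)
})

test_that("a fully extended chain with no partners has no helix or sheet", {
  bb <- ringswap:::.buildBackboneFromTorsions(rep(-180, 15), rep(180, 15))
  res <- ringswap:::.residueAtomsFromBackbone(bb, rep(180, 15))
  tab <- ringswap:::.atomTableFromResidues(res, resno = 1:15)
  s <- new("MonomerStructure", atoms = tab, annotations = list())
  lab <- assignSecondaryStructure(s)
  expect_equal(sum(lab %in% c("H", "E")), 0L)
})

test_that("two registered antiparallel strands are labelled E on both", {
  e <- asNamespace("ringswap")
  tpl <- e$.alignedSegment(12, -139, 135, rollObjective = "carbonylY")
  s1 <- e$.placeSegment(tpl, c(0, 0, 0))
  s2 <- e$.placeSegment(tpl, c(2.75, 4.2, 0), flipAxis = c(0, 0, 1))
  t1 <- e$.atomTableFromResidues(s1, resno = 1:12, chain = "A")
  t2 <- e$.atomTableFromResidues(s2, resno = 1:12, chain = "B")
  tab <- rbind(t1, t2); tab$serial <- seq_len(nrow(tab))
  s <- new("RingAssembly", atoms = tab, annotations = list(),
           nSubunits = 2L, transforms = list(), symmetryAxis = c(0, 0, 1),
           placement = list(axisKnown = FALSE))
  lab <- assignSecondaryStructure(s)
  perChain <- split(lab, rep(c("A", "B"), each = 12))
  expect_gte(mean(perChain$A == "E"), 0.7)
  expect_gte(mean(perChain$B == "E"), 0.7)
})

test_that("assignment is backbone-only: residue identity does not matter", {
  m <- makeToyMonomer(seed = 17)
  lab1 <- assignSecondaryStructure(m)
  a <- atoms(m)
  a$resid <- "GLY"
  a <- a[a$name != "CB", ]
  a$serial <- seq_len(nrow(a))
  g <- new("MonomerStructure", atoms = a, annotations = list())
  expect_identical(unname(assignSecondaryStructure(g)), unname(lab1))
})

test_that("incomplete backbones fall back to coil with a counter", {
  m <- makeToyMonomer(seed = 17)
  a <- atoms(m)
  a <- a[!(a$resno == 15 & a$name == "O"), ]
  a$serial <- seq_len(nrow(a))
  s <- new("MonomerStructure", atoms = a, annotations = list())
  lab <- assignSecondaryStructure(s)
  expect_equal(unname(lab[15]), "C")
  expect_gte(attr(lab, "incomplete"), 1L)
})

test_that("ss content fractions are exact and sum to one", {
  expect_equal(ssContent(rep("H", 10)),
               c(helix = 1, sheet = 0, turn = 0, coil = 0))
  expect_equal(ssContent(strsplit("HHEETTCC", "")[[1]]),
               c(helix = 0.25, sheet = 0.25, turn = 0.25, coil = 0.25))
  m <- makeToyMonomer(seed = 17)
  ss <- ssContent(assignSecondaryStructure(m))
  expect_equal(sum(ss), 1, tolerance = 1e-12)
  expect_error(ssContent(character(0)), "empty")
})

test_that("designed truth labels are recovered on segment interiors", {
  m <- makeToyMonomer(seed = 1)
  truth <- annotations(m)$ssTruth
  lab <- assignSecondaryStructure(m)
  keep <- interiorMask(truth)
  expect_gte(mean(lab[keep] == truth[keep]), 0.9)
  expect_gte(mean(lab == truth), 0.75)
})
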
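# Probabilities below are frozen from two- and four-outcome Boltzmann
# ratios evaluated by hand: e/(e + e^-1) = 0.880797,
# e^2/(e^2 + e^-2) = 0.982014, e/(2e + 2) = 0.365529.

test_that("random walk is uniform over conserving outcomes", {
  lat <- fillNode(createLattice(1, 5, a = 2), 3, 2)
  expect_equal(reorientationProbabilities(lat, 3, randomWalkRule())$probabilities,
               rep(1 / 6, 6))
  latFull <- fillNode(createLattice(1, 5), 3, 2)
  expect_equal(reorientationProbabilities(latFull, 3, randomWalkRule())$probabilities,
               1)
})

test_that("chemotaxis biases motion up the signal gradient", {
  lat <- singleCell1D(5, 3)
  signalField(lat) <- c(0, 0, 0.5, 1, 1)
  p <- reorientationProbabilities(lat, 3, chemotaxisRule(1))$probabilities
  expect_equal(p[1], 0.8807971, tolerance = 1e-7)
  # negating beta mirrors the distribution
  pm <- reorientationProbabilities(lat, 3, chemotaxisRule(-1))$probabilities
  expect_equal(pm, rev(p))
  # uniform signal: random walk
  lat2 <- singleCell1D(5, 3)
  signalField(lat2) <- rep(2, 5)
  expect_equal(reorientationProbabilities(lat2, 3, chemotaxisRule(3))$probabilities,
               c(0.5, 0.5))
  expect_error(reorientationProbabilities(singleCell1D(5, 3), 3,
                                          chemotaxisRule(1)),
               class = "biolgca_config")
})

test_that("haptotaxis drifts along the vector field", {
  lat <- singleCell1D(5, 3)
  vectorField(lat) <- rep(1, 5)
  p <- reorientationProbabilities(lat, 3, haptotaxisRule(1))$probabilities
  expect_equal(p[1], 0.8807971, tolerance = 1e-7)
  latR <- reflectLattice(lat)               # the cell moves to node -3 = 4
  pr <- reorientationProbabilities(latR, wrapIndex(2L - 3L, 5L),
                                   haptotaxisRule(1))$probabilities
  expect_equal(pr, rev(p))                  # reflecting E reflects the law
  lat0 <- singleCell1D(5, 3)
  vectorField(lat0) <- rep(0, 5)
  expect_equal(reorientationProbabilities(lat0, 3, haptotaxisRule(5))$probabilities,
               c(0.5, 0.5))
  expect_error(reorientationProbabilities(singleCell1D(5, 3), 3,
                                          haptotaxisRule(1)),
               class = "biolgca_config")
})

test_that("contact guidance is orientational, not directional", {
  lat <- singleCell1D(5, 3)
  vectorField(lat) <- rep(1, 5)
  expect_equal(reorientationProbabilities(lat, 3, contactGuidanceRule(2.7))$probabilities,
               c(0.5, 0.5))                 # |+-1| symmetry in 1D
  lat2 <- createLattice(2, c(5, 5))
  occ <- latticeOccupancy(lat2); occ[13, 1] <- 1L; latticeOccupancy(lat2) <- occ
  vectorField(lat2) <- cbind(rep(1, 25), 0)
  p <- reorientationProbabilities(lat2, 13, contactGuidanceRule(1))$probabilities
  expect_equal(p, c(exp(1), 1, exp(1), 1) / (2 * exp(1) + 2),
               tolerance = 1e-12)
  # invariant under sign flip of E
  vectorField(lat2) <- cbind(rep(-1, 25), 0)
  expect_equal(reorientationProbabilities(lat2, 13,
                                          contactGuidanceRule(1))$probabilities,
               p)
  expect_equal(reorientationProbabilities(lat2, 13,
                                          contactGuidanceRule(0))$probabilities,
               rep(0.25, 4))
})

test_that("alignment follows the local cell momentum", {
  lat <- singleCell1D(5, 3)
  expect_equal(reorientationProbabilities(lat, 3, alignmentRule(1))$probabilities,
               c(0.5, 0.5))                 # empty neighbourhood
  # both neighbours carry one right-mover: D = +2
  lat <- singleCell1D(5, 3)
  occ <- latticeOccupancy(lat); occ[2, 1] <- 1L; occ[4, 1] <- 1L
  latticeOccupancy(lat) <- occ
  p <- reorientationProbabilities(lat, 3, alignmentRule(1))$probabilities
  expect_equal(p[1], 0.9820138, tolerance = 1e-7)
  # equal and opposite neighbour fluxes cancel
  occ[4, ] <- c(0L, 1L); latticeOccupancy(lat) <- occ
  expect_equal(reorientationProbabilities(lat, 3, alignmentRule(1))$probabilities,
               c(0.5, 0.5))
})

test_that("adhesion climbs the density gradient field", {
  lat <- fillNode(fillNode(singleCell1D(5, 3), 2, 1), 4, 1)
  expect_equal(reorientationProbabilities(lat, 3, adhesionRule(1))$probabilities,
               c(0.5, 0.5))                 # balanced neighbours: G = 0
  lat2 <- singleCell1D(5, 3)
  occ <- latticeOccupancy(lat2); occ[4, ] <- 1L; latticeOccupancy(lat2) <- occ
  p <- reorientationProbabilities(lat2, 3, adhesionRule(1))$probabilities
  expect_equal(p[1], 0.9820138, tolerance = 1e-7)   # G = +2
})

test_that("directional rules are equivariant under lattice reflection", {
  set.seed(17)
  lat <- initializeRandom(createLattice(1, 9, a = 1), 1.2, seed = 17)
  signalField(lat) <- runif(9)
  vectorField(lat) <- rnorm(9)
  ref <- reflectLattice(lat)
  g <- geometry(lat)
  chanPerm <- c(2L, 1L, 3L)                 # opposite velocity channels, rest fixed
  for (rule in list(chemotaxisRule(0.7), haptotaxisRule(1.3),
                    alignmentRule(0.9), adhesionRule(1.1))) {
    for (r in which(cellCounts(lat) > 0)) {
      rp <- reorientationProbabilities(lat, r, rule)
      rr <- reorientationProbabilities(ref, wrapIndex(2L - r, 9L), rule)
      m <- match(outcomeKey(rp$outcomes[, chanPerm, drop = FALSE]),
                 outcomeKey(rr$outcomes))
      expect_equal(rr$probabilities[m], rp$probabilities, tolerance = 1e-12)
    }
  }
})

test_that("invasion rule reproduces its energy decomposition", {
  # all sensitivities zero: random walk
  lat <- fillNode(createLattice(1, 6, a = 1), 3, 1)
  expect_equal(reorientationProbabilities(lat, 3,
                 invasionRule(0, 0, 0, nCrit = 2))$probabilities,
               rep(1 / 3, 3))
  # right neighbour n = 1, left empty, nCrit = 2: gAgg = +0.5;
  # right-moving candidate with betaAgg = 2 has energy 1.0
  lat2 <- fillNode(fillNode(createLattice(1, 6, a = 1), 3, 1), 4, 1)
  rp <- reorientationProbabilities(lat2, 3, invasionRule(2, 0, 0, nCrit = 2))
  iPlus <- which(rp$outcomes[, 1] == 1)
  iMinus <- which(rp$outcomes[, 2] == 1)
  expect_equal(rp$energies[iPlus], 1.0)
  expect_equal(rp$energies[iMinus], -1.0)
  # neighbour densities at nCrit on both sides: homeostatic saturation
  lat3 <- fillNode(fillNode(fillNode(createLattice(1, 6, a = 1), 3, 1), 2, 2),
                   4, 2)
  expect_equal(reorientationProbabilities(lat3, 3,
                 invasionRule(5, 0, 0, nCrit = 2))$probabilities,
               rep(1 / 3, 3))
  # resting energy couples resting candidates to resting neighbours
  latR <- createLattice(1, 6, a = 1)
  occ <- latticeOccupancy(latR)
  occ[3, 1] <- 1L; occ[2, 3] <- 1L; occ[4, 3] <- 1L
  latticeOccupancy(latR) <- occ
  rpR <- reorientationProbabilities(latR, 3, invasionRule(0, 0, 0.5, nCrit = 2))
  iRest <- which(rpR$outcomes[, 3] == 1)
  expect_equal(rpR$energies[iRest], 0.5 * 1 * 2)
  expect_error(invasionRule(1, 0, 0, nCrit = 0), class = "biolgca_config")
  lat2D <- fillNode(createLattice(2, c(4, 4), a = 1), 3, 1)
  expect_error(reorientationProbabilities(lat2D, 3,
                 invasionRule(1, 0, 0, nCrit = 2)),
               class = "biolgca_capability")
})

test_that("invasion with pure weak-saturation adhesion matches adhesionRule", {
  lat <- fillNode(fillNode(singleCell1D(7, 4, a = 0), 3, 1), 5, 2)
  latR <- createLattice(1, 7, a = 0)
  latticeOccupancy(latR) <- latticeOccupancy(lat)
  beta <- 1.3
  pAdh <- reorientationProbabilities(lat, 4, adhesionRule(beta))$probabilities
  pInv <- reorientationProbabilities(latR, 4,
            invasionRule(beta, 0, 0, nCrit = 1e12))$probabilities
  expect_lt(max(abs(pAdh - pInv)), 1e-9)
})

test_that("rule lookup resolves configuration names", {
  expect_identical(makeRule("randomwalk")@name, "randomwalk")
  expect_identical(makeRule("adhesion", list(beta = 2))@params$beta, 2)
  inv <- makeRule("invasion", list(betaAgg = 1, nCrit = 3))
  expect_identical(inv@params$betaAlign, 0)
  expect_error(makeRule("betta"), class = "biolgca_config")
})
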
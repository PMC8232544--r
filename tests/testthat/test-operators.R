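test_that("outcome enumeration matches binomial counts and respects the K cap", {
  g <- geometry(createLattice(1, 5))          # K = 2
  expect_identical(nrow(enumerateOutcomes(1, g)), 2L)
  g4 <- geometry(createLattice(1, 5, a = 2))  # K = 4
  expect_identical(nrow(enumerateOutcomes(2, g4)), 6L)
  expect_identical(nrow(enumerateOutcomes(0, g4)), 1L)
  expect_identical(nrow(enumerateOutcomes(4, g4)), 1L)
  expect_true(all(rowSums(enumerateOutcomes(2, g4)) == 2))
  gBig <- geometry(createLattice(1, 5, a = 15))  # K = 17
  expect_error(enumerateOutcomes(2, gBig), class = "biolgca_capability")
})

test_that("reorientation distributions are Boltzmann over conserving outcomes", {
  # zero sensitivity: uniform over C(K, n) outcomes
  lat <- fillNode(createLattice(1, 5, a = 2), 3, 2)
  rp <- reorientationProbabilities(lat, 3, randomWalkRule())
  expect_equal(rp$probabilities, rep(1 / 6, 6))
  expect_equal(sum(rp$probabilities), 1, tolerance = 1e-12)
  expect_true(all(rowSums(rp$outcomes) == 2))

  # two-outcome Boltzmann ratio under a unit signal gradient
  lat <- singleCell1D(5, 3)
  signalField(lat) <- c(0, 0, 0.5, 1, 1)      # Gsig(node 3) = +1
  rp <- reorientationProbabilities(lat, 3, chemotaxisRule(1))
  expect_equal(rp$probabilities[1], exp(1) / (exp(1) + exp(-1)),
               tolerance = 1e-12)
  expect_equal(rp$Z, exp(1) + exp(-1), tolerance = 1e-12)

  # full node: a single outcome with probability one
  latF <- fillNode(createLattice(1, 5), 2, 2)
  rpF <- reorientationProbabilities(latF, 2, randomWalkRule())
  expect_equal(rpF$probabilities, 1)
})

test_that("sampled outcome frequencies match enumerated probabilities", {
  # adhesion on an asymmetric neighbourhood, n = 2 at the focal node
  lat <- fillNode(fillNode(createLattice(1, 5, a = 1), 3, 2), 4, 3)
  rule <- adhesionRule(0.8)
  rp <- reorientationProbabilities(lat, 3, rule)
  set.seed(99)
  nDraw <- 20000L
  counts <- integer(nrow(rp$outcomes))
  keys <- outcomeKey(rp$outcomes)
  for (i in seq_len(nDraw)) {
    out <- applyReorientation(lat, rule)
    counts[match(paste(latticeOccupancy(out)[3, ], collapse = ""), keys)] <-
      counts[match(paste(latticeOccupancy(out)[3, ], collapse = ""), keys)] + 1L
  }
  expect_gt(suppressWarnings(
    chisq.test(counts, p = rp$probabilities)$p.value), 0.01)
})

test_that("reorientation conserves per-phenotype counts and is synchronous", {
  lat <- initializeRandom(createLattice(1, 40, a = 2), 1.5, seed = 2)
  before <- cellCounts(lat)
  set.seed(1); out1 <- applyReorientation(lat, adhesionRule(2))
  expect_identical(cellCounts(out1), before)        # exact mass conservation
  set.seed(1); out2 <- applyReorientation(lat, adhesionRule(2))
  expect_identical(latticeOccupancy(out1), latticeOccupancy(out2))
  empty <- createLattice(1, 10)
  expect_identical(latticeOccupancy(applyReorientation(empty, adhesionRule(2))),
                   latticeOccupancy(empty))
})

test_that("propagation translocates movers, keeps resters, conserves momentum", {
  lat <- singleCell1D(3, 1)                 # +1 mover at node 1
  out <- applyPropagation(lat)
  expect_equal(which(cellCounts(out) > 0), 2)
  expect_equal(latticeOccupancy(out)[2, 1], 1L)
  expect_identical(timeStep(out), 1L)

  latR <- createLattice(1, 3, a = 1)
  occ <- latticeOccupancy(latR); occ[2, 3] <- 1L; latticeOccupancy(latR) <- occ
  outR <- applyPropagation(latR)            # rest channel stays put
  expect_identical(latticeOccupancy(outR), occ)

  lat2 <- initializeRandom(createLattice(2, c(5, 5), a = 1), 2, seed = 4)
  expect_equal(colSums(nodeFlux(applyPropagation(lat2))),
               colSums(nodeFlux(lat2)))
  expect_identical(sum(cellCounts(applyPropagation(lat2))),
                   sum(cellCounts(lat2)))
})

test_that("birth/death respects exclusion and its limiting cases", {
  lat <- initializeRandom(createLattice(1, 20, a = 1), 1.5, seed = 3)
  expect_identical(
    latticeOccupancy(applyBirthDeath(lat, demographicRates(0, 0))),
    latticeOccupancy(lat))
  set.seed(1)
  expect_equal(sum(cellCounts(applyBirthDeath(lat, demographicRates(0, 1)))), 0)
  full <- fillNode(createLattice(1, 5), 2, 2)
  set.seed(1)
  expect_equal(sum(cellCounts(applyBirthDeath(full, demographicRates(1, 0)))),
               2)                            # saturated node: births fail
  set.seed(1)
  grown <- applyBirthDeath(singleCell1D(5, 2, a = 2), demographicRates(1, 0))
  expect_equal(sum(cellCounts(grown)), 2)    # one parent, one daughter
  expect_error(demographicRates(1.2, 0), "birth")
})

test_that("phenotype switching exchanges labels but never cells", {
  lat <- createLattice(1, 10, a = 0, phenotypes = 2)
  occ <- latticeOccupancy(lat)
  occ[1:5, 1] <- 1L                          # phenotype 1, channel +1
  latticeOccupancy(lat) <- occ
  expect_identical(
    latticeOccupancy(applyPhenotypeSwitch(lat, diag(2))),
    latticeOccupancy(lat))
  set.seed(1)
  sw <- applyPhenotypeSwitch(lat, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sum(latticeOccupancy(sw)[, 3]), 5)  # all moved to block 2
  expect_equal(sum(latticeOccupancy(sw)[, 1]), 0)
  expect_equal(sum(cellCounts(sw)), 5)
  expect_error(applyPhenotypeSwitch(lat, matrix(0.7, 2, 2)),
               class = "biolgca_config")
})

test_that("runs conserve mass without demography and are seed-reproducible", {
  lat <- initializeRandom(createLattice(1, 30, a = 1), 1.2, seed = 8)
  tr0 <- lgcaRun(lat, randomWalkRule(), steps = 0)
  expect_equal(nrow(trajectoryDensity(tr0)), 1)

  tr <- lgcaRun(lat, randomWalkRule(), steps = 1000, seed = 21)
  tot <- rowSums(trajectoryDensity(tr))
  expect_true(all(tot == tot[1]))            # exact conservation, 1000 steps
  tr2 <- lgcaRun(lat, randomWalkRule(), steps = 50, seed = 33,
                 snapshots = "all")
  tr3 <- lgcaRun(lat, randomWalkRule(), steps = 50, seed = 33,
                 snapshots = "all")
  expect_identical(tr2@snapshots, tr3@snapshots)
})

test_that("every rule collapses to the random walk as sensitivity vanishes", {
  lat <- fillNode(fillNode(createLattice(1, 7, a = 2), 4, 2), 5, 3)
  signalField(lat) <- seq(0, 1, length.out = 7)
  vectorField(lat) <- rep(1, 7)
  uni <- reorientationProbabilities(lat, 4, randomWalkRule())$probabilities
  rules <- list(chemotaxisRule(1e-12), haptotaxisRule(1e-12),
                contactGuidanceRule(1e-12), alignmentRule(1e-12),
                adhesionRule(1e-12),
                invasionRule(1e-12, 1e-12, 1e-12, nCrit = 4))
  for (rule in rules) {
    p <- reorientationProbabilities(lat, 4, rule)$probabilities
    expect_lt(tvDistance(p, uni), 1e-9)
  }
})

test_that("an unbiased single cell diffuses: MSD grows linearly in time", {
  L <- 201L; mid <- 101L; steps <- 100L; reps <- 150L
  set.seed(314)
  disp2 <- matrix(0, reps, steps)
  for (r in seq_len(reps)) {
    tr <- lgcaRun(singleCell1D(L, mid), randomWalkRule(), steps = steps)
    pos <- apply(trajectoryDensity(tr), 1L, which.max)
    disp2[r, ] <- (pos[-1L] - mid)^2        # no wrap: steps < L/2
  }
  msd <- colMeans(disp2)
  fit <- lm(msd ~ seq_len(steps))
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)  # slope ~ 2Dt, D = 1/2
})
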
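test_that("the adhesion FDE conserves mass and fixes uniform profiles", {
  rho0 <- rep(0.8, 40)
  tr <- adhesionFdeTrajectory(rho0, beta = 3, a = 2, steps = 20)
  expect_equal(tr[21, ], rho0, tolerance = 1e-13)
  set.seed(2)
  rho1 <- pmax(0.5 + rnorm(40, 0, 0.05), 0)
  tr1 <- adhesionFdeTrajectory(rho1, beta = 0.4, a = 1, steps = 500)
  tot <- rowSums(tr1)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
  # beta = 0 is a pure averaging stencil: perturbations decay monotonically
  tr0 <- adhesionFdeTrajectory(0.5 + 0.1 * cos(2 * pi * (0:39) / 8),
                               beta = 0, a = 1, steps = 50)
  amp <- apply(tr0, 1, function(x) max(x) - min(x))
  expect_true(all(diff(amp) <= 1e-14))
  expect_error(adhesionFdeTrajectory(rep(1, 4), 1, 1, 1),
               class = "biolgca_config")
  expect_error(adhesionFdeTrajectory(rep(9, 10), 1, 1, 1),
               class = "biolgca_config")
})

test_that("the dispersion relation matches its closed-form values", {
  set.seed(3)
  for (i in 1:10) {
    beta <- runif(1, 0, 5); rho <- runif(1, 0, 2); a <- sample(0:4, 1)
    expect_identical(adhesionGrowthRate(0, beta, rho, a), 0)  # conserved mode
    expect_equal(adhesionGrowthRate(pi, beta, rho, a), -4 / (a + 2),
                 tolerance = 1e-12)
  }
  expect_equal(adhesionGrowthRate(pi / 3, 0.5, 1, 2), 0.125, tolerance = 1e-12)
})

test_that("perturbation growth in the FDE matches the dispersion relation", {
  L <- 60L; m <- 10L
  kappa <- 2 * pi * m / L
  eps <- 1e-6; rhoBar <- 1; beta <- 0.5; a <- 2
  rho0 <- rhoBar + eps * cos(kappa * (0:(L - 1)))
  tr <- adhesionFdeTrajectory(rho0, beta, a, steps = 1)
  amp <- function(x) Mod(fft(x - mean(x))[m + 1])
  measured <- (amp(tr[2, ]) - amp(tr[1, ])) / amp(tr[1, ])
  expect_equal(measured, adhesionGrowthRate(kappa, beta, rhoBar, a),
               tolerance = 1e-6)
})

test_that("critical wavenumber and wavelength follow cos(kc) = 1/(4 b rho)", {
  cr <- adhesionCritical(0.5)
  expect_equal(cr$kappaC, pi / 3, tolerance = 1e-12)
  expect_equal(cr$lambdaC, 6, tolerance = 1e-12)
  expect_true(cr$unstable)
  expect_false(adhesionCritical(0.2)$unstable)
  expect_identical(adhesionCritical(0.25)$lambdaC, Inf)
  # threshold bracketing of the critical combination 1/4
  expect_false(adhesionCritical(0.2499)$unstable)
  expect_true(adhesionCritical(0.2501)$unstable)
  # lambda_c decreases strictly towards its infimum of 4
  brs <- c(0.3, 0.5, 1, 5, 50, 1e4)
  lams <- vapply(brs, function(b) adhesionCritical(b)$lambdaC, numeric(1))
  expect_true(all(diff(lams) < 0))
  expect_true(all(lams > 4))
  expect_equal(adhesionCritical(1e6)$lambdaC, 4, tolerance = 1e-3)
  expect_error(adhesionCritical(-1), class = "biolgca_domain")
})

test_that("the LBE steady state satisfies its fixed-point equations", {
  s0 <- invasionSteadyState(0.3, 1, 0)
  expect_equal(s0$fv, 0.1, tolerance = 1e-12)
  expect_equal(s0$fr, 0.1, tolerance = 1e-12)
  s <- invasionSteadyState(0.3, 1, 1)
  expect_equal(2 * s$fv + 1 * s$fr, 0.3, tolerance = 1e-10)
  expect_equal(s$fv, 0.3 / (2 + s$PiR), tolerance = 1e-10)
  expect_lt(s$residual, 1e-12)
  # independent dense grid search over fr in [0, rho]
  phi <- function(fr) 0.3 * exp(2 * fr) / (2 + exp(2 * fr))
  grid <- seq(0, 0.3, length.out = 200001)
  expect_lt(abs(s$fr - grid[which.min(abs(grid - phi(grid)))]), 1e-5)
  # strong resting interaction freezes everything into rest channels
  sBig <- invasionSteadyState(0.5, 2, 1e3)
  expect_equal(sBig$fr, 0.25, tolerance = 1e-6)
  expect_equal(sBig$fv, 0, tolerance = 1e-6)
  expect_error(invasionSteadyState(9, 1, 1), class = "biolgca_config")
  expect_error(invasionSteadyState(0.5, 0, 1), class = "biolgca_config")
})

test_that("the Boltzmann propagator conserves density and is conjugate-symmetric", {
  for (pars in list(c(0, 0, 0), c(1.2, 0.4, 0.8))) {
    pr0 <- invasionPropagator(0, pars[1], pars[2], pars[3], 0.3, 1, 3)
    expect_lt(min(Mod(pr0$eigenvalues - 1)), 1e-10)
    q <- 1.1
    ev1 <- invasionPropagator(q, pars[1], pars[2], pars[3], 0.3, 1, 3)$eigenvalues
    ev2 <- invasionPropagator(2 * pi - q, pars[1], pars[2], pars[3],
                              0.3, 1, 3)$eigenvalues
    expect_equal(sort(Re(ev1)), sort(Re(ev2)), tolerance = 1e-10)
    expect_equal(sort(Im(ev1)), sort(-Im(ev2)), tolerance = 1e-10)
  }
  # free propagation never amplifies
  qs <- seq(0.01, 2 * pi - 0.01, length.out = 100)
  mods <- vapply(qs, function(q)
    max(Mod(invasionPropagator(q, 0, 0, 0, 0.4, 2, 4)$eigenvalues)),
    numeric(1))
  expect_true(all(mods <= 1 + 1e-10))
})

test_that("analytic propagator derivatives agree with the LBE map", {
  set.seed(11)
  for (i in 1:10) {
    a <- sample(1:3, 1)
    worst <- validatePropagator(runif(1, 0, 3), runif(1, 0, 3),
                                runif(1, 0, 3), runif(1, 0.05, 0.6),
                                a, runif(1, 1, 6))
    expect_lt(worst, 1e-5)
  }
})

test_that("the LBE map conserves density and matches the steady state", {
  s <- invasionSteadyState(0.3, 1, 0.8)
  f0 <- matrix(c(s$fv, s$fv, s$fr), 3, 12)
  f1 <- lbeMap(f0, 0.5, 0.5, 0.8, 3)
  expect_equal(f1, f0, tolerance = 1e-10)   # homogeneous fixed point
  set.seed(4)
  f <- matrix(runif(36, 0, 0.3), 3, 12)
  expect_equal(sum(lbeMap(f, 1, 1, 1, 3)), sum(f), tolerance = 1e-12)
})

test_that("phase classification recovers the four migration modes", {
  expect_identical(classifyPhase(0, 0, 0.5, 0.2, 1, 3)$phase, "diffusive")
  expect_identical(classifyPhase(0, 6, 0.5, 0.2, 1, 3)$phase, "collective")
  expect_identical(classifyPhase(6, 0, 0.5, 0.2, 1, 3)$phase, "aggregation")
  cl <- classifyPhase(0, 0, 8, 0.2, 1, 3)
  expect_identical(cl$phase, "jammed")
  expect_gte(cl$restingFraction, 0.75)
  expect_error(classifyPhase(0, 0, 0, 0.2, 1, 3, qPoints = 10),
               class = "biolgca_config")
  # labels are stable under refining the wavenumber grid
  for (pars in list(c(0, 0, 0.5), c(0, 6, 0.5), c(6, 0, 0.5), c(0, 0, 8))) {
    expect_identical(
      classifyPhase(pars[1], pars[2], pars[3], 0.2, 1, 3, qPoints = 256)$phase,
      classifyPhase(pars[1], pars[2], pars[3], 0.2, 1, 3, qPoints = 1024)$phase)
  }
})

test_that("a single-point diagram at the origin is diffusive", {
  pd <- phaseDiagram(betaAgg = 0, betaAlign = 0, betaRest = 0.5)
  expect_identical(nrow(pd), 1L)
  expect_identical(pd$phase, "diffusive")
})
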
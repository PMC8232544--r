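# Mean-field machinery: the 1D adhesion finite-difference equation (FDE)
# with its dispersion relation and critical wavelength, and the invasion
# model's lattice-Boltzmann equation (LBE), homogeneous steady state,
# Boltzmann propagator and phase classification.

#' Mean-field density trajectory of the 1D adhesion model
#'
#' Iterates the mean-field finite-difference equation of the adhesive
#' BIO-LGCA on a periodic 1D lattice (K = a + 2 channels):
#' \deqn{\rho(r,k+1) = \frac{a}{K}\rho(r,k) + \frac{1}{K}[\rho(r-1,k)+\rho(r+1,k)]
#'   + \frac{\beta}{K}\{\rho(r-1,k)[\rho(r,k)-\rho(r-2,k)] +
#'     \rho(r+1,k)[\rho(r,k)-\rho(r+2,k)]\}}
#' The total density is conserved exactly; a uniform profile is a fixed
#' point for any `beta`.
#'
#' @param rho0 initial density profile (values in `[0, K]`, length >= 5 for
#'   the five-point stencil).
#' @param beta adhesion sensitivity (>= 0).
#' @param a number of rest channels.
#' @param steps number of iterations.
#' @return numeric `(steps + 1) x length(rho0)` matrix of density profiles.
#' @export
adhesionFdeTrajectory <- function(rho0, beta, a, steps) {
  rho0 <- as.numeric(rho0)
  L <- length(rho0)
  if (L < 5L)
    .lgcaStop("config", "profile must have at least 5 nodes (stencil width)")
  K <- a + 2
  if (any(rho0 < 0 | rho0 > K))
    .lgcaStop("config", "densities must lie in [0, K]")
  out <- matrix(0, steps + 1L, L)
  out[1L, ] <- rho0
  rho <- rho0
  for (k in seq_len(steps)) {
    rm1 <- .shiftVec(rho, 1L);  rp1 <- .shiftVec(rho, -1L)
    rm2 <- .shiftVec(rho, 2L);  rp2 <- .shiftVec(rho, -2L)
    rho <- (a / K) * rho + (rm1 + rp1) / K +
      (beta / K) * (rm1 * (rho - rm2) + rp1 * (rho - rp2))
    out[k + 1L, ] <- rho
  }
  out
}

#' Dispersion relation of the adhesion mean-field equation
#'
#' Per-step growth factor of a density perturbation with wavenumber
#' `kappa` under the linearised adhesion FDE:
#' \deqn{F(\kappa) = \frac{2}{K}\left[2\beta\bar\rho - 1 + \cos\kappa -
#'   2\beta\bar\rho\cos^2\kappa\right]}
#' A positive value means the mode grows. `F(0) = 0` exactly (mass
#' conservation) and `F(pi) = -4/K` independently of `beta` and `rhoBar`.
#'
#' @param kappa wavenumber(s) in `[0, pi]`.
#' @param beta adhesion sensitivity.
#' @param rhoBar mean density.
#' @param a number of rest channels (K = a + 2).
#' @return numeric growth factor(s), same length as `kappa`.
#' @export
adhesionGrowthRate <- function(kappa, beta, rhoBar, a) {
  K <- a + 2
  br <- beta * rhoBar
  ck <- cos(kappa)
  # factored form of 2 br - 1 + cos k - 2 br cos^2 k: exact zero at k = 0
  (2 / K) * ((1 - ck) * (2 * br * (1 + ck) - 1))
}

#' Dominant wavenumber and critical wavelength of the adhesion instability
#'
#' The dominant (fastest-growing) wavenumber of the adhesion dispersion
#' relation satisfies `cos(kappa_c) = 1 / (4 beta rhoBar)`, which has a
#' solution only for `beta * rhoBar >= 1/4`: the critical parameter
#' combination is `(beta rhoBar)_c = 1/4`. Above threshold the critical
#' wavelength is `lambda_c = 2 pi / kappa_c`; it diverges at threshold and
#' decreases monotonically to the limit `lambda_c -> 4` lattice sites as
#' `beta * rhoBar -> Inf`.
#'
#' @param betaRho product of sensitivity and mean density (>= 0).
#' @return a list with `betaRho`, `kappaC` (dominant wavenumber, `NA` below
#'   threshold, 0 at threshold), `lambdaC` (critical wavelength in lattice
#'   sites; `Inf` at threshold, `NA` below), and `unstable` (logical).
#' @examples
#' adhesionCritical(0.5)$lambdaC   # = 6 (kappa_c = pi/3)
#' adhesionCritical(1e6)$lambdaC   # ~ 4, the large-sensitivity limit
#' @export
adhesionCritical <- function(betaRho) {
  if (!is.finite(betaRho) || betaRho < 0)
    .lgcaStop("domain", "betaRho must be a non-negative number")
  if (betaRho > 0.25) {
    kappaC <- acos(1 / (4 * betaRho))
    list(betaRho = betaRho, kappaC = kappaC, lambdaC = 2 * pi / kappaC,
         unstable = TRUE)
  } else if (betaRho == 0.25) {
    list(betaRho = betaRho, kappaC = 0, lambdaC = Inf, unstable = FALSE)
  } else {
    list(betaRho = betaRho, kappaC = NA_real_, lambdaC = NA_real_,
         unstable = FALSE)
  }
}

#' Dominant spatial period of a density pattern
#'
#' Identifies the dominant wavelength of a (late-time) spatial density
#' pattern as the discrete Fourier mode with maximal average power: for a
#' kymograph the power spectra of the mean-subtracted rows in the late-time
#' window are averaged, and the wavelength is `L / m*` for the maximising
#' mode `m*`. Used to compare simulated aggregation patterns against the
#' mean-field prediction of [adhesionCritical()].
#'
#' @param density numeric matrix (time x nodes) or a single profile vector.
#' @param lateFraction fraction of final rows to average over (matrix input).
#' @return a list with `mode`, `wavelength` (lattice sites) and the
#'   averaged `power` spectrum over modes `1..floor(L/2)`.
#' @export
dominantPeriod <- function(density, lateFraction = 0.2) {
  if (is.null(dim(density))) density <- matrix(density, nrow = 1)
  L <- ncol(density)
  first <- max(1L, nrow(density) - ceiling(lateFraction * nrow(density)) + 1L)
  rows <- density[first:nrow(density), , drop = FALSE]
  mmax <- L %/% 2L
  power <- numeric(mmax)
  for (i in seq_len(nrow(rows))) {
    x <- rows[i, ] - mean(rows[i, ])
    power <- power + Mod(fft(x)[2:(mmax + 1L)])^2
  }
  power <- power / nrow(rows)
  mStar <- which.max(power)
  list(mode = mStar, wavelength = L / mStar, power = power)
}

#' Homogeneous steady state of the invasion-model LBE
#'
#' Solves the homogeneous steady state of the lattice-Boltzmann equation of
#' the 1D invasion model: velocity-channel occupancy `fv` and rest-channel
#' occupancy `fr` satisfying
#' `rhoBar = 2 fv + a fr`, `fv = rhoBar / (2 + a Pi_r)` and
#' `Pi_r = exp(2 betaRest a fr)`. The fixed point for `fr` is found by
#' damped fixed-point iteration (damping 0.5) with a bracketed root search
#' as fallback, to residual below 1e-12.
#'
#' @param rhoBar mean density (0 < rhoBar <= K).
#' @param a number of rest channels (>= 1 when `betaRest` is nonzero).
#' @param betaRest resting sensitivity.
#' @return a list with `rhoBar`, `a`, `betaRest`, `fv`, `fr`, `PiR` and the
#'   fixed-point `residual`.
#' @export
invasionSteadyState <- function(rhoBar, a, betaRest) {
  K <- a + 2
  if (rhoBar <= 0 || rhoBar > K)
    .lgcaStop("config", "rhoBar must lie in (0, K]")
  if (a < 1 && betaRest != 0)
    .lgcaStop("config", "a rest channel is required when betaRest is nonzero")
  if (a == 0)
    return(list(rhoBar = rhoBar, a = a, betaRest = betaRest,
                fv = rhoBar / 2, fr = 0, PiR = 1, residual = 0))
  # phi(fr) = rhoBar * Pi / (2 + a * Pi), written overflow-stably
  phi <- function(fr) rhoBar / (2 * exp(-2 * betaRest * a * fr) + a)
  fr <- rhoBar / (2 + a)
  converged <- FALSE
  for (it in seq_len(10000L)) {
    nxt <- 0.5 * fr + 0.5 * phi(fr)
    if (abs(nxt - fr) < 1e-14 && abs(nxt - phi(nxt)) < 1e-12) {
      fr <- nxt; converged <- TRUE; break
    }
    fr <- nxt
  }
  if (!converged || abs(fr - phi(fr)) >= 1e-12) {
    h <- function(x) x - phi(x)
    upper <- min(1, rhoBar / a)
    fr <- uniroot(h, c(0, upper), tol = 1e-15)$root
    for (i in seq_len(50L)) {          # Newton polish of the residual
      x <- 2 * betaRest * a * fr
      dphi <- rhoBar * 2 * betaRest * a * 2 * exp(-x) / (2 * exp(-x) + a)^2
      step <- (fr - phi(fr)) / (1 - dphi)
      if (!is.finite(step)) break
      fr <- fr - step
      if (abs(fr - phi(fr)) < 1e-13) break
    }
    if (abs(fr - phi(fr)) >= 1e-12)
      .lgcaStop("numeric", "steady state did not converge (residual %.3g)",
                abs(fr - phi(fr)))
  }
  em <- exp(-2 * betaRest * a * fr)
  fv <- rhoBar * em / (2 * em + a)       # = rhoBar / (2 + a * Pi_r)
  list(rhoBar = rhoBar, a = a, betaRest = betaRest, fv = fv, fr = fr,
       PiR = exp(2 * betaRest * a * fr), residual = abs(fr - phi(fr)))
}

# Single-particle transition probabilities T and their derivatives with
# respect to the neighbour occupancies, evaluated at the homogeneous steady
# state. Returns T (length K) and dT (K x K x 2 array; third index: offset
# +1 then -1).
.invasionLinearisation <- function(betaAgg, betaAlign, betaRest, rhoBar, a,
                                   nCrit, steady = NULL) {
  K <- a + 2L
  if (is.null(steady)) steady <- invasionSteadyState(rhoBar, a, betaRest)
  x <- 2 * betaRest * a * steady$fr
  em <- exp(-x)
  Tv <- em / (2 * em + a)                 # velocity channels
  Tr <- 1 / (2 * em + a)                  # rest channels (a > 0)
  Tm <- c(Tv, Tv, rep(Tr, a))
  S <- a / (2 * em + a)                   # a * Pi / Z
  cAgg <- betaAgg * (1 - 2 * rhoBar / nCrit)
  dT <- array(0, c(K, K, 2L))
  for (ei in 1:2) {
    e <- c(1, -1)[ei]
    for (n in seq_len(K)) {
      dA <- cAgg * e +
        betaAlign * (if (n == 1L) 1 else if (n == 2L) -1 else 0)
      dGrest <- as.numeric(n > 2L)
      dlnZ <- S * betaRest * dGrest
      dT[1L, n, ei] <- Tv * (dA - dlnZ)
      dT[2L, n, ei] <- Tv * (-dA - dlnZ)
      if (a > 0L)
        dT[3:K, n, ei] <- Tr * (betaRest * dGrest - dlnZ)
    }
  }
  list(T = Tm, dT = dT, steady = steady, K = K)
}

#' Boltzmann propagator of the invasion model
#'
#' Builds the K x K Boltzmann propagator
#' \deqn{\Gamma_{m,n}(q) = e^{-i c_m q}\left[T_m + \sum_{\ell=1,2}
#'   e^{i c_\ell q}\,\partial f_m(r+c_m,k+1)/\partial f_n(r+c_\ell,k)\right]}
#' — the Fourier-space linearisation of the LBE around the homogeneous
#' steady state — and its eigenvalues. Derivatives are analytic (validated
#' against central finite differences of the LBE map by
#' [validatePropagator()]). At `q = 0` one eigenvalue equals 1 (total
#' density is conserved); eigenvalues at `q` and `2 pi - q` are complex
#' conjugates. A spectral radius above 1 at some `q` signals an instability
#' whose wavelength is `2 pi / q`; the argument of the dominant eigenvalue
#' distinguishes travelling from stationary modes.
#'
#' @param q wavenumber in `[0, 2 pi)`.
#' @param betaAgg,betaAlign,betaRest interaction sensitivities.
#' @param rhoBar mean density.
#' @param a number of rest channels.
#' @param nCrit homeostatic density parameter.
#' @param steady optional precomputed [invasionSteadyState()] result.
#' @return a list with `q`, the complex matrix `Gamma`, its `eigenvalues`,
#'   and `dominant` (eigenvalue of maximal modulus).
#' @export
invasionPropagator <- function(q, betaAgg, betaAlign, betaRest, rhoBar, a,
                               nCrit, steady = NULL) {
  lin <- .invasionLinearisation(betaAgg, betaAlign, betaRest, rhoBar, a,
                                nCrit, steady)
  .propagatorAt(q, lin, rhoBar)
}

# build Gamma(q) and its spectrum from a precomputed linearisation
.propagatorAt <- function(q, lin, rhoBar) {
  K <- lin$K
  cm <- c(1, -1, rep(0, K - 2L))
  ep <- exp(1i * q); emq <- exp(-1i * q)
  Gamma <- (lin$T + rhoBar * (ep * lin$dT[, , 1L] + emq * lin$dT[, , 2L])) *
    exp(-1i * cm * q)
  ev <- eigen(Gamma, only.values = TRUE)$values
  list(q = q, Gamma = Gamma, eigenvalues = ev,
       dominant = ev[which.max(Mod(ev))])
}

#' Mean-field LBE map of the invasion model
#'
#' One synchronous update of the lattice-Boltzmann equation
#' `f_j(r + c_j, k+1) = rho(r, k) T_j(r, k)` on a periodic 1D lattice,
#' where `T_j` are the single-particle transition probabilities of the
#' invasion rule evaluated on the mean-field neighbourhood fields. Total
#' density is conserved. Serves as the nonlinear map whose linearisation
#' the Boltzmann propagator encodes (and as the finite-difference oracle
#' for its derivatives).
#'
#' @param f numeric `K x L` matrix of expected channel occupancies
#'   (rows: channels `+1`, `-1`, then rest; columns: nodes).
#' @param betaAgg,betaAlign,betaRest interaction sensitivities.
#' @param nCrit homeostatic density parameter.
#' @return the updated `K x L` matrix.
#' @export
lbeMap <- function(f, betaAgg, betaAlign, betaRest, nCrit) {
  K <- nrow(f); L <- ncol(f); a <- K - 2L
  rho <- colSums(f)
  j <- f[1L, ] - f[2L, ]
  nr <- if (a > 0L) colSums(f[3:K, , drop = FALSE]) else numeric(L)
  np <- .shiftVec(rho, -1L); nm <- .shiftVec(rho, 1L)
  gAgg <- np * (1 - np / nCrit) - nm * (1 - nm / nCrit)
  gAlign <- .shiftVec(j, -1L) + .shiftVec(j, 1L)
  gRest <- .shiftVec(nr, -1L) + .shiftVec(nr, 1L)
  A <- betaAgg * gAgg + betaAlign * gAlign
  lw <- rbind(A, -A, matrix(rep(betaRest * gRest, each = max(a, 0L)),
                            nrow = a, ncol = L))
  mx <- apply(lw, 2L, max)
  w <- exp(sweep(lw, 2L, mx, "-"))
  Tj <- sweep(w, 2L, colSums(w), "/")
  if (any(!is.finite(Tj)))
    .lgcaStop("numeric", "transition probabilities overflowed or degenerated")
  out <- matrix(0, K, L)
  out[1L, ] <- .shiftVec(rho * Tj[1L, ], 1L)
  out[2L, ] <- .shiftVec(rho * Tj[2L, ], -1L)
  if (a > 0L)
    out[3:K, ] <- sweep(Tj[3:K, , drop = FALSE], 2L, rho, "*")
  out
}

#' Validate the analytic propagator derivatives against the LBE map
#'
#' Cross-checks every analytic derivative entering the Boltzmann propagator
#' against central finite differences of [lbeMap()] on a small periodic
#' lattice around the homogeneous steady state. Any disagreement beyond
#' `tol` raises a validation error rather than proceeding silently.
#'
#' @param betaAgg,betaAlign,betaRest,rhoBar,a,nCrit model parameters.
#' @param h finite-difference step.
#' @param tol maximal tolerated absolute disagreement.
#' @return invisibly, the maximal absolute disagreement.
#' @export
validatePropagator <- function(betaAgg, betaAlign, betaRest, rhoBar, a, nCrit,
                               h = 1e-6, tol = 1e-5) {
  lin <- .invasionLinearisation(betaAgg, betaAlign, betaRest, rhoBar, a, nCrit)
  K <- lin$K; L <- 8L; r0 <- 4L
  cm <- c(1L, -1L, rep(0L, a))
  f0 <- matrix(c(lin$steady$fv, lin$steady$fv, rep(lin$steady$fr, a)),
               K, L)
  worst <- 0
  for (ei in 1:2) {
    e <- c(1L, -1L)[ei]
    for (n in seq_len(K)) {
      fp <- f0; fp[n, r0 + e] <- fp[n, r0 + e] + h
      fm <- f0; fm[n, r0 + e] <- fm[n, r0 + e] - h
      num <- (lbeMap(fp, betaAgg, betaAlign, betaRest, nCrit) -
                lbeMap(fm, betaAgg, betaAlign, betaRest, nCrit)) / (2 * h)
      for (m in seq_len(K)) {
        fd <- num[m, r0 + cm[m]]
        an <- rhoBar * lin$dT[m, n, ei]
        worst <- max(worst, abs(fd - an))
      }
    }
  }
  if (worst > tol)
    .lgcaStop("validation",
              "analytic propagator derivatives disagree with finite differences (max %.3g > %.3g)",
              worst, tol)
  invisible(worst)
}

#' Classify the dynamical phase of the invasion model
#'
#' Sweeps the Boltzmann propagator spectrum over a wavenumber grid on
#' `(0, 2 pi)` plus the `q = 0` point (where the conservation eigenvalue 1
#' is discarded and the remaining modes capture homogeneous
#' symmetry-breaking, in particular the uniform-flux mode behind
#' collective motion) and labels the regime:
#' \itemize{
#'   \item resting fraction `a fr / rhoBar >= restThreshold`: `"jammed"` —
#'     almost all cells sit in rest channels and the dynamics is frozen
#'     (this takes precedence: the residual rest-clustering mode is at most
#'     marginally unstable there);
#'   \item otherwise stable everywhere (spectral radius `<= 1 + eps`):
#'     `"diffusive"`;
#'   \item otherwise unstable: `"collective"` when the homogeneous `q = 0`
#'     flux mode dominates the spectrum (the wavelength of the fastest
#'     structure diverges — uniform migration) or the maximising interior
#'     mode travels (`|arg| > argTol`); else `"aggregation"` (stationary
#'     finite-wavelength mode).
#' }
#'
#' @param betaAgg,betaAlign,betaRest interaction sensitivities.
#' @param rhoBar mean density.
#' @param a number of rest channels.
#' @param nCrit homeostatic density parameter.
#' @param qPoints number of wavenumber grid points (>= 256).
#' @param restThreshold resting fraction above which the state is jammed.
#' @param argTol argument tolerance separating travelling from stationary.
#' @param eps spectral-radius tolerance for marginal stability.
#' @return a list with `phase` (label), `maxModulus` (over interior q),
#'   `q0Modulus` (largest non-conserved modulus at q = 0), `qStar`,
#'   `dominant` (eigenvalue there), `restingFraction` and the `steady`
#'   state.
#' @export
classifyPhase <- function(betaAgg, betaAlign, betaRest, rhoBar, a, nCrit,
                          qPoints = 256L, restThreshold = 0.75,
                          argTol = 1e-6, eps = 1e-9) {
  if (qPoints < 256L) .lgcaStop("config", "qPoints must be at least 256")
  steady <- invasionSteadyState(rhoBar, a, betaRest)
  lin <- .invasionLinearisation(betaAgg, betaAlign, betaRest, rhoBar, a,
                                nCrit, steady)
  qs <- 2 * pi * seq_len(qPoints) / (qPoints + 1L)
  maxMod <- -Inf; qStar <- NA_real_; dom <- NA_complex_
  for (q in qs) {
    pr <- .propagatorAt(q, lin, rhoBar)
    m <- Mod(pr$dominant)
    if (m > maxMod) { maxMod <- m; qStar <- q; dom <- pr$dominant }
  }
  ev0 <- .propagatorAt(0, lin, rhoBar)$eigenvalues
  q0Mod <- max(Mod(ev0[-which.min(Mod(ev0 - 1))]))  # drop conserved mode
  restFrac <- if (rhoBar > 0) a * steady$fr / rhoBar else 0
  phase <- if (restFrac >= restThreshold) {
    "jammed"
  } else if (max(maxMod, q0Mod) <= 1 + eps) {
    "diffusive"
  } else if (q0Mod >= maxMod || abs(Arg(dom)) > argTol) {
    "collective"
  } else {
    "aggregation"
  }
  list(phase = phase, maxModulus = maxMod, q0Modulus = q0Mod, qStar = qStar,
       dominant = dom, restingFraction = restFrac, steady = steady)
}

#' Phase diagram of the invasion model
#'
#' Applies [classifyPhase()] over a grid of aggregation and alignment
#' sensitivities at one or more resting-sensitivity levels. The default
#' grid is the package's demonstration window (see the methods vignette):
#' it spans all four migration modes — diffusive near the origin,
#' collective at high `betaAlign`, aggregation at high `betaAgg`, jammed at
#' high `betaRest`.
#'
#' @param betaAgg,betaAlign numeric grids of sensitivities.
#' @param betaRest numeric vector of resting-sensitivity levels.
#' @param rhoBar mean density.
#' @param a number of rest channels.
#' @param nCrit homeostatic density parameter.
#' @param ... passed to [classifyPhase()] (`qPoints`, thresholds).
#' @return a data.frame with columns `betaAgg`, `betaAlign`, `betaRest`,
#'   `phase`, `maxModulus`, `qStar`, `restingFraction`.
#' @export
phaseDiagram <- function(betaAgg = seq(0, 6, length.out = 20),
                         betaAlign = seq(0, 6, length.out = 20),
                         betaRest = c(0.5, 8),
                         rhoBar = 0.2, a = 1, nCrit = a + 2, ...) {
  grid <- expand.grid(betaAgg = betaAgg, betaAlign = betaAlign,
                      betaRest = betaRest, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cl <- classifyPhase(grid$betaAgg[i], grid$betaAlign[i], grid$betaRest[i],
                        rhoBar, a, nCrit, ...)
    res[[i]] <- data.frame(phase = cl$phase, maxModulus = cl$maxModulus,
                           qStar = cl$qStar,
                           restingFraction = cl$restingFraction)
  }
  cbind(grid, do.call(rbind, res))
}
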
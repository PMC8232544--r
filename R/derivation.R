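# Deriving reorientation probabilities from biophysical potentials (via the
# stationary orientation distribution of the associated Fokker-Planck
# equation) and from measured observables (via maximum caliber).

#' Stationary orientation distribution of a self-propelled particle
#'
#' For an overdamped self-propelled particle whose orientation relaxes in a
#' potential `U(theta)` under rotational noise, the stationary orientation
#' density is the Boltzmann form `P(theta) proportional to
#' exp(-beta * U(theta))` with sensitivity `beta = gamma / Dtheta` (drift
#' relaxation over angular diffusion). The density is normalised on the
#' supplied grid so that `sum(P) * dtheta = 1`.
#'
#' @param U potential: a function of theta, or a numeric vector already
#'   evaluated on the grid.
#' @param beta sensitivity (> 0).
#' @param nTheta grid resolution (>= 8); the grid is uniform on
#'   `[0, 2 pi)`.
#' @return a data.frame with columns `theta` and `density`.
#' @examples
#' p <- stationaryOrientationDistribution(function(th) -cos(th), beta = 1)
#' p$density[1] / p$density[which.min(abs(p$theta - pi))]  # ~ exp(2)
#' @export
stationaryOrientationDistribution <- function(U, beta, nTheta = 256L) {
  if (beta <= 0) .lgcaStop("config", "beta must be positive")
  if (nTheta < 8L) .lgcaStop("config", "grid resolution must be at least 8")
  theta <- 2 * pi * (seq_len(nTheta) - 1L) / nTheta
  u <- if (is.function(U)) U(theta) else as.numeric(U)
  if (length(u) != nTheta || any(!is.finite(u)))
    .lgcaStop("numeric", "potential must be finite on the whole grid")
  logw <- -beta * u
  w <- exp(logw - max(logw))
  dens <- w / (sum(w) * (2 * pi / nTheta))
  data.frame(theta = theta, density = dens)
}

#' Reorientation distribution induced by a discretised potential
#'
#' Discretising the stationary orientation distribution onto the lattice
#' directions, and assuming independent channel occupations, the outcome
#' weight of a mass-conserving candidate configuration is
#' `exp(-beta * sum_j U(c_j) * s^O_j)`. Rest channels are assigned zero
#' potential unless values are supplied for all `K` channels.
#'
#' @param U numeric potential per direction: length `b` (rest channels get
#'   0) or length `K`.
#' @param beta sensitivity.
#' @param counts cells per phenotype at the node.
#' @param geom an [LGCAGeometry-class].
#' @return a list with `outcomes`, `probabilities`, `energies`, `Z` and
#'   `logZ`, as in [reorientationProbabilities()].
#' @export
reorientationFromPotential <- function(U, beta, counts, geom) {
  U <- as.numeric(U)
  if (length(U) == geom@b) U <- c(U, numeric(geom@a))
  if (length(U) != geom@K)
    .lgcaStop("structure", "potential must have length b = %d or K = %d",
              geom@b, geom@K)
  if (any(!is.finite(U))) .lgcaStop("numeric", "potential must be finite")
  tab <- .outcomeTable(as.integer(counts), geom)
  Ufull <- rep.int(U, geom@nPhenotypes)
  e <- -beta * drop(tab$occ %*% Ufull)
  m <- max(e)
  p <- exp(e - m)
  list(outcomes = tab$occ, probabilities = p / sum(p), energies = e,
       Z = sum(exp(e)), logZ = m + log(sum(p)))
}

#' Director-field rule from a cosine interaction potential
#'
#' Self-propelled particle models of collective migration typically use
#' potentials of the form `U = -C cos^n(theta - phi)`. For `n = 1` the
#' induced reorientation energy is `beta * J(s^O) . G` with the local
#' director field `G` of norm `C` and argument `phi` (polar order); for
#' `n = 2` it is `beta * N(s^O) . G` with the nematic alignment vector `N`
#' (orientational order: outcomes related by channel reversal get the same
#' energy).
#'
#' @param C interaction strength (>= 0), the norm of the director field.
#' @param phi optimal orientation in `[0, 2 pi)`, its argument.
#' @param order cosine order `n`, 1 (polar) or 2 (nematic).
#' @param beta sensitivity.
#' @return an [LGCARule-class] whose director field is fixed (an external
#'   alignment field); on a 1D lattice the x component of `G` is used.
#' @export
directorFieldRule <- function(C, phi, order = 1L, beta = 1) {
  if (!order %in% c(1L, 2L))
    .lgcaStop("capability", "only cosine orders n = 1 and n = 2 are supported")
  if (C < 0) .lgcaStop("config", "interaction strength C must be >= 0")
  G <- C * c(cos(phi), sin(phi))
  force(beta)
  if (order == 1L)
    .newRule("director_field", list(C = C, phi = phi, order = 1L, beta = beta,
                                    G = G), character(0),
             function(tab, fields, r)
               beta * drop(tab$J %*% G[seq_len(ncol(tab$J))]))
  else
    .newRule("director_field", list(C = C, phi = phi, order = 2L, beta = beta,
                                    G = G), character(0),
             function(tab, fields, r)
               beta * drop(tab$N %*% G[seq_len(ncol(tab$N))]))
}

# expectation of the observable under P(i) ~ exp(beta * u_i)
.maxcalExpectation <- function(beta, u) {
  w <- exp(beta * u - max(beta * u))
  sum(u * w) / sum(w)
}

#' Maximum-caliber Lagrange multipliers from observable targets
#'
#' Given a per-channel observable `uTilde` and target expectation values
#' `E_j` (one per time step, or a single time-independent value), finds the
#' Lagrange multipliers `beta(j)` such that the maximum-caliber channel
#' distribution `P_j(i) proportional to exp(beta(j) * uTilde_i)`
#' reproduces each target: `<uTilde>_{P_j} = E_j`. The expectation is
#' strictly increasing in `beta`, so each multiplier is found by a
#' bracketed monotone root search (bracket expanded geometrically until a
#' sign change) to tolerance 1e-10. A time-independent target yields a
#' constant multiplier.
#'
#' @param uTilde numeric observable value per channel.
#' @param targets numeric target expectation(s) `E_j`; each must lie in the
#'   open range of `uTilde`.
#' @param tol root tolerance on the fitted expectation.
#' @return numeric vector `beta(j)`, one multiplier per target.
#' @examples
#' u <- c(1, 0, -1, 0)                 # directional persistence observable
#' maxcalMultipliers(u, mean(u))       # uniform mean -> beta = 0
#' @export
maxcalMultipliers <- function(uTilde, targets, tol = 1e-10) {
  u <- as.numeric(uTilde)
  if (diff(range(u)) == 0)
    .lgcaStop("domain", "observable is constant; any target is degenerate")
  lo <- min(u); hi <- max(u)
  vapply(as.numeric(targets), function(E) {
    if (E <= lo || E >= hi)
      .lgcaStop("domain",
                "target %.6g is not attainable; feasible open interval is (%.6g, %.6g)",
                E, lo, hi)
    f <- function(b) .maxcalExpectation(b, u) - E
    if (abs(f(0)) < tol) return(0)
    span <- 1
    while (f(-span) * f(span) > 0 && span < 1e8) span <- span * 2
    if (f(-span) * f(span) > 0)
      .lgcaStop("numeric", "failed to bracket the multiplier for target %.6g", E)
    uniroot(f, c(-span, span), tol = tol * 1e-2)$root
  }, numeric(1))
}

#' Outcome probabilities of the time-independent maximum-caliber rule
#'
#' For a time-independent per-channel observable the maximum-caliber path
#' distribution factorises into node transitions with probabilities
#' `P(s -> s^O) proportional to exp(beta * sum_i uTilde_i s^O_i)` over the
#' mass-conserving outcomes. When `uTilde_i = c_i . G` this coincides with
#' the director-field form derived from an interaction potential — the two
#' derivation routes meet.
#'
#' @param uTilde numeric observable value per channel (length `b` or `K`;
#'   rest channels default to 0).
#' @param beta Lagrange multiplier.
#' @param counts cells per phenotype at the node.
#' @param geom an [LGCAGeometry-class].
#' @return a list with `outcomes`, `probabilities`, `energies`, `Z`, `logZ`.
#' @export
maxcalOutcomeProbabilities <- function(uTilde, beta, counts, geom) {
  reorientationFromPotential(-as.numeric(uTilde), beta, counts, geom)
}

#' Sample synthetic single-cell channel choices
#'
#' Draws independent channel choices from the maximum-caliber single-cell
#' distribution `P(i) proportional to exp(beta * uTilde_i)` — the
#' generative model for testing observable-based rule inference (fit the
#' multiplier back from the empirical mean of the observable).
#'
#' @param uTilde numeric observable value per channel.
#' @param beta generating multiplier.
#' @param n number of choices.
#' @param seed optional integer seed.
#' @return integer vector of channel indices.
#' @export
simulateChannelChoices <- function(uTilde, beta, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- .softmax(beta * as.numeric(uTilde))
  sample.int(length(p), n, replace = TRUE, prob = p)
}

#' Persistent-walk channel probabilities from an autocorrelation function
#'
#' If the measured observable is the velocity autocorrelation function
#' `g(k) = <v_0 . v_k>`, the maximum-caliber channel probabilities at step
#' `k` are `P_{i,k} proportional to exp(d * g(k) * (c_i0 . c_i))` over the
#' `b` lattice directions (`d` the spatial dimension, `c_i0` the initial
#' direction). Weights are computed in log space, so large `|g|` does not
#' overflow; as `g -> Inf` all probability concentrates on `c_i0`.
#'
#' @param g numeric autocorrelation series, one value per time step.
#' @param i0 index of the initial direction channel.
#' @param geom an [LGCAGeometry-class] (supplies `d` and the directions).
#' @return numeric `length(g) x b` matrix of channel probabilities (rows
#'   sum to 1).
#' @examples
#' g <- geometry(createLattice(2, c(4, 4)))
#' persistenceFromAutocorrelation(1, i0 = 1, geom = g)[1, 1]
#' # = exp(2) / (exp(2) + 2 + exp(-2))
#' @export
persistenceFromAutocorrelation <- function(g, i0, geom) {
  if (any(!is.finite(g))) .lgcaStop("numeric", "autocorrelation must be finite")
  if (!i0 %in% seq_len(geom@b)) .lgcaStop("config", "i0 must index a direction")
  d <- geom@dimension
  dots <- drop(geom@velocities %*% geom@velocities[i0, ])
  P <- t(vapply(as.numeric(g), function(gk) .softmax(d * gk * dots),
                numeric(geom@b)))
  colnames(P) <- paste0("c", seq_len(geom@b))
  P
}
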
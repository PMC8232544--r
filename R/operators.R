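# The BIO-LGCA update cycle: stochastic reorientation (O), birth/death (R),
# phenotypic switching (S), deterministic propagation (P). One time step
# applies O, then R, then S, then P (operator composition S.R.O read
# right-to-left, propagation last).

.tableCache <- new.env(parent = emptyenv())
.maxEnumK <- 16L

# Candidate-outcome table for one phenotype block: all C(K, n) 0/1 vectors
# with n occupied channels, in canonical (combn) order, plus precomputed
# per-outcome flux J, nematic vector N and resting count.
.singleTable <- function(n, geom) {
  key <- sprintf("s%d_%d_%d", n, geom@K, geom@b)
  tab <- .tableCache[[key]]
  if (!is.null(tab)) return(tab)
  K <- geom@K; b <- geom@b
  if (n == 0L) {
    occ <- matrix(0L, 1L, K)
  } else if (n == K) {
    occ <- matrix(1L, 1L, K)
  } else {
    pos <- utils::combn(K, n)
    occ <- matrix(0L, ncol(pos), K)
    occ[cbind(rep(seq_len(ncol(pos)), each = n), as.vector(pos))] <- 1L
  }
  vel <- geom@velocities
  nem <- vel[.nematicChannel(seq_len(b), b), , drop = FALSE] / 2
  mov <- occ[, seq_len(b), drop = FALSE]
  tab <- list(occ = occ,
              J = mov %*% vel,
              N = mov %*% nem,
              nRest = rowSums(occ) - rowSums(mov))
  .tableCache[[key]] <- tab
  tab
}

# Combined outcome table across phenotypes for a vector of per-phenotype
# counts; mass conservation holds per phenotype.
.outcomeTable <- function(counts, geom) {
  if (geom@K > .maxEnumK)
    .lgcaStop("capability",
              "exact outcome enumeration supports K <= %d (got K = %d); reduce a",
              .maxEnumK, geom@K)
  if (any(counts < 0L) || any(counts > geom@K))
    .lgcaStop("config", "per-phenotype counts must lie in 0..K")
  if (geom@nPhenotypes == 1L) return(.singleTable(counts[1L], geom))
  key <- sprintf("m%s_%d_%d", paste(counts, collapse = "."), geom@K, geom@b)
  tab <- .tableCache[[key]]
  if (!is.null(tab)) return(tab)
  parts <- lapply(counts, .singleTable, geom = geom)
  idx <- expand.grid(lapply(parts, function(t) seq_len(nrow(t$occ))))
  occ <- do.call(cbind, lapply(seq_along(parts),
                               function(p) parts[[p]]$occ[idx[[p]], , drop = FALSE]))
  J <- Reduce(`+`, lapply(seq_along(parts),
                          function(p) parts[[p]]$J[idx[[p]], , drop = FALSE]))
  N <- Reduce(`+`, lapply(seq_along(parts),
                          function(p) parts[[p]]$N[idx[[p]], , drop = FALSE]))
  nRest <- Reduce(`+`, lapply(seq_along(parts),
                              function(p) parts[[p]]$nRest[idx[[p]]]))
  tab <- list(occ = occ, J = J, N = N, nRest = nRest)
  .tableCache[[key]] <- tab
  tab
}

#' Enumerate mass-conserving candidate outcomes
#'
#' Lists every node configuration with the given per-phenotype cell counts:
#' the support of the reorientation operator's transition distribution
#' (`prod(choose(K, n_sigma))` configurations, in a deterministic canonical
#' order). Enumeration is exact and bounded at `K <= 16`.
#'
#' @param counts integer vector of cells per phenotype.
#' @param geom an [LGCAGeometry-class].
#' @return integer 0/1 matrix, one row per candidate configuration.
#' @examples
#' g <- geometry(createLattice(1, 5, a = 2))
#' nrow(enumerateOutcomes(2, g))  # choose(4, 2) = 6
#' @export
enumerateOutcomes <- function(counts, geom) {
  .outcomeTable(as.integer(counts), geom)$occ
}

# per-node, per-phenotype counts (L x P matrix)
.phenotypeCounts <- function(lattice) {
  g <- lattice@geometry
  occ <- lattice@occupancy
  out <- matrix(0L, nrow(occ), g@nPhenotypes)
  for (p in seq_len(g@nPhenotypes))
    out[, p] <- rowSums(occ[, (p - 1L) * g@K + seq_len(g@K), drop = FALSE])
  out
}

#' Reorientation distribution at one node
#'
#' Enumerates all mass-conserving outcomes at node `r` and computes their
#' Boltzmann probabilities `exp(E) / Z` under the rule's energy, with the
#' neighbourhood configuration and environment taken from the (pre-update)
#' lattice. Weights are handled in log space, so large sensitivities do not
#' overflow. With all sensitivities zero the distribution is uniform.
#'
#' @param lattice an [LGCALattice-class].
#' @param r node index.
#' @param rule an [LGCARule-class].
#' @return a list with `outcomes` (0/1 matrix), `probabilities` (summing to
#'   1), `energies`, and the normalisation `Z = sum(exp(E))` together with
#'   its logarithm `logZ`.
#' @export
reorientationProbabilities <- function(lattice, r, rule) {
  g <- lattice@geometry
  fields <- .ruleFields(rule, lattice)
  counts <- .phenotypeCounts(lattice)[r, ]
  tab <- .outcomeTable(counts, g)
  e <- as.numeric(rule@energy(tab, fields, r))
  if (any(!is.finite(e)))
    .lgcaStop("numeric", "rule '%s' produced a non-finite energy", rule@name)
  m <- max(e)
  p <- exp(e - m)
  list(outcomes = tab$occ, probabilities = p / sum(p), energies = e,
       Z = sum(exp(e)), logZ = m + log(sum(p)))
}

#' Apply the stochastic reorientation operator
#'
#' Synchronously redistributes the cells of every node among its channels:
#' each node is replaced by an independent sample from its Boltzmann
#' outcome distribution (see [reorientationProbabilities()]), with every
#' node's neighbourhood read from the pre-update lattice. Per-phenotype
#' cell counts of every node are conserved exactly.
#'
#' @param lattice an [LGCALattice-class].
#' @param rule an [LGCARule-class].
#' @return the lattice after reorientation (time step unchanged).
#' @export
applyReorientation <- function(lattice, rule) {
  g <- lattice@geometry
  fields <- .ruleFields(rule, lattice)
  counts <- .phenotypeCounts(lattice)
  occ <- lattice@occupancy
  active <- which(rowSums(counts) > 0L)
  for (r in active) {
    tab <- .outcomeTable(counts[r, ], g)
    nOut <- nrow(tab$occ)
    if (nOut == 1L) next
    e <- rule@energy(tab, fields, r)
    if (any(!is.finite(e)))
      .lgcaStop("numeric", "rule '%s' produced a non-finite energy", rule@name)
    occ[r, ] <- tab$occ[sample.int(nOut, 1L, prob = exp(e - max(e))), ]
  }
  lattice@occupancy <- occ
  lattice
}

#' Apply the deterministic propagation operator
#'
#' Moves every cell in a velocity channel to the neighbouring node in its
#' channel direction (`s_j(r + c_j, k + 1) = s_j(r, k)`); rest-channel
#' cells stay. Each target channel receives from exactly one source, so the
#' exclusion principle cannot be violated. The time step is incremented.
#'
#' @param lattice an [LGCALattice-class].
#' @return the propagated lattice.
#' @export
applyPropagation <- function(lattice) {
  g <- lattice@geometry
  occ <- lattice@occupancy
  new <- occ
  for (p in seq_len(g@nPhenotypes)) {
    for (j in seq_len(g@b)) {
      col <- (p - 1L) * g@K + j
      new[lattice@neighbours[, j], col] <- occ[, col]
    }
  }
  lattice@occupancy <- new
  lattice@timeStep <- lattice@timeStep + 1L
  lattice
}

#' Construct demographic rates
#'
#' @param birth per-cell birth probability per step, in \[0, 1\].
#' @param death per-cell death probability per step, in \[0, 1\].
#' @param switch optional `nPhenotypes x nPhenotypes` switch probability
#'   matrix with row sums at most 1 (remainder = stay).
#' @return an [LGCARates-class].
#' @export
demographicRates <- function(birth = 0, death = 0, switch = NULL) {
  if (is.null(switch)) switch <- matrix(numeric(0), 0, 0)
  obj <- new("LGCARates", birth = as.numeric(birth), death = as.numeric(death),
             switch = switch)
  validObject(obj)
  obj
}

#' Apply the stochastic birth/death operator
#'
#' Each cell dies independently with probability `death`; each surviving
#' cell then attempts one birth with probability `birth`, placing the
#' daughter into a uniformly chosen free channel of the same node and
#' phenotype (the birth fails if no channel is free, so exclusion is
#' preserved).
#'
#' @param lattice an [LGCALattice-class].
#' @param rates an [LGCARates-class].
#' @return the lattice after birth and death.
#' @export
applyBirthDeath <- function(lattice, rates) {
  if (rates@death == 0 && rates@birth == 0) return(lattice)
  g <- lattice@geometry
  occ <- lattice@occupancy
  if (rates@death > 0) {
    occIdx <- which(occ == 1L)
    if (length(occIdx))
      occ[occIdx[runif(length(occIdx)) < rates@death]] <- 0L
  }
  if (rates@birth > 0) {
    L <- nrow(occ)
    for (r in which(rowSums(occ) > 0L)) {
      for (p in seq_len(g@nPhenotypes)) {
        cols <- (p - 1L) * g@K + seq_len(g@K)
        parents <- cols[occ[r, cols] == 1L]
        for (pc in parents) {
          if (runif(1) >= rates@birth) next
          free <- cols[occ[r, cols] == 0L]
          if (!length(free)) next
          tgt <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
          occ[r, tgt] <- 1L
        }
      }
    }
  }
  lattice@occupancy <- occ
  lattice
}

#' Apply the stochastic phenotypic switch operator
#'
#' Each cell independently switches phenotype with the probabilities of its
#' row of the switch matrix, keeping its channel; if the same channel in
#' the target phenotype block is occupied the switch fails. Total cell
#' number is unchanged. With one phenotype or an empty matrix this is a
#' no-op.
#'
#' @param lattice an [LGCALattice-class].
#' @param switch switch probability matrix (rows: current phenotype).
#' @return the lattice after switching.
#' @export
applyPhenotypeSwitch <- function(lattice, switch) {
  g <- lattice@geometry
  if (g@nPhenotypes == 1L || !length(switch)) return(lattice)
  if (nrow(switch) != g@nPhenotypes || ncol(switch) != g@nPhenotypes)
    .lgcaStop("config", "switch matrix must be %d x %d", g@nPhenotypes,
              g@nPhenotypes)
  if (any(switch < 0) || any(rowSums(switch) > 1 + 1e-12))
    .lgcaStop("config", "switch matrix rows must be non-negative and sum to <= 1")
  occ <- lattice@occupancy
  orig <- occ                               # each original cell switches at most once
  P <- g@nPhenotypes; K <- g@K
  for (r in which(rowSums(orig) > 0L)) {
    for (p in seq_len(P)) {
      chans <- which(orig[r, (p - 1L) * K + seq_len(K)] == 1L)
      for (ch in chans) {
        pr <- switch[p, ]
        tgt <- sample.int(P + 1L, 1L, prob = c(pr, max(0, 1 - sum(pr))))
        if (tgt > P || tgt == p) next
        tcol <- (tgt - 1L) * K + ch
        if (occ[r, tcol] == 0L) {
          occ[r, tcol] <- 1L
          occ[r, (p - 1L) * K + ch] <- 0L
        }
      }
    }
  }
  lattice@occupancy <- occ
  lattice
}

#' Advance a BIO-LGCA by one time step
#'
#' Applies reorientation, then birth/death, then phenotypic switching, then
#' deterministic propagation (composition `S.R.O` read right-to-left, with
#' propagation last).
#'
#' @param lattice an [LGCALattice-class].
#' @param rule an [LGCARule-class].
#' @param rates optional [LGCARates-class] (default: no birth/death or
#'   switching, so the dynamics conserves cell number exactly).
#' @return the lattice at the next time step.
#' @export
lgcaStep <- function(lattice, rule, rates = NULL) {
  lattice <- applyReorientation(lattice, rule)
  if (!is.null(rates)) {
    lattice <- applyBirthDeath(lattice, rates)
    if (length(rates@switch))
      lattice <- applyPhenotypeSwitch(lattice, rates@switch)
  }
  applyPropagation(lattice)
}

#' Run a BIO-LGCA simulation
#'
#' Advances the lattice `steps` times with [lgcaStep()], recording the node
#' density and flux after every step (and, optionally, full occupancy
#' snapshots). A given seed makes the trajectory bit-for-bit reproducible:
#' node updates consume random draws in canonical node order.
#'
#' @param lattice initial [LGCALattice-class].
#' @param rule an [LGCARule-class].
#' @param steps number of time steps (>= 0).
#' @param rates optional [LGCARates-class].
#' @param seed optional integer seed.
#' @param snapshots `"none"` or `"all"`: whether to keep full occupancy
#'   matrices per step.
#' @return an [LGCATrajectory-class] with `steps + 1` recorded states
#'   (the initial state first).
#' @examples
#' lat <- initializeRandom(createLattice(1, 20, a = 1), 1, seed = 1)
#' tr <- lgcaRun(lat, randomWalkRule(), steps = 5, seed = 1)
#' trajectoryDensity(tr)[1:3, 1:5]
#' @export
lgcaRun <- function(lattice, rule, steps, rates = NULL, seed = NULL,
                    snapshots = c("none", "all")) {
  snapshots <- match.arg(snapshots)
  if (steps < 0) .lgcaStop("config", "steps must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  g <- lattice@geometry
  L <- nNodes(lattice)
  dens <- matrix(0, steps + 1L, L)
  flux <- array(0, c(steps + 1L, L, g@dimension))
  snaps <- if (snapshots == "all") vector("list", steps + 1L) else list()
  dens[1L, ] <- cellCounts(lattice)
  flux[1L, , ] <- nodeFlux(lattice)
  if (snapshots == "all") snaps[[1L]] <- lattice@occupancy
  for (k in seq_len(steps)) {
    lattice <- lgcaStep(lattice, rule, rates)
    dens[k + 1L, ] <- cellCounts(lattice)
    flux[k + 1L, , ] <- nodeFlux(lattice)
    if (snapshots == "all") snaps[[k + 1L]] <- lattice@occupancy
  }
  new("LGCATrajectory", lattice = lattice, density = dens, flux = flux,
      snapshots = snaps,
      seed = if (is.null(seed)) integer(0) else as.integer(seed))
}

#' Trajectory accessors
#'
#' @param trajectory an [LGCATrajectory-class].
#' @return `trajectoryDensity()` the `(steps + 1) x nodes` density matrix
#'   (a kymograph); `trajectoryFlux()` the flux array; `finalLattice()` the
#'   final [LGCALattice-class].
#' @export
trajectoryDensity <- function(trajectory) trajectory@density

#' @rdname trajectoryDensity
#' @export
trajectoryFlux <- function(trajectory) trajectory@flux

#' @rdname trajectoryDensity
#' @export
finalLattice <- function(trajectory) trajectory@lattice
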
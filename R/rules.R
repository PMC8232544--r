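# Built-in reorientation rules. Every rule induces Boltzmann transition
# probabilities P(s -> s^O) = exp(E(s^O, s_N)) / Z over the mass-conserving
# outcomes; the energies below are the elementary interaction moduli for
# single and collective cell migration.

.newRule <- function(name, params, fieldsNeeded, energy) {
  new("LGCARule", name = name, params = params, fieldsNeeded = fieldsNeeded,
      energy = energy)
}

# Neighbourhood fields consumed by the built-in energies, computed
# vectorised over all nodes from the pre-update lattice. The neighbourhood
# is the von Neumann template (the b adjacent nodes; the central node is
# excluded).
.ruleFields <- function(rule, lattice) {
  g <- lattice@geometry
  nb <- lattice@neighbours
  L <- nNodes(lattice)
  need <- rule@fieldsNeeded
  fields <- list()
  if (any(c("G", "gAgg") %in% need))
    nTot <- cellCounts(lattice)
  if (any(c("D", "gAlign") %in% need))
    Jn <- nodeFlux(lattice)
  if ("G" %in% need) {
    nN <- matrix(nTot[nb], L, g@b)
    fields$G <- nN %*% g@velocities
  }
  if ("D" %in% need) {
    D <- matrix(0, L, g@dimension)
    for (p in seq_len(g@b)) D <- D + Jn[nb[, p], , drop = FALSE]
    fields$D <- D
  }
  if ("Gsig" %in% need) {
    if (!length(lattice@signal))
      .lgcaStop("config", "rule '%s' requires a scalar signal field", rule@name)
    sN <- matrix(lattice@signal[nb], L, g@b)
    fields$Gsig <- sN %*% g@velocities
  }
  if ("E" %in% need) {
    if (!nrow(lattice@field))
      .lgcaStop("config", "rule '%s' requires a vector environment field",
                rule@name)
    fields$E <- lattice@field
  }
  if (any(c("gAgg", "gAlign", "nRestN") %in% need) && g@b != 2L)
    .lgcaStop("capability", "rule '%s' is defined for 1D lattices (b = 2)",
              rule@name)
  if ("gAgg" %in% need) {
    nCrit <- rule@params$nCrit
    np <- nTot[nb[, 1L]]; nm <- nTot[nb[, 2L]]
    fields$gAgg <- np * (1 - np / nCrit) - nm * (1 - nm / nCrit)
  }
  if ("gAlign" %in% need) {
    jx <- Jn[, 1L]
    fields$gAlign <- jx[nb[, 1L]] + jx[nb[, 2L]]
  }
  if ("nRestN" %in% need) {
    nr <- restingCounts(lattice)
    fields$nRestN <- nr[nb[, 1L]] + nr[nb[, 2L]]
  }
  fields
}

#' Random walk rule
#'
#' Zero interaction energy: the reorientation distribution is uniform over
#' all mass-conserving outcomes, and cells perform unbiased lattice walks.
#'
#' @return an [LGCARule-class].
#' @export
randomWalkRule <- function() {
  .newRule("randomwalk", list(), character(0),
           function(tab, fields, r) numeric(nrow(tab$occ)))
}

#' Chemotaxis rule
#'
#' Energy `beta * Gsig(s_N) . J(s^O)` with the signal gradient field
#' `Gsig = sum_p c_p csig(r + c_p)` built from the static scalar signal
#' concentration at the neighbour nodes. Cells are statistically biased up
#' the signal gradient; a uniform signal gives a random walk.
#'
#' @param beta chemotactic sensitivity.
#' @return an [LGCARule-class]; requires a signal field on the lattice
#'   (see [signalField<-]).
#' @export
chemotaxisRule <- function(beta) {
  force(beta)
  .newRule("chemotaxis", list(beta = beta), "Gsig",
           function(tab, fields, r) beta * drop(tab$J %*% fields$Gsig[r, ]))
}

#' Haptotaxis rule
#'
#' Energy `beta * E(r) . J(s^O)` for a static vector field `E` (e.g. a
#' gradient of adhesion-ligand concentration in the extracellular matrix):
#' cells drift along `E`.
#'
#' @param beta haptotactic sensitivity.
#' @return an [LGCARule-class]; requires a vector field on the lattice
#'   (see [vectorField<-]).
#' @export
haptotaxisRule <- function(beta) {
  force(beta)
  .newRule("haptotaxis", list(beta = beta), "E",
           function(tab, fields, r) beta * drop(tab$J %*% fields$E[r, ]))
}

#' Contact guidance rule
#'
#' Energy `beta * |E(r) . J(s^O)|`: the environment conveys orientational
#' rather than directional guidance, so motion is biased along the axis of
#' `E` with no preferred sign (the distribution is invariant under
#' `E -> -E`).
#'
#' @param beta sensitivity.
#' @return an [LGCARule-class]; requires a vector field on the lattice.
#' @export
contactGuidanceRule <- function(beta) {
  force(beta)
  .newRule("contact_guidance", list(beta = beta), "E",
           function(tab, fields, r) beta * abs(drop(tab$J %*% fields$E[r, ])))
}

#' Polar alignment rule
#'
#' Energy `beta * D(s_N) . J(s^O)` with the local cell momentum
#' `D = sum_p J(s_p)` (sum of neighbour node fluxes): outcomes aligned with
#' the neighbourhood momentum are favoured, triggering polar collective
#' motion.
#'
#' @param beta alignment sensitivity.
#' @return an [LGCARule-class].
#' @export
alignmentRule <- function(beta) {
  force(beta)
  .newRule("alignment", list(beta = beta), "D",
           function(tab, fields, r) beta * drop(tab$J %*% fields$D[r, ]))
}

#' Adhesion (attractive interaction) rule
#'
#' Energy `beta * G(s_N) . J(s^O)` with the density gradient field
#' `G = sum_p n(s_p) c_p` over the b lattice neighbours: cells move towards
#' denser neighbourhoods, favouring agglomeration. Above the critical
#' sensitivity (see [adhesionCritical()]) a homogeneous population
#' destabilises into periodic clusters.
#'
#' @param beta adhesion sensitivity.
#' @return an [LGCARule-class].
#' @export
adhesionRule <- function(beta) {
  force(beta)
  .newRule("adhesion", list(beta = beta), "G",
           function(tab, fields, r) beta * drop(tab$J %*% fields$G[r, ]))
}

#' Combined invasion rule (aggregation + alignment + resting)
#'
#' One-dimensional rule combining three independent interaction
#' mechanisms, used to analyse invasion plasticity of tumour cells in
#' confined environments:
#' \itemize{
#'   \item aggregation energy `betaAgg * j(s^O) * gAgg(s_N)` with the
#'     logistic density gradient
#'     `gAgg = sum_j n(r + c_j) (1 - n(r + c_j) / nCrit) c_j`, whose
#'     carrying-capacity factor models the homeostatic cell density;
#'   \item alignment energy `betaAlign * j(s^O) * gAlign(s_N)` with the
#'     neighbourhood flux `gAlign = sum_j j(r + c_j)`;
#'   \item resting energy `betaRest * nRest(s^O) * nRest(s_N)`, an
#'     increased tendency to rest next to resting neighbours (steric
#'     interaction).
#' }
#' With all sensitivities zero the rule is the random walk; with
#' `(betaAgg, 0, 0)` and `nCrit -> Inf` it reproduces [adhesionRule()] on
#' single-cell neighbourhoods.
#'
#' @param betaAgg aggregation sensitivity.
#' @param betaAlign alignment sensitivity.
#' @param betaRest resting sensitivity.
#' @param nCrit homeostatic density parameter (> 0; non-integers allowed).
#' @return an [LGCARule-class]; only defined for 1D lattices.
#' @export
invasionRule <- function(betaAgg = 0, betaAlign = 0, betaRest = 0, nCrit) {
  if (nCrit <= 0) .lgcaStop("config", "nCrit must be positive")
  force(betaAgg); force(betaAlign); force(betaRest)
  .newRule("invasion",
           list(betaAgg = betaAgg, betaAlign = betaAlign,
                betaRest = betaRest, nCrit = nCrit),
           c("gAgg", "gAlign", "nRestN"),
           function(tab, fields, r) {
             j <- tab$J[, 1L]
             betaAgg * j * fields$gAgg[r] +
               betaAlign * j * fields$gAlign[r] +
               betaRest * tab$nRest * fields$nRestN[r]
           })
}

#' Look up a built-in rule by name
#'
#' Resolves the rule name strings used in run configurations
#' (`randomwalk`, `chemotaxis`, `haptotaxis`, `contact_guidance`,
#' `alignment`, `adhesion`, `invasion`) to rule constructors.
#'
#' @param name rule name string.
#' @param params named list of rule parameters (`beta`, or `betaAgg`,
#'   `betaAlign`, `betaRest`, `nCrit`).
#' @return an [LGCARule-class].
#' @export
makeRule <- function(name, params = list()) {
  switch(name,
    randomwalk       = randomWalkRule(),
    chemotaxis       = chemotaxisRule(params$beta),
    haptotaxis       = haptotaxisRule(params$beta),
    contact_guidance = contactGuidanceRule(params$beta),
    alignment        = alignmentRule(params$beta),
    adhesion         = adhesionRule(params$beta),
    invasion         = invasionRule(betaAgg = params$betaAgg %||% 0,
                                    betaAlign = params$betaAlign %||% 0,
                                    betaRest = params$betaRest %||% 0,
                                    nCrit = params$nCrit),
    .lgcaStop("config", "unknown rule name '%s'", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
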
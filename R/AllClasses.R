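#' @import methods
NULL

#' Lattice geometry of a BIO-LGCA
#'
#' Describes the regular lattice underlying a BIO-LGCA model: its dimension
#' (1 or 2), extents, velocity channels and rest channels. Each node carries
#' `b` velocity channels (unit vectors to the nearest neighbours) and `a`
#' zero-velocity rest channels, for a node capacity of `K = a + b` cells per
#' phenotype under the exclusion principle.
#'
#' Channel ordering is normative throughout the package: velocity channels
#' come first, in counterclockwise angular order (1D: `+1`, `-1`;
#' 2D square: `+x`, `+y`, `-x`, `-y`), followed by the `a` rest channels.
#' With this order channel `j` and channel `j + b/2` are opposite, and the
#' nematic alignment vector's index arithmetic (see [nodeObservables()])
#' is well defined.
#'
#' @slot dimension integer, 1 or 2.
#' @slot shape integer vector of node extents per axis.
#' @slot a integer, number of rest channels.
#' @slot b integer, number of velocity channels (2 in 1D, 4 in 2D).
#' @slot K integer, node capacity `a + b`.
#' @slot velocities numeric `b x dimension` matrix of channel unit vectors.
#' @slot nPhenotypes integer, number of phenotypes sharing the lattice.
#' @slot boundary character, boundary condition (only `"periodic"`).
#'
#' @seealso [createLattice()]
#' @export
setClass("LGCAGeometry",
  representation(
    dimension   = "integer",
    shape       = "integer",
    a           = "integer",
    b           = "integer",
    K           = "integer",
    velocities  = "matrix",
    nPhenotypes = "integer",
    boundary    = "character"
  )
)

setValidity("LGCAGeometry", function(object) {
  msg <- character()
  if (!object@dimension %in% c(1L, 2L))
    msg <- c(msg, "dimension must be 1 or 2")
  if (length(object@shape) != object@dimension || any(object@shape < 1L))
    msg <- c(msg, "shape must give a positive extent per axis")
  if (object@a < 0L) msg <- c(msg, "a (rest channels) must be non-negative")
  if (object@K != object@a + object@b) msg <- c(msg, "K must equal a + b")
  if (nrow(object@velocities) != object@b ||
      ncol(object@velocities) != object@dimension)
    msg <- c(msg, "velocities must be a b x dimension matrix")
  else {
    if (max(abs(colSums(object@velocities))) > 1e-12)
      msg <- c(msg, "velocity vectors must sum to zero")
    opp <- object@velocities[.oppositeChannel(seq_len(object@b), object@b), ,
                             drop = FALSE]
    if (max(abs(opp + object@velocities)) > 1e-12)
      msg <- c(msg, "each velocity channel must have an opposite channel")
  }
  if (object@nPhenotypes < 1L) msg <- c(msg, "need at least one phenotype")
  if (!identical(object@boundary, "periodic"))
    msg <- c(msg, "only periodic boundaries are supported")
  if (length(msg)) msg else TRUE
})

#' Lattice state of a BIO-LGCA
#'
#' The full state of a BIO-LGCA at one time step: a 0/1 occupancy matrix
#' (nodes x channels, channels blocked per phenotype), the time step, and
#' optional static environment fields (a scalar signal concentration per
#' node used by chemotaxis, and a vector field per node used by haptotaxis
#' and contact guidance).
#'
#' Nodes are indexed 1..L; in 2D the x coordinate varies fastest
#' (node index `x + (y - 1) * shape[1]`), which is also the row order
#' expected of environment-field files.
#'
#' @slot geometry an [LGCAGeometry-class].
#' @slot occupancy integer 0/1 matrix, `nodes x (nPhenotypes * K)`.
#' @slot neighbours integer `nodes x b` matrix; entry `[r, p]` is the index
#'   of node `r + c_p` under periodic wrapping.
#' @slot timeStep integer, non-negative.
#' @slot signal numeric; length 0 (absent) or one non-negative value per node.
#' @slot field numeric matrix; 0 rows (absent) or one row per node with
#'   `dimension` columns.
#'
#' @seealso [createLattice()], [initializeRandom()], [lgcaRun()]
#' @export
setClass("LGCALattice",
  representation(
    geometry   = "LGCAGeometry",
    occupancy  = "matrix",
    neighbours = "matrix",
    timeStep   = "integer",
    signal     = "numeric",
    field      = "matrix"
  )
)

setValidity("LGCALattice", function(object) {
  g <- object@geometry
  L <- prod(g@shape)
  msg <- character()
  occ <- object@occupancy
  if (nrow(occ) != L || ncol(occ) != g@nPhenotypes * g@K)
    msg <- c(msg, "occupancy must be nodes x (nPhenotypes * K)")
  if (!all(occ %in% c(0L, 1L)))
    msg <- c(msg, "occupancy entries must be 0 or 1 (exclusion principle)")
  if (nrow(object@neighbours) != L || ncol(object@neighbours) != g@b)
    msg <- c(msg, "neighbours must be nodes x b")
  if (object@timeStep < 0L) msg <- c(msg, "timeStep must be non-negative")
  if (length(object@signal) && (length(object@signal) != L ||
                                any(object@signal < 0)))
    msg <- c(msg, "signal must hold one non-negative value per node")
  if (nrow(object@field) && (nrow(object@field) != L ||
                             ncol(object@field) != g@dimension))
    msg <- c(msg, "field must hold one d-vector per node")
  if (length(msg)) msg else TRUE
})

#' Reorientation rule of a BIO-LGCA
#'
#' A reorientation rule assigns an interaction energy to every candidate
#' post-interaction node configuration given the configuration of the von
#' Neumann neighbourhood (and static environment fields). The reorientation
#' operator samples outcomes with Boltzmann probabilities proportional to
#' `exp(energy)`, restricted to outcomes conserving the per-phenotype cell
#' count. With all sensitivities zero every rule reduces to the unbiased
#' random walk.
#'
#' @slot name character rule identifier (e.g. `"adhesion"`).
#' @slot params named list of sensitivities and constants.
#' @slot fieldsNeeded character vector of neighbourhood fields the energy
#'   consumes (computed once per lattice sweep).
#' @slot energy function `(tab, fields, node)` returning one energy per
#'   candidate outcome; `tab` is an outcome table as built by
#'   [enumerateOutcomes()] (with flux and rest-count columns precomputed).
#'
#' @seealso [randomWalkRule()], [adhesionRule()], [invasionRule()]
#' @export
setClass("LGCARule",
  representation(
    name         = "character",
    params       = "list",
    fieldsNeeded = "character",
    energy       = "function"
  )
)

#' Demographic rates for birth, death and phenotypic switching
#'
#' Per-cell per-step probabilities for the stochastic birth/death operator
#' and the phenotypic switch operator. The paper-level model class leaves
#' the functional forms open; the defaults here are the simplest
#' exclusion-respecting choice: each cell dies independently with
#' probability `death`; each survivor attempts one birth with probability
#' `birth` into a uniformly chosen free channel of its node and phenotype
#' (failing if none is free); each cell switches phenotype sigma -> tau
#' with probability `switch[sigma, tau]`, keeping its channel if the target
#' phenotype's channel is free and failing otherwise.
#'
#' @slot birth numeric in \[0, 1\].
#' @slot death numeric in \[0, 1\].
#' @slot switch numeric matrix `nPhenotypes x nPhenotypes` with row sums
#'   at most 1 (the remainder is the stay probability); a 0 x 0 matrix
#'   means no switching.
#'
#' @seealso [demographicRates()], [lgcaStep()]
#' @export
setClass("LGCARates",
  representation(
    birth  = "numeric",
    death  = "numeric",
    switch = "matrix"
  )
)

setValidity("LGCARates", function(object) {
  msg <- character()
  if (object@birth < 0 || object@birth > 1) msg <- c(msg, "birth must be in [0, 1]")
  if (object@death < 0 || object@death > 1) msg <- c(msg, "death must be in [0, 1]")
  sw <- object@switch
  if (nrow(sw)) {
    if (nrow(sw) != ncol(sw)) msg <- c(msg, "switch matrix must be square")
    if (any(sw < 0)) msg <- c(msg, "switch probabilities must be non-negative")
    if (any(rowSums(sw) > 1 + 1e-12))
      msg <- c(msg, "switch matrix rows must sum to at most 1")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated BIO-LGCA trajectory
#'
#' Stores the outcome of [lgcaRun()]: the final lattice, per-step node
#' densities and fluxes, optionally full occupancy snapshots, and the seed.
#'
#' @slot lattice final [LGCALattice-class].
#' @slot density numeric `(steps + 1) x nodes` matrix of total cell counts.
#' @slot flux numeric array `(steps + 1) x nodes x dimension` of node fluxes.
#' @slot snapshots list of occupancy matrices (possibly empty).
#' @slot seed integer of length 0 or 1.
#'
#' @export
setClass("LGCATrajectory",
  representation(
    lattice   = "LGCALattice",
    density   = "matrix",
    flux      = "array",
    snapshots = "list",
    seed      = "integer"
  )
)

#' @describeIn LGCAGeometry-class compact display
#' @param object object to display
#' @export
setMethod("show", "LGCAGeometry", function(object) {
  cat(sprintf("LGCAGeometry: %dD %s lattice, b = %d velocity + a = %d rest channels (K = %d), %d phenotype(s), %s boundary\n",
              object@dimension, paste(object@shape, collapse = " x "),
              object@b, object@a, object@K, object@nPhenotypes,
              object@boundary))
})

#' @describeIn LGCALattice-class compact display
#' @param object object to display
#' @export
setMethod("show", "LGCALattice", function(object) {
  g <- object@geometry
  cat(sprintf("LGCALattice at step %d: %d nodes, %d cells (capacity %d/node)\n",
              object@timeStep, prod(g@shape), sum(object@occupancy),
              g@nPhenotypes * g@K))
  if (length(object@signal)) cat("  + scalar signal field\n")
  if (nrow(object@field)) cat("  + vector environment field\n")
})

#' @describeIn LGCARule-class compact display
#' @param object object to display
#' @export
setMethod("show", "LGCARule", function(object) {
  p <- if (length(object@params))
    paste(names(object@params),
          vapply(object@params, function(x) paste(format(x), collapse = ","),
                 character(1)),
          sep = " = ", collapse = ", ")
  else "none"
  cat(sprintf("LGCARule '%s' (parameters: %s)\n", object@name, p))
})

#' @describeIn LGCATrajectory-class compact display
#' @param object object to display
#' @export
setMethod("show", "LGCATrajectory", function(object) {
  cat(sprintf("LGCATrajectory: %d steps on %d nodes (%d snapshot(s) kept)\n",
              nrow(object@density) - 1L, ncol(object@density),
              length(object@snapshots)))
})
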
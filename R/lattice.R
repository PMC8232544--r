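#' Create an empty BIO-LGCA lattice
#'
#' Builds a periodic 1D chain or 2D square lattice with `b` velocity
#' channels (2 in 1D, 4 in 2D) and `a` rest channels per node and no cells.
#' Velocity channels are ordered counterclockwise (1D: `+1`, `-1`; 2D:
#' `+x`, `+y`, `-x`, `-y`) followed by rest channels; the von Neumann
#' neighbour table is precomputed in the same order.
#'
#' @param dimension lattice dimension, 1 or 2.
#' @param shape integer vector of node extents per axis (length `dimension`).
#' @param a number of rest channels per node (non-negative integer).
#' @param boundary boundary condition; only `"periodic"` is supported.
#' @param phenotypes number of phenotypes; each phenotype has its own block
#'   of `K` channels per node (exclusion applies per phenotype per channel).
#' @return an empty [LGCALattice-class].
#' @examples
#' lat <- createLattice(1, 10, a = 2)
#' geometry(lat)
#' @export
createLattice <- function(dimension, shape, a = 0L, boundary = "periodic",
                          phenotypes = 1L) {
  if (!is.numeric(dimension) || length(dimension) != 1 ||
      !dimension %in% c(1, 2))
    .lgcaStop("config", "unsupported lattice dimension %s (must be 1 or 2)",
              paste(dimension, collapse = ","))
  dimension <- as.integer(dimension)
  shape <- as.integer(shape)
  if (length(shape) == 1L && dimension == 2L) shape <- rep(shape, 2L)
  if (length(shape) != dimension || any(is.na(shape)) || any(shape < 1L))
    .lgcaStop("config", "shape must give a positive node extent per axis")
  if (is.na(a) || a < 0) .lgcaStop("config", "a must be a non-negative integer")
  a <- as.integer(a)
  phenotypes <- as.integer(phenotypes)
  if (is.na(phenotypes) || phenotypes < 1L)
    .lgcaStop("config", "phenotypes must be a positive integer")

  vel <- if (dimension == 1L) matrix(c(1, -1), ncol = 1) else
    matrix(c(1, 0, 0, 1, -1, 0, 0, -1), ncol = 2, byrow = TRUE)
  b <- nrow(vel)
  geom <- new("LGCAGeometry", dimension = dimension, shape = shape,
              a = a, b = b, K = a + b, velocities = vel,
              nPhenotypes = phenotypes, boundary = boundary)
  validObject(geom)

  L <- prod(shape)
  nb <- .neighbourTable(geom)
  occ <- matrix(0L, nrow = L, ncol = phenotypes * geom@K)
  new("LGCALattice", geometry = geom, occupancy = occ, neighbours = nb,
      timeStep = 0L, signal = numeric(0),
      field = matrix(numeric(0), nrow = 0, ncol = dimension))
}

# nodes x b table of neighbour indices, column p = node + c_p wrapped
.neighbourTable <- function(geom) {
  L <- as.integer(prod(geom@shape))
  idx <- seq_len(L)
  if (geom@dimension == 1L) {
    nb <- cbind(.wrap(idx + 1L, L), .wrap(idx - 1L, L))
  } else {
    nx <- geom@shape[1]; ny <- geom@shape[2]
    x <- (idx - 1L) %% nx + 1L
    y <- (idx - 1L) %/% nx + 1L
    nb <- matrix(0L, L, geom@b)
    for (p in seq_len(geom@b)) {
      xp <- .wrap(x + as.integer(geom@velocities[p, 1]), nx)
      yp <- .wrap(y + as.integer(geom@velocities[p, 2]), ny)
      nb[, p] <- xp + (yp - 1L) * nx
    }
  }
  nb
}

#' Geometry, occupancy and node count accessors
#'
#' @param lattice an [LGCALattice-class].
#' @return `geometry()` the [LGCAGeometry-class]; `latticeOccupancy()` the
#'   integer 0/1 occupancy matrix (nodes x channels); `nNodes()` the number
#'   of lattice nodes; `timeStep()` the current time step.
#' @export
geometry <- function(lattice) lattice@geometry

#' @rdname geometry
#' @export
latticeOccupancy <- function(lattice) lattice@occupancy

#' @rdname geometry
#' @export
nNodes <- function(lattice) as.integer(prod(lattice@geometry@shape))

#' @rdname geometry
#' @export
timeStep <- function(lattice) lattice@timeStep

#' Replace the occupancy matrix of a lattice
#'
#' @param lattice an [LGCALattice-class].
#' @param value integer 0/1 matrix of the same shape as the current
#'   occupancy.
#' @return the modified lattice.
#' @export
`latticeOccupancy<-` <- function(lattice, value) {
  storage.mode(value) <- "integer"
  lattice@occupancy <- value
  validObject(lattice)
  lattice
}

#' Attach static environment fields
#'
#' `signalField<-` sets the per-node scalar signal concentration used by
#' the chemotaxis rule; `vectorField<-` sets the per-node vector field used
#' by haptotaxis and contact guidance. Both are static during a run.
#'
#' @param lattice an [LGCALattice-class].
#' @param value for the signal, a non-negative numeric of length `nNodes`;
#'   for the vector field, a numeric `nNodes x dimension` matrix (in 1D a
#'   plain numeric vector is accepted).
#' @return the modified lattice.
#' @export
`signalField<-` <- function(lattice, value) {
  lattice@signal <- as.numeric(value)
  validObject(lattice)
  lattice
}

#' @rdname signalField-set
#' @export
`vectorField<-` <- function(lattice, value) {
  if (is.null(dim(value))) value <- matrix(value, ncol = 1)
  lattice@field <- value
  validObject(lattice)
  lattice
}

#' @rdname signalField-set
#' @export
signalField <- function(lattice) lattice@signal

#' @rdname signalField-set
#' @export
vectorField <- function(lattice) lattice@field

#' Node-level observables of a configuration
#'
#' For a node configuration `s` (0/1 vector over the `nPhenotypes * K`
#' channels) computes the total cell number `n`, per-phenotype counts
#' `nSigma`, the node flux `J` (sum of occupied velocity vectors), the
#' nematic alignment vector
#' `N = 1/2 sum_p c_{[2(p-1) mod b] + 1} s_p` (opposite channels contribute
#' along the same direction), and the number of occupied rest channels
#' `nRest`.
#'
#' @param s integer 0/1 vector of length `nPhenotypes * K`.
#' @param geom an [LGCAGeometry-class].
#' @return a list with elements `n`, `nSigma`, `J`, `N`, `nRest`.
#' @examples
#' lat <- createLattice(2, c(3, 3), a = 1)
#' nodeObservables(c(1, 0, 1, 0, 0), geometry(lat))
#' @export
nodeObservables <- function(s, geom) {
  P <- geom@nPhenotypes; K <- geom@K; b <- geom@b
  if (length(s) != P * K)
    .lgcaStop("structure", "configuration has length %d, expected %d",
              length(s), P * K)
  if (!all(s %in% c(0, 1)))
    .lgcaStop("structure", "channel occupations must be 0 or 1")
  sm <- matrix(as.numeric(s), nrow = P, ncol = K, byrow = TRUE)
  nSigma <- rowSums(sm)
  svel <- colSums(sm[, seq_len(b), drop = FALSE])  # per-channel over phenotypes
  J <- drop(crossprod(geom@velocities, svel))
  nem <- geom@velocities[.nematicChannel(seq_len(b), b), , drop = FALSE]
  N <- drop(crossprod(nem, svel)) / 2
  list(n = sum(nSigma), nSigma = nSigma, J = J, N = N,
       nRest = sum(sm[, seq_len(geom@a) + b, drop = FALSE]))
}

#' Von Neumann neighbours of a node
#'
#' Returns the `b` neighbour node indices of node `r`, ordered like the
#' velocity channels (neighbour `p` is `r + c_p`, wrapped periodically).
#'
#' @param r node index (1-based; 2D nodes are numbered x-fastest).
#' @param lattice an [LGCALattice-class].
#' @return integer vector of `b` node indices.
#' @export
neighbourhoodOf <- function(r, lattice) {
  L <- nNodes(lattice)
  if (any(r < 1L | r > L)) .lgcaStop("index", "node index out of range 1..%d", L)
  lattice@neighbours[r, ]
}

#' Seeded homogeneous-random initial state
#'
#' Occupies every channel independently with probability `meanDensity / K`,
#' producing a spatially homogeneous random state with expected node
#' occupancy `meanDensity` per phenotype. With a seed the state is
#' bit-for-bit reproducible.
#'
#' @param lattice an [LGCALattice-class] (existing occupancy is replaced).
#' @param meanDensity target mean cells per node per phenotype, in
#'   `[0, K]`.
#' @param seed optional integer seed.
#' @return the lattice with randomised occupancy and time step 0.
#' @export
initializeRandom <- function(lattice, meanDensity, seed = NULL) {
  K <- lattice@geometry@K
  if (meanDensity < 0 || meanDensity > K)
    .lgcaStop("config", "meanDensity must lie in [0, %d]", K)
  if (!is.null(seed)) set.seed(seed)
  occ <- lattice@occupancy
  occ[] <- rbinom(length(occ), 1L, meanDensity / K)
  lattice@occupancy <- occ
  lattice@timeStep <- 0L
  lattice
}

#' Per-node totals, fluxes and resting counts of a lattice
#'
#' Vectorised observables over all nodes: `cellCounts()` the total cell
#' number per node, `nodeFlux()` the nodes x dimension matrix of node
#' fluxes, `restingCounts()` the occupied rest channels per node.
#'
#' @param lattice an [LGCALattice-class].
#' @return numeric vector or matrix over nodes.
#' @export
cellCounts <- function(lattice) as.numeric(rowSums(lattice@occupancy))

#' @rdname cellCounts
#' @export
nodeFlux <- function(lattice) {
  g <- lattice@geometry
  J <- matrix(0, nNodes(lattice), g@dimension)
  for (p in seq_len(g@nPhenotypes)) {
    cols <- (p - 1L) * g@K + seq_len(g@b)
    J <- J + lattice@occupancy[, cols, drop = FALSE] %*% g@velocities
  }
  J
}

#' @rdname cellCounts
#' @export
restingCounts <- function(lattice) {
  g <- lattice@geometry
  if (g@a == 0L) return(numeric(nNodes(lattice)))
  cols <- as.vector(outer(g@b + seq_len(g@a), (seq_len(g@nPhenotypes) - 1L) * g@K, "+"))
  as.numeric(rowSums(lattice@occupancy[, cols, drop = FALSE]))
}

#' Reflect a lattice through the origin
#'
#' Maps every channel to its opposite channel and every node `r` to `-r`
#' (periodically). Reflection negates all node fluxes and environment
#' vector fields while preserving cell numbers; directional rules are
#' equivariant under it.
#'
#' @param lattice an [LGCALattice-class].
#' @return the reflected lattice.
#' @export
reflectLattice <- function(lattice) {
  g <- lattice@geometry
  L <- nNodes(lattice)
  idx <- seq_len(L)
  if (g@dimension == 1L) {
    perm <- .wrap(2L - idx, L)               # r -> -r
  } else {
    nx <- g@shape[1]; ny <- g@shape[2]
    x <- (idx - 1L) %% nx + 1L
    y <- (idx - 1L) %/% nx + 1L
    perm <- .wrap(2L - x, nx) + (.wrap(2L - y, ny) - 1L) * nx
  }
  chanPerm <- unlist(lapply(seq_len(g@nPhenotypes), function(p) {
    off <- (p - 1L) * g@K
    c(off + .oppositeChannel(seq_len(g@b), g@b), off + g@b + seq_len(g@a))
  }))
  occ <- lattice@occupancy[perm, chanPerm, drop = FALSE]
  lattice@occupancy <- occ
  if (length(lattice@signal)) lattice@signal <- lattice@signal[perm]
  if (nrow(lattice@field)) lattice@field <- -lattice@field[perm, , drop = FALSE]
  lattice
}
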
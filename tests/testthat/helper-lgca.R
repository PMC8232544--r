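# Shared fixture builders: all fixtures are constructed in code.

# 1D lattice with a prescribed occupancy laid out as a nodes x channels matrix
makeLattice1D <- function(occ, a = 0L) {
  lat <- createLattice(1, nrow(occ), a = a)
  latticeOccupancy(lat) <- occ
  lat
}

# 1D lattice with a single cell in the +1 channel of `node`
singleCell1D <- function(L, node, a = 0L, channel = 1L) {
  lat <- createLattice(1, L, a = a)
  occ <- latticeOccupancy(lat)
  occ[node, channel] <- 1L
  latticeOccupancy(lat) <- occ
  lat
}

# place `n` cells into the first n channels of `node`
fillNode <- function(lat, node, n) {
  occ <- latticeOccupancy(lat)
  occ[node, seq_len(n)] <- 1L
  latticeOccupancy(lat) <- occ
  lat
}

# total-variation distance between two distributions over the same outcomes
tvDistance <- function(p, q) 0.5 * sum(abs(p - q))

# map each outcome row to a string key for cross-matching permuted tables
outcomeKey <- function(m) apply(m, 1L, paste, collapse = "")

# periodic wrap of 1-based indices
wrapIndex <- function(i, L) ((i - 1L) %% L) + 1L
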
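# Internal helpers shared across modules.

# periodic wrap of 1-based indices onto 1..L
.wrap <- function(i, L) ((i - 1L) %% L) + 1L

# index of the channel opposite to velocity channel j (1 <= j <= b)
.oppositeChannel <- function(j, b) ((j - 1L + b %/% 2L) %% b) + 1L

# angle-doubled channel index used by the nematic alignment vector:
# velocity channel p contributes along c_{[2(p-1) mod b] + 1}
.nematicChannel <- function(p, b) ((2L * (p - 1L)) %% b) + 1L

# circular shift of a vector: element r of the result is x[r - k] (periodic),
# i.e. shiftVec(x, 1) moves content one site to the right
.shiftVec <- function(x, k) {
  L <- length(x)
  x[.wrap(seq_len(L) - k, L)]
}

# probabilities from unnormalised log-weights, stable at large magnitude
.softmax <- function(logw) {
  w <- exp(logw - max(logw))
  w / sum(w)
}

# stop() with a consistent condition class so callers can test error kinds
.lgcaStop <- function(kind, fmt, ...) {
  stop(structure(
    class = c(paste0("biolgca_", kind), "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
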
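# Small deterministic value generator for test spectra (keeps the global
# RNG untouched and the expected values frozen).
runif_det <- function(n, min = 0, max = 1, offset = 0) {
  x <- (sin(seq_len(n) * 12.9898 + offset) * 43758.5453) %% 1
  min + x * (max - min)
}

with_seed_test <- function(seed, expr) canopyrt:::with_seed(seed, expr)

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# 10%-90% transition width (px) of a monotone-ish edge profile, by linear
# interpolation at the first crossing of each level.
edge_transition_width <- function(prof) {
  prof <- prof / max(prof)
  crossing <- function(level) {
    idx <- which(diff(sign(prof - level)) != 0)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    i + (level - prof[i]) / (prof[i + 1] - prof[i])
  }
  abs(crossing(0.9) - crossing(0.1))
}
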
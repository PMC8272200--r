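# Shared fixtures for the synthetic bench.

# The standard wedge: broad, low-relief, laterally offset from the body —
# the scenario the removal stage is designed for.
bench_wedge <- function() {
  object_spec(rows = 28:52, cols = 2:14, relief = 50, edge_softness = 3)
}

wedge_scene <- function(seed) {
  generate_scene(scene_spec("supine", objects = list(bench_wedge()), seed = seed))
}

body_scene <- function(seed, posture = "supine") {
  generate_scene(scene_spec(posture, seed = seed))
}

# Fraction of squared-pressure energy of `raw` surviving in `cleaned`,
# restricted to `mask`.
energy_fraction <- function(cleaned, raw, mask) {
  sum(cleaned[mask]^2) / sum(raw[mask]^2)
}

# Brute-force Savitzky-Golay oracle: refit the window polynomial at every
# sample with lm-free least squares and evaluate at the window centre
# (interior) or at the off-centre position (edges). Independent of the
# convolution implementation under test.
sg_oracle <- function(x, degree, M) {
  L <- length(x)
  out <- numeric(L)
  for (i in seq_len(L)) {
    lo <- max(1, min(i - M, L - 2 * M))
    win <- lo:(lo + 2 * M)
    A <- outer(win - ((lo + lo + 2 * M) / 2), 0:degree, `^`)
    coef <- qr.solve(A, x[win])
    tt <- i - ((lo + lo + 2 * M) / 2)
    out[i] <- sum(coef * tt^(0:degree))
  }
  out
}

# A tiny labelled dataset reused by the posture unit tests (kept small; the
# acceptance suite runs the full-size benchmark).
small_posture_dataset <- function(seed = 5) {
  labelled_dataset(16, seed = seed, n_subjects = 8)
}
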
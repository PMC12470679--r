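# Small phantom configurations shared across tests; generated in code, no
# stored fixtures.

tiny_config <- function(...) {
  phantom_config(volume_shape = c(32, 32, 24), spacing_mm = c(1, 1, 1),
                 lesion_radii_mm = c(6, 5, 4), ...)
}

default_noisefree <- function(...) phantom_config(noise_sigma_hu = 0, ...)

# Analytic ellipsoid rasterization on the phantom grid, independent of the
# generator's own mask construction path.
rasterize_ellipsoid <- function(cfg) {
  d <- cfg$volume_shape; sp <- cfg$spacing_mm
  arr <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- (c(i, j, k) - 1) * sp - cfg$lesion_center_mm
    arr[i, j, k] <- sum((p / cfg$lesion_radii_mm)^2) <= 1
  }
  arr
}

# Exact binomial (two-sided) McNemar p for a 2x2 discordant split.
exact_mcnemar_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * sum(dbinom(max(b, c):n, n, 0.5)))
}
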
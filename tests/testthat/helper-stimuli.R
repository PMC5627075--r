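# shared fixtures: a reduced 10 x 10-element geometry keeps the carrier and
# element size (hence the filter physics) of the full stimulus while cutting
# pixel counts 4-fold for image-level tests
small_spec <- function(A = 8, B = 8, j = 1, parity = 0L) {
  battenberg_spec(contrast_A = A, contrast_B = B, cluster_size_j = j,
                  n_elements = 10, parity = parity)
}

small_geometry <- list(n_elements = 10)

# independent PSE oracle: invert the match-family response by dense grid +
# linear interpolation, never by the package's bisection
grid_invert_pse <- function(r_target, r_fun, lo = 0.5, hi = 50, n = 20001) {
  m <- exp(seq(log(lo), log(hi), length.out = n))
  r <- vapply(m, r_fun, 0)
  i <- which(r >= r_target)[1]
  stopifnot(!is.na(i), i > 1)
  w <- (r_target - r[i - 1]) / (r[i] - r[i - 1])
  exp((1 - w) * log(m[i - 1]) + w * log(m[i]))
}

db_ratio <- function(a, b) 20 * log10(a / b)
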
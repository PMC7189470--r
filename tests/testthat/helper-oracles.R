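## Independent oracles, kept free of the package's code paths.

## Exhaustive rank-sum null distribution: enumerate every assignment of
## ranks to group x and compute the two-sided tail probability of the
## observed rank sum.  Only valid without ties.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(seq_len(n)[combos], nrow = n1))
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

## weighted-sum grayscale oracle, one pixel at a time
gray_oracle <- function(rgb) {
  out <- matrix(NA_real_, dim(rgb)[1], dim(rgb)[2])
  for (i in seq_len(dim(rgb)[1]))
    for (j in seq_len(dim(rgb)[2]))
      out[i, j] <- sum(c(0.299, 0.587, 0.114) * rgb[i, j, ])
  out
}

## small noiseless slide set reused across tests
tiny_slide <- function(seed = 3L, ...) {
  generate_slide_set(slide_spec(noise_sd = 0, seed = seed, ...))
}
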
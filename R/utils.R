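# Small shared numerics.

# Wrap angles into (-pi, pi].
wrap_phase <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi  # map the -pi boundary (floor rounding) to +pi
  w
}

# Euclidean distance matrix between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  sqrt(d2)
}
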
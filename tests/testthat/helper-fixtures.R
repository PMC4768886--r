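# Random composition fixtures used across metric tests.
random_simplex <- function(m, P) {
  x <- matrix(rexp(m * P), m, P)
  x / rowSums(x)
}

random_counts <- function(m, P, lambda = 20) {
  th <- random_simplex(m, P)
  n <- rpois(m, lambda)
  t(vapply(seq_len(m), function(i) {
    if (n[i] == 0) integer(P) else as.integer(rmultinom(1, n[i], th[i, ]))
  }, integer(P)))
}

# Dense enumeration oracle for cardinal adjacency on an nx x ny lattice.
adjacency_oracle <- function(nx, ny) {
  co <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  m <- nrow(co)
  C <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (k in seq_len(m)) {
      if (abs(co$ix[i] - co$ix[k]) + abs(co$iy[i] - co$iy[k]) == 1) {
        C[i, k] <- 1
      }
    }
  }
  C
}
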
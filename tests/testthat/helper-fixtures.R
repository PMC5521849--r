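# Small fixed models used across the tests.

# m = 2 toy matrix: preferred sequence "AA"; "CG" has energy 1.5 + 0.7 = 2.2.
toy_em2 <- function() {
  energy_matrix(rbind(A = c(0,   0),
                      C = c(1.5, 2.0),
                      G = c(0.7, 0.7),
                      T = c(2.0, 1.0))[c("A", "C", "G", "T"), ])
}

# m = 1 matrix with energies 0, 1, 2, 3 for A, C, G, T.
toy_em1 <- function() energy_matrix(rbind(A = 0, C = 1, G = 2, T = 3))

# naive reference: enumerate an m <= 3 landscape with explicit loops,
# independent of the package's index arithmetic
naive_landscape <- function(em, mu) {
  eps <- unclass(em)
  m <- ncol(eps)
  bases <- c("A", "C", "G", "T")
  seqs <- character(0); energies <- numeric(0)
  loop <- function(prefix, e) {
    if (nchar(prefix) == m) {
      seqs <<- c(seqs, prefix)
      energies <<- c(energies, e)
    } else {
      j <- nchar(prefix) + 1L
      for (b in 1:4) loop(paste0(prefix, bases[b]), e + eps[b, j])
    }
  }
  loop("", attr(em, "offset"))
  data.frame(sequence = seqs, energy = energies,
             occupancy = 1 / (1 + exp(energies - mu)),
             stringsAsFactors = FALSE)
}
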
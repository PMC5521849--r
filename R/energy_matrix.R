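#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Construct an additive binding-energy matrix
#'
#' An energy matrix stores, for each base and each position of a binding site
#' of length `m`, its additive contribution to the free energy of binding, in
#' units of kT (lower energy = higher affinity). Matrices are kept in the
#' Berg-von Hippel zero gauge: the lowest-energy base at every position has
#' energy 0, and any per-column residue is carried in a scalar offset `E0`
#' added to every sequence energy.
#'
#' @param eps numeric 4 x m matrix of energies (kT). Rows must be the bases
#'   A, C, G, T; if rownames are present they are used to map rows, so rows
#'   may appear in any order.
#' @param offset scalar energy offset `E0` in kT, added to every sequence
#'   energy (default 0).
#' @param regauge if `TRUE` (default), columns whose minimum is not 0 are
#'   shifted to the zero gauge and the residue moved into `offset`, with a
#'   warning. If `FALSE`, a violated gauge is an error.
#'
#' @return an object of class `energy_matrix`: a 4 x m numeric matrix with
#'   rownames A,C,G,T and attribute `offset`.
#' @examples
#' em <- energy_matrix(rbind(A = c(0, 0), C = c(1.5, 2), G = c(0.7, 0.4),
#'                           T = c(2, 1)))
#' sequence_energy(em, "CG")
#' @export
energy_matrix <- function(eps, offset = 0, regauge = TRUE) {
  eps <- as.matrix(eps)
  if (nrow(eps) != 4L)
    stop("an energy matrix must have exactly 4 rows (bases A, C, G, T)")
  if (!is.null(rownames(eps))) {
    if (!setequal(rownames(eps), BASES))
      stop("energy matrix rownames must be A, C, G, T; got: ",
           paste(rownames(eps), collapse = ", "))
    eps <- eps[BASES, , drop = FALSE]
  } else {
    rownames(eps) <- BASES
  }
  storage.mode(eps) <- "double"
  if (!all(is.finite(eps))) stop("energy matrix entries must be finite")
  if (!is.finite(offset)) stop("offset must be finite")
  mins <- apply(eps, 2L, min)
  if (any(abs(mins) > 1e-9)) {
    if (!regauge)
      stop("column minima are not 0 (zero-gauge violated); ",
           "use regauge = TRUE to repair")
    warning(sprintf(
      "re-gauging energy matrix: column minima moved into offset (E0 += %g)",
      sum(mins)))
    eps <- sweep(eps, 2L, mins)
    offset <- offset + sum(mins)
  } else if (any(mins != 0)) {
    # tiny numerical residue: snap exactly to gauge without warning
    eps <- sweep(eps, 2L, mins)
    offset <- offset + sum(mins)
  }
  structure(eps, offset = as.numeric(offset), class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Binding-energy matrix (kT), m = %d, offset E0 = %g\n",
              ncol(x), attr(x, "offset")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Motif length of a model
#' @param model an `energy_matrix` or `prob_matrix`.
#' @return integer number of positions.
#' @export
motif_length <- function(model) ncol(model)

#' Generate a random binding-energy matrix
#'
#' Emulates specificity of a typical DNA-binding protein: at each position one
#' base, chosen uniformly at random, is the preferred base with energy 0; the
#' other three bases receive independent draws from a normal distribution
#' truncated to strictly positive values (draws <= 0 are redrawn), so the
#' preferred base always attains the per-column minimum required by the zero
#' gauge.
#'
#' Uses R's global RNG stream; call [set.seed()] first for reproducibility.
#'
#' @param m motif length (positive integer).
#' @param mean,sd mean and standard deviation (kT) of the untruncated normal
#'   for non-preferred energies. Defaults 2.5 and 1.0. `sd = 0` yields all
#'   non-preferred energies equal to `mean` (which must then be positive).
#' @return an [energy_matrix()] with offset 0.
#' @examples
#' set.seed(1)
#' random_energy_matrix(8)
#' @export
random_energy_matrix <- function(m, mean = 2.5, sd = 1.0) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m))
    stop("m must be a positive integer")
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("sd must be >= 0")
  if (sd == 0 && mean <= 0)
    stop("with sd = 0, mean must be positive")
  m <- as.integer(m)
  preferred <- sample.int(4L, m, replace = TRUE)
  draw <- function(n) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  eps <- matrix(0, 4L, m, dimnames = list(BASES, NULL))
  others <- draw(3L * m)
  k <- 0L
  for (j in seq_len(m)) {
    rows <- setdiff(1:4, preferred[j])
    eps[rows, j] <- others[k + 1:3]
    k <- k + 3L
  }
  energy_matrix(eps, offset = 0, regauge = FALSE)
}

## ---- sequence handling -----------------------------------------------------

#' Convert sequences to a base-index matrix
#'
#' @param seqs character vector of equal-length DNA sequences over A,C,G,T.
#' @return integer matrix, one row per sequence, entries 1..4 for A,C,G,T.
#' @keywords internal
seq_to_idx <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("sequences must be a nonempty character vector")
  n <- nchar(seqs)
  if (any(n != n[1L])) stop("sequences must all have the same length")
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  codes <- map[utf8ToInt(paste(seqs, collapse = ""))]
  if (any(codes == 0L)) stop("sequences may only contain A, C, G, T")
  matrix(codes, nrow = length(seqs), ncol = n[1L], byrow = TRUE)
}

#' @keywords internal
idx_to_seq <- function(idx) {
  chars <- matrix(BASES[idx], nrow = nrow(idx))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' @keywords internal
energy_from_idx <- function(model, idx) {
  eps <- unclass(model)
  e <- rep(attr(model, "offset"), nrow(idx))
  for (j in seq_len(ncol(idx))) e <- e + unname(eps[idx[, j], j])
  e
}

#' Total binding energy of sequences under an additive model
#'
#' The energy of a sequence is `E0 + sum_j eps(seq[j], j)` (kT): perfectly
#' additive and context-independent by construction.
#'
#' @param model an [energy_matrix()].
#' @param seqs character vector of sequences of length `motif_length(model)`.
#' @return numeric vector of energies in kT.
#' @export
sequence_energy <- function(model, seqs) {
  stopifnot(inherits(model, "energy_matrix"))
  idx <- seq_to_idx(seqs)
  if (ncol(idx) != ncol(model))
    stop(sprintf("sequence length %d does not match motif length %d",
                 ncol(idx), ncol(model)))
  energy_from_idx(model, idx)
}

## ---- occupancy -------------------------------------------------------------

#' Equilibrium occupancy of a site
#'
#' Probability that a site of energy `E` (kT) is bound by the factor at
#' chemical potential `mu` (= ln of effective free protein concentration):
#' `P = 1 / (1 + exp(E - mu))`. Strictly decreasing in `E`, strictly
#' increasing in `mu`.
#'
#' @param E energy in kT (vectorized).
#' @param mu chemical potential (dimensionless; vectorized).
#' @return occupancy in (0, 1).
#' @examples
#' occupancy(0, c(-3, 0, 3))  # 0.047, 0.5, 0.953
#' @export
occupancy <- function(E, mu) {
  if (!all(is.finite(E)) || !all(is.finite(mu)))
    stop("E and mu must be finite")
  stats::plogis(mu - E)
}

#' Binding probability after an energy perturbation
#'
#' Given a site bound with probability `p` at chemical potential `mu`, return
#' its binding probability after its energy changes by `dE` kT: the occupancy
#' formula is inverted to recover the energy, `dE` is added, and the formula
#' is re-applied. The chemical potential cancels exactly, so the result is
#' independent of `mu`; the argument is retained to mirror the physical
#' derivation.
#'
#' @param p current binding probability, strictly inside (0, 1) (vectorized).
#' @param dE energy change in kT (positive = weaker binding).
#' @param mu chemical potential (does not affect the result).
#' @return new binding probability.
#' @examples
#' mutate_probability(occupancy(0, 3), 1.69)  # 0.95 -> 0.79
#' mutate_probability(0.62, 1.69)             # -> 0.23
#' @export
mutate_probability <- function(p, dE, mu = 0) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)")
  E <- mu - log(p / (1 - p))
  occupancy(E + dE, mu)
}
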
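## Probability matrices (PWMs), log-odds scoring and information content.

#' Construct a probability matrix
#'
#' A probability matrix (the standard probabilistic model of binding
#' specificity, a PWM) gives the probability of each base at each position,
#' assumed independent across positions. Columns must each sum to 1.
#'
#' @param pm numeric 4 x m matrix of probabilities; rows A, C, G, T (mapped
#'   by rowname when present).
#' @param background per-base prior probabilities, default uniform 0.25.
#' @return an object of class `prob_matrix`.
#' @export
prob_matrix <- function(pm, background = rep(0.25, 4)) {
  pm <- as.matrix(pm)
  if (nrow(pm) != 4L) stop("a probability matrix must have 4 rows")
  if (!is.null(rownames(pm))) {
    if (!setequal(rownames(pm), BASES))
      stop("probability matrix rownames must be A, C, G, T")
    pm <- pm[BASES, , drop = FALSE]
  } else rownames(pm) <- BASES
  storage.mode(pm) <- "double"
  if (any(!is.finite(pm)) || any(pm < 0) || any(pm > 1))
    stop("probabilities must lie in [0, 1]")
  cs <- colSums(pm)
  if (any(abs(cs - 1) > 1e-12))
    stop("each column must sum to 1 (max |deviation| = ",
         format(max(abs(cs - 1))), ")")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-12)
    stop("background must be 4 probabilities summing to 1")
  names(background) <- BASES
  structure(pm, background = background, class = "prob_matrix")
}

#' @export
print.prob_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Probability matrix, m = %d\n", ncol(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Estimate a probability matrix from a site sample
#'
#' Each column is the (weighted) frequency of the four bases at that position:
#' `PM(b,j) = (pseudoweight/4 + sum_i w_i S_i(b,j)) / (pseudoweight + sum_i
#' w_i)`. Unweighted samples use `w_i = 1`. The default pseudoweight is 0:
#' samples derived from full occupancy-weighted landscapes have no empty
#' cells; raise it for sparse user data.
#'
#' @param sample a [site_sample()].
#' @param pseudoweight nonnegative total pseudocount, split evenly over the
#'   four bases (default 0).
#' @return a [prob_matrix()] with uniform background.
#' @examples
#' estimate_pm(site_sample(c("AA", "AC"), weights = c(3, 1)))
#' @export
estimate_pm <- function(sample, pseudoweight = 0) {
  stopifnot(inherits(sample, "site_sample"))
  if (pseudoweight < 0) stop("pseudoweight must be >= 0")
  idx <- sample$idx
  w <- if (is.null(sample$weights)) rep(1, nrow(idx)) else sample$weights
  if (sum(w) == 0) stop("cannot estimate a PM from all-zero weights")
  m <- ncol(idx)
  pm <- matrix(pseudoweight / 4, 4L, m, dimnames = list(BASES, NULL))
  for (j in seq_len(m)) {
    cnt <- vapply(1:4, function(b) sum(w[idx[, j] == b]), numeric(1))
    pm[, j] <- pm[, j] + cnt
  }
  pm <- sweep(pm, 2L, colSums(pm), "/")
  prob_matrix(pm)
}

#' Probability of sequences under a probability matrix
#'
#' The factorized site probability `prod_j PM(seq[j], j)`, computed in log
#' space; a zero factor yields probability 0.
#'
#' @param pm a [prob_matrix()].
#' @param seqs character vector of sequences of matching length.
#' @return numeric vector of probabilities.
#' @export
pm_sequence_probability <- function(pm, seqs) {
  stopifnot(inherits(pm, "prob_matrix"))
  idx <- seq_to_idx(seqs)
  if (ncol(idx) != ncol(pm))
    stop(sprintf("sequence length %d does not match PM length %d",
                 ncol(idx), ncol(pm)))
  exp(pm_logprob_idx(pm, idx))
}

# log site probability from a base-index matrix; -Inf where a factor is 0
pm_logprob_idx <- function(pm, idx) {
  lp <- suppressWarnings(log(unclass(pm)))  # log(0) = -Inf intended
  s <- numeric(nrow(idx))
  for (j in seq_len(ncol(idx))) s <- s + unname(lp[idx[, j], j])
  s
}

#' Log-odds weight matrix from a probability matrix
#'
#' `WM(b,j) = ln(PM(b,j) / P(b))` against the (strictly positive) background.
#' Zero-probability entries map to `-Inf`. Scoring a sequence by the sum of
#' its `WM` entries preserves the probability-matrix ranking exactly.
#'
#' @param pm a [prob_matrix()].
#' @param background optional override of the PM's background.
#' @return 4 x m numeric matrix of natural-log odds.
#' @export
log_odds <- function(pm, background = NULL) {
  stopifnot(inherits(pm, "prob_matrix"))
  bg <- if (is.null(background)) attr(pm, "background") else as.numeric(background)
  if (length(bg) != 4L || any(bg <= 0))
    stop("background must be 4 strictly positive probabilities")
  wm <- suppressWarnings(log(sweep(unclass(pm), 1L, bg, "/")))
  matrix(wm, 4L, ncol(pm), dimnames = list(BASES, NULL))
}

#' Information content of a probability matrix
#'
#' Per-column information content relative to a uniform background,
#' `IC_j = 2 + sum_b PM(b,j) log2 PM(b,j)` bits (with `0 log 0 = 0`), and its
#' mean over columns (MCIC).
#'
#' @param pm a [prob_matrix()].
#' @return list with `ic` (per-column bits, in [0, 2]) and `mcic` (mean bits).
#' @export
information_stats <- function(pm) {
  stopifnot(inherits(pm, "prob_matrix"))
  p <- unclass(pm)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  list(ic = ic, mcic = mean(ic))
}

#' Mean-centered energy-logo heights
#'
#' The energy-logo convention sets the average energy of each position to 0
#' and plots lower-energy (higher-affinity) bases upward: heights are
#' `-(eps(b,j) - mean_b eps(b,j))`, so every column sums to 0.
#'
#' @param model an [energy_matrix()].
#' @return 4 x m numeric matrix of logo heights (kT).
#' @export
energy_logo_values <- function(model) {
  stopifnot(inherits(model, "energy_matrix"))
  eps <- unclass(model)
  -sweep(eps, 2L, colMeans(eps))
}

#' Per-column Boltzmann factorization of an energy matrix
#'
#' The probability matrix obtained by treating each column independently:
#' `PM(b,j) = exp(-eps(b,j)) / sum_b' exp(-eps(b',j))`. This is the
#' low-concentration (mu -> -Inf) limit of the PM estimated from the full
#' occupancy-weighted landscape.
#'
#' @param model an [energy_matrix()].
#' @return a [prob_matrix()].
#' @export
boltzmann_pm <- function(model) {
  stopifnot(inherits(model, "energy_matrix"))
  w <- exp(-unclass(model))
  prob_matrix(sweep(w, 2L, colSums(w), "/"))
}
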
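## Exhaustive binding landscapes and site samples.

#' Enumerate the complete binding landscape of a model
#'
#' Computes energy, affinity `K = exp(-E)` and occupancy for every one of the
#' `4^m` possible binding sites at a given chemical potential. Sequences are
#' listed in canonical lexicographic order (A < C < G < T, leftmost position
#' most significant), which also fixes downstream tie-breaking.
#'
#' @param model an [energy_matrix()].
#' @param mu chemical potential (scalar).
#' @param max_m enumeration guard; refuse motifs longer than this (default 12,
#'   i.e. ~16.8M sequences) to keep the computation desk-scale.
#' @return a `binding_landscape`: a data.frame with columns `sequence`,
#'   `energy` (kT), `affinity`, `occupancy`, one row per sequence, with
#'   attributes `model`, `mu` and an internal base-index matrix.
#' @examples
#' em <- energy_matrix(rbind(A = 0, C = 1, G = 2, T = 3))
#' enumerate_landscape(em, mu = 0)$occupancy
#' @export
enumerate_landscape <- function(model, mu, max_m = 12L) {
  stopifnot(inherits(model, "energy_matrix"), is.numeric(mu), length(mu) == 1L)
  m <- ncol(model)
  if (m > max_m)
    stop(sprintf(
      "m = %d would enumerate 4^%d sequences; refusing beyond m = %d",
      m, m, max_m))
  n <- 4L^m
  idx <- all_sites_idx(m)
  energy <- energy_from_idx(model, idx)
  df <- data.frame(
    sequence = idx_to_seq(idx),
    energy = energy,
    affinity = exp(-energy),
    occupancy = occupancy(energy, mu),
    stringsAsFactors = FALSE
  )
  structure(df, model = model, mu = mu, idx = idx,
            class = c("binding_landscape", "data.frame"))
}

#' @keywords internal
all_sites_idx <- function(m) {
  n <- 4L^m
  i <- 0:(n - 1L)
  idx <- matrix(0L, n, m)
  for (j in seq_len(m)) idx[, j] <- (i %/% 4L^(m - j)) %% 4L + 1L
  idx
}

#' @export
print.binding_landscape <- function(x, ...) {
  cat(sprintf("Binding landscape: %d sites of length %d at mu = %g\n",
              nrow(x), ncol(attr(x, "model")), attr(x, "mu")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

## ---- site samples ----------------------------------------------------------

#' Construct a sample of binding sites
#'
#' A site sample is the input to probability-matrix estimation and to energy
#' regression: a set of equal-length sequences with optional nonnegative
#' per-sequence weights (absent = uniform). When built from a landscape the
#' weights are the occupancies.
#'
#' @param sequences character vector of equal-length sequences.
#' @param weights optional nonnegative numeric vector, one per sequence, not
#'   all zero. `NULL` means unweighted.
#' @return an object of class `site_sample`.
#' @export
site_sample <- function(sequences, weights = NULL) {
  idx <- seq_to_idx(sequences)
  if (!is.null(weights)) {
    if (length(weights) != length(sequences))
      stop("weights must match sequences in length")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and nonnegative")
    if (sum(weights) == 0) stop("weights must not all be zero")
  }
  structure(list(sequences = sequences, weights = weights, idx = idx),
            class = "site_sample")
}

#' @export
print.site_sample <- function(x, ...) {
  cat(sprintf("Site sample: %d sequences of length %d (%s)\n",
              length(x$sequences), ncol(x$idx),
              if (is.null(x$weights)) "unweighted" else "weighted"))
  invisible(x)
}

#' @export
length.site_sample <- function(x) length(x$sequences)

#' Convert a full landscape into a site sample
#'
#' @param landscape a `binding_landscape`.
#' @param weighted attach the occupancies as weights (default `TRUE`)?
#' @return a [site_sample()] over all `4^m` sequences.
#' @export
as_site_sample <- function(landscape, weighted = TRUE) {
  stopifnot(inherits(landscape, "binding_landscape"))
  structure(list(sequences = landscape$sequence,
                 weights = if (weighted) landscape$occupancy else NULL,
                 idx = attr(landscape, "idx")),
            class = "site_sample")
}

#' Select the top fraction of a landscape by true occupancy
#'
#' Returns the `ceiling(q * 4^m)` sequences of highest true occupancy
#' (equivalently lowest energy), ties broken by canonical sequence order, with
#' the true occupancies attached as weights. Drop the weights (set
#' `weights = NULL` or pass `weighted = FALSE`) for the unweighted variant.
#'
#' @param landscape a `binding_landscape`.
#' @param q fraction in (0, 1].
#' @param weighted attach occupancies as weights (default `TRUE`)?
#' @return a [site_sample()].
#' @examples
#' \donttest{
#' set.seed(1)
#' ls8 <- enumerate_landscape(random_energy_matrix(8), mu = 3)
#' length(top_fraction(ls8, 0.01))  # 656 sites
#' }
#' @export
top_fraction <- function(landscape, q, weighted = TRUE) {
  stopifnot(inherits(landscape, "binding_landscape"))
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  n <- nrow(landscape)
  k <- as.integer(ceiling(q * n))
  ord <- order(landscape$energy, seq_len(n))  # lowest energy first, then
                                              # canonical order breaks ties
  sel <- sort(ord[seq_len(k)])                # keep canonical order in output
  structure(list(sequences = landscape$sequence[sel],
                 weights = if (weighted) landscape$occupancy[sel] else NULL,
                 idx = attr(landscape, "idx")[sel, , drop = FALSE]),
            class = "site_sample")
}
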
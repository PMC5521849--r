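## Rank-agreement statistics between predicted and true site distributions.

#' Squared Spearman rank correlation
#'
#' Ranks both score vectors with midranks (average ranks for ties), takes the
#' Pearson correlation of the rank vectors, and squares it. The sign of the
#' underlying rho is retained in the result for diagnostics but the headline
#' statistic is `r2 = rho^2`.
#'
#' @param pred,true numeric vectors of equal length >= 2.
#' @param subset_label optional label recorded in the result.
#' @return an object of class `correlation_result`: list with `r2`, `rho`,
#'   `n`, `subset_label`.
#' @examples
#' spearman_r2(c(1, 2, 3, 5, 4), 1:5)  # rho = 0.9, r2 = 0.81
#' @export
spearman_r2 <- function(pred, true, subset_label = "all") {
  if (length(pred) != length(true))
    stop("pred and true must have equal length")
  n <- length(pred)
  if (n < 2L) stop("need at least 2 observations")
  if (any(is.na(pred)) || any(is.na(true)))
    stop("scores must not contain NA")
  rp <- rank(pred)  # midranks
  rt <- rank(true)
  if (stats::var(rp) == 0 || stats::var(rt) == 0)
    stop("rank correlation undefined: a score vector has zero rank variance ",
         "(all values tied)")
  rho <- stats::cor(rp, rt)
  structure(list(r2 = rho^2, rho = rho, n = n, subset_label = subset_label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Squared Spearman rank correlation: r2 = %.6f (rho = %+.6f), n = %d, subset = %s\n",
              x$r2, x$rho, x$n, x$subset_label))
  invisible(x)
}

#' Rank agreement between a predicted scoring and the true landscape
#'
#' Internal work-horse shared by [evaluate_pm()] and
#' [evaluate_energy_model()]: every sequence is midranked by its predicted
#' score and by its true occupancy, and the squared Pearson correlation of
#' the two rank vectors is reported, possibly restricted to a subset.
#'
#' For restricted subsets, `ranking = "global"` (the default) ranks all `4^m`
#' sites first and then restricts the global ranks to the subset, so a site
#' badly mis-ranked relative to the rest of the landscape counts in full;
#' `ranking = "within"` discards the rest of the landscape and re-ranks the
#' subset internally.
#'
#' @keywords internal
rank_agreement <- function(landscape, score, subset, q, ranking) {
  truth <- landscape$occupancy
  if (subset == "all")
    return(spearman_r2(score, truth, "all"))
  n <- nrow(landscape)
  k <- as.integer(ceiling(q * n))
  keep <- if (subset == "top")
    order(landscape$energy, seq_len(n))[seq_len(k)]
  else
    order(-score, seq_len(n))[seq_len(k)]
  label <- sprintf("%s-%g%%", sub("-top", "", subset), 100 * q)
  if (ranking == "within")
    return(spearman_r2(score[keep], truth[keep], label))
  rp <- rank(score)[keep]
  rt <- rank(truth)[keep]
  if (stats::var(rp) == 0 || stats::var(rt) == 0)
    stop("rank correlation undefined: a score vector has zero rank variance ",
         "on the selected subset")
  rho <- stats::cor(rp, rt)
  structure(list(r2 = rho^2, rho = rho, n = k, subset_label = label),
            class = "correlation_result")
}

#' Rank agreement between a probability matrix and the true landscape
#'
#' Scores each sequence by its factorized PM probability, takes the true
#' occupancy as the reference, and reports the squared Spearman correlation.
#' With `subset = "top"` the comparison is restricted to the *true* top
#' fraction of sites (highest true occupancy) -- the set of genuine interest
#' when only strong sites are functional; note the true top fraction need not
#' coincide with the PM-predicted top fraction. `subset = "predicted-top"`
#' restricts to the PM-predicted top fraction instead (diagnostic only).
#'
#' By default restricted subsets keep the *global* ranks of their sites
#' (computed over the whole landscape), so mis-placing a strong site among
#' the bulk of the landscape is penalized in full; `ranking = "within"`
#' re-ranks the subset internally instead.
#'
#' @param landscape a `binding_landscape`.
#' @param pm a [prob_matrix()] of matching length.
#' @param subset one of `"all"`, `"top"`, `"predicted-top"`.
#' @param q top fraction (default 0.01) when `subset != "all"`.
#' @param ranking `"global"` or `"within"` (see Details).
#' @return a [spearman_r2()] result.
#' @export
evaluate_pm <- function(landscape, pm, subset = c("all", "top", "predicted-top"),
                        q = 0.01, ranking = c("global", "within")) {
  stopifnot(inherits(landscape, "binding_landscape"), inherits(pm, "prob_matrix"))
  subset <- match.arg(subset)
  ranking <- match.arg(ranking)
  if (ncol(pm) != ncol(attr(landscape, "model")))
    stop("PM length does not match landscape motif length")
  score <- pm_logprob_idx(pm, attr(landscape, "idx"))
  rank_agreement(landscape, score, subset, q, ranking)
}
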
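## Replicated simulation experiments: how well do PMs estimated from
## occupancy data preserve the true rank order of binding sites?

#' Configuration for a replicated rank-correlation experiment
#'
#' Defaults match the headline simulation: 100 replicates of 8-long binding
#' sites, non-preferred energies N(2.5, 1.0) kT truncated to positive values,
#' chemical potentials -3, 0, 3 (preferred site bound at 0.05, 0.50, 0.95),
#' and a top fraction of 1%.
#'
#' @param m motif length.
#' @param mu_values chemical potentials to examine (nonempty).
#' @param replicates number of independent random matrices (>= 1).
#' @param top_q top fraction of sites used for subset PMs and for the
#'   restricted evaluation.
#' @param energy_mean,energy_sd parameters of the random-matrix generator
#'   ([random_energy_matrix()]).
#' @param base_seed integer; replicate `r` seeds R's RNG with `base_seed + r`,
#'   so every output is reproducible from the config alone.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(m = 8, mu_values = c(-3, 0, 3), replicates = 100,
                              top_q = 0.01, energy_mean = 2.5, energy_sd = 1.0,
                              base_seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (length(mu_values) == 0) stop("mu_values must be nonempty")
  structure(list(m = as.integer(m), mu_values = as.numeric(mu_values),
                 replicates = as.integer(replicates), top_q = top_q,
                 energy_mean = energy_mean, energy_sd = energy_sd,
                 base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

# The three PM estimation regimes compared throughout.
PM_METHODS <- c("all_weighted", "top_weighted", "top_unweighted")

#' Run one simulation replicate
#'
#' Draws a single random energy matrix (shared across all chemical potentials
#' within the replicate so cross-mu contrasts are paired), and for each mu:
#' enumerates the landscape, estimates three PMs (all sites weighted by
#' occupancy; true top fraction weighted; true top fraction unweighted), and
#' evaluates each on the full landscape and on the true top fraction.
#'
#' The unweighted top-fraction PM, and hence its correlations, are identical
#' across mu: the top fraction is determined by energy alone and its
#' occupancies are ignored.
#'
#' @param config an [experiment_config()].
#' @param replicate_index 1-based replicate number; the RNG is seeded with
#'   `config$base_seed + replicate_index`.
#' @return data.frame with columns `replicate`, `mu`, `pm_method`, `subset`,
#'   `r2`, `n`, `seed`.
#' @export
run_replicate <- function(config, replicate_index) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$base_seed + as.integer(replicate_index)
  set.seed(seed)
  model <- random_energy_matrix(config$m, config$energy_mean, config$energy_sd)
  rows <- vector("list", length(config$mu_values) * 6L)
  k <- 0L
  for (mu in config$mu_values) {
    ls <- enumerate_landscape(model, mu)
    pms <- list(
      all_weighted  = estimate_pm(as_site_sample(ls, weighted = TRUE)),
      top_weighted  = estimate_pm(top_fraction(ls, config$top_q, weighted = TRUE)),
      top_unweighted = estimate_pm(top_fraction(ls, config$top_q, weighted = FALSE))
    )
    for (method in PM_METHODS) {
      for (subset in c("all", "top")) {
        res <- evaluate_pm(ls, pms[[method]], subset, q = config$top_q)
        k <- k + 1L
        rows[[k]] <- data.frame(replicate = replicate_index, mu = mu,
                                pm_method = method, subset = subset,
                                r2 = res$r2, n = res$n, seed = seed,
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full replicated experiment
#'
#' Aggregates [run_replicate()] over all replicates and summarizes each
#' (mu, PM method, evaluation subset) cell by the mean and population standard
#' deviation (divisor n) of the squared Spearman correlations.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_summary` with elements `results` (per-
#'   replicate data.frame) and `summary` (per-cell data.frame with columns
#'   `mu`, `pm_method`, `subset`, `mean_r2`, `sd_r2`, `replicates`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$replicates == 1L)
    warning("a single replicate: standard deviations will be reported as 0")
  results <- do.call(rbind, lapply(seq_len(config$replicates), function(r) {
    tryCatch(run_replicate(config, r),
             error = function(e) stop(sprintf(
               "replicate %d (seed %d) failed: %s",
               r, config$base_seed + r, conditionMessage(e)), call. = FALSE))
  }))
  summary <- summarize_results(results)
  structure(list(results = results, summary = summary, config = config),
            class = "experiment_summary")
}

#' @keywords internal
summarize_results <- function(results) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- aggregate(r2 ~ mu + pm_method + subset, data = results,
                   FUN = function(x) c(mean = mean(x), sd = pop_sd(x),
                                       n = length(x)))
  out <- data.frame(mu = agg$mu, pm_method = agg$pm_method,
                    subset = agg$subset,
                    mean_r2 = agg$r2[, "mean"], sd_r2 = agg$r2[, "sd"],
                    replicates = as.integer(agg$r2[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$subset, match(out$pm_method, c(PM_METHODS,
                                               "energy_fit_all",
                                               "energy_fit_top")), out$mu), ]
}

#' @export
print.experiment_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Rank-correlation experiment: m = %d, %d replicates, mu = {%s}\n",
              x$config$m, x$config$replicates,
              paste(x$config$mu_values, collapse = ", ")))
  for (ss in unique(x$summary$subset)) {
    cat(sprintf("\nEvaluation subset: %s\n", ss))
    print(correlation_table(x, subset = ss, digits = digits))
  }
  invisible(x)
}

#' Format an experiment summary as a method-by-mu table
#'
#' One row per PM estimation method, one column per chemical potential, cells
#' `mean (sd)` rounded to `digits` decimals -- the layout of the headline
#' result tables.
#'
#' @param x an `experiment_summary`.
#' @param subset `"all"` (all-sequence ranking) or `"top"` (true top
#'   fraction).
#' @param digits rounding for display (default 3).
#' @return character matrix with method rows and mu columns.
#' @export
correlation_table <- function(x, subset = "all", digits = 3) {
  s <- x$summary[x$summary$subset == subset, ]
  mus <- sort(unique(s$mu))
  methods <- unique(s$pm_method)
  tab <- matrix("", length(methods), length(mus),
                dimnames = list(methods, paste0("mu=", mus)))
  for (i in seq_along(methods)) for (j in seq_along(mus)) {
    row <- s[s$pm_method == methods[i] & s$mu == mus[j], ]
    tab[i, j] <- sprintf("%.*f (%.*f)", digits, row$mean_r2, digits, row$sd_r2)
  }
  tab
}

#' The mutation-context worked example
#'
#' A fixed energy change `dE` produces context-dependent changes in binding
#' probability: the same mutation costs a strongly bound site a modest
#' fraction of its occupancy but a weakly bound site most of it, even though
#' the energies are perfectly additive. This apparent non-independence is an
#' artifact of working on the probability scale.
#'
#' @param p_start starting binding probability, in (0, 1).
#' @param dE energy change in kT.
#' @param mu chemical potential (cancels; kept for the physical reading).
#' @return list with `p_start`, `p_end`, `percent_decrease`
#'   (`100 (p_start - p_end) / p_start`).
#' @examples
#' mutation_context_example(occupancy(0, 3), 1.69)  # 0.95 -> 0.79, ~17%
#' mutation_context_example(0.62, 1.69)             # 0.62 -> 0.23, ~63%
#' @export
mutation_context_example <- function(p_start, dE, mu = 3) {
  p_end <- mutate_probability(p_start, dE, mu)
  list(p_start = p_start, p_end = p_end,
       percent_decrease = 100 * (p_start - p_end) / p_start)
}
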
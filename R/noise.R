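## Experimental-noise simulation and recovery of energy matrices by
## nonlinear least squares on observed occupancies.

#' Configuration for the noise experiment
#'
#' Extends [experiment_config()] with the standard deviation of the
#' per-sequence energy noise. The default 0.5 kT is deliberately larger than
#' the ~0.2 kT measurement error typical of careful binding assays.
#'
#' @inheritParams experiment_config
#' @param noise_sd standard deviation (kT) of the zero-mean Gaussian noise
#'   added independently to every sequence energy before occupancies are
#'   generated.
#' @return list of class `noise_config` (also an `experiment_config`).
#' @export
noise_config <- function(m = 8, mu_values = c(-3, 0, 3), replicates = 100,
                         top_q = 0.01, energy_mean = 2.5, energy_sd = 1.0,
                         base_seed = 1, noise_sd = 0.5) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cfg <- experiment_config(m, mu_values, replicates, top_q,
                           energy_mean, energy_sd, base_seed)
  cfg$noise_sd <- noise_sd
  class(cfg) <- c("noise_config", class(cfg))
  cfg
}

#' Landscape with noisy observed energies
#'
#' Adds independent N(0, noise_sd^2) noise to every sequence energy and
#' recomputes the occupancies from the noisy energies, emulating measurement
#' error in per-sequence binding data. The true (noise-free) energies and
#' occupancies are retained alongside for evaluation.
#'
#' Uses R's global RNG stream; seed it for reproducibility.
#'
#' @param model an [energy_matrix()].
#' @param mu chemical potential.
#' @param noise_sd noise standard deviation in kT (0 reproduces
#'   [enumerate_landscape()] exactly).
#' @param noise optional pre-drawn noise vector of length `4^m` (one draw per
#'   sequence, in canonical order); used to share one noise realization
#'   across several values of `mu`.
#' @return a `binding_landscape` with extra columns `energy_obs` and
#'   `occupancy_obs`.
#' @export
noisy_landscape <- function(model, mu, noise_sd, noise = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ls <- enumerate_landscape(model, mu)
  if (is.null(noise))
    noise <- if (noise_sd > 0) stats::rnorm(nrow(ls), 0, noise_sd) else
      numeric(nrow(ls))
  if (length(noise) != nrow(ls))
    stop("noise vector must have one entry per sequence")
  ls$energy_obs <- ls$energy + noise
  ls$occupancy_obs <- occupancy(ls$energy_obs, mu)
  ls
}

#' Fit an additive energy matrix to observed occupancies
#'
#' Recovers the free column energies of an additive model plus a scalar
#' offset `E0` from per-sequence occupancies observed at a known, fixed
#' chemical potential, by regression through the nonlinear occupancy
#' formula. One base per column (the most abundant in the weighted sample)
#' is the reference with energy 0 during fitting; the result is re-gauged to
#' zero-minimum columns with the residue absorbed into `E0`.
#'
#' Two objectives are available:
#' \describe{
#'   \item{`"energy"` (default)}{each observed occupancy is inverted through
#'     the occupancy formula to an observed energy,
#'     `E_obs = mu - ln(p/(1-p))`, and the additive model is fitted by
#'     linear least squares on the energy scale. When the measurement error
#'     is homoscedastic on energies -- the standard model for binding
#'     free-energy assays -- this is the maximum-likelihood estimator.}
#'   \item{`"probability"`}{direct least squares on the probability scale,
#'     `sum_i (p_obs_i - 1/(1 + exp(E(S_i) - mu)))^2`, solved by
#'     Levenberg-Marquardt (minpack) with an analytic Jacobian, started from
#'     the Berg-von Hippel inversion of the weighted-sample probability
#'     matrix (`eps_init(b,j) = -ln(PM(b,j)/max_b PM(b,j))`), which lies
#'     near the optimum and avoids the flat low-occupancy region. This
#'     objective downweights sites far from half-occupancy.}
#' }
#'
#' A base never observed at some position is unidentifiable from the sample;
#' its entry is pinned to a 20 kT ceiling with a warning.
#'
#' @param sample a [site_sample()] whose `weights` are the observed
#'   occupancies (the regression targets).
#' @param mu the (known, fixed) chemical potential of the observations.
#' @param objective `"energy"` or `"probability"` (see Details).
#' @param max_iter maximum optimizer iterations for the probability
#'   objective (default 1000).
#' @param ftol relative tolerance on the decrease of the objective
#'   (default 1e-12).
#' @return list of class `energy_fit`: `model` (the re-gauged
#'   [energy_matrix()]), `objective` (residual sum of squares on the fitted
#'   scale), `converged`, `iterations`, `message`.
#' @export
fit_energy_matrix <- function(sample, mu, objective = c("energy", "probability"),
                              max_iter = 1000, ftol = 1e-12) {
  stopifnot(inherits(sample, "site_sample"))
  objective <- match.arg(objective)
  p_obs <- sample$weights
  if (is.null(p_obs))
    stop("the sample must carry observed occupancies as weights")
  if (any(p_obs < 0) || any(p_obs > 1))
    stop("observed occupancies must lie in [0, 1]")
  idx <- sample$idx
  n <- nrow(idx); m <- ncol(idx)

  counts <- vapply(seq_len(m), function(j)
    vapply(1:4, function(b) sum(p_obs[idx[, j] == b]), numeric(1)),
    numeric(4))                       # 4 x m weighted base counts
  ref <- apply(counts, 2L, which.max) # reference base per column (energy 0)
  observed <- vapply(seq_len(m), function(j)
    vapply(1:4, function(b) any(idx[, j] == b), logical(1)), logical(4))

  # free parameters: non-reference, observed (b, j) entries, then E0 last
  free_list <- list()
  for (j in seq_len(m)) for (b in 1:4)
    if (b != ref[j] && observed[b, j])
      free_list[[length(free_list) + 1L]] <- c(b, j)
  nfree <- length(free_list)
  X <- matrix(0, n, nfree)
  for (k in seq_len(nfree)) {
    bj <- free_list[[k]]
    X[, k] <- as.numeric(idx[, bj[2L]] == bj[1L])
  }

  if (objective == "energy") {
    pc <- pmin(pmax(p_obs, 1e-15), 1 - 1e-15)   # guard exact 0/1 targets
    E_obs <- mu - log(pc / (1 - pc))
    sol <- stats::lm.fit(cbind(X, 1), E_obs)
    par <- sol$coefficients
    par[is.na(par)] <- 0              # rank-deficient directions (tiny n)
    rss <- sum(sol$residuals^2)
    niter <- 1L; conv <- TRUE; msg <- "linear least squares on energies"
  } else {
    # init: Berg-von Hippel inversion of the weighted-sample PM
    pm0 <- sweep(counts, 2L, colSums(counts), "/")
    eps0 <- -log(sweep(pm0, 2L, apply(pm0, 2L, max), "/"))
    eps0[!is.finite(eps0) | eps0 > 20] <- 20
    theta0 <- vapply(free_list, function(bj) eps0[bj[1L], bj[2L]], numeric(1))
    best <- which.max(p_obs)
    p_best <- min(max(p_obs[best], 1e-12), 1 - 1e-12)
    e_best <- sum(vapply(seq_len(m), function(j) eps0[idx[best, j], j],
                         numeric(1)))
    par0 <- c(theta0, (mu - log(p_best / (1 - p_best))) - e_best)

    resid_fn <- function(par) {
      E <- par[nfree + 1L] + as.vector(X %*% par[seq_len(nfree)])
      p_obs - stats::plogis(mu - E)
    }
    jac_fn <- function(par) {
      E <- par[nfree + 1L] + as.vector(X %*% par[seq_len(nfree)])
      ph <- stats::plogis(mu - E)
      cbind(X, 1) * (ph * (1 - ph))
    }
    fit <- minpack.lm::nls.lm(
      par = par0, fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1024), ftol = ftol, ptol = 1e-12, gtol = 0))
    par <- fit$par
    rss <- fit$deviance
    niter <- fit$niter
    conv <- fit$info %in% 1:4
    msg <- fit$message
  }

  eps <- matrix(0, 4L, m, dimnames = list(BASES, NULL))
  for (k in seq_len(nfree)) {
    bj <- free_list[[k]]
    eps[bj[1L], bj[2L]] <- par[k]
  }
  E0 <- par[nfree + 1L]
  pinned <- which(!observed, arr.ind = TRUE)
  if (nrow(pinned) > 0) {
    eps[cbind(pinned[, 1L], pinned[, 2L])] <- NA  # excluded from re-gauge
    warning(sprintf(
      "%d base/position combinations unobserved in the sample; pinned to 20 kT",
      nrow(pinned)))
  }
  mins <- apply(eps, 2L, min, na.rm = TRUE)  # silent re-gauge to zero-minimum
  eps <- sweep(eps, 2L, mins)
  E0 <- E0 + sum(mins)
  eps[is.na(eps)] <- 20                      # ceiling applied post-gauge
  structure(list(model = energy_matrix(eps, offset = E0, regauge = FALSE),
                 objective = rss, converged = conv,
                 iterations = niter, message = msg),
            class = "energy_fit")
}

#' @export
print.energy_fit <- function(x, ...) {
  cat(sprintf("Energy-matrix fit: RSS = %.3e after %d iterations (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$model, ...)
  invisible(x)
}

#' Rank agreement between a fitted energy model and the true landscape
#'
#' Scores every sequence by its negated fitted energy (equivalently its
#' fitted occupancy: the ranks coincide) and compares with the true
#' noise-free occupancies, optionally restricted to the true top fraction.
#'
#' @param landscape the true `binding_landscape`.
#' @param model a fitted [energy_matrix()] (or an `energy_fit`'s `$model`).
#' @param subset `"all"` or `"top"`.
#' @param q top fraction (default 0.01).
#' @param ranking `"global"` (restrict whole-landscape ranks to the subset,
#'   default) or `"within"` (re-rank the subset internally); see
#'   [evaluate_pm()].
#' @return a [spearman_r2()] result.
#' @export
evaluate_energy_model <- function(landscape, model,
                                  subset = c("all", "top"), q = 0.01,
                                  ranking = c("global", "within")) {
  stopifnot(inherits(landscape, "binding_landscape"),
            inherits(model, "energy_matrix"))
  subset <- match.arg(subset)
  ranking <- match.arg(ranking)
  score <- -energy_from_idx(model, attr(landscape, "idx"))
  rank_agreement(landscape, score, subset, q, ranking)
}

#' Run the replicated noise experiment
#'
#' Per replicate: draw a random energy matrix, add one realization of
#' per-sequence energy noise (shared across the `mu` values), and from the
#' noisy occupancies estimate the three PM regimes plus two regression-based
#' energy matrices (fitted on all sites and on the true top fraction). All
#' five models are evaluated against the TRUE noise-free landscape on the
#' full set of sites and on the true top fraction.
#'
#' @param config a [noise_config()].
#' @param ranking rank convention for the restricted subset, `"global"`
#'   (default) or `"within"`; see [evaluate_pm()].
#' @return an `experiment_summary` whose `pm_method` column additionally
#'   takes the values `energy_fit_all` and `energy_fit_top`.
#' @export
run_noise_experiment <- function(config, ranking = c("global", "within")) {
  stopifnot(inherits(config, "noise_config"))
  ranking <- match.arg(ranking)
  one <- function(r) {
    seed <- config$base_seed + as.integer(r)
    set.seed(seed)
    model <- random_energy_matrix(config$m, config$energy_mean,
                                  config$energy_sd)
    noise <- stats::rnorm(4^config$m, 0, config$noise_sd)
    rows <- list()
    for (mu in config$mu_values) {
      ls <- noisy_landscape(model, mu, config$noise_sd, noise = noise)
      n <- nrow(ls)
      k <- as.integer(ceiling(config$top_q * n))
      top <- order(ls$energy, seq_len(n))[seq_len(k)]  # TRUE top fraction
      top_idx <- attr(ls, "idx")[sort(top), , drop = FALSE]
      top_sample_w <- structure(list(sequences = ls$sequence[sort(top)],
                                     weights = ls$occupancy_obs[sort(top)],
                                     idx = top_idx), class = "site_sample")
      top_sample_u <- structure(list(sequences = top_sample_w$sequences,
                                     weights = NULL, idx = top_idx),
                                class = "site_sample")
      all_sample <- structure(list(sequences = ls$sequence,
                                   weights = ls$occupancy_obs,
                                   idx = attr(ls, "idx")),
                              class = "site_sample")
      models <- list(
        all_weighted   = estimate_pm(all_sample),
        top_weighted   = estimate_pm(top_sample_w),
        top_unweighted = estimate_pm(top_sample_u),
        energy_fit_all = fit_energy_matrix(all_sample, mu)$model,
        energy_fit_top = fit_energy_matrix(top_sample_w, mu)$model
      )
      for (method in names(models)) {
        for (subset in c("all", "top")) {
          res <- if (inherits(models[[method]], "prob_matrix"))
            evaluate_pm(ls, models[[method]], subset, q = config$top_q,
                        ranking = ranking)
          else
            evaluate_energy_model(ls, models[[method]], subset,
                                  q = config$top_q, ranking = ranking)
          rows[[length(rows) + 1L]] <-
            data.frame(replicate = r, mu = mu, pm_method = method,
                       subset = subset, r2 = res$r2, n = res$n, seed = seed,
                       stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  results <- do.call(rbind, lapply(seq_len(config$replicates), function(r) {
    tryCatch(one(r), error = function(e) stop(sprintf(
      "replicate %d (seed %d) failed: %s",
      r, config$base_seed + r, conditionMessage(e)), call. = FALSE))
  }))
  structure(list(results = results, summary = summarize_results(results),
                 config = config),
            class = "experiment_summary")
}
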
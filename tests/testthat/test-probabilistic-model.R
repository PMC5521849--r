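# Probability-matrix estimation, scoring, log-odds and information content.

test_that("PM estimation matches hand-normalized weighted counts", {
  # single sequence: point mass
  pm1 <- estimate_pm(site_sample("ACG"))
  expect_equal(unclass(pm1)[cbind(c(1, 2, 3), 1:3)], c(1, 1, 1))
  expect_equal(colSums(unclass(pm1)), rep(1, 3))

  # {"AA","AC"} with weights {3,1}: col1 all A; col2 A 0.75 / C 0.25
  pm2 <- estimate_pm(site_sample(c("AA", "AC"), weights = c(3, 1)))
  expect_equal(unclass(pm2)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(pm2)[, 2], c(A = 0.75, C = 0.25, G = 0, T = 0))

  # invariant under uniform rescaling of the weights
  pm2b <- estimate_pm(site_sample(c("AA", "AC"), weights = c(30, 10)))
  expect_equal(unclass(pm2), unclass(pm2b))

  # pseudoweight spreads mass over the four bases
  pm3 <- estimate_pm(site_sample("AA"), pseudoweight = 2)
  expect_equal(unclass(pm3)[, 1], c(A = 1.5, C = 0.5, G = 0.5, T = 0.5) / 3)

  expect_error(estimate_pm(site_sample(c("AA", "AC"), weights = c(0, 0))),
               "zero")
  expect_error(site_sample(character(0)), "nonempty")
})

test_that("full-landscape weighted PM approaches the Boltzmann columns at low concentration", {
  set.seed(11)
  em <- random_energy_matrix(6)
  ls <- enumerate_landscape(em, mu = -10)
  pm <- estimate_pm(as_site_sample(ls, weighted = TRUE))
  expect_equal(unclass(pm), unclass(boltzmann_pm(em)), tolerance = 1e-3)
})

test_that("per-column base order in the weighted PM reverses the energy order at every mu", {
  set.seed(12)
  em <- random_energy_matrix(5)
  for (mu in c(-3, 0, 3)) {
    pm <- estimate_pm(as_site_sample(enumerate_landscape(em, mu)))
    for (j in seq_len(5)) {
      expect_equal(order(unclass(pm)[, j], decreasing = TRUE),
                   order(unclass(em)[, j]))
    }
  }
})

test_that("sequence probabilities multiply column probabilities", {
  pm <- estimate_pm(site_sample(c("AA", "AC"), weights = c(3, 1)))
  expect_equal(pm_sequence_probability(pm, "AC"), 0.25)   # 1 * 0.25
  expect_equal(pm_sequence_probability(pm, "CA"), 0)      # zero factor
  u8 <- prob_matrix(matrix(0.25, 4, 8))
  expect_equal(pm_sequence_probability(u8, "ACGTACGT"), 0.25^8)
  point <- estimate_pm(site_sample("ACG"))
  expect_equal(pm_sequence_probability(point, c("ACG", "ACT")), c(1, 0))
  expect_error(pm_sequence_probability(pm, "AAA"), "length")
})

test_that("log-odds scoring preserves the PM ranking on a full landscape", {
  expect_equal(log_odds(prob_matrix(matrix(0.25, 4, 3))),
               matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  half <- prob_matrix(matrix(c(0.5, 0.25, 0.125, 0.125), 4, 1))
  expect_equal(unname(log_odds(half)[1, 1]), log(2))

  set.seed(13)
  ls <- enumerate_landscape(random_energy_matrix(3), mu = 0)
  pm <- estimate_pm(as_site_sample(ls))
  wm <- log_odds(pm)
  wm_score <- vapply(strsplit(ls$sequence, ""), function(ch)
    sum(wm[cbind(match(ch, rownames(wm)), seq_along(ch))]), numeric(1))
  p_score <- pm_sequence_probability(pm, ls$sequence)
  expect_equal(order(wm_score), order(p_score))
  expect_error(log_odds(pm, background = c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("information content and energy-logo heights follow their conventions", {
  uniform <- prob_matrix(matrix(0.25, 4, 2))
  expect_equal(information_stats(uniform)$ic, c(0, 0))
  point <- estimate_pm(site_sample("AC"))
  expect_equal(information_stats(point)$ic, c(2, 2))      # 0 log 0 handled
  mixed <- prob_matrix(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  st <- information_stats(mixed)
  expect_equal(st$ic, 1)                                   # 2 - 1 bit
  expect_equal(st$mcic, 1)

  set.seed(14)
  em <- random_energy_matrix(7)
  logo <- energy_logo_values(em)
  expect_equal(colSums(logo), rep(0, 7))                   # mean-centered
  # lower energy = taller logo letter
  expect_equal(apply(logo, 2, which.max), apply(unclass(em), 2, which.min))
})

test_that("high concentration compresses the mean column information content", {
  # over many random proteins, the PM seen at high protein concentration
  # carries less information per column than at low concentration
  set.seed(15)
  diffs <- replicate(50, {
    em <- random_energy_matrix(5)
    lo <- information_stats(estimate_pm(as_site_sample(
      enumerate_landscape(em, -3))))$mcic
    hi <- information_stats(estimate_pm(as_site_sample(
      enumerate_landscape(em, 3))))$mcic
    lo - hi
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})
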
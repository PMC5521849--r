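# Additive energy model: generation, sequence energies, occupancies.

test_that("random matrices respect the zero gauge and the generator's distribution", {
  set.seed(101)
  em <- random_energy_matrix(8)
  expect_s3_class(em, "energy_matrix")
  expect_equal(ncol(em), 8)
  mins <- apply(unclass(em), 2, min)
  expect_equal(mins, rep(0, 8))
  expect_equal(colSums(unclass(em) == 0), rep(1, 8))   # exactly one preferred base
  expect_true(all(unclass(em)[unclass(em) != 0] > 0))  # others strictly positive
  expect_equal(attr(em, "offset"), 0)

  # zero-variance generator: every non-preferred entry is exactly the mean
  set.seed(1)
  em0 <- random_energy_matrix(3, mean = 2.5, sd = 0)
  expect_equal(sort(unique(as.vector(unclass(em0)))), c(0, 2.5))

  # determinism under a fixed seed
  set.seed(7); a <- random_energy_matrix(6)
  set.seed(7); b <- random_energy_matrix(6)
  expect_identical(a, b)

  expect_error(random_energy_matrix(0), "positive integer")
  expect_error(random_energy_matrix(4, sd = -1), ">= 0")
})

test_that("non-preferred energies follow the positive-truncated normal", {
  # closed-form mean of N(2.5, 1) truncated to (0, Inf) as the oracle
  alpha <- (0 - 2.5) / 1
  trunc_mean <- 2.5 + 1 * dnorm(alpha) / (1 - pnorm(alpha))
  set.seed(202)
  draws <- replicate(500, {
    em <- random_energy_matrix(8)
    v <- as.vector(unclass(em))
    v[v > 0]
  })
  draws <- as.vector(draws)  # 500 * 24 = 12,000 draws
  expect_gt(length(draws), 10000)
  expect_equal(mean(draws), trunc_mean, tolerance = 0.01)
  expect_true(all(draws > 0))
})

test_that("sequence energies are additive sums of column contributions", {
  em <- toy_em2()
  expect_equal(sequence_energy(em, "CG"), 2.2)       # 1.5 + 0.7, hand sum
  expect_equal(sequence_energy(em, "AA"), 0)         # preferred site = E0
  # a substitution shifts the energy by the column difference, regardless of
  # the other positions
  d1 <- sequence_energy(em, "CA") - sequence_energy(em, "AA")
  d2 <- sequence_energy(em, "CG") - sequence_energy(em, "AG")
  expect_equal(d1, d2)
  expect_equal(d1, 1.5)
  # vectorized, and offset carried through
  em_off <- energy_matrix(unclass(em), offset = 1.25)
  expect_equal(sequence_energy(em_off, c("AA", "CG")), c(1.25, 3.45))
  expect_error(sequence_energy(em, "AAA"), "length")
  expect_error(sequence_energy(em, "AX"), "A, C, G, T")
})

test_that("occupancy follows the Fermi-Dirac form in E and mu", {
  expect_equal(occupancy(0, 0), 0.5)
  expect_equal(occupancy(3, 3), 0.5)                    # E = mu symmetry point
  expect_equal(occupancy(0, -3), 1 / (1 + exp(3)))      # 0.0474
  expect_equal(round(occupancy(0, c(-3, 0, 3)), 2), c(0.05, 0.50, 0.95))
  E <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(occupancy(E, 1)) < 0))           # decreasing in E
  expect_true(all(diff(occupancy(1, E)) > 0))           # increasing in mu
  expect_error(occupancy(Inf, 0), "finite")
})

test_that("mutation of binding probability is mu-invariant and matches hand values", {
  # the chemical potential cancels exactly in the invert-shift-reapply chain
  p <- c(0.01, 0.3, 0.62, 0.9526, 0.999)
  for (mu in c(-5, 0, 3, 10)) {
    expect_equal(mutate_probability(p, 1.69, mu),
                 mutate_probability(p, 1.69, 0), tolerance = 1e-12)
  }
  expect_equal(mutate_probability(0.4, 0, 2), 0.4)       # dE = 0 identity
  # closed form: p' = p / (p + (1-p) e^dE)
  expect_equal(mutate_probability(0.62, 1.69),
               0.62 / (0.62 + 0.38 * exp(1.69)), tolerance = 1e-12)
  expect_error(mutate_probability(0, 1), "strictly inside")
  expect_error(mutate_probability(1, 1), "strictly inside")
})

test_that("landscape enumeration is exhaustive, ordered, and matches a naive oracle", {
  ls1 <- enumerate_landscape(toy_em1(), mu = 0)
  expect_equal(nrow(ls1), 4)
  expect_equal(ls1$sequence, c("A", "C", "G", "T"))  # canonical order
  expect_equal(ls1$occupancy, 1 / (1 + exp((0:3) - 0)))

  set.seed(33)
  em3 <- random_energy_matrix(3)
  ls3 <- enumerate_landscape(em3, mu = 1)
  ref <- naive_landscape(em3, mu = 1)
  expect_equal(nrow(ls3), 64)
  expect_equal(ls3$sequence, ref$sequence)
  expect_equal(ls3$energy, ref$energy)
  expect_equal(ls3$occupancy, ref$occupancy)
  # expected number of bound sites agrees with the loop-based oracle
  expect_equal(sum(ls3$occupancy), sum(ref$occupancy))
  # occupancy rank equals reverse energy rank at any mu
  for (mu in c(-4, 2)) {
    lsx <- enumerate_landscape(em3, mu)
    expect_equal(order(lsx$occupancy, decreasing = TRUE), order(lsx$energy))
  }
  expect_equal(ls3$affinity, exp(-ls3$energy))
  expect_error(enumerate_landscape(random_energy_matrix(13), 0), "refusing")
})

test_that("gauge repair moves column residues into the offset", {
  raw <- rbind(A = c(0.3, 0), C = c(1, 2), G = c(0.5, 0.2), T = c(2, 1))
  expect_warning(em <- energy_matrix(raw, offset = 1), "re-gauging")
  expect_equal(apply(unclass(em), 2, min), c(0, 0))
  expect_equal(attr(em, "offset"), 1.3)
  # total sequence energies unchanged by the re-gauge
  expect_equal(sequence_energy(em, "CG"), 1 + 1 + 0.2)
  expect_error(energy_matrix(raw, regauge = FALSE), "zero-gauge")
})
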
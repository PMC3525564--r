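toy_uniform <- function() unit_cell(rep(4L, 9L), 8L)          # 9 x (4 of 8)
toy_altered <- function() unit_cell(c(rep(4L, 8L), 6L), 8L)   # one unit at 6 of 8

test_that("cell heteroplasmy is the molecule-weighted unit average", {
  expect_equal(cell_heteroplasmy(toy_uniform()), 0.5)
  expect_equal(cell_heteroplasmy(toy_altered()), 38 / 72)
  expect_equal(cell_heteroplasmy(unit_cell(rep(8L, 3L), 8L)), 1)
  expect_error(unit_cell(9, 8), "0 <= mutant_copies")
})

test_that("replication duplicates units faithfully and conserves the multiset", {
  set.seed(301)
  cell <- unit_cell(c(1L, 3L, 5L, 7L), 8L)
  for (i in 1:50) {
    ds <- replicate_and_partition_units(cell)
    got <- sort(c(ds[[1]]$k, ds[[2]]$k))
    expect_identical(got, sort(rep(cell$k, 2L)))
  }
  # homogeneous cell: any non-empty daughter has the parent's heteroplasmy
  homog <- unit_cell(rep(3L, 6L), 8L)
  ds <- replicate_and_partition_units(homog)
  for (d in ds) {
    if (!is_dead(d)) expect_equal(cell_heteroplasmy(d), 3 / 8)
  }
  # balanced split halves the duplicated pool exactly
  ds_bal <- replicate_and_partition_units(cell, split = "balanced")
  expect_identical(length(ds_bal[[1]]$k), 4L)
})

test_that("daughter unit count of a 1-unit cell is Binomial(2, 1/2)", {
  set.seed(302)
  reps <- 10000
  counts <- vapply(seq_len(reps), function(i) {
    length(replicate_and_partition_units(unit_cell(2L, 4L))[[1]]$k)
  }, integer(1))
  law <- dbinom(0:2, 2, 0.5)
  emp <- tabulate(counts + 1L, nbins = 3) / reps
  for (j in 1:3) {
    se <- sqrt(law[j] * (1 - law[j]) / reps)
    expect_lt(abs(emp[j] - law[j]), 3 * se)
  }
})

test_that("fixation probability equals initial genotype frequency", {
  fp <- fixation_probabilities(toy_altered())
  expect_equal(fp$probability[fp$load == 0.75], 1 / 9)
  expect_equal(fp$probability[fp$load == 0.50], 8 / 9)
  # the 100-unit rearrangement: 1% of cells fix at 10% load, 99% at 5%
  re <- fixation_probabilities(unit_cell(c(rep(1L, 99L), 2L), 20L))
  expect_equal(re$probability[re$load == 0.10], 0.01)
  expect_equal(re$probability[re$load == 0.05], 0.99)
  expect_equal(re$load, c(0.05, 0.10))
  # single genotype fixes with probability one
  one <- fixation_probabilities(unit_cell(rep(2L, 5L), 8L))
  expect_identical(nrow(one), 1L)
  expect_equal(one$probability, 1)
})

test_that("lineage simulation converges to the analytic fixation law", {
  set.seed(303)
  sim <- simulate_unit_lineages(toy_altered(), reps = 10000)
  emp <- sim$fixed$empirical_probability[sim$fixed$load == 0.75]
  se <- sqrt((1 / 9) * (8 / 9) / 10000)
  expect_lt(abs(emp - 1 / 9), 3 * se)
  expect_identical(sum(sim$fixed$n_fixed) + sim$n_unfixed, 10000L)
  # a single-genotype cell fixes immediately
  quick <- simulate_unit_lineages(unit_cell(rep(1L, 4L), 2L), reps = 50)
  expect_identical(quick$fixed$n_fixed, 50L)
})

test_that("small-cell fixation matches the exact Markov-chain solve", {
  set.seed(304)
  # two units, distinct genotypes: start (1, 1)
  p11 <- two_genotype_fixation_exact(1L, 1L)
  expect_equal(p11, 0.5, tolerance = 1e-3)   # martingale sanity on the oracle
  sim2 <- simulate_unit_lineages(unit_cell(c(1L, 3L), 4L), reps = 8000)
  emp2 <- sim2$fixed$empirical_probability[sim2$fixed$mutant_copies == 1L]
  expect_lt(abs(emp2 - p11), 3 * sqrt(p11 * (1 - p11) / 8000) + 1e-3)
  # three units: two of genotype A, one of B: start (2, 1)
  p21 <- two_genotype_fixation_exact(2L, 1L)
  expect_equal(p21, 2 / 3, tolerance = 2e-3)
  sim3 <- simulate_unit_lineages(unit_cell(c(1L, 1L, 3L), 4L), reps = 8000)
  emp3 <- sim3$fixed$empirical_probability[sim3$fixed$mutant_copies == 1L]
  expect_lt(abs(emp3 - p21), 3 * sqrt(p21 * (1 - p21) / 8000) + 2e-3)
})

test_that("single-unit reorganization changes only the indexed unit", {
  fig1b <- reorganize_single_unit(toy_uniform(), 1, 6)
  expect_identical(sort(fig1b$k), sort(toy_altered()$k))
  expect_identical(reorganize_single_unit(toy_uniform(), 3, 4), toy_uniform())
  # the near-homoplasmic rearrangement scenario
  re <- reorganize_single_unit(unit_cell(rep(1L, 100L), 20L), 100, 2)
  expect_identical(sum(re$k), 101L)
  expect_error(reorganize_single_unit(toy_uniform(), 10, 4), "out of range")
  expect_error(reorganize_single_unit(toy_uniform(), 1, 9), "exceeds")
})

test_that("redistribution conserves molecules and matches closed-form variance", {
  set.seed(305)
  toy <- toy_uniform()
  for (method in c("exact", "binomial")) {
    for (i in 1:25) {
      out <- redistribute_all(toy, method)
      expect_identical(sum(out$k), 36L)
      expect_identical(out$n, toy$n)
    }
  }
  reps <- 3000
  ke <- as.vector(replicate(reps, redistribute_all(toy, "exact")$k))
  kb <- as.vector(replicate(reps, redistribute_all(toy, "binomial")$k))
  # exact method: per-unit k is multivariate hypergeometric with
  # Var = n p (1-p) (T - n) / (T - 1)
  v_hyper <- 8 * 0.25 * (72 - 8) / (72 - 1)
  expect_equal(var(ke), v_hyper, tolerance = 0.05)
  expect_equal(mean(ke), 4, tolerance = 0.05)
  # binomial method spreads more than the without-replacement deal
  expect_gt(var(kb), var(ke))
  # and its unit-load frequencies track Binomial(8, 1/2)
  tv <- 0.5 * sum(abs(tabulate(kb + 1L, nbins = 9) / length(kb) -
                        dbinom(0:8, 8, 0.5)))
  expect_lt(tv, 0.03)
})

test_that("hitchhiking arithmetic reproduces the worked examples", {
  hh <- hitchhike_bulk_fraction(100, 0.1, 0)
  expect_equal(hh$max_subpopulation_fraction, 0.01)
  expect_equal(hh$bulk_minor_allele_fraction, 0.001)
  expect_equal(hitchhike_bulk_fraction(1, 0.4, 0)$max_subpopulation_fraction, 1)
  expect_equal(hitchhike_bulk_fraction(9, 0.75, 0.5)$max_subpopulation_fraction,
               1 / 9)
})

test_that("peak spacing bounds the unit copy number", {
  expect_identical(min_unit_size_from_spacing(0.05), 20L)
  expect_identical(min_unit_size_from_spacing(0.10), 10L)
  expect_identical(min_unit_size_from_spacing(1), 1L)
  expect_error(min_unit_size_from_spacing(0), "fraction")
})

test_that("single-copy units reproduce strict molecule-level drift", {
  set.seed(306)
  g <- 3L
  for (N in c(8L, 32L)) {
    cell <- unit_cell(rep(c(0L, 1L), N / 2), 1L)
    h_unit <- simulate_unit_drift(cell, g, reps = 3000)
    h_mol <- simulate_drift_lineages(0.5, N, g, 3000, "strict_doubling")$heteroplasmy
    se <- sqrt(var_se(h_unit)^2 + var_se(h_mol)^2)
    expect_lt(abs(var(h_unit) - var(h_mol)), 3 * se)
  }
})

test_that("faithful replication keeps a homogeneous cell's load forever", {
  set.seed(307)
  cell <- unit_cell(rep(4L, 9L), 8L)
  for (gen in 1:30) {
    ds <- replicate_and_partition_units(cell)
    cell <- if (!is_dead(ds[[1]])) ds[[1]] else ds[[2]]
    expect_equal(cell_heteroplasmy(cell), 0.5)
  }
})

test_that("mean heteroplasmy is preserved by redistribution", {
  set.seed(308)
  cell <- unit_cell(c(0L, 2L, 5L, 8L, 3L, 3L, 7L, 1L, 7L), 8L)
  loads <- vapply(1:2000, function(i) {
    cell_heteroplasmy(redistribute_all(cell, "exact"))
  }, numeric(1))
  expect_true(all(loads == cell_heteroplasmy(cell)))  # conservation is exact
})
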
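test_that("strict doubling is exact and replication errors are caught", {
  expect_equal(replicate_molecules(molecule_cell(3, 1), 8, "strict_doubling"),
               molecule_cell(6, 2))
  # two successive doublings through the generalised strict path
  expect_equal(replicate_molecules(molecule_cell(3, 1), 16, "strict_doubling"),
               molecule_cell(12, 4))
  expect_error(replicate_molecules(molecule_cell(0, 0), 4), "dead|extinct")
  expect_error(replicate_molecules(molecule_cell(3, 1), 2), "below")
})

test_that("homoplasmy is absorbing under both replication modes", {
  set.seed(101)
  for (mode in c("relaxed_urn", "strict_doubling")) {
    out <- replicate_molecules(molecule_cell(4, 0), 8, mode)
    expect_equal(out$mutant, 8L)
    expect_equal(out$wildtype, 0L)
  }
  # and through divisions: descendants of a homoplasmic cell stay homoplasmic
  fin <- simulate_drift_lineages(1, 50, 10, 200)
  expect_true(all(fin$heteroplasmy == 1))
  fin0 <- simulate_drift_lineages(0, 50, 10, 200)
  expect_true(all(fin0$heteroplasmy == 0))
})

test_that("relaxed-urn replication follows the exact Polya-urn law", {
  set.seed(102)
  cases <- list(c(m = 1, w = 1, target = 4), c(m = 2, w = 3, target = 10))
  for (cs in cases) {
    law <- urn_exact_law(cs["m"], cs["w"], cs["target"])
    reps <- 20000
    draws <- vapply(seq_len(reps), function(i) {
      replicate_molecules(molecule_cell(cs[["m"]], cs[["w"]]),
                          cs[["target"]], "relaxed_urn")$mutant
    }, integer(1))
    emp <- table(factor(draws, levels = names(law))) / reps
    for (lvl in names(law)) {
      se <- sqrt(law[lvl] * (1 - law[lvl]) / reps)
      expect_lt(abs(emp[lvl] - law[lvl]), 3 * se + 1e-12)
    }
  }
  # the (1,1) -> 4 case is exactly uniform over {1, 2, 3}
  expect_equal(unname(urn_exact_law(1, 1, 4)), rep(1 / 3, 3))
})

test_that("division conserves molecules and matches the enumeration law", {
  set.seed(103)
  for (i in 1:25) {
    parent <- molecule_cell(sample(0:20, 1), sample(0:20, 1))
    if (parent$mutant + parent$wildtype < 2) next
    ds <- divide_cell(parent)
    expect_identical(ds[[1]]$mutant + ds[[2]]$mutant, parent$mutant)
    expect_identical(ds[[1]]$wildtype + ds[[2]]$wildtype, parent$wildtype)
  }
  # homoplasmic parent: both daughters homoplasmic mutant regardless of split
  ds <- divide_cell(molecule_cell(8, 0))
  expect_identical(ds[[1]]$wildtype, 0L)
  expect_identical(ds[[2]]$wildtype, 0L)
  # (2, 2): all 16 assignments enumerated exactly
  law <- division_exact_law(2, 2)
  reps <- 100000
  d1 <- split_pool(rep(2L, reps), rep(2L, reps))
  emp <- table(factor(paste0(d1$mutant, "/", d1$wildtype), levels = names(law))) / reps
  for (lvl in names(law)) {
    se <- sqrt(law[lvl] * (1 - law[lvl]) / reps)
    expect_lt(abs(emp[lvl] - law[lvl]), 3 * se)
  }
})

test_that("growth to capacity preserves mean heteroplasmy (martingale)", {
  set.seed(104)
  cfg <- drift_config(0.5, 100, n_passages = 0, population_cap = 64)
  means <- vapply(1:200, function(i) {
    pop <- grow_population(molecule_cell(50, 50), 64, cfg)
    mean(pop$mutant / (pop$mutant + pop$wildtype))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * se)
})

test_that("growth handles trivial and degenerate cases", {
  set.seed(105)
  cfg <- drift_config(0.5, 10, n_passages = 0, population_cap = 2,
                      bottleneck_fraction = 0.5)
  pop <- grow_population(molecule_cell(5, 5), 2, cfg)
  expect_identical(nrow(pop), 2L)           # exactly one division occurred
  # all-homoplasmic input stays all-homoplasmic
  pop0 <- data.frame(mutant = c(10L, 10L), wildtype = c(0L, 0L))
  grown <- grow_population(pop0, 50, cfg)
  expect_true(all(grown$wildtype == 0L))
  expect_error(grow_population(pop0, 1, cfg), "capacity")
})

test_that("passaging is uniform sampling without replacement", {
  set.seed(106)
  pop <- data.frame(mutant = rep(67L, 10), wildtype = rep(33L, 10))
  out <- passage_population(pop, 0.1)
  expect_identical(nrow(out), 1L)
  expect_identical(out$mutant, 67L)
  # inclusion probability of a tagged cell is the split fraction
  tagged <- data.frame(mutant = 1:50, wildtype = rep(50L, 50))
  reps <- 2000
  hits <- vapply(seq_len(reps), function(i) {
    1L %in% passage_population(tagged, 0.1)$mutant
  }, logical(1))
  se <- sqrt(0.1 * 0.9 / reps)
  expect_lt(abs(mean(hits) - 0.1), 3 * se)
  # sampling is unbiased for the mean load
  expect_error(passage_population(tagged[1:5, ], 0.1), "no cells")
})

test_that("simulate_drift records snapshots and variance grows under drift", {
  sim <- simulate_drift(drift_config(1, 40, n_passages = 3,
                                     population_cap = 200, seed = 107))
  expect_length(sim$snapshots, 4L)
  for (s in sim$snapshots) {
    expect_length(s$heteroplasmies, 200L)
    expect_true(all(s$heteroplasmies == 1))
  }
  sim2 <- simulate_drift(drift_config(0.67, 100, n_passages = 8,
                                      population_cap = 500, seed = 108))
  sds <- summary(sim2)$sd_load
  expect_gt(sds[9], sds[2])   # SD at P8 exceeds SD at P1
  df <- as.data.frame(sim2)
  expect_identical(nrow(df), 9L * 500L)
  expect_true(all(df$heteroplasmy >= 0 & df$heteroplasmy <= 1))
})

test_that("turnover conserves copy number and accelerates drift", {
  set.seed(109)
  m <- rep(30L, 500); w <- rep(70L, 500)
  tc <- turnover_cycle(m, w, 2)
  expect_true(all(tc$mutant + tc$wildtype == 100L))
  expect_true(all(tc$mutant >= 0 & tc$wildtype >= 0))
  g <- 20
  v_plain <- var(simulate_drift_lineages(0.5, 100, g, 2000)$heteroplasmy)
  v_turn <- var(simulate_drift_lineages(0.5, 100, g, 2000,
                                        turnover_events_per_cycle = 2)$heteroplasmy)
  expect_gt(v_turn, v_plain)
})

test_that("low-copy clone drifts to majority homoplasmy with turnover", {
  set.seed(110)
  g <- effective_generations(32)
  fin <- simulate_drift_lineages(0.55, 350, g, 1500,
                                 turnover_events_per_cycle = 2)
  expect_gt(mean(fin$heteroplasmy %in% c(0, 1)), 0.5)
})

test_that("founder rounding and config validation follow the contract", {
  expect_error(drift_config(1.2, 100, 1), "fraction")
  expect_error(drift_config(0.5, 100, 1, population_cap = 5,
                            bottleneck_fraction = 0.1), ">= 1")
  # founder mutant count rounds half away from zero
  expect_identical(round_half_up(0.5 * 5), 3)
  expect_identical(round_half_up(0.67 * 1800), 1206)
  expect_identical(effective_generations(81), 269L)
  expect_identical(effective_generations(32), 106L)
})
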
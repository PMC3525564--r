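test_that("binning follows the left-closed convention with a closed top bin", {
  h <- build_histogram(rep(1, 7), bin_width = 5)
  expect_identical(h$counts[20], 7L)
  expect_identical(sum(h$counts), 7L)
  h2 <- build_histogram(c(0.50, 0.52, 0.54), bin_width = 5)
  expect_identical(h2$counts[11], 3L)       # all three in [50, 55)
  expect_identical(sum(h2$counts), h2$n_cells)
  # bin edges go left: 0.55 belongs to [55, 60)
  h3 <- build_histogram(c(0.55), bin_width = 5)
  expect_identical(h3$counts[12], 1L)
  expect_error(build_histogram(numeric(0)), "no cells")
  expect_error(build_histogram(c(0.5), bin_width = 7), "bin_width")
})

test_that("stringency filtering retains the right cells and errors when empty", {
  loads <- c(0.1, 0.5, 0.9)
  ro <- data.frame(red_dots = c(5L, 30L, 50L), green_dots = c(5L, 30L, 10L))
  h <- build_histogram(loads, ro, bin_width = 10, min_dots = 40)
  expect_identical(h$n_cells, 2L)
  expect_equal(h$retained_fraction, 2 / 3)
  expect_identical(sum(h$counts), 2L)
  expect_error(build_histogram(loads, ro, bin_width = 10, min_dots = 100),
               "stringency")
})

test_that("stringency selection implements the >30% contribution rule", {
  well <- data.frame(red_dots = rep(30L, 100), green_dots = rep(30L, 100))
  s <- select_stringency(well)
  expect_identical(s$min_dots, 40L)
  expect_identical(s$bin_width, 5)
  # 35% of cells at >=20 dots, 10% at >=40: fall back to (20, 10%)
  mixed <- data.frame(
    red_dots = c(rep(25L, 10), rep(12L, 25), rep(2L, 65)),
    green_dots = c(rep(25L, 10), rep(12L, 25), rep(2L, 65))
  )
  s2 <- select_stringency(mixed)
  expect_identical(s2$min_dots, 20L)
  expect_identical(s2$bin_width, 10)
  expect_false(s2$under_detected)
  dark <- data.frame(red_dots = rep(0L, 10), green_dots = rep(0L, 10))
  expect_true(select_stringency(dark)$under_detected)
})

test_that("peak detection flags local maxima and shoulders", {
  # unimodal histogram: exactly one peak
  h <- build_histogram(c(rep(0.52, 50), rep(0.47, 20), rep(0.57, 15),
                         runif(15, 0, 0.4)), bin_width = 5)
  ps <- detect_subpopulations(h, min_fraction = 0.1)
  expect_identical(length(ps$peak_bins), 1L)
  expect_equal(ps$peak_loads, 52.5)
  expect_true(all(ps$shoulder_loads %in% c(47.5, 57.5)))
  # flat histogram: nothing above min_fraction = 2 / nbins
  flat <- build_histogram(seq(0.025, 0.975, by = 0.05), bin_width = 5)
  expect_identical(length(detect_subpopulations(flat, 0.1)$peak_bins), 0L)
})

test_that("two planted subpopulations are recovered at both stringencies", {
  set.seed(501)
  # V_50 P52-like mixture: modes near 50-55% and 90-95%
  n <- 1000
  true <- c(rep(0.52, round(0.6 * n)), rep(0.93, n - round(0.6 * n)))
  dots <- rpois(n, 60)
  red <- rbinom(n, dots, true)
  ro <- data.frame(red_dots = red, green_dots = dots - red)
  loads <- estimate_load(ro)
  for (min_dots in c(20, 40)) {
    h <- build_histogram(loads, ro, bin_width = 5, min_dots = min_dots)
    ps <- detect_subpopulations(h, min_fraction = 0.1)
    expect_true(11L %in% ps$peak_bins)   # [50, 55)
    expect_true(19L %in% ps$peak_bins)   # [90, 95)
  }
})

test_that("mode recovery holds across seeds for >=10% mixture weights", {
  hits <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    set.seed(600 + seed)
    n <- 1000
    w <- 0.85
    true <- c(rep(0.47, round(w * n)), rep(0.92, n - round(w * n)))
    dots <- rpois(n, 60)
    red <- rbinom(n, dots, true)
    ro <- data.frame(red_dots = red, green_dots = dots - red)
    h <- build_histogram(estimate_load(ro), ro, bin_width = 5, min_dots = 20)
    ps <- detect_subpopulations(h, min_fraction = 0.05)
    ok <- any(ps$peak_bins %in% 9:10) && any(ps$peak_bins %in% 18:19)
    hits <- hits + ok
  }
  expect_gte(hits, round(0.95 * n_seeds))
})

test_that("peak spacing converts to a minimum unit copy number", {
  mk_peaks <- function(loads, spacings) {
    structure(list(peak_bins = seq_along(loads), peak_loads = loads,
                   peak_fractions = rep(0.3, length(loads)),
                   shoulder_bins = integer(0), shoulder_loads = numeric(0),
                   spacings = spacings, min_fraction = 0.1),
              class = "peak_set")
  }
  out <- peak_spacing_to_unit_size(mk_peaks(c(50, 55), 5))
  expect_equal(out$min_spacing, 5)
  expect_identical(out$min_unit_copies, 20L)
  out2 <- peak_spacing_to_unit_size(mk_peaks(c(50, 60), 10))
  expect_equal(out2$min_spacing, 10)
  expect_identical(out2$min_unit_copies, 10L)
  out3 <- peak_spacing_to_unit_size(mk_peaks(c(0, 100), 100))
  expect_equal(out3$min_spacing, 100)
  expect_identical(out3$min_unit_copies, 1L)
  expect_error(peak_spacing_to_unit_size(mk_peaks(55, numeric(0))), "two peaks")
  # end to end: two detected modes a gap apart
  set.seed(503)
  loads <- c(rep(0.52, 60), rep(0.62, 50), rep(0.57, 8), runif(20, 0, 0.4))
  h <- build_histogram(loads, bin_width = 5)
  ps <- detect_subpopulations(h, min_fraction = 0.2)
  expect_identical(length(ps$peak_bins), 2L)
  ee <- peak_spacing_to_unit_size(ps)
  expect_equal(ee$min_spacing, 10)
  expect_identical(ee$min_unit_copies, 10L)
})

test_that("distribution comparison flags excess simulated variation", {
  set.seed(502)
  # an observed distribution: stable 67% clone within the 7% measurement SD
  obs_loads <- pmin(1, pmax(0, rnorm(500, 0.67, 0.07)))
  obs <- build_histogram(obs_loads, bin_width = 5)
  ident <- compare_distributions(obs_loads, obs)
  expect_equal(ident$chisq_distance, 0, tolerance = 1e-12)
  g <- effective_generations(81)
  # random segregation at N = 1800 predicts much greater variation
  sim_low <- simulate_drift_lineages(0.67, 1800, g, 800)$heteroplasmy
  cmp_low <- compare_distributions(sim_low, obs)
  expect_identical(cmp_low$verdict, "greater variation")
  expect_gt(cmp_low$simulated$sd, 2 * cmp_low$observed$sd)
  # at N ~ 12,000 the simulated spread sits within the measurement envelope
  sim_high <- simulate_drift_lineages(0.67, 12000, g, 800)$heteroplasmy
  cmp_high <- compare_distributions(sim_high, obs)
  expect_lt(cmp_high$simulated$sd, 0.08)
  expect_lt(cmp_high$chisq_distance, cmp_low$chisq_distance)
})
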
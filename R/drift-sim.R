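#' Configuration for the molecule-level drift simulator
#'
#' Bundles the parameters of a cell-culture passaging experiment simulated at
#' the level of individual mtDNA molecules: a single founder cell is grown to
#' confluence (`population_cap` cells), then repeatedly bottlenecked to
#' `bottleneck_fraction` of the population and regrown, as in routine 1/10
#' split culture.
#'
#' @param founder_heteroplasmy Founder cell mutation load, a fraction in
#'   `[0, 1]`. The founder mutant count is `round(founder_heteroplasmy *
#'   copy_number)` with halves rounded away from zero.
#' @param copy_number Target mtDNA copies per cell (N). At each division the
#'   dividing cell is replicated to `2 * copy_number` molecules before the
#'   pool is partitioned.
#' @param n_passages Number of bottleneck-and-regrowth cycles after the first
#'   outgrowth.
#' @param population_cap Number of cells at confluence. The study system
#'   reaches about a million cells per dish; the default of 10^4 is a
#'   scaled-down cap, justified because per-cell heteroplasmy drift is
#'   dominated by within-cell sampling, not by the population size (see the
#'   package vignette).
#' @param bottleneck_fraction Fraction of cells carried over at each passage
#'   (default 0.1, the 1/10 split).
#' @param replication_mode `"relaxed_urn"` (default): molecules are added one
#'   at a time, each copied from a template drawn uniformly with replacement
#'   from the current pool (a Polya urn). `"strict_doubling"`: every molecule
#'   is copied exactly once per doubling; a non-doubling remainder is drawn
#'   without replacement.
#' @param turnover_events_per_cycle Optional intra-cycle mtDNA turnover rate:
#'   expected degradation events per molecule per cell cycle. Each molecule
#'   survives a cycle with probability `exp(-rate)`; losses are replaced by
#'   relaxed replication from the survivors, restoring copy number. Default 0
#'   (no turnover).
#' @param seed Optional integer seed applied at the start of
#'   [simulate_drift()].
#'
#' @return An object of class `drift_config`.
#' @examples
#' drift_config(0.67, 1800, n_passages = 81)
#' @export
drift_config <- function(founder_heteroplasmy,
                         copy_number,
                         n_passages,
                         population_cap = 10000,
                         bottleneck_fraction = 0.1,
                         replication_mode = c("relaxed_urn", "strict_doubling"),
                         turnover_events_per_cycle = 0,
                         seed = NULL) {
  founder_heteroplasmy <- check_fraction(founder_heteroplasmy, "founder_heteroplasmy")
  copy_number <- check_count(copy_number, "copy_number", min = 1L)
  n_passages <- check_count(n_passages, "n_passages")
  population_cap <- check_count(population_cap, "population_cap", min = 1L)
  bottleneck_fraction <- check_fraction(bottleneck_fraction, "bottleneck_fraction",
                                        open_low = TRUE, open_high = TRUE)
  if (population_cap * bottleneck_fraction < 1) {
    stop("population_cap * bottleneck_fraction must be >= 1", call. = FALSE)
  }
  replication_mode <- match.arg(replication_mode)
  if (!is.numeric(turnover_events_per_cycle) || turnover_events_per_cycle < 0) {
    stop("turnover_events_per_cycle must be >= 0", call. = FALSE)
  }
  structure(
    list(
      founder_heteroplasmy = founder_heteroplasmy,
      copy_number = copy_number,
      n_passages = n_passages,
      population_cap = population_cap,
      bottleneck_fraction = bottleneck_fraction,
      replication_mode = replication_mode,
      turnover_events_per_cycle = turnover_events_per_cycle,
      seed = seed
    ),
    class = "drift_config"
  )
}

#' @export
print.drift_config <- function(x, ...) {
  cat(sprintf(
    "<drift_config> founder %.3f, N = %d, %d passages, cap %d, split %.2g, %s%s\n",
    x$founder_heteroplasmy, x$copy_number, x$n_passages, x$population_cap,
    x$bottleneck_fraction, x$replication_mode,
    if (x$turnover_events_per_cycle > 0)
      sprintf(", turnover %.2g/cycle", x$turnover_events_per_cycle) else ""
  ))
  invisible(x)
}

#' Replicate a cell's mtDNA molecules up to a target pool size
#'
#' Templates are copied with no preference for either allele. Under
#' `"relaxed_urn"` replication, copies are added one at a time, each from a
#' template drawn uniformly (with replacement) from the current pool, so the
#' number of mutant additions follows the exact Polya-urn (beta-binomial)
#' law. Under `"strict_doubling"`, every molecule is copied exactly once per
#' doubling round (a target of twice the current total doubles both counts
#' deterministically); a remainder that is not a full doubling copies
#' templates drawn without replacement.
#'
#' @param cell A [molecule_cell()] with at least one molecule.
#' @param target_total Desired pool size, at least the current total.
#' @param mode `"relaxed_urn"` or `"strict_doubling"`.
#' @return A `molecule_cell` with `target_total` molecules.
#' @examples
#' set.seed(1)
#' replicate_molecules(molecule_cell(3, 1), 8, "strict_doubling") # exactly (6, 2)
#' replicate_molecules(molecule_cell(1, 1), 4, "relaxed_urn")
#' @export
replicate_molecules <- function(cell, target_total,
                                mode = c("relaxed_urn", "strict_doubling")) {
  stopifnot(inherits(cell, "molecule_cell"))
  mode <- match.arg(mode)
  total <- cell$mutant + cell$wildtype
  if (total < 1L) stop("cannot replicate a dead cell (extinct lineage)", call. = FALSE)
  target_total <- check_count(target_total, "target_total")
  if (target_total < total) {
    stop("target_total is below the current molecule count", call. = FALSE)
  }
  res <- replicate_pool(cell$mutant, cell$wildtype, target_total, mode)
  molecule_cell(res$mutant, res$wildtype)
}

# vectorised replication kernel shared by the population and lineage loops
replicate_pool <- function(mutant, wildtype, target_total, mode) {
  n <- length(mutant)
  target_total <- rep_len(as.integer(target_total), n)
  if (mode == "relaxed_urn") {
    add <- rbetabinom(n, target_total - (mutant + wildtype), mutant, wildtype)
    list(mutant = mutant + add, wildtype = target_total - mutant - add)
  } else {
    m <- mutant; w <- wildtype
    repeat {
      dbl <- (m + w) > 0L & (m + w) * 2L <= target_total
      if (!any(dbl)) break
      m[dbl] <- 2L * m[dbl]
      w[dbl] <- 2L * w[dbl]
    }
    j <- target_total - (m + w)
    add <- integer(n)
    pick <- j > 0L
    if (any(pick)) add[pick] <- rhyper(sum(pick), m[pick], w[pick], j[pick])
    list(mutant = m + add, wildtype = w + (j - add))
  }
}

#' Divide a cell, distributing each molecule independently to a daughter
#'
#' Every molecule is assigned to daughter 1 with probability 1/2,
#' independently of all others, so daughter totals are unequal in general but
#' always sum to the parent counts.
#'
#' @param cell A [molecule_cell()] with at least 2 molecules (a
#'   post-replication state).
#' @return A list of two `molecule_cell` daughters. A daughter that received
#'   no molecules is dead; callers detect this with [is_dead()] (the
#'   population simulator removes and counts such daughters).
#' @examples
#' set.seed(1)
#' divide_cell(replicate_molecules(molecule_cell(2, 2), 8, "strict_doubling"))
#' @export
divide_cell <- function(cell) {
  stopifnot(inherits(cell, "molecule_cell"))
  if (cell$mutant + cell$wildtype < 2L) {
    stop("cell must hold at least 2 molecules to divide", call. = FALSE)
  }
  d1 <- split_pool(cell$mutant, cell$wildtype)
  list(
    molecule_cell(d1$mutant, d1$wildtype),
    molecule_cell(cell$mutant - d1$mutant, cell$wildtype - d1$wildtype)
  )
}

as_population <- function(pop) {
  if (inherits(pop, "molecule_cell")) {
    pop <- data.frame(mutant = pop$mutant, wildtype = pop$wildtype)
  }
  stopifnot(is.data.frame(pop), all(c("mutant", "wildtype") %in% names(pop)))
  pop
}

#' Grow a cell population to a target size by asynchronous random divisions
#'
#' Repeatedly selects a live cell uniformly at random, applies one cell cycle
#' to it (optional turnover, replication of its molecules to twice the target
#' copy number, and division), and replaces it by its two daughters, until the
#' population reaches `capacity`. Growth from a 1/10 bottleneck back to
#' confluence therefore corresponds to about `log2(10)`, roughly 3.3,
#' population doublings.
#'
#' @param pop A data frame with integer columns `mutant` and `wildtype`, one
#'   row per cell (a single [molecule_cell()] is also accepted).
#' @param capacity Target population size (>= current size).
#' @param config A [drift_config()]; its `copy_number`, `replication_mode` and
#'   `turnover_events_per_cycle` drive the cell cycle.
#' @return A data frame of `capacity` rows with columns `mutant`, `wildtype`.
#'   The (typically zero) number of dead zero-molecule daughters that were
#'   discarded is attached as attribute `"n_dead"`.
#' @examples
#' set.seed(1)
#' cfg <- drift_config(0.5, 100, n_passages = 0, population_cap = 64)
#' pop <- grow_population(molecule_cell(50, 50), 64, cfg)
#' mean(pop$mutant / (pop$mutant + pop$wildtype))
#' @export
grow_population <- function(pop, capacity, config) {
  stopifnot(inherits(config, "drift_config"))
  pop <- as_population(pop)
  capacity <- check_count(capacity, "capacity", min = 1L)
  size <- nrow(pop)
  if (size < 1L) stop("population is extinct", call. = FALSE)
  if (capacity < size) stop("capacity is below the current population size", call. = FALSE)
  m <- integer(capacity); w <- integer(capacity)
  m[seq_len(size)] <- pop$mutant
  w[seq_len(size)] <- pop$wildtype
  n_dead <- 0L
  target2 <- 2L * config$copy_number
  rate <- config$turnover_events_per_cycle
  mode <- config$replication_mode
  while (size < capacity) {
    i <- if (size == 1L) 1L else sample.int(size, 1L)
    mi <- m[i]; wi <- w[i]
    if (rate > 0) {
      tc <- turnover_cycle(mi, wi, rate)
      mi <- tc$mutant; wi <- tc$wildtype
    }
    rep <- replicate_pool(mi, wi, target2, mode)
    d1 <- split_pool(rep$mutant, rep$wildtype)
    d1m <- d1$mutant; d1w <- d1$wildtype
    d2m <- rep$mutant - d1m; d2w <- rep$wildtype - d1w
    if (d1m + d1w < 1L) {               # daughter 1 dead
      n_dead <- n_dead + 1L
      m[i] <- d2m; w[i] <- d2w
    } else if (d2m + d2w < 1L) {        # daughter 2 dead
      n_dead <- n_dead + 1L
      m[i] <- d1m; w[i] <- d1w
    } else {
      m[i] <- d1m; w[i] <- d1w
      size <- size + 1L
      m[size] <- d2m; w[size] <- d2w
    }
  }
  out <- data.frame(mutant = m, wildtype = w)
  attr(out, "n_dead") <- n_dead
  out
}

#' Bottleneck a population by uniform random sampling without replacement
#'
#' Models the passaging split: `floor(fraction * n)` cells are carried over,
#' sampled uniformly without replacement.
#'
#' @param pop A population data frame (columns `mutant`, `wildtype`).
#' @param fraction Fraction of cells retained, in (0, 1).
#' @return The sampled population data frame.
#' @export
passage_population <- function(pop, fraction) {
  pop <- as_population(pop)
  fraction <- check_fraction(fraction, "fraction", open_low = TRUE, open_high = TRUE)
  keep <- floor(fraction * nrow(pop))
  if (keep < 1L) stop("bottleneck would leave no cells", call. = FALSE)
  idx <- sample.int(nrow(pop), keep)
  pop[idx, , drop = FALSE]
}

population_snapshot <- function(passage_index, mutant, total) {
  structure(
    list(
      passage_index = passage_index,
      heteroplasmies = mutant / total,
      copy_numbers = total,
      mutant = mutant
    ),
    class = "population_snapshot"
  )
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf(
    "<population_snapshot> passage %d: %d cells, mean load %.3f, SD %.3f, %.1f%% homoplasmic\n",
    x$passage_index, length(x$heteroplasmies), mean(x$heteroplasmies),
    sd(x$heteroplasmies),
    100 * mean(x$heteroplasmies == 0 | x$heteroplasmies == 1)
  ))
  invisible(x)
}

#' Simulate random mitotic mtDNA segregation through culture passages
#'
#' Starts from a single founder cell with `round(founder_heteroplasmy *
#' copy_number)` mutant molecules, grows it to `population_cap` cells (the
#' first outgrowth, recorded as passage 0), then simulates `n_passages`
#' cycles of a random `bottleneck_fraction` split followed by regrowth to the
#' cap, recording a per-cell snapshot after each regrowth.
#'
#' @param config A [drift_config()].
#' @return An object of class `drift_sim`: a list with `snapshots` (one
#'   `population_snapshot` per recorded passage, starting at passage 0),
#'   `config`, and `n_dead` (zero-molecule daughters discarded).
#'   `as.data.frame()` flattens it to a per-passage per-cell table.
#' @examples
#' sim <- simulate_drift(drift_config(0.67, 50, n_passages = 3,
#'                                    population_cap = 200, seed = 1))
#' summary(sim)
#' @export
simulate_drift <- function(config) {
  stopifnot(inherits(config, "drift_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  founder_m <- as.integer(round_half_up(config$founder_heteroplasmy * config$copy_number))
  founder <- molecule_cell(founder_m, config$copy_number - founder_m)
  if (is_dead(founder)) stop("founder cell has no molecules", call. = FALSE)
  n_dead <- 0L
  pop <- grow_population(founder, config$population_cap, config)
  n_dead <- n_dead + attr(pop, "n_dead")
  snapshots <- vector("list", config$n_passages + 1L)
  snapshots[[1L]] <- population_snapshot(0L, pop$mutant, pop$mutant + pop$wildtype)
  for (p in seq_len(config$n_passages)) {
    pop <- passage_population(pop, config$bottleneck_fraction)
    pop <- grow_population(pop, config$population_cap, config)
    n_dead <- n_dead + attr(pop, "n_dead")
    snapshots[[p + 1L]] <- population_snapshot(p, pop$mutant, pop$mutant + pop$wildtype)
  }
  structure(list(snapshots = snapshots, config = config, n_dead = n_dead),
            class = "drift_sim")
}

#' @export
print.drift_sim <- function(x, ...) {
  cat(sprintf("<drift_sim> %d snapshots (passages 0-%d), cap %d cells\n",
              length(x$snapshots), x$config$n_passages, x$config$population_cap))
  last <- x$snapshots[[length(x$snapshots)]]
  print(last)
  invisible(x)
}

#' @export
summary.drift_sim <- function(object, ...) {
  rows <- lapply(object$snapshots, function(s) {
    h <- s$heteroplasmies
    data.frame(
      passage = s$passage_index,
      n_cells = length(h),
      mean_load = mean(h),
      sd_load = sd(h),
      fraction_homoplasmic = mean(h == 0 | h == 1)
    )
  })
  do.call(rbind, rows)
}

#' @export
as.data.frame.drift_sim <- function(x, ...) {
  rows <- lapply(x$snapshots, function(s) {
    data.frame(
      passage = s$passage_index,
      cell_id = seq_along(s$heteroplasmies),
      mutant = s$mutant,
      wildtype = s$copy_numbers - s$mutant,
      heteroplasmy = s$heteroplasmies
    )
  })
  do.call(rbind, rows)
}

#' Effective cell generations in a passaging protocol
#'
#' Regrowth from a `bottleneck_fraction` split back to confluence takes about
#' `log2(1 / bottleneck_fraction)` population doublings (about 3.3 for a 1/10
#' split), so `n_passages` passages correspond to roughly `n_passages *
#' log2(1 / bottleneck_fraction)` cell generations along a lineage.
#'
#' @param n_passages Number of passages.
#' @param bottleneck_fraction Split fraction (default 0.1).
#' @return The rounded number of effective generations.
#' @examples
#' effective_generations(81) # about 269
#' @export
effective_generations <- function(n_passages, bottleneck_fraction = 0.1) {
  check_count(n_passages, "n_passages")
  check_fraction(bottleneck_fraction, "bottleneck_fraction",
                 open_low = TRUE, open_high = TRUE)
  as.integer(round_half_up(n_passages * log2(1 / bottleneck_fraction)))
}

#' Simulate single-cell lineages of the molecule-level drift model
#'
#' Follows `n_lineages` independent single-cell lineages (one random daughter
#' per division) for a fixed number of generations. This samples exactly the
#' within-cell component of heteroplasmy drift - the component that dominates
#' the per-cell load distribution in large populations - and is orders of
#' magnitude faster than the full population simulator, which makes it the
#' workhorse for copy-number scans and Monte Carlo checks.
#'
#' @param founder_heteroplasmy Founder load in `[0, 1]`.
#' @param copy_number Target copies per cell (N).
#' @param n_generations Number of cell generations to simulate.
#' @param n_lineages Number of independent lineages.
#' @param replication_mode `"relaxed_urn"` or `"strict_doubling"`.
#' @param turnover_events_per_cycle Turnover rate per molecule per cycle
#'   (see [drift_config()]).
#' @return A data frame with one row per lineage: `mutant`, `total`,
#'   `heteroplasmy` at the final generation.
#' @examples
#' set.seed(1)
#' fin <- simulate_drift_lineages(0.67, 350, 100, n_lineages = 500)
#' sd(fin$heteroplasmy)
#' @export
simulate_drift_lineages <- function(founder_heteroplasmy, copy_number,
                                    n_generations, n_lineages,
                                    replication_mode = c("relaxed_urn", "strict_doubling"),
                                    turnover_events_per_cycle = 0) {
  founder_heteroplasmy <- check_fraction(founder_heteroplasmy, "founder_heteroplasmy")
  copy_number <- check_count(copy_number, "copy_number", min = 1L)
  n_generations <- check_count(n_generations, "n_generations")
  n_lineages <- check_count(n_lineages, "n_lineages", min = 1L)
  replication_mode <- match.arg(replication_mode)
  m <- rep.int(as.integer(round_half_up(founder_heteroplasmy * copy_number)), n_lineages)
  t <- rep.int(copy_number, n_lineages)
  target2 <- 2L * copy_number
  for (gen in seq_len(n_generations)) {
    if (turnover_events_per_cycle > 0) {
      tc <- turnover_cycle(m, t - m, turnover_events_per_cycle)
      m <- tc$mutant
      t <- tc$mutant + tc$wildtype
    }
    rep <- replicate_pool(m, t - m, target2, replication_mode)
    d <- split_pool(rep$mutant, rep$wildtype, alive = TRUE)
    m <- d$mutant
    t <- d$mutant + d$wildtype
  }
  data.frame(mutant = m, total = t, heteroplasmy = m / t)
}
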
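#' Create a cell described as a collection of mtDNA segregation units
#'
#' In the metastable-segregation-unit model a cell's mtDNA is organised in
#' multi-copy units, each with a fixed mutant/wild-type composition. Units
#' replicate faithfully (daughter units are exact copies) and segregate
#' randomly at mitosis, so a cell whose units all share one composition
#' transmits its heteroplasmy level exactly to all descendants.
#'
#' @param mutant_copies Integer vector: mutant copies k per unit (0 <= k <= n).
#' @param total_copies Integer vector (or scalar, recycled): total copies n
#'   per unit (n >= 1).
#'
#' @return An object of class `unit_cell` with fields `k` and `n`.
#' @examples
#' toy <- unit_cell(rep(4, 9), 8)  # 72 molecules in 9 units of 8, half mutant
#' cell_heteroplasmy(toy)
#' @export
unit_cell <- function(mutant_copies, total_copies) {
  if (length(mutant_copies) < 1L) stop("a cell needs at least one unit", call. = FALSE)
  n <- rep_len(as.integer(total_copies), length(mutant_copies))
  k <- as.integer(mutant_copies)
  if (any(is.na(k)) || any(is.na(n)) || any(n < 1L) || any(k < 0L) || any(k > n)) {
    stop("each unit must satisfy 0 <= mutant_copies <= total_copies, total_copies >= 1",
         call. = FALSE)
  }
  structure(list(k = k, n = n), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  geno <- paste0(x$k, "/", x$n)
  tab <- sort(table(geno), decreasing = TRUE)
  cat(sprintf("<unit_cell> %d units, %d molecules, heteroplasmy %.3f\n",
              length(x$k), sum(x$n), cell_heteroplasmy(x)))
  cat("  units: ", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
is_dead.unit_cell <- function(cell) length(cell$k) < 1L

#' Aggregate heteroplasmy of a unit cell
#'
#' @param cell A [unit_cell()].
#' @return `sum(k) / sum(n)`, the cell's mutation load.
#' @examples
#' cell_heteroplasmy(unit_cell(c(rep(4, 8), 6), 8)) # 38/72
#' @export
cell_heteroplasmy <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  sum(cell$k) / sum(cell$n)
}

#' @export
heteroplasmy.unit_cell <- function(cell) cell_heteroplasmy(cell)

#' Faithfully replicate all units and partition them to two daughters
#'
#' Each unit is duplicated exactly (both copies keep the parental `(k, n)`
#' composition); the `2 U` unit copies are then distributed at random to the
#' daughters. The default `"bernoulli"` rule assigns each copy independently
#' with probability 1/2 (mirroring the per-molecule partition of the drift
#' model), so daughter unit counts are Binomial(2U, 1/2); `"balanced"` splits
#' the duplicated pool exactly in half, sampling without replacement.
#'
#' @param cell A [unit_cell()].
#' @param split `"bernoulli"` (default) or `"balanced"`.
#' @return A list of two `unit_cell` daughters. Under the Bernoulli rule a
#'   daughter may receive zero units; it is returned as a zero-unit cell that
#'   [is_dead()] reports, and population-level callers remove and count it.
#' @examples
#' set.seed(1)
#' replicate_and_partition_units(unit_cell(c(rep(4, 8), 6), 8))
#' @export
replicate_and_partition_units <- function(cell, split = c("bernoulli", "balanced")) {
  stopifnot(inherits(cell, "unit_cell"))
  split <- match.arg(split)
  k <- rep(cell$k, each = 2L)
  n <- rep(cell$n, each = 2L)
  total <- length(k)
  if (split == "bernoulli") {
    to1 <- runif(total) < 0.5
  } else {
    to1 <- logical(total)
    to1[sample.int(total, total %/% 2L)] <- TRUE
  }
  d1 <- structure(list(k = k[to1], n = n[to1]), class = "unit_cell")
  d2 <- structure(list(k = k[!to1], n = n[!to1]), class = "unit_cell")
  list(d1, d2)
}

#' Neutral fixation probabilities of the distinct unit genotypes of a cell
#'
#' Under faithful replication and random partitioning, the frequency of each
#' distinct unit composition is a martingale, so the probability that a
#' lineage eventually fixes on a given `(k, n)` genotype equals that
#' genotype's initial frequency among the cell's units, and the fixed cell's
#' heteroplasmy is the genotype's own load `k/n`. A cell with one altered
#' unit among `U` therefore founds a subpopulation of at most `1/U` of its
#' descendants fixed at the altered unit's load.
#'
#' @param cell A [unit_cell()].
#' @return A data frame with one row per distinct genotype: `mutant_copies`,
#'   `total_copies`, `load` (= k/n), `probability` (initial frequency),
#'   sorted by load.
#' @examples
#' fixation_probabilities(unit_cell(c(rep(4, 8), 6), 8)) # 8/9 at 50%, 1/9 at 75%
#' @export
fixation_probabilities <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  key <- paste(cell$k, cell$n, sep = "/")
  tab <- table(key)
  parts <- strsplit(names(tab), "/", fixed = TRUE)
  k <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  n <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  out <- data.frame(
    mutant_copies = k,
    total_copies = n,
    load = k / n,
    probability = as.vector(tab) / length(cell$k)
  )
  out[order(out$load, out$total_copies), , drop = FALSE]
}

#' Simulate unit-model lineages to fixation
#'
#' Monte Carlo counterpart of [fixation_probabilities()]: follows `reps`
#' independent single-cell lineages (one random daughter per division, dead
#' zero-unit daughters redrawn) until all units of the cell share one
#' genotype, or `max_generations` is reached. Empirical fixation frequencies
#' converge to the genotypes' initial frequencies.
#'
#' @param cell A [unit_cell()].
#' @param reps Number of lineages (>= 1).
#' @param max_generations Cap on generations per lineage (default `50 *
#'   number of units`). Lineages still segregating at the cap are reported in
#'   `n_unfixed`, not silently dropped.
#' @return A list with `fixed`: the [fixation_probabilities()] table plus
#'   columns `n_fixed` and `empirical_probability` (relative to all `reps`),
#'   and `n_unfixed`.
#' @examples
#' set.seed(1)
#' simulate_unit_lineages(unit_cell(c(rep(4, 8), 6), 8), reps = 2000)
#' @export
simulate_unit_lineages <- function(cell, reps, max_generations = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  reps <- check_count(reps, "reps", min = 1L)
  U <- length(cell$k)
  if (is.null(max_generations)) max_generations <- 50L * U
  max_generations <- check_count(max_generations, "max_generations", min = 1L)
  probs <- fixation_probabilities(cell)
  G <- nrow(probs)
  key <- paste(cell$k, cell$n, sep = "/")
  geno_key <- paste(probs$mutant_copies, probs$total_copies, sep = "/")
  # counts[r, g]: number of units of genotype g in lineage r
  counts <- matrix(rep(as.vector(table(factor(key, levels = geno_key))), each = reps),
                   nrow = reps, ncol = G)
  fixed_at <- integer(G)
  active <- seq_len(reps)
  gen <- 0L
  while (length(active) && gen < max_generations) {
    gen <- gen + 1L
    sub <- counts[active, , drop = FALSE]
    nxt <- matrix(rbinom(length(sub), 2L * sub, 0.5), nrow = nrow(sub))
    bad <- which(rowSums(nxt) < 1L)  # dead daughters: redraw (negligible at U >> 1)
    while (length(bad)) {
      subb <- sub[bad, , drop = FALSE]
      nxt[bad, ] <- rbinom(length(subb), 2L * subb, 0.5)
      bad <- bad[rowSums(nxt[bad, , drop = FALSE]) < 1L]
    }
    counts[active, ] <- nxt
    present <- nxt > 0L
    mono <- rowSums(present) == 1L
    if (any(mono)) {
      fixed_geno <- max.col(present[mono, , drop = FALSE], ties.method = "first")
      fixed_at <- fixed_at + tabulate(fixed_geno, nbins = G)
      active <- active[!mono]
    }
  }
  probs$n_fixed <- fixed_at
  probs$empirical_probability <- fixed_at / reps
  list(fixed = probs, n_unfixed = length(active))
}

#' Simulate unit-model lineages for a fixed number of generations
#'
#' Companion to [simulate_unit_lineages()] that runs the same faithful
#' replicate-and-partition dynamics for exactly `n_generations` divisions and
#' returns each lineage's final heteroplasmy, whether or not it has fixed.
#' With single-copy units (`n = 1`) this reduces to molecule-level drift with
#' strict doubling, which makes it the bridge for checking the two models
#' against each other.
#'
#' @param cell A [unit_cell()].
#' @param n_generations Number of divisions to follow.
#' @param reps Number of independent lineages.
#' @return A numeric vector of `reps` final heteroplasmy values.
#' @examples
#' set.seed(1)
#' sd(simulate_unit_drift(unit_cell(rep(c(0, 1), 8), 1), 5, reps = 500))
#' @export
simulate_unit_drift <- function(cell, n_generations, reps) {
  stopifnot(inherits(cell, "unit_cell"))
  n_generations <- check_count(n_generations, "n_generations")
  reps <- check_count(reps, "reps", min = 1L)
  probs <- fixation_probabilities(cell)
  G <- nrow(probs)
  key <- paste(cell$k, cell$n, sep = "/")
  geno_key <- paste(probs$mutant_copies, probs$total_copies, sep = "/")
  counts <- matrix(rep(as.vector(table(factor(key, levels = geno_key))), each = reps),
                   nrow = reps, ncol = G)
  for (gen in seq_len(n_generations)) {
    nxt <- matrix(rbinom(length(counts), 2L * counts, 0.5), nrow = reps)
    bad <- which(rowSums(nxt) < 1L)
    while (length(bad)) {
      subb <- counts[bad, , drop = FALSE]
      nxt[bad, ] <- rbinom(length(subb), 2L * subb, 0.5)
      bad <- bad[rowSums(nxt[bad, , drop = FALSE]) < 1L]
    }
    counts <- nxt
  }
  as.vector(counts %*% probs$mutant_copies) /
    as.vector(counts %*% probs$total_copies)
}

#' Change the composition of a single segregation unit (metastable event)
#'
#' Models the elementary metastable reorganization: one unit's mutant content
#' changes while its copy number and all other units stay intact.
#'
#' @param cell A [unit_cell()].
#' @param unit_index Index of the unit to alter.
#' @param new_mutant_copies New mutant count for that unit, in `[0, n]`.
#' @return The modified `unit_cell`.
#' @examples
#' reorganize_single_unit(unit_cell(rep(4, 9), 8), 1, 6)
#' @export
reorganize_single_unit <- function(cell, unit_index, new_mutant_copies) {
  stopifnot(inherits(cell, "unit_cell"))
  unit_index <- check_count(unit_index, "unit_index", min = 1L)
  if (unit_index > length(cell$k)) stop("unit_index out of range", call. = FALSE)
  new_mutant_copies <- check_count(new_mutant_copies, "new_mutant_copies")
  if (new_mutant_copies > cell$n[unit_index]) {
    stop("new_mutant_copies exceeds the unit's copy number", call. = FALSE)
  }
  cell$k[unit_index] <- new_mutant_copies
  cell
}

#' Randomly redistribute all of a cell's mtDNA molecules into fresh units
#'
#' Models the full-reorganization metastable event: the cell's pooled mutant
#' molecules are dealt into `U` new units. `method = "exact"` deals the pool
#' without replacement (multivariate hypergeometric; requires a uniform unit
#' size), so the total mutant count is conserved by construction.
#' `method = "binomial"` draws each unit's mutant count independently as
#' Binomial(n, pooled load) - giving the binomially distributed unit-load
#' frequencies of the model sketch - and then repairs the total back to the
#' pooled mutant count by reassigning the excess or deficit to uniformly
#' chosen units, since a real cell has a fixed molecule pool.
#'
#' @param cell A [unit_cell()].
#' @param method `"exact"` or `"binomial"`.
#' @return A new `unit_cell` with the same unit sizes and the same total
#'   mutant count.
#' @examples
#' set.seed(1)
#' redistribute_all(unit_cell(rep(4, 9), 8))
#' @export
redistribute_all <- function(cell, method = c("exact", "binomial")) {
  stopifnot(inherits(cell, "unit_cell"))
  method <- match.arg(method)
  U <- length(cell$k)
  total_k <- sum(cell$k)
  total_n <- sum(cell$n)
  if (method == "exact") {
    if (length(unique(cell$n)) != 1L) {
      stop("exact redistribution requires a uniform unit size", call. = FALSE)
    }
    n <- cell$n[1L]
    slots <- sample.int(total_n, total_k)   # which molecule slots are mutant
    k_new <- tabulate((slots - 1L) %/% n + 1L, nbins = U)
  } else {
    p <- total_k / total_n
    k_new <- rbinom(U, cell$n, p)
    diff <- total_k - sum(k_new)
    while (diff != 0L) {
      if (diff > 0L) {
        eligible <- which(k_new < cell$n)
        i <- eligible[sample.int(length(eligible), 1L)]
        k_new[i] <- k_new[i] + 1L
        diff <- diff - 1L
      } else {
        eligible <- which(k_new > 0L)
        i <- eligible[sample.int(length(eligible), 1L)]
        k_new[i] <- k_new[i] - 1L
        diff <- diff + 1L
      }
    }
  }
  unit_cell(k_new, cell$n)
}

#' Maximal subpopulation and bulk minor-allele contribution of one altered unit
#'
#' A single altered segregation unit among `U` fixes in at most `1/U` of a
#' clone's descendants (its neutral fixation probability). If the remaining
#' units are homoplasmic, the fixed subpopulation contributes a bulk
#' minor-allele fraction of `(1/U) * |special - background|`. With 100 units
#' and one unit carrying 1/10 wild type on an otherwise homoplasmic-mutant
#' background this caps the subpopulation at 1% of cells and the bulk
#' wild-type load at 0.1% - a near-homoplasmic bulk measurement despite a
#' genetically heteroplasmic founder.
#'
#' @param units_per_cell Number of segregation units U (>= 1).
#' @param special_unit_load Minor-allele load of the altered unit, in `[0,1]`.
#' @param background_load Minor-allele load of all other units (0 for a
#'   homoplasmic background).
#' @return A list with `max_subpopulation_fraction` (= 1/U) and
#'   `bulk_minor_allele_fraction`.
#' @examples
#' hitchhike_bulk_fraction(100, 0.1, 0) # 1% of cells, 0.1% bulk minor allele
#' @export
hitchhike_bulk_fraction <- function(units_per_cell, special_unit_load,
                                    background_load = 0) {
  units_per_cell <- check_count(units_per_cell, "units_per_cell", min = 1L)
  special_unit_load <- check_fraction(special_unit_load, "special_unit_load")
  background_load <- check_fraction(background_load, "background_load")
  list(
    max_subpopulation_fraction = 1 / units_per_cell,
    bulk_minor_allele_fraction =
      abs(special_unit_load - background_load) / units_per_cell
  )
}

#' Minimum unit copy number implied by a heteroplasmy peak spacing
#'
#' A segregation unit of `n` copies can only shift a fixed cell's load in
#' steps of `1/n`, so the smallest observed spacing between stable
#' heteroplasmy peaks bounds the unit size from below:
#' `n >= ceiling(1 / spacing)`. Spacings of 5-10% imply units of at least
#' 10-20 mtDNA copies.
#'
#' @param spacing Peak spacing as a fraction in (0, 1].
#' @return The minimum unit copy number, an integer.
#' @examples
#' min_unit_size_from_spacing(0.05) # 20
#' min_unit_size_from_spacing(0.10) # 10
#' @export
min_unit_size_from_spacing <- function(spacing) {
  spacing <- check_fraction(spacing, "spacing", open_low = TRUE)
  as.integer(ceiling(round(1 / spacing, 9)))
}
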
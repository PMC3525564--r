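# Internal sampling helpers. All draws go through R's global RNG so that
# set.seed() / the seed fields of config objects give full reproducibility.

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Vectorised Polya-urn additions: starting from an urn with `alpha` mutant and
# `beta` wild-type templates, add `size` copies one at a time, each copied from
# a template drawn uniformly (with replacement) from the current urn.  By
# exchangeability the number of mutant additions is exactly
# BetaBinomial(size, alpha, beta), sampled here through its beta mixture.
rbetabinom <- function(n, size, alpha, beta) {
  size <- rep_len(as.integer(size), n)
  alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n)
  out <- integer(n)
  all_mut <- alpha > 0 & beta == 0
  out[all_mut] <- size[all_mut]
  mix <- alpha > 0 & beta > 0 & size > 0
  if (any(mix)) {
    p <- rbeta(sum(mix), alpha[mix], beta[mix])
    out[mix] <- rbinom(sum(mix), size[mix], p)
  }
  out
}

# Binomial split of (mutant, wildtype) pools, conditioned on the daughter
# receiving at least one molecule when `alive` is TRUE (a zero-molecule
# daughter is dead; conditioning on survival is redrawing it).
split_pool <- function(mutant, wildtype, alive = FALSE) {
  n <- length(mutant)
  dm <- rbinom(n, mutant, 0.5)
  dw <- rbinom(n, wildtype, 0.5)
  if (alive) {
    idx <- which(dm + dw < 1L)
    while (length(idx)) {
      dm[idx] <- rbinom(length(idx), mutant[idx], 0.5)
      dw[idx] <- rbinom(length(idx), wildtype[idx], 0.5)
      idx <- idx[dm[idx] + dw[idx] < 1L]
    }
  }
  list(mutant = dm, wildtype = dw)
}

# One degradation/replication turnover cycle, vectorised over cells: each
# molecule survives with probability exp(-rate); losses are replaced by
# relaxed (urn) replication from the survivors, restoring the copy number.
turnover_cycle <- function(mutant, wildtype, rate) {
  if (rate <= 0) {
    return(list(mutant = mutant, wildtype = wildtype))
  }
  n <- length(mutant)
  surv <- exp(-rate)
  sm <- rbinom(n, mutant, surv)
  sw <- rbinom(n, wildtype, surv)
  # a cell cannot lose its whole pool to turnover: keep at least one survivor,
  # drawn in proportion to the pre-turnover composition
  idx <- which(sm + sw < 1L)
  if (length(idx)) {
    keep_mut <- rbinom(length(idx), 1L, mutant[idx] / (mutant[idx] + wildtype[idx]))
    sm[idx] <- keep_mut
    sw[idx] <- 1L - keep_mut
  }
  lost <- (mutant + wildtype) - (sm + sw)
  add <- rbetabinom(n, lost, sm, sw)
  list(mutant = sm + add, wildtype = wildtype + mutant - sm - add)
}

check_fraction <- function(x, name, open_low = FALSE, open_high = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 || (open_low && x == 0) || (open_high && x == 1)) {
    stop(sprintf("`%s` must be a fraction in %s0, 1%s", name,
                 if (open_low) "(" else "[", if (open_high) ")" else "]"),
         call. = FALSE)
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round_half_up(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
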
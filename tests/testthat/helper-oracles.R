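# Independent oracles used across the test files. These deliberately avoid
# the package's sampling code paths: exact enumeration and dynamic
# programming only.

# Exact Polya-urn law: starting from an urn with m mutant and w wild-type
# templates, add copies one at a time (uniform template, with replacement)
# until `target` molecules. Returns the probability of each final mutant
# count, named by count.
urn_exact_law <- function(m, w, target) {
  probs <- c(1)
  ms <- m
  tot <- m + w
  while (tot < target) {
    newp <- numeric(length(probs) + 1L)
    for (i in seq_along(probs)) {
      pm <- ms[i] / tot
      newp[i + 1L] <- newp[i + 1L] + probs[i] * pm
      newp[i] <- newp[i] + probs[i] * (1 - pm)
    }
    probs <- newp
    ms <- c(ms, ms[length(ms)] + 1L)
    tot <- tot + 1L
  }
  stats::setNames(probs, ms)
}

# Exact law of daughter 1 under per-molecule Bernoulli(1/2) division of a
# (m mutant, w wild-type) cell: probability of each (a, b) outcome, named
# "a/b". Enumerates all 2^(m+w) assignments via the binomial product.
division_exact_law <- function(m, w) {
  out <- c()
  for (a in 0:m) {
    for (b in 0:w) {
      p <- choose(m, a) * choose(w, b) / 2^(m + w)
      out[paste0(a, "/", b)] <- p
    }
  }
  out
}

# Exact variance of daughter-1 heteroplasmy after one strict doubling of a
# (m, w) cell followed by Bernoulli(1/2) partition, conditioned on the
# daughter being alive.
doubling_partition_exact_var <- function(m, w) {
  M <- 2L * m
  W <- 2L * w
  den <- 0; e1 <- 0; e2 <- 0
  for (a in 0:M) {
    for (b in 0:W) {
      if (a + b == 0L) next
      p <- choose(M, a) * choose(W, b) / 2^(M + W)
      h <- a / (a + b)
      den <- den + p
      e1 <- e1 + p * h
      e2 <- e2 + p * h^2
    }
  }
  e1 <- e1 / den
  e2 <- e2 / den
  e2 - e1^2
}

# Exact fixation probability of genotype A for a two-genotype unit cell
# starting from (a units of A, b units of B), under duplicate-then-
# Bernoulli(1/2) partition with dead daughters redrawn. Solves the absorbing
# Markov chain on states (a, b) truncated at total <= cap (the mass escaping
# the truncation is negligible for the small starts used in tests).
two_genotype_fixation_exact <- function(a0, b0, cap = 40L) {
  grid <- expand.grid(a = 0:cap, b = 0:cap)
  grid <- grid[grid$a + grid$b >= 1L & grid$a + grid$b <= cap, ]
  n <- nrow(grid)
  idx <- matrix(NA_integer_, cap + 1L, cap + 1L)
  idx[cbind(grid$a + 1L, grid$b + 1L)] <- seq_len(n)
  P <- matrix(0, n, n)
  for (s in seq_len(n)) {
    a <- grid$a[s]; b <- grid$b[s]
    if (a == 0L || b == 0L) { P[s, s] <- 1; next }   # absorbed
    pa <- stats::dbinom(0:(2 * a), 2 * a, 0.5)
    pb <- stats::dbinom(0:(2 * b), 2 * b, 0.5)
    for (na in 0:(2 * a)) {
      nb_max <- min(2 * b, cap - na)
      if (nb_max < 0L) next
      for (nb in 0:nb_max) {
        if (na + nb < 1L) next
        t <- idx[na + 1L, nb + 1L]
        P[s, t] <- P[s, t] + pa[na + 1L] * pb[nb + 1L]
      }
    }
    P[s, ] <- P[s, ] / sum(P[s, ])   # condition on alive and within truncation
  }
  absorbed_A <- grid$b == 0L
  transient <- !(grid$a == 0L | grid$b == 0L)
  Q <- P[transient, transient, drop = FALSE]
  R <- P[transient, absorbed_A, drop = FALSE]
  f <- solve(diag(sum(transient)) - Q, rowSums(R))
  f[match(idx[a0 + 1L, b0 + 1L], which(transient))]
}

# 3-sigma Monte Carlo band for a variance estimate, from the asymptotic
# SE(var) = sqrt((m4 - var^2) / n).
var_se <- function(x) {
  v <- stats::var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - v^2, 0) / length(x))
}
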
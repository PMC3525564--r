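#' Build a single-cell mutation-load histogram under a dot-count stringency
#'
#' Bins per-cell mutation loads (fractions in `[0, 1]`) into 5%- or 10%-wide
#' bins over 0-100%. Bins are left-closed and right-open except the final
#' bin, which is closed (`[95, 100]` for 5% bins), so fully mutant cells land
#' in the top bin. If per-cell readouts are supplied, cells whose informative
#' dot count (`red + green`) falls below `min_dots` are excluded first.
#'
#' @param loads Numeric vector of per-cell loads in `[0, 1]`.
#' @param readouts Optional data frame with columns `red_dots`, `green_dots`
#'   aligned with `loads`, used to apply the stringency filter.
#' @param bin_width Bin width in percent: 5 or 10.
#' @param min_dots Minimum informative dots per cell (>= 0).
#' @return An object of class `load_histogram`: a list with `counts` (per-bin
#'   cell counts), `breaks` and `mids` (percent), `bin_width`, `n_cells`,
#'   `min_dots`, and `retained_fraction`.
#' @examples
#' h <- build_histogram(c(0.50, 0.52, 0.54, 0.93), bin_width = 5)
#' h$counts[h$counts > 0]
#' @export
build_histogram <- function(loads, readouts = NULL, bin_width = 5, min_dots = 0) {
  if (!bin_width %in% c(5, 10)) stop("bin_width must be 5 or 10 (percent)", call. = FALSE)
  min_dots <- check_count(min_dots, "min_dots")
  n_all <- length(loads)
  if (n_all < 1L) stop("no cells supplied", call. = FALSE)
  if (any(loads < 0 | loads > 1)) stop("loads must be fractions in [0, 1]", call. = FALSE)
  if (!is.null(readouts)) {
    stopifnot(all(c("red_dots", "green_dots") %in% names(readouts)),
              nrow(readouts) == n_all)
    keep <- (readouts$red_dots + readouts$green_dots) >= min_dots
    loads <- loads[keep]
  }
  if (length(loads) < 1L) {
    stop("no cells pass the dot-count stringency", call. = FALSE)
  }
  breaks <- seq(0, 100, by = bin_width)
  nbins <- length(breaks) - 1L
  idx <- pmin(floor(loads * 100 / bin_width), nbins - 1L) + 1L
  structure(
    list(
      counts = tabulate(idx, nbins = nbins),
      breaks = breaks,
      mids = breaks[-length(breaks)] + bin_width / 2,
      bin_width = bin_width,
      n_cells = length(loads),
      min_dots = min_dots,
      retained_fraction = length(loads) / n_all
    ),
    class = "load_histogram"
  )
}

#' @export
print.load_histogram <- function(x, ...) {
  cat(sprintf(
    "<load_histogram> %d cells (%.0f%% retained at >=%d dots), %d%% bins\n",
    x$n_cells, 100 * x$retained_fraction, x$min_dots, x$bin_width))
  nz <- which(x$counts > 0)
  for (i in nz) {
    cat(sprintf("  [%3d,%3d%s %5d  %s\n", x$breaks[i], x$breaks[i + 1L],
                if (i == length(x$counts)) "]" else ")", x$counts[i],
                strrep("#", round(40 * x$counts[i] / max(x$counts)))))
  }
  invisible(x)
}

#' Choose the dots-per-cell stringency and bin width for a sample
#'
#' To keep sampling error acceptable, more than 30% of a sample's cells must
#' contribute to the histogram. If more than 30% of cells have at least 40
#' informative dots, the preferred stringency (>= 40 dots, 5% bins) is used;
#' otherwise, if more than 30% have at least 20 dots, the fallback (>= 20
#' dots, 10% bins) applies; otherwise the sample is flagged as
#' under-detected.
#'
#' @param readouts Data frame with columns `red_dots`, `green_dots`.
#' @return A list with `min_dots`, `bin_width`, `under_detected` (flag),
#'   and `fraction_ge_40` / `fraction_ge_20`.
#' @examples
#' select_stringency(data.frame(red_dots = rep(30, 10), green_dots = rep(30, 10)))
#' @export
select_stringency <- function(readouts) {
  stopifnot(all(c("red_dots", "green_dots") %in% names(readouts)),
            nrow(readouts) >= 1L)
  dots <- readouts$red_dots + readouts$green_dots
  f40 <- mean(dots >= 40)
  f20 <- mean(dots >= 20)
  if (f40 > 0.3) {
    list(min_dots = 40L, bin_width = 5, under_detected = FALSE,
         fraction_ge_40 = f40, fraction_ge_20 = f20)
  } else if (f20 > 0.3) {
    list(min_dots = 20L, bin_width = 10, under_detected = FALSE,
         fraction_ge_40 = f40, fraction_ge_20 = f20)
  } else {
    list(min_dots = NA_integer_, bin_width = NA_real_, under_detected = TRUE,
         fraction_ge_40 = f40, fraction_ge_20 = f20)
  }
}

#' Detect subpopulation peaks (and shoulders) in a load histogram
#'
#' A peak is a bin that is a strict local maximum of the bin frequencies
#' (greater than both neighbours; plateaus are resolved to their leftmost
#' bin; edge bins are compared to their single neighbour) with frequency at
#' least `min_fraction`. Bins exceeding `min_fraction` that adjoin a peak
#' without being one are reported separately as shoulders. This makes the
#' by-eye identification of subpopulations and distribution shoulders a
#' reproducible rule.
#'
#' @param hist A [build_histogram()] result.
#' @param min_fraction Minimum bin frequency for a peak, in (0, 1); default
#'   0.1.
#' @return An object of class `peak_set`: a list with `peak_bins` (indices),
#'   `peak_loads` (bin midpoints, percent), `peak_fractions`,
#'   `shoulder_bins`, `shoulder_loads`, and `spacings` (consecutive peak
#'   distances in percent).
#' @examples
#' h <- build_histogram(c(rep(0.52, 60), rep(0.93, 35), 0.2, 0.3, 0.7))
#' detect_subpopulations(h)
#' @export
detect_subpopulations <- function(hist, min_fraction = 0.1) {
  stopifnot(inherits(hist, "load_histogram"))
  min_fraction <- check_fraction(min_fraction, "min_fraction",
                                 open_low = TRUE, open_high = TRUE)
  f <- hist$counts / hist$n_cells
  nb <- length(f)
  # strict local maximum over neighbouring distinct values; plateaus are
  # resolved to their leftmost bin
  is_peak <- logical(nb)
  i <- 1L
  while (i <= nb) {
    j <- i
    while (j < nb && f[j + 1L] == f[i]) j <- j + 1L   # plateau [i, j]
    lval <- if (i == 1L) -Inf else f[i - 1L]
    rval <- if (j == nb) -Inf else f[j + 1L]
    if (f[i] > lval && f[i] > rval && f[i] >= min_fraction) is_peak[i] <- TRUE
    i <- j + 1L
  }
  peak_bins <- which(is_peak)
  shoulder <- which(!is_peak & f >= min_fraction &
                      (c(FALSE, is_peak[-nb]) | c(is_peak[-1L], FALSE)))
  loads <- hist$mids[peak_bins]
  structure(
    list(
      peak_bins = peak_bins,
      peak_loads = loads,
      peak_fractions = f[peak_bins],
      shoulder_bins = shoulder,
      shoulder_loads = hist$mids[shoulder],
      spacings = if (length(loads) >= 2L) diff(loads) else numeric(0),
      min_fraction = min_fraction
    ),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s) at %s%% load",
              length(x$peak_bins),
              paste(format(x$peak_loads), collapse = ", ")))
  if (length(x$shoulder_bins)) {
    cat(sprintf("; shoulder(s) at %s%%",
                paste(format(x$shoulder_loads), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Infer the minimum segregation-unit size from peak spacing
#'
#' The closest spacing between detected heteroplasmy peaks bounds the
#' segregation-unit copy number from below via
#' [min_unit_size_from_spacing()]: peaks 5% apart imply units of at least 20
#' copies, peaks 10% apart at least 10.
#'
#' @param peaks A `peak_set` from [detect_subpopulations()] with at least two
#'   peaks.
#' @return A list with `min_spacing` (percent) and `min_unit_copies`.
#' @export
peak_spacing_to_unit_size <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$peak_bins) < 2L) {
    stop("need at least two peaks to measure a spacing", call. = FALSE)
  }
  min_spacing <- min(peaks$spacings)
  list(
    min_spacing = min_spacing,
    min_unit_copies = min_unit_size_from_spacing(min_spacing / 100)
  )
}

#' Compare a simulated load distribution with an observed histogram
#'
#' Summarises both distributions (mean, SD, fraction of homoplasmic cells)
#' and computes a chi-square distance between them on the observed
#' histogram's bins. For simulated cells, homoplasmy means literally 0 or
#' 100% of molecules; for the observed (dot-based) histogram, the extreme
#' bins contain "apparently homoplasmic" cells - cells showing only one
#' colour - and the two notions are reported separately, not conflated. The
#' verdict is `"greater variation"` when the simulation's SD exceeds the
#' observed SD, reproducing the diagnostic by which random molecule-level
#' segregation is rejected for a stably heteroplasmic clone.
#'
#' @param simulated A `population_snapshot` (from [simulate_drift()]) or a
#'   numeric vector of simulated per-cell loads in `[0, 1]`.
#' @param observed_hist A [build_histogram()] result.
#' @return An object of class `distribution_comparison`: a list with
#'   `simulated` and `observed` summaries, `chisq_distance`, and `verdict`.
#' @export
compare_distributions <- function(simulated, observed_hist) {
  stopifnot(inherits(observed_hist, "load_histogram"))
  loads <- if (inherits(simulated, "population_snapshot")) {
    simulated$heteroplasmies
  } else {
    as.numeric(simulated)
  }
  if (length(loads) < 1L) stop("simulated distribution is empty", call. = FALSE)
  sim_hist <- build_histogram(loads, bin_width = observed_hist$bin_width)
  f_sim <- sim_hist$counts / sim_hist$n_cells
  f_obs <- observed_hist$counts / observed_hist$n_cells
  nz <- (f_sim + f_obs) > 0
  chisq <- 0.5 * sum((f_sim[nz] - f_obs[nz])^2 / (f_sim[nz] + f_obs[nz]))
  obs_mean <- sum(f_obs * observed_hist$mids) / 100
  obs_sd <- sqrt(max(0, sum(f_obs * (observed_hist$mids / 100 - obs_mean)^2)))
  extreme <- c(1L, length(f_obs))
  out <- list(
    simulated = list(
      mean = mean(loads), sd = sd(loads),
      fraction_homoplasmic = mean(loads == 0 | loads == 1),
      n = length(loads)
    ),
    observed = list(
      mean = obs_mean, sd = obs_sd,
      fraction_extreme_bins = sum(f_obs[extreme]),
      n = observed_hist$n_cells
    ),
    chisq_distance = chisq,
    verdict = if (sd(loads) > obs_sd) "greater variation" else "comparable variation"
  )
  class(out) <- "distribution_comparison"
  out
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf(
    "<distribution_comparison> simulated mean %.3f SD %.3f (%.1f%% homoplasmic) vs observed mean %.3f SD %.3f\n  chi-square distance %.4f: %s\n",
    x$simulated$mean, x$simulated$sd, 100 * x$simulated$fraction_homoplasmic,
    x$observed$mean, x$observed$sd, x$chisq_distance, x$verdict))
  invisible(x)
}
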
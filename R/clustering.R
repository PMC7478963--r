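# Subclone number / purity estimation: Gaussian KDE over pooled candidate
# prevalences, peak enumeration on a fine grid with Nelder-Mead refinement.

#' Select the prevalence values used for clustering
#'
#' Copy-number-free loci give a single unambiguous prevalence per SNV, so
#' when enough of them are available (strictly more than `threshold`
#' distinct SNVs) only those values are used to estimate the subclone
#' structure. Otherwise every scenario of every SNV gets a vote — except
#' candidates from multistate segments, whose subclone mixture makes the
#' inversion unreliable (they are still assigned to subclones later).
#'
#' @param candidates candidate table from [enumerate_candidates()].
#' @param threshold the no-CNA SNV count above which only no-CNA SNVs vote
#'   (default 100, strict `>`).
#' @return numeric vector of prevalence values.
#' @export
select_clustering_input <- function(candidates, threshold = 100) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no usable SNVs")
  }
  no_cna <- candidates$scenario %in% c("no_cna", "male_no_cna")
  n_free <- length(unique(candidates$snv_id[no_cna]))
  vals <- if (n_free > threshold) {
    candidates$rho[no_cna]
  } else {
    candidates$rho[!candidates$multistate]
  }
  if (length(vals) == 0) stop("no usable SNVs")
  vals
}

#' Scott's rule bandwidth factor
#'
#' The dimension-dependent factor `n^(-1/(d+4))` of Scott's rule for kernel
#' density bandwidth selection. For single-sample prevalence data `d = 1`.
#' The full rule scales this factor by the dispersion of the data; the
#' fitting pipeline multiplies by the sample standard deviation of the
#' prevalence values.
#'
#' @param n number of data points (must be at least 1).
#' @param d dimensionality (number of samples; default 1).
#' @return the bandwidth factor.
#' @examples
#' scott_bandwidth(100)   # 100^(-1/5) = 0.3981...
#' @export
scott_bandwidth <- function(n, d = 1) {
  if (n < 1) stop("n must be at least 1")
  n^(-1 / (d + 4))
}

#' Gaussian kernel density over prevalence values
#'
#' Returns the density function
#' `f(x) = 1/(n*Z) * sum_j exp(-((x - x_j)/h)^2)` with `Z = h*sqrt(pi)`, so
#' that `f` integrates to 1 over the real line. (The kernel has standard
#' deviation `h/sqrt(2)`.)
#'
#' @param values numeric vector of prevalence values.
#' @param h bandwidth, positive.
#' @return a vectorised function of `x`.
#' @export
kde_density <- function(values, h) {
  if (length(values) == 0) stop("values must be non-empty")
  if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  values <- as.numeric(values)
  n <- length(values)
  z <- n * h * sqrt(pi)
  function(x) {
    vapply(x, function(xi) sum(exp(-((xi - values) / h)^2)) / z, numeric(1))
  }
}

#' Find the peaks of a density on [0, 1]
#'
#' Evaluates the density on a regular grid, takes every strict interior
#' local maximum (plus a boundary point exceeding its single neighbour),
#' refines each by Nelder-Mead maximisation seeded at the grid point, merges
#' refined peaks closer than `merge_tol` (keeping the higher-density one)
#' and drops peaks whose density falls below `prune_frac` of the global
#' maximum.
#'
#' @param density a function of one variable, as from [kde_density()].
#' @param grid_res grid resolution (default 0.001).
#' @param merge_tol minimum separation between reported peaks (default 0.01).
#' @param prune_frac peaks below this fraction of the maximum density are
#'   dropped (default 0.01).
#' @param nm_tol Nelder-Mead convergence tolerance on location.
#' @return numeric vector of peak locations in `[0, 1]`, sorted decreasing.
#' @export
find_peaks <- function(density, grid_res = 0.001, merge_tol = 0.01,
                       prune_frac = 0.01, nm_tol = 1e-6) {
  x <- seq(0, 1, by = grid_res)
  y <- density(x)
  n <- length(x)
  is_max <- logical(n)
  if (n >= 3) {
    mid <- 2:(n - 1)
    is_max[mid] <- y[mid] > y[mid - 1] & y[mid] > y[mid + 1]
  }
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  seeds <- x[is_max]
  if (length(seeds) == 0) {                 # flat or monotone: take argmax
    seeds <- x[which.max(y)]
  }
  neg <- function(p) {
    p <- min(max(p, 0), 1)
    -density(p)
  }
  refined <- vapply(seeds, function(s) {
    opt <- suppressWarnings(stats::optim(
      s, neg, method = "Nelder-Mead",
      control = list(reltol = nm_tol, warn.1d.NelderMead = FALSE)))
    min(max(opt$par, 0), 1)
  }, numeric(1))
  dens <- density(refined)
  ord <- order(dens, decreasing = TRUE)
  kept <- numeric(0)
  kept_dens <- numeric(0)
  for (i in ord) {
    if (all(abs(refined[i] - kept) >= merge_tol)) {
      kept <- c(kept, refined[i])
      kept_dens <- c(kept_dens, dens[i])
    }
  }
  keep <- kept_dens >= prune_frac * max(kept_dens)
  sort(kept[keep], decreasing = TRUE)
}

#' Tumor purity from subclone peaks
#'
#' Every tumor cell carries the founder mutations, so the largest peak on
#' the prevalence spectrum is the fraction of tumor cells in the sample.
#'
#' @param peaks numeric vector of peak prevalences.
#' @return the purity estimate, at most 1.
#' @export
estimate_purity <- function(peaks) {
  if (length(peaks) == 0) stop("no peaks: cannot estimate purity")
  min(max(peaks), 1)
}
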
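# The model-fitting interface: subclones() runs the whole inference and
# returns a classed object with the usual modelling methods.

#' Control parameters for subclone inference
#'
#' @param grid_res resolution of the density grid on `[0, 1]` used to seed
#'   peak finding (default 0.001).
#' @param merge_tol minimum separation between subclone peaks; closer
#'   refined peaks are merged, keeping the higher-density one (default 0.01).
#' @param prune_frac peaks whose density is below this fraction of the
#'   global maximum are discarded (default 0.01).
#' @param nocna_threshold when strictly more than this many SNVs lie on
#'   copy-number-free loci, only those SNVs vote in the clustering
#'   (default 100).
#' @param nm_tol Nelder-Mead convergence tolerance on peak location.
#' @param em_tol,em_max_iter convergence tolerance and iteration cap of the
#'   mixture-weight EM.
#' @param tree_cap maximum number of subclones for exhaustive tree
#'   enumeration (default 8).
#' @param verbose log stage progress to stderr.
#' @return a list of class `subclone_control`.
#' @export
subclone_control <- function(grid_res = 0.001, merge_tol = 0.01,
                             prune_frac = 0.01, nocna_threshold = 100,
                             nm_tol = 1e-6, em_tol = 1e-8,
                             em_max_iter = 500, tree_cap = 8,
                             verbose = FALSE) {
  stopifnot(grid_res > 0, grid_res <= 0.1, merge_tol >= 0,
            prune_frac >= 0, prune_frac < 1, nocna_threshold >= 0)
  structure(list(grid_res = grid_res, merge_tol = merge_tol,
                 prune_frac = prune_frac, nocna_threshold = nocna_threshold,
                 nm_tol = nm_tol, em_tol = em_tol,
                 em_max_iter = em_max_iter, tree_cap = tree_cap,
                 verbose = verbose),
            class = "subclone_control")
}

stage_log <- function(verbose, ...) {
  if (verbose) message("[subclones] ", ...)
}

#' Deconvolute tumor heterogeneity from a bulk sample
#'
#' Fits the full subclone model to one tumor sample: observed variant
#' allele frequencies are inverted to candidate cellular prevalences under
#' every mutation/copy-number timing scenario; subclones are the peaks of a
#' Gaussian kernel density over the pooled candidates (Scott's rule
#' bandwidth, fine-grid search with Nelder-Mead refinement; the largest
#' peak is the tumor purity); every SNV is then assigned to a subclone by
#' binomial maximum likelihood with EM-fitted mixture weights; finally all
#' phylogenies compatible with the prevalence ordering and sum constraints
#' are enumerated and ranked. Inference is deterministic given the inputs.
#'
#' @param snv SNV table: a data frame or TSV path accepted by
#'   [read_snv_table()].
#' @param cna copy-number segment table: a data frame or TSV path accepted
#'   by [read_cna_segments()], or `NULL` for none.
#' @param sex `"female"` (default) or `"male"`; male switches X/Y loci to
#'   the haploid prevalence model.
#' @param control a [subclone_control()] list.
#' @return an object of class `"subclones"`: a list with `peaks`,
#'   `n_subclones`, `purity`, `weights`, `snv_support`, `P` (posterior
#'   assignment matrix), `assignment` (hard labels), `prevalence` (per-SNV
#'   assigned prevalence, named), `fitted_beta`, `logLik`, `trees` (ranked),
#'   `tree` (best), `bandwidth`, `cluster_values`, plus the inputs.
#' @examples
#' sim <- simulate_tumor(n_subclones = 2, purity = 0.7, n_snvs = 400,
#'                       cna_fraction = 0, seed = 7)
#' fit <- subclones(sim$snv)
#' fit
#' coef(fit)
#' @export
subclones <- function(snv, cna = NULL, sex = c("female", "male"),
                      control = subclone_control()) {
  sex <- match.arg(sex)
  cl <- match.call()
  snv <- read_snv_table(snv, sex = sex)
  segments <- if (!is.null(cna)) read_cna_segments(cna) else NULL
  if (nrow(snv) == 0) stop("no usable SNVs: empty SNV table")
  stage_log(control$verbose, "read ", nrow(snv), " SNVs, ",
            if (is.null(segments)) 0 else length(unique(segments$segment_id)),
            " CNA segments")

  cand <- enumerate_candidates(snv, segments)
  stage_log(control$verbose, nrow(cand), " scenario candidates")

  vals <- select_clustering_input(cand, threshold = control$nocna_threshold)
  n <- length(vals)
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma < 1e-6) sigma <- 1  # degenerate spread
  h <- sigma * scott_bandwidth(n, 1)
  dens <- kde_density(vals, h)
  peaks <- find_peaks(dens, grid_res = control$grid_res,
                      merge_tol = control$merge_tol,
                      prune_frac = control$prune_frac,
                      nm_tol = control$nm_tol)
  peaks <- peaks[peaks > 0]           # prevalence 0 is the normal population
  if (length(peaks) == 0) stop("no subclone peaks found")
  purity <- estimate_purity(peaks)
  stage_log(control$verbose, length(peaks), " peaks from ", n,
            " values (h = ", signif(h, 4), "), purity ", signif(purity, 4))

  asg <- assign_all(snv, peaks, segments)
  stage_log(control$verbose, "assignment log-likelihood ",
            signif(asg$logLik, 6))

  trees <- enumerate_trees(peaks, cap = control$tree_cap)
  trees <- rank_trees(trees, asg$snv_support)
  stage_log(control$verbose, length(trees), " valid tree(s)")

  prevalence <- peaks[asg$hard_label]
  names(prevalence) <- snv$id
  structure(list(
    peaks = peaks,
    n_subclones = length(peaks),
    purity = purity,
    weights = asg$weights,
    snv_support = asg$snv_support,
    P = asg$P,
    assignment = asg$hard_label,
    prevalence = prevalence,
    fitted_beta = asg$beta_hat,
    logLik = asg$logLik,
    trees = trees,
    tree = trees[[1]],
    bandwidth = h,
    cluster_values = vals,
    candidates = cand,
    snv = snv,
    cna = segments,
    sex = sex,
    control = control,
    call = cl
  ), class = "subclones")
}

#' Export a fit in the prediction layout used for scoring
#'
#' @param fit a fitted [subclones()] object.
#' @return a list (`purity`, `peaks`, `P`, `hard_label`, `prevalence`,
#'   `parent`) comparable against [truth_to_prediction()] with
#'   [score_all()].
#' @export
as_prediction <- function(fit) {
  list(purity = fit$purity, peaks = fit$peaks, P = fit$P,
       hard_label = fit$assignment, prevalence = fit$prevalence,
       parent = fit$tree$parent)
}

#' @export
print.subclones <- function(x, ...) {
  cat("Subclone deconvolution\n")
  cat(sprintf("  %d SNVs, %s\n", nrow(x$snv),
              if (is.null(x$cna)) "no CNA segments" else
                paste(length(unique(x$cna$segment_id)), "CNA segments")))
  cat(sprintf("  subclones: %d   purity: %.3f\n", x$n_subclones, x$purity))
  tab <- data.frame(prevalence = round(x$peaks, 4),
                    weight = round(x$weights, 4),
                    n_snvs = x$snv_support)
  rownames(tab) <- paste0("clone", seq_along(x$peaks))
  print(tab)
  invisible(x)
}

#' @export
summary.subclones <- function(object, ...) {
  structure(list(fit = object), class = "summary.subclones")
}

#' @export
print.summary.subclones <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat(sprintf("\n  log-likelihood: %.4f\n", fit$logLik))
  cat(sprintf("  valid trees: %d (best shown)\n", length(fit$trees)))
  par <- fit$tree$parent
  for (j in seq_along(par)) {
    cat(sprintf("    clone%d (rho %.3f, phi %.3f) <- %s\n",
                j, fit$peaks[j], fit$tree$proportions[j],
                if (par[j] == 0) "normal" else paste0("clone", par[j])))
  }
  invisible(x)
}

#' @export
coef.subclones <- function(object, ...) {
  stats::setNames(object$peaks, paste0("clone", seq_along(object$peaks)))
}

#' @export
logLik.subclones <- function(object, ...) {
  structure(object$logLik, df = length(object$peaks) - 1,
            nobs = nrow(object$snv), class = "logLik")
}

#' @export
fitted.subclones <- function(object, ...) {
  stats::setNames(object$fitted_beta, object$snv$id)
}

#' @export
residuals.subclones <- function(object, ...) {
  stats::setNames(object$snv$beta - object$fitted_beta, object$snv$id)
}

#' Assign new SNVs to the fitted subclones
#'
#' @param object a fitted [subclones()] object.
#' @param newdata SNV table (data frame or TSV path); defaults to the
#'   training SNVs.
#' @param cna copy-number table for the new SNVs; defaults to the fit's.
#' @param type `"class"` for hard labels, `"posterior"` for the full
#'   probability matrix, `"prevalence"` for the assigned clone prevalence.
#' @param ... unused.
#' @return per-SNV labels, prevalences, or an `n x C` matrix.
#' @export
predict.subclones <- function(object, newdata = NULL, cna = NULL,
                              type = c("class", "posterior", "prevalence"),
                              ...) {
  type <- match.arg(type)
  snv <- if (is.null(newdata)) object$snv else
    read_snv_table(newdata, sex = object$sex)
  segments <- if (is.null(cna)) object$cna else read_cna_segments(cna)
  asg <- assign_all(snv, object$peaks, segments, weights = object$weights)
  switch(type,
         class = stats::setNames(asg$hard_label, snv$id),
         posterior = asg$P,
         prevalence = stats::setNames(object$peaks[asg$hard_label], snv$id))
}

#' Plot the prevalence density and fitted subclone peaks
#'
#' Draws the kernel density over the clustering prevalence values, a rug of
#' the values, and a vertical line at each fitted peak.
#'
#' @param x a fitted [subclones()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subclones <- function(x, ...) {
  dens <- kde_density(x$cluster_values, x$bandwidth)
  grid <- seq(0, 1, by = x$control$grid_res)
  graphics::plot(grid, dens(grid), type = "l",
                 xlab = "cellular prevalence", ylab = "density",
                 main = "Subclone prevalence spectrum", ...)
  graphics::rug(x$cluster_values)
  graphics::abline(v = x$peaks, lty = 2, col = "red3")
  graphics::mtext(sprintf("purity %.3f, %d subclones", x$purity,
                          x$n_subclones), side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Simulate read counts from a fitted subclone model
#'
#' Parametric bootstrap: keeps each SNV's observed depth and redraws its
#' variant reads binomially at the fitted expected allele frequency.
#'
#' @param object a fitted [subclones()] object.
#' @param nsim number of replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` SNV tables in the [read_snv_table()] layout.
#' @export
simulate.subclones <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  beta <- object$fitted_beta
  beta[is.na(beta)] <- object$snv$beta[is.na(beta)]
  lapply(seq_len(nsim), function(i) {
    alt <- stats::rbinom(nrow(object$snv), object$snv$total, beta)
    out <- object$snv
    out$alt_count <- alt
    out$ref_count <- out$total - alt
    out$beta <- alt / out$total
    out
  })
}
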
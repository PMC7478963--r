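# Challenge-style scoring of a prediction against a known truth:
# purity (1A), clone count (1B), per-SNV prevalences (1C), co-clustering
# (sub-challenge 2) and ancestry (sub-challenge 3).

#' Score the purity prediction
#'
#' One minus the absolute difference between true and inferred purity.
#'
#' @param truth,pred purities in `[0, 1]`.
#' @return score in `[0, 1]`, 1 = perfect.
#' @export
score_purity <- function(truth, pred) {
  stopifnot(truth >= 0, truth <= 1, pred >= 0, pred <= 1)
  1 - abs(truth - pred)
}

#' Score the subclone-count prediction
#'
#' Relative error score `1 - |n_truth - n_pred| / n_truth`, clamped below at
#' 0. `method = "max"` uses the variant denominator
#' `max(n_truth, n_pred)` instead.
#'
#' @param n_truth,n_pred subclone counts, at least 1.
#' @param method `"truth"` (canonical) or `"max"`.
#' @return score in `[0, 1]`.
#' @examples
#' score_nclones(4, 3)  # 0.75
#' @export
score_nclones <- function(n_truth, n_pred, method = c("truth", "max")) {
  method <- match.arg(method)
  stopifnot(n_truth >= 1, n_pred >= 1)
  den <- switch(method, truth = n_truth, max = max(n_truth, n_pred))
  max(0, 1 - abs(n_truth - n_pred) / den)
}

#' Score the per-SNV cellular prevalence prediction
#'
#' One minus the mean absolute difference between the true and inferred
#' cellular prevalence of each SNV. Vectors are matched by name when named;
#' predicted SNVs absent from the truth (false-positive calls) are excluded
#' before comparison.
#'
#' @param truth,pred numeric vectors of per-SNV prevalences in `[0, 1]`,
#'   optionally named by SNV id.
#' @return score in `[0, 1]`, clamped below at 0.
#' @export
score_proportions <- function(truth, pred) {
  if (!is.null(names(truth)) && !is.null(names(pred))) {
    pred <- pred[names(pred) %in% names(truth)]   # drop false positives
    if (!all(names(truth) %in% names(pred))) {
      stop("prediction is missing SNVs present in the truth")
    }
    pred <- pred[names(truth)]
  } else if (length(truth) != length(pred)) {
    stop("truth and prediction have different lengths and no names to match")
  }
  stopifnot(all(truth >= 0 & truth <= 1), all(pred >= 0 & pred <= 1))
  max(0, 1 - mean(abs(truth - pred)))
}

# Pearson correlation of two flattened matrices with the degenerate-case
# rule: when either side is constant the score is 1 for equal matrices and
# 0 otherwise (with a warning).
matrix_correlation <- function(M_truth, M_pred) {
  a <- as.vector(M_truth)
  b <- as.vector(M_pred)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant matrix in correlation score; ",
            "scoring by exact equality")
    return(if (isTRUE(all.equal(a, b, tolerance = 1e-12))) 1 else 0)
  }
  stats::cor(a, b)
}

#' Co-clustering score (sub-challenge 2)
#'
#' Both assignments are summarised as the SNV-by-SNV co-clustering matrix
#' `S = P P^T` (entry `[k, l]` = probability SNVs `k` and `l` share a
#' subclone); the score is the Pearson correlation between the flattened
#' predicted and true matrices. Invariant to subclone relabelling.
#'
#' @param P_truth,P_pred row-stochastic `n x C` assignment matrices over the
#'   same SNVs (C may differ between the two).
#' @return the correlation; 1 = perfect.
#' @export
coclustering_score <- function(P_truth, P_pred) {
  if (nrow(P_truth) != nrow(P_pred)) {
    stop("assignment matrices cover different SNV sets")
  }
  matrix_correlation(tcrossprod(P_truth), tcrossprod(P_pred))
}

#' Ancestry score (sub-challenge 3)
#'
#' Assignments and trees are summarised as the SNV-by-SNV ancestry matrix
#' `M = P A P^T` (entry `[k, l]` = probability that SNV `k`'s subclone is a
#' strict ancestor of SNV `l`'s); the score is the Pearson correlation
#' between the flattened matrices, with the same degenerate-case rule as
#' [coclustering_score()].
#'
#' @inheritParams coclustering_score
#' @param A_truth,A_pred subclone ancestor matrices ([ancestor_matrix()]).
#' @return the correlation; 1 = perfect.
#' @export
ancestry_score <- function(P_truth, A_truth, P_pred, A_pred) {
  if (nrow(P_truth) != nrow(P_pred)) {
    stop("assignment matrices cover different SNV sets")
  }
  M_truth <- P_truth %*% A_truth %*% t(P_truth)
  M_pred <- P_pred %*% A_pred %*% t(P_pred)
  matrix_correlation(M_truth, M_pred)
}

#' Score a full prediction against a truth record
#'
#' Computes all five challenge-style scores. `truth` and `pred` are lists
#' with elements `purity`, `peaks`, `P` (n x C assignment matrix),
#' `prevalence` (per-SNV cellular prevalence, named by SNV id) and `parent`
#' (tree parent vector) — the layout produced by [truth_to_prediction()]
#' and by [as_prediction()] on a fitted model.
#'
#' @param truth,pred prediction-layout lists.
#' @return list with `purity`, `nclones`, `proportions`, `coclustering`,
#'   `ancestry`.
#' @export
score_all <- function(truth, pred) {
  list(
    purity = score_purity(truth$purity, pred$purity),
    nclones = score_nclones(length(truth$peaks), length(pred$peaks)),
    proportions = score_proportions(truth$prevalence, pred$prevalence),
    coclustering = coclustering_score(truth$P, pred$P),
    ancestry = ancestry_score(truth$P, ancestor_matrix(truth$parent),
                              pred$P, ancestor_matrix(pred$parent))
  )
}
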
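# SNV -> subclone assignment: binomial likelihood of observed read counts
# under the best-fitting multiplicity scenario, mixture weights by EM.

#' Expected allele frequencies of a subclone's mutations at one locus
#'
#' For a subclone of prevalence `rho_j`, enumerates the allele frequency
#' expected for each way the mutation could relate to the local copy-number
#' state: on the major allele before/during the event (multiplicity
#' `2..N_major`), on the minor allele (multiplicity `1..N_minor`; not
#' considered when the minor allele is deleted), or after the event
#' (multiplicity 1). Without a copy-number event the single candidate is
#' `rho_j / 2` (or `rho_j` on a male X/Y locus). Candidates from every state
#' of a multistate segment are pooled. Duplicates are collapsed keeping the
#' smallest multiplicity; values are clipped to `[0, 1]`.
#'
#' @param rho_j subclone prevalence in `(0, 1]`.
#' @param states copy-number states of the segment (data frame with `major`,
#'   `minor`), or `NULL` for no CNA event.
#' @param male `TRUE` for a male X/Y locus.
#' @return data frame with columns `beta_hat`, `scenario`, `multiplicity`,
#'   ordered by multiplicity.
#' @export
expected_beta_candidates <- function(rho_j, states = NULL, male = FALSE) {
  if (rho_j <= 0 || rho_j > 1) stop("rho_j must lie in (0, 1]")
  rows <- list()
  add <- function(scenario, multiplicity, beta_hat) {
    rows[[length(rows) + 1L]] <<- data.frame(
      beta_hat = beta_hat, scenario = scenario,
      multiplicity = as.integer(multiplicity), stringsAsFactors = FALSE)
  }
  if (is.null(states) || nrow(states) == 0) {
    add(if (male) "male_no_cna" else "no_cna", 1L,
        if (male) rho_j else rho_j / 2)
  } else {
    for (s in seq_len(nrow(states))) {
      n_maj <- states$major[s]
      n_min <- states$minor[s]
      if (n_maj < 1) next                   # homozygous deletion
      if (male) {
        den <- n_maj * rho_j + (1 - rho_j)
        for (m in seq_len(n_maj)) add("male_with_cna", m, m * rho_j / den)
        add("male_after_cna", 1L, rho_j / den)
      } else {
        den <- (n_maj + n_min) * rho_j + 2 * (1 - rho_j)
        if (n_maj >= 2) {
          for (m in 2:n_maj) add("major_with_cna", m, m * rho_j / den)
        }
        if (n_min >= 1) {
          for (m in seq_len(n_min)) add("minor_with_cna", m, m * rho_j / den)
        }
        add("after_cna", 1L, rho_j / den)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(beta_hat = numeric(), scenario = character(),
                      multiplicity = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$beta_hat <- pmin(pmax(out$beta_hat, 0), 1)
  out <- out[order(out$multiplicity), , drop = FALSE]
  out <- out[!duplicated(round(out$beta_hat / 1e-12) * 1e-12), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial likelihood of observed read counts
#'
#' Probability of observing `m` variant reads out of `r` at expected allele
#' frequency `beta_hat`, i.e. the binomial pmf `C(r,m) beta^m (1-beta)^(r-m)`
#' (with the convention `0^0 = 1`).
#'
#' @param m variant read count, `0 <= m <= r`.
#' @param r total read count.
#' @param beta_hat expected allele frequency in `[0, 1]`.
#' @return the probability.
#' @export
binomial_likelihood <- function(m, r, beta_hat) {
  if (any(m < 0) || any(m > r)) stop("need 0 <= m <= r")
  if (any(beta_hat < 0) || any(beta_hat > 1)) {
    stop("beta_hat must lie in [0, 1]")
  }
  stats::dbinom(m, r, beta_hat)
}

#' Best-scenario likelihood of one SNV under one subclone
#'
#' The mutation multiplicity is unknown, so the likelihood of an SNV
#' belonging to subclone `j` is the maximum of the binomial likelihood over
#' all expected-frequency candidates ([expected_beta_candidates()]). Ties go
#' to the smaller multiplicity.
#'
#' @param m,r variant and total read counts.
#' @inheritParams expected_beta_candidates
#' @return list with elements `likelihood`, `beta_hat`, `scenario`,
#'   `multiplicity`.
#' @export
best_likelihood <- function(m, r, rho_j, states = NULL, male = FALSE) {
  cand <- expected_beta_candidates(rho_j, states, male)
  if (nrow(cand) == 0) {
    return(list(likelihood = 0, beta_hat = NA_real_,
                scenario = NA_character_, multiplicity = NA_integer_))
  }
  lik <- binomial_likelihood(m, r, cand$beta_hat)
  i <- which.max(lik)    # candidates ordered by multiplicity: ties -> smaller
  list(likelihood = lik[i], beta_hat = cand$beta_hat[i],
       scenario = cand$scenario[i], multiplicity = cand$multiplicity[i])
}

#' Fit subclone mixture weights by EM
#'
#' Maximises the mixture log-likelihood
#' `lambda = sum_k ln sum_j w_j L[k, j]` over the weight simplex, with the
#' component likelihoods held fixed: standard expectation-maximisation with
#' uniform initialisation. SNVs whose likelihood is zero under every
#' subclone carry no information and are dropped with a warning.
#'
#' @param L an `n x C` matrix of per-SNV, per-subclone likelihoods.
#' @param tol convergence tolerance on the log-likelihood improvement.
#' @param max_iter iteration cap.
#' @return list with `weights` (length `C`, summing to 1), `logLik`,
#'   `iterations` and `used` (logical vector of rows kept).
#' @export
fit_weights <- function(L, tol = 1e-8, max_iter = 500) {
  L <- as.matrix(L)
  if (any(L < 0)) stop("likelihoods must be non-negative")
  C <- ncol(L)
  used <- rowSums(L) > 0
  if (!all(used)) {
    warning(sum(!used), " SNV(s) with zero likelihood under every subclone",
            " dropped from the weight fit")
  }
  Lu <- L[used, , drop = FALSE]
  n <- nrow(Lu)
  if (n == 0) stop("no SNV has positive likelihood under any subclone")
  w <- rep(1 / C, C)
  ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    num <- sweep(Lu, 2, w, `*`)
    den <- rowSums(num)
    ll_new <- sum(log(den))
    gamma <- num / den
    w <- colMeans(gamma)
    if (ll_new - ll < tol || iter >= max_iter) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(weights = w, logLik = ll, iterations = iter, used = used)
}

# Build the n x C likelihood matrix plus per-cell chosen expected beta.
# SNVs are grouped by (segment, male flag) so the candidate set is computed
# once per group and peak.
likelihood_matrix <- function(snv, peaks, segments = NULL) {
  seg_of <- lookup_cna(snv, segments)
  state_sets <- list()
  if (!is.null(segments) && nrow(segments) > 0) {
    state_sets <- split(segments[, c("major", "minor")], segments$segment_id)
  }
  n <- nrow(snv)
  C <- length(peaks)
  L <- matrix(0, n, C)
  B <- matrix(NA_real_, n, C)          # chosen expected beta per (SNV, clone)
  grp <- paste(ifelse(is.na(seg_of), "<none>", seg_of), snv$male_sex_chrom)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sid <- seg_of[idx[1]]
    st <- if (!is.na(sid)) state_sets[[sid]] else NULL
    male <- snv$male_sex_chrom[idx[1]]
    for (j in seq_len(C)) {
      cand <- expected_beta_candidates(peaks[j], st, male)
      if (nrow(cand) == 0) next
      lik <- vapply(cand$beta_hat, function(b) {
        stats::dbinom(snv$alt_count[idx], snv$total[idx], b)
      }, numeric(length(idx)))
      lik <- matrix(lik, nrow = length(idx))
      best <- max.col(lik, ties.method = "first")  # ties -> smaller mult
      L[idx, j] <- lik[cbind(seq_along(idx), best)]
      B[idx, j] <- cand$beta_hat[best]
    }
  }
  list(L = L, beta_hat = B, segment = seg_of)
}

#' Assign every SNV to a subclone
#'
#' The association score of SNV `k` with subclone `j` is the prior-weighted
#' likelihood `w_j * L[k, j]`; normalising each row gives the posterior
#' probability matrix `P`, and each SNV is hard-assigned to the subclone
#' with the highest score (ties to the larger-prevalence subclone). SNVs on
#' multistate segments are assigned like any other, pooling the candidate
#' frequencies of every state.
#'
#' @param snv SNV data frame from [read_snv_table()].
#' @param peaks subclone peak prevalences, sorted decreasing.
#' @param segments CNA state table or `NULL`.
#' @param weights mixture weights; fitted by [fit_weights()] when `NULL`.
#' @return list with `P` (n x C posterior matrix), `hard_label`,
#'   `beta_hat` (chosen expected frequency of the assigned subclone),
#'   `weights`, `logLik`, `snv_support` (SNV count per subclone), `L`,
#'   and `segment` (matched segment id per SNV).
#' @export
assign_all <- function(snv, peaks, segments = NULL, weights = NULL) {
  lm <- likelihood_matrix(snv, peaks, segments)
  L <- lm$L
  if (is.null(weights)) {
    fw <- fit_weights(L)
    weights <- fw$weights
    ll <- fw$logLik
  } else {
    pos <- rowSums(sweep(L, 2, weights, `*`)) > 0
    ll <- sum(log(rowSums(sweep(L[pos, , drop = FALSE], 2, weights, `*`))))
  }
  score <- sweep(L, 2, weights, `*`)
  tot <- rowSums(score)
  P <- score / ifelse(tot > 0, tot, 1)
  uninformative <- tot == 0
  if (any(uninformative)) {
    P[uninformative, ] <- 1 / length(peaks)
  }
  hard <- max.col(P, ties.method = "first")   # peaks sorted desc: ties -> larger rho
  support <- tabulate(hard, nbins = length(peaks))
  chosen_beta <- lm$beta_hat[cbind(seq_len(nrow(snv)), hard)]
  list(P = P, hard_label = hard, beta_hat = chosen_beta, weights = weights,
       logLik = ll, snv_support = support, L = L, segment = lm$segment)
}
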
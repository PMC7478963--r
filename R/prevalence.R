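# Cellular prevalence <-> allele frequency conversion under every
# mutation/copy-number timing scenario.
#
# For a diploid locus with no copy-number event, a mutation present in a
# fraction rho of all cells contributes rho * n_cell mutated alleles out of
# 2 * n_cell, so beta = rho / 2. With an allele-specific copy-number state
# (N_major, N_minor) carried by the same cells, the denominator becomes
# (N_major + N_minor) * rho + 2 * (1 - rho) and the numerator is
# multiplicity * rho, where the multiplicity (number of allele copies
# carrying the mutation) depends on whether the mutation sat on the major or
# minor allele before/during amplification (1..N_major or 1..N_minor) or
# arose after the event (exactly 1). Male X/Y loci are haploid at baseline:
# beta = rho without CNA, and multiplicity * rho / (N_major*rho + (1-rho))
# with CNA.

.timings <- c("no_cna", "major", "minor", "after")

#' Expected allele frequency of a mutation (forward model)
#'
#' Maps a cellular prevalence to the allele frequency expected in reads,
#' given the local copy-number state, the mutation multiplicity and the
#' timing of the mutation relative to the copy-number event. This single
#' function is the shared oracle for the simulator and for the inversion in
#' [candidate_rhos()].
#'
#' @param rho cellular prevalence in `[0, 1]`.
#' @param multiplicity number of allele copies per cell carrying the
#'   mutation; must be 1 for `timing = "after"` and `timing = "no_cna"`,
#'   at most `n_major` (`"major"`) or `n_minor` (`"minor"`).
#' @param n_major,n_minor allele-specific copy numbers (ignored for
#'   `timing = "no_cna"`).
#' @param male `TRUE` for a male X/Y locus (haploid baseline; `n_minor` is
#'   treated as 0 and minor-allele timing is unavailable).
#' @param timing one of `"no_cna"`, `"major"`, `"minor"`, `"after"`.
#' @return the expected allele frequency, in `[0, 1]`.
#' @examples
#' forward_beta(0.6, timing = "no_cna")                       # 0.3
#' forward_beta(0.5, 2, n_major = 2, n_minor = 1, timing = "major")  # 0.4
#' @export
forward_beta <- function(rho, multiplicity = 1L, n_major = NA_integer_,
                         n_minor = NA_integer_, male = FALSE,
                         timing = c("no_cna", "major", "minor", "after")) {
  timing <- match.arg(timing)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  if (any(multiplicity < 1)) stop("multiplicity must be a positive integer")
  if (timing == "no_cna") {
    if (any(multiplicity != 1)) stop("multiplicity must be 1 without CNA")
    return(if (male) rho else rho / 2)
  }
  if (any(is.na(n_major))) stop("n_major required for CNA timings")
  if (male) {
    if (timing == "minor") stop("minor-allele timing undefined for male X/Y")
    if (timing == "after" && any(multiplicity != 1)) {
      stop("multiplicity must be 1 after the CNA event")
    }
    if (timing == "major" && any(multiplicity > n_major)) {
      stop("multiplicity exceeds n_major")
    }
    return(multiplicity * rho / (n_major * rho + (1 - rho)))
  }
  if (any(is.na(n_minor))) stop("n_minor required for diploid CNA timings")
  cap <- switch(timing, major = n_major, minor = n_minor, after = 1L)
  if (any(multiplicity > cap)) {
    stop("multiplicity inconsistent with timing ", timing)
  }
  multiplicity * rho / ((n_major + n_minor) * rho + 2 * (1 - rho))
}

# Invert beta -> rho for one scenario. The diploid inversion is
# rho = 2*beta / (mult + 2*beta - beta*(N_major + N_minor)); the male form
# is rho = beta / (mult + beta - beta*N_major). A non-positive denominator
# means the scenario is impossible (equivalent to rho > 1).
invert_rho <- function(beta, multiplicity, n_major, n_minor, male) {
  if (male) {
    den <- multiplicity + beta - beta * n_major
    num <- beta
  } else {
    den <- multiplicity + 2 * beta - beta * (n_major + n_minor)
    num <- 2 * beta
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Candidate cellular prevalences of one SNV
#'
#' Because the order of the mutation and any copy-number event at its locus
#' is unknown, every timing scenario that could have produced the observed
#' allele frequency is inverted separately, yielding a set of candidate
#' prevalences. Scenarios implying a prevalence above 1 are impossible and
#' are discarded (a prevalence of exactly 1 is kept); scenarios that
#' coincide analytically are collapsed to a single candidate, keeping the
#' smallest multiplicity.
#'
#' @param beta observed allele frequency in `[0, 1]`.
#' @param states `NULL` for no CNA event, otherwise a data frame of
#'   copy-number states with columns `major` and `minor` (one row per state;
#'   several rows encode a multistate segment).
#' @param male `TRUE` for a male X/Y locus.
#' @return data frame with columns `scenario`, `multiplicity`, `rho`,
#'   `state` (row index into `states`, NA without CNA) and `multistate`.
#'   Zero rows when every scenario is impossible; a single `rho = 0` row when
#'   `beta` is 0.
#' @export
candidate_rhos <- function(beta, states = NULL, male = FALSE) {
  if (is.na(beta) || beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  empty <- data.frame(scenario = character(), multiplicity = integer(),
                      rho = numeric(), state = integer(),
                      multistate = logical(), stringsAsFactors = FALSE)
  if (beta == 0) {
    return(data.frame(scenario = "no_cna", multiplicity = 1L, rho = 0,
                      state = NA_integer_,
                      multistate = !is.null(states) && nrow(states) > 1,
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  add <- function(scenario, multiplicity, rho, state) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scenario, multiplicity = as.integer(multiplicity),
      rho = rho, state = state, stringsAsFactors = FALSE)
  }
  if (is.null(states) || nrow(states) == 0) {
    rho <- if (male) beta else 2 * beta
    add(if (male) "male_no_cna" else "no_cna", 1L, rho, NA_integer_)
  } else {
    for (s in seq_len(nrow(states))) {
      n_maj <- states$major[s]
      n_min <- states$minor[s]
      if (n_maj < 1) next                       # homozygous deletion
      if (male) {
        for (m in seq_len(n_maj)) {
          add("male_with_cna", m, invert_rho(beta, m, n_maj, 0, TRUE), s)
        }
        add("male_after_cna", 1L, invert_rho(beta, 1L, n_maj, 0, TRUE), s)
      } else {
        for (m in seq_len(n_maj)) {
          add("major_with_cna", m, invert_rho(beta, m, n_maj, n_min, FALSE), s)
        }
        if (n_min >= 1) {
          for (m in seq_len(n_min)) {
            add("minor_with_cna", m,
                invert_rho(beta, m, n_maj, n_min, FALSE), s)
          }
        }
        add("after_cna", 1L, invert_rho(beta, 1L, n_maj, n_min, FALSE), s)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$rho) & out$rho <= 1 + 1e-9, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$rho <- pmin(out$rho, 1)
  # collapse numerically identical candidates, keeping smallest multiplicity
  out <- out[order(out$multiplicity), , drop = FALSE]
  keep <- !duplicated(round(out$rho / 1e-12) * 1e-12)
  out <- out[keep, , drop = FALSE]
  out$multistate <- !is.null(states) && nrow(states) > 1
  rownames(out) <- NULL
  out
}

#' Candidate prevalences for a whole SNV table
#'
#' Applies [candidate_rhos()] to every SNV, using its matched copy-number
#' segment (if any).
#'
#' @param snv SNV data frame from [read_snv_table()].
#' @param segments CNA state table from [read_cna_segments()], or `NULL`.
#' @return data frame with one row per (SNV, scenario) candidate: columns
#'   `snv_id`, `scenario`, `multiplicity`, `rho`, `multistate`, `has_cna`
#'   and `segment_id`.
#' @export
enumerate_candidates <- function(snv, segments = NULL) {
  seg_of <- lookup_cna(snv, segments)
  state_sets <- list()
  if (!is.null(segments) && nrow(segments) > 0) {
    state_sets <- split(segments[, c("major", "minor")], segments$segment_id)
  }
  # copy-number-free SNVs invert in closed form: vectorised
  free <- which(is.na(seg_of))
  out_free <- NULL
  if (length(free) > 0) {
    male <- snv$male_sex_chrom[free]
    rho <- ifelse(male, snv$beta[free], 2 * snv$beta[free])
    keep <- rho <= 1 + 1e-9
    rho <- pmin(rho[keep], 1)
    out_free <- data.frame(
      snv_id = snv$id[free][keep],
      scenario = ifelse(male[keep], "male_no_cna", "no_cna"),
      multiplicity = 1L, rho = rho, multistate = FALSE, has_cna = FALSE,
      segment_id = NA_character_, stringsAsFactors = FALSE)
  }
  on_seg <- which(!is.na(seg_of))
  res <- vector("list", length(on_seg))
  for (i in seq_along(on_seg)) {
    k <- on_seg[i]
    cand <- candidate_rhos(snv$beta[k], state_sets[[seg_of[k]]],
                           male = snv$male_sex_chrom[k])
    if (nrow(cand) == 0) next
    cand$snv_id <- snv$id[k]
    cand$has_cna <- TRUE
    cand$segment_id <- seg_of[k]
    res[[i]] <- cand
  }
  res <- res[!vapply(res, is.null, TRUE)]
  out <- rbind(out_free,
               if (length(res) > 0) {
                 x <- do.call(rbind, res)
                 x[, c("snv_id", "scenario", "multiplicity", "rho",
                       "multistate", "has_cna", "segment_id")]
               })
  if (is.null(out) || nrow(out) == 0) {
    stop("no usable SNVs: every scenario of every SNV was impossible")
  }
  rownames(out) <- NULL
  out
}
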
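# Forward tumor simulator with known ground truth. The generative model is
# the same forward_beta() used by the inference: a random subclone tree with
# prevalence ordering/sum constraints, per-clone SNV sets with mutation
# multiplicities drawn uniformly among the timings legal for the local
# copy-number state, and binomial read counts at Poisson depth.

.sim_chroms <- c(as.character(1:22), "X")
.sim_chrom_len <- 1e8
.sim_state_pool <- list(c(2L, 1L), c(3L, 1L), c(2L, 0L),
                        c(2L, 2L), c(3L, 2L), c(4L, 2L))

# sample clone prevalences (rho_1 = purity) and a tree satisfying the
# ordering + sum constraints, with all pairwise gaps >= gap
sample_clone_structure <- function(n_subclones, purity, gap,
                                   max_tries = 10000) {
  if (n_subclones == 1) {
    return(list(prevalence = purity, parent = 0L))
  }
  lo <- 0.05
  hi <- purity - gap
  if (hi - lo < (n_subclones - 2) * gap || hi <= lo) {
    stop("infeasible configuration: ", n_subclones, " subclones with gap ",
         gap, " do not fit below purity ", purity)
  }
  for (try in seq_len(max_tries)) {
    rho <- sort(stats::runif(n_subclones - 1, lo, hi), decreasing = TRUE)
    all_rho <- c(purity, rho)
    if (min(-diff(all_rho)) < gap) next
    # random topology honouring the budget phi_j >= 0
    parent <- integer(n_subclones)
    budget <- all_rho
    ok <- TRUE
    for (j in 2:n_subclones) {
      eligible <- which(budget[seq_len(j - 1)] >= all_rho[j])
      if (length(eligible) == 0) {
        ok <- FALSE
        break
      }
      p <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      parent[j] <- p
      budget[p] <- budget[p] - all_rho[j]
    }
    if (ok) return(list(prevalence = all_rho, parent = parent))
  }
  stop("could not sample a clone structure satisfying the gap constraint")
}

# split n_snvs among clones: Dirichlet-uniform proportions with a floor
sample_clone_sizes <- function(n_snvs, n_subclones, min_per_clone) {
  m0 <- min(min_per_clone, n_snvs %/% n_subclones)
  m0 <- max(m0, 1L)
  rest <- n_snvs - m0 * n_subclones
  p <- stats::rgamma(n_subclones, 1, 1)
  p <- p / sum(p)
  extra <- if (rest > 0) {
    as.vector(stats::rmultinom(1, rest, p))
  } else {
    rep(0L, n_subclones)
  }
  m0 + extra
}

#' Simulate a bulk tumor with known ground truth
#'
#' Generates a random subclone tree (root prevalence = purity, children
#' summing within their parent, pairwise prevalence gaps at least
#' `min_prevalence_gap`), splits SNVs among clones (Dirichlet-uniform with a
#' per-clone floor), places them on a synthetic genome, lays copy-number
#' segments over a fraction of that genome (optionally with a second,
#' independent state on some segments), draws each SNV's timing scenario
#' uniformly among those legal for its copy-number state, computes its
#' expected allele frequency through [forward_beta()], and samples read
#' counts (`total ~ Poisson(mean_depth)` floored at 1,
#' `alt ~ Binomial(total, beta)`). Fully reproducible from `seed`.
#'
#' SNVs landing on a multistate segment take their expected frequency from
#' their own clone's state through the single-state forward model; the
#' inference treats such SNVs as unusable for clustering but still assigns
#' them to subclones.
#'
#' @param n_subclones number of subclones (tree nodes), at least 1.
#' @param purity fraction of tumor cells in the sample, in `(0, 1]`.
#' @param n_snvs total number of somatic SNVs.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param min_prevalence_gap minimum pairwise distance between clone
#'   prevalences (default 0.1).
#' @param cna_fraction fraction of the genome under a copy-number event.
#' @param multistate_fraction fraction of CNA segments carrying two
#'   independent states.
#' @param sex `"female"` or `"male"` (male makes chromosome X haploid).
#' @param min_clone_snvs per-clone SNV floor (default 20, reduced when
#'   `n_snvs` is small).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with `snv` (read-count table, [read_snv_table()] layout),
#'   `cna` (state table, [read_cna_segments()] layout or `NULL`), and
#'   `truth`: a list with `parent`, `prevalence`, `purity`, `sex`, and the
#'   per-SNV data frame `snvs` (`id`, `clone`, `segment_id`, `timing`,
#'   `multiplicity`, `expected_beta`, `prevalence`).
#' @export
simulate_tumor <- function(n_subclones = 3, purity = 0.7, n_snvs = 2000,
                           mean_depth = 100, min_prevalence_gap = 0.1,
                           cna_fraction = 0.2, multistate_fraction = 0.2,
                           sex = c("female", "male"), min_clone_snvs = 20,
                           seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(n_subclones >= 1, purity > 0, purity <= 1, n_snvs >= n_subclones,
            mean_depth > 0, cna_fraction >= 0, cna_fraction <= 1,
            multistate_fraction >= 0, multistate_fraction <= 1)
  if ((n_subclones - 1) * min_prevalence_gap >= purity) {
    stop("infeasible configuration: gap x clones exceeds purity")
  }
  if (!is.null(seed)) set.seed(seed)

  structure_ <- sample_clone_structure(n_subclones, purity,
                                       min_prevalence_gap)
  rho <- structure_$prevalence
  sizes <- sample_clone_sizes(n_snvs, n_subclones, min_clone_snvs)
  clone_of <- rep(seq_len(n_subclones), sizes)

  # genome and CNA segments: one segment per chromosome covering
  # cna_fraction of its length (none when cna_fraction = 0)
  cna <- NULL
  if (cna_fraction > 0) {
    seg_len <- round(cna_fraction * .sim_chrom_len)
    rows <- list()
    for (ch in .sim_chroms) {
      s0 <- sample.int(.sim_chrom_len - seg_len, 1)
      st <- .sim_state_pool[[sample.int(length(.sim_state_pool), 1)]]
      two_state <- stats::runif(1) < multistate_fraction
      if (two_state) {
        st2 <- st
        while (identical(st2, st)) {
          st2 <- .sim_state_pool[[sample.int(length(.sim_state_pool), 1)]]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = c(s0, s0), end = c(s0 + seg_len, s0 + seg_len),
          major = c(st[1], st2[1]), minor = c(st[2], st2[2]),
          frac = c(0.6, 0.4), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = s0, end = s0 + seg_len,
          major = st[1], minor = st[2], frac = 1, stringsAsFactors = FALSE)
      }
    }
    cna <- read_cna_segments(do.call(rbind, rows))
  }

  chrom <- sample(.sim_chroms, n_snvs, replace = TRUE)
  pos <- sample.int(.sim_chrom_len, n_snvs, replace = TRUE)
  id <- sprintf("snv%05d", seq_len(n_snvs))
  male_flag <- is_sex_chromosome(chrom) & sex == "male"

  snv_stub <- data.frame(id = id, chrom = chrom, pos = pos,
                         male_sex_chrom = male_flag,
                         stringsAsFactors = FALSE)
  seg_of <- lookup_cna(snv_stub, cna)
  state_sets <- list()
  if (!is.null(cna)) {
    state_sets <- split(cna[, c("major", "minor")], cna$segment_id)
  }

  timing <- character(n_snvs)
  mult <- integer(n_snvs)
  state_row <- rep(NA_integer_, n_snvs)
  ebeta <- numeric(n_snvs)
  for (k in seq_len(n_snvs)) {
    rk <- rho[clone_of[k]]
    if (is.na(seg_of[k])) {
      timing[k] <- "no_cna"
      mult[k] <- 1L
      ebeta[k] <- forward_beta(rk, 1L, male = male_flag[k],
                               timing = "no_cna")
      next
    }
    st <- state_sets[[seg_of[k]]]
    s <- if (nrow(st) == 1) 1L else sample.int(nrow(st), 1)
    state_row[k] <- s
    n_maj <- st$major[s]
    n_min <- st$minor[s]
    legal <- list()
    if (n_maj >= 1) {
      for (m in seq_len(n_maj)) legal[[length(legal) + 1L]] <- c("major", m)
      if (!male_flag[k] && n_min >= 1) {
        for (m in seq_len(n_min)) legal[[length(legal) + 1L]] <- c("minor", m)
      }
      legal[[length(legal) + 1L]] <- c("after", 1L)
    }
    if (length(legal) == 0) {         # homozygous deletion: no SNV possible
      timing[k] <- "no_cna"
      mult[k] <- 1L
      state_row[k] <- NA_integer_
      seg_of[k] <- NA_character_
      ebeta[k] <- forward_beta(rk, 1L, male = male_flag[k],
                               timing = "no_cna")
      next
    }
    pick <- legal[[sample.int(length(legal), 1)]]
    timing[k] <- pick[1]
    mult[k] <- as.integer(pick[2])
    ebeta[k] <- forward_beta(rk, mult[k], n_major = n_maj, n_minor = n_min,
                             male = male_flag[k], timing = timing[k])
  }

  total <- pmax(stats::rpois(n_snvs, mean_depth), 1L)
  alt <- stats::rbinom(n_snvs, total, ebeta)
  snv <- data.frame(
    id = id, chrom = chrom, pos = pos,
    ref_count = total - alt, alt_count = alt, total = total,
    beta = alt / total, male_sex_chrom = male_flag,
    stringsAsFactors = FALSE
  )
  truth <- list(
    parent = structure_$parent,
    prevalence = rho,
    purity = purity,
    sex = sex,
    snvs = data.frame(
      id = id, clone = clone_of, segment_id = seg_of, state = state_row,
      timing = timing, multiplicity = mult, expected_beta = ebeta,
      prevalence = rho[clone_of], stringsAsFactors = FALSE)
  )
  list(snv = snv, cna = cna, truth = truth)
}

#' Re-encode a truth record in the prediction layout
#'
#' Produces the same structure a fitted model exports ([as_prediction()]):
#' peak prevalences, purity, a one-hot assignment matrix, per-SNV cellular
#' prevalences and the tree parent vector. Feeding the result to
#' [score_all()] against its own truth scores 1 on every metric.
#'
#' @param truth the `truth` element of a [simulate_tumor()] result.
#' @return a prediction-layout list (`purity`, `peaks`, `P`, `hard_label`,
#'   `prevalence`, `parent`).
#' @export
truth_to_prediction <- function(truth) {
  C <- length(truth$prevalence)
  n <- nrow(truth$snvs)
  P <- matrix(0, n, C)
  P[cbind(seq_len(n), truth$snvs$clone)] <- 1
  prevalence <- truth$snvs$prevalence
  names(prevalence) <- truth$snvs$id
  list(purity = truth$purity, peaks = truth$prevalence, P = P,
       hard_label = truth$snvs$clone, prevalence = prevalence,
       parent = truth$parent)
}

#' Write a simulated tumor to disk
#'
#' Writes the two canonical TSV inputs (`snv.tsv`, `cna.tsv` when present)
#' plus the truth record (`truth.json`).
#'
#' @param sim result of [simulate_tumor()].
#' @param dir output directory, created if needed.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_snv_table(sim$snv, file.path(dir, "snv.tsv"))
  if (!is.null(sim$cna)) {
    write_cna_segments(sim$cna, file.path(dir, "cna.tsv"))
  }
  jsonlite::write_json(
    list(parent = sim$truth$parent, prevalence = sim$truth$prevalence,
         purity = sim$truth$purity, sex = sim$truth$sex,
         snvs = sim$truth$snvs),
    file.path(dir, "truth.json"), digits = NA, dataframe = "columns")
  invisible(dir)
}
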
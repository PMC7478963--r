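# Independent oracles used across tests.

# Discrete-population oracle for the forward model: build an explicit
# population of n_cells cells, count mutated and total alleles at the locus.
# rho must be a multiple of 1/n_cells.
population_beta <- function(rho, multiplicity, n_major, n_minor, male,
                            timing, n_cells = 1000) {
  n_mut <- round(rho * n_cells)
  if (timing == "no_cna") {
    alleles_mut_cell <- if (male) 1 else 2
    mutated <- n_mut * 1
    total <- n_mut * alleles_mut_cell +
      (n_cells - n_mut) * alleles_mut_cell
    return(mutated / total)
  }
  per_cell <- if (male) n_major else n_major + n_minor
  normal_per_cell <- if (male) 1 else 2
  mutated <- n_mut * multiplicity
  total <- n_mut * per_cell + (n_cells - n_mut) * normal_per_cell
  mutated / total
}

# Numerical inversion oracle: solve forward_beta(rho) = beta for one
# scenario by bisection on [0, 1].
solve_rho <- function(beta, multiplicity, n_major, n_minor, male, timing) {
  f <- function(r) {
    forward_beta(r, multiplicity, n_major, n_minor, male, timing) - beta
  }
  if (f(0) > 0 || f(1) < 0) return(NA_real_)   # no solution in [0, 1]
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

# Brute-force simplex grid search oracle for the mixture log-likelihood.
grid_loglik <- function(L, res = 0.01) {
  C <- ncol(L)
  stopifnot(C %in% c(2, 3))
  best <- -Inf
  ws <- seq(0, 1, by = res)
  if (C == 2) {
    for (w1 in ws) {
      ll <- sum(log(L %*% c(w1, 1 - w1)))
      if (is.finite(ll) && ll > best) best <- ll
    }
  } else {
    for (w1 in ws) for (w2 in seq(0, 1 - w1, by = res)) {
      ll <- sum(log(L %*% c(w1, w2, 1 - w1 - w2)))
      if (is.finite(ll) && ll > best) best <- ll
    }
  }
  best
}

# Brute-force tree count: all parent functions on C labelled nodes with
# node 1 as root, acyclic, ordering rule (parent has larger peak) and
# non-negative own fractions.
brute_tree_count <- function(peaks) {
  C <- length(peaks)
  if (C == 1) return(1L)
  count <- 0L
  grid <- do.call(expand.grid, rep(list(seq_len(C)), C - 1))
  for (i in seq_len(nrow(grid))) {
    parent <- c(0L, as.integer(unlist(grid[i, ])))
    # acyclicity: walk up from each node
    ok <- TRUE
    for (j in 2:C) {
      seen <- integer(0)
      p <- j
      while (p != 0L) {
        if (p %in% seen) { ok <- FALSE; break }
        seen <- c(seen, p)
        p <- parent[p]
      }
      if (!ok) break
    }
    if (!ok) next
    # ordering rule
    for (j in 2:C) {
      if (peaks[parent[j]] < peaks[j]) { ok <- FALSE; break }
    }
    if (!ok) next
    phi <- peaks
    for (j in 2:C) phi[parent[j]] <- phi[parent[j]] - peaks[j]
    if (all(phi >= -1e-9)) count <- count + 1L
  }
  count
}

# Small literal SNV / CNA tables for io tests.
snv_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], pos = as.integer(r[[2]]),
               ref_count = as.integer(r[[3]]), alt_count = as.integer(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

cna_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), major = as.integer(r[[4]]),
               minor = as.integer(r[[5]]), stringsAsFactors = FALSE)
  }))
}

# Random truth record (prediction layout) for metric identity tests.
random_truth <- function(seed) {
  set.seed(seed)
  C <- sample(1:4, 1)
  sim <- simulate_tumor(n_subclones = C, purity = runif(1, 0.55, 1),
                        n_snvs = 60, mean_depth = 80,
                        min_prevalence_gap = 0.1,
                        cna_fraction = sample(c(0, 0.2), 1),
                        min_clone_snvs = 5, seed = seed + 10000)
  sim$truth
}
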
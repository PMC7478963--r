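test_that("the simulator is byte-identical under a fixed seed", {
  s1 <- simulate_tumor(n_subclones = 3, n_snvs = 200, cna_fraction = 0.3,
                       min_clone_snvs = 10, seed = 77)
  s2 <- simulate_tumor(n_subclones = 3, n_snvs = 200, cna_fraction = 0.3,
                       min_clone_snvs = 10, seed = 77)
  expect_identical(s1, s2)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("a clonal tumor has the expected mean VAF", {
  sim <- simulate_tumor(n_subclones = 1, purity = 0.6, n_snvs = 2000,
                        mean_depth = 100, cna_fraction = 0, seed = 123)
  # beta = rho/2 = 0.3; 3 standard errors of the mean of 2000 binomials
  se <- sqrt(0.3 * 0.7 / 100 / 2000)
  expect_lt(abs(mean(sim$snv$beta) - 0.3), 3 * se)
  expect_equal(unique(sim$truth$snvs$prevalence), 0.6)
})

test_that("a pure clonal tumor without CNA has expected beta exactly 0.5", {
  sim <- simulate_tumor(n_subclones = 1, purity = 1, n_snvs = 100,
                        cna_fraction = 0, seed = 5)
  expect_equal(unique(sim$truth$snvs$expected_beta), 0.5)
})

test_that("tree and clone structure honour the generative constraints", {
  for (seed in 1:10) {
    sim <- simulate_tumor(n_subclones = 4, purity = 0.9, n_snvs = 400,
                          min_prevalence_gap = 0.1, min_clone_snvs = 20,
                          cna_fraction = 0.2, seed = seed)
    rho <- sim$truth$prevalence
    expect_equal(rho[1], 0.9)                       # root = purity
    expect_true(all(diff(rho) < 0))                 # sorted decreasing
    expect_gte(min(abs(outer(rho, rho, "-")[lower.tri(diag(4))])), 0.1)
    # children sums within parents
    phi <- rho
    for (j in 2:4) phi[sim$truth$parent[j]] <-
        phi[sim$truth$parent[j]] - rho[j]
    expect_true(all(phi >= -1e-9))
    expect_true(all(table(factor(sim$truth$snvs$clone, 1:4)) >= 20))
  }
})

test_that("infeasible configurations are rejected up front", {
  expect_error(simulate_tumor(n_subclones = 8, purity = 0.6,
                              min_prevalence_gap = 0.1, n_snvs = 100,
                              min_clone_snvs = 1),
               "infeasible")
})

test_that("noise-free forward/inverse consistency off multistate segments", {
  sim <- simulate_tumor(n_subclones = 3, purity = 0.85, n_snvs = 300,
                        cna_fraction = 0.4, multistate_fraction = 0.3,
                        min_clone_snvs = 20, seed = 99)
  ms <- unique(sim$cna$segment_id[sim$cna$multistate])
  tr <- sim$truth$snvs
  state_sets <- split(sim$cna[, c("major", "minor")], sim$cna$segment_id)
  for (k in seq_len(nrow(tr))) {
    if (!is.na(tr$segment_id[k]) && tr$segment_id[k] %in% ms) next
    st <- if (is.na(tr$segment_id[k])) NULL else state_sets[[tr$segment_id[k]]]
    cand <- candidate_rhos(tr$expected_beta[k], st,
                           male = sim$snv$male_sex_chrom[k])
    expect_true(any(abs(cand$rho - tr$prevalence[k]) < 1e-9),
                info = paste("snv", k))
  }
})

test_that("male simulations use the haploid model on X", {
  sim <- simulate_tumor(n_subclones = 1, purity = 0.5, n_snvs = 3000,
                        cna_fraction = 0, sex = "male", seed = 8)
  on_x <- sim$snv$male_sex_chrom
  expect_gt(sum(on_x), 0)
  expect_equal(unique(sim$truth$snvs$expected_beta[on_x]), 0.5)   # rho
  expect_equal(unique(sim$truth$snvs$expected_beta[!on_x]), 0.25) # rho/2
})

test_that("truth re-encoding preserves structure and self-scores 1", {
  truth <- random_truth(17)
  pred <- truth_to_prediction(truth)
  expect_equal(length(pred$peaks), length(truth$prevalence))
  expect_equal(dim(pred$P), c(nrow(truth$snvs), length(truth$prevalence)))
  expect_equal(rowSums(pred$P), rep(1, nrow(truth$snvs)))
  expect_equal(ancestor_matrix(pred$parent),
               ancestor_matrix(list(parent = truth$parent)))
  scores <- suppressWarnings(score_all(pred, pred))
  expect_equal(unname(unlist(scores)), rep(1, 5))
})
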
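test_that("expected allele-frequency candidates match the worked cases", {
  # rho 0.5 on (2,1): major mult-2 -> 0.4; minor mult-1 and after -> 0.2
  cand <- expected_beta_candidates(0.5, data.frame(major = 2L, minor = 1L))
  expect_setequal(round(cand$beta_hat, 12), c(0.4, 0.2))

  # clonal heterozygous SNV, no CNA
  expect_equal(expected_beta_candidates(1.0)$beta_hat, 0.5)
  expect_equal(expected_beta_candidates(0.8, male = TRUE)$beta_hat, 0.8)

  # minor-allele deletion: minor scenarios absent
  cand <- expected_beta_candidates(0.5, data.frame(major = 2L, minor = 0L))
  expect_setequal(round(cand$beta_hat, 12), c(0.5, 0.25))
  expect_false("minor_with_cna" %in% cand$scenario)

  # candidates agree with the forward model
  for (i in seq_len(nrow(cand))) {
    timing <- if (cand$scenario[i] == "after_cna") "after" else "major"
    expect_equal(cand$beta_hat[i],
                 forward_beta(0.5, cand$multiplicity[i], 2, 0,
                              timing = timing), tolerance = 1e-12)
  }
})

test_that("male X/Y candidates use the haploid denominator", {
  cand <- expected_beta_candidates(0.5, data.frame(major = 2L, minor = 0L),
                                   male = TRUE)
  den <- 2 * 0.5 + (1 - 0.5)
  expect_setequal(round(cand$beta_hat, 12),
                  round(c(0.5 / den, 2 * 0.5 / den), 12))
})

test_that("binomial likelihood is the exact pmf with 0^0 = 1", {
  expect_equal(binomial_likelihood(5, 10, 0.5), 252 / 1024)
  expect_equal(binomial_likelihood(0, 10, 0), 1)
  expect_equal(binomial_likelihood(3, 10, 0.3),
               choose(10, 3) * 0.3^3 * 0.7^7)
  expect_error(binomial_likelihood(11, 10, 0.5), "m <= r")
  expect_error(binomial_likelihood(1, 10, 1.5), "beta_hat")
})

test_that("best_likelihood picks the scenario maximising the pmf", {
  b1 <- best_likelihood(40, 100, 0.8)
  expect_equal(b1$beta_hat, 0.4)
  expect_equal(b1$likelihood, dbinom(40, 100, 0.4))
  b2 <- best_likelihood(40, 100, 0.2)
  expect_equal(b2$beta_hat, 0.1)
  expect_lt(b2$likelihood, b1$likelihood)
  # deleted minor allele: only major/after candidates compete
  b3 <- best_likelihood(50, 100, 0.5,
                        data.frame(major = 2L, minor = 0L))
  expect_equal(b3$beta_hat, 0.5)
  expect_equal(b3$scenario, "major_with_cna")
})

test_that("EM weight fitting handles the worked degenerate cases", {
  L <- matrix(c(0.2, 0.2, 0.5, 0.5, 0.2, 0.2, 0.5, 0.5), ncol = 2)
  fw <- fit_weights(L)
  expect_equal(fw$weights, c(0.5, 0.5), tolerance = 1e-6)

  L2 <- cbind(runif(10, 0.1, 0.9), 0)
  fw2 <- fit_weights(L2)
  expect_equal(fw2$weights, c(1, 0), tolerance = 1e-9)

  # near-disjoint support split 70/30
  set.seed(3)
  L3 <- rbind(cbind(runif(70, 0.4, 0.6), runif(70, 0, 1e-12)),
              cbind(runif(30, 0, 1e-12), runif(30, 0.4, 0.6)))
  fw3 <- fit_weights(L3)
  expect_equal(fw3$weights, c(0.7, 0.3), tolerance = 0.01)
})

test_that("EM reaches the simplex-grid optimum on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- matrix(runif(60, 0.01, 1), nrow = 20, ncol = 3)
    fw <- fit_weights(L)
    expect_gte(fw$logLik, grid_loglik(L) - 1e-3)
  }
})

test_that("the EM log-likelihood is non-decreasing across iterations", {
  set.seed(9)
  L <- matrix(runif(90, 0.001, 1), ncol = 3)
  lls <- numeric(0)
  w <- rep(1 / 3, 3)
  for (it in 1:50) {
    num <- sweep(L, 2, w, `*`)
    den <- rowSums(num)
    lls <- c(lls, sum(log(den)))
    w <- colMeans(num / den)
  }
  expect_true(all(diff(lls) >= -1e-12))
  # the converged fit can only improve on any truncated iteration path
  expect_gte(fit_weights(L)$logLik, max(lls) - 1e-9)
})

test_that("zero-likelihood SNVs are dropped with a warning", {
  L <- rbind(c(0.5, 0.2), c(0, 0), c(0.1, 0.4))
  expect_warning(fw <- fit_weights(L), "zero likelihood")
  expect_equal(sum(fw$used), 2)
})

test_that("assignment posteriors are normalised and row-scale invariant", {
  set.seed(21)
  sim <- simulate_tumor(n_subclones = 2, purity = 0.8, n_snvs = 300,
                        min_prevalence_gap = 0.4, cna_fraction = 0.2,
                        seed = 31)
  asg <- assign_all(sim$snv, c(0.8, 0.4), sim$cna)
  expect_equal(rowSums(asg$P), rep(1, 300), tolerance = 1e-9)
  expect_equal(asg$hard_label, max.col(asg$P, ties.method = "first"))
  expect_equal(sum(asg$snv_support), 300)
  expect_equal(sum(asg$weights), 1, tolerance = 1e-9)

  # scaling a row of L leaves its posterior unchanged
  L <- asg$L
  P1 <- L[7, ] * asg$weights / sum(L[7, ] * asg$weights)
  L7 <- L[7, ] * 1000
  P2 <- L7 * asg$weights / sum(L7 * asg$weights)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("worked assignment cases go to the correct subclone", {
  snv <- read_snv_table(snv_df(list("chr1", 100, 60, 40)))
  asg <- assign_all(snv, c(0.8, 0.2), weights = c(0.5, 0.5))
  expect_equal(asg$hard_label, 1L)
  # single subclone: the whole posterior collapses onto it
  asg1 <- assign_all(snv, 0.8, weights = 1)
  expect_equal(asg1$P, matrix(1, 1, 1))
  # a zero-weight subclone gets no assignments
  asg0 <- assign_all(snv, c(0.8, 0.2), weights = c(1, 0))
  expect_equal(asg0$P[1, 2], 0)
})
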
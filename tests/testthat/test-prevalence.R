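test_that("forward model matches a discrete cell-population count", {
  expect_equal(forward_beta(0.6, timing = "no_cna"), 0.3)
  expect_equal(forward_beta(0.5, 2, 2, 1, timing = "major"), 0.4)
  expect_equal(forward_beta(1.0, 1, 2, male = TRUE, timing = "major"), 0.5)

  cases <- expand.grid(rho = c(0.2, 0.5, 0.9), n_major = 1:3, mult = 1:3,
                       male = c(FALSE, TRUE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    if (cs$mult > cs$n_major) next
    n_minor <- if (cs$male) 0L else 1L
    got <- forward_beta(cs$rho, cs$mult, cs$n_major, n_minor,
                        male = cs$male, timing = "major")
    want <- population_beta(cs$rho, cs$mult, cs$n_major, n_minor,
                            cs$male, "major")
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("forward model rejects inconsistent arguments", {
  expect_error(forward_beta(1.2, timing = "no_cna"), "rho")
  expect_error(forward_beta(0.5, 2, timing = "no_cna"), "multiplicity")
  expect_error(forward_beta(0.5, 2, n_major = 3, n_minor = 1,
                            timing = "after"), "multiplicity")
  expect_error(forward_beta(0.5, 1, n_major = 2, male = TRUE,
                            timing = "minor"), "male")
})

test_that("scenario inversion recovers the worked candidate sets", {
  # beta 0.4 on a (2,1) segment: only the multiplicity-2 major scenario
  # stays below prevalence 1
  cand <- candidate_rhos(0.4, data.frame(major = 2L, minor = 1L))
  expect_equal(sort(cand$rho), 0.5)
  expect_equal(cand$multiplicity[abs(cand$rho - 0.5) < 1e-9], 2L)

  # beta 0.25 on (3,1): major multiplicities 1,2,3 -> 1, 1/3, 0.2
  cand <- candidate_rhos(0.25, data.frame(major = 3L, minor = 1L))
  expect_equal(sort(cand$rho), sort(c(1, 1 / 3, 0.2)), tolerance = 1e-12)

  # male Y, beta 0.5 on N_major 2: 1 and 1/3
  cand <- candidate_rhos(0.5, data.frame(major = 2L, minor = 0L),
                         male = TRUE)
  expect_equal(sort(cand$rho), sort(c(1, 1 / 3)), tolerance = 1e-12)

  # matches numerical inversion of the forward model, scenario by scenario
  for (m in 1:3) {
    want <- solve_rho(0.25, m, 3, 1, FALSE, "major")
    expect_equal(sort(candidate_rhos(0.25, data.frame(major = 3L, minor = 1L))$rho),
                 sort(c(1, 1 / 3, 0.2)), tolerance = 1e-9)
    expect_true(any(abs(candidate_rhos(0.25,
      data.frame(major = 3L, minor = 1L))$rho - want) < 1e-9))
  }
})

test_that("no-CNA and degenerate inputs invert as stated", {
  expect_equal(candidate_rhos(0.3)$rho, 0.6)
  expect_equal(candidate_rhos(0.3, male = TRUE)$rho, 0.3)
  expect_equal(candidate_rhos(0)$rho, 0)
  # beta > 0.5 without CNA implies rho > 1: discarded, empty set
  expect_equal(nrow(candidate_rhos(0.8)), 0)
  # homozygous deletion state yields no scenarios
  expect_equal(nrow(candidate_rhos(0.4, data.frame(major = 0L, minor = 0L))), 0)
})

test_that("inversion round trip holds on a grid of scenarios", {
  rhos <- seq(0.05, 1, by = 0.05)
  for (n_major in 1:4) for (n_minor in 0:n_major) {
    states <- data.frame(major = n_major, minor = n_minor)
    for (timing in c("major", "minor", "after")) {
      cap <- switch(timing, major = n_major, minor = n_minor, after = 1L)
      if (cap < 1) next
      for (mult in seq_len(cap)) {
        for (rho in rhos) {
          beta <- forward_beta(rho, mult, n_major, n_minor, FALSE, timing)
          cand <- candidate_rhos(beta, states)
          expect_true(any(abs(cand$rho - rho) < 1e-9),
                      info = sprintf("rho=%g mult=%d (%d,%d) %s",
                                     rho, mult, n_major, n_minor, timing))
        }
      }
    }
  }
})

test_that("candidates are monotone in beta and never leave [0, 1]", {
  states <- data.frame(major = 3L, minor = 2L)
  betas <- seq(0.01, 0.99, by = 0.01)
  prev <- -Inf
  for (b in betas) {
    cand <- candidate_rhos(b, states)
    expect_true(all(cand$rho >= 0 & cand$rho <= 1))
    m2 <- cand$rho[cand$multiplicity == 2 & cand$scenario == "major_with_cna"]
    if (length(m2) == 1) {
      expect_gt(m2, prev)
      prev <- m2
    }
  }
})

test_that("enumerate_candidates ties candidates to segments and flags multistate", {
  snv <- read_snv_table(snv_df(list("chr1", 100, 60, 40),
                               list("chr2", 500, 70, 30),
                               list("chr3", 10, 80, 20)))
  seg <- read_cna_segments(cna_df(list("chr2", 0, 1000, 2, 1),
                                  list("chr3", 0, 1000, 2, 1),
                                  list("chr3", 0, 1000, 3, 0)))
  cand <- enumerate_candidates(snv, seg)
  expect_setequal(unique(cand$snv_id), snv$id)
  expect_true(all(cand$multistate[cand$snv_id == "chr3:10"]))
  expect_false(any(cand$multistate[cand$snv_id != "chr3:10"]))
  expect_false(any(cand$has_cna[cand$snv_id == "chr1:100"]))
})
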
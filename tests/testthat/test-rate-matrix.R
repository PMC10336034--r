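test_that("rate matrix entries follow the multi-hit factorization", {
  gc <- genetic_code()
  theta <- nucleotide_bias(0.6, 1.4, 0.3, 1.8, 0.7)
  pi <- positional_frequencies(matrix(runif(12, 0.1, 0.4), 3, 4))
  omega <- 0.42
  mh <- mh_rates(0.3, 0.11)
  q <- build_rate_matrix(theta, pi, omega, mh)
  sense <- gc$sense_codons

  # one-step nonsynonymous: q(ACT -> AGT) = omega * theta_CG * pi2(G)
  expect_equal(q["ACT", "AGT"],
               omega * theta[["CG"]] * unclass(pi)[2, "G"])
  # three-step synonymous Ser -> Ser carries psi but NO omega factor
  expect_equal(q["TCA", "AGT"],
               mh$psi * theta[["AT"]] * theta[["CG"]] * theta[["AT"]] *
                 unclass(pi)[1, "A"] * unclass(pi)[2, "G"] *
                 unclass(pi)[3, "T"])
  # rows sum to zero; off-diagonals nonnegative
  expect_equal(unname(rowSums(q)), rep(0, 61), tolerance = 1e-12)
  offdiag <- unclass(q); diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
})

test_that("multi-hit rates at zero recover the single-hit matrix exactly", {
  theta <- nucleotide_bias(0.5, 1.2, 0.8, 2, 0.9)
  pi <- positional_frequencies()
  q0 <- build_rate_matrix(theta, pi, 0.7, mh_rates(0, 0))
  tabs <- codon_tables(genetic_code())
  expect_true(all(unclass(q0)[tabs$n_diff >= 2] == 0))
  q1 <- build_rate_matrix(theta, pi, 0.7, mh_rates(0.5, 0.5))
  expect_identical(unclass(q0)[tabs$n_diff == 1],
                   unclass(q1)[tabs$n_diff == 1])
})

test_that("the positional-product distribution is stationary and the chain
          reversible for random parameter draws", {
  set.seed(19)
  for (i in 1:10) {
    theta <- nucleotide_bias(runif(1, .2, 3), runif(1, .2, 3),
                             runif(1, .2, 3), runif(1, .2, 3),
                             runif(1, .2, 3))
    pi <- positional_frequencies(matrix(runif(12, 0.05, 0.5), 3, 4))
    q <- build_rate_matrix(theta, pi, runif(1, 0, 3),
                           mh_rates(runif(1, 0, 1), runif(1, 0, 1)))
    pic <- codon_frequencies(pi)
    expect_lt(max(abs(pic %*% unclass(q))), 1e-14)
    flux <- unclass(q) * pic  # pi_i q_ij (rows scaled by source freq)
    expect_lt(max(abs(flux - t(flux))), 1e-15)
  }
})

test_that("invalid rate parameters are rejected", {
  pi <- positional_frequencies()
  expect_error(build_rate_matrix(nucleotide_bias(), pi, -0.1),
               "nonnegative")
  expect_error(mh_rates(-0.2, 0), "nonnegative")
  expect_error(mh_rates(0, -1), "nonnegative")
})

test_that("branch-length decomposition matches its flux definition and is
          scale invariant", {
  og <- null_omega_mix()
  theta <- hky_bias(2)
  pi <- positional_frequencies()
  d <- branch_length_decomposition(theta, pi, og, mh_rates(0.4, 0.2))
  # independent tally: average source-weighted flux by hit class (equal to
  # the printed target-weighted form under reversibility)
  tabs <- codon_tables(genetic_code())
  pic <- codon_frequencies(pi)
  B <- B2 <- B3 <- 0
  for (k in 1:3) {
    q <- unclass(build_rate_matrix(theta, pi, og$omegas[k],
                                   mh_rates(0.4, 0.2)))
    flux <- q * pic
    diag(flux) <- 0
    B <- B + og$weights[k] * sum(flux)
    B2 <- B2 + og$weights[k] * sum(flux[tabs$n_diff == 2])
    B3 <- B3 + og$weights[k] * sum(flux[tabs$n_diff == 3])
  }
  expect_equal(d$B, B)
  expect_equal(d$frac2H, B2 / B)
  expect_equal(d$frac3H, B3 / B)
})

test_that("no multi-hit flux without multi-hit rates, and 2H flux grows
          with delta", {
  og <- null_omega_mix()
  d0 <- branch_length_decomposition(hky_bias(2), positional_frequencies(),
                                    og, mh_rates(0, 0))
  expect_identical(d0$frac2H, 0)
  expect_identical(d0$frac3H, 0)
  fr <- vapply(seq(0.1, 1, by = 0.1), function(dl) {
    branch_length_decomposition(hky_bias(2), positional_frequencies(),
                                og, mh_rates(dl, 0))$frac2H
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("HKY embedding reproduces kappa-ratio behavior", {
  th <- hky_bias(2)
  expect_equal(th[["AG"]], 1)
  expect_equal(th[["CT"]], 1)
  expect_equal(unname(th[c("AC", "AT", "CG", "GT")]), rep(0.5, 4))
})
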
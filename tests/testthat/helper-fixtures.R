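# Shared fixtures built in code.  Heavyweight objects are memoized within a
# test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# a small random codon alignment on 4 taxa (no shared ancestry; used for
# machinery tests, not for fitting)
random_tiny_alignment <- function(n_sites = 3, seed = 42) {
  set.seed(seed)
  gc <- genetic_code()
  seqs <- vapply(1:4, function(i) {
    paste(sample(gc$sense_codons, n_sites, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- c("a", "b", "c", "d")
  codon_alignment(seqs)
}

quartet_tree <- function(text = "((a:0.1,b:0.2):0.15,c:0.3,d:0.05);") {
  read_tree(text)
}

random_params <- function(seed = 1, K = 2, L = 2, delta = 0.3,
                          psi = 0.15) {
  set.seed(seed)
  pi <- matrix(runif(12, 0.1, 0.4), 3, 4)
  model_parameters(
    theta = nucleotide_bias(runif(1, 0.3, 2), runif(1, 0.3, 2),
                            runif(1, 0.3, 2), runif(1, 0.3, 2),
                            runif(1, 0.3, 2)),
    pi = positional_frequencies(pi),
    omega_grid = omega_grid(sort(c(runif(K - 1, 0, 1),
                                   runif(1, 1, 4))),
                            runif(K, 0.2, 1)),
    alpha_grid = alpha_grid(sort(runif(L, 0.2, 2.5)), runif(L, 0.2, 1)),
    mh = mh_rates(delta, psi)
  )
}

# an independent brute-force likelihood for the quartet topology
# ((a,b),c,d): explicit summation over internal-node codon states, all
# per-branch omega categories and per-site alpha categories, with
# transition matrices from Matrix::expm on the R-side generator.
brute_force_loglik <- function(aln, tree, params) {
  gc <- genetic_code()
  pic <- codon_frequencies(params$pi)
  C <- bustedmh:::.flux_constant(params$theta, params$pi,
                                 params$omega_grid, params$mh)
  s <- 3 / C
  Qs <- lapply(params$omega_grid$omegas, function(o) {
    unclass(build_rate_matrix(params$theta, params$pi, o, params$mh)) * s
  })
  tp <- bustedmh:::.prep_tree(tree, aln)
  edge <- tp$edge
  tl <- tp$t
  E <- nrow(edge)
  K <- length(Qs)
  wk <- params$omega_grid$weights
  states <- aln$states[match(tp$tree$tip.label, aln$names), , drop = FALSE]
  n_tips <- tp$n_tips
  internal <- sort(setdiff(unique(as.vector(edge)), seq_len(n_tips)))
  stopifnot(length(internal) == 2)  # quartet only
  root <- tp$root
  other <- setdiff(internal, root)
  # explicit summation over the two internal-node codon assignments:
  # lik = sum_{nr} pic[nr] * f_root[nr] * sum_{no} M_int[nr, no] *
  #       f_other[no], with f_* the products of leaf-edge transition
  # probabilities hanging off each internal node.
  # transition matrices per (omega category, edge, alpha category)
  L <- length(params$alpha_grid$alphas)
  Mtab <- array(list(), c(K, E, L))
  for (k in seq_len(K)) for (e in seq_len(E)) for (l in seq_len(L)) {
    Mtab[[k, e, l]] <- as.matrix(Matrix::expm(
      Qs[[k]] * params$alpha_grid$alphas[l] * tl[e]))
  }
  site_lik_one <- function(site, l_cat, ks) {
    Ms <- lapply(seq_len(E), function(e) Mtab[[ks[e], e, l_cat]])
    f_root <- rep(1, 61)
    f_other <- rep(1, 61)
    M_int <- NULL
    for (e in seq_len(E)) {
      par <- edge[e, 1]; ch <- edge[e, 2]
      if (ch <= n_tips) {
        if (par == root) {
          f_root <- f_root * Ms[[e]][, states[ch, site]]
        } else {
          f_other <- f_other * Ms[[e]][, states[ch, site]]
        }
      } else {
        M_int <- Ms[[e]]  # the internal edge root -> other
      }
    }
    sum(pic * f_root * as.vector(M_int %*% f_other))
  }
  combos <- as.matrix(expand.grid(rep(list(seq_len(K)), E)))
  fl <- params$alpha_grid$weights
  total <- 0
  for (site in seq_len(aln$n_sites)) {
    site_lik <- 0
    for (l in seq_len(L)) {
      mix <- 0
      for (r in seq_len(nrow(combos))) {
        ks <- combos[r, ]
        mix <- mix + prod(wk[ks]) * site_lik_one(site, l, ks)
      }
      site_lik <- site_lik + fl[l] * mix
    }
    total <- total + log(site_lik)
  }
  total
}

null_omega_mix <- function() omega_grid(c(0.1, 0.5, 1.0),
                                        c(0.5, 0.25, 0.25))

# a busted_fit-shaped object at fixed (not estimated) parameters, for
# exercising the diagnostics contracts deterministically
pseudo_fit <- function(aln, tree, params, config = model_config("BUSTED")) {
  keep <- intersect(c("theta", "pi", "omega_grid", "alpha_grid", "mh",
                      "strict_nonsyn_psi"), names(params))
  params <- params[keep]
  prep <- bustedmh:::.ll_prep(aln, tree)
  structure(list(
    config = config, constrained = FALSE,
    mle = c(params, list(branch_lengths = prep$tp$t)),
    lnL = log_likelihood(aln, tree, params)$lnL,
    prep = prep), class = "busted_fit")
}

grid_ctl <- function() bustedmh:::.grid_fit_control()
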
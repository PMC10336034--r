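#' Model parameter bundles
#'
#' A convenience constructor collecting everything the likelihood needs
#' besides data: nucleotide biases, positional frequencies, the omega and
#' alpha mixtures and the multiple-hit rates.
#'
#' @param theta A [nucleotide_bias()].
#' @param pi A [positional_frequencies()].
#' @param omega_grid An [omega_grid()].
#' @param alpha_grid An [alpha_grid()] (defaults to the degenerate
#'   unit-rate mixture, i.e. no synonymous rate variation).
#' @param mh An [mh_rates()].
#' @export
model_parameters <- function(theta = nucleotide_bias(),
                             pi = positional_frequencies(),
                             omega_grid,
                             alpha_grid = bustedmh::alpha_grid(1, 1),
                             mh = mh_rates(0, 0)) {
  stopifnot(inherits(omega_grid, "omega_grid"),
            inherits(alpha_grid, "alpha_grid"), inherits(mh, "mh_rates"))
  list(theta = nucleotide_bias(theta[1], theta[3], theta[4], theta[5],
                               theta[6]),
       pi = positional_frequencies(pi), omega_grid = omega_grid,
       alpha_grid = alpha_grid, mh = mh)
}

# Constant per-(alignment, tree) preparation for the likelihood core.
.ll_prep <- function(aln, tree, code = aln$code) {
  tp <- .prep_tree(tree, aln)
  tabs <- codon_tables(code)
  ord <- match(tp$tree$tip.label, aln$names)
  pat <- aln$patterns
  ls <- t(pat$states[ord, , drop = FALSE]) - 1L
  ls[is.na(ls)] <- -1L
  storage.mode(ls) <- "integer"
  la <- t(pat$amb_key[ord, , drop = FALSE]) - 1L
  storage.mode(la) <- "integer"
  prep <- list(
    tp = tp, tabs = tabs, code = code,
    leaf_states0 = ls, leaf_amb0 = la,
    amb_partials = aln$amb_partials,
    weights = pat$weights,
    site_to_pattern = pat$site_to_pattern,
    n_seq = nrow(aln$states), n_sites = aln$n_sites,
    cache = new.env(parent = emptyenv())
  )
  prep
}

# Products of target positional frequencies per codon pair (fixed while pi
# is fixed, which is the case throughout one fit).
.pair_pi_prod <- function(prep, pi) {
  key <- paste(signif(as.numeric(pi), 15), collapse = ",")
  hit <- prep$cache$pi_key
  if (!is.null(hit) && hit == key) {
    return(list(pi_prod = prep$cache$pi_prod,
                pi_codon = prep$cache$pi_codon))
  }
  pr <- prep$tabs$pairs
  pi_prod <- rep(1, length(pr$i))
  for (q in 1:3) {
    has <- pr$pos[, q] > 0
    pi_prod[has] <- pi_prod[has] *
      pi[cbind(pr$pos[has, q], pr$target_nt[has, q])]
  }
  pi_codon <- codon_frequencies(pi, prep$code)
  prep$cache$pi_key <- key
  prep$cache$pi_prod <- pi_prod
  prep$cache$pi_codon <- pi_codon
  list(pi_prod = pi_prod, pi_codon = pi_codon)
}

# Low-level call into the C++ pruning core.  branch_p overrides the
# per-branch omega mixture weights (rows = edges in postorder); t overrides
# branch lengths; s_fixed freezes the generator scaling (used during
# optimization, where a free tree-scale parameter absorbs the
# reparameterization).
.core_call <- function(prep, params, branch_p = NULL, t = NULL,
                       s_fixed = -1) {
  pr <- prep$tabs$pairs
  pp <- .pair_pi_prod(prep, params$pi)
  K <- length(params$omega_grid$omegas)
  E <- nrow(prep$tp$edge)
  if (is.null(branch_p)) {
    branch_p <- matrix(params$omega_grid$weights, E, K, byrow = TRUE)
  }
  if (is.null(t)) t <- prep$tp$t
  cpp_site_loglik(
    pair_i = pr$i, pair_j = pr$j, pair_nd = pr$nd,
    pair_nonsyn = as.integer(pr$nonsyn),
    pair_theta_idx = pr$theta_idx, pair_pi_prod = pp$pi_prod,
    theta = as.numeric(params$theta), omegas = params$omega_grid$omegas,
    p_omega = params$omega_grid$weights, branch_p = branch_p,
    delta = params$mh$delta, psi = params$mh$psi,
    strict_nonsyn_psi = isTRUE(params$strict_nonsyn_psi),
    alphas = params$alpha_grid$alphas,
    pi_codon = pp$pi_codon,
    edge = prep$tp$edge, t_branch = t,
    root = prep$tp$root, n_tips = prep$tp$n_tips,
    n_nodes = prep$tp$n_nodes,
    leaf_states = prep$leaf_states0, leaf_amb = prep$leaf_amb0,
    amb_partials = prep$amb_partials, s_fixed = s_fixed
  )
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning under the branch-site omega mixture and site-level
#' alpha mixture.  The iid branch-site omega draws factorize into
#' per-branch mixture transition matrices; the alpha mixture is summed at
#' the site level with its fitted weights.  The root is closed with the
#' stationary codon distribution, under which the likelihood is
#' root-placement invariant (the model is reversible).
#'
#' @param aln A [codon_alignment()].
#' @param tree An [ape::phylo] with branch lengths in expected
#'   substitutions per nucleotide site.
#' @param params A [model_parameters()] bundle.
#' @return An object of class `site_lik`: a list with `lnL` (total
#'   log-likelihood), `log_site_lik` (unique patterns x alpha categories),
#'   `site_lnL` (per original site), `pattern_weights`,
#'   `site_to_pattern`, `alpha_weights` and `scale` (the generator scaling
#'   constant).
#' @export
log_likelihood <- function(aln, tree, params) {
  prep <- .ll_prep(aln, tree)
  res <- .core_call(prep, params)
  .site_lik(res, prep, params)
}

.site_lik <- function(res, prep, params) {
  lsl <- res$log_site_lik
  fw <- params$alpha_grid$weights
  # log-sum-exp over alpha categories
  m <- apply(lsl, 1, max)
  pat_lnL <- m + log(as.vector(exp(lsl - m) %*% fw))
  if (any(!is.finite(pat_lnL))) {
    bad <- which(!is.finite(pat_lnL))[1]
    site <- which(prep$site_to_pattern == bad)[1]
    stop("non-finite site likelihood at codon site ", site)
  }
  structure(list(
    lnL = sum(prep$weights * pat_lnL),
    log_site_lik = lsl,
    pattern_lnL = pat_lnL,
    site_lnL = pat_lnL[prep$site_to_pattern],
    pattern_weights = prep$weights,
    site_to_pattern = prep$site_to_pattern,
    alpha_weights = fw,
    flux = res$flux, scale = res$scale
  ), class = "site_lik")
}

#' Per-branch mixture transition probability matrix
#'
#' The transition matrix of one branch under the branch-site model:
#' `M = sum_k p_k expm(alpha * Q(omega_k) * s * t)`, where `s` rescales the
#' generator so branch lengths are expected substitutions per nucleotide
#' site under the alignment-wide mixture.  Computed by symmetric
#' eigendecomposition (the model is reversible); rows sum to one.
#'
#' This is a reference implementation in R used for validation; the fitting
#' core computes the same matrices in compiled code.
#'
#' @param params A [model_parameters()] bundle.
#' @param t Branch length (>= 0).
#' @param alpha Synonymous rate multiplier for the site category.
#' @param code A [genetic_code()].
#' @return A 61 x 61 stochastic matrix.
#' @export
mixture_transition_matrix <- function(params, t, alpha = 1,
                                      code = genetic_code()) {
  if (!is.finite(t) || t < 0) stop("branch length must be nonnegative")
  og <- params$omega_grid
  pic <- codon_frequencies(params$pi, code)
  C <- .flux_constant(params$theta, params$pi, og, params$mh, code,
                      isTRUE(params$strict_nonsyn_psi))
  s <- 3 / C
  n <- length(pic)
  M <- matrix(0, n, n)
  sq <- sqrt(pic)
  for (k in seq_along(og$omegas)) {
    q <- build_rate_matrix(params$theta, params$pi, og$omegas[k],
                           params$mh, code,
                           isTRUE(params$strict_nonsyn_psi))
    B <- sweep(sweep(unclass(q), 1, sq, "*"), 2, sq, "/")
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    U <- e$vectors / sq
    W <- sweep(t(e$vectors), 2, sq, "*")
    M <- M + og$weights[k] *
      (U %*% (exp(e$values * s * alpha * t) * W))
  }
  pmax(M, 0)
}
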
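#' Build a multi-hit codon instantaneous rate matrix
#'
#' Constructs the 61 x 61 generator over sense codons.  The rate from codon
#' i to codon j differing at positions n_1..n_d is
#'
#'     q_ij = m_d * (omega if nonsynonymous) * prod_n theta(i_n, j_n) *
#'            prod_n pi^n(j_n)
#'
#' with hit-class multipliers m_1 = 1, m_2 = delta, m_3 = psi.  The
#' site-level synonymous rate alpha enters as a scalar multiplier on the
#' whole generator and is applied by the caller.  The diagonal is set to the
#' negative row sum.  With `delta = psi = 0` this is exactly the classic
#' single-hit MG94-style codon matrix.
#'
#' @param theta A [nucleotide_bias()].
#' @param pi A [positional_frequencies()].
#' @param omega Nonnegative nonsynonymous/synonymous rate ratio.
#' @param mh A [mh_rates()].
#' @param code A [genetic_code()].
#' @param strict_nonsyn_psi If `TRUE`, psi multiplies only nonsynonymous
#'   triple changes (synonymous triple changes are then forbidden).
#' @return A 61 x 61 matrix with class `rate_matrix`; rows sum to zero and
#'   it is reversible with respect to [codon_frequencies()].
#' @export
build_rate_matrix <- function(theta, pi, omega, mh = mh_rates(0, 0),
                              code = genetic_code(),
                              strict_nonsyn_psi = FALSE) {
  if (!is.finite(omega) || omega < 0) stop("omega must be nonnegative")
  stopifnot(inherits(mh, "mh_rates"))
  pi <- positional_frequencies(pi)
  theta <- as.numeric(theta)
  tabs <- codon_tables(code)
  pr <- tabs$pairs
  n <- nrow(tabs$nt_idx)
  rate <- .pair_rates(pr, theta, pi, omega, mh$delta, mh$psi,
                      strict_nonsyn_psi)
  q <- matrix(0, n, n, dimnames = list(code$sense_codons, code$sense_codons))
  q[cbind(pr$i, pr$j)] <- rate
  diag(q) <- -rowSums(q)
  structure(q, class = c("rate_matrix", "matrix"))
}

# Vectorized per-pair rates; `pr` is codon_tables()$pairs.
.pair_rates <- function(pr, theta, pi, omega, delta, psi,
                        strict_nonsyn_psi = FALSE) {
  mult <- c(1, delta, psi)[pr$nd]
  if (strict_nonsyn_psi) mult[pr$nd == 3 & !pr$nonsyn] <- 0
  r <- mult
  r[pr$nonsyn] <- r[pr$nonsyn] * omega
  for (q in 1:3) {
    has <- pr$pos[, q] > 0
    r[has] <- r[has] * theta[pr$theta_idx[has, q]] *
      pi[cbind(pr$pos[has, q], pr$target_nt[has, q])]
  }
  r
}

#' Expected substitution flux and its multi-hit decomposition
#'
#' Computes the standard Markov branch-length quantity B = sum_{i != j}
#' q_ij pi_j together with its restrictions B2H and B3H to codon pairs
#' differing at exactly two or three positions, averaged over the omega
#' mixture.  The unit-mean alpha mixture contributes a factor of one.  The
#' ratios `frac2H = B2H / B` and `frac3H = B3H / B` are the expected
#' fractions of substitutions realized as instantaneous double- and
#' triple-nucleotide changes; they are invariant to rescaling the generator.
#'
#' @param theta A [nucleotide_bias()].
#' @param pi A [positional_frequencies()].
#' @param omega_grid An [omega_grid()] (a single omega value is promoted).
#' @param mh A [mh_rates()].
#' @param code A [genetic_code()].
#' @return A [tibble::tibble()] with columns `B`, `B2H`, `B3H`, `frac2H`,
#'   `frac3H`.
#' @examples
#' branch_length_decomposition(
#'   hky_bias(2), positional_frequencies(),
#'   omega_grid(c(0.1, 0.5, 1.0), c(0.5, 0.25, 0.25)),
#'   mh_rates(delta = 0.25)
#' )
#' @export
branch_length_decomposition <- function(theta, pi, omega_grid,
                                        mh = mh_rates(0, 0),
                                        code = genetic_code()) {
  if (is.numeric(omega_grid)) {
    omega_grid <- omega_grid(omega_grid, rep(1, length(omega_grid)))
  }
  stopifnot(inherits(omega_grid, "omega_grid"))
  pi <- positional_frequencies(pi)
  tabs <- codon_tables(code)
  pr <- tabs$pairs
  pic <- codon_frequencies(pi, code)
  target <- pic[pr$j]
  B <- B2 <- B3 <- 0
  for (k in seq_along(omega_grid$omegas)) {
    rate <- .pair_rates(pr, as.numeric(theta), pi, omega_grid$omegas[k],
                        mh$delta, mh$psi)
    flux <- rate * target
    w <- omega_grid$weights[k]
    B <- B + w * sum(flux)
    B2 <- B2 + w * sum(flux[pr$nd == 2])
    B3 <- B3 + w * sum(flux[pr$nd == 3])
  }
  tibble::tibble(B = B, B2H = B2, B3H = B3,
                 frac2H = if (B > 0) B2 / B else 0,
                 frac3H = if (B > 0) B3 / B else 0)
}

# Alignment-wide scaling constant: expected codon substitutions per unit
# time under the omega mixture at stationarity.  Dividing the generator by
# C/3 expresses branch lengths as expected substitutions per NUCLEOTIDE
# site.
.flux_constant <- function(theta, pi, omega_grid, mh, code = genetic_code(),
                           strict_nonsyn_psi = FALSE) {
  tabs <- codon_tables(code)
  pr <- tabs$pairs
  pic <- codon_frequencies(pi, code)
  target <- pic[pr$j]
  B <- 0
  for (k in seq_along(omega_grid$omegas)) {
    rate <- .pair_rates(pr, as.numeric(theta), pi, omega_grid$omegas[k],
                        mh$delta, mh$psi, strict_nonsyn_psi)
    B <- B + omega_grid$weights[k] * sum(rate * target)
  }
  B
}
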
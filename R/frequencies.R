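#' Positional frequency estimation from codon counts
#'
#' `f3x4()` tallies the observed positional nucleotide marginals of the
#' sense-codon counts (the classic F3x4 estimator).  `cf3x4()` corrects for
#' the exclusion of stop codons: it maximizes the multinomial likelihood of
#' the observed codon counts under the model in which codon frequencies are
#' proportional to the positional product restricted to sense codons.  The
#' correction matters because the raw marginals are biased when stop codons
#' are removed from the state space.
#'
#' @param counts Numeric vector of length 61: observed sense-codon counts in
#'   sense-codon order.
#' @param code A [genetic_code()].
#' @param tol Convergence tolerance on the log-likelihood for `cf3x4()`.
#' @return A [positional_frequencies()] object.
#' @examples
#' gc <- genetic_code()
#' counts <- rep(1, 61)           # uniform over sense codons
#' f3x4(counts)
#' @export
f3x4 <- function(counts, code = genetic_code()) {
  counts <- .check_counts(counts, code)
  tabs <- codon_tables(code)
  pi <- matrix(0, 3, 4)
  for (p in 1:3) {
    for (b in 1:4) pi[p, b] <- sum(counts[tabs$nt_idx[, p] == b])
  }
  positional_frequencies(pi)
}

#' @rdname f3x4
#' @export
cf3x4 <- function(counts, code = genetic_code(), tol = 1e-8) {
  counts <- .check_counts(counts, code)
  tabs <- codon_tables(code)
  nt_idx <- tabs$nt_idx
  # multinomial log-likelihood over sense codons; frequencies as the
  # normalized positional product.  9 free parameters: per-position
  # multinomial logits with the T entry as reference.
  nll <- function(x) {
    pi <- .logits_to_pi(x)
    p <- pi[cbind(1, nt_idx[, 1])] * pi[cbind(2, nt_idx[, 2])] *
      pi[cbind(3, nt_idx[, 3])]
    -(sum(counts * log(p)) - sum(counts) * log(sum(p)))
  }
  start <- log(pmax(unclass(f3x4(counts, code))[, 1:3], 1e-8) /
                 pmax(unclass(f3x4(counts, code))[, 4], 1e-8))
  opt <- stats::optim(as.vector(start), nll, method = "L-BFGS-B",
                      lower = -30, upper = 30,
                      control = list(factr = tol / .Machine$double.eps))
  positional_frequencies(.logits_to_pi(opt$par))
}

.logits_to_pi <- function(x) {
  m <- cbind(matrix(x, 3, 3), 0)
  e <- exp(m)
  e / rowSums(e)
}

.check_counts <- function(counts, code) {
  n <- length(code$sense_codons)
  if (length(counts) != n) stop("counts must have length ", n)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be nonnegative with a positive total")
  }
  as.numeric(counts)
}

#' Sense-codon counts of an alignment
#'
#' Tallies unambiguous codon states across all sequences and sites; partial
#' (ambiguous or gapped) codons are skipped.
#'
#' @param aln A codon alignment (see [read_codon_alignment()]).
#' @return Numeric vector of length 61 in sense-codon order.
#' @export
codon_counts <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  st <- aln$states[!is.na(aln$states)]
  tabulate(st, nbins = length(aln$code$sense_codons))
}
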
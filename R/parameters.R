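#' Nucleotide exchangeability biases
#'
#' The general time-reversible (GTR) nucleotide biases theta over the six
#' unordered nucleotide pairs AC, AG, AT, CG, CT, GT.  The AG rate is the
#' reference and is fixed at 1, leaving five identifiable parameters.
#'
#' @param ac,at,cg,ct,gt Nonnegative rate multipliers relative to AG = 1.
#' @return A named numeric vector of length 6 with class `nucleotide_bias`.
#' @seealso [hky_bias()] for the HKY embedding.
#' @export
nucleotide_bias <- function(ac = 1, at = 1, cg = 1, ct = 1, gt = 1) {
  th <- c(AC = ac, AG = 1, AT = at, CG = cg, CT = ct, GT = gt)
  if (any(!is.finite(th)) || any(th < 0)) {
    stop("nucleotide bias parameters must be nonnegative and finite")
  }
  structure(th, class = "nucleotide_bias")
}

#' HKY-style biases embedded in the GTR parameterization
#'
#' With the AG transition as the unit reference, an HKY model with
#' transition/transversion rate ratio `kappa` sets the CT transition to 1 and
#' all four transversions to `1/kappa`.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @export
hky_bias <- function(kappa = 2) {
  stopifnot(is.numeric(kappa), kappa > 0)
  nucleotide_bias(ac = 1 / kappa, at = 1 / kappa, cg = 1 / kappa,
                  ct = 1, gt = 1 / kappa)
}

#' Positional nucleotide frequencies
#'
#' A 3 x 4 matrix of per-codon-position nucleotide frequencies (rows =
#' positions, columns = A, C, G, T), each row a probability vector.  These
#' parameterize the codon equilibrium distribution as a positional product
#' restricted to sense codons.
#'
#' @param pi A 3 x 4 numeric matrix (or a single probability 4-vector reused
#'   at all positions).  Rows are renormalized to sum to one.
#' @export
positional_frequencies <- function(pi = rep(0.25, 4)) {
  if (is.null(dim(pi))) pi <- matrix(pi, 3, 4, byrow = TRUE)
  pi <- as.matrix(pi)
  if (!all(dim(pi) == c(3, 4))) stop("pi must be 3 positions x 4 nucleotides")
  if (any(pi <= 0)) stop("positional frequencies must be strictly positive")
  pi <- pi / rowSums(pi)
  dimnames(pi) <- list(paste0("pos", 1:3), c("A", "C", "G", "T"))
  structure(pi, class = c("positional_frequencies", "matrix"))
}

#' Stationary codon distribution implied by positional frequencies
#'
#' The positional product distribution restricted to sense codons and
#' renormalized (the CF3x4 stationary distribution).
#'
#' @param pi A [positional_frequencies()] object.
#' @param code A [genetic_code()].
#' @return Numeric vector of length 61 (sense-codon order), summing to 1.
#' @export
codon_frequencies <- function(pi, code = genetic_code()) {
  pi <- positional_frequencies(pi)
  tabs <- codon_tables(code)
  p <- pi[cbind(1, tabs$nt_idx[, 1])] *
    pi[cbind(2, tabs$nt_idx[, 2])] *
    pi[cbind(3, tabs$nt_idx[, 3])]
  p <- p / sum(p)
  names(p) <- code$sense_codons
  p
}

#' Branch-site omega mixture (general discrete distribution)
#'
#' The K-bin general discrete distribution of the nonsynonymous/synonymous
#' rate ratio omega, drawn independently for every branch-site pair.  The
#' alternative selection model orders the grid as
#' 0 <= omega_1 <= ... <= omega_{K-1} <= 1 <= omega_K; the constrained null
#' pins omega_K = 1.
#'
#' @param omegas Nondecreasing nonnegative rate values.
#' @param weights Mixture weights (renormalized to sum to one).
#' @return A list with class `omega_grid`.
#' @export
omega_grid <- function(omegas, weights) {
  stopifnot(length(omegas) == length(weights), length(omegas) >= 1)
  if (any(omegas < 0)) stop("omega values must be nonnegative")
  if (is.unsorted(omegas)) stop("omega values must be nondecreasing")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid omega weights")
  structure(list(omegas = as.numeric(omegas),
                 weights = as.numeric(weights / sum(weights))),
            class = "omega_grid")
}

#' Site-level synonymous rate mixture with unit mean
#'
#' The L-bin general discrete distribution of the site-wise synonymous rate
#' multiplier alpha.  Its mean is constrained to one for identifiability
#' against branch lengths; the constructor rescales the rate values so the
#' constraint holds exactly.
#'
#' @param alphas Nonnegative rate values.
#' @param weights Mixture weights (renormalized).
#' @return A list with class `alpha_grid`; `sum(weights * alphas) == 1` to
#'   machine precision.
#' @export
alpha_grid <- function(alphas = 1, weights = 1) {
  stopifnot(length(alphas) == length(weights), length(alphas) >= 1)
  if (any(alphas < 0)) stop("alpha values must be nonnegative")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid alpha weights")
  weights <- weights / sum(weights)
  m <- sum(weights * alphas)
  if (m <= 0) stop("alpha mixture must have positive mean")
  structure(list(alphas = as.numeric(alphas / m),
                 weights = as.numeric(weights)),
            class = "alpha_grid")
}

#' Multiple-hit substitution rates
#'
#' Alignment-wide relative rates of instantaneous multinucleotide codon
#' changes: `delta` for double-nucleotide (2H) and `psi` for
#' triple-nucleotide (3H) substitutions, both relative to the single-hit
#' synonymous baseline.  `mh_rates(0, 0)` recovers the single-hit model
#' exactly.
#'
#' @param delta,psi Nonnegative rates.
#' @export
mh_rates <- function(delta = 0, psi = 0) {
  if (!is.finite(delta) || !is.finite(psi) || delta < 0 || psi < 0) {
    stop("multiple-hit rates must be nonnegative and finite")
  }
  structure(list(delta = delta, psi = psi), class = "mh_rates")
}

#' Model configurations in the BUSTED hierarchy
#'
#' The four models of the family, plus the intermediate double-hit-only
#' model, are combinations of two switches: site-to-site synonymous rate
#' variation (`srv`) and multiple-hit support (`mh_mode`):
#'
#' * `"BUSTED"`: `srv = FALSE`, `mh_mode = "none"`
#' * `"+S"`:     `srv = TRUE`,  `mh_mode = "none"`
#' * `"+MH"`:    `srv = FALSE`, `mh_mode = "double+triple"`
#' * `"+S+MH"`:  `srv = TRUE`,  `mh_mode = "double+triple"`
#' * `"+S+2H"`:  `srv = TRUE`,  `mh_mode = "double"` (psi fixed at 0)
#'
#' @param model One of the model names above, or `NULL` to use the switches.
#' @param srv Logical; model synonymous rate variation?
#' @param mh_mode One of `"none"`, `"double"`, `"double+triple"`.
#' @param K Number of omega bins (default 3).
#' @param L Number of alpha bins (default 3; ignored when `srv = FALSE`).
#' @param strict_nonsyn_psi Logical; if `TRUE`, the triple-hit rate psi is
#'   applied only to nonsynonymous triple changes (off by default: psi
#'   multiplies all triple changes).
#' @return A list with class `model_config`.
#' @export
model_config <- function(model = NULL, srv = FALSE, mh_mode = "none",
                         K = 3, L = 3, strict_nonsyn_psi = FALSE) {
  if (!is.null(model)) {
    m <- match.arg(model, c("BUSTED", "+S", "+MH", "+S+MH", "+S+2H"))
    srv <- m %in% c("+S", "+S+MH", "+S+2H")
    mh_mode <- switch(m, "BUSTED" = "none", "+S" = "none",
                      "+MH" = "double+triple", "+S+MH" = "double+triple",
                      "+S+2H" = "double")
  }
  mh_mode <- match.arg(mh_mode, c("none", "double", "double+triple"))
  if (K < 1 || L < 1) stop("K and L must be >= 1")
  name <- if (!srv && mh_mode == "none") "BUSTED"
          else if (srv && mh_mode == "none") "+S"
          else if (!srv && mh_mode == "double+triple") "+MH"
          else if (srv && mh_mode == "double+triple") "+S+MH"
          else if (srv && mh_mode == "double") "+S+2H"
          else "+2H"
  structure(list(name = name, srv = srv, mh_mode = mh_mode,
                 K = as.integer(K), L = as.integer(if (srv) L else 1L),
                 strict_nonsyn_psi = isTRUE(strict_nonsyn_psi)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config:", x$name, "| K =", x$K,
      if (x$srv) paste("| L =", x$L) else "| no SRV",
      "| MH =", x$mh_mode, ">\n")
  invisible(x)
}
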
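#' Genetic code tables
#'
#' A genetic code maps the 64 trinucleotides onto amino acids and stops, and
#' fixes the ordering of sense codons used by every rate matrix in the
#' package.  Only the universal (standard) code ships with the package, but
#' the type is table-driven: adding an NCBI translation table is a matter of
#' registering another codon-to-amino-acid map.
#'
#' Sense codons are ordered lexicographically over the alphabet A, C, G, T
#' (AAA, AAC, AAG, ..., TTT with stops removed).  All 61x61 matrices in the
#' package index codons in this order.
#'
#' @param code_id Identifier of the code. Only `"universal"` is available.
#' @return An object of class `genetic_code`: a list with `code_id`,
#'   `codon_to_aa` (named character of length 64, stops as `"*"`),
#'   `sense_codons` (character, length 61 for the universal code) and
#'   `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$stop_codons           # TAA, TAG, TGA
#' @export
genetic_code <- function(code_id = "universal") {
  if (!identical(code_id, "universal")) {
    stop("unknown genetic code: ", code_id)
  }
  .gc_cache(code_id)
}

# Standard (NCBI table 1) amino acids with codons enumerated in lexicographic
# ACGT order: first position slowest, third fastest.
.universal_aa <- paste0(
  "KNKN", "TTTT", "RSRS", "IIMI",  # AAA..ATT block (A--)
  "QHQH", "PPPP", "RRRR", "LLLL",  # C--
  "EDED", "AAAA", "GGGG", "VVVV",  # G--
  "*Y*Y", "SSSS", "*CWC", "LFLF"   # T--
)

.build_genetic_code <- function(code_id) {
  nt <- c("A", "C", "G", "T")
  codons <- as.vector(t(outer(
    as.vector(t(outer(nt, nt, paste0))), nt, paste0
  )))
  # codons above enumerate third position fastest; matches .universal_aa
  aa <- strsplit(.universal_aa, "")[[1]]
  names(aa) <- codons
  ord <- sort(codons)  # lexicographic (identical here, kept for clarity)
  aa <- aa[ord]
  sense <- names(aa)[aa != "*"]
  structure(
    list(
      code_id = code_id,
      codon_to_aa = aa,
      sense_codons = sense,
      stop_codons = names(aa)[aa == "*"]
    ),
    class = "genetic_code"
  )
}

.gc_env <- new.env(parent = emptyenv())
.gc_cache <- function(code_id) {
  if (is.null(.gc_env[[code_id]])) {
    .gc_env[[code_id]] <- .build_genetic_code(code_id)
  }
  .gc_env[[code_id]]
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code:", x$code_id, "|", length(x$sense_codons),
      "sense codons,", length(x$stop_codons), "stops>\n")
  invisible(x)
}

#' Classify a pair of sense codons by hit class
#'
#' Computes the number of differing nucleotide positions (the "hit" count of
#' an instantaneous change between the two codons), which positions differ,
#' and whether the exchange is synonymous under the code.
#'
#' @param codon_i,codon_j Sense codon strings (e.g. `"ACT"`).
#' @param code A [genetic_code()].
#' @return A list with `n_diff` (0-3), `positions` (integer vector of changed
#'   positions) and `synonymous` (logical; `TRUE` for the identity pair).
#' @examples
#' hit_class("TCA", "AGT")  # a three-position synonymous Ser->Ser exchange
#' @export
hit_class <- function(codon_i, codon_j, code = genetic_code()) {
  for (cod in c(codon_i, codon_j)) {
    aa <- code$codon_to_aa[[cod]]
    if (is.null(aa) || is.na(aa)) stop("not a codon: ", cod)
    if (aa == "*") stop("stop codon is not a valid state: ", cod)
  }
  si <- strsplit(codon_i, "")[[1]]
  sj <- strsplit(codon_j, "")[[1]]
  pos <- which(si != sj)
  list(
    n_diff = length(pos),
    positions = pos,
    synonymous = code$codon_to_aa[[codon_i]] == code$codon_to_aa[[codon_j]]
  )
}

# Integer machinery shared by the rate-matrix builder, the likelihood core
# and the simulator.  Everything is precomputed once per genetic code.
#
# Returns a list:
#   nt_idx      61 x 3 integer matrix, nucleotide (1=A..4=T) at each position
#   aa          character(61) translations
#   n_diff      61 x 61 integer Hamming distances
#   synonymous  61 x 61 logical
#   pairs       data frame of ordered pairs i != j with columns
#               i, j, nd, nonsyn, t1..t3 (theta pair index, 0-padded),
#               p1..p3 (changed position, 0-padded), n1..n3 (target nt)
codon_tables <- function(code = genetic_code()) {
  key <- paste0(code$code_id, "_tables")
  if (!is.null(.gc_env[[key]])) return(.gc_env[[key]])
  nt <- c("A", "C", "G", "T")
  sense <- code$sense_codons
  n <- length(sense)
  nt_idx <- t(vapply(strsplit(sense, ""), function(x) match(x, nt),
                     integer(3)))
  aa <- unname(code$codon_to_aa[sense])
  nd <- matrix(0L, n, n)
  for (p in 1:3) nd <- nd + outer(nt_idx[, p], nt_idx[, p], "!=")
  syn <- outer(aa, aa, "==")
  # theta index over unordered nucleotide pairs AC, AG, AT, CG, CT, GT
  pair_idx <- matrix(0L, 4, 4)
  k <- 0L
  for (a in 1:3) for (b in (a + 1):4) {
    k <- k + 1L
    pair_idx[a, b] <- k
    pair_idx[b, a] <- k
  }
  ij <- which(nd > 0, arr.ind = TRUE)
  d <- nd[ij]
  t123 <- matrix(0L, nrow(ij), 3)
  p123 <- matrix(0L, nrow(ij), 3)
  n123 <- matrix(0L, nrow(ij), 3)
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    pos <- which(nt_idx[i, ] != nt_idx[j, ])
    for (q in seq_along(pos)) {
      p <- pos[q]
      t123[r, q] <- pair_idx[nt_idx[i, p], nt_idx[j, p]]
      p123[r, q] <- p
      n123[r, q] <- nt_idx[j, p]
    }
  }
  tabs <- list(
    nt_idx = nt_idx, aa = aa, n_diff = nd, synonymous = syn,
    pairs = list(
      i = ij[, 1], j = ij[, 2], nd = d, nonsyn = !syn[ij],
      theta_idx = t123, pos = p123, target_nt = n123
    ),
    theta_pair_names = c("AC", "AG", "AT", "CG", "CT", "GT")
  )
  .gc_env[[key]] <- tabs
  tabs
}
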
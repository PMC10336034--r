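# IUPAC nucleotide ambiguity sets (indices into A, C, G, T)
.iupac <- list(
  A = 1L, C = 2L, G = 3L, T = 4L, U = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
  K = c(3L, 4L), M = c(1L, 2L),
  B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L),
  V = c(1L, 2L, 3L), N = 1:4, "-" = 1:4, "?" = 1:4
)

#' Construct a codon alignment from character sequences
#'
#' Maps in-frame nucleotide sequences onto sense-codon states.  Unambiguous
#' codons become indices into the sense-codon ordering; codons containing
#' IUPAC ambiguity codes or gaps become partial states (indicator vectors
#' over the compatible sense codons).  Site patterns are compressed: the
#' likelihood is computed once per unique column and weighted by its
#' multiplicity.
#'
#' @param sequences Named character vector of nucleotide sequences (equal
#'   lengths, divisible by 3), or a character matrix with one row per
#'   sequence and one column per nucleotide.
#' @param code A [genetic_code()].
#' @param mask_stops If `TRUE`, codons matching a stop are replaced by fully
#'   missing states instead of raising an error.
#' @return An object of class `codon_alignment` with elements `states`
#'   (n_seq x n_sites integer matrix, `NA` marking partial states),
#'   `amb_key` (parallel matrix of indices into `amb_partials`),
#'   `amb_partials` (61 x n_amb indicator matrix), `n_sites`, `names`,
#'   `patterns` (compressed unique columns and multiplicities) and `code`.
#' @export
codon_alignment <- function(sequences, code = genetic_code(),
                            mask_stops = FALSE) {
  if (is.matrix(sequences)) {
    seq_names <- rownames(sequences)
    seq_chars <- sequences
  } else {
    seq_names <- names(sequences)
    if (is.null(seq_names)) stop("sequences must be named")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1) stop("sequences must have equal length")
    seq_chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  if (anyDuplicated(seq_names)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(seq_names[duplicated(seq_names)]), collapse = ", "))
  }
  n_nt <- ncol(seq_chars)
  if (n_nt %% 3 != 0) {
    stop("alignment length ", n_nt, " is not divisible by 3")
  }
  n_sites <- n_nt %/% 3L
  n_seq <- nrow(seq_chars)
  seq_chars <- toupper(seq_chars)

  sense <- code$sense_codons
  n_state <- length(sense)
  tabs <- codon_tables(code)

  states <- matrix(NA_integer_, n_seq, n_sites)
  amb_key <- matrix(0L, n_seq, n_sites)
  amb_partials <- list()
  amb_index <- new.env(parent = emptyenv())

  nt_of <- function(ch, sq, st) {
    set <- .iupac[[ch]]
    if (is.null(set)) {
      stop("invalid nucleotide '", ch, "' in sequence ", sq, ", codon ", st)
    }
    set
  }
  for (sq in seq_len(n_seq)) {
    for (st in seq_len(n_sites)) {
      cod <- seq_chars[sq, (3 * st - 2):(3 * st)]
      codstr <- paste(cod, collapse = "")
      idx <- match(codstr, sense)
      if (!is.na(idx)) {
        states[sq, st] <- idx
        next
      }
      if (codstr %in% code$stop_codons) {
        if (!mask_stops) {
          stop("in-frame stop codon ", codstr, " in sequence '",
               seq_names[sq], "' at codon ", st,
               " (use mask_stops = TRUE to replace with missing data)")
        }
        codstr <- "---"
        cod <- c("-", "-", "-")
      }
      key <- codstr
      cached <- amb_index[[key]]
      if (is.null(cached)) {
        sets <- lapply(seq_along(cod), function(p) nt_of(cod[p], sq, st))
        compat <- tabs$nt_idx[, 1] %in% sets[[1]] &
          tabs$nt_idx[, 2] %in% sets[[2]] &
          tabs$nt_idx[, 3] %in% sets[[3]]
        if (!any(compat)) {
          stop("codon '", codstr, "' in sequence '", seq_names[sq],
               "' at site ", st, " matches no sense codon")
        }
        amb_partials[[length(amb_partials) + 1L]] <- as.numeric(compat)
        cached <- length(amb_partials)
        amb_index[[key]] <- cached
      }
      amb_key[sq, st] <- cached
    }
  }
  amb_mat <- if (length(amb_partials)) {
    matrix(unlist(amb_partials), nrow = n_state)
  } else {
    matrix(0, n_state, 0)
  }
  aln <- structure(
    list(states = states, amb_key = amb_key, amb_partials = amb_mat,
         n_sites = n_sites, names = seq_names, code = code),
    class = "codon_alignment"
  )
  aln$patterns <- .compress_patterns(aln)
  aln
}

# Unique site columns with multiplicities.
.compress_patterns <- function(aln) {
  keys <- apply(rbind(aln$states, aln$amb_key), 2, paste, collapse = ",")
  first <- !duplicated(keys)
  site_of <- match(keys, keys[first])
  list(
    states = aln$states[, first, drop = FALSE],
    amb_key = aln$amb_key[, first, drop = FALSE],
    weights = as.numeric(tabulate(site_of, nbins = sum(first))),
    site_to_pattern = site_of
  )
}

#' Read an in-frame codon alignment from a FASTA file
#'
#' @param path Path to a FASTA file of aligned, in-frame nucleotide
#'   sequences.
#' @inheritParams codon_alignment
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, code = genetic_code(),
                                 mask_stops = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no sequences in ", path)
  chars <- toupper(do.call(rbind, as.character(dna)))
  rownames(chars) <- names(dna)
  codon_alignment(chars, code = code, mask_stops = mask_stops)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment:", nrow(x$states), "sequences x", x$n_sites,
      "codons,", length(x$patterns$weights), "unique patterns>\n")
  invisible(x)
}

#' Write a codon alignment (or named sequences) to FASTA
#'
#' @param x A `codon_alignment` or a named character vector of sequences.
#' @param path Output file path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "codon_alignment")) {
    x <- alignment_sequences(x)
  }
  lines <- as.vector(rbind(paste0(">", names(x)), unname(x)))
  writeLines(lines, path)
  invisible(path)
}

#' Recover character sequences from a codon alignment
#'
#' Unambiguous states map back to their codon; partial states are written as
#' `NNN` (or `---` for fully missing codons).
#'
#' @param aln A [codon_alignment()].
#' @return Named character vector of nucleotide sequences.
#' @export
alignment_sequences <- function(aln) {
  sense <- aln$code$sense_codons
  out <- vapply(seq_len(nrow(aln$states)), function(sq) {
    cods <- ifelse(is.na(aln$states[sq, ]), NA, sense[aln$states[sq, ]])
    if (anyNA(cods)) {
      amb <- which(is.na(cods))
      full <- aln$amb_key[sq, amb] > 0 &
        colSums(aln$amb_partials[, aln$amb_key[sq, amb], drop = FALSE]) ==
          length(sense)
      cods[amb] <- ifelse(full, "---", "NNN")
    }
    paste(cods, collapse = "")
  }, character(1))
  names(out) <- aln$names
  out
}
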
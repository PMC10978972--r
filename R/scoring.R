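#' Protein scoring scheme
#'
#' Substitution matrix, affine gap penalties and Karlin-Altschul constants
#' used to express raw Smith-Waterman scores in bits. The defaults (BLOSUM62,
#' gap open 11 / extend 1, gapped lambda = 0.267, K = 0.041) are the de facto
#' defaults behind protein-search bit scores, and are pinned because the
#' candidate thresholds downstream are stated in bits.
#'
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix name of a substitution matrix shipped with Biostrings
#'   (default "BLOSUM62"), or a numeric matrix with residue dimnames
#' @param gap_open,gap_extend affine gap penalties (non-negative)
#' @param lambda,K Karlin-Altschul scale and constant (both > 0)
#' @return a `scoring_scheme` object
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    submat <- get(matrix, envir = env)
  } else {
    submat <- matrix
  }
  stopifnot(is.matrix(submat), !is.null(rownames(submat)),
            lambda > 0, K > 0, gap_open >= 0, gap_extend >= 0)
  structure(list(submat = submat, charmap = build_charmap(submat),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, alphabet = "protein"),
            class = "scoring_scheme")
}

#' Nucleotide scoring scheme
#'
#' Match/mismatch scoring for the amplicon classifier's blastn-like searches.
#' Ambiguity codes score as mismatches. Identity thresholds, not bit scores,
#' drive the two-tier classifier, so the Karlin-Altschul constants matter
#' only for E-value bookkeeping.
#'
#' @param match,mismatch match reward and mismatch penalty
#' @param gap_open,gap_extend affine gap penalties
#' @param lambda,K Karlin-Altschul constants (nominal values for +2/-3)
#' @return a `scoring_scheme` object
#' @export
dna_scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                               gap_extend = 2, lambda = 0.625, K = 0.41) {
  letters_nt <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V")
  submat <- matrix(mismatch, length(letters_nt), length(letters_nt),
                   dimnames = list(letters_nt, letters_nt))
  diag(submat)[1:4] <- match
  structure(list(submat = submat, charmap = build_charmap(submat),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, alphabet = "dna"),
            class = "scoring_scheme")
}

# map raw bytes to 0-based rows of the substitution matrix; unknown
# characters fall back to 'X' (protein) or 'N' (dna) when present, else to
# the last row.
build_charmap <- function(submat) {
  letters_m <- rownames(submat)
  fallback <- if ("X" %in% letters_m) which(letters_m == "X") else
    if ("N" %in% letters_m) which(letters_m == "N") else length(letters_m)
  charmap <- rep.int(fallback - 1L, 256L)
  for (i in seq_along(letters_m)) {
    charmap[utf8ToInt(letters_m[i]) + 1L] <- i - 1L
  }
  as.integer(charmap)
}

#' Convert a raw alignment score to bits
#'
#' Standard Karlin-Altschul normalization:
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw raw score in matrix units (vectorized)
#' @param scheme a [scoring_scheme()]
#' @return bit score(s)
#' @export
to_bits <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' E-value of a bit score in a given search space
#'
#' `E = m * n * 2^(-bits)` with `m`, `n` the query and database residue
#' totals; no length corrections are applied.
#'
#' @param bits bit score(s)
#' @param m query length in residues
#' @param n database size in residues
#' @return expected chance-hit count(s)
#' @export
bit_evalue <- function(bits, m, n) {
  m * n * 2^(-bits)
}
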
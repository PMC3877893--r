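## IUPAC nucleotide code tables and bitmask arithmetic.
##
## Every base set is encoded as a 4-bit mask over (A, C, G, T) so that
## set intersection is bitwAnd() and set size is a popcount lookup.

IUPAC_BASES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

.iupac_mask_table <- local({
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(IUPAC_BASES, function(s) {
    sum(bit[strsplit(s, "")[[1]]])
  }, integer(1))
})

## popcount of masks 1..15 (index = mask; masks are never 0)
.popcount4 <- c(1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Encode an IUPAC string as base-set bitmasks
#'
#' Internal workhorse: maps each character of an upper-case IUPAC nucleotide
#' string to a 4-bit mask over (A, C, G, T). Gaps are not allowed.
#'
#' @param x character scalar, IUPAC nucleotide string (no gaps).
#' @return integer vector of bitmasks, one per position.
#' @keywords internal
iupac_mask <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  m <- .iupac_mask_table[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("illegal IUPAC code '", chars[bad], "' at position ", bad, call. = FALSE)
  }
  unname(m)
}

#' Do two IUPAC codes denote intersecting base sets?
#'
#' The matching rule underlying degenerate-primer annealing: two codes are
#' compatible iff at least one plain base is shared, e.g. Y = \{C,T\} matches
#' C but not R = \{A,G\}. N matches everything.
#'
#' @param code_a,code_b single IUPAC nucleotide codes (characters).
#' @return logical scalar.
#' @examples
#' iupac_match("Y", "C")  # TRUE
#' iupac_match("R", "Y")  # FALSE
#' @export
iupac_match <- function(code_a, code_b) {
  bitwAnd(iupac_mask(code_a), iupac_mask(code_b)) > 0L
}

#' Reverse complement of an IUPAC string
#'
#' Complementation maps R to Y, K to M, B to V and D to H (and back); S, W and
#' N are self-complementary. Gap characters are preserved.
#'
#' @param x character scalar over IUPAC codes and '-'.
#' @return the reverse-complemented string.
#' @examples
#' revcomp_iupac("TTVGGY")  # "RCCBAA"
#' @export
revcomp_iupac <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  comp <- .iupac_complement[chars]
  if (anyNA(comp)) {
    bad <- which(is.na(comp))[1]
    stop("illegal IUPAC code '", chars[bad], "' at position ", bad, call. = FALSE)
  }
  paste(rev(unname(comp)), collapse = "")
}

#' Number of plain sequences a degenerate IUPAC string denotes
#'
#' The degeneracy of a degenerate oligonucleotide: the product over positions
#' of each code's base-set size. "ACGT" has degeneracy 1; the screening primer
#' "TTVGGYTAYGAYTTYGG" has 3 * 2^4 = 48.
#'
#' @param primer_sequence ungapped IUPAC string.
#' @return positive number (may exceed integer range for long primers).
#' @export
primer_degeneracy <- function(primer_sequence) {
  m <- iupac_mask(primer_sequence)
  prod(.popcount4[m])
}

#' Enumerate all plain-base expansions of an IUPAC string
#'
#' @param x ungapped IUPAC string with degeneracy at most `limit`.
#' @param limit refuse enumeration beyond this many expansions.
#' @return character vector of plain ACGT strings.
#' @keywords internal
iupac_expand <- function(x, limit = 1e4) {
  deg <- primer_degeneracy(x)
  if (deg > limit) {
    stop("degeneracy ", deg, " exceeds enumeration limit ", limit, call. = FALSE)
  }
  sets <- strsplit(IUPAC_BASES[strsplit(toupper(x), "")[[1]]], "")
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Sample one random plain expansion of an IUPAC string
#'
#' Each position draws uniformly from its code's base set; used when the
#' synthetic generator implants concrete primer-binding sites.
#'
#' @param x ungapped IUPAC string.
#' @return one plain ACGT string.
#' @keywords internal
iupac_sample_expansion <- function(x) {
  sets <- strsplit(IUPAC_BASES[strsplit(toupper(x), "")[[1]]], "")
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

## Minimal IUPAC code whose base set equals a given mask.
.mask_to_code <- local({
  inv <- character(15L)
  for (code in names(.iupac_mask_table)) inv[.iupac_mask_table[[code]]] <- code
  inv
})

mask_to_iupac <- function(mask) .mask_to_code[mask]
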
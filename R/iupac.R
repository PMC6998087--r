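#' @useDynLib primerscout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bitmask encoding of the IUPAC nucleotide alphabet: A=1, C=2, G=4, T=8.
# A degenerate code is the bitwise OR of the concrete bases it stands for.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.BITS_TO_CODE <- character(15L)
.BITS_TO_CODE[.IUPAC_BITS] <- names(.IUPAC_BITS)

.CONCRETE <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to canonical IUPAC form
#'
#' Uppercases, converts RNA `U` to `T`, and validates every character against
#' the IUPAC nucleotide alphabet.  All package entry points run their sequence
#' inputs through this function, so downstream code can assume canonical form.
#'
#' @param x character vector of nucleotide strings (DNA or RNA alphabet,
#'   any case, IUPAC degenerate codes allowed).
#' @param what label used in error messages.
#' @return character vector of the same length, uppercase DNA alphabet.
#' @examples
#' normalize_seq("agagtttgatymtggctcag")
#' normalize_seq("uuccgguugauccugccgga")  # RNA input
#' @export
normalize_seq <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- regexpr(sprintf("[^%s]", paste(names(.IUPAC_BITS), collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s '%s'",
                 substr(x[i], bad[i], bad[i]), bad[i], what, x[i]),
         call. = FALSE)
  }
  if (any(!nzchar(x))) stop(sprintf("empty %s", what), call. = FALSE)
  x
}

# Integer bitmask vector for one sequence string (assumed normalized).
seq_bits <- function(s) {
  unname(.IUPAC_BITS[strsplit(s, "", fixed = TRUE)[[1L]]])
}

bits_to_seq <- function(bits) {
  paste(.BITS_TO_CODE[bits], collapse = "")
}

#' Does an IUPAC code match a concrete base?
#'
#' `code_matches(code, base)` is TRUE when `base` belongs to the expansion set
#' of `code`.  Both arguments are recycled; bases may themselves be ambiguous,
#' in which case the match is subset-wise: an ambiguous read base only counts
#' as matching when every base it could be is allowed by the code (the
#' conservative rule used throughout site evaluation).
#'
#' @param code character vector of IUPAC codes (e.g. the primer positions).
#' @param base character vector of observed bases.
#' @return logical vector.
#' @examples
#' code_matches("Y", "T")  # TRUE: Y = C/T
#' code_matches("G", "A")  # FALSE
#' code_matches("N", "G")  # TRUE
#' @export
code_matches <- function(code, base) {
  cb <- .IUPAC_BITS[toupper(chartr("uU", "TT", as.character(code)))]
  bb <- .IUPAC_BITS[toupper(chartr("uU", "TT", as.character(base)))]
  if (anyNA(cb)) stop("invalid IUPAC code: ",
                      paste(unique(code[is.na(cb)]), collapse = ", "),
                      call. = FALSE)
  if (anyNA(bb)) stop("invalid base: ",
                      paste(unique(base[is.na(bb)]), collapse = ", "),
                      call. = FALSE)
  unname(bitwAnd(bb, bitwNot(cb)) == 0L)
}

#' Degeneracy of a degenerate sequence
#'
#' The number of concrete oligonucleotides a degenerate sequence expands to:
#' the product over positions of the expansion-set sizes.
#'
#' @param seq a nucleotide string (IUPAC codes allowed) or a [primer()].
#' @return integer (>= 1).
#' @examples
#' degeneracy("TTCCGGTTGATCCTGCCGGA")  # 1
#' degeneracy("AGAGTTTGATYMTGGCTCAG")  # 4
#' @export
degeneracy <- function(seq) {
  s <- normalize_seq(primer_sequence(seq))
  counts <- vapply(seq_bits(s), function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), 1L)
  as.integer(prod(counts))
}

#' Expand a degenerate sequence into all concrete variants
#'
#' @param seq nucleotide string or [primer()].
#' @param cap maximum degeneracy to expand (guards accidental blow-up).
#' @return character vector of concrete A/C/G/T sequences.
#' @export
expand_iupac <- function(seq, cap = 4096L) {
  s <- normalize_seq(primer_sequence(seq))
  d <- degeneracy(s)
  if (d > cap) {
    stop(sprintf("degeneracy %d exceeds expansion cap %d", d, cap), call. = FALSE)
  }
  sets <- lapply(seq_bits(s), function(b) .CONCRETE[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L])
  out <- do.call(expand.grid, c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- rev(out)
  apply(as.matrix(out), 1L, paste, collapse = "")
}

#' Positions at which a site mismatches a (degenerate) primer
#'
#' Compares a concrete binding site of equal length against a primer and
#' returns the 1-based positions where the site base falls outside the
#' primer code's expansion set.  Ambiguous site bases are counted as
#' mismatches unless their expansion set is a subset of the primer code's.
#'
#' @param primer primer sequence (IUPAC) or [primer()] object.
#' @param site concrete site sequence of the same length.
#' @return ascending integer vector of mismatch positions (possibly empty).
#' @examples
#' mismatch_positions("TTCCGGTTGATCCTGCCGGA", "CTCTAGTTGATCCTGCTAGA")
#' @export
mismatch_positions <- function(primer, site) {
  p <- normalize_seq(primer_sequence(primer), "primer")
  s <- normalize_seq(site, "site")
  if (nchar(p) != nchar(s)) {
    stop(sprintf(paste0("primer (%d nt) and site (%d nt) lengths differ; ",
                        "extract a complete binding site before comparing"),
                 nchar(p), nchar(s)), call. = FALSE)
  }
  pb <- seq_bits(p)
  sb <- seq_bits(s)
  which(bitwAnd(sb, bitwNot(pb)) != 0L)
}

.COMPLEMENT_BITS <- function(bits) {
  # complement of a bitmask: swap A<->T (1<->8) and C<->G (2<->4)
  bitwOr(bitwOr(ifelse(bitwAnd(bits, 1L) > 0L, 8L, 0L),
                ifelse(bitwAnd(bits, 8L) > 0L, 1L, 0L)),
         bitwOr(ifelse(bitwAnd(bits, 2L) > 0L, 4L, 0L),
                ifelse(bitwAnd(bits, 4L) > 0L, 2L, 0L)))
}

#' Reverse complement of a degenerate sequence
#'
#' Complements each IUPAC code as a set (R<->Y, K<->M, B<->V, D<->H; S, W and
#' N are self-complementary) and reverses the order.
#'
#' @param seq nucleotide string or [primer()].
#' @return character string.
#' @examples
#' reverse_complement("GGTTACCTTGTTAYGACTT")  # "AAGTCRTAACAAGGTAACC"
#' @export
reverse_complement <- function(seq) {
  s <- normalize_seq(primer_sequence(seq))
  bits_to_seq(rev(.COMPLEMENT_BITS(seq_bits(s))))
}

#' Minimal degenerate consensus covering a set of sites
#'
#' For each position, returns the IUPAC code whose expansion set is exactly
#' the union of bases observed at that position across all sites.  This is
#' the primitive behind degenerate primer merging: every input site matches
#' the consensus with zero mismatches, and the consensus is the least
#' degenerate sequence with that property.
#'
#' @param sites character vector of equal-length sequences (IUPAC allowed:
#'   a degenerate input position contributes its whole expansion set).
#' @return character string of the same length.
#' @examples
#' union_consensus(c("ACGT", "ACGT"))       # "ACGT"
#' union_consensus(c("AACC", "GACC"))       # "RACC"
#' @export
union_consensus <- function(sites) {
  if (length(sites) == 0L) stop("no sites supplied", call. = FALSE)
  sites <- normalize_seq(sites, "site")
  n <- unique(nchar(sites))
  if (length(n) != 1L) {
    stop("sites have unequal lengths: ", paste(sort(n), collapse = ", "),
         call. = FALSE)
  }
  bits <- vapply(sites, seq_bits, integer(n), USE.NAMES = FALSE)
  if (n == 1L) bits <- matrix(bits, nrow = 1L)
  bits_to_seq(apply(bits, 1L, function(b) Reduce(bitwOr, b)))
}

#' Convert between IUPAC codes and the parenthesized primer dialect
#'
#' Primer sequences published in the field are often written with
#' parenthesized alternates, e.g. `"AGAGTTTGAT(C/T)(A/C)TGGCTCAG"` for 8F.
#' `parse_primer_dialect()` converts that dialect (or plain IUPAC) to
#' canonical IUPAC; `to_primer_dialect()` renders IUPAC degeneracies back as
#' parenthesized alternates.
#'
#' @param x character vector of primer sequences in either notation.
#' @return character vector of the same length.
#' @examples
#' parse_primer_dialect("AGAGTTTGAT(C/T)(A/C)TGGCTCAG")
#' to_primer_dialect("AGAGTTTGATYMTGGCTCAG")
#' @export
parse_primer_dialect <- function(x) {
  vapply(as.character(x), function(s) {
    while (grepl("(", s, fixed = TRUE)) {
      m <- regmatches(s, regexpr("\\(([ACGTUacgtu]/)+[ACGTUacgtu]\\)", s))
      if (length(m) == 0L) {
        stop("malformed parenthesized alternate in primer '", s, "'",
             call. = FALSE)
      }
      alts <- strsplit(gsub("[()]", "", m), "/", fixed = TRUE)[[1L]]
      code <- union_consensus(alts)
      s <- sub(m, code, s, fixed = TRUE)
    }
    normalize_seq(s, "primer")
  }, character(1L), USE.NAMES = FALSE)
}

#' @rdname parse_primer_dialect
#' @export
to_primer_dialect <- function(x) {
  vapply(normalize_seq(as.character(x), "primer"), function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    out <- vapply(chars, function(ch) {
      b <- .IUPAC_BITS[[ch]]
      bases <- .CONCRETE[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
      if (length(bases) == 1L) bases else
        paste0("(", paste(bases, collapse = "/"), ")")
    }, character(1L))
    paste(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
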
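#' Construct a primer object
#'
#' A lightweight record for a (possibly degenerate) primer: name, canonical
#' IUPAC sequence, and orientation.  Most package functions also accept a bare
#' sequence string wherever a primer is expected.
#'
#' @param name primer identifier.
#' @param sequence nucleotide string, IUPAC codes or the parenthesized
#'   `"(C/T)"` dialect.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an object of class `"ssu_primer"`.
#' @examples
#' primer("8F", "AGAGTTTGAT(C/T)(A/C)TGGCTCAG")
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seq <- parse_primer_dialect(sequence)
  structure(
    list(name = as.character(name), sequence = seq, orientation = orientation),
    class = "ssu_primer"
  )
}

#' @export
print.ssu_primer <- function(x, ...) {
  cat(sprintf("<primer %s (%s)> %s  [%s, degeneracy %d, %d nt]\n",
              x$name, x$orientation, x$sequence, to_primer_dialect(x$sequence),
              degeneracy(x$sequence), nchar(x$sequence)))
  invisible(x)
}

# Accept either an ssu_primer or a plain string.
primer_sequence <- function(x) {
  if (inherits(x, "ssu_primer")) x$sequence else as.character(x)
}

primer_name <- function(x, default = "primer") {
  if (inherits(x, "ssu_primer")) x$name else default
}

#' Built-in primer set
#'
#' The universal primers routinely used for near-full-length prokaryotic 16S
#' rRNA amplification (8F for Bacteria, Arch21F for Archaea, reverse 1492R,
#' and the older archaeal 4F), together with targeted forward primers against
#' the two primer-evading archaeal groups recovered from mudflat
#' meta-transcriptomes ("Type A" and "Type B") and the degenerate primer
#' 26ABF that covers both.
#'
#' @return named list of [primer()] objects.
#' @examples
#' builtin_primers()[["Arch21F"]]
#' @export
builtin_primers <- function() {
  fw <- function(name, s) primer(name, s, "forward")
  rv <- function(name, s) primer(name, s, "reverse")
  list(
    `8F`       = fw("8F", "AGAGTTTGAT(C/T)(A/C)TGGCTCAG"),
    Arch21F    = fw("Arch21F", "TTCCGGTTGATCCTGCCGGA"),
    `4F`       = fw("4F", "TCCGGTTGATCCTGCC(A/G)G"),
    `1492R`    = rv("1492R", "GGTTACCTTGTTA(C/T)GACTT"),
    `1492R-22W` = rv("1492R-22W", "TACGG(A/T)TACCTTGTTACGACTT"),
    `21AF`     = fw("21AF", "CTCTAGTTGATCCTGCTAGA"),
    `26AF`     = fw("26AF", "GG(A/G)CACTGCTATCGGCTT"),
    `59AF`     = fw("59AF", "AAGTCGAACGGACACGCAT"),
    `12BF`     = fw("12BF", "CGATCCTGACGGAGCCTA"),
    `15BF`     = fw("15BF", "ATCCTGACGGAGCCTA"),
    `16BF`     = fw("16BF", "TCCTGACGGAGCCTAC"),
    `17BF`     = fw("17BF", "CCTGACGGAGCCTACT"),
    `26BF`     = fw("26BF", "GCCTACTGCTATCGGATT"),
    `27BF`     = fw("27BF", "CCTACTGCTATCGGATT"),
    `26ABF`    = fw("26ABF", "G(G/C)(G/A/C)(C/T)ACTGCTATCGG(A/C)TT")
  )
}

#' Read primers from FASTA or 3-column TSV
#'
#' TSV columns: name, sequence, orientation (orientation optional, default
#' forward).  Sequences may use IUPAC codes or the parenthesized dialect.
#'
#' @param path file path.
#' @return named list of [primer()] objects.
#' @export
read_primers <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, ">")) {
    seqs <- read_fasta(path)
    prs <- mapply(primer, names(seqs), unname(seqs),
                  SIMPLIFY = FALSE, USE.NAMES = TRUE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 2L) stop("primer TSV needs columns: name, sequence",
                             call. = FALSE)
    ori <- if (ncol(tab) >= 3L && all(tab[[3L]] %in% c("forward", "reverse")))
      tab[[3L]] else rep("forward", nrow(tab))
    prs <- mapply(primer, tab[[1L]], tab[[2L]], ori, SIMPLIFY = FALSE)
    names(prs) <- tab[[1L]]
  }
  prs
}

#' Write primers to a 3-column TSV (IUPAC and parenthesized dialect)
#'
#' @param primers named list of [primer()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primers <- function(primers, path) {
  df <- data.frame(
    name = vapply(primers, primer_name, ""),
    sequence = vapply(primers, primer_sequence, ""),
    orientation = vapply(primers, function(p)
      if (inherits(p, "ssu_primer")) p$orientation else "forward", ""),
    dialect = to_primer_dialect(vapply(primers, primer_sequence, "")),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# name\tsequence\torientation\tdialect", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
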
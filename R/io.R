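#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a named
#' character vector (so degenerate and gapped alignment FASTA both load).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two-column TSV: sequence id, semicolon-delimited lineage (SILVA style,
#' ranks positional: domain; phylum; class; ...).  Lines may omit the
#' lineage for fully unclassified sequences.
#'
#' @param path TSV file.
#' @return data.frame with columns `id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "#",
                           col.names = c("id", "lineage")[1:2], fill = TRUE)
  if (ncol(tab) == 1L) tab$lineage <- ""
  tab$lineage[is.na(tab$lineage)] <- ""
  tab[, c("id", "lineage")]
}

#' @rdname read_taxonomy
#' @param taxonomy data.frame with columns `id`, `lineage`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV with a commented header line
#'
#' All tabular outputs of the pipeline go through this helper: tab-separated,
#' no quoting, a `#`-prefixed key: value preamble for provenance.
#'
#' @param df data.frame.
#' @param path output path.
#' @param preamble optional named character vector written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, preamble = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(preamble)) {
    writeLines(sprintf("# %s: %s", names(preamble), preamble), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in PHYLIP lower-triangle format
#'
#' @param d square numeric matrix with row names, or a [stats::dist] object.
#' @param path output path.
#' @param digits number of digits to print.
#' @return `path`, invisibly.
#' @export
write_phylip_lower <- function(d, path, digits = 6L) {
  m <- as.matrix(d)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    row <- if (i > 1L) paste(formatC(m[i, seq_len(i - 1L)], digits = digits,
                                     format = "f"), collapse = "\t") else ""
    writeLines(paste(c(ids[i], row), collapse = "\t"), con)
  }
  invisible(path)
}
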
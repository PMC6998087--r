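#' Screening criteria for novel primer-evading OTUs
#'
#' The defaults encode the published screening rule: an OTU is kept when its
#' reads are taxonomically unclassified at the domain and/or phylum level,
#' every read has a complete primer-binding site, every read carries at least
#' `min_mismatches` mismatches against its universal primer, and the OTU
#' holds at least `min_otu_size` reads.
#'
#' @param min_mismatches minimum per-read mismatch count (default 3).
#' @param min_otu_size minimum read support (default 10; reference sequences
#'   never count).
#' @param require_complete_sites demand complete binding sites in all reads.
#' @param novelty_ranks ranks at which lack of classification counts as novel
#'   (an OTU qualifies if unclassified at *any* of them).
#' @return list of class `"screening_criteria"`.
#' @export
screening_criteria <- function(min_mismatches = 3L, min_otu_size = 10L,
                               require_complete_sites = TRUE,
                               novelty_ranks = c("domain", "phylum")) {
  stopifnot(min_mismatches >= 0L, min_otu_size >= 1L)
  novelty_ranks <- match.arg(novelty_ranks, c("domain", "phylum"),
                             several.ok = TRUE)
  structure(list(min_mismatches = as.integer(min_mismatches),
                 min_otu_size = as.integer(min_otu_size),
                 require_complete_sites = isTRUE(require_complete_sites),
                 novelty_ranks = novelty_ranks),
            class = "screening_criteria")
}

#' Screen annotated OTUs for novel primer-evading groups
#'
#' Applies [screening_criteria()] to the per-OTU table from
#' [annotate_otus()] and returns the passing rows.
#'
#' @param otus data.frame from [annotate_otus()].
#' @param criteria a [screening_criteria()] object.
#' @return data.frame of passing OTUs (possibly 0 rows), same columns.
#' @export
screen_novel <- function(otus, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  if (nrow(otus) == 0L) return(otus)
  considered <- otus$size >= criteria$min_otu_size
  missing <- otus$n_missing_eval > 0L & considered
  if (any(missing)) {
    stop("OTU members without a site evaluation in: ",
         paste(otus$otu_id[missing], collapse = ", "), call. = FALSE)
  }
  novel <- Reduce(`|`, lapply(criteria$novelty_ranks, function(r) {
    otus[[paste0("unclassified_", r)]]
  }))
  pass <- considered &
    novel &
    (!criteria$require_complete_sites | (!is.na(otus$all_complete) & otus$all_complete)) &
    (!is.na(otus$min_mismatch) & otus$min_mismatch >= criteria$min_mismatches)
  out <- otus[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mismatch-type table for screened OTUs
#'
#' Formats screened OTUs as the standard mismatch-type report: one row per
#' OTU with its primer, dominant mismatch pattern, read support and taxonomy
#' calls, sorted by primer then by size descending.
#'
#' @param screened data.frame from [screen_novel()].
#' @return data.frame with columns `primer`, `otu_id`, `pattern`, `size`,
#'   `taxonomy`, `unclassified_domain`, `unclassified_phylum`.
#' @export
mismatch_table <- function(screened) {
  if (nrow(screened) == 0L) {
    return(data.frame(primer = character(), otu_id = character(),
                      pattern = character(), size = integer(),
                      taxonomy = character(),
                      unclassified_domain = logical(),
                      unclassified_phylum = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    primer = screened$primer, otu_id = screened$otu_id,
    pattern = screened$dominant_pattern, size = screened$size,
    taxonomy = ifelse(is.na(screened$lineage) | !nzchar(screened$lineage),
                      "Unclassified", screened$lineage),
    unclassified_domain = screened$unclassified_domain,
    unclassified_phylum = screened$unclassified_phylum,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$primer, -out$size, out$otu_id), ]
  rownames(out) <- NULL
  out
}
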
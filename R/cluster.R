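#' Greedy centroid clustering of sequences at an identity cutoff
#'
#' Reproduces the centroid-greedy contract of the usual amplicon clustering
#' tools: sequences are visited in order (by default sorted by decreasing
#' length, stable on ties) and each joins the first existing centroid whose
#' pairwise identity is at least `cutoff`, otherwise it founds a new
#' centroid.  Identity is computed from an end-gap-free global alignment
#' (match +1, mismatch -1, first gap position -5, extension -1) as matching
#' columns divided by all alignment columns including terminal gap overhangs
#' (`identity_mode = "alncols"`, two-way); `"oneway"` divides by the shorter
#' sequence length instead.
#'
#' @param seqs named character vector of sequences.
#' @param cutoff identity cutoff in (0, 1].
#' @param sort_by_length visit sequences longest-first (stable).
#' @param identity_mode `"alncols"` (default) or `"oneway"`.
#' @param match,mismatch,gap_open,gap_ext alignment scores (gap_open is the
#'   cost of the first gap position).
#' @param prefilter skip centroids sharing no 5-mer with the query (safe
#'   speedup for realistic cutoffs).
#' @param banded restrict the alignment to a diagonal band wide enough for
#'   any alignment that could reach `cutoff` (exact for accept decisions).
#' @return object of class `"ssu_clustering"`: list with `membership`
#'   (data.frame `id`, `otu_id`, `is_centroid`), `otus` (data.frame `otu_id`,
#'   `representative_id`, `n_members`), and the call parameters.
#' @examples
#' cl <- cluster_greedy(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"), 0.85)
#' cl$otus
#' @export
cluster_greedy <- function(seqs, cutoff = 0.85, sort_by_length = TRUE,
                           identity_mode = c("alncols", "oneway"),
                           match = 1L, mismatch = -1L,
                           gap_open = 5L, gap_ext = 1L,
                           prefilter = TRUE, banded = TRUE) {
  identity_mode <- match.arg(identity_mode)
  if (length(seqs) == 0L) stop("no sequences to cluster", call. = FALSE)
  stopifnot(cutoff > 0, cutoff <= 1)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ord <- if (sort_by_length) order(-nchar(seqs)) else seq_along(seqs)

  res <- greedy_cluster_cpp(unname(as.character(seqs[ord])), cutoff,
                            match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_ext = gap_ext,
                            mode = if (identity_mode == "oneway") 1L else 0L,
                            prefilter = prefilter, banded = banded)
  otu_id <- sprintf("OTU%d", res$assignment)
  centroid_pos <- ord[res$centroids]

  membership <- data.frame(
    id = ids[ord], otu_id = otu_id,
    is_centroid = seq_along(ord) %in% res$centroids,
    stringsAsFactors = FALSE
  )
  membership <- membership[match(ids, membership$id), ]
  rownames(membership) <- NULL

  otus <- data.frame(
    otu_id = sprintf("OTU%d", seq_along(centroid_pos)),
    representative_id = ids[centroid_pos],
    n_members = as.integer(table(factor(res$assignment,
                                        levels = seq_along(centroid_pos)))),
    stringsAsFactors = FALSE
  )
  structure(list(membership = membership, otus = otus, cutoff = cutoff,
                 identity_mode = identity_mode),
            class = "ssu_clustering")
}

#' @export
print.ssu_clustering <- function(x, ...) {
  cat(sprintf("<clustering> %d sequences in %d OTUs (cutoff %.2f, %s identity)\n",
              nrow(x$membership), nrow(x$otus), x$cutoff, x$identity_mode))
  invisible(x)
}

#' Pairwise alignment identity
#'
#' The identity function used by [cluster_greedy()], exposed for inspection
#' and testing.
#'
#' @inheritParams cluster_greedy
#' @param a,b sequences.
#' @param band band half-width (`NULL` = automatic from cutoff semantics is
#'   not applied here; `-1` = full matrix).
#' @return list with `identity`, `matches`, `columns`, `score`.
#' @export
pair_identity <- function(a, b, identity_mode = c("alncols", "oneway"),
                          match = 1L, mismatch = -1L, gap_open = 5L,
                          gap_ext = 1L, band = -1L) {
  identity_mode <- match.arg(identity_mode)
  pair_identity_cpp(as.character(a), as.character(b), match = match,
                    mismatch = mismatch, gap_open = gap_open,
                    gap_ext = gap_ext, band = as.integer(band),
                    mode = if (identity_mode == "oneway") 1L else 0L)
}

#' Annotate OTUs with taxonomy, evaluations and read support
#'
#' Joins a clustering with per-read site evaluations and taxonomy to produce
#' the per-OTU table consumed by [screen_novel()].  Reference sequences
#' (ids in `ref_ids`) may be co-clustered but never count toward OTU size.
#'
#' @param clustering result of [cluster_greedy()].
#' @param evals data.frame from [evaluate_reads()] (reference ids may be
#'   absent).
#' @param taxonomy data.frame (`id`, `lineage`).
#' @param ref_ids character vector of reference (non-read) sequence ids.
#' @param unclassified_regex regex identifying unclassified rank labels.
#' @return data.frame with one row per OTU: `otu_id`, `size` (reads only),
#'   `n_ref`, `representative_id`, `primer`, `dominant_pattern`,
#'   `min_mismatch`, `all_complete`, `unclassified_domain`,
#'   `unclassified_phylum`, `lineage` (modal read lineage).
#' @export
annotate_otus <- function(clustering, evals = NULL, taxonomy = NULL,
                          ref_ids = character(),
                          unclassified_regex = "unclassified|unknown|uncultured") {
  mem <- clustering$membership
  mem$is_ref <- mem$id %in% ref_ids
  ev <- if (!is.null(evals)) evals[match(mem$id, evals$read_id), ] else NULL
  lin <- if (!is.null(taxonomy)) {
    ifelse(is.na(match(mem$id, taxonomy$id)), "",
           taxonomy$lineage[match(mem$id, taxonomy$id)])
  } else rep("", nrow(mem))
  # per-member classification state, computed once (cheap on unique lineages)
  ulin <- unique(lin)
  uncls_dom <- is_unclassified_at(ulin, "domain", unclassified_regex)[match(lin, ulin)]
  uncls_phy <- is_unclassified_at(ulin, "phylum", unclassified_regex)[match(lin, ulin)]

  rows <- lapply(split(seq_len(nrow(mem)), mem$otu_id), function(ix) {
    reads <- ix[!mem$is_ref[ix]]
    rl <- lin[reads]
    modal <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_character_)
      tt <- table(x)
      names(tt)[order(-tt, names(tt))][1L]  # ties broken lexicographically
    }
    e <- if (!is.null(ev)) ev[reads, ] else NULL
    has_eval <- !is.null(e) && length(reads) > 0L && !all(is.na(e$read_id))
    data.frame(
      otu_id = mem$otu_id[ix[1L]],
      size = length(reads),
      n_ref = sum(mem$is_ref[ix]),
      representative_id = mem$id[ix][mem$is_centroid[ix]][1L],
      primer = if (has_eval) modal(e$primer) else NA_character_,
      dominant_pattern = if (has_eval) modal(e$pattern) else NA_character_,
      min_mismatch = if (has_eval && any(!is.na(e$mismatch_count)))
        min(e$mismatch_count, na.rm = TRUE) else NA_integer_,
      all_complete = if (has_eval)
        all(e$status %in% c("matching", "mismatching")) else NA,
      n_missing_eval = if (is.null(ev)) length(reads) else sum(is.na(e$read_id)),
      unclassified_domain = length(reads) > 0L && all(uncls_dom[reads]),
      unclassified_phylum = length(reads) > 0L && all(uncls_phy[reads]),
      lineage = modal(rl),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(as.integer(sub("^OTU", "", out$otu_id))), ]
  rownames(out) <- NULL
  out
}
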
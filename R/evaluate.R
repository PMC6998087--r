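#' Taxonomy helpers
#'
#' Lineages are semicolon-delimited, SILVA style, with positional ranks
#' (domain; phylum; class; order; family; genus).  A sequence is
#' "unclassified at rank r" when the lineage has no entry at that rank or the
#' entry matches the unclassified regex (default
#' `"unclassified|unknown|uncultured"`, case-insensitive).
#'
#' @param lineage character vector of semicolon-delimited lineages.
#' @param rank rank name or 1-based index (domain = 1, phylum = 2, ...).
#' @param unclassified_regex regex identifying unclassified labels.
#' @return logical vector.
#' @export
is_unclassified_at <- function(lineage, rank,
                               unclassified_regex = "unclassified|unknown|uncultured") {
  ranks <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
             family = 5L, genus = 6L, species = 7L)
  idx <- if (is.character(rank)) ranks[[match.arg(rank, names(ranks))]] else as.integer(rank)
  parts <- strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) < idx || !nzchar(p[idx])) return(TRUE)
    grepl(unclassified_regex, p[idx], ignore.case = TRUE)
  }, logical(1L))
}

#' Domain call from a lineage
#'
#' @param lineage character vector of lineages.
#' @return character vector over \{"Bacteria", "Archaea", "Eukaryota",
#'   "Unclassified"\}.
#' @export
domain_call <- function(lineage) {
  first <- trimws(vapply(strsplit(ifelse(is.na(lineage), "", lineage), ";",
                                  fixed = TRUE),
                         function(p) if (length(p)) p[1L] else "", ""))
  out <- rep("Unclassified", length(first))
  out[grepl("^bacteria", first, ignore.case = TRUE)] <- "Bacteria"
  out[grepl("^archaea", first, ignore.case = TRUE)] <- "Archaea"
  out[grepl("^eukary", first, ignore.case = TRUE)] <- "Eukaryota"
  out[is_unclassified_at(lineage, "domain")] <- "Unclassified"
  out
}

#' Default domain-to-primer assignment
#'
#' Bacterial reads are evaluated against 8F; archaeal and domain-unclassified
#' reads against Arch21F (unclassified reads sit with the archaeal primer in
#' the standard evaluation layout).  Eukaryotic reads, when present, are
#' grouped with Unclassified.
#'
#' @return named character vector mapping domain call to primer name.
#' @export
default_primer_assignment <- function() {
  c(Bacteria = "8F", Archaea = "Arch21F",
    Unclassified = "Arch21F", Eukaryota = "Arch21F")
}

#' Evaluate 5'-anchored reads against universal forward primers
#'
#' Extracts the primer-binding site at the 5' terminus of each read (optionally
#' scanning offsets `0..max_offset` and keeping the placement with the fewest
#' mismatches, smallest offset on ties), compares it position-by-position to
#' the primer assigned to the read's domain call, and classifies the read:
#'
#' * `incomplete`  — the read is too short to contain the full site;
#' * `unevaluable` — more than `max_ambig_frac` of site bases are ambiguous;
#' * `matching`    — 0 mismatches, or exactly 1 mismatch outside the last
#'   four primer positions;
#' * `mismatching` — 2 or more mismatches, or a single mismatch within the
#'   last four positions (a 3'-end mismatch abolishes amplification).
#'
#' The mismatch pattern records `=` at matching positions and the observed
#' read base at mismatched positions, e.g. `"C==TA===========TA=="`.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param taxonomy optional data.frame (`id`, `lineage`); reads without an
#'   entry are treated as domain-unclassified.
#' @param primers named list of primers (see [builtin_primers()]).
#' @param assignment named vector mapping domain calls to primer names.
#' @param max_offset maximum 5' offset scanned for the binding site.
#' @param max_ambig_frac maximum tolerated fraction of ambiguous site bases.
#' @return data.frame with columns `read_id`, `domain_call`, `primer`,
#'   `status`, `pattern`, `mismatch_count`, `site_start` (0-based).
#' @examples
#' ev <- evaluate_reads(c(r1 = "TTCCGGTTGATCCTGCCGGAAACCTT"))
#' ev$status
#' @export
evaluate_reads <- function(reads, taxonomy = NULL,
                           primers = builtin_primers(),
                           assignment = default_primer_assignment(),
                           max_offset = 0L, max_ambig_frac = 0.1) {
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  if (anyDuplicated(ids)) {
    stop("duplicate read ids: ", paste(unique(ids[duplicated(ids)])[1:3],
                                       collapse = ", "), call. = FALSE)
  }
  reads <- toupper(chartr("uU", "TT", as.character(reads)))

  lineage <- rep("", length(reads))
  if (!is.null(taxonomy)) {
    m <- match(ids, taxonomy$id)
    lineage[!is.na(m)] <- taxonomy$lineage[m[!is.na(m)]]
  }
  dom <- domain_call(lineage)
  primer_for <- unname(assignment[dom])
  if (anyNA(primer_for)) {
    stop("no primer assigned for domain call(s): ",
         paste(unique(dom[is.na(primer_for)]), collapse = ", "), call. = FALSE)
  }

  out <- data.frame(read_id = ids, domain_call = dom, primer = primer_for,
                    status = NA_character_, pattern = NA_character_,
                    mismatch_count = NA_integer_, site_start = 0L,
                    stringsAsFactors = FALSE)

  for (pname in unique(primer_for)) {
    p <- primers[[pname]]
    if (is.null(p)) stop("primer '", pname, "' not in primer set", call. = FALSE)
    sel <- which(primer_for == pname)
    res <- .evaluate_against(reads[sel], primer_sequence(p),
                             max_offset = max_offset,
                             max_ambig_frac = max_ambig_frac)
    out$status[sel] <- res$status
    out$pattern[sel] <- res$pattern
    out$mismatch_count[sel] <- res$mismatch_count
    out$site_start[sel] <- res$site_start
  }
  out
}

# Vectorized core: evaluate all `reads` against one primer.
.evaluate_against <- function(reads, primer_seq, max_offset = 0L,
                              max_ambig_frac = 0.1) {
  L <- nchar(primer_seq)
  pb <- seq_bits(primer_seq)
  n <- length(reads)
  nlen <- nchar(reads)

  best_mm <- rep(Inf, n)
  best_off <- rep(0L, n)
  best_site <- rep(NA_character_, n)
  for (off in 0:max_offset) {
    ok <- nlen >= off + L
    if (!any(ok)) next
    sites <- substr(reads[ok], off + 1L, off + L)
    mm <- .site_mismatch_count(sites, pb)
    idx <- which(ok)
    better <- mm < best_mm[idx]
    best_mm[idx[better]] <- mm[better]
    best_off[idx[better]] <- off
    best_site[idx[better]] <- sites[better]
  }

  complete <- is.finite(best_mm)
  status <- rep("incomplete", n)
  pattern <- rep(NA_character_, n)
  mmcount <- rep(NA_integer_, n)

  if (any(complete)) {
    sites <- best_site[complete]
    ambig <- 1 - (nchar(gsub("[^ACGT]", "", sites)) / L)
    uneval <- ambig > max_ambig_frac
    det <- .site_detail(sites, pb)
    st <- ifelse(det$count == 0L |
                   (det$count == 1L & !det$last4),
                 "matching", "mismatching")
    st[uneval] <- "unevaluable"
    status[complete] <- st
    keep <- !uneval
    pattern[complete][keep] <- det$pattern[keep]
    mmcount[complete][keep] <- det$count[keep]
  }
  list(status = status, pattern = pattern, mismatch_count = mmcount,
       site_start = best_off)
}

# number of primer-mismatched positions per site (vectorized over sites)
.site_mismatch_count <- function(sites, pb) {
  L <- length(pb)
  tot <- integer(length(sites))
  for (i in seq_len(L)) {
    ch <- substr(sites, i, i)
    sb <- .IUPAC_BITS[ch]
    sb[is.na(sb)] <- 0L  # non-IUPAC char never matches
    tot <- tot + as.integer(bitwAnd(sb, bitwNot(pb[i])) != 0L | sb == 0L)
  }
  tot
}

.site_detail <- function(sites, pb) {
  L <- length(pb)
  cols <- vector("list", L)
  count <- integer(length(sites))
  last4 <- logical(length(sites))
  for (i in seq_len(L)) {
    ch <- substr(sites, i, i)
    sb <- .IUPAC_BITS[ch]
    sb[is.na(sb)] <- 0L
    mm <- bitwAnd(sb, bitwNot(pb[i])) != 0L | sb == 0L
    count <- count + as.integer(mm)
    if (i > L - 4L) last4 <- last4 | mm
    cols[[i]] <- ifelse(mm, ch, "=")
  }
  list(pattern = do.call(paste0, cols), count = count, last4 = last4)
}

#' Reconstruct a binding site from a primer and a mismatch pattern
#'
#' Inverts the pattern notation: `=` positions take the primer base (for a
#' degenerate primer position, the alphabetically first base of its expansion
#' set), mismatch positions take the recorded read base.
#'
#' @param primer primer sequence or [primer()].
#' @param pattern pattern string of the same length over `=`/A/C/G/T.
#' @return concrete site sequence.
#' @examples
#' apply_pattern("TTCCGGTTGATCCTGCCGGA", "C==TA===========TA==")
#' @export
apply_pattern <- function(primer, pattern) {
  p <- normalize_seq(primer_sequence(primer), "primer")
  if (nchar(p) != nchar(pattern)) {
    stop("pattern length differs from primer length", call. = FALSE)
  }
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  ref <- vapply(pc, function(ch) {
    .CONCRETE[bitwAnd(.IUPAC_BITS[[ch]], c(1L, 2L, 4L, 8L)) > 0L][1L]
  }, character(1L))
  tc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(tc), c("=", .CONCRETE))
  if (length(bad)) stop("invalid pattern characters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  paste(ifelse(tc == "=", ref, tc), collapse = "")
}

#' Summarize site evaluations into the standard contingency layout
#'
#' Per (domain call, primer): number of reads with incomplete sites, matching
#' reads, mismatching reads split into 1-2 vs >= 3 mismatches, and
#' unevaluable reads.  Attribute `"complete_sites"` carries the two
#' bookkeeping totals: reads whose sites were complete and evaluable
#' (`evaluated`) and the plain column sum over matching + mismatching
#' (`category_sum`); they differ only when unevaluable reads are present.
#'
#' @param evals data.frame from [evaluate_reads()].
#' @return data.frame with one row per (domain_call, primer).
#' @export
summarize_evaluations <- function(evals) {
  if (anyDuplicated(evals$read_id)) {
    stop("duplicate read ids in evaluations", call. = FALSE)
  }
  key <- interaction(evals$domain_call, evals$primer, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    e <- evals[key == k, ]
    mm <- e$mismatch_count[e$status == "mismatching"]
    data.frame(
      domain_call = e$domain_call[1L], primer = e$primer[1L],
      incomplete = sum(e$status == "incomplete"),
      matching = sum(e$status == "matching"),
      mismatch_1_2 = sum(mm <= 2L),
      mismatch_ge3 = sum(mm >= 3L),
      unevaluable = sum(e$status == "unevaluable"),
      total = nrow(e),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "complete_sites") <- c(
    evaluated = sum(out$matching + out$mismatch_1_2 + out$mismatch_ge3),
    category_sum = sum(out$matching) + sum(out$mismatch_1_2) + sum(out$mismatch_ge3)
  )
  out
}

#' Fraction of mismatching reads unclassified at a rank
#'
#' The headline statistic of the evaluation stage: among reads classified
#' `mismatching`, the percentage whose lineage is unclassified at the given
#' rank (default phylum).
#'
#' @param evals data.frame from [evaluate_reads()].
#' @param taxonomy data.frame (`id`, `lineage`).
#' @param rank rank at which classification is required.
#' @param unclassified_regex regex identifying unclassified labels.
#' @return percentage in `[0, 100]` (NA when there are no mismatching reads).
#' @export
unclassified_mismatch_percent <- function(evals, taxonomy, rank = "phylum",
                                          unclassified_regex = "unclassified|unknown|uncultured") {
  mm <- evals$read_id[evals$status == "mismatching"]
  if (length(mm) == 0L) return(NA_real_)
  lin <- taxonomy$lineage[match(mm, taxonomy$id)]
  100 * mean(is_unclassified_at(lin, rank, unclassified_regex))
}
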
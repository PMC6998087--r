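.GAP_CHARS <- c("-", ".")

#' Drop alignment columns dominated by gaps
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param max_gap_frac columns with a larger gap fraction are removed
#'   (default 0.5).
#' @return filtered alignment (same names).
#' @export
filter_alignment_columns <- function(aln, max_gap_frac = 0.5) {
  n <- unique(nchar(aln))
  if (length(n) != 1L) stop("sequences are not aligned (unequal lengths)",
                            call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  gapfrac <- colMeans(matrix(mat %in% .GAP_CHARS, nrow = nrow(mat)))
  keep <- gapfrac <= max_gap_frac
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(aln)
  out
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Distance = differences / compared columns, with the standard conventions
#' of the classical 16S distance tools: columns gapped in both sequences are
#' skipped; terminal gap overhangs are ignored; and, when
#' `gap_mode = "onegap"` (default), a run of consecutive gap columns in one
#' sequence counts as a single difference (and a single compared column).
#' `gap_mode = "eachgap"` counts every gap column separately;
#' `terminal_gaps = "count"` treats overhangs like internal gaps.
#'
#' @param a,b aligned sequences (equal length; `-` or `.` for gaps).
#' @param gap_mode `"onegap"` or `"eachgap"`.
#' @param terminal_gaps `"ignore"` or `"count"`.
#' @return distance in `[0, 1]` (NA when no columns are comparable).
#' @examples
#' pairwise_distance("ACGT", "ACGA")  # 0.25
#' @export
pairwise_distance <- function(a, b, gap_mode = c("onegap", "eachgap"),
                              terminal_gaps = c("ignore", "count")) {
  gap_mode <- match.arg(gap_mode)
  terminal_gaps <- match.arg(terminal_gaps)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  ga <- ca %in% .GAP_CHARS
  gb <- cb %in% .GAP_CHARS
  keep <- !(ga & gb)
  if (terminal_gaps == "ignore") {
    nga <- which(!ga); ngb <- which(!gb)
    if (!length(nga) || !length(ngb)) return(NA_real_)
    lo <- max(min(nga), min(ngb)); hi <- min(max(nga), max(ngb))
    keep <- keep & seq_along(ca) >= lo & seq_along(ca) <= hi
  }
  ca <- ca[keep]; cb <- cb[keep]
  ga <- ga[keep]; gb <- gb[keep]
  if (!length(ca)) return(NA_real_)
  state <- ifelse(ga, "GA", ifelse(gb, "GB", ifelse(ca == cb, "M", "X")))
  if (gap_mode == "onegap") {
    r <- rle(state)
    events <- r$values
    nmatch <- sum(r$lengths[events == "M"])
    nmis <- sum(r$lengths[events == "X"])
    ngap <- sum(events %in% c("GA", "GB"))  # one event per run
  } else {
    nmatch <- sum(state == "M")
    nmis <- sum(state == "X")
    ngap <- sum(state %in% c("GA", "GB"))
  }
  total <- nmatch + nmis + ngap
  if (total == 0L) return(NA_real_)
  (nmis + ngap) / total
}

#' Full uncorrected distance matrix of an alignment
#'
#' @param aln named character vector of aligned sequences.
#' @inheritParams pairwise_distance
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, gap_mode = "onegap",
                            terminal_gaps = "ignore") {
  n <- length(aln)
  ids <- names(aln)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(aln[[i]], aln[[j]],
                                              gap_mode, terminal_gaps)
    }
  }
  d
}

#' Intra- and inter-group distance summaries
#'
#' Computes, for each group and each group pair, the minimum, mean and
#' maximum uncorrected pairwise distance -- the quantities behind
#' violin-plot style novelty assessments and candidate-phylum calls.
#' Singleton groups have no intra-group pairs and are reported with
#' `n_pairs = 0` and NA distances.
#'
#' @param aln named character vector of aligned sequences (or a precomputed
#'   square distance matrix).
#' @param groups named character vector or data.frame (`id`, `group`)
#'   mapping sequence ids to group labels.
#' @inheritParams pairwise_distance
#' @param keep_raw also return the raw per-pair distance vectors (for
#'   plotting) as attribute `"raw"`.
#' @return data.frame: `group_a`, `group_b`, `type` (`intra`/`inter`),
#'   `min_dist`, `mean_dist`, `max_dist`, `n_pairs`.
#' @export
group_summaries <- function(aln, groups, gap_mode = "onegap",
                            terminal_gaps = "ignore", keep_raw = FALSE) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$id)
  }
  d <- if (is.matrix(aln)) aln else
    distance_matrix(aln, gap_mode, terminal_gaps)
  ids <- rownames(d)
  g <- groups[ids]
  if (anyNA(g)) stop("sequences without a group label: ",
                     paste(utils::head(ids[is.na(g)], 3L), collapse = ", "),
                     call. = FALSE)
  gl <- sort(unique(g))
  rows <- list(); raw <- list()
  summ <- function(v) {
    if (!length(v)) c(NA_real_, NA_real_, NA_real_) else
      c(min(v), mean(v), max(v))
  }
  for (i in seq_along(gl)) {
    for (j in i:length(gl)) {
      ai <- which(g == gl[i]); aj <- which(g == gl[j])
      if (i == j) {
        v <- if (length(ai) > 1L) d[ai, ai][upper.tri(d[ai, ai])] else numeric()
        type <- "intra"
      } else {
        v <- as.vector(d[ai, aj, drop = FALSE])
        type <- "inter"
      }
      s <- summ(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gl[i], group_b = gl[j], type = type,
        min_dist = s[1L], mean_dist = s[2L], max_dist = s[3L],
        n_pairs = length(v), stringsAsFactors = FALSE
      )
      if (keep_raw) raw[[paste(gl[i], gl[j], sep = "|")]] <- v
    }
  }
  out <- do.call(rbind, rows)
  if (keep_raw) attr(out, "raw") <- raw
  out
}

#' Candidate-phylum call from an inter-group distance summary
#'
#' A group is called a candidate phylum relative to another when even its
#' closest member exceeds the phylum-level identity threshold: the call fires
#' iff `min_dist > 1 - identity_threshold` (strictly; with the proposed 0.75
#' identity threshold that is a minimum distance strictly above 0.25).
#'
#' @param min_dist minimum inter-group distance (or a row/data.frame from
#'   [group_summaries()], in which case `min_dist` columns are used).
#' @param identity_threshold phylum-level identity threshold (default 0.75).
#' @return logical.
#' @examples
#' candidate_phylum_call(0.26)  # TRUE
#' candidate_phylum_call(0.25)  # FALSE (boundary is exclusive)
#' @export
candidate_phylum_call <- function(min_dist, identity_threshold = 0.75) {
  if (is.data.frame(min_dist)) min_dist <- min_dist$min_dist
  min_dist > (1 - identity_threshold)
}

#' Cluster near-full-length sequences into OTUs
#'
#' Applies the full-length workflow: drop gaps, discard sequences not longer
#' than `min_length` (near-full-length filter), and cluster the remainder
#' with [cluster_greedy()] at the species-level cutoff.
#'
#' @param seqs named character vector (aligned or unaligned).
#' @param cutoff identity cutoff (default 0.97).
#' @param min_length sequences must be strictly longer than this many
#'   ungapped nucleotides (default 1200).
#' @param ... passed to [cluster_greedy()].
#' @return an `"ssu_clustering"` object (see [cluster_greedy()]); attribute
#'   `"excluded"` lists ids removed by the length filter.
#' @export
cluster_full_length <- function(seqs, cutoff = 0.97, min_length = 1200L, ...) {
  degap <- gsub("[-.]", "", seqs)
  keep <- nchar(degap) > min_length
  if (!any(keep)) stop("no sequence passes the length filter", call. = FALSE)
  cl <- cluster_greedy(degap[keep], cutoff = cutoff, ...)
  attr(cl, "excluded") <- names(seqs)[!keep]
  cl
}

#' Progressive center-star alignment for small sequence sets
#'
#' A bundled fallback for aligning *small synthetic* test sets when no
#' external aligner output is available: the longest sequence is the center,
#' every other sequence is globally aligned to it, and insertions relative to
#' the center are propagated across the set.  Not intended for real rRNA
#' alignments.
#'
#' @param seqs named character vector (ungapped).
#' @return named character vector of equal-length aligned sequences.
#' @export
align_small <- function(seqs) {
  if (length(seqs) < 2L) return(seqs)
  if (length(seqs) > 200L) {
    stop("align_small is a small-set fallback (<= 200 sequences)", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  center_i <- which.max(nchar(seqs))
  center <- as.character(seqs[[center_i]])
  others <- setdiff(seq_along(seqs), center_i)

  pats <- subjs <- vector("list", length(seqs))
  for (i in others) {
    al <- Biostrings::pairwiseAlignment(seqs[[i]], center, type = "global",
                                        gapOpening = 4, gapExtension = 1)
    pats[[i]] <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    subjs[[i]] <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  }
  nc <- nchar(center)
  # maximum insertion length after each center position (0 = before first)
  ins <- integer(nc + 1L)
  for (i in others) {
    sj <- subjs[[i]]
    pos <- cumsum(sj != "-")           # center coordinate per column
    run <- rle(sj == "-")
    idx <- cumsum(run$lengths)
    for (k in which(run$values)) {
      at <- if (k == 1L) 0L else pos[idx[k - 1L]]
      ins[at + 1L] <- max(ins[at + 1L], run$lengths[k])
    }
  }
  pad <- function(chars, subj_chars) {
    # rebuild one row in the global (center + max insertions) coordinates
    out <- character(0L)
    ci <- 0L
    buf <- character(0L)
    for (col in seq_along(subj_chars)) {
      if (subj_chars[col] == "-") {
        buf <- c(buf, chars[col])
      } else {
        out <- c(out, buf, rep("-", ins[ci + 1L] - length(buf)))
        buf <- character(0L)
        ci <- ci + 1L
        out <- c(out, chars[col])
      }
    }
    out <- c(out, buf, rep("-", ins[ci + 1L] - length(buf)))
    paste(out, collapse = "")
  }
  res <- character(length(seqs))
  ctr_chars <- strsplit(center, "")[[1L]]
  out <- character(0L)
  for (p in seq_len(nc)) {
    out <- c(out, rep("-", ins[p]), ctr_chars[p])
  }
  out <- c(out, rep("-", ins[nc + 1L]))
  res[center_i] <- paste(out, collapse = "")
  for (i in others) {
    res[i] <- pad(pats[[i]], subjs[[i]])
  }
  names(res) <- ids
  res
}
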
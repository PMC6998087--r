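# Nearest-neighbor thermodynamic parameters (unified duplex set):
# dH kcal/mol, dS cal/(mol K), 5'->3' dinucleotides; complements share values.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
.NN_INIT_DH <- c(AT = 2.3, GC = 0.1)   # per terminal A/T or G/C end
.NN_INIT_DS <- c(AT = 4.1, GC = -2.8)

.nn_key <- function(din) {
  if (din %in% names(.NN_DH)) return(din)
  rc <- reverse_complement(din)
  if (!rc %in% names(.NN_DH)) stop("no NN parameters for ", din, call. = FALSE)
  rc
}

#' Oligonucleotide melting temperature
#'
#' Two models are available.  `"wallace"` (default) is the Wallace rule
#' `Tm = 2(A+T) + 4(G+C)`: transparent, hand-checkable, and adequate for the
#' 16-20-mer primers gated to a 45-52 degree window here.  `"nn"` is the
#' unified nearest-neighbor model with entropy-based monovalent salt
#' correction (`dS + 0.368 (N-1) ln[Na+]`) evaluated at 50 mM Na+ and 500 nM
#' oligonucleotide (`Tm = 1000 dH / (dS_corr + R ln(C/4)) - 273.15`).
#'
#' @param seq concrete A/C/G/T sequence (expand degenerate primers first,
#'   see [expand_iupac()]).
#' @param method `"wallace"` or `"nn"`.
#' @param Na_mM monovalent cation concentration (nearest-neighbor only).
#' @param oligo_nM total oligonucleotide concentration (nearest-neighbor only).
#' @return melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ATCGATCGATCGATCG")            # Wallace: 48
#' melting_temperature("ATCGATCGATCGATCG", "nn")
#' @export
melting_temperature <- function(seq, method = c("wallace", "nn"),
                                Na_mM = 50, oligo_nM = 500) {
  method <- match.arg(method)
  s <- normalize_seq(primer_sequence(seq))
  if (degeneracy(s) > 1L) {
    stop("degenerate sequence: expand with expand_iupac() before computing Tm",
         call. = FALSE)
  }
  n <- nchar(s)
  if (n < 10L || n > 40L) {
    stop("melting_temperature supports 10-40 nt oligos", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (method == "wallace") {
    at <- sum(chars %in% c("A", "T"))
    return(2 * at + 4 * (n - at))
  }
  dins <- paste0(chars[-n], chars[-1L])
  keys <- vapply(dins, .nn_key, "")
  ends <- ifelse(chars[c(1L, n)] %in% c("G", "C"), "GC", "AT")
  dH <- sum(.NN_DH[keys]) + sum(.NN_INIT_DH[ends])
  dS <- sum(.NN_DS[keys]) + sum(.NN_INIT_DS[ends])
  dS <- dS + 0.368 * (n - 1) * log(Na_mM / 1000)
  R <- 1.987
  1000 * dH / (dS + R * log(oligo_nM * 1e-9 / 4)) - 273.15
}

# Tm range over all expansions of a degenerate sequence.  Under the Wallace
# rule the extremes follow per-position from the expansion sets; the NN model
# enumerates expansions.
.tm_range <- function(seq, method, cap = 64L) {
  s <- normalize_seq(seq)
  if (method == "wallace") {
    contrib <- lapply(seq_bits(s), function(b) {
      bases <- .CONCRETE[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
      ifelse(bases %in% c("G", "C"), 4, 2)
    })
    c(sum(vapply(contrib, min, 0)), sum(vapply(contrib, max, 0)))
  } else {
    tms <- vapply(expand_iupac(s, cap = cap), melting_temperature,
                  0, method = "nn")
    range(tms)
  }
}

#' Degenerate consensus of a group's design window
#'
#' @param seqs group member sequences (5'-anchored).
#' @param window number of leading nucleotides to use.
#' @return IUPAC consensus of the first `window` nt (members shorter than
#'   `window` are dropped with a warning).
#' @export
group_consensus <- function(seqs, window = 100L) {
  keep <- nchar(seqs) >= window
  if (!any(keep)) stop("no sequence reaches the design window", call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " sequence(s) shorter than the design window dropped")
  }
  union_consensus(substr(seqs[keep], 1L, window))
}

#' Enumerate targeted forward-primer candidates in a design window
#'
#' Scans every substring of the group consensus within the 5' design window
#' (default first 100 nt) at lengths 16-20 and keeps those whose melting
#' temperature lies inside the gate for *all* expansions (strict gate: every
#' covered variant must be amplifiable) and whose degeneracy does not exceed
#' the cap.  By construction every candidate covers all group members used to
#' build the consensus with zero mismatches.
#'
#' @param consensus group consensus (IUPAC) from [group_consensus()].
#' @param window design window length in nt from the 5' end.
#' @param lengths candidate lengths.
#' @param tm_range numeric length-2, inclusive Tm gate in degrees Celsius.
#' @param tm_method `"wallace"` or `"nn"` (see [melting_temperature()]).
#' @param degeneracy_cap maximum candidate degeneracy.
#' @param references,target_ids optional reference set for an immediate
#'   [specificity_check()]; candidates are then sorted by off-target hits
#'   (ascending) and maximum Tm.
#' @param max_mismatches passed to [specificity_check()].
#' @return data.frame: `sequence`, `dialect`, `start` (0-based), `length`,
#'   `tm_min`, `tm_max`, `degeneracy`, `on_target_hits`, `off_target_hits`.
#' @export
enumerate_candidates <- function(consensus, window = 100L, lengths = 16:20,
                                 tm_range = c(45, 52),
                                 tm_method = c("wallace", "nn"),
                                 degeneracy_cap = 32L,
                                 references = NULL, target_ids = NULL,
                                 max_mismatches = 0L) {
  tm_method <- match.arg(tm_method)
  cons <- normalize_seq(primer_sequence(consensus), "consensus")
  win <- substr(cons, 1L, min(window, nchar(cons)))
  if (nchar(win) < min(lengths)) {
    stop("design window shorter than the smallest primer length", call. = FALSE)
  }
  rows <- list()
  for (len in lengths) {
    if (nchar(win) < len) next
    for (start in 0:(nchar(win) - len)) {
      cand <- substr(win, start + 1L, start + len)
      d <- degeneracy(cand)
      if (d > degeneracy_cap) next
      tm <- .tm_range(cand, tm_method, cap = degeneracy_cap)
      if (tm[1L] < tm_range[1L] || tm[2L] > tm_range[2L]) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = cand, dialect = to_primer_dialect(cand),
        start = start, length = len, tm_min = tm[1L], tm_max = tm[2L],
        degeneracy = d, on_target_hits = NA_integer_,
        off_target_hits = NA_integer_, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), dialect = character(),
               start = integer(), length = integer(), tm_min = numeric(),
               tm_max = numeric(), degeneracy = integer(),
               on_target_hits = integer(), off_target_hits = integer(),
               stringsAsFactors = FALSE)
  if (!is.null(references) && nrow(out)) {
    sp <- lapply(out$sequence, specificity_check, references = references,
                 target_ids = target_ids, max_mismatches = max_mismatches)
    out$on_target_hits <- vapply(sp, `[[`, 0L, "on_target")
    out$off_target_hits <- vapply(sp, `[[`, 0L, "off_target")
    out <- out[order(out$off_target_hits, -out$tm_max, out$start), ]
    rownames(out) <- NULL
  }
  out
}

# Per-offset mismatch counts of a primer along one subject sequence.
# Returns integer vector over 0-based offsets 0..(nchar(subject)-L).
.scan_mismatches <- function(primer_bits, subject) {
  L <- length(primer_bits)
  sb <- seq_bits(subject)
  n <- length(sb)
  if (n < L) return(integer(0L))
  W <- n - L + 1L
  tot <- integer(W)
  for (p in seq_len(L)) {
    slice <- sb[p:(p + W - 1L)]
    tot <- tot + as.integer(bitwAnd(slice, bitwNot(primer_bits[p])) != 0L)
  }
  tot
}

#' Count reference hits of a forward-primer candidate
#'
#' A reference is a hit when it contains, on its forward strand, a site
#' matching the candidate with at most `max_mismatches` mismatches and no
#' mismatch in the last `protect_3prime` primer positions (the 3'-weighted
#' matching rule).  Hits are split into on-target and off-target by
#' membership in `target_ids`.
#'
#' @param candidate candidate sequence (IUPAC) or [primer()].
#' @param references named character vector of reference sequences.
#' @param target_ids reference ids belonging to the target group.
#' @param max_mismatches maximum mismatches outside the protected 3' end.
#' @param protect_3prime number of 3'-terminal positions that must match.
#' @return list with `on_target`, `off_target`, and logical `hit` per
#'   reference.
#' @export
specificity_check <- function(candidate, references, target_ids = character(),
                              max_mismatches = 0L, protect_3prime = 4L) {
  if (length(references) == 0L) stop("empty reference set", call. = FALSE)
  p <- normalize_seq(primer_sequence(candidate), "candidate")
  pb <- seq_bits(p)
  L <- length(pb)
  core <- seq_len(max(L - protect_3prime, 0L))
  tail3 <- setdiff(seq_len(L), core)
  hit <- vapply(references, function(s) {
    s <- toupper(chartr("uU", "TT", s))
    sb <- seq_bits(s)
    n <- length(sb)
    if (n < L) return(FALSE)
    W <- n - L + 1L
    mm_core <- integer(W)
    for (q in core) {
      slice <- sb[q:(q + W - 1L)]
      mm_core <- mm_core + as.integer(bitwAnd(slice, bitwNot(pb[q])) != 0L)
    }
    mm_tail <- integer(W)
    for (q in tail3) {
      slice <- sb[q:(q + W - 1L)]
      mm_tail <- mm_tail + as.integer(bitwAnd(slice, bitwNot(pb[q])) != 0L)
    }
    any(mm_tail == 0L & mm_core <= max_mismatches)
  }, logical(1L))
  ids <- names(references)
  if (is.null(ids)) ids <- paste0("ref", seq_along(references))
  on <- sum(hit[ids %in% target_ids])
  list(on_target = as.integer(on),
       off_target = as.integer(sum(hit) - on),
       hit = stats::setNames(hit, ids))
}

#' Merge group binding sites into one degenerate primer
#'
#' Takes concrete (or degenerate) sites from one or more groups, already
#' registered over a common window, and returns their [union_consensus()].
#' Fails when the merged degeneracy exceeds the cap, reporting the most
#' degenerate positions.
#'
#' @param site_groups character vector or list of character vectors of
#'   equal-length sites.
#' @param degeneracy_cap maximum permitted degeneracy.
#' @return the merged degenerate sequence (character).
#' @examples
#' merge_degenerate(list(c("GGACACTGCTATCGGCTT", "GGGCACTGCTATCGGCTT"),
#'                       "GCCTACTGCTATCGGATT"))
#' @export
merge_degenerate <- function(site_groups, degeneracy_cap = 32L) {
  sites <- unlist(site_groups, use.names = FALSE)
  merged <- union_consensus(sites)
  d <- degeneracy(merged)
  if (d > degeneracy_cap) {
    counts <- vapply(seq_bits(merged), function(b)
      sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), 1L)
    off <- which(counts > 1L)
    stop(sprintf("merged degeneracy %d exceeds cap %d; degenerate positions: %s",
                 d, degeneracy_cap,
                 paste(sprintf("%d(%s)", off,
                               strsplit(merged, "")[[1L]][off]), collapse = " ")),
         call. = FALSE)
  }
  merged
}

#' Register two groups' design windows for merging
#'
#' The published record of a merged degenerate primer rarely states the
#' alignment offset between the two target regions, so the registration is
#' recovered by search: all (start, start) placements of a `length`-nt window
#' in the two group consensuses are scored by the number of positions whose
#' expansion sets are disjoint, and the placement minimizing that count wins
#' (ties: smaller offset difference, then smaller first start).
#'
#' @param sites_a,sites_b character vectors of 5'-anchored sequences for the
#'   two groups (equal lengths within each group).
#' @param length window length to register.
#' @param window search region from the 5' end.
#' @return list with `start_a`, `start_b` (0-based), `length`, `disjoint`
#'   (mismatched-set positions), `merged` (degenerate sequence) and
#'   `degeneracy`.
#' @export
find_shared_window <- function(sites_a, sites_b, length = 18L, window = 100L) {
  consa <- union_consensus(substr(sites_a, 1L, min(window, min(nchar(sites_a)))))
  consb <- union_consensus(substr(sites_b, 1L, min(window, min(nchar(sites_b)))))
  ba <- seq_bits(consa); bb <- seq_bits(consb)
  na <- base::length(ba); nb <- base::length(bb)
  if (na < length || nb < length) stop("window shorter than requested length",
                                       call. = FALSE)
  best <- NULL
  for (sa in 0:(na - length)) {
    wa <- ba[(sa + 1L):(sa + length)]
    for (sb in 0:(nb - length)) {
      wb <- bb[(sb + 1L):(sb + length)]
      disjoint <- sum(bitwAnd(wa, wb) == 0L)
      cand <- list(start_a = sa, start_b = sb, disjoint = disjoint)
      # ties: smaller offset difference, then the 3'-most window (sequence
      # conservation increases downstream of the V1 region, so the most
      # distal of equally good windows is the better merge target)
      if (is.null(best) ||
          disjoint < best$disjoint ||
          (disjoint == best$disjoint &&
           (abs(sa - sb) < abs(best$start_a - best$start_b) ||
            (abs(sa - sb) == abs(best$start_a - best$start_b) &&
             sa > best$start_a)))) {
        best <- cand
      }
    }
  }
  wa <- substr(consa, best$start_a + 1L, best$start_a + length)
  wb <- substr(consb, best$start_b + 1L, best$start_b + length)
  merged <- union_consensus(c(wa, wb))
  list(start_a = best$start_a, start_b = best$start_b, length = length,
       disjoint = best$disjoint, merged = merged,
       degeneracy = degeneracy(merged))
}

#' In-silico coverage of a primer over a sequence set
#'
#' For each sequence, finds the best placement of the primer (minimum
#' mismatch count over all forward-strand offsets, smallest offset on ties)
#' and classifies it with the site-evaluation rule: `matching` for 0
#' mismatches or a single mismatch outside the last four primer positions,
#' `mismatching` otherwise.
#'
#' @param primer primer sequence (IUPAC) or [primer()].
#' @param seqs named character vector of sequences.
#' @return data.frame: `id`, `best_start` (0-based), `mismatches`, `call`
#'   (`matching`/`mismatching`/`too_short`).
#' @export
coverage <- function(primer, seqs) {
  p <- normalize_seq(primer_sequence(primer), "primer")
  pb <- seq_bits(p)
  L <- length(pb)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- toupper(chartr("uU", "TT", seqs[[i]]))
    mm <- .scan_mismatches(pb, s)
    if (length(mm) == 0L) {
      return(data.frame(id = ids[i], best_start = NA_integer_,
                        mismatches = NA_integer_, call = "too_short",
                        stringsAsFactors = FALSE))
    }
    off <- which.min(mm) - 1L
    site <- substr(s, off + 1L, off + L)
    pos <- mismatch_positions(p, site)
    call <- if (length(pos) == 0L ||
                (length(pos) == 1L && pos <= L - 4L)) "matching" else "mismatching"
    data.frame(id = ids[i], best_start = off,
               mismatches = length(pos), call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
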
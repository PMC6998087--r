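# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own matching/alignment code paths.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# all concrete expansions of a degenerate sequence, by explicit recursion
oracle_expand <- function(seq) {
  sets <- IUPAC_SETS[strsplit(toupper(seq), "")[[1L]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# minimum Hamming distance of a concrete site to any expansion of the primer
oracle_min_mismatch <- function(primer, site) {
  exps <- oracle_expand(primer)
  sc <- strsplit(site, "")[[1L]]
  min(vapply(exps, function(e) {
    sum(strsplit(e, "")[[1L]] != sc)
  }, 0L))
}

# the published classification rule, written straight from its definition
oracle_status <- function(primer, site) {
  exps <- oracle_expand(primer)
  sc <- strsplit(site, "")[[1L]]
  L <- length(sc)
  best <- NULL
  for (e in exps) {
    mm <- which(strsplit(e, "")[[1L]] != sc)
    if (is.null(best) || length(mm) < length(best)) best <- mm
  }
  if (length(best) == 0L) return("matching")
  if (length(best) == 1L && best > L - 4L) return("mismatching")
  if (length(best) == 1L) return("matching")
  "mismatching"
}

# uncorrected distance by an explicit column walk (gap runs = one event,
# both-gap columns skipped, terminal overhangs ignored)
oracle_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  gap <- function(x) x %in% c("-", ".")
  nga <- which(!gap(ca)); ngb <- which(!gap(cb))
  lo <- max(min(nga), min(ngb)); hi <- min(max(nga), max(ngb))
  diffs <- 0; total <- 0
  in_ga <- FALSE; in_gb <- FALSE
  for (i in seq_along(ca)) {
    if (i < lo || i > hi) next
    ga <- gap(ca[i]); gb <- gap(cb[i])
    if (ga && gb) next
    if (ga) {
      if (!in_ga) { diffs <- diffs + 1; total <- total + 1 }
      in_ga <- TRUE; in_gb <- FALSE
    } else if (gb) {
      if (!in_gb) { diffs <- diffs + 1; total <- total + 1 }
      in_gb <- TRUE; in_ga <- FALSE
    } else {
      in_ga <- in_gb <- FALSE
      total <- total + 1
      if (ca[i] != cb[i]) diffs <- diffs + 1
    }
  }
  if (total == 0) return(NA_real_)
  diffs / total
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# mutate a concrete sequence at k random positions (always to a new base)
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

ARCH21F <- "TTCCGGTTGATCCTGCCGGA"

# random aligned pair with internal gap runs and terminal overhangs
random_gapped_pair <- function(n = 60) {
  gapify <- function(x) {
    if (stats::runif(1) < 0.7) {
      at <- sample(5:(n - 6), 1)
      x[at:(at + sample(1:3, 1))] <- "-"
    }
    if (stats::runif(1) < 0.3) x[1:sample(1:4, 1)] <- "-"
    if (stats::runif(1) < 0.3) x[(n - sample(0:3, 1)):n] <- "-"
    x
  }
  a <- gapify(strsplit(random_seq(n), "")[[1L]])
  b <- gapify(strsplit(mutate_seq(paste(a, collapse = ""), sample(0:8, 1)),
                       "")[[1L]])
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}
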
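primers <- builtin_primers()

eval1 <- function(read, lineage = "", ...) {
  tax <- data.frame(id = "r1", lineage = lineage, stringsAsFactors = FALSE)
  evaluate_reads(c(r1 = read), taxonomy = tax, ...)
}

test_that("published site patterns are reproduced exactly", {
  # Type A site (OTU11)
  ev <- eval1(paste0("CTCTAGTTGATCCTGCTAGA", random_seq(60)))
  expect_identical(ev$pattern, "C==TA===========TA==")
  expect_identical(ev$mismatch_count, 5L)
  expect_identical(ev$status, "mismatching")
  # Type B site (OTU8)
  ev <- eval1(paste0("TTCCGTTCGATCCTGACGGA", random_seq(60)))
  expect_identical(ev$pattern, "=====T=C=======A====")
  expect_identical(ev$mismatch_count, 3L)
  expect_identical(ev$status, "mismatching")
})

test_that("single-mismatch classification follows the 3'-end rule", {
  site <- ARCH21F
  # position 20 (inside the last four): mismatching
  s <- site; substr(s, 20, 20) <- "C"
  expect_identical(eval1(paste0(s, random_seq(40)))$status, "mismatching")
  # position 5 (outside): matching
  s <- site; substr(s, 5, 5) <- "A"
  ev <- eval1(paste0(s, random_seq(40)))
  expect_identical(ev$status, "matching")
  expect_identical(ev$mismatch_count, 1L)
})

test_that("reads shorter than the primer are incomplete, never scored", {
  ev <- eval1(substr(ARCH21F, 1, 10))
  expect_identical(ev$status, "incomplete")
  expect_true(is.na(ev$pattern))
  expect_true(is.na(ev$mismatch_count))
})

test_that("excessively ambiguous sites are unevaluable, not dropped", {
  s <- ARCH21F
  substr(s, 2, 4) <- "NNN"
  ev <- eval1(paste0(s, random_seq(40)))
  expect_identical(ev$status, "unevaluable")
  ev2 <- eval1(paste0(s, random_seq(40)), max_ambig_frac = 0.5)
  expect_identical(ev2$status, "mismatching")  # N counted as mismatches
})

test_that("offset scanning finds shifted sites and is monotone", {
  read <- paste0("GCT", ARCH21F, random_seq(40))  # 3-nt adaptor residue
  ev0 <- eval1(read, max_offset = 0)
  ev5 <- eval1(read, max_offset = 5)
  expect_identical(ev5$site_start, 3L)
  expect_identical(ev5$mismatch_count, 0L)
  expect_true(ev0$mismatch_count >= ev5$mismatch_count)
  # monotonicity across a sweep of offsets
  set.seed(21)
  for (i in 1:10) {
    r <- paste0(random_seq(sample(0:4, 1)), mutate_seq(ARCH21F, 2),
                random_seq(40))
    mm <- vapply(0:5, function(k) eval1(r, max_offset = k)$mismatch_count, 0L)
    expect_true(all(diff(mm) <= 0L), info = r)
  }
})

test_that("reads are routed to their domain's primer", {
  reads <- c(b = paste0("AGAGTTTGATCCTGGCTCAG", random_seq(40)),
             a = paste0(ARCH21F, random_seq(40)),
             u = paste0(ARCH21F, random_seq(40)))
  tax <- data.frame(id = c("b", "a", "u"),
                    lineage = c("Bacteria;Proteobacteria",
                                "Archaea;Euryarchaeota", ""))
  ev <- evaluate_reads(reads, tax)
  expect_identical(ev$primer, c("8F", "Arch21F", "Arch21F"))
  expect_identical(ev$domain_call, c("Bacteria", "Archaea", "Unclassified"))
  expect_identical(ev$status, rep("matching", 3))
})

test_that("evaluation agrees with the brute-force expansion oracle", {
  set.seed(77)
  for (p in list(primers$`8F`, primers$Arch21F, primers$`26ABF`)) {
    L <- nchar(p$sequence)
    for (i in 1:40) {
      base <- sample(oracle_expand(p$sequence), 1)
      site <- mutate_seq(base, sample(0:5, 1))
      ev <- evaluate_reads(c(r1 = paste0(site, random_seq(30))),
                           primers = stats::setNames(list(p), "Arch21F"),
                           assignment = c(Unclassified = "Arch21F"))
      expect_identical(ev$mismatch_count,
                       oracle_min_mismatch(p$sequence, site),
                       info = site)
      expect_identical(ev$status, oracle_status(p$sequence, site),
                       info = site)
    }
  }
})

test_that("patterns round-trip through the primer reference expansion", {
  reconstructed <- apply_pattern(primers$Arch21F, "C==TA===========TA==")
  expect_identical(reconstructed, "CTCTAGTTGATCCTGCTAGA")
  expect_identical(reconstructed, primers$`21AF`$sequence)
  set.seed(13)
  for (i in 1:20) {
    site <- mutate_seq(ARCH21F, sample(0:6, 1))
    ev <- eval1(paste0(site, random_seq(30)))
    if (ev$status %in% c("matching", "mismatching")) {
      expect_identical(apply_pattern(ARCH21F, ev$pattern), site)
    }
  }
})

test_that("every read lands in exactly one status class", {
  set.seed(31)
  reads <- c(
    stats::setNames(replicate(30, paste0(mutate_seq(ARCH21F, sample(0:6, 1)),
                                         random_seq(30))),
                    paste0("m", 1:30)),
    stats::setNames(replicate(5, random_seq(sample(3:15, 1))),
                    paste0("s", 1:5))
  )
  ev <- evaluate_reads(reads)
  expect_true(all(ev$status %in%
    c("incomplete", "matching", "mismatching", "unevaluable")))
  expect_identical(nrow(ev), length(reads))
  expect_false(anyNA(ev$status))
})

test_that("summaries recover planted category counts exactly", {
  set.seed(41)
  mk <- function(n, f) stats::setNames(replicate(n, f()), NULL)
  match0 <- replicate(50, paste0(ARCH21F, random_seq(30)))
  one_mm <- replicate(12, {
    s <- ARCH21F; substr(s, 7, 7) <- "A"; paste0(s, random_seq(30))
  })
  two_mm <- replicate(8, {
    s <- ARCH21F; substr(s, 2, 2) <- "G"; substr(s, 9, 9) <- "T"
    paste0(s, random_seq(30))
  })
  heavy <- replicate(5, paste0("CTCTAGTTGATCCTGCTAGA", random_seq(30)))
  short <- replicate(3, substr(ARCH21F, 1, 8))
  reads <- c(match0, one_mm, two_mm, heavy, short)
  names(reads) <- paste0("r", seq_along(reads))
  ev <- evaluate_reads(reads)
  sm <- summarize_evaluations(ev)
  expect_identical(sm$matching, 62L)       # 50 perfect + 12 one-mismatch
  expect_identical(sm$mismatch_1_2, 8L)
  expect_identical(sm$mismatch_ge3, 5L)
  expect_identical(sm$incomplete, 3L)
  expect_identical(sm$total, 78L)
  cs <- attr(sm, "complete_sites")
  expect_identical(unname(cs["evaluated"]), 75L)
  expect_identical(unname(cs["category_sum"]), 75L)
})

test_that("duplicate read ids are rejected", {
  expect_error(evaluate_reads(c(a = ARCH21F, a = ARCH21F)), "duplicate")
})

test_that("unclassified fraction among mismatched reads matches arithmetic", {
  # printed-count identity: 11145 / 15882 = 70.2% at one decimal
  expect_identical(round(100 * 11145 / 15882, 1), 70.2)
  # and the function computes the same statistic from evaluations
  n_un <- 53; n_cl <- 22
  reads <- stats::setNames(
    replicate(n_un + n_cl, paste0("CTCTAGTTGATCCTGCTAGA", random_seq(30))),
    paste0("r", seq_len(n_un + n_cl)))
  tax <- data.frame(id = names(reads),
                    lineage = c(rep("", n_un),
                                rep("Archaea;Euryarchaeota", n_cl)))
  ev <- evaluate_reads(reads, tax)
  expect_equal(unclassified_mismatch_percent(ev, tax),
               100 * n_un / (n_un + n_cl))
})
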
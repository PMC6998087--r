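primers <- builtin_primers()

test_that("Wallace melting temperatures follow the closed form", {
  expect_identical(melting_temperature("ATCGATCGATCGATCG"), 48)
  expect_lt(melting_temperature(strrep("A", 16)),
            melting_temperature(strrep("G", 16)))
  set.seed(7)
  for (i in 1:15) {
    s <- random_seq(sample(16:20, 1))
    gc <- nchar(gsub("[AT]", "", s))
    expect_identical(melting_temperature(s),
                     2 * (nchar(s) - gc) + 4 * gc)
  }
  expect_error(melting_temperature("ACGT"), "10-40")
  expect_error(melting_temperature("ACGTRACGTA"), "degenerate")
})

test_that("nearest-neighbor Tm matches a published-parameter reference", {
  # reference values from an independent implementation of the unified NN
  # model (50 mM Na+, 500 nM oligo, entropy salt correction)
  ref <- c(ATCGATCGATCGATCG = 48.2806,
           GCCTACTGCTATCGGATT = 51.2577,
           AAGTCGAACGGACACGCAT = 57.6081,
           CTCTAGTTGATCCTGCTAGA = 50.3780)
  for (s in names(ref)) {
    expect_lt(abs(melting_temperature(s, "nn") - ref[[s]]), 0.5)
  }
})

test_that("candidate enumeration is exhaustive and correctly gated", {
  cons <- paste0("CTCTAGTTGATCCTGCTAGA", strrep("AT", 15))
  cand <- enumerate_candidates(cons, window = 50, tm_method = "nn")
  # the published Type A primer sits at offset 0 and passes the NN gate
  expect_true("CTCTAGTTGATCCTGCTAGA" %in% cand$sequence)
  # brute-force exhaustiveness oracle
  win <- substr(cons, 1, 50)
  expected <- character()
  for (len in 16:20) {
    for (st in 0:(nchar(win) - len)) {
      sub <- substr(win, st + 1, st + len)
      tms <- vapply(oracle_expand(sub), melting_temperature, 0, method = "nn")
      if (length(oracle_expand(sub)) <= 32 &&
          min(tms) >= 45 && max(tms) <= 52) {
        expected <- c(expected, sub)
      }
    }
  }
  expect_setequal(cand$sequence, expected)
})

test_that("homopolymer windows yield no candidate under the Tm gate", {
  expect_identical(nrow(enumerate_candidates(strrep("A", 100))), 0L)
  expect_error(enumerate_candidates("ACGTACGT", window = 8), "shorter")
})

test_that("degenerate candidates respect the strict all-expansion gate", {
  # R at one position: both expansions must sit inside the window
  cons <- paste0("GCCTACTGCTATCGGATT", strrep("A", 40))
  cand <- enumerate_candidates(cons, tm_method = "wallace")
  for (i in seq_len(nrow(cand))) {
    tms <- vapply(oracle_expand(cand$sequence[i]), melting_temperature, 0)
    expect_gte(min(tms), 45); expect_lte(max(tms), 52)
  }
})

test_that("specificity counts planted on/off-target hits exactly", {
  set.seed(88)
  cand <- "GCCTACTGCTATCGGATT"
  targets <- stats::setNames(lapply(1:7, function(i)
    paste0(random_seq(30), cand, random_seq(50))), paste0("t", 1:7))
  decoys <- stats::setNames(lapply(1:5, function(i) random_seq(100)),
                            paste0("d", 1:5))
  refs <- unlist(c(targets, decoys))
  sp <- specificity_check(cand, refs, target_ids = paste0("t", 1:7))
  expect_identical(sp$on_target, 7L)
  expect_identical(sp$off_target, 0L)
  # planting the site in a decoy creates one off-target hit
  refs[["d1"]] <- paste0(cand, random_seq(60))
  sp2 <- specificity_check(cand, refs, target_ids = paste0("t", 1:7))
  expect_identical(sp2$off_target, 1L)
})

test_that("the protected 3' end vetoes hits even with mismatch budget", {
  cand <- "GCCTACTGCTATCGGATT"
  hit_site <- cand
  substr(hit_site, 2, 2) <- "T"            # 5'-side mismatch
  veto_site <- cand
  substr(veto_site, 17, 17) <- "C"         # inside the last four
  refs <- c(ok = paste0(random_seq(20), hit_site, random_seq(20)),
            veto = paste0(random_seq(20), veto_site, random_seq(20)))
  sp <- specificity_check(cand, refs, target_ids = "ok", max_mismatches = 1)
  expect_identical(sp$on_target, 1L)
  expect_identical(sp$off_target, 0L)
})

test_that("merging group sites reproduces the published degenerate primer", {
  sitesA <- c("GGACACTGCTATCGGCTT", "GGGCACTGCTATCGGCTT")
  siteB <- "GCCTACTGCTATCGGATT"
  merged <- merge_degenerate(list(sitesA, siteB))
  expect_identical(merged, primers$`26ABF`$sequence)
  expect_identical(degeneracy(merged), 24L)
  # defining property: the merged primer covers every input with 0 mismatches
  for (s in c(sitesA, siteB)) {
    expect_identical(mismatch_positions(merged, s), integer(0))
  }
  expect_identical(merge_degenerate(c("ACGTACGTACGTACGT", "ACGTACGTACGTACGT")),
                   "ACGTACGTACGTACGT")
  expect_identical(substr(merge_degenerate(c("AACC", "GACC"),
                                           degeneracy_cap = 4), 1, 1), "R")
  expect_error(merge_degenerate(c("AAAA", "CCCC", "GGGG", "TTTT"),
                                degeneracy_cap = 4), "cap")
})

test_that("merged degeneracy equals the brute-force expansion count", {
  set.seed(19)
  for (i in 1:10) {
    sites <- replicate(2, random_seq(8))
    m <- merge_degenerate(sites, degeneracy_cap = 4096)
    expect_identical(degeneracy(m), length(oracle_expand(m)))
    expect_identical(length(unique(oracle_expand(m))), degeneracy(m))
  }
})

test_that("window registration recovers the published merge offset", {
  prefixA <- c("CTCTAGTTGATCCTGCTAGAGGACACTGCTATCGGCTT",
               "CTCTAGTTGATCCTGCTAGAGGGCACTGCTATCGGCTT")
  prefixB <- "TTCCGTTCGATCCTGACGGAGCCTACTGCTATCGGATT"
  fs <- find_shared_window(prefixA, prefixB, length = 18, window = 38)
  expect_identical(fs$start_a, 20L)
  expect_identical(fs$start_b, 20L)
  expect_identical(fs$merged, primers$`26ABF`$sequence)
  expect_identical(fs$degeneracy, 24L)
})

test_that("coverage reports best-placement mismatches and calls", {
  siteB <- apply_pattern(ARCH21F, "=====T=C=======A====")
  cov <- coverage(primers$`4F`, c(b = paste0(siteB, random_seq(40))))
  expect_identical(cov$mismatches, 3L)
  expect_identical(cov$call, "mismatching")
  covA <- coverage(primers$Arch21F,
                   c(a = paste0("CTCTAGTTGATCCTGCTAGA", random_seq(40))))
  expect_identical(covA$mismatches, 5L)
  # a primer covers its own expansion set perfectly
  for (e in oracle_expand(primers$`26ABF`$sequence)) {
    cv <- coverage(primers$`26ABF`, c(x = e))
    expect_identical(cv$mismatches, 0L)
    expect_identical(cv$call, "matching")
  }
})
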
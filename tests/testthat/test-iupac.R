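test_that("code_matches follows the IUPAC expansion sets", {
  expect_true(code_matches("Y", "T"))
  expect_false(code_matches("G", "A"))
  expect_true(code_matches("N", "G"))
  # exhaustive against the definition table
  for (code in names(IUPAC_SETS)) {
    for (base in c("A", "C", "G", "T")) {
      expect_identical(code_matches(code, base),
                       base %in% IUPAC_SETS[[code]],
                       info = paste(code, base))
    }
  }
  # ambiguous observed base: subset rule
  expect_true(code_matches("N", "R"))
  expect_false(code_matches("R", "N"))
  expect_error(code_matches("Z", "A"), "invalid")
})

test_that("degeneracy equals the brute-force expansion count", {
  expect_identical(degeneracy("TTCCGGTTGATCCTGCCGGA"), 1L)
  p <- builtin_primers()
  for (nm in c("8F", "26ABF", "1492R", "4F", "26AF")) {
    seq <- p[[nm]]$sequence
    expect_identical(degeneracy(seq), length(oracle_expand(seq)), info = nm)
  }
  expect_identical(degeneracy(p$`8F`), 4L)
  expect_identical(degeneracy(p$`26ABF`), 24L)
})

test_that("expansion sets round-trip through union_consensus", {
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(names(IUPAC_SETS), sample(4:8, 1), TRUE), collapse = "")
    if (degeneracy(s) > 64) next
    expect_identical(union_consensus(expand_iupac(s)), normalize_seq(s))
  }
  expect_identical(union_consensus(c("ACGT", "ACGT")), "ACGT")
  expect_identical(substr(union_consensus(c("AAAA", "GAAA")), 1, 1), "R")
  expect_error(union_consensus(character()), "no sites")
  expect_error(union_consensus(c("AC", "ACG")), "unequal")
})

test_that("mismatch_positions reproduces the published site comparisons", {
  expect_identical(mismatch_positions(ARCH21F, ARCH21F), integer(0))
  expect_identical(mismatch_positions(ARCH21F, "CTCTAGTTGATCCTGCTAGA"),
                   c(1L, 4L, 5L, 17L, 18L))
  # the older archaeal forward primer against the Type B site interior
  siteB <- apply_pattern(ARCH21F, "=====T=C=======A====")
  expect_length(mismatch_positions("TCCGGTTGATCCTGCC(A/G)G" |> parse_primer_dialect(),
                                   substr(siteB, 2, 19)), 3L)
  expect_error(mismatch_positions(ARCH21F, "ACGT"), "length")
})

test_that("every expansion of a primer matches it with zero mismatches", {
  p <- builtin_primers()
  for (nm in c("8F", "26ABF", "1492R-22W")) {
    for (e in oracle_expand(p[[nm]]$sequence)) {
      expect_identical(mismatch_positions(p[[nm]], e), integer(0))
    }
  }
})

test_that("reverse_complement is the set-wise complement and an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("GGTTACCTTGTTAYGACTT"),
                   "AAGTCRTAACAAGGTAACC")
  # expansion-enumeration check: rc of expansions == expansions of rc
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  for (s in c("GGTTACCTTGTTAYGACTT", "GSVYACTGCTATCGGMTT")) {
    expect_setequal(vapply(oracle_expand(s), rc1, ""),
                    oracle_expand(reverse_complement(s)))
  }
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(names(IUPAC_SETS), 12, TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)),
                     normalize_seq(s))
  }
})

test_that("mismatch count is invariant under joint reverse complement", {
  set.seed(9)
  for (i in 1:25) {
    primer <- random_seq(18)
    site <- mutate_seq(primer, sample(0:4, 1))
    expect_identical(length(mismatch_positions(primer, site)),
                     length(mismatch_positions(reverse_complement(primer),
                                               reverse_complement(site))))
  }
})

test_that("sequence normalization handles RNA, case and bad input", {
  expect_identical(normalize_seq("uuccgg"), "TTCCGG")
  expect_identical(normalize_seq("acGTn"), "ACGTN")
  expect_error(normalize_seq("ACXGT"), "position 3")
  expect_error(normalize_seq(""), "empty")
})

test_that("the parenthesized primer dialect round-trips through IUPAC", {
  expect_identical(parse_primer_dialect("AGAGTTTGAT(C/T)(A/C)TGGCTCAG"),
                   "AGAGTTTGATYMTGGCTCAG")
  expect_identical(to_primer_dialect("AGAGTTTGATYMTGGCTCAG"),
                   "AGAGTTTGAT(C/T)(A/C)TGGCTCAG")
  expect_identical(
    parse_primer_dialect("G(G/C)(G/A/C)(C/T)ACTGCTATCGG(A/C)TT"),
    "GSVYACTGCTATCGGMTT")
  set.seed(3)
  for (i in 1:15) {
    s <- paste(sample(names(IUPAC_SETS), 10, TRUE), collapse = "")
    expect_identical(parse_primer_dialect(to_primer_dialect(s)),
                     normalize_seq(s))
  }
  expect_error(parse_primer_dialect("AC(Q/T)G"), "malformed|invalid")
})
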
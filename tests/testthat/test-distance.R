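test_that("pairwise distances match hand counts on simple cases", {
  expect_identical(pairwise_distance("ACGT", "ACGT"), 0)
  expect_identical(pairwise_distance("ACGT", "ACGA"), 0.25)
  # internal gap run of length 3 counts once: 1 event / (5 bases + 1 event)
  expect_equal(pairwise_distance("AAATTTGG", "AAA---GG"), 1 / 6)
  # each-gap convention counts all three
  expect_equal(pairwise_distance("AAATTTGG", "AAA---GG", gap_mode = "eachgap"),
               3 / 8)
  # terminal overhang ignored by default, counted on request
  expect_equal(pairwise_distance("AAGGTT", "--GGTT"), 0)
  expect_equal(pairwise_distance("AAGGTT", "--GGTT",
                                 terminal_gaps = "count"), 1 / 5)
  # both-gap columns are skipped entirely
  expect_equal(pairwise_distance("AA--TT", "AA--TT"), 0)
  expect_error(pairwise_distance("ACGT", "ACG"), "equal length")
})

test_that("distances agree exactly with the column-walk oracle", {
  set.seed(202)
  for (i in 1:300) {
    p <- random_gapped_pair()
    expect_identical(pairwise_distance(p[1], p[2]),
                     oracle_distance(p[1], p[2]), info = paste(p, collapse = " / "))
  }
})

test_that("the distance is symmetric with a zero diagonal", {
  set.seed(303)
  aln <- stats::setNames(replicate(6, random_gapped_pair()[1]),
                         paste0("s", 1:6))
  d <- distance_matrix(aln)
  expect_identical(d, t(d))
  expect_identical(unname(diag(d)), rep(0, 6))
})

test_that("extra substitutions never decrease the distance", {
  set.seed(404)
  a <- random_seq(80)
  b <- a
  prev <- 0
  changed <- integer()
  for (k in 1:20) {
    p <- sample(setdiff(1:80, changed), 1)
    changed <- c(changed, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(b, p, p))[sample(3, 1)]
    d <- pairwise_distance(a, b)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("group summaries separate planted tight and distant clusters", {
  set.seed(505)
  base <- random_seq(300)
  groups <- c(rep("new", 4), rep("phylumA", 4))
  aln <- c(replicate(4, mutate_seq(base, sample(3:10, 1))),       # <= 0.04
           replicate(4, {
             far <- mutate_seq(base, 110)                          # ~ 0.30+
             mutate_seq(far, sample(0:5, 1))
           }))
  names(aln) <- paste0(groups, 1:8)
  gs <- group_summaries(aln, stats::setNames(groups, names(aln)))
  intra_new <- gs[gs$type == "intra" & gs$group_a == "new", ]
  inter <- gs[gs$type == "inter", ]
  expect_lt(intra_new$max_dist, inter$min_dist)
  expect_identical(intra_new$n_pairs, 6L)
  expect_identical(inter$n_pairs, 16L)
  expect_true(gs$min_dist[gs$type == "intra"][1] >= 0)
})

test_that("degenerate group cases are reported, not faked", {
  aln <- c(a1 = "ACGTACGT", a2 = "ACGAACGT", b1 = "ACGTACGT")
  gs <- group_summaries(aln, c(a1 = "A", a2 = "A", b1 = "B"))
  single <- gs[gs$group_a == "B" & gs$type == "intra", ]
  expect_identical(single$n_pairs, 0L)
  expect_true(is.na(single$min_dist))
  # a group duplicated under two labels touches at distance zero
  inter <- gs[gs$type == "inter", ]
  expect_identical(inter$min_dist, 0)
})

test_that("candidate-phylum calls use a strict 0.25 boundary", {
  expect_true(candidate_phylum_call(0.26))
  expect_false(candidate_phylum_call(0.25))
  expect_false(candidate_phylum_call(0.05))
  # monotone in min_dist
  expect_identical(candidate_phylum_call(seq(0, 0.5, by = 0.05)),
                   seq(0, 0.5, by = 0.05) > 0.25)
  # threshold is configurable
  expect_true(candidate_phylum_call(0.11, identity_threshold = 0.9))
})

test_that("full-length clustering filters short sequences then clusters", {
  set.seed(606)
  base <- random_seq(1400)
  seqs <- c(stats::setNames(replicate(20, base), paste0("dup", 1:20)),
            short = substr(base, 1, 1100))
  cl <- cluster_full_length(seqs)
  expect_identical(nrow(cl$otus), 1L)
  expect_identical(attr(cl, "excluded"), "short")
  # planted clusters at within ~0.99 / between ~0.90
  tpl <- build_templates(10, template_length = 1400, between_identity = 0.90,
                         seed = 17)
  seqs10 <- unlist(lapply(names(tpl), function(g)
    stats::setNames(replicate(3, mutate_seq(tpl[[g]], 10)),
                    paste0(g, "_", 1:3))))
  cl10 <- cluster_full_length(seqs10, cutoff = 0.97)
  expect_identical(nrow(cl10$otus), 10L)
})

test_that("gap-heavy alignment columns are dropped by the filter", {
  aln <- c(s1 = "A-CGT", s2 = "A-CGA", s3 = "AACG-")
  out <- filter_alignment_columns(aln, max_gap_frac = 0.5)
  expect_identical(unname(nchar(out)), rep(4L, 3))
  expect_identical(out[["s1"]], "ACGT")
})

test_that("the center-star fallback aligns small indel sets consistently", {
  seqs <- c(a = "ACGTACGTACGTACGTACGT",
            b = "ACGTACGTACGTACGTACGT",
            c = "ACGTACGTACGACGTACGT")       # one deletion
  aln <- align_small(seqs)
  expect_identical(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln[["c"]]), seqs[["c"]])
  expect_equal(pairwise_distance(aln[["a"]], aln[["b"]]), 0)
  expect_lt(pairwise_distance(aln[["a"]], aln[["c"]]), 0.1)
})
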
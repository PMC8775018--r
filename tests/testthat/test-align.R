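test_that("exact tandem copies align perfectly", {
  a <- align_repeat(strrep("CCCTCT", 5), "CCCTCT")
  expect_identical(a$repeat_count, 5L)
  expect_identical(a$start, 0L)
  expect_identical(a$end, 30L)
  expect_identical(a$substitutions, 0L)
  expect_identical(a$insertions, 0L)
  expect_identical(a$deletions, 0L)
  expect_identical(a$strand, "+")
  expect_identical(a$score, 60L)
})

test_that("a single internal deletion is classified as one deletion", {
  # 10 copies with one base deleted inside copy 6 (59 bp read)
  copies <- strrep("CCCTCT", 10)
  read <- paste0(substr(copies, 1, 32), substr(copies, 34, 60))
  expect_identical(nchar(read), 59L)
  a <- align_repeat(read, "CCCTCT")
  expect_identical(a$repeat_count, 10L)
  expect_identical(a$deletions, 1L)
  expect_identical(a$insertions, 0L)
  expect_identical(a$substitutions, 0L)
  # confirmed independently by the brute-force tiled aligner
  expect_same_alignment(a, svarepeat:::align_repeat_tiled(read, "CCCTCT"))
})

test_that("reads without repeat content yield no call", {
  expect_null(align_repeat(strrep("A", 100), "CCCTCT"))
  # and thresholds are honoured: a short perfect tract below min_score
  expect_null(align_repeat("CCCTCT", "CCCTCT"))  # score 12 < default 40
})

test_that("reverse-complement reads give the flipped strand, same counts", {
  read <- strrep("CCCTCT", 8)
  rc <- svarepeat:::revcomp(read)
  a <- align_repeat(read, "CCCTCT")
  b <- align_repeat(rc, "CCCTCT")
  expect_identical(b$strand, "-")
  expect_identical(b$repeat_count, 8L)
  expect_identical(a$score, b$score)
  expect_identical(a[c("matches", "substitutions", "insertions", "deletions")],
                   b[c("matches", "substitutions", "insertions", "deletions")])
})

test_that("strand symmetry holds for noisy reads", {
  set.seed(31)
  for (i in 1:25) {
    motif <- rand_dna(sample(2:8, 1))
    read <- rand_read(motif)
    sc <- rand_scoring()
    a <- align_repeat(read, motif, sc)
    b <- align_repeat(svarepeat:::revcomp(read), motif, sc)
    expect_identical(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_identical(a$score, b$score)
      expect_identical(a$repeat_count, b$repeat_count)
      expect_identical(
        a[c("matches", "substitutions", "insertions", "deletions")],
        b[c("matches", "substitutions", "insertions", "deletions")])
    }
  }
})

test_that("alignment accounting identities hold on random inputs", {
  set.seed(7)
  for (i in 1:100) {
    motif <- rand_dna(sample(1:8, 1))
    read <- rand_read(motif)
    a <- align_repeat(read, motif,
                      scoring_scheme(min_score = 1, min_span_bp = 1))
    if (is.null(a)) next
    expect_identical(a$matches + a$substitutions + a$deletions,
                     a$motif_consumed_bp)
    expect_identical(a$matches + a$substitutions + a$insertions,
                     a$end - a$start)
    expect_identical(a$repeat_count,
                     as.integer(floor(a$motif_consumed_bp / nchar(motif) + 0.5)))
    expect_true(a$start >= 0 && a$end <= nchar(read))
  }
})

test_that("wraparound DP equals brute-force tiled Smith-Waterman", {
  # the full 500-instance battery runs in the acceptance suite; this is a
  # quick smoke version covering period-1 motifs and random scoring
  set.seed(99)
  for (i in 1:60) {
    motif <- rand_dna(sample(1:8, 1))
    read <- rand_read(motif, max_len = 120L)
    sc <- rand_scoring()
    expect_same_alignment(align_repeat(read, motif, sc),
                          svarepeat:::align_repeat_tiled(read, motif, sc))
  }
})

test_that("scoring scheme validation", {
  expect_error(scoring_scheme(match = 0), "positive")
  expect_error(scoring_scheme(gap_extend = 0), "at least 1")
  expect_error(align_repeat("ACGT", "CCNTCT"), "A/C/G/T")
  expect_error(align_repeat("", "CCCTCT"), "non-empty")
})
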
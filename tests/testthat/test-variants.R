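test_that("hemizygous filter applies the three rules in order", {
  # locus with a clean region and an AAAAA homopolymer at positions 20-24
  locus <- paste0(strrep("ACGT", 5), "AAAAA", strrep("TGCA", 5))
  rec <- variant_records(
    position = c(5L, 5L, 5L, 22L, 19L, 26L),
    ref = "C", alt = "T",
    allele_frequency = c(0.95, 0.50, 0.95, 0.95, 0.95, 0.95),
    quality = c(30, 30, 15, 30, 30, 30))

  res <- filter_variants(rec, locus, hp_len = 4L, margin = 1L)
  # record 1 passes; 2 fails AF; 3 fails quality; 4 inside homopolymer;
  # 5 adjacent (margin 1); 6 two bases clear of the run
  expect_identical(res$kept$position, c(5L, 26L))
  expect_identical(res$rejected$reason,
                   c("allele_frequency", "quality", "homopolymer",
                     "homopolymer"))
})

test_that("thresholds are strict inequalities", {
  locus <- strrep("ACGT", 20)
  at_af <- variant_records(1L, "C", "T", allele_frequency = 0.90, quality = 30)
  at_q <- variant_records(1L, "C", "T", allele_frequency = 0.95, quality = 20)
  above <- variant_records(1L, "C", "T", allele_frequency = 0.901,
                           quality = 20.1)
  expect_identical(nrow(filter_variants(at_af, locus)$kept), 0L)
  expect_identical(filter_variants(at_af, locus)$rejected$reason,
                   "allele_frequency")
  expect_identical(filter_variants(at_q, locus)$rejected$reason, "quality")
  expect_identical(nrow(filter_variants(above, locus)$kept), 1L)
})

test_that("filter partitions input, is idempotent and order-independent", {
  set.seed(21)
  locus <- paste0(rand_dna(50), "GGGGGG", rand_dna(50))
  n <- 40L
  rec <- variant_records(position = sample(0:(nchar(locus) - 1L), n,
                                           replace = TRUE),
                         ref = "A", alt = "C",
                         allele_frequency = runif(n),
                         quality = runif(n, 0, 60))
  res <- filter_variants(rec, locus)
  expect_identical(nrow(res$kept) + nrow(res$rejected), n)
  # idempotent on the kept set
  res2 <- filter_variants(res$kept, locus)
  expect_identical(res2$kept, res$kept)
  expect_identical(nrow(res2$rejected), 0L)
  # order-independent
  perm <- sample(n)
  resp <- filter_variants(rec[perm, ], locus)
  expect_identical(resp$kept[order(resp$kept$position), "allele_frequency"],
                   res$kept[order(res$kept$position), "allele_frequency"])
})

test_that("empty input returns empty kept set (the zero-SNV case)", {
  rec <- variant_records(integer(0), character(0), character(0),
                         numeric(0), numeric(0))
  res <- filter_variants(rec, strrep("ACGT", 10))
  expect_identical(nrow(res$kept), 0L)
  expect_identical(nrow(res$rejected), 0L)
})

test_that("out-of-bounds positions raise an error", {
  rec <- variant_records(100L, "A", "C", 0.95, 30)
  expect_error(filter_variants(rec, "ACGTACGT"), "bounds")
})

test_that("homopolymer mask marks runs and their margin", {
  mask <- homopolymer_mask("TTAAAAGG", hp_len = 4L, margin = 1L)
  #          position:      01234567  -> run AAAA at 2..5, margin 1..6
  expect_identical(which(mask) - 1L, 1:6)
  expect_identical(sum(homopolymer_mask("ACGTACGT", hp_len = 4L)), 0L)
})

test_that("variant_records validates its fields", {
  expect_error(variant_records(1L, "A", "A", 0.5, 30), "differ")
  expect_error(variant_records(1L, "A", "C", 1.5, 30), "\\[0, 1\\]")
  expect_error(variant_records(1L, "A", "C", 0.5, -1), "non-negative")
})
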
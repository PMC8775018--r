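test_that("noise-free simulation returns exact template copies", {
  loc <- locus_model(left_flank = "AAA", motif = "CCCTCT", right_flank = "GGG")
  tpl <- build_template(loc, 10)
  sim <- simulate_reads(tpl, coverage = 10, profile = error_profile(0, 0, 0),
                        seed = 7)
  expect_length(sim$reads, 10L)
  for (i in seq_along(sim$reads)) {
    expected <- if (sim$truth$strand[i] == "+") as.character(tpl)
                else svarepeat:::revcomp(as.character(tpl))
    expect_identical(unname(sim$reads[i]), expected)
  }
  expect_true(all(sim$truth$injected_subs == 0))
  expect_true(all(sim$truth$injected_ins == 0))
  expect_true(all(sim$truth$injected_dels == 0))
})

test_that("injected error counts follow the binomial law", {
  tpl <- build_template(locus_model(motif = "ACGTGA"), 500)  # 3000 bp
  sim <- simulate_reads(tpl, coverage = 1,
                        profile = error_profile(0, 0, del_rate = 0.05),
                        seed = 1)
  # Binomial(3000, 0.05): mean 150, SD ~11.9; 3-SD window
  expect_true(abs(sim$truth$injected_dels - 150) < 3 * sqrt(3000 * 0.05 * 0.95))
  expect_identical(sim$truth$injected_subs, 0L)
  expect_identical(sim$truth$injected_ins, 0L)

  # sub and ins rates obey the same law (averaged over reads)
  sim2 <- simulate_reads(tpl, coverage = 30,
                         profile = error_profile(0.02, 0.01, 0.03), seed = 2)
  expect_true(abs(mean(sim2$truth$injected_subs) - 60) < 3 * sqrt(60 / 30))
  expect_true(abs(mean(sim2$truth$injected_ins) - 30) < 3 * sqrt(30 / 30))
  expect_true(abs(mean(sim2$truth$injected_dels) - 90) < 3 * sqrt(90 / 30))
})

test_that("identical seeds reproduce identical reads and truth", {
  tpl <- build_template(locus_model(motif = "CCCTCT"), 40)
  s1 <- simulate_reads(tpl, 5, error_preset("fast"), seed = 11)
  s2 <- simulate_reads(tpl, 5, error_preset("fast"), seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_reads(tpl, 5, error_preset("fast"), seed = 12)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("error presets match the advertised total error", {
  sup <- error_preset("sup")
  fast <- error_preset("fast")
  expect_equal(sup$sub_rate + sup$ins_rate + sup$del_rate, 0.017)
  expect_equal(fast$sub_rate + fast$ins_rate + fast$del_rate, 0.042)
  expect_error(error_profile(sub_rate = 0.6), "0.5")
})

test_that("targeted length model truncates reads to 50-100% of template", {
  tpl <- build_template(locus_model(left_flank = strrep("ACGT", 250),
                                    motif = "CCCTCT",
                                    right_flank = strrep("TTGA", 250)), 20)
  sim <- simulate_reads(tpl, 40, error_profile(0, 0, 0),
                        length_model = "targeted", seed = 3)
  frac <- sim$truth$read_length / nchar(tpl)
  expect_true(all(frac >= 0.5 - 1e-9 & frac <= 1 + 1e-9))
  expect_true(stats::sd(frac) > 0)  # actually varies
})

test_that("simulated methylation calls respect degenerate probabilities", {
  # true MF 1 with strong separation: every LLR positive
  m1 <- simulate_methylation_calls(sites = 100L, true_mf = 1.0,
                                   coverage = 20L, llr_separation = 10,
                                   seed = 5)
  expect_identical(nrow(m1$calls), 20L)
  expect_true(all(m1$calls$log_lik_ratio > 0))

  # true MF 0 propagates to a site frequency of exactly 0
  m0 <- simulate_methylation_calls(sites = c(10L, 20L), true_mf = 0.0,
                                   coverage = 25L, seed = 6)
  sites <- compute_site_mf(m0$calls, llr_threshold = 2, min_coverage = 10L)
  expect_true(all(sites$mf == 0))

  # balanced site: methylated fraction within 3 binomial SDs of 0.5
  mh <- simulate_methylation_calls(sites = 1L, true_mf = 0.5,
                                   coverage = 10000L, seed = 7)
  frac <- mean(mh$calls$log_lik_ratio > 0)
  expect_true(abs(frac - 0.5) < 3 * sqrt(0.25 / 10000))

  # empty site list gives empty tables
  me <- simulate_methylation_calls(integer(0), numeric(0))
  expect_identical(nrow(me$calls), 0L)
})

test_that("fragment sizes are linear in repeat number and invertible", {
  f <- simulate_fragment_sizes(c(45L, 0L), offset_bp = 300, jitter_sd = 0)
  expect_identical(f$size_bp, c(570L, 300L))

  # cohort of 96 with 1 bp jitter: >= 95% recovered exactly
  set.seed(123)
  ns <- sample(35:57, 96, replace = TRUE)
  f2 <- simulate_fragment_sizes(ns, offset_bp = 300, jitter_sd = 1, seed = 9)
  rec <- fragment_to_repeat(f2$size_bp, offset_bp = 300)
  expect_true(mean(rec == ns) >= 0.95)

  expect_error(simulate_fragment_sizes(10L, offset_bp = -5), "non-negative")
})
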
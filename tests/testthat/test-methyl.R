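mk_calls <- function(read_id, position, llr) {
  data.frame(read_id = read_id, position = as.integer(position),
             log_lik_ratio = llr, stringsAsFactors = FALSE)
}

test_that("read-length filter is strict and reports orphans", {
  calls <- mk_calls(c("a", "b", "c"), c(10, 10, 10), c(5, 5, 5))
  meta <- data.frame(read_id = c("a", "b", "c"),
                     alignment_length = c(3500L, 3000L, 2999L))
  kept <- filter_reads_by_length(calls, meta, min_len_bp = 3000)
  expect_identical(kept$read_id, "a")  # 3000 dropped: strict >

  expect_identical(nrow(filter_reads_by_length(calls, meta, 0)), 3L)

  orphan <- mk_calls("zz", 10, 5)
  expect_error(filter_reads_by_length(orphan, meta, 0), "zz")
})

test_that("site MF arithmetic and the coverage rule", {
  # 12 confident calls, 9 methylated -> mf 0.75
  calls <- mk_calls(sprintf("r%02d", 1:12), rep(50, 12),
                    c(rep(5, 9), rep(-5, 3)))
  s <- compute_site_mf(calls, llr_threshold = 2, min_coverage = 10L)
  expect_identical(s$coverage, 12L)
  expect_identical(s$methylated, 9L)
  expect_equal(s$mf, 0.75)

  # a site with exactly 10 confident calls is excluded (needs > 10)
  ten <- mk_calls(sprintf("r%02d", 1:10), rep(60, 10), rep(5, 10))
  expect_identical(nrow(compute_site_mf(ten, 2, 10L)), 0L)
  eleven <- mk_calls(sprintf("r%02d", 1:11), rep(60, 11), rep(5, 11))
  expect_identical(nrow(compute_site_mf(eleven, 2, 10L)), 1L)

  # ambiguous calls (|llr| < threshold) do not count towards coverage
  mixed <- mk_calls(sprintf("r%02d", 1:14), rep(70, 14),
                    c(rep(5, 8), rep(-5, 4), 1, -1))
  s2 <- compute_site_mf(mixed, 2, 10L)
  expect_identical(s2$coverage, 12L)
  expect_equal(s2$mf, 8 / 12)

  expect_identical(nrow(compute_site_mf(mk_calls(character(0), integer(0),
                                                 numeric(0)))), 0L)
})

test_that("region aggregation uses sample SD and flags empty regions", {
  sites <- data.frame(site_position = c(5L, 15L, 100L),
                      coverage = 20L, methylated = c(16L, 20L, 20L),
                      mf = c(0.8, 1.0, 1.0))
  regions <- region_annotation(c("enh1", "enh8", "enh9"),
                               start = c(0L, 50L, 90L),
                               end = c(20L, 60L, 110L))
  out <- region_mf(sites, regions)
  expect_equal(out$mean_mf[1], 0.9)
  expect_equal(out$sd_mf[1], 0.1414214, tolerance = 1e-6)
  expect_true(out$excluded[2])       # no CpG site in the region
  expect_identical(out$n_sites[2], 0L)
  expect_false(out$excluded[3])
  expect_equal(out$sd_mf[3], 0)      # single site: zero spread

  all_one <- sites; all_one$mf <- 1.0
  out2 <- region_mf(all_one, regions[1, ])
  expect_equal(out2$mean_mf, 1.0)
  expect_equal(out2$sd_mf, 0)
})

test_that("Mann-Whitney exact p matches hand enumeration", {
  res <- compare_mf(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")

  # identical groups: exchangeable null, p = 1
  same <- compare_mf(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$p_value, 1.0)
})

test_that("exact path agrees with wilcox.test when ties are absent", {
  set.seed(12)
  for (i in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    x <- runif(m); y <- runif(n)
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation path matches wilcox.test tie correction", {
  set.seed(13)
  for (i in 1:10) {
    x <- sample(seq(0, 1, by = 0.1), 25, replace = TRUE)
    y <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE) + 0.1
    mine <- mann_whitney_u(x, y)
    expect_identical(mine$method, "normal_approx")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("p-values fall monotonically with increasing shift", {
  set.seed(14)
  base <- runif(40)
  shifts <- c(0.05, 0.2, 0.5)
  ps <- vapply(shifts, function(d)
    mann_whitney_u(base, base + d)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("pipeline stages run in the documented order with known counts", {
  fx <- sva_fixture_locus(45)
  sva <- fx$locus$region_annotations
  sva_int <- sva[sva$name == "SVA", ]
  sites <- fx$cpg_positions[fx$cpg_positions >= sva_int$start &
                              fx$cpg_positions < sva_int$end]
  sim <- simulate_methylation_calls(
    sites, true_mf = 0.9, coverage = 25L,
    read_length_sampler = function(n) rep(c(4000L, 2000L), length.out = n),
    seed = 42)
  n0 <- nrow(sim$calls)
  after_len <- filter_reads_by_length(sim$calls, sim$meta, 3000)
  expect_true(nrow(after_len) < n0)     # short reads dropped
  expect_true(nrow(after_len) > 0)
  s <- compute_site_mf(after_len, llr_threshold = 2, min_coverage = 10L)
  expect_true(all(s$coverage > 10))
  expect_true(all(s$mf >= 0 & s$mf <= 1))
  expect_true(all(s$methylated <= s$coverage))
})

test_that("cross-sample comparisons pair regions by name", {
  sites_a <- data.frame(site_position = c(5L, 6L, 7L), coverage = 20L,
                        methylated = 18L, mf = c(0.9, 0.95, 1.0))
  sites_b <- data.frame(site_position = c(105L, 106L, 107L), coverage = 20L,
                        methylated = 10L, mf = c(0.5, 0.55, 0.6))
  reg_a <- region_annotation("enh1", 0L, 50L)
  reg_b <- region_annotation("enh1", 100L, 150L)   # shifted coordinates
  out <- compare_regions_by_name(sites_a, sites_b, reg_a, reg_b)
  expect_identical(out$name, "enh1")
  expect_identical(out$n_sites_a, 3L)
  expect_identical(out$n_sites_b, 3L)
  expect_equal(out$U, 9)  # complete separation
})
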
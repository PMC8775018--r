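#' Filter methylation calls by read alignment length
#'
#' Keeps calls whose read has an alignment strictly longer than `min_len_bp`.
#' Targeted (Cas9-guided) enrichment produces off-target reads with short
#' alignments; restricting to long alignments is the standard counter-measure
#' before aggregating per-read methylation calls.
#'
#' @param calls data frame with columns `read_id`, `position`,
#'   `log_lik_ratio` (one row per read x CpG site).
#' @param meta data frame with columns `read_id`, `alignment_length`; every
#'   read in `calls` must be present.
#' @param min_len_bp strict lower bound on alignment length (e.g. 3000 for
#'   samples carrying the insertion, 1500 for controls without it).
#' @return filtered `calls` data frame.
#' @export
filter_reads_by_length <- function(calls, meta, min_len_bp) {
  stopifnot(is.data.frame(calls), is.data.frame(meta))
  if (any(meta$alignment_length <= 0)) stop("alignment lengths must be positive")
  idx <- match(calls$read_id, meta$read_id)
  if (anyNA(idx)) {
    missing_ids <- unique(calls$read_id[is.na(idx)])
    stop("read(s) absent from metadata: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  keep <- meta$alignment_length[idx] > min_len_bp
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site methylation frequency with confidence and coverage filters
#'
#' Aggregates per-read log-likelihood-ratio calls into per-CpG-site
#' methylation frequencies.  A call is *confident* when `|llr| >=
#' llr_threshold`; ambiguous calls are discarded.  Site coverage is the
#' number of confident calls, the methylated count those with
#' `llr >= +llr_threshold`, and `mf = methylated / coverage`.  Sites with
#' coverage of `min_coverage` or fewer reads are removed (the ">10 reads"
#' rule: with the default 10, a site needs at least 11 confident calls).
#'
#' @param calls data frame with `read_id`, `position`, `log_lik_ratio`
#'   (already filtered by read length if applicable).
#' @param llr_threshold confidence cutoff on `|llr|` (default 2).
#' @param min_coverage strict lower bound on confident coverage (default 10).
#' @return data frame of class `cpg_site_summary` with columns
#'   `site_position`, `coverage`, `methylated`, `mf`, sorted by position.
#' @export
compute_site_mf <- function(calls, llr_threshold = 2, min_coverage = 10L) {
  stopifnot(is.data.frame(calls))
  empty <- data.frame(site_position = integer(0), coverage = integer(0),
                      methylated = integer(0), mf = numeric(0))
  class(empty) <- c("cpg_site_summary", "data.frame")
  if (nrow(calls) == 0L) return(empty)

  confident <- abs(calls$log_lik_ratio) >= llr_threshold
  calls <- calls[confident, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty)

  pos <- calls$position
  meth <- calls$log_lik_ratio >= llr_threshold
  cov <- tapply(meth, pos, length)
  met <- tapply(meth, pos, sum)
  out <- data.frame(site_position = as.integer(names(cov)),
                    coverage = as.integer(cov),
                    methylated = as.integer(met))
  out$mf <- out$methylated / out$coverage
  out <- out[out$coverage > min_coverage, , drop = FALSE]
  out <- out[order(out$site_position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_site_summary", "data.frame")
  out
}

#' Aggregate site methylation frequencies over annotated regions
#'
#' For each named region (0-based half-open interval), computes the mean and
#' sample standard deviation (n - 1) of the methylation frequencies of the
#' CpG sites whose C position lies inside the interval.  Regions containing
#' no retained CpG site are reported with `excluded = TRUE` and `NA`
#' summaries rather than dropped silently, so the caller can see *why* a
#' region is missing from downstream comparisons.
#'
#' @param sites a `cpg_site_summary` data frame from [compute_site_mf()].
#' @param regions data frame from [region_annotation()] (columns `name`,
#'   `start`, `end`).
#' @return data frame with columns `name`, `start`, `end`, `n_sites`,
#'   `mean_mf`, `sd_mf`, `excluded`.
#' @export
region_mf <- function(sites, regions) {
  stopifnot(is.data.frame(sites), is.data.frame(regions))
  out <- regions[, c("name", "start", "end"), drop = FALSE]
  out$n_sites <- 0L
  out$mean_mf <- NA_real_
  out$sd_mf <- NA_real_
  out$excluded <- TRUE
  for (i in seq_len(nrow(regions))) {
    inside <- sites$site_position >= regions$start[i] &
      sites$site_position < regions$end[i]
    n <- sum(inside)
    out$n_sites[i] <- n
    if (n >= 1L) {
      mfs <- sites$mf[inside]
      out$mean_mf[i] <- mean(mfs)
      out$sd_mf[i] <- if (n > 1L) stats::sd(mfs) else 0
      out$excluded[i] <- FALSE
    }
  }
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (exact for small samples, ties allowed)
#'
#' Rank-sum test of two independent samples.  U is computed from average
#' ranks.  For `m + n <= exact_max_n` the two-sided p-value is exact: the
#' null distribution of U is obtained by enumerating all `choose(m+n, m)`
#' assignments of the pooled (tied) ranks to the groups, and
#' `p = min(1, 2 * min(P(U <= u), P(U >= u)))`.  Unlike the textbook exact
#' tables this enumeration remains valid in the presence of ties, which are
#' ubiquitous in per-site methylation frequencies.  Larger samples use the
#' normal approximation with the tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact_max_n largest `m + n` for which the exact enumeration is used
#'   (default 20).
#' @return list with `U` (statistic for the first sample), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 20L) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2

  if (N <= exact_max_n) {
    combos <- utils::combn(N, m)
    base <- m * (m + 1) / 2
    us <- colSums(matrix(r[combos], nrow = m)) - base
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    return(list(U = u, p_value = p, method = "exact"))
  }

  mu <- m * n / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (m * n / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "normal_approx"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = u, p_value = p, method = "normal_approx")
}

#' Compare methylation frequencies between two site sets
#'
#' Mann-Whitney U test on the per-site methylation frequencies of two
#' samples (e.g. patient vs control, or two tissues), the standard
#' non-parametric comparison for such data.  P-values are exploratory (no
#' multiplicity correction is applied).
#'
#' @param sites_a,sites_b `cpg_site_summary` data frames (or numeric vectors
#'   of methylation frequencies).
#' @param exact_max_n see [mann_whitney_u()].
#' @return list with `U`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
compare_mf <- function(sites_a, sites_b, exact_max_n = 20L) {
  a <- if (is.data.frame(sites_a)) sites_a$mf else as.numeric(sites_a)
  b <- if (is.data.frame(sites_b)) sites_b$mf else as.numeric(sites_b)
  if (length(a) < 1L || length(b) < 1L)
    stop("each group needs at least one site")
  res <- mann_whitney_u(a, b, exact_max_n = exact_max_n)
  res$n_a <- length(a); res$n_b <- length(b)
  res
}

#' Compare regions between two samples by name
#'
#' Region-level methylation comparisons across samples whose reference
#' coordinate systems differ (e.g. one carries the insertion and one does
#' not) must pair regions by *name*, never by coordinate.  For every region
#' name present in both summaries and excluded in neither, runs
#' [compare_mf()] on the per-site frequencies falling in that region in each
#' sample.
#'
#' @param sites_a,sites_b per-sample `cpg_site_summary` data frames.
#' @param regions_a,regions_b per-sample region annotations (same names,
#'   possibly different coordinates).
#' @return data frame with one row per shared region: `name`, `n_sites_a`,
#'   `n_sites_b`, `mean_mf_a`, `mean_mf_b`, `U`, `p_value`, `method`.
#' @export
compare_regions_by_name <- function(sites_a, sites_b, regions_a, regions_b) {
  ra <- region_mf(sites_a, regions_a)
  rb <- region_mf(sites_b, regions_b)
  shared <- intersect(ra$name[!ra$excluded], rb$name[!rb$excluded])
  rows <- lapply(shared, function(nm) {
    ia <- regions_a[regions_a$name == nm, ][1, ]
    ib <- regions_b[regions_b$name == nm, ][1, ]
    mfa <- sites_a$mf[sites_a$site_position >= ia$start &
                        sites_a$site_position < ia$end]
    mfb <- sites_b$mf[sites_b$site_position >= ib$start &
                        sites_b$site_position < ib$end]
    cmp <- mann_whitney_u(mfa, mfb)
    data.frame(name = nm, n_sites_a = length(mfa), n_sites_b = length(mfb),
               mean_mf_a = mean(mfa), mean_mf_b = mean(mfb),
               U = cmp$U, p_value = cmp$p_value, method = cmp$method,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(name = character(0), n_sites_a = integer(0),
                      n_sites_b = integer(0), mean_mf_a = numeric(0),
                      mean_mf_b = numeric(0), U = numeric(0),
                      p_value = numeric(0), method = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
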
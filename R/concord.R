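#' Convert a fragment-analysis size to a repeat number
#'
#' Inverts the linear sizing model `size = offset + motif_len * n` by
#' nearest-integer rounding (half rounds up).  The calibration offset is
#' assay-specific and must be supplied explicitly.
#'
#' @param size_bp fragment sizes in bp.
#' @param offset_bp calibration offset (non-repeat bp in the fragment).
#' @param motif_len motif length (default 6).
#' @return integer repeat numbers.
#' @export
fragment_to_repeat <- function(size_bp, offset_bp, motif_len = 6L) {
  if (any(size_bp < offset_bp)) stop("fragment size smaller than offset")
  as.integer(floor((size_bp - offset_bp) / motif_len + 0.5))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the cohorts this package
#' targets have many repeated integer repeat numbers, so tie handling
#' matters).  The two-sided p-value comes from the asymptotic t
#' approximation via [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` (rho) and `p_value`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  r <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  list(r = unname(r), p_value = unname(p))
}

#' N50 of a set of read lengths
#'
#' The largest length L such that reads of length >= L together contain at
#' least half of all sequenced bases.
#'
#' @param read_lengths numeric vector of read lengths (non-empty, positive).
#' @return N50 in bp.
#' @export
compute_n50 <- function(read_lengths) {
  if (length(read_lengths) == 0L) stop("no read lengths supplied")
  if (any(read_lengths <= 0)) stop("read lengths must be positive")
  s <- sort(read_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Cohort concordance and association report
#'
#' Summarises a cohort table of per-sample repeat calls: descriptive
#' statistics of the sequencing-based and fragment-analysis repeat numbers,
#' Spearman concordance between the two, the median paired difference
#' (sequencing minus fragment analysis; surfaced as a diagnostic for the
#' systematic offset between the methods rather than "corrected"), and --
#' when an age-at-onset column is present -- the Spearman correlation of
#' repeat number with onset age.
#'
#' @param table data frame with columns `sample_id`, `nanopore_median_repeat`
#'   (and optionally `nanopore_iqr`), `fragment_repeat`, and optionally
#'   `aao_years`.
#' @return object of class `cohort_report`.
#' @export
cohort_report <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("sample_id", "nanopore_median_repeat", "fragment_repeat")
  if (!all(need %in% names(table)))
    stop("cohort table must contain columns: ", paste(need, collapse = ", "))
  np <- table$nanopore_median_repeat
  fr <- table$fragment_repeat
  if (any(stats::na.omit(c(np, fr)) <= 0))
    stop("repeat numbers must be positive")

  desc <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        min = min(x), max = max(x))
  conc <- spearman(np, fr)
  aao <- NULL
  if ("aao_years" %in% names(table)) {
    aao <- spearman(np, table$aao_years)
  } else {
    warning("no aao_years column; onset-age correlation skipped")
  }
  structure(list(
    n = nrow(table),
    nanopore = desc(np),
    fragment = desc(fr),
    concordance_r = conc$r, concordance_p = conc$p_value,
    median_paired_diff = stats::median(np - fr),
    aao_r = if (is.null(aao)) NA_real_ else aao$r,
    aao_p = if (is.null(aao)) NA_real_ else aao$p_value,
    table = table), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d samples\n", x$n))
  cat(sprintf("  sequencing repeat calls: mean %.2f (SD %.2f), range %.0f-%.0f\n",
              x$nanopore["mean"], x$nanopore["sd"],
              x$nanopore["min"], x$nanopore["max"]))
  cat(sprintf("  fragment analysis:       mean %.2f (SD %.2f), range %.0f-%.0f\n",
              x$fragment["mean"], x$fragment["sd"],
              x$fragment["min"], x$fragment["max"]))
  cat(sprintf("  concordance: Spearman r = %.4f (p = %.3g)\n",
              x$concordance_r, x$concordance_p))
  cat(sprintf("  median paired difference (seq - fragment): %+.1f repeats\n",
              x$median_paired_diff))
  if (!is.na(x$aao_r))
    cat(sprintf("  repeat number vs onset age: Spearman r = %.4f (p = %.3g)\n",
                x$aao_r, x$aao_p))
  invisible(x)
}
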
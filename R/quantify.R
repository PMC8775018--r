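#' Quantify repeat number for one sample
#'
#' Aligns every read against the tandem motif with [align_repeat()], keeps
#' reads with a reported alignment, and summarises the per-read repeat counts
#' as the sample call: the median and the interquartile range (Q3 - Q1,
#' linear-interpolation quantiles, `stats::quantile(type = 7)`).  Per-read
#' interruption counts (deletions, insertions, substitutions within the
#' repeat tract) are averaged per read.
#'
#' When no read yields an alignment the function returns an explicit
#' "no call" object (`n_reads = 0`, `NA` summaries) rather than failing, so
#' cohort loops degrade gracefully.
#'
#' @param reads named character vector of read sequences, or a path to a
#'   FASTQ/FASTA file (read with [read_fastx()]).
#' @param motif repeat motif.
#' @param scoring a [scoring_scheme()].
#' @param sample_id sample label stored in the result.
#' @return object of class `sample_repeat_call` with fields `sample_id`,
#'   `median_repeat`, `iqr`, `n_reads`, `mean_dels`, `mean_ins`, `mean_subs`,
#'   and `alignments` (per-read data frame).
#' @export
quantify_sample <- function(reads, motif = "CCCTCT",
                            scoring = scoring_scheme(),
                            sample_id = NA_character_) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    reads <- read_fastx(reads)
  }
  if (length(reads) == 0L) stop("no reads supplied")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(reads))

  hits <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    hits[[i]] <- align_repeat(reads[[i]], motif, scoring, read_id = ids[i])
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]

  if (length(hits) == 0L) {
    return(structure(list(sample_id = sample_id, no_call = TRUE,
                          median_repeat = NA_real_, iqr = NA_real_,
                          n_reads = 0L, mean_dels = NA_real_,
                          mean_ins = NA_real_, mean_subs = NA_real_,
                          alignments = alignment_table(list())),
                     class = "sample_repeat_call"))
  }

  tab <- alignment_table(hits)
  counts <- tab$repeat_count
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(sample_id = sample_id, no_call = FALSE,
                 median_repeat = q[2], iqr = q[3] - q[1],
                 n_reads = nrow(tab),
                 mean_dels = mean(tab$deletions),
                 mean_ins = mean(tab$insertions),
                 mean_subs = mean(tab$substitutions),
                 alignments = tab),
            class = "sample_repeat_call")
}

alignment_table <- function(hits) {
  cols <- c("read_id", "strand", "start", "end", "repeat_count",
            "motif_consumed_bp", "matches", "substitutions", "insertions",
            "deletions", "score")
  if (length(hits) == 0L) {
    out <- data.frame(read_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      repeat_count = integer(0), motif_consumed_bp = integer(0),
                      matches = integer(0), substitutions = integer(0),
                      insertions = integer(0), deletions = integer(0),
                      score = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  do.call(rbind, lapply(hits, function(h)
    data.frame(h[cols], stringsAsFactors = FALSE)))
}

#' @export
print.sample_repeat_call <- function(x, ...) {
  if (isTRUE(x$no_call)) {
    cat(sprintf("<sample_repeat_call> %s: NO CALL (0 aligned reads)\n",
                x$sample_id))
    return(invisible(x))
  }
  cat(sprintf("<sample_repeat_call> %s: median repeat %.1f (IQR %.1f), %d reads\n",
              x$sample_id, x$median_repeat, x$iqr, x$n_reads))
  cat(sprintf("  mean interruptions/read: del %.2f  ins %.2f  sub %.2f\n",
              x$mean_dels, x$mean_ins, x$mean_subs))
  invisible(x)
}

#' @export
summary.sample_repeat_call <- function(object, ...) {
  print(object)
  if (!isTRUE(object$no_call)) {
    cat("  repeat count distribution:\n")
    print(table(object$alignments$repeat_count))
  }
  invisible(object)
}

#' Cohort-level repeat interruption summary
#'
#' Mean and standard deviation, across samples, of the per-sample mean number
#' of repeat-motif interruptions per read, stratified by type (deletion,
#' insertion, substitution) -- the quantities plotted as bar-and-whisker
#' interruption charts for repeat cohorts.  SD is the sample standard
#' deviation (n - 1).
#'
#' @param calls list of `sample_repeat_call` objects (no-call samples are
#'   dropped with a warning).
#' @return data frame with columns `type`, `mean_per_read`, `sd`, `n_samples`.
#' @export
interruption_summary <- function(calls) {
  if (inherits(calls, "sample_repeat_call")) calls <- list(calls)
  if (length(calls) == 0L) stop("at least one sample call is required")
  no_call <- vapply(calls, function(x) isTRUE(x$no_call), logical(1))
  if (any(no_call)) {
    warning(sum(no_call), " no-call sample(s) dropped from interruption summary")
    calls <- calls[!no_call]
  }
  if (length(calls) == 0L) stop("no callable samples")
  dels <- vapply(calls, `[[`, numeric(1), "mean_dels")
  ins <- vapply(calls, `[[`, numeric(1), "mean_ins")
  subs <- vapply(calls, `[[`, numeric(1), "mean_subs")
  sd1 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(type = c("deletion", "insertion", "substitution"),
             mean_per_read = c(mean(dels), mean(ins), mean(subs)),
             sd = c(sd1(dels), sd1(ins), sd1(subs)),
             n_samples = length(calls), stringsAsFactors = FALSE)
}
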
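#' Scoring scheme for repeat alignment
#'
#' Affine-gap local-alignment scoring: a length-k gap costs
#' `gap_open + k * gap_extend`.  Alignments scoring below `min_score` or
#' spanning fewer than `min_span_bp` read bases are discarded (no call for
#' that read).  The defaults are tuned for a 6-bp motif in reads with a few
#' percent error; all values are exposed because repeat-finder scoring is not
#' standardised.
#'
#' `gap_extend` must be at least 1: with free gap extension, deleting whole
#' motif copies from the (conceptually unbounded) tandem reference costs
#' nothing, and the number of reference bases an optimal alignment consumes --
#' hence the repeat count -- would be ill-defined.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (>= 0, applied as a subtraction).
#' @param gap_open gap opening penalty (>= 0).
#' @param gap_extend gap extension penalty per base (>= 1).
#' @param min_score minimum alignment score to report a repeat call.
#' @param min_span_bp minimum read-interval length to report a call.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = 3L, gap_open = 4L,
                           gap_extend = 2L, min_score = 40L,
                           min_span_bp = NULL) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match reward must be positive")
  if (mismatch < 0L || gap_open < 0L) stop("penalties must be non-negative")
  if (gap_extend < 1L) stop("gap_extend must be at least 1")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = as.integer(min_score),
                 min_span_bp = if (is.null(min_span_bp)) NULL
                               else as.integer(min_span_bp)),
            class = "scoring_scheme")
}

# Resolve the default min_span_bp = 5 * motif length.
min_span_for <- function(scoring, motif) {
  if (is.null(scoring$min_span_bp)) 5L * nchar(motif) else scoring$min_span_bp
}

#' Align one read against an unbounded tandem repeat of a motif
#'
#' Finds the maximum-score local alignment (affine gap penalties, both
#' strands) of `read` against `motif` repeated without bound, using
#' wraparound dynamic programming: the DP has one column per motif position
#' and diagonal/horizontal moves wrap modulo the motif length, which is
#' equivalent to plain Smith-Waterman against any sufficiently large explicit
#' tiling of the motif.  Between equal-scoring alignments, the smallest read
#' start and then the shortest span wins.
#'
#' The repeat count is the number of reference (motif) bases the alignment
#' consumes divided by the motif length, rounded half up, so partially
#' covered terminal copies resolve deterministically.
#'
#' @param read DNA string (the read, any case handled by the caller; must be
#'   uppercase A/C/G/T/N-free for exact matching).
#' @param motif repeat motif, uppercase A/C/G/T.
#' @param scoring a [scoring_scheme()].
#' @param read_id optional identifier stored in the result.
#' @return an object of class `repeat_alignment`, or `NULL` when no alignment
#'   reaches `min_score` and `min_span_bp`.
#' @examples
#' align_repeat(strrep("CCCTCT", 8), "CCCTCT")
#' @export
align_repeat <- function(read, motif, scoring = scoring_scheme(),
                         read_id = NA_character_) {
  check_dna(motif, allow_empty = FALSE, what = "motif")
  if (length(read) != 1L || is.na(read) || nchar(read) == 0L)
    stop("read must be a single non-empty string")
  stopifnot(inherits(scoring, "scoring_scheme"))

  fwd <- .wrap_align_cpp(read, motif, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  rc <- revcomp(read)
  rev <- .wrap_align_cpp(rc, motif, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  pick_strand(fwd, rev, nchar(read), motif, scoring, read_id)
}

# Shared between the wraparound aligner and the naive tiled reference:
# choose the better strand, apply score/span thresholds, and package the
# result.  Reverse-strand intervals are mapped back to original read
# coordinates.  The cross-strand comparison uses only orientation-independent
# keys (score, then interruption counts, then span) so that aligning a read
# and its reverse complement always reports the same numbers, even when the
# two strands tie; a full tie goes to the forward strand.
pick_strand <- function(fwd, rev, read_len, motif, scoring, read_id) {
  key <- function(h) {
    if (!isTRUE(h$found)) return(NULL)
    c(-h$score, h$deletions, h$insertions, h$substitutions, h$end - h$start)
  }
  kf <- key(fwd); kr <- key(rev)
  if (is.null(kf) && is.null(kr)) return(NULL)
  use_fwd <- if (is.null(kr)) TRUE else if (is.null(kf)) FALSE else {
    d <- kf - kr
    nz <- which(d != 0)
    length(nz) == 0L || d[nz[1L]] < 0
  }
  if (use_fwd) {
    hit <- fwd; strand <- "+"
    start <- hit$start; end <- hit$end
  } else {
    hit <- rev; strand <- "-"
    start <- read_len - hit$end; end <- read_len - hit$start
  }
  span <- end - start
  if (hit$score < scoring$min_score) return(NULL)
  if (span < min_span_for(scoring, motif)) return(NULL)
  m <- nchar(motif)
  consumed <- hit$matches + hit$substitutions + hit$deletions
  structure(list(
    read_id = read_id,
    strand = strand,
    start = start,
    end = end,
    motif = motif,
    motif_consumed_bp = consumed,
    repeat_count = as.integer(floor(consumed / m + 0.5)),
    matches = hit$matches,
    substitutions = hit$substitutions,
    insertions = hit$insertions,
    deletions = hit$deletions,
    score = hit$score), class = "repeat_alignment")
}

#' @export
print.repeat_alignment <- function(x, ...) {
  cat(sprintf(
    "<repeat_alignment> %s strand %s  [%d,%d)  %d x %s  score %d\n",
    if (is.na(x$read_id)) "" else x$read_id, x$strand, x$start, x$end,
    x$repeat_count, x$motif, x$score))
  cat(sprintf("  matches %d  substitutions %d  insertions %d  deletions %d\n",
              x$matches, x$substitutions, x$insertions, x$deletions))
  invisible(x)
}

# Brute-force reference aligner: plain affine-gap Smith-Waterman against an
# explicit tiling of the motif with enough copies that adding more cannot
# change the optimum.  Every deleted reference base costs at least
# gap_extend, and the total score gained by read bases is at most
# |read| * match, so an optimal alignment consumes fewer than
# |read| * (1 + match / gap_extend) reference bases; the tiling covers that
# bound with a margin.  Used as the independent check of align_repeat in the
# test suite; not exported.
align_repeat_tiled <- function(read, motif, scoring = scoring_scheme(),
                               read_id = NA_character_, extra_copies = 3L) {
  check_dna(motif, allow_empty = FALSE, what = "motif")
  max_ref <- nchar(read) * (1 + scoring$match / scoring$gap_extend)
  k <- ceiling(max_ref / nchar(motif)) + extra_copies
  ref <- strrep(motif, k)
  fwd <- .sw_affine_cpp(read, ref, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
  rev <- .sw_affine_cpp(revcomp(read), ref, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
  pick_strand(fwd, rev, nchar(read), motif, scoring, read_id)
}
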
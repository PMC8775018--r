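#' Construct variant records
#'
#' Minimal representation of called variants on the locus reference, as used
#' by the hemizygous post-filter: 0-based position, ref/alt alleles, allele
#' frequency (alt-supporting reads / depth, taken verbatim from the upstream
#' caller), Phred quality and depth.
#'
#' @param position integer vector, 0-based positions on the locus sequence.
#' @param ref,alt allele strings.
#' @param allele_frequency numeric in `[0, 1]`.
#' @param quality Phred-scaled variant quality (>= 0).
#' @param depth read depth (optional, `NA` allowed).
#' @return data frame of class `variant_records`.
#' @export
variant_records <- function(position, ref, alt, allele_frequency, quality,
                            depth = NA_integer_) {
  if (any(allele_frequency < 0 | allele_frequency > 1))
    stop("allele_frequency must be in [0, 1]")
  if (any(quality < 0)) stop("quality must be non-negative")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  n <- length(position)
  out <- data.frame(position = as.integer(position),
                    ref = rep(as.character(ref), length.out = n),
                    alt = rep(as.character(alt), length.out = n),
                    allele_frequency = rep(as.numeric(allele_frequency),
                                           length.out = n),
                    quality = rep(as.numeric(quality), length.out = n),
                    depth = rep(as.integer(depth), length.out = n),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Identify homopolymer positions in a sequence
#'
#' Returns a logical mask over the sequence marking every base inside a
#' single-base run of at least `hp_len`, widened by `margin` bases on each
#' side.  Variant calls at such positions in noisy long reads are enriched
#' for basecalling artifacts; this rule is the reproducible surrogate for
#' manual browser review of such calls.
#'
#' @param seq DNA string.
#' @param hp_len minimum run length (default 4).
#' @param margin adjacency margin in bp (default 1).
#' @return logical vector of length `nchar(seq)` (index 1 = position 0).
#' @export
homopolymer_mask <- function(seq, hp_len = 4L, margin = 1L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  mask <- logical(length(chars))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$lengths >= hp_len)) {
    lo <- max(1L, starts[k] - margin)
    hi <- min(length(chars), ends[k] + margin)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' Post-filter hemizygous variant calls
#'
#' Applies the hemizygous filtering rules to upstream variant calls: a record
#' is kept iff its allele frequency is strictly above `af_min`, its Phred
#' quality strictly above `q_min`, and its position does not fall inside (or
#' within `margin` bp of) a homopolymer run of length >= `hp_len` in the
#' locus sequence.  Rejected records carry the *first* failing rule as their
#' reason, checked in the order allele_frequency, quality, homopolymer.
#'
#' The filter is deterministic, idempotent and order-independent; kept and
#' rejected partition the input.
#'
#' @param records a [variant_records()] data frame.
#' @param locus_sequence the locus reference sequence the positions refer to.
#' @param af_min allele-frequency threshold (default 0.90, strict `>`).
#' @param q_min Phred-quality threshold (default 20, strict `>`).
#' @param hp_len homopolymer run length (default 4).
#' @param margin homopolymer adjacency margin in bp (default 1).
#' @return list with `kept` (variant records) and `rejected` (variant records
#'   plus a `reason` column).
#' @export
filter_variants <- function(records, locus_sequence, af_min = 0.90,
                            q_min = 20, hp_len = 4L, margin = 1L) {
  stopifnot(is.data.frame(records))
  L <- nchar(locus_sequence)
  if (nrow(records) > 0 &&
      (any(records$position < 0) || any(records$position >= L)))
    stop("variant position out of locus bounds")

  if (nrow(records) == 0L) {
    rej <- records; rej$reason <- character(0)
    return(list(kept = records, rejected = rej))
  }

  hp <- homopolymer_mask(locus_sequence, hp_len = hp_len, margin = margin)
  reason <- rep(NA_character_, nrow(records))
  fail_af <- !(records$allele_frequency > af_min)
  fail_q <- !(records$quality > q_min)
  fail_hp <- hp[records$position + 1L]
  reason[fail_hp] <- "homopolymer"
  reason[fail_q] <- "quality"
  reason[fail_af] <- "allele_frequency"

  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- NULL; rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
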
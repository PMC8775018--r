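#' Describe a motif-repeat locus
#'
#' A locus model captures the structure of an amplicon or targeted region
#' containing a tandem repeat tract: a left flank, a repeat motif (default the
#' XDP-associated SVA hexanucleotide `CCCTCT`), a right flank, and optional
#' named region annotations (enhancers, repeat domain subunits, the SVA span)
#' given in template coordinates.
#'
#' @param left_flank,right_flank DNA strings (possibly empty) flanking the
#'   repeat tract.
#' @param motif repeat motif, uppercase A/C/G/T, non-empty.
#' @param region_annotations optional data frame from [region_annotation()].
#' @return an object of class `locus_model`.
#' @seealso [build_template()], [sva_fixture_locus()]
#' @export
locus_model <- function(left_flank = "", motif = "CCCTCT", right_flank = "",
                        region_annotations = NULL) {
  check_dna(motif, allow_empty = FALSE, what = "motif")
  check_dna(left_flank, allow_empty = TRUE, what = "left_flank")
  check_dna(right_flank, allow_empty = TRUE, what = "right_flank")
  if (!is.null(region_annotations)) {
    stopifnot(is.data.frame(region_annotations),
              all(c("name", "start", "end") %in% names(region_annotations)))
  }
  structure(list(left_flank = left_flank, motif = motif,
                 right_flank = right_flank,
                 region_annotations = region_annotations),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model>\n")
  cat(sprintf("  motif: %s (%d bp)\n", x$motif, nchar(x$motif)))
  cat(sprintf("  flanks: %d bp / %d bp\n",
              nchar(x$left_flank), nchar(x$right_flank)))
  n_anno <- if (is.null(x$region_annotations)) 0L else nrow(x$region_annotations)
  cat(sprintf("  region annotations: %d\n", n_anno))
  invisible(x)
}

#' Named region annotations (0-based half-open intervals)
#'
#' @param name character vector of region names.
#' @param start,end integer vectors; 0-based half-open template coordinates.
#' @return data frame with columns `name`, `start`, `end`.
#' @export
region_annotation <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("region end must be greater than start")
  if (any(start < 0)) stop("region start must be non-negative")
  data.frame(name = as.character(name), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Build the template sequence for a locus with a given repeat number
#'
#' Concatenates `left_flank + motif x n_repeats + right_flank`.  The returned
#' string carries attributes `n_repeats` and `repeat_interval` (0-based
#' half-open span of the repeat tract) used by the simulator's ground-truth
#' log.
#'
#' @param locus a [locus_model()].
#' @param n_repeats number of motif copies, >= 0.
#' @return character scalar template with attributes.
#' @export
build_template <- function(locus, n_repeats) {
  stopifnot(inherits(locus, "locus_model"))
  if (length(n_repeats) != 1L || is.na(n_repeats) || n_repeats < 0)
    stop("n_repeats must be a single non-negative integer")
  n_repeats <- as.integer(n_repeats)
  tract <- strrep(locus$motif, n_repeats)
  tpl <- paste0(locus$left_flank, tract, locus$right_flank)
  attr(tpl, "n_repeats") <- n_repeats
  attr(tpl, "repeat_interval") <-
    c(nchar(locus$left_flank), nchar(locus$left_flank) + nchar(tract))
  tpl
}

#' Locate CpG sites in a sequence
#'
#' Returns the 0-based positions of the C of every CG dinucleotide on the
#' forward strand (the convention used by per-read CpG methylation callers
#' after collapsing strands).
#'
#' @param seq DNA string.
#' @return integer vector of 0-based positions (possibly empty).
#' @export
cpg_sites <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# -- internal helpers ---------------------------------------------------------

check_dna <- function(x, allow_empty, what) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a single string")
  if (!allow_empty && nchar(x) == 0L) stop(what, " must be non-empty")
  if (nchar(x) > 0L && grepl("[^ACGT]", x))
    stop(what, " must contain only uppercase A/C/G/T")
  invisible(TRUE)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
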
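#' Synthetic SVA-like fixture locus
#'
#' Builds a fully synthetic locus that mirrors the *structure* of the
#' XDP-associated SVA insertion in *TAF1* without using any real genomic
#' sequence: a 1.5 kb upstream flank carrying two predicted-enhancer
#' annotations, a `(CCCTCT)n` hexanucleotide repeat tract, a 1.8 kb SVA body
#' (Alu-like, VNTR and SINE-R subunits) containing exactly 153 CpG
#' dinucleotides, and a 1.5 kb downstream flank carrying ten enhancer
#' annotations of which one ("enhancer8") deliberately contains no CpG site
#' (so region summaries must report it as excluded).  At the default
#' `n_repeats = 45` the template is about 5.1 kb, comparable to a targeted
#' enrichment product over such a locus.
#'
#' The sequence is generated deterministically (an internal fixed seed; the
#' global RNG state is preserved).  Flank/repeat junctions are forced to
#' break the motif so local alignment of error-free reads recovers exactly
#' `n_repeats` copies.
#'
#' @param n_repeats repeat copies in the hexanucleotide tract (default 45).
#' @return list with elements `locus` (a [locus_model()] whose annotations are
#'   in template coordinates for this `n_repeats`), `template` (from
#'   [build_template()]), `cpg_positions` (0-based C positions of all CpGs in
#'   the template) and `n_repeats`.
#' @export
sva_fixture_locus <- function(n_repeats = 45L) {
  n_repeats <- as.integer(n_repeats)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(902613L)

  flank_len <- 1500L
  body_len <- 1800L
  motif <- "CCCTCT"

  left <- paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
                collapse = "")
  # junction must not extend the motif pattern
  substr(left, flank_len - 5L, flank_len) <- "GAAGGA"

  # SVA body: G-free backbone, then exactly 153 CpG dinucleotides placed on an
  # even grid (all >= 2 bp apart), so the only CGs in the SVA are the placed ones
  body <- sample(c("A", "C", "T"), body_len, replace = TRUE)
  body[1:6] <- c("A", "A", "G", "G", "A", "A")
  cpg_body <- as.integer(round(seq(12, body_len - 10L, length.out = 153L)))
  body[cpg_body] <- "C"
  body[cpg_body + 1L] <- "G"
  body <- paste(body, collapse = "")

  body <- strsplit(body, "", fixed = TRUE)[[1]]
  body[body_len] <- "A"  # no C right before the downstream flank junction
  body <- paste(body, collapse = "")

  right_genomic <- sample(c("A", "C", "G", "T"), flank_len, replace = TRUE)
  # ten downstream enhancers, 100 bp each, every 140 bp; offsets are 0-based
  enh_off <- 50L + (0:9) * 140L
  # "enhancer8" (the 6th downstream = overall 8th) must contain no CpG:
  # remove every G that follows a C inside or at the edge of its interval
  e8 <- (enh_off[6L] + 1L):(enh_off[6L] + 100L)  # 1-based vector indices
  bad <- e8[right_genomic[e8] == "G" & right_genomic[e8 - 1L] == "C"]
  right_genomic[bad] <- "A"
  right_genomic <- paste(right_genomic, collapse = "")

  tract_len <- n_repeats * nchar(motif)
  sva_start <- flank_len
  sva_end <- flank_len + tract_len + body_len
  right_start <- sva_end

  regions <- region_annotation(
    name = c("SVA", "hexamer", "Alu_like", "VNTR", "SINE_R",
             paste0("enhancer", 1:12)),
    start = c(sva_start, sva_start,
              sva_start + tract_len, sva_start + tract_len + 600L,
              sva_start + tract_len + 1400L,
              100L, 700L,
              right_start + enh_off),
    end = c(sva_end, sva_start + tract_len,
            sva_start + tract_len + 600L, sva_start + tract_len + 1400L,
            sva_end,
            260L, 860L,
            right_start + enh_off + 100L))

  locus <- locus_model(left_flank = left, motif = motif,
                       right_flank = paste0(body, right_genomic),
                       region_annotations = regions)
  template <- build_template(locus, n_repeats)
  list(locus = locus, template = template,
       cpg_positions = cpg_sites(template), n_repeats = n_repeats)
}
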
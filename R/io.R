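#' Read FASTA/FASTQ sequences
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()`.  The format is taken
#' from the file extension (`.fastq`/`.fq`, optionally `.gz`, are FASTQ;
#' anything else FASTA).  Qualities are not retained: nothing downstream
#' consumes them.
#'
#' @param path path to a (optionally gzipped) FASTA or FASTQ file.
#' @return named character vector of sequences (names are the record ids up
#'   to the first whitespace).
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write reads as FASTQ
#'
#' Writes 4-line FASTQ records with a constant placeholder quality (`I`),
#' matching the simulator's contract that qualities are never consumed.
#' Output is byte-deterministic.
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @param qual_char quality character (default `"I"`).
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", ids)
  lines[seq(2, by = 4, length.out = length(reads))] <- unname(reads)
  lines[seq(3, by = 4, length.out = length(reads))] <- "+"
  lines[seq(4, by = 4, length.out = length(reads))] <-
    strrep(qual_char, nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Write a sequence as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read region annotations from BED
#'
#' Parses BED (0-based half-open) via `rtracklayer::import()` and returns the
#' package's region-annotation data frame.  Only the first three columns plus
#' the name column are used.
#'
#' @param path BED file path.
#' @return data frame with `name`, `start`, `end` (0-based half-open) and
#'   `chrom`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- sprintf("region%d", seq_along(gr))
  out <- region_annotation(name = nm,
                           start = GenomicRanges::start(gr) - 1L,
                           end = GenomicRanges::end(gr))
  out$chrom <- as.character(GenomicRanges::seqnames(gr))
  out
}

#' Write region annotations as BED
#'
#' @param regions data frame from [region_annotation()].
#' @param path output path.
#' @param chrom chromosome/contig label (recycled).
#' @export
write_bed <- function(regions, path, chrom = "locus") {
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, regions$start, regions$end,
                   regions$name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal VCF into variant records
#'
#' Reads a VCF via `vcfR::read.vcfR()` and extracts the fields the
#' hemizygous post-filter needs: position (converted to 0-based), REF, ALT,
#' QUAL, and allele frequency / depth from the INFO fields `AF` and `DP`
#' (falling back to `AD` in the first sample's FORMAT fields when `AF` is
#' absent).
#'
#' @param path VCF file path.
#' @return a [variant_records()] data frame.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_records(integer(0), character(0), character(0),
                           numeric(0), numeric(0)))
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(val))
  }
  af <- info_field("AF")
  dp <- info_field("DP")
  if (all(is.na(af))) {
    ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[, 1L],
                   error = function(e) NULL)
    if (!is.null(ad)) {
      parts <- strsplit(ad, ",", fixed = TRUE)
      refn <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
      altn <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
      af <- altn / (refn + altn)
      if (all(is.na(dp))) dp <- refn + altn
    }
  }
  if (anyNA(af)) stop("VCF records lack an AF INFO field (or AD genotype field)")
  variant_records(position = as.integer(fix$POS) - 1L,
                  ref = fix$REF, alt = fix$ALT,
                  allele_frequency = af,
                  quality = suppressWarnings(as.numeric(fix$QUAL)),
                  depth = as.integer(round(dp)))
}

#' Write variant records as a minimal VCF
#'
#' @param records a [variant_records()] data frame.
#' @param path output path.
#' @param chrom contig label.
#' @export
write_vcf_minimal <- function(records, path, chrom = "locus") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(records) == 0L) character(0) else sprintf(
    "%s\t%d\t.\t%s\t%s\t%.6g\t.\tAF=%.6g;DP=%d",
    chrom, records$position + 1L, records$ref, records$alt,
    records$quality, records$allele_frequency,
    ifelse(is.na(records$depth), 0L, records$depth))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Plain TSV with a header row; the interchange format for per-read, per-site
#' and per-sample tables.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Reproducibility metadata written next to every CLI output set.  Contains
# the resolved configuration, seed and package version -- deliberately no
# timestamp, so identical runs are byte-identical.
write_run_metadata <- function(config, dir) {
  config$package_version <-
    as.character(utils::packageVersion("svarepeat"))
  jsonlite::write_json(config, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config)
}
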
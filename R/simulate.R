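#' Per-base sequencing error profile
#'
#' Independent per-base substitution, insertion and deletion probabilities.
#' Presets mirror published basecaller accuracies for the two models used for
#' repeat calling: `"sup"` (super-accuracy, 98.3% accurate, total error
#' 0.017) and `"fast"` (95.8% accurate, total error 0.042).  The total error
#' is split 60% indels (evenly between deletions and insertions) and 40%
#' substitutions, reflecting the indel-dominated error structure of nanopore
#' reads; all three rates can be overridden.
#'
#' @param sub_rate,ins_rate,del_rate per-base event probabilities, each in
#'   `[0, 0.5)` with total below 1.
#' @param preset_name optional label (`"sup"`, `"fast"`, or custom).
#' @return object of class `error_profile`.
#' @export
error_profile <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                          preset_name = NA_character_) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 0.5) || sum(rates) >= 1)
    stop("each rate must be in [0, 0.5) and their sum below 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, preset_name = preset_name),
            class = "error_profile")
}

#' @rdname error_profile
#' @param name preset name, `"sup"` or `"fast"`.
#' @export
error_preset <- function(name = c("sup", "fast")) {
  name <- match.arg(name)
  total <- switch(name, sup = 0.017, fast = 0.042)
  error_profile(sub_rate = 0.4 * total,
                ins_rate = 0.3 * total,
                del_rate = 0.3 * total,
                preset_name = name)
}

#' Simulate noisy reads from a template
#'
#' Draws `coverage` reads from a template (or its reverse complement, with
#' probability 1/2 each) by applying independent per-base errors: each
#' template base is deleted with probability `del_rate`, otherwise
#' substituted (uniformly among the three alternatives) with probability
#' `sub_rate`; independently, a uniform random base is inserted after each
#' template position with probability `ins_rate`.  FASTQ qualities are a
#' constant placeholder (`I`); downstream analysis never consumes them.
#'
#' The returned ground-truth log records the exact number of injected events
#' per read, enabling parameter-recovery tests; identical seeds produce
#' identical output.
#'
#' @param template DNA string, typically from [build_template()].
#' @param coverage number of reads (>= 1).
#' @param profile an [error_profile()].
#' @param length_model `"amplicon"` (full-length reads) or `"targeted"`
#'   (reads truncated to a uniform `[0.5, 1]` fraction of the template,
#'   anchored at a random end, emulating targeted-enrichment fragments), or a
#'   function `(template_length) -> read length`.
#' @param seed integer seed.
#' @param id_prefix prefix for read identifiers.
#' @return list with `reads` (named character vector) and `truth` (data frame
#'   with columns `read_id`, `true_repeat_n`, `strand`, `read_length`,
#'   `injected_subs`, `injected_ins`, `injected_dels`).
#' @export
simulate_reads <- function(template, coverage, profile = error_profile(),
                           length_model = "amplicon", seed = 1L,
                           id_prefix = "read") {
  if (length(template) != 1L || is.na(template) || nchar(template) == 0L)
    stop("template must be a single non-empty string")
  if (coverage < 1) stop("coverage must be >= 1")
  stopifnot(inherits(profile, "error_profile"))
  set.seed(as.integer(seed))

  true_n <- attr(template, "n_repeats")
  if (is.null(true_n)) true_n <- NA_integer_
  tpl_chars <- strsplit(as.character(template), "", fixed = TRUE)[[1]]
  L0 <- length(tpl_chars)

  reads <- character(coverage)
  truth <- data.frame(
    read_id = sprintf("%s%04d", id_prefix, seq_len(coverage)),
    true_repeat_n = rep(as.integer(true_n), coverage),
    strand = character(coverage),
    read_length = integer(coverage),
    injected_subs = integer(coverage),
    injected_ins = integer(coverage),
    injected_dels = integer(coverage),
    stringsAsFactors = FALSE)

  for (i in seq_len(coverage)) {
    chars <- tpl_chars
    if (is.function(length_model)) {
      len <- min(L0, max(1L, as.integer(length_model(L0))))
      from_left <- runif(1) < 0.5
      chars <- if (from_left) chars[seq_len(len)]
               else chars[seq.int(L0 - len + 1L, L0)]
    } else if (identical(length_model, "targeted")) {
      len <- max(1L, as.integer(round(runif(1, 0.5, 1.0) * L0)))
      from_left <- runif(1) < 0.5
      chars <- if (from_left) chars[seq_len(len)]
               else chars[seq.int(L0 - len + 1L, L0)]
    } else if (!identical(length_model, "amplicon")) {
      stop("length_model must be 'amplicon', 'targeted', or a function")
    }
    L <- length(chars)

    u <- runif(L)
    del <- u < profile$del_rate
    sub <- !del & u < profile$del_rate + profile$sub_rate
    ins <- runif(L) < profile$ins_rate

    out <- chars
    if (any(sub)) {
      alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
      idx <- which(sub)
      pick <- ceiling(runif(length(idx)) * 3)
      out[idx] <- vapply(seq_along(idx), function(k)
        substr(alt[[chars[idx[k]]]], pick[k], pick[k]), character(1))
    }
    out[del] <- ""
    if (any(ins)) {
      insbase <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
      out[ins] <- paste0(out[ins], insbase)
    }
    seq <- paste(out, collapse = "")
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") seq <- revcomp(seq)

    reads[i] <- seq
    truth$strand[i] <- strand
    truth$read_length[i] <- nchar(seq)
    truth$injected_subs[i] <- sum(sub)
    truth$injected_ins[i] <- sum(ins)
    truth$injected_dels[i] <- sum(del)
  }
  names(reads) <- truth$read_id
  list(reads = reads, truth = truth)
}

#' Simulate per-read CpG methylation calls
#'
#' Emulates the table a signal-level CpG methylation caller emits: one row
#' per read x site with a log-likelihood ratio (positive = evidence for
#' 5-methylcytosine).  Each site receives a sampled number of reads; each
#' read is truly methylated with the site's probability and its LLR is drawn
#' from a unit-variance normal centred at `+llr_separation/2` (methylated) or
#' `-llr_separation/2` (unmethylated).
#'
#' Read identifiers are drawn from a shared pool so that several sites can be
#' covered by the same read, as in real long-read data; each pool read gets
#' an alignment length from `read_length_sampler` for use with
#' [filter_reads_by_length()].
#'
#' @param sites integer vector of 0-based CpG positions.
#' @param true_mf named numeric vector (or plain vector parallel to `sites`)
#'   of true per-site methylation probabilities in `[0, 1]`.
#' @param coverage integer, integer vector per site, or function
#'   `(n_sites) -> integer vector`: reads covering each site.
#' @param llr_separation distance between the methylated and unmethylated
#'   LLR means (default 10; calls are then essentially always confident at
#'   the default LLR threshold of 2).
#' @param read_length_sampler function `(n_reads) -> lengths` for the read
#'   pool metadata (default: constant 5000 bp).
#' @param seed integer seed.
#' @return list with `calls` (data frame `read_id`, `position`,
#'   `log_lik_ratio`), `meta` (data frame `read_id`, `alignment_length`) and
#'   `truth` (data frame `position`, `true_mf`).
#' @export
simulate_methylation_calls <- function(sites, true_mf, coverage = 30L,
                                       llr_separation = 10,
                                       read_length_sampler = NULL,
                                       seed = 1L) {
  if (length(sites) == 0L) {
    return(list(calls = data.frame(read_id = character(0),
                                   position = integer(0),
                                   log_lik_ratio = numeric(0)),
                meta = data.frame(read_id = character(0),
                                  alignment_length = integer(0)),
                truth = data.frame(position = integer(0),
                                   true_mf = numeric(0))))
  }
  if (length(true_mf) == 1L) true_mf <- rep(true_mf, length(sites))
  if (length(true_mf) != length(sites))
    stop("true_mf must be scalar or parallel to sites")
  if (any(true_mf < 0 | true_mf > 1)) stop("true_mf values must be in [0, 1]")
  set.seed(as.integer(seed))

  cov <- if (is.function(coverage)) as.integer(coverage(length(sites)))
         else rep(as.integer(coverage), length.out = length(sites))
  n_pool <- max(cov)
  pool <- sprintf("mread%05d", seq_len(n_pool))
  lens <- if (is.null(read_length_sampler)) rep(5000L, n_pool)
          else as.integer(read_length_sampler(n_pool))

  rows <- vector("list", length(sites))
  for (s in seq_along(sites)) {
    k <- cov[s]
    ids <- pool[sample.int(n_pool, k)]
    methylated <- runif(k) < true_mf[s]
    llr <- stats::rnorm(k, mean = ifelse(methylated, llr_separation / 2,
                                         -llr_separation / 2), sd = 1)
    rows[[s]] <- data.frame(read_id = ids,
                            position = rep(as.integer(sites[s]), k),
                            log_lik_ratio = llr, stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, rows),
       meta = data.frame(read_id = pool, alignment_length = lens,
                         stringsAsFactors = FALSE),
       truth = data.frame(position = as.integer(sites), true_mf = true_mf))
}

#' Simulate fragment-analysis sizes for a cohort
#'
#' Capillary-electrophoresis fragment sizing is linear in the repeat number:
#' `size = offset_bp + motif_len * n + jitter`, with Gaussian jitter rounded
#' to whole base pairs.  The calibration (offset) of real instruments is
#' assay-specific, so it is an explicit parameter; [fragment_to_repeat()]
#' inverts the map.
#'
#' @param true_ns integer vector of true repeat numbers (one per sample).
#' @param offset_bp non-repeat portion of the sized fragment (default 300).
#' @param jitter_sd Gaussian sizing noise in bp (default 0).
#' @param motif_len motif length in bp (default 6).
#' @param seed integer seed.
#' @param sample_ids optional sample identifiers.
#' @return data frame with columns `sample_id`, `true_repeat_n`, `size_bp`.
#' @export
simulate_fragment_sizes <- function(true_ns, offset_bp = 300L, jitter_sd = 0,
                                    motif_len = 6L, seed = 1L,
                                    sample_ids = NULL) {
  if (offset_bp < 0) stop("offset_bp must be non-negative")
  set.seed(as.integer(seed))
  n <- length(true_ns)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%03d", seq_len(n))
  jitter <- if (jitter_sd > 0) stats::rnorm(n, 0, jitter_sd) else numeric(n)
  size <- as.integer(round(offset_bp + motif_len * as.numeric(true_ns) + jitter))
  data.frame(sample_id = sample_ids, true_repeat_n = as.integer(true_ns),
             size_bp = size, stringsAsFactors = FALSE)
}

#' Simulate a patient cohort with known repeat truth
#'
#' Generates a cohort mirroring an amplicon resequencing study of a
#' polymorphic repeat: true repeat numbers drawn uniformly from `n_range`,
#' noisy reads per sample at the given error preset and coverage,
#' fragment-analysis sizes, and ages at onset linearly (negatively) related
#' to repeat number.  The default onset model `aao = 92.3 - 1.12 n + eps`,
#' `eps ~ N(0, 4.6^2)`, reproduces an onset distribution with mean ~40.7,
#' SD ~8.75 and a rank correlation of about -0.85 with repeat number when
#' `n ~ Uniform{35..57}`.
#'
#' @param n_samples cohort size (default 96).
#' @param n_range integer vector of possible true repeat numbers.
#' @param locus a [locus_model()]; default [sva_fixture_locus()]'s locus.
#' @param profile an [error_profile()] (default preset `"sup"`).
#' @param coverage reads per sample (default 50).
#' @param fragment_offset_bp,fragment_jitter_sd fragment-size model, see
#'   [simulate_fragment_sizes()].
#' @param aao_intercept,aao_slope,aao_sd onset model parameters.
#' @param seed integer seed.
#' @return list with `samples` (named list of per-sample read sets as in
#'   [simulate_reads()]), `truth` (data frame `sample_id`, `true_repeat_n`,
#'   `aao_years`) and `fragment_sizes` (data frame).
#' @export
simulate_cohort <- function(n_samples = 96L, n_range = 35:57,
                            locus = NULL, profile = error_preset("sup"),
                            coverage = 50L, fragment_offset_bp = 300L,
                            fragment_jitter_sd = 1,
                            aao_intercept = 92.3, aao_slope = 1.12,
                            aao_sd = 4.6, seed = 1L) {
  if (is.null(locus)) locus <- sva_fixture_locus()$locus
  set.seed(as.integer(seed))
  true_ns <- if (length(n_range) == 1L) rep(as.integer(n_range), n_samples)
             else sample(n_range, n_samples, replace = TRUE)
  sample_ids <- sprintf("sample%03d", seq_len(n_samples))
  aao <- aao_intercept - aao_slope * true_ns + stats::rnorm(n_samples, 0, aao_sd)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)

  samples <- vector("list", n_samples)
  names(samples) <- sample_ids
  for (i in seq_len(n_samples)) {
    tpl <- build_template(locus, true_ns[i])
    samples[[i]] <- simulate_reads(tpl, coverage = coverage, profile = profile,
                                   seed = sample_seeds[i],
                                   id_prefix = paste0(sample_ids[i], "_read"))
  }
  frag <- simulate_fragment_sizes(true_ns, offset_bp = fragment_offset_bp,
                                  jitter_sd = fragment_jitter_sd,
                                  seed = sample_seeds[1L] + 1L,
                                  sample_ids = sample_ids)
  list(samples = samples,
       truth = data.frame(sample_id = sample_ids,
                          true_repeat_n = as.integer(true_ns),
                          aao_years = round(aao, 1),
                          stringsAsFactors = FALSE),
       fragment_sizes = frag)
}
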
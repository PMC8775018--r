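---
title: "Methods: tandem-repeat quantification and locus methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem-repeat quantification and locus methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svarepeat)
```

# Scope and model

`svarepeat` quantifies the copy number of a short tandem repeat motif
(canonically the hexanucleotide `CCCTCT` of the XDP-associated SVA insertion
in *TAF1*) from individual noisy long reads, profiles deviations from the
perfect motif, post-filters variant calls under a hemizygous model, and
aggregates per-read CpG methylation calls into filtered site- and
region-level methylation frequencies. A synthetic-data generator with full
ground-truth logging stands in for raw sequencing data, so every stage can
be tested as a parameter-recovery problem.

The package assumes:

* one repeat tract per read (amplicon or targeted enrichment of a single
  locus); multi-tract discovery is out of scope, and the motif is an input,
  not something to be detected;
* a hemizygous sample (single allele), so variant calls are expected at
  allele frequencies near 1;
* per-read CpG calls arriving as log-likelihood ratios with strands already
  collapsed to the forward-strand C of each CpG, the dialect of signal-level
  methylation callers.

# The aligner

## Wraparound dynamic programming

A read $r$ is aligned against the unbounded tandem reference
$m^\infty$ with local (Smith–Waterman) scoring and affine gap penalties:
match $+a$, mismatch $-b$, and a gap of length $k$ costing $-(g_o + k
g_e)$. Rather than materialising a tiled reference, the DP keeps one column
per motif position and takes diagonal and reference-gap transitions modulo
$|m|$, for $O(|r|\,|m|)$ time. Reference-consuming gap runs can wrap the
column boundary within a row; because $g_e \ge 1$, an optimal alignment
never consumes a full motif period inside one row (deleting a whole period
can be dropped for a strict score gain of $|m| g_e$), so a run wraps at most
once and two sweeps per row reach the fixed point.

Both strands are aligned (the reverse complement of the read against the
same motif) and the better alignment kept; reverse-strand intervals are
mapped back to original read coordinates.

## Canonical optimum and tie-breaking

Affine-gap alignments are frequently co-optimal, and different co-optimal
paths can carry different interruption counts. To make the output a
deterministic function of the read alone, the DP state is a lexicographic
value — score (maximised), then read start (minimised), then deletions,
insertions and substitutions (each minimised) — all additive along
alignment edges, so Bellman optimality holds for the whole tuple. Among end
cells the alignment with the highest score, then smallest start, then
shortest read span, then the canonical counts is reported. The cross-strand
choice compares only orientation-independent keys (score, counts, span) so
a read and its reverse complement always report identical numbers; a full
tie is labelled forward-strand.

The same objective is implemented twice: the production wraparound DP and a
deliberately naive full-matrix Smith–Waterman against an explicit motif
tiling (`svarepeat:::align_repeat_tiled`). Since both optimise the same
functional over the same set of candidate alignments, they must agree
exactly; the test suite checks this on hundreds of random
(read, motif, scoring) instances, including period-1 motifs. The tiling
uses $\lceil |r|(1 + a/g_e)/|m|\rceil + 3$ copies: every deleted reference
base costs at least $g_e$ and read bases contribute at most $a$ each, which
bounds the reference consumption of any optimal alignment.

## Repeat number and interruptions

The repeat count of a read is the number of reference bases the optimal
alignment consumes divided by $|m|$, rounded half up — partially aligned
terminal copies therefore resolve deterministically (a dangling fragment of
less than half a copy is dropped, at least half a copy counts). Alignment
substitutions, insertions and deletions within the tract are reported as
repeat interruptions per read. Two accounting identities hold for every
alignment and are asserted in tests: matches + substitutions + deletions =
consumed reference bases, and matches + substitutions + insertions = read
span.

## Scoring defaults

Repeat-finder scoring is not standardised, so all constants are exposed:

| parameter | default | rationale |
|---|---|---|
| `match` | +2 | conventional local-alignment reward |
| `mismatch` | 3 | penalises substitutions above gap extension |
| `gap_open` | 4, `gap_extend` 2 | indel-tolerant, as appropriate for nanopore-type errors |
| `min_score` | 40 | ≈ 20 perfectly matched bases; rejects spurious low-complexity hits |
| `min_span_bp` | 5·\|m\| | a reported tract must span at least five motif copies |

`gap_extend` must be ≥ 1: with free gap extension the reference consumption
of an optimal alignment (hence the repeat count) is not well defined, since
whole motif copies could be deleted at zero cost.

## Sample calls

A sample's repeat number is the median of the per-read counts, with the
interquartile range (Q3 − Q1) as spread; both use linear-interpolation
quantiles (`stats::quantile(type = 7)`), a choice that matters for small
read sets and is therefore documented rather than left implicit. Zero
aligned reads produce an explicit no-call object, not an error. Cohort
interruption summaries report, per type, the mean and sample SD (n − 1)
across samples of the per-sample mean interruptions per read.

# Variant post-filter

A call is kept iff allele frequency > 0.90 **and** Phred quality > 20
**and** its position is not inside, or within 1 bp of, a single-base run of
length ≥ 4 in the locus sequence. Thresholds are strict inequalities, and
each rejection records the first failing rule (frequency, then quality,
then homopolymer). The homopolymer rule replaces manual inspection of
alignments in a genome browser; visual review has no objective criterion,
so a deterministic surrogate with exposed `hp_len` and `margin` was chosen
for reproducibility. The filter partitions its input, and is idempotent and
order-independent (property-tested).

# Methylation pipeline

The stage order is fixed and each stage logs record counts:

1. **Alignment-length filter** (strict `>`): removes calls from reads whose
   alignment is shorter than the threshold — 3000 bp for samples carrying
   the insertion, 1500 bp for controls without it — the standard
   countermeasure against off-target reads from Cas9 enrichment. Unknown
   read ids are an error naming the read, never silently dropped.
2. **Confidence filter**: calls with $|\mathrm{LLR}| < 2$ are ambiguous and
   discarded. The cutoff follows the conventional 2–2.5 family used with
   log-likelihood-ratio callers and is exposed (`llr_threshold`) because
   published analyses rarely state it.
3. **Site summaries**: coverage = confident calls, methylated = calls with
   LLR ≥ +2, MF = methylated/coverage; sites with coverage ≤ 10 are removed
   (">10 reads" read strictly, i.e. at least 11).
4. **Region aggregation**: a site belongs to a region if its C position
   lies in the 0-based half-open interval; regions report mean and sample
   SD (n − 1) of site MFs. Regions containing no retained CpG site are
   flagged `excluded` instead of dropped — the repeat tract itself
   (`CCCTCT` contains no CG) and one fixture enhancer behave this way by
   construction.
5. **Comparisons**: Mann–Whitney U on per-site MFs. For $n_a+n_b \le 20$
   the two-sided p-value is exact by enumerating all
   $\binom{n_a+n_b}{n_a}$ assignments of the pooled mid-ranks — unlike
   table-based exact tests this remains valid under ties, which are
   ubiquitous in MF data; larger samples use the normal approximation with
   tie-corrected variance and continuity correction. P-values are labelled
   exploratory; no multiplicity correction is applied.

Because a sample carrying the insertion and a control without it live on
different coordinate systems, cross-sample region comparisons are made by
region **name** (`compare_regions_by_name`), never by coordinate.

# Concordance statistics

Fragment-analysis sizes convert to repeat numbers by inverting the linear
model $\mathrm{size} = \mathrm{offset} + |m| \cdot n$ with nearest-integer
rounding. No published calibration exists for such assays, so the offset is
an explicit parameter (default 300 bp) rather than a guess baked into the
code. Spearman correlations use average ranks for ties — cohorts contain
many repeated integer repeat numbers, so tie handling materially affects
the estimate. The systematic offset between sequencing-based and
fragment-analysis calls is surfaced as the median paired difference, a
diagnostic, not a correction, since its cause (motif interruptions versus
sizing calibration) cannot be resolved from the data the package sees. N50
is the largest length L such that reads ≥ L hold at least half of all
bases.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* **Templates**: left flank + motif×n + right flank. The bundled fixture
  locus (`sva_fixture_locus`) is fully synthetic — labelled as such — and
  mirrors the targeted-locus structure: 1.5 kb flanks, an SVA-like body
  with Alu-like/VNTR/SINE-R subunits containing exactly 153 CpG sites, 12
  enhancer annotations (2 upstream, 10 downstream) of which "enhancer8"
  deliberately contains none, and clean motif junctions.
* **Reads**: per base, deletion with $p_d$, else substitution with $p_s$
  (uniform over the three alternatives); independently an insertion of a
  uniform base after each position with $p_i$; strand uniform. Error
  presets mirror published basecaller accuracies — "sup" 98.3% accurate
  (total error 0.017) and "fast" 95.8% (0.042) — split 60% indels (evenly
  deletion/insertion) and 40% substitutions to reflect the indel-dominated
  error structure of nanopore reads. Read-length models: full-length
  (amplicon) or uniform 50–100% truncation (targeted enrichment). FASTQ
  qualities are a constant placeholder; nothing downstream reads them.
* **Methylation calls**: per site, each covering read is truly methylated
  with the site's probability; LLRs are unit-variance normals at ±5
  (separation 10), making calls essentially always confident at the
  default threshold — the intent is to test aggregation, not caller
  uncertainty.
* **Fragment sizes**: offset + 6n + rounded Gaussian jitter.
* **Cohorts**: true repeat numbers uniform on {35..57} (the observed
  patient range), and ages at onset $\mathrm{AAO} = 92.3 - 1.12\,n +
  \varepsilon$, $\varepsilon \sim N(0, 4.6^2)$ — chosen once so that the
  onset distribution has mean ≈ 40.7, SD ≈ 8.75 and rank correlation
  ≈ −0.85 with repeat number, matching the reported cohort demographics
  and the strength of the published inverse association.

What the generator does **not** emulate: homopolymer-dependent error
inflation (errors are i.i.d. per base), basecaller-specific biases (such as
the systematic overcount of repeat copies relative to fragment analysis
seen with some high-accuracy models — simulated sequencing and fragment
data share one truth, so the median paired difference is centred at zero),
positionally coherent read spans in the methylation simulator (a read's
covered sites are sampled independently per site), and caller uncertainty
near the LLR decision boundary. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated error model,
not robustness to every artifact of real signal-level data.

# Test and acceptance problem sizes

The suite checks oracle equivalence on 500+ random alignment instances
(reads ≤ 200 bp, motifs ≤ 8 bp, randomised scoring), exact repeat recovery
for n = 1..60 on both strands, a 96-sample cohort at the "sup" preset with
50 reads/sample (recovery of medians within ±1 and rank concordance with
simulated fragment analysis), interruption-rate monotonicity and
rate-doubling response, the variant-filter contract on randomized records,
site-MF recovery at 30× coverage over the 153-CpG fixture (3-binomial-SD
tolerance), exact Mann–Whitney enumeration for all group sizes with
$n_a+n_b \le 8$, and byte-identical reruns of every CLI subcommand under a
fixed seed. These sizes were chosen as the smallest at which the binomial
tolerances quoted above are meaningful.

# Known limitations

* Exact numeric agreement with any particular external repeat-finder is not
  claimed: published tools do not document their scoring constants. The
  contract is equivalence to affine-gap Smith–Waterman against a tiled
  reference under the documented canonical objective.
* Only the single best repeat tract per read is reported.
* The homopolymer rule is a reproducible surrogate for, not a reconstruction
  of, manual review practice.
* Methylation comparisons are exploratory rank tests; no differential
  methylation model or multiple-testing correction is provided.
* Fragment-size calibration (offset, rounding) must be supplied by the
  user for real assays; defaults are only self-consistent with the bundled
  simulator.
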
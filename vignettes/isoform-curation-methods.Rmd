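---
title: "Methods: curation of full-length isoforms and detection of specifically-expressed transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation of full-length isoforms and detection of specifically-expressed transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocurate)
```

## Scope

`isocurate` turns a raw set of long-read transcript models into a curated
isoform catalog and, given a TPM matrix over a sample cohort, calls
tissue-specific and tumor-specific transcripts. This vignette documents the
model behind each stage, the tunable parameters and their defaults, the
design of the synthetic-fixture generator, and the numerical and tie-breaking
choices that make the pipeline deterministic. The tests that accompany the
package verify structural invariants and recovery of planted truth on
synthetic data; they do not compute or reproduce any empirical result from
real sequencing cohorts.

## Coordinate model and assumptions

Internally all intervals are 0-based, half-open `[start, end)`; GTF I/O
converts to and from the 1-based inclusive convention. A `transcript_model`
is a strand (`+`/`-` only; unstranded features are rejected with a counted
warning), a chromosome and a sorted set of non-overlapping, non-touching
exons. Introns are keyed as `chrom:strand:start-end` and splice sites as
`chrom:strand:pos`; the intron *chain* is the `|`-joined key sequence.
Assumptions: one locus per transcript, no fusion or trans-spliced models,
and junction evidence aggregated across samples refers to the same genome
build as the transcript models.

## Stage 1 — junction validation

Every intron of a spliced transcript must be supported by at least
`min_unique_reads` (default 1) uniquely-mapped reads in at least
`min_samples` (default **5**, inclusive) short-read samples, read from STAR
`SJ.out.tab` files. The 5-sample default demands independent replication
rather than deep coverage in a single library, which is the failure mode of
reverse-transcription artifacts. A junction reported with strand code 0 is
credited to both strands, since the aligner could not resolve it. Mono-exonic
models carry no junctions and are dropped by default
(`keep_monoexonic = FALSE`): without junctions the filter has no evidence to
act on, and mono-exonic long-read models are dominated by genomic
contamination.

## Stage 2 — structural classification

The cascade is evaluated in a fixed order so every transcript receives
exactly one label: FSM (identical intron chain), ISM (proper contiguous
sub-chain of one reference chain, matched at any offset), antisense,
intergenic, NIC (all sites known, novel chain), NNC (at least one novel
site). ISM transcripts are removed from the catalog: a contiguous sub-chain
is exactly the signature of 5′ or 3′ truncation. Locus assignment takes the
same-strand gene with maximal exonic overlap in base pairs, breaking ties by
span overlap and then lexicographic gene id; antisense requires
opposite-strand span overlap after same-strand assignment fails.
Classification of a mono-exonic transcript is an error by design — the
cascade is defined on intron chains, and stage 1 has already removed
unspliced models.

## Stage 3 — consolidation

Two isoforms at the same locus are merged when they are *comparable*:

* equal exon counts;
* at most `max_exonic_variations = 3` exons whose boundaries differ;
* per exon, the summed shift of its *internal* boundaries is at most
  `max_bp_per_exon = 4` bp — terminal boundaries (the TSS side of the first
  exon and the TTS side of the last) are excluded from this cap and governed
  instead by the end criterion;
* TSS and TTS each differ by at most `max_end_dissimilarity = 100` bp;
* when both isoforms are coding, their genomic ORF coordinates are identical
  (`require_identical_orf = TRUE`); a coding/non-coding pair is never merged.

The 4-bp cap absorbs alignment wobble at splice sites while 100 bp at the
ends absorbs soft-clipped termini; identical-ORF protects protein-level
distinctions from being collapsed. A `per_boundary = TRUE` switch applies
the 4-bp cap to each boundary separately instead of summed per exon, for
users who prefer the stricter reading.

Comparability is reflexive and symmetric but **not transitive**, so the
clustering rule matters: candidates are sorted by a total order (length
descending, then start ascending, then id lexicographic) and each unmerged
transcript in turn absorbs every remaining transcript comparable to it. The
longest isoform becomes the representative and inherits the union of source
samples. The total order makes the greedy result independent of input order,
which the tests verify by permutation.

## Stage 4 — functional annotation

* **ORF**: longest open reading frame of at least `min_orf_len_nt = 300` nt
  (100 codons) across the three forward frames of the spliced sequence;
  ties go to the 5′-most start. 300 nt is the conventional floor below
  which random ORFs become frequent.
* **NMD**: a coding transcript is NMD-sensitive when its stop codon lies
  *strictly* more than 50 nt upstream of the last exon–exon junction
  (`distance > 50`, the classical 50-nt rule; a stop exactly 50 nt upstream
  is not flagged).
* **TSS/TTS features**: the transcript start (or end, strand-aware) is
  tested against transposable-element, CAGE and polyA annotation tracks in a
  closed ±`window = 100` bp window, the usual promoter-assignment tolerance
  for CAGE clusters; the same window is reused for all three tracks for
  want of a track-specific calibration.
* **polyA motif**: the 3′-terminal 50 nt are scanned for `AATAAA`/`ATTAAA`;
  the 3′-most hit wins, matching the positional bias of the signal.

## Stage 5 — specifically-expressed transcripts

Expression fractions `p_i = x_i / Σ x_i` over `N` tissues give the
specificity score `S = log2(N) − H(p)` with `H` the Shannon entropy in bits;
`S` ranges from 0 (uniform) to `log2(N)` (single-tissue). A **tissue-SRT**
requires the top tissue fraction to be at least `min_ratio_fold = 2` times
the runner-up and `S ≥ min_score = 1`.

A **tumor-SRT** call for one cancer type requires:

* **A**: median TPM across that type's tumor samples at least
  `fold = 10`× the maximum over normal tissues, where each normal tissue is
  first summarized by its median (`aggregate_normals = TRUE`) so one outlier
  sample in one tissue does not dominate; when the normal maximum is 0 the
  criterion reduces to a positive tumor median. Testis is excluded from the
  normal panel by default (`excluded_normals = "testis"`) because of its
  permissive transcription.
* **B**: TPM above `tpm_min = 0.5` in strictly more than
  `frac_expressed = 5%` of that type's tumor samples, guarding against calls
  driven by a single sample.

Adjacent-normal samples are pooled into the normal side of criterion A.

## The synthetic-fixture generator

`simulate_fixture()` builds, from a single seed, a small genome, a reference
annotation, a query transcript set with **planted truth labels**, STAR-style
junction tables and a TPM matrix. Truth holds *by construction*, not by
running the classifier: an FSM plant copies a reference chain and jitters
the ends (≤ 20 bp); an ISM plant drops the first exon; a NIC plant skips an
internal exon (known sites, novel junction); an NNC plant shifts one
boundary by 10 bp (novel site); antisense plants a two-exon model on the
opposite strand inside a gene span; intergenic uses a reserved empty region.
Chain-derived plants are placed in distinct genes so their intron sets are
disjoint, which makes the planted junction-support partition provable:
supported transcripts receive their junctions in at least `min_samples`
samples, unsupported in fewer. Planted tumor-SRTs are absent from all normal
tissues and expressed at `fold × 0.5` TPM in one cancer type; planted
tissue-SRTs are enriched 4× in a single tissue. Background expression is
log-normal (`noise_sdlog = 0.5`) around 5 TPM with 5% dropout.

What the generator does **not** emulate: read-level errors and alignment,
multiple annotated isoforms per gene, overlapping genes on the same strand,
fusion transcripts, batch effects or library-size variation in expression,
and intron retention. It is a correctness instrument for the curation logic,
not a sequencing simulator. Problem sizes (12 genes, 8 short-read samples,
2 cancer types × 30 tumors, 22 normal tissues × 5 samples) are this
package's own choice: large enough to exercise every code path and the 5%
fraction threshold, small enough that the full test suite runs in about a
minute.

## Numerical and design choices

* All thresholds are inclusive or strict exactly as stated above
  (≥ 5 samples, > 50 nt NMD, ≥ 10× fold, > 5% of samples, > 0.5 TPM);
  the tests pin each boundary from both sides.
* The pipeline contains no random number generation; given identical inputs
  it writes byte-identical outputs. The generator draws all randomness from
  the seed in `fixture_spec()` and restores the RNG state afterwards.
* GTF and BED parsing, FASTA access and interval overlap use Bioconductor
  infrastructure (`rtracklayer`, `Biostrings`, `GenomicRanges`); GTF
  *writing* is plain formatted text so the attribute layout is under the
  package's control and round-trips exactly.
* Junction evidence is aggregated by junction key across samples once, then
  queried per transcript — sample identity matters only through the count
  of supporting samples.

## Limitations

Classification depends entirely on the supplied reference; an incomplete
annotation inflates NIC/NNC. The ISM rule removes genuine short isoforms
whose chains happen to be sub-chains of a longer reference chain. The
tumor-SRT criterion compares medians and is insensitive to bimodal
expression within a tumor type. Specificity scores are computed on relative
fractions and therefore inherit any compositional bias of TPM
normalization. The entire package is single-threaded; very large catalogs
(millions of models) would need chunked classification.
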
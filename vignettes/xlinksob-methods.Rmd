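---
title: "Methods: crosslink-site scoring and interactome statistics in xlinksob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crosslink-site scoring and interactome statistics in xlinksob}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinksob)
```

# Scope

xlinksob implements the computational spine of an iCLIP study of an
RNA-binding protein and its companion proteomics and phenotype
statistics. This vignette is the package's own account of the models it
implements, the parameters that matter, the places where the design was
genuinely open and what we chose, and what the passing test suite does
and does not demonstrate about real data.

# The iCLIP read model

iCLIP libraries are sequenced as 75-nt single-end reads whose first nine
nucleotides are a composite barcode: positions 4–7 carry the 4-nt
experimental (sample) barcode, positions 1–3 and 8–9 the 5-nt random
barcode (UMI) identifying the original cDNA molecule. Reverse
transcription truncates at the protein-crosslinked nucleotide, so the
biological insert starts one nucleotide downstream — in transcript
orientation — of the crosslink. Consequently, after alignment, the
crosslinked nucleotide is recovered as the position immediately upstream
of the read's 5' mapping position: `start − 1` on the plus strand and,
mirroring the rule in genome coordinates, the position one base 3'-ward
of the rightmost aligned base (`end` in 0-based half-open coordinates) on
the minus strand. We document this minus-strand convention prominently
because an off-by-one here silently shifts every site; the test suite
pins it by simulating minus-strand genes and demanding exact positional
recovery.

## Preprocessing rules

* **Barcode quality.** A read is dropped when more than one
  experimental-barcode position scores below Phred 20, or any
  random-barcode position scores below Phred 17. Decisions are verified
  against an exhaustive oracle over all 2^9 pass/fail patterns of the
  nine prefix positions.
* **Demultiplexing** requires an exact match of positions 4–7 to a sample
  barcode; `N` counts as a mismatch. The published scheme tolerates one
  low-quality experimental-barcode base at QC but zero mismatches at
  assignment, so a genuinely miscalled base leaves a read unassigned;
  that interaction is inherent to the scheme and left as-is.
* **Adapter trimming** removes the longest 3'-terminal read suffix
  matching a prefix of the adapter with mismatch fraction ≤ 0.1 at
  overlap ≥ 1 nt. The search is anchored at the read end, because these
  libraries read into the 3' adapter; internal occurrences are not
  searched. With 1-nt minimum overlap, a read whose last base happens to
  equal the adapter's first base loses it — that is the documented
  contract, not a bug, and the brute-force suffix oracle in the tests
  enforces exactly this behaviour.
* **Length filter.** "Shorter than 15 nt" is read strictly: 14-nt inserts
  are dropped, 15-nt inserts kept. The rule is applied to the
  barcode-free insert, since mapping operates on inserts.

## Alignment and duplicate collapsing

The built-in aligner is an ungapped Hamming scan of both strands allowing
at most two mismatches; a read is unique iff exactly one hit attains the
minimal mismatch count. It is deliberately minimal — a desk-scale
stand-in for a splice-aware aligner, sufficient for synthetic references
— and external SAM/BAM can be ingested instead (`read_sam()`), where
spliced means a CIGAR `N` operation and uniqueness evidence is the `NH`
tag or a mapping-quality threshold. Only unique, unspliced alignments
proceed.

Duplicates are reads whose 5' ends map to the same genomic position.
Among duplicates sharing a random barcode exactly one read is kept
(technical duplicates); differing barcodes are kept as biological
duplicates. Two choices were open:

* **Strand** is part of the duplicate key. Collapsing opposite-strand
  reads at the same coordinate would conflate independent molecules.
* **Tie-break** within a class keeps the lexicographically smallest read
  name, making the output independent of input order (tested by
  shuffling).

With a 5-nt barcode (1024 states) and desk-scale molecule counts,
barcode collisions at a position are rare; the tests quantify recovery
exactly against the simulator's molecule table rather than assuming
collision-freeness.

# Signal-over-background (SOB)

For each gene, the background density is the sum of crosslink events
inside the gene's *effective* exonic extent but outside every binding
site extended by 5 nt to either side, divided by the merged exon length
(events per nucleotide). The flank exclusion applies only to the
numerator; the denominator remains the merged exonic length. A site's SOB
is its event count divided by that density, so SOB has units of
nucleotides.

* **Width normalisation.** Whether the site signal should additionally be
  divided by site width is not recoverable from the verbal definition;
  both variants are implemented (`per_width` switch) and the default
  reports count over density, because the definition contrasts a site
  *sum* with a background *density*.
* **3'UTR truncation.** The 3'UTR contributes only up to 10 nt past the
  3'-most site overlapping it, or 500 nt from the UTR start when no site
  does; truncation never extends an annotation. On the minus strand the
  rule mirrors at the transcript 3' end (the left genomic end).
* **Exclusions.** Ribosomal genes (an annotation flag) and genes with
  fewer than 10 background events receive no SOB. The threshold is
  applied per replicate; a site's mean uses only replicates whose gene
  passed, because replicate-level granularity is the only way to keep
  each replicate's score self-contained.
* **Averaging** across replicates is arithmetic (the natural reading of
  "averaged"), over defined replicates only.
* **Degenerate inputs.** A gene with zero merged effective length is a
  hard error; background ≥ 10 events guarantees a positive density, so a
  defined SOB never divides by zero.

Correctness is established two ways: equality with a brute-force oracle
that enumerates every exonic nucleotide on small instances, and scale
invariance (multiplying all counts by *k* cancels between numerator and
density).

The plumbing peak caller (`call_sites()`: maximal runs of positions with
count ≥ threshold, merged across gaps ≤ `merge_gap`) exists so the
pipeline is runnable end to end; real analyses may substitute any site
catalogue as a BED-like tibble.

# Dimer profiles

Sites restricted to 3'UTRs are centred at their midpoint — for
even-width sites the lower-median position, a ≤ 1 nt convention — and a
±100 nt window is read on the gene's sense strand. For each offset the
profile reports the mean occurrence of each homopolymeric dinucleotide
(AA, CC, GG, TT). Windows clipped at contig ends are dropped with a
warning. Over the full 16-dinucleotide alphabet the positional means sum
to one (a sanity extension used in tests); on i.i.d. uniform sequence
each dinucleotide's mean occurrence is 1/16, checked within binomial
error.

# Interactome statistics

The analysis starts from a protein-groups LFQ table (peptide
identification itself is out of scope).

1. **Filtering.** Contaminant, reverse and only-by-site rows are removed.
   The peptide rule is implemented as *peptides ≥ 2 and unique ≥ 1*: the
   literal both-fail reading of the published wording would retain
   single-peptide groups, contradicting standard protein-group filtering
   practice; the literal variant remains available (`literal = TRUE`).
2. **Log2 transform.** Log base 2 throughout; the significance threshold
   is stated in log2 units.
3. **Imputation.** Missing values become `m · u` with `m` the lowest
   measured log2 value in the table and `u ~ Beta(1, 1)` rescaled to
   [0.001, 0.015]. The interval (0.1%–1.5% of the lowest measured value)
   is the specified contract; the Beta shape is not, so the uniform
   member of the family is the default and both shape and per-column
   operation are configurable. The order of operations — transform, then
   impute — places the bounds on the log scale, and the minimum is global
   across the matrix by default. The resulting imputed values sit far
   below the measured range: this encodes left censoring (absent in one
   condition ⇒ enormous fold change with tiny within-group variance) and
   is exactly why partial dropout of a well-measured protein is harmful —
   see the generator notes below.
4. **Presence filter.** Rows need measured values in at least two
   replicates of at least one condition, evaluated on the original
   missingness mask even when run after imputation; otherwise imputation
   would defeat the filter.
5. **Moderated test.** Per-row pooled variances `s²` on `d` residual df
   are shrunk toward a prior `s0²` with prior df `d0`, both estimated by
   moment matching on `log s²` (the digamma/trigamma equations inverted
   by Newton iteration; `trigamma_inverse` guards the extreme regimes
   `y > 1e7` and `y < 1e-6` with asymptotic starts and converges to
   relative tolerance 1e-8). The statistic `Δmean / (s_post √(1/n1+1/n2))`
   with `s_post² = (d0 s0² + d s²)/(d0 + d)` is referred to a
   t-distribution on `d0 + d` df; `d0 = 0` recovers the ordinary pooled
   t-test and `d0 = ∞` the `s0`-scaled statistic, and both limits are
   exposed (`prior_df =`) and tested. When the observed log-variance
   spread is no larger than its sampling noise the moment equation has no
   positive solution and `d0 = ∞` is returned. Rows with zero residual
   variance are excluded with a warning. p-values are two-sided and
   BH-adjusted; BH is `stats::p.adjust`, checked against a brute-force
   implementation of the definition.
6. **Classification.** Significant ⇔ FDR ≤ 0.05 and log2FC ≥ 2 in the
   bait-over-control direction. Only two-condition comparisons are
   supported.

An independent cross-check in the test suite fits the same matrices with
limma (`lmFit` + `eBayes`) and requires agreement of prior df, prior
variance, t and p to 1e-6 — limma is never the implementation.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline targets, fixed once:

* multiplexed 75-nt single-end reads, 9-nt composite barcode, six bait
  replicates and one control in the default barcode map;
* crosslink events Poisson-distributed at `signal_rate = 1` per site
  nucleotide inside planted sites and `background_rate = 0.1` per exonic
  nucleotide elsewhere — the tenfold signal:background regime the
  site-ranking checks are calibrated to;
* PCR copies = 1 + Poisson(`duplication_rate`), so rate 0 means no
  amplification and reads equal molecules;
* cDNA insert lengths uniform on 20–40 nt (RNase-digested iCLIP inserts),
  exons 350–600 nt, introns 60–150 nt, 300-nt 3'UTRs, 150-nt contig
  padding so ±100 nt profile windows rarely clip;
* base qualities from a two-state model (Phred 38, or Phred 10–19 with
  per-position probability `corruption_prob`) — the simplest model that
  can trip both barcode-QC rules independently;
* LFQ matrices with 3 replicates × 2 conditions, 500 protein groups, 25
  enriched at true log2FC 3, baseline log2 abundances ~ N(25, 2) (the
  typical MaxQuant LFQ intensity range), replicate noise SD 0.3, and
  missing-not-at-random dropout `P(missing) = plogis((21 − x)/0.5)` — a
  sharp detection limit two baseline SDs below typical abundance, so
  censoring concentrates in the left tail (~5–7% of cells overall). A
  diffuse dropout curve reaching well-quantified mid-range proteins
  would censor single replicates whose near-zero imputation wrecks the
  within-group variance; that regime contradicts the left-censoring
  assumption the imputation encodes, so it is not the default. Rows
  planted to fail the peptide-evidence filter are drawn from the
  non-enriched background only, keeping the enrichment flags a clean
  recovery target.

One RNG stream per generator call, seeded from the config; identical
configs give byte-identical FASTQ and tables.

**What the simulator does not emulate** — and hence what green tests do
not show about real data: sequencing substitution errors in the insert,
spliced reads (the pipeline discards them anyway), non-uniform base
composition and mappability structure of real genomes, crosslinking
sequence bias, readthrough or deletion events at the crosslink site,
peptide-level effects in proteomics (shared peptides, match between
runs), and correlated replicate structure. Exact-recovery results are
statements about the pipeline's bookkeeping, not about biological
sensitivity on real libraries.

# Problem sizes and numerics

The test suite runs 3-gene simulations for exact-recovery and oracle
checks, a 40-gene single-sample simulation for the site-ranking property,
120 random sites on a 30-kb uniform contig for the dimer expectation, and
200-row 3-vs-3 matrices for the null-calibration check; the acceptance
script uses an 8-gene two-sample library with 2% quality corruption plus
the same 40-gene and 500-protein designs. These sizes make every check a
few seconds while keeping the Monte-Carlo bands meaningful (binomial
3–5 SE). Exact comparisons use equality; floating-point comparisons use
1e-10…1e-12 except the limma cross-check at 1e-6. Printed percentages
round half away from zero (`round_half_up()`), matching how such tables
are typeset; base R's round-half-even would print 0.05 as 0 at one
decimal.

# Known limitations

* The naive aligner is ungapped and exhaustive: fine for kilobase
  synthetic contigs, unusable for real genomes — ingest external
  alignments instead.
* Binding-site discovery is a threshold/merge heuristic, not a peak
  model; SOB scoring accepts any site catalogue.
* The moderated test covers two-condition designs with equal per-row
  df; no trend prior, no multi-factor designs.
* The one-sample fold-enrichment tests apply no multiplicity correction
  by default (a correction flag exists), reflecting how such per-transcript
  panels are usually reported.
* SOB values depend on the supplied site catalogue through both the
  numerator and the background exclusion; comparing SOB across different
  catalogues mixes those effects.
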
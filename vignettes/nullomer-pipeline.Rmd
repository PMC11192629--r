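---
title: "Nullomer emergence and cfRNA classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nullomer emergence and cfRNA classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullorna)
```

## The problem

Nullomers are the shortest DNA sequences absent from a genome. For a
k-mer length k, the universe of possible sequences has size 4^k; a
genome of length L covers at most 2(L - k + 1) of them (both strands),
so once 4^k outgrows the genome, absent k-mers necessarily exist. Two
facts make them useful in oncology. First, a somatic mutation edits the
tumor genome and can create sequences the reference genome never
contained — *nullomer emergence*. Second, tumor-derived nucleic acids
circulate in peripheral blood, so reads from a liquid biopsy can be
screened for a panel of known emerging nullomers: any match is, by
construction, a sequence that cannot have come from the unmutated
genome. `nullorna` implements this whole chain — absence indexing,
per-mutation emergence, cohort aggregation, read screening, and a
penalized classifier over the resulting count matrix — together with
synthetic-data generators that make every stage testable without
controlled-access data.

## The absence index

The index is a flat bit-array over all 4^k codes (A=0, C=1, G=2, T=3,
base 4, leftmost base most significant). Design choices:

* **Both strands.** A k-mer is "present" if it or its reverse
  complement occurs in any contig. DNA is double-stranded and read
  orientation is arbitrary, so absence is only meaningful
  strand-symmetrically; it also makes the nullomer set closed under
  reverse complement, which in turn makes the *canonical form* (the
  lexicographically smaller of a k-mer and its reverse complement) a
  well-defined deduplication key for everything downstream.
* **Ambiguous bases.** Windows containing any non-ACGT character are
  skipped, never enumerated over IUPAC expansions; this is the standard
  k-mer-counting convention. Soft-masked lowercase is uppercased:
  repeat masking has no bearing on absence.
* **Bounds.** k is capped at 16 (4^16 bits = 512 MiB, and codes stay
  well inside exact double precision); tests and examples use k = 4-10,
  where the index is at most 128 KiB. No succinct data structures: O(1)
  bit lookup and a trivially portable serialization (header + raw
  little-endian bit-array) are worth more here than compression.

Two invariants are enforced by property tests: `n_present +
nullomer_count == 4^k`, and presence equals the brute-force substring
set of genome plus reverse complement on random genomes.

## Emergence from somatic mutations

For a variant (MAF conventions: 1-based inclusive positions, `-` for
the empty allele) the package rebuilds the local mutated sequence with
up to k-1 bp of reference flank on each side of the edit, enumerates
its k-mer windows, and keeps those whose presence bit is unset. k-1
flanks suffice: a k-mer that does not overlap the edit is a reference
substring and can never be novel. The converse filtering is done purely
by index membership, which provably subsumes "overlaps the edit" — a
property pinned by a test that widens the flanks and checks the result
is unchanged. Emerged k-mers are reported in canonical form and
deduplicated per variant; per-patient tallies count distinct canonical
nullomers, so strand choice and repeated creation never inflate counts.

One consequence worth naming because it mirrors a structural feature of
the data: a single-base deletion inside a homopolymer run of reference
length >= k cannot emerge anything — every window of the shortened run
is still a window of the original run. The suite asserts zero emergence
across 1,000 such deletions. Since mononucleotide-repeat slippage is a
very common indel class, emergence is structurally biased against this
mutational mode.

Variants are processed independently against the unmutated reference
(no phasing of co-occurring mutations in a sample), and germline
subtraction is assumed to have happened upstream in the caller.

## Mutational channels

SNPs are labelled with the standard 96-channel trinucleotide scheme:
six pyrimidine-strand substitution types times sixteen flank contexts,
e.g. `A[C>T]G`; purine-reference variants are reverse-complemented
first, making the labelling strand-symmetric. Indels use the 83-channel
scheme: 1 bp events typed by the affected base (C or T after
pyrimidine-strand normalization) and homopolymer context, longer events
by size (2, 3, 4, 5+) and tandem-repeat copy number, and
non-repeat deletions by junction microhomology depth. Numbering
follows homopolymer run length 1-6+ for 1 bp deletions and adjacent
identical-base count 0-5+ for 1 bp insertions; both classifier
universes are enumerated exhaustively in tests (96 and 83 labels
exactly). The 28-channel indel taxonomy and doublet-substitution
channels are not implemented; multi-nucleotide substitutions still go
through the generic emergence window but receive no channel label.

## Cohort statistics

Aggregations are deliberately plain: emergence proportion per cancer
type; Pearson correlation (t-transform p) between per-patient mutation
and distinct-nullomer counts; a recurrence table ranked by
distinct-patient count with lexicographic tie-breaks (deterministic
under input shuffling); the top-n recurrent nullomers as a screening
panel (default n = 100,000); cancer-type-specific nullomers defined
strictly as "emerged in at least one patient of the type and in no
patient of any other type"; gene ranking by emerging mutations per
coding bp (lengths supplied by the user as a two-column table — no gene
model downloads); and VAF stratified by emergence status, compared with
a two-sided Mann-Whitney test. The rank test is used because VAFs are
bounded and skewed; recurrence fractions use the full cohort as
denominator.

## cfRNA screening and classification

`scan_reads` counts, for each panel nullomer, all (possibly
overlapping) window matches across reads, on both strands — library
strandedness in cfRNA protocols is not guaranteed. A palindromic panel
sequence is counted once per window. Windows containing N never match.
Upstream read hygiene (trimming, contaminant removal, deduplication,
alignment) is an explicit non-goal: the scanner takes clean reads.

The classification pipeline is fixed, in this order:

1. `zero_low_counts`: entries <= 2 are set to 0 (guards against
   spurious isolated matches);
2. `filter_low_sum`: features with column sum < 10 are dropped;
3. `cpm_normalize`: each sample row is scaled to one million (per-sample
   totals over the retained features, the edgeR convention);
4. `tune_and_cv`: an L1-regularized logistic model tuned over 20
   penalty values evenly spaced on (0, 1] (0.05 to 1.0 — a zero
   penalty is degenerate), with stratified 10-fold cross-validation
   repeated 100 times under a seeded fold stream. The best penalty
   maximizes mean out-of-fold ROC AUC across repeats, with ties going
   to the larger (sparser) penalty.

Out-of-fold probabilities at the best penalty are pooled across repeats
for the ROC and precision-recall AUCs and the Brier score (mean squared
probability error). Calibration is summarized by the slope and
intercept of a logistic regression of outcomes on the logit of the
predictions; when the slope departs from 1 by more than 0.2 —
a deterministic surrogate for judging a sigmoid-shaped reliability
curve by eye — the probabilities are recalibrated by Platt scaling
(maximum-likelihood sigmoid of the logit score), a monotone transform
that leaves discrimination untouched. Probabilities are clipped to
[1e-6, 1 - 1e-6] before any logit. Feature stability refits the lasso
at the chosen penalty on each of the folds x repeats training
partitions (a separate seed stream from tuning) and calls a feature
stable when its coefficient is non-zero in more than 90% of fits. No
class reweighting is applied anywhere.

## What the synthetic data emulates — and what it does not

`generate_genome` draws i.i.d. bases at a target GC (default 0.41, the
approximate human genome-wide value). `generate_cohort` emulates a
multi-cancer-type WES cohort: per-patient Poisson mutation counts at a
per-type mean, a substitution/insertion/deletion simplex (default
0.9/0.05/0.05, roughly the exome ratio), indels of 1-3 bp, read depths
of 30-200x with Beta-distributed allele fractions, and an optional
hypermutator multiplying one patient's mean. `simulate_reads` draws
fixed-length reads uniformly from the genome and embeds a panel
nullomer per read with a group-specific probability (defaults: 30
cases at 0.1 against 30 controls at 0.01 — the 10x case-to-control
ratio the classifier experiments assume); rejection sampling
guarantees a spiked read contains its embedded nullomer exactly once
and no other panel member, so at zero error rate a scan reproduces the
returned truth table exactly. Base-call errors, when enabled, never
touch the embedded span.

Real data differ in ways these generators deliberately ignore: i.i.d.
bases have no repeat structure, so toy genomes have *more* distinct
k-mers (fewer nullomers) than an equally long genomic region;
mutational signatures, transcript abundance structure, fragment-length
biases and quality-dependent errors are all absent. Passing tests
therefore demonstrate correctness of the computations, monotonicities
and recovery under controlled signal — not clinical performance.

A normalization subtlety found while designing the classifier tests is
worth recording. With a small all-informative panel, CPM is
compositionally degenerate: every nonzero row rescales to the same
total, so a control whose few surviving counts sit on one feature and a
case spread over all features can receive identical linear scores.
Real matrices do not behave this way because the screened panel is
large and tumor signal is a small fraction of each library. The
classifier tests therefore compose two read simulations per sample: a
background sub-panel spiked equally in cases and controls (the cfRNA
noise floor) plus a tumor-derived sub-panel at the 10x case rate. Under
those conditions the pooled out-of-fold ROC AUC reaches 1, the Brier
score after recalibration is near 0, and the stability rule selects
only truly informative nullomers.

## Numerical and scale choices

Problem sizes were chosen so the full suite runs in minutes on one
core: toy genomes of 6-10 kb with k = 6-10 for emergence and
classification (the same code paths handle k up to 16 and arbitrary
FASTA sizes), 50 random genomes up to 5 kb for brute-force oracle
comparisons, 1,000 deletions for the homopolymer property, and 10x10
repeated cross-validation (instead of the full 100 repeats, which the
configuration exposes) for classifier end-to-end checks. Determinism
is end-to-end: every stochastic step takes an explicit seed, generators
restore the caller's RNG state, and repeated runs produce identical
reports byte for byte.

Known limitations: no haplotype-aware emergence for nearby co-occurring
variants; no BAM/VCF ingestion (MAF-style TSV and FASTQ cover the
supported workflow); single-genome runs only, so reconciling panels
across reference assemblies is left to the user; and the permutation
null for the classifier is estimated from a handful of label
permutations, which at n = 60 still fluctuates a few points around 0.5.
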
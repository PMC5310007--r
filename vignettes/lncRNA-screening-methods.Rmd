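---
title: "Methods: lncRNA screening, classification and target analysis"
author: "caprilnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA screening, classification and target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`caprilnc` implements the downstream half of a strand-specific bulk
RNA-seq lncRNA study: it starts from *assembled transcript models*
(read QC, alignment and assembly are out of scope) and carries them
through candidate screening, positional classification, two-group
differential expression, cis/trans target prediction, functional
enrichment and qPCR validation.

The central containers follow Bioconductor conventions:

* `TranscriptSet` — exon structures as a `GRangesList` plus per
  transcript gene ids and optional spliced sequences
  (`DNAStringSet`).
* `GeneAnnotation` — reference gene spans, biotypes and per-gene exon
  unions.
* `ExpressionData` — a `SummarizedExperiment` with integer counts, a
  two-level group factor (first level = control/calibrator), per-row
  transcript lengths and the derived FPKM assay.

Coordinates are 1-based inclusive throughout, the GRanges norm.  All
interval work (widths, gap distances, overlaps) is done with
GenomicRanges/IRanges machinery, and GTF needs no coordinate
conversion on IO.  Gap distance between two spans is the number of
bases strictly between them: abutting or overlapping spans have
distance 0.

# Screening model

lncRNAs are transcripts **greater than 200 nt** with no evident
protein-coding capacity.  `basicFilter()` first removes transcripts
failing the structural/expression rules:

| parameter | default | meaning |
|---|---|---|
| `minLength` | 200 bp | spliced length must be strictly greater |
| `minExons`  | 1      | minimum exon count (inclusive) |
| `minFpkm`   | 0.5    | required in at least one sample |

`minExons` defaults to 1 rather than the stricter lincRNA practice of
2: assembled single-exon lincRNAs are genuine and frequent (the
shifted-Poisson exon model with mean ≈ 2.8 puts ~15% of lincRNAs at
one exon), so an exon-2 default would silently discard a sizeable
fraction of true loci.  The stricter filter remains one argument
away.  Neither the expression cutoff nor the exon rule has a
canonical published value; both are deliberately configuration, not
constants.

Three scorers then emulate the roles of an ORF-based coding-potential
calculator, a nucleotide-composition classifier and a protein-family
scan:

1. **ORF extent** (`orfCodingScore`).  `findOrfs()` enumerates every
   ATG→stop ORF in the three forward frames (the libraries are
   strand-specific, so transcripts are oriented; the reverse frames
   are not scanned).  ORFs require a terminal stop codon; an ATG run
   hitting the transcript end is reported as `incomplete` and never
   chosen as the longest ORF — a conservative, testable convention.
   The call is `coding` iff the longest complete ORF reaches 300 nt
   or covers ≥ 0.5 of the transcript (both inclusive).
2. **Adjoining triplets** (`tripletCodingScore`).  The score is the
   mean log-ratio of hexamer (codon-pair) frequencies under a coding
   versus a noncoding model, maximised over the three frames;
   positive means coding.  The shipped tables derive from the
   package's biased codon-usage constant against a uniform
   background; both tables are arguments, so empirically trained
   tables can be dropped in.
3. **Motif scan** (`motifScan`).  Translations are *per-ORF
   segments*; a motif whose peptide would span a stop codon never
   matches.  The shipped library is a small stand-in; result tables
   from a real protein-family scan can be supplied instead, and
   `screenTranscripts(externalCalls =)` accepts full external
   verdicts from dedicated coding-potential tools.

The consensus is an intersection: a transcript predicted coding by
*any* scorer is filtered out; candidates are those all three call
noncoding.  This is monotone by construction — flipping any verdict
to coding can only shrink the candidate set.

The scorer thresholds are stand-ins for the internals of external
coding-potential tools, which are not published as formulas; they are
all configuration keys.

# Biotype cascade

Classification against protein-coding genes proceeds in a fixed
order: antisense (≥ 1 bp exon–exon overlap, opposite strand), then
intronic (span entirely within one intron of a same-strand gene, zero
exonic overlap), then lincRNA (no span overlap with any coding gene
on either strand).  Antisense is tested first because exonic
opposite-strand overlap is the stronger, more specific signal when a
locus also lies inside an intron.  Overlap is tested at exon level
for antisense but span level for the lincRNA exclusion, mirroring
what the class names mean.  Transcripts matching no rule (e.g.
same-strand exonic overlap) are labelled `ambiguous`, excluded, and
counted — classification is a partition, never a double label.

# Expression model

FPKM is `1e9 * count / (librarySize * length)` with library size the
column sum of counts, so FPKM is zero exactly where the count is
zero.

`nbTest()` is a deliberately transparent stand-in for the
negative-binomial machinery of full DE frameworks: per-transcript
method-of-moments dispersions (pooled within-group variance of
size-factor-normalised counts) are smoothed against the log mean by
robust loess, and every transcript is tested with its trend value —
maximal shrinkage, which is what n = 3 per group supports.  The Wald
statistic compares log group means with the delta-method standard
error under variance μ + αμ² (a 0.5-count offset guards the
logarithms), against the normal reference.  The choice of the normal
rather than a t reference is an empirical calibration decision: on
2000-transcript null simulations at the study's dispersion the
rejection rate at p < 0.05 sits at 0.047–0.061 with near-uniform
p-values (KS 0.015–0.042), whereas a t(4) reference is markedly
conservative.

Significance thresholds on the **raw** p-value (0.05 by default),
with BH q-values reported alongside: published analyses of this
design threshold on P, and whether their correction entered the
threshold is ambiguous, so the package reports both and lets the
caller choose.  log₂ fold changes use group-mean FPKM with a
pseudocount of 1 FPKM; `direction` is "up" when expression is higher
in the case (second-level) group.  All-zero rows are flagged
untestable with p = 1 and log₂FC = 0.  The test is antisymmetric
under label swap (log₂FC negates, p unchanged).

"Group-specific" expression has no canonical definition; the package
uses presence ≥ 1.0 FPKM in every on-group sample and ≤ 0.1 FPKM in
every off-group sample, both exposed.

# Target prediction

*Cis*: for each lncRNA, protein-coding genes whose span lies within
10 kb / 100 kb of the lncRNA span, either side, strand-agnostic.
Distance is span-gap (not TSS-to-TSS) and window boundaries are
inclusive — the simplest defensible convention, declared and tested
(a gene at exactly 10,000 bp is a 10 kb-window pair).  Each pair is
labelled with the smallest qualifying window.

*Trans*: Pearson correlation of FPKM rows across all samples pooled
over groups, keeping |r| strictly greater than 0.95.  Zero-variance
rows are skipped and counted.  With six samples this threshold
carries a heavy multiple-testing burden; the package reports pair
counts and leaves any correction to the caller rather than silently
adjusting.

# Enrichment

The enrichment engine is the hypergeometric upper tail
(`fisherOneSided`) and its EASE variant, `ease(k) = fisher(max(k−1,
0))`, which makes single-gene overlaps never significant and is
uniformly conservative.  The background defaults to all annotated
protein-coding genes of the run — not a genome-wide unknown — and is
an argument.  BH q-values are computed over tested terms (k ≥ 1;
empty terms skipped).  No term-hierarchy propagation and no
length-bias correction are attempted; this single engine stands in
for the mixture of enrichment services typically used in published
pipelines, and that substitution is intentional and documented.

# qPCR

`ddctFoldChange()` averages technical replicates per biological
sample, normalises target Ct to the reference gene (β-actin by
default), references the calibrator-group mean, and exponentiates:
fold = 2^−ΔΔCt.  The quantity is invariant to per-sample global Ct
shifts, and the calibrator group's log-scale mean fold is 1 by
construction.  The group test is an equal-variance two-sided t-test
computed on ΔCt — approximately normal, the standard choice; testing
on the fold scale is available via `qpcrAnalysis(testOn = "fold")`.
Stars follow the `*` p < 0.05, `**` p < 0.01 convention.  When both
groups have zero variance the test degenerates to p = 1 (equal
means) or p = 0.  No amplification-efficiency correction is applied.

# The synthetic-study generator

`synthConfig()` fixes the study conditions; its defaults emulate a
goat hypothalamus assembly at desk scale:

| parameter | default | emulates |
|---|---|---|
| lncRNA mean length | 1180 nt | observed lncRNA length scale |
| mRNA mean length | 2869 nt | observed mRNA length scale |
| lncRNA longest-ORF mean | 105 nt | short incidental ORFs |
| exon means (lnc / mRNA) | 2.8 / 9 | fewer exons in lncRNAs |
| class fractions | 0.8 / 0.1 / 0.1 | lincRNA / antisense / intronic balance |
| design | 3 vs 3 | prepubertal vs pubertal groups |
| dispersion α | 0.1 | NB biological noise |
| planted DE | 10% at &#124;log₂FC&#124; = 2 | detectable group effects |
| cis offsets | 0 / 5 / 50 kb | neighbours inside both windows |
| trans pairs | 20 at r = 0.99 | strong coexpression |
| group-specific | 10 per group | on/off lncRNAs |
| library sizes | 10⁶ per sample | human-checkable FPKM |

Lengths are log-normal with the configured means, exon counts shifted
Poisson (`1 + Pois(mean − 1)`), and loci are laid out
non-overlapping with antisense/intronic lncRNAs anchored to host
genes and planted cis lincRNAs placed at exact gap distances.  The
seed fully determines every output.

Two generator behaviours are worth knowing:

* **lncRNA ORF suppression.**  A uniform random sequence of ~1.2 kb
  has an expected longest ORF of roughly 180–300 nt — longer than
  real lncRNA ORF statistics.  The generator therefore plants one ORF
  of target length (log-normal around the 105 nt mean) and injects
  in-frame stop codons into any longer incidental ORF, so the
  realised longest-ORF distribution matches the configured mean.
* **Trans-pair planting.**  Per-sample expected FPKMs of a planted
  pair are built with *exact in-sample* Pearson correlation r
  (Gram–Schmidt on latent profiles, then a positive affine map, which
  preserves r).  Pairs are highly expressed (~10⁴ expected counts) so
  Poisson shot noise cannot attenuate the correlation below the call
  threshold, and successive pairs carry antithetic latent profiles so
  their contributions to the per-sample library sums cancel — FPKM
  divides by realised column totals, and without this cancellation
  the planted loci would perturb their own normalisation.

What the generator does **not** emulate: positional read coverage or
assembly artefacts, isoform structure (one transcript per locus),
GC/mappability biases, realistic codon usage (the coding model is a
deliberately strong synthetic bias), overlapping genes, or a genuine
GO/KEGG hierarchy.  Passing the recovery tests therefore demonstrates
the *correctness of the algorithms under their stated model*, not
performance on real goat data — on real data the scorers should be
replaced by the external tools they stand in for, via the
`externalCalls` hook.

# Numerical and design choices

* Sequence generation, counts, term map and Ct tables consume
  dedicated seed offsets, so each artefact is reproducible in
  isolation; identical configurations produce byte-identical output
  tables (`runPipeline` writes and the test suite hashes them).
* Dispersion trend: loess span 0.5, degree 1, direct surface,
  evaluated at each transcript's mean, floored at 1e-8; transcripts
  below mean 0.5 use the trend's nearest fitted region.
* Ties in longest-ORF selection break to the lowest frame, then the
  leftmost start.
* `fisherOneSided` evaluates the tail via `phyper`; the EASE
  jackknife may place k−1 below the hypergeometric support, where the
  upper tail is exactly 1.
* Degenerate inputs are first-class: all-zero expression rows,
  zero-variance correlation rows, empty motif libraries, empty
  queries and empty verdict sets all have defined, tested behaviour.
* Problem sizes used by the shipped tests and the acceptance script —
  600 transcripts per study, 2000-transcript null calibrations, a
  200×200 correlation oracle, 1000 randomised interval fixtures —
  were chosen as comfortable desk-scale sizes at which every planted
  effect is statistically unambiguous.

# Known limitations

* The three scorers are stand-ins; their thresholds (300 nt, 0.5
  coverage, score > 0) are conventions, not reproductions of any
  external tool's numerics.
* One transcript per gene locus in the generator: isoform-level
  screening is untested territory.
* The NB test supports exactly two groups and no covariates.
* Trans targeting reports raw correlations; with n = 6 the
  false-positive burden at |r| > 0.95 is material and intentionally
  left visible.
* The enrichment engine ignores term hierarchy and gene-length bias.
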
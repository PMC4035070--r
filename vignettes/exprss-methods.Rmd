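---
title: "Methods: tag-seq quantification from randomly sheared cDNA"
author: "exprss package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-seq quantification from randomly sheared cDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprss)
```

## The measurement model

EXPRSS-style tag sequencing quantifies gene expression by sequencing exactly
one short cDNA fragment ("tag") per transcript. Double-stranded cDNA primed
from the poly(A) junction with a 48 bp oligo-dT/flow-cell primer is
acoustically sheared to ~200 bp; a Y-shaped adapter ensures that only the
3'-most fragment of each cDNA amplifies. The tag therefore starts at the
shear breakpoint, at distance

$$d = \max(1,\; F - \ell_p), \qquad F \sim \mathrm{TruncNormal}(\mu, \sigma;\, [a, b])$$

upstream of the poly(A) site, where $F$ is the sheared fragment length,
$\ell_p = 48$ bp the primer length, and $[a, b]$ the gel size-selection
window. With the package defaults ($\mu = 200$, $\sigma = 30$,
$[a,b] = [100, 350]$) the distance distribution has its mode near
$200 - 48 = 152$ bp and essentially all mass below 300 bp, which is the
geometry real libraries of this design show. Because each transcript yields
one tag regardless of its length, tag counts are directly proportional to
transcript abundance and no length normalization is required.

The instrument settings behind the shear are not a probability model, so the
truncated Normal is this package's explicit stand-in; its three parameters
are user-tunable in `shearing_model()` and every downstream expectation
(distance profile shape, APA resolution) follows from them.

## Read processing

`quality_filter()` reproduces the FASTX-toolkit semantics of `-q20 -p50`: a
read passes when at least 50% of bases (inclusive at the boundary) have
phred quality of at least 20, and any read containing `N` is discarded.
`artifact_filter()` reconstructs the FASTX artifact rule as: a read is
removed when all but at most 3 of its bases are the same base — the
signature of the poly(A)/oligo-dT ligation artifacts these libraries
accumulate. The exact historical FASTX definition is not documented; this
reconstruction is stated here so it can be audited, and the threshold is
configurable.

Demultiplexing handles the protocol's variable-length (3–6 nt) barcodes,
designed so that an equimolar pool keeps all four bases near 25% at each of
the first six cycles (`barcode_balance()` checks this). In `exprss` mode a
read must match a barcode prefix exactly; barcodes are matched longest
first, and the set is required to be prefix-free at construction, which
makes the matching order immaterial. In `nlaiii` mode (the restriction
enzyme-anchored dialect) one mismatch is tolerated, counted over the barcode
length only; a read within one mismatch of two barcodes is deliberately
routed to the unassigned stream rather than guessed. After clipping the
NlaIII 3' adapter (`TCGTATGCCGTCTTC`), tags shorter than 18 nt are dropped
and the anchoring-enzyme site `CATG` is restored at the 5' end with constant
quality `FFFF` (phred 37), since the site is implied by the chemistry rather
than sequenced.

Phred-offset auto-detection scans the first 10,000 reads: any quality
character below `'@'` proves phred+33; all characters at or above `'B'`
indicate phred+64; anything else raises an error asking for an explicit
offset rather than guessing.

## Tag-to-gene assignment

Alignments are consumed from two passes — genome first, then the reads that
failed the genome pass aligned against transcript sequences (which recovers
exon-junction tags). The cascade, per alignment and then aggregated over a
read's candidate set:

1. sense overlap with a gene's limits makes that gene a sense candidate;
   all splice variants of a gene collapse to a single candidate;
2. a read inside overlapping gene limits makes all of them candidates;
3. an antisense overlap is first tested for rescue: if the read's 5'-most
   base lies within 500 bp past the 3' end of a gene on the read's own
   strand, it becomes a *sense* candidate of that neighbour (a 3' UTR
   overhang), otherwise an antisense candidate of the overlapped gene;
4. reads with more than `max_genes` (default 10) candidate genes are
   discarded; otherwise the read is split equally, weight $1/n$ per
   candidate;
5. reads with no candidates stay unassigned and feed novel-region
   detection.

Design choices worth stating because the rules alone do not fix them:

* **Gene limits** are the full annotated span including introns and UTRs.
  Tags concentrate near 3' ends where introns are rare, and junction reads
  are caught by the transcript pass, so intron-aware limits would add
  complexity without changing results materially.
* **Precedence**: sense containment beats window rescue; the window applies
  only to alignments not sense-contained anywhere. A read antisense to
  several genes with no rescue splits equally across all of them.
* **Joint split**: when overlap-splitting and paralog multi-mapping occur
  for one read, a single equal split over the final candidate set is used
  rather than a nested split.
* **Representative position**: "falls within 500 bp" is evaluated at the
  read's 5'-most aligned base.
* A read that overlaps no gene but sits inside a downstream window stays
  unassigned: the rescue rule exists to redirect *antisense-looking* tags,
  and purely intergenic downstream tags are left for novel-region
  detection, where they are more informative.
* Coordinates are 1-based inclusive everywhere (the GRanges convention of
  the R/Bioconductor stack); BED export converts at the boundary.

Weights are plain doubles; per-read weights sum to 1 within 1e-9 and the
count matrix conserves total assigned mass per sample exactly, which the
test suite asserts continuously. Counts are kept fractional; a rounding
export exists for integer-only downstream tools.

## Profiles and peak calling

`distance_profile()` histograms the signed distance from each uniquely
aligned sense tag's start to the 3' end of its gene's *longest* splice
variant (summed exon length, ties broken by transcript id) — using one
consistent reference end keeps tags shared between variants from smearing
the profile. Multi-mapping and antisense tags are excluded.

For poly(A) sites no published algorithm exists for this data type, so
`call_apa_sites()` uses the simplest procedure honouring the known ~200 bp
resolvability limit of sheared-tag peaks: a 25 bp histogram, 3-bin moving
average, local maxima filtered by support (≥ 5 tags in the smoothing
window) and by share of the gene's tags (≥ 10%), then greedy acceptance by
descending height rejecting candidates within 200 bp of an accepted call.
After selection each tag is attributed to its nearest call, which produces
the reported support and usage fraction; this matters because a cluster's
mass spans several bins, so bin counts alone would understate usage. All
thresholds are arguments. Two planted sites 500 bp apart at 0.7/0.3 usage
are recovered with usage within binomial error; sites 100 bp apart collapse
to one call by construction — the method is honest about its resolution
rather than attempting sub-bin deconvolution.

Antisense peaks reuse the same caller and report the strongest surviving
peak, reflecting that abundant antisense transcripts show a defined
polyadenylation site. Novel regions are strand-wise merges of unassigned
alignments (gap ≤ 100 bp) with at least 10 supporting reads — a default
chosen because intergenic signal is sparse enough that pooling samples is
usually needed; it is not a protocol constant. Read-2 poly(A) positions take
the 3'-most aligned base in transcript orientation (soft-clipped tail
handling is assumed done by the aligner upstream) and calls within 50 bp of
an annotated transcript end are flagged `annotated`.

## Expression summaries

TPM (tags per million) divides each count by the sample's total assigned
mass times $10^6$. The denominator pools sense and antisense layers because
both come from the same sequencing pool — a choice, stated here, that makes
the two layers of one sample jointly sum to one million. Detection uses
"mean TPM ≥ 1 over at least 4 replicates"; since that phrasing is ambiguous
between a mean criterion and a per-replicate criterion, the mean reading is
the default and `mode = "each"` provides the strict one. Fold changes are
`log2((mean_t + 1)/(mean_c + 1))` on TPM with a configurable pseudocount.
Replicate QC is the Pearson correlation of `log10(TPM + 1)`.
Differential-expression testing itself is out of scope: the package exports
rounded integer counts plus a design table for negative-binomial count
tools (edgeR, DESeq2, baySeq).

## What the simulator does and does not emulate

`make_transcriptome()` builds single-exon gene models spaced 1 kb apart on
a random genome, with: two-member paralog families sharing an identical
3'-terminal 300 bp (the shortest shared stretch that makes most tags
multi-map), alternative poly(A) isoforms 300–600 bp upstream used at 30%,
polyadenylated antisense transcripts inside 17% of genes (the fraction
detected in real libraries of this design), rRNA decoy loci, and lognormal
transcript lengths with mean 1.5 kb (the Arabidopsis transcriptome mean).
`simulate_library()` draws reads under the shearing model and emits, besides
FASTQ, the exact alignment records an ideal aligner would produce —
including the paralog multi-hits — plus full ground truth. That closes the
loop for testing: with unique 3' sequences and zero error rate,
demultiplexing, assignment and counting recover the truth *exactly*, and
the test suite asserts this end to end at $10^5$ reads.

Deliberate non-features: no PCR/GC bias, no indels (substitution errors
only), no intron structure, no fragment-size bias from gel extraction
beyond hard truncation, and no NlaIII library simulator (that dialect is
exercised with hand-built FASTQ fixtures). Passing tests on this generator
therefore validate the *bookkeeping* — rule cascade, weights, conservation,
peak geometry — not robustness to alignment noise or biochemical bias in
real data.

## Numerical and scale choices

Deterministic seeding: every stochastic entry point takes a `seed` and a
fixed seed yields byte-identical outputs. Problem sizes in the test suite —
$10^5$ reads for the end-to-end and replicate checks, 1,000 reads against
the brute-force rule oracle on a 50-gene annotation, 25 random histograms
against the exhaustive peak-calling oracle — were chosen as the smallest
sizes at which the stochastic properties (Pearson $r \ge 0.95$ between
technical replicates, binomial-error usage recovery) have comfortable
margins. Degenerate inputs are defined: empty profiles flag their summaries
`NA`, an empty candidate histogram returns zero calls, zero-variance samples
yield `NA` correlations with a warning, and a zero-assigned sample is an
error at TPM time, named.

## Known limitations

* The artifact rule and the smoothed-histogram peak caller are documented
  reconstructions, not ports, of tools whose exact behaviour is
  unpublished.
* APA usage estimates are biased when true sites are 200–300 bp apart
  (cluster tails cross the nearest-call boundary).
* The window rescue cannot distinguish a genuine antisense transcript from
  a 3' UTR overhang when both interpretations are available; the rescue
  always wins, as in the original rule set.
* Transcript-pass alignments carry no genomic coordinate, so window rescue
  does not apply to them; minus-strand transcript hits are counted as
  antisense directly.
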
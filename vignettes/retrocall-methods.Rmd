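---
title: "Somatic retrotransposition calling: models and methods"
author: "retrocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic retrotransposition calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Active LINE-1 (L1) elements copy themselves into new genomic locations
through an RNA intermediate and target-primed reverse transcription
(TPRT). In tumors this machinery also mobilizes Alu, SVA and ERV-K
elements, mRNAs (producing processed pseudogenes, PSD) and unique DNA
downstream of active L1 loci (3' transductions), and it can delete the
DNA between its integration site and a distal double-strand break
(L1-mediated deletions). `retrocall` detects and characterizes these
somatic events from paired-end tumor/normal whole-genome alignments, and
ships a synthetic-genome simulator that replays the whole detection
problem under controlled conditions.

## Detection model

**Discordant read-pair clustering.** A retrotransposition insertion that
is absent from the reference produces read pairs with one uniquely mapped
end (the anchor) and one end that either fails to map uniquely (its
sequence matches a retroelement consensus) or maps to a distal unique
locus (transduced sequence, or the far side of a deletion). Anchors on
the + strand upstream of the insertion form the *positive* cluster
(supporting the 5' side); anchors on the − strand downstream form the
*negative* cluster. Candidates are grouped per (chromosome, side) by
single-linkage with a `max_gap` of 400 bp — roughly the read length plus
1.5 insert-size standard deviations of the default library — and clusters
need `min_support = 3` pairs. A positive cluster is paired with the
nearest negative cluster within a 500-bp reciprocal window; unpaired
clusters ("orphans") are the substrate of the rearrangement module.
Clusters supported by discordant reads of the same side and class in the
matched normal (default tolerance 0) are removed as germline.

**Breakpoints and structure.** Soft-clipped reads pile up at the exact
junctions: the modal clip position (leftmost on ties, for determinism)
gives a base-pair breakpoint, and a majority-vote consensus of the
clipped tails reconstructs the first bases of the inserted sequence. From
the two breakpoints and their consensus tails the caller measures:

* the poly(A)/poly(T) tract — longest A-initiated terminal window with
  ≥ 80% adenine and ≥ 10 bp (defaults; the A-window form tolerates the
  occasional sequencing error inside real tracts);
* the target-site duplication — when the 3'-side breakpoint falls left of
  the 5'-side breakpoint by at most 50 bp, the duplicated reference
  sequence between them; a 3'-side breakpoint at or right of the 5' one
  is target-site loss (0 = blunt), the signature that feeds deletion
  calling;
* the L1-endonuclease motif — best match to TTTT|R (+ strand) or Y|AAAA
  (− strand) within ±10 bp of the 5' breakpoint, reported with its 0–5
  mismatch count (≤ 3 to report a site at all; the mismatch count also
  drives cohort-level motif binning);
* subfamily and length — best consensus hit over the supporting mate
  reads; the inserted length is the covered consensus span plus
  transduced span plus poly(A).

**Transduction tracing.** Transduced fragments are unique DNA from the
10-kb window downstream of a full-length L1 source, so a distal-unique
mate cluster that is ≥ 80% contained in a registry window identifies the
source unambiguously; two candidate windows yield NA with a warning
rather than a guess. The registry is built in two passes: annotated
reference full-length L1 loci and polymorphic full-length insertions
found in the normal are cohort-scoped; somatic full-length insertions
found in the tumor join the registry sample-scoped for a second tracing
pass. Calls with L1 consensus mates plus a traced interval are
*partnered* transductions; traced intervals with poly(A) but no L1
content are *orphan* transductions; L1 content alone is a *solo* L1.
Cluster pairs with neither element content nor a traced transduction are
rejected — this also suppresses the echo clusters that transductions
create at their own source locus.

**Processed pseudogenes.** Reciprocal pairs whose distal mates hit exons
of a single gene on both sides (≥ 3 exon-hitting mates per side and
≥ 80% of each side's distal mates, a dominant-fraction reading of
"mates map to exons" that tolerates stray reads) become PSD candidates;
candidates without a detectable poly(A) tract are discarded, which is
what separates retrocopies from ordinary genomic duplications of coding
loci. Ambiguous source genes (tied exon support) yield no call.

**L1-mediated deletions.** Two strategies over somatic orphan clusters:

1. *Copy-number matched* (any size): a loss segment whose upstream
   breakpoint matches a positive orphan and downstream breakpoint a
   negative orphan, each within 1 kb (segment boundaries are imprecise),
   with the intervening insertion passing the single-event rule table.
2. *Depth drop* (< 100 kb): for each positive/negative orphan pair less
   than 100 kb apart, the tumor/normal-normalized read depth inside the
   putative deletion is compared with the outer flank on both sides
   (window 1,000 bp by default, within the admissible 200–5,000 bp range,
   auto-shrunk for short spans; 300-bp buffers adjacent to each cluster
   are excluded to dodge local repeat artifacts). Observed ratios get
   left-tail empirical p-values against a null of ratios resampled at
   100,000 random positions of the predominant-copy-number territory
   (10,000 under the `fast` flag used by desk-scale tests), are
   Benjamini–Hochberg adjusted across all tests in the sample, and the
   pair is tier 1 when both adjusted P < 0.1, tier 2 when exactly one is.
   Span continuity is checked on non-overlapping 500-bp windows.

The "compatible with one single retrotransposition event" criterion is an
explicit rule table: element-body (L1 or transduction) content on the
plus side, poly(A) on the minus side, consistent element identity across
sides, no target-site duplication; the inverted pattern (poly(A) on the
plus side with 5' element content on the minus) is rejected.

**Junction signatures.** At a precise 5' breakpoint, the longest exact
overlap (≥ 1 bp) between the reference suffix and the inserted 5' start
is microhomology; when the expected element start is known, leading
observed bases absent from it are untemplated insertion; neither is a
blunt joint.

**Rearrangement flags.** Orphans with ≥ 3 distal mates on another
chromosome at a copy-number breakpoint are flagged interchromosomal
bridges; two same-side clusters < 10 kb apart at a copy-number step are
fold-back-inversion candidates; losses running from an L1 cluster to a
contig end are telomeric-loss candidates. These are annotations only —
multi-cycle rearrangement histories are out of scope.

## Copy-number input

Consensus segment calls arrive as logR; they are smoothed with a running
median (default window 11 bins — unstated upstream, configurable) and
transformed to absolute copy number with
$n = \frac{(2(1-\rho)+\psi\rho)\,2^{logR} - 2(1-\rho)}{\rho}$
for purity $\rho$ and ploidy $\psi$. Noisy logR at high purity can
produce negative $n$; values are floored at 0 with a warning.

## Cohort statistics

* **Tumor-type enrichment** uses a zero-inflated negative binomial model
  fitted by direct maximum likelihood (BFGS on the joint likelihood,
  method-of-moments starting values; both the logistic zero part and the
  log-link count part carry the binary group covariate). The
  count-component group z-score is the effect measure; groups need ≥ 15
  samples. The zero-inflation component absorbs the excess of
  retrotransposition-silent tumors, the NB dispersion the heavy upper
  tail.
* **Genomic-feature association** bins the genome by closeness to the
  endonuclease motif (mismatches ≥ 4 → bin 0, 3 → 1, 2 → 2, ≤ 1 → 3,
  best of both strands), and regresses per-(window × bin) insertion
  counts on bin indicators with a log bp-footprint offset (negative
  binomial, Poisson fallback when the NB theta diverges). Bin 0 is the
  reference (enrichment ≡ 1). Windowed cells with footprint offsets are
  an equivalent, desk-tractable form of per-nucleotide regression;
  covariate tracks enter as additional modal-bin indicators.
* **Group tests** are two-sided Mann–Whitney U with Benjamini–Hochberg
  adjustment over the invoked family, significant at adjusted P < 0.05;
  **MEI vs structural-variant burden** is Spearman rank correlation.

## The simulator

The simulator is the package's study design, not a fixture: a seeded
i.i.d. reference (41% GC) with N-gap runs, embedded full-length L1
source elements (with unique 10-kb downstream flanks) and multi-exon
genes; planted events drawn per class with TSD 5–20 bp, poly(A)
10–60 bp, solo-L1 5'-truncation probability 0.9 (length-matched to the
heavily truncated somatic insertions seen in tumors), transduced
fragments of 200–1,500 bp, deletions replacing their interval with a
truncated L1 plus poly(A) and no TSD, PSDs concatenating spliced exons,
and 80% of L1-machinery sites at TTTT|R cleavage points (mirroring the
observed preference without hard-coding it). Reads are 100-bp pairs with
Gaussian fragments (mean 450, SD 50 — so elements shorter than the
library size produce junction-spanning pairs), uniform substitution
errors at 0.2%, and default depths of 38× tumor / 30× normal. Clonality
mixing subsamples tumor pairs and tops up with normal-haplotype pairs at
constant depth.

Reads are placed by a *perfect aligner*: exact interval arithmetic on the
haplotype piece map, soft-clipping at junctions, repeat-derived mates
left unmapped with their sequence retained, and MAPQ zeroed inside
annotated reference L1 loci. This isolates the caller's logic from
aligner behavior; consequences for interpretation are below. Transduced
and retro-copied unique sequence maps back to its source locus, exactly
as a real aligner maps reads of a tumor-only copy to the single reference
copy.

Scoring is greedy one-to-one matching by class and position within
150 bp; duplicate calls on one truth event count as false positives.

**What passing does and does not show.** The simulation covers the
geometric and statistical core of the problem — cluster geometry,
reciprocal pairing, clipped-read breakpoints, TSD/poly(A)/motif
signatures, transduction source attribution, clonality-thinned support,
depth-drop nulls. It does not emulate alignment ambiguity in old
repeats, reference repeats absent from the consensus library, chimeric
artifacts, indel/quality error structure, or GC-coverage bias; real-data
precision/recall will be bounded by those factors, which is why the
validation figures here sit at the optimistic end of their claimed
bounds.

## Scale and determinism choices

The default validation uses a 2-Mb reference (two 1-Mb contigs), ~150
somatic events plus a small germline set, four clonalities (25/50/75/
100%) — large enough that every class occurs tens of times while one
clonality runs in about a minute on one CPU. The depth-drop null uses
10,000 locations in desk-scale tests and 100,000 by default. All
randomness flows from one integer seed through tagged child seeds (each
below 2^31), so every run is bit-reproducible; ties in breakpoint voting
are broken leftmost, and cluster pairing is greedy by |gap|, making call
sets order-invariant.

## Known limitations

Twin-priming/inverted insertions are only flagged as orientation
conflicts, not resolved. Subfamily assignment is best-identity, without
diagnostic-nucleotide weighting. Tumor-only calling (no matched normal)
and CRAM input are unsupported. The ZINB model carries only the group
covariate; additional covariates (e.g. sequencing depth) would need to
be added to the likelihood. Transductions compatible with several nearby
sources are deliberately left unattributed.
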
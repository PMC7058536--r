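# retrocall

Somatic retrotransposition calling from tumor/normal paired-end
whole-genome sequencing, in R.

Cancer genomes acquire somatic insertions of LINE-1 (L1), Alu, SVA and
ERV-K retroelements, processed pseudogenes, and L1 3' transductions —
unique DNA mobilized from the 10-kb region downstream of an active L1
source element. Integration by the L1 machinery leaves a characteristic
footprint: a target-site duplication (TSD), a 3' poly(A) tract, a
cleavage site resembling the L1-endonuclease motif TTTT|R (Y|AAAA on the
other strand), and frequent 5' truncation of the element. Occasionally
integration deletes the DNA between the insertion site and a distal
break: an L1-mediated deletion, recognizable by its bridging element,
poly(A) at one junction, and the absence of a TSD.

`retrocall` implements the full detection chain:

* **Cluster detection** — discordant read pairs with one uniquely mapped
  anchor are classified (repeat-consensus mate vs distal unique mate),
  clustered by strand into positive (5'-side) and negative (3'-side)
  clusters, paired reciprocally within 500 bp, and purged of germline
  events by matched-normal subtraction.
* **Breakpoint characterization** — base-pair breakpoints from
  soft-clipped read consensus; TSD, poly(A), endonuclease motif
  (0–5 mismatches), subfamily, inserted length; solo vs
  partnered/orphan-transduction classification with source tracing via
  strand-aware 10-kb downstream windows (germline, polymorphic and
  somatic sources).
* **Processed pseudogenes** — reciprocal clusters whose mates hit exons
  of one source gene, with a mandatory poly(A) tract.
* **L1-mediated deletions** — copy-number breakpoint matching for large
  events; for events under 100 kb, a tumor/normal read-depth-drop test
  against an empirical null resampled at 100,000 genomic locations,
  Benjamini–Hochberg adjusted, reported as tier 1 (both clusters
  adjusted P < 0.1) or tier 2 (one cluster). Translocation bridges,
  fold-back inversions and telomeric losses are flagged from single
  clusters.
* **Cohort statistics** — zero-inflated negative-binomial enrichment of
  per-sample MEI counts by tumor type (direct ML), endonuclease-motif
  genome binning with negative-binomial enrichment regression,
  Mann–Whitney group tests with BH correction, Spearman MEI-vs-SV
  correlation, per-Mb rate tracks.
* **Simulation & validation** — a seeded synthetic-genome engine (gapped
  reference, planted events of every class with full structural detail,
  38× paired-end reads, clonality mixing by read subsampling,
  perfect-aligner placement) and truth-registry precision/recall
  scoring.

Copy-number input uses the purity/ploidy transform
`n = ((2(1-rho) + psi*rho) * 2^logR - 2(1-rho)) / rho` with
running-median smoothing.

## A worked example

Simulate a small tumor/normal pair, call somatic MEIs, and score them:

```r
library(retrocall)

ref <- make_reference(n_contigs = 1, contig_len = 3e5,
                      n_sources = 2, n_genes = 2, seed = 7)
sim <- plant_events(ref, counts = c(solo_L1 = 6, L1_partnered_TD = 2,
                                    L1_orphan_TD = 2, Alu = 4, SVA = 2),
                    seed = 7)
t_aln <- align_reads_perfect(sim$tumor,
           generate_reads(sim$tumor, coverage = 38, seed = 11), ref,
           sample_id = "tumor")
n_aln <- align_reads_perfect(sim$normal,
           generate_reads(sim$normal, coverage = 30, seed = 12), ref,
           sample_id = "normal")
res <- run_call(t_aln, n_aln, ref$seqs, ref$library,
                sources_l1 = ref$sources, exons = ref$exons)
res$calls[1:3, c("class", "chrom", "pos", "strand", "polyA_len",
                 "tsd_len", "src_id", "status")]
#>     class chrom   pos strand polyA_len tsd_len src_id  status
#> 1     SVA  chr1 14392      +        35      19   <NA> precise
#> 2 solo_L1  chr1 29171      +        71      10   <NA> precise
#> 3     Alu  chr1 62128      -        67       5   <NA> precise

evaluate_calls(res$calls, sim$truth)
#> $tp [1] 16   $fp [1] 0   $fn [1] 0
#> $precision [1] 1   $recall [1] 1
```

Each call row reads: an SVA insertion on the plus strand at chr1:14392
with a 19-bp target-site duplication and 35-bp poly(A); transduction
calls additionally carry `src_id` (the source element) and the transduced
interval. `write_mei_vcf()` emits the call set as VCF 4.2 with
MEITYPE/SUBFAMILY/POLYA_LEN/TSD_LEN/ENMOTIF_MM/SRCID/TDCOORDS/STATUS
INFO fields; `run_rearrange()` adds deletion calls and rearrangement
flags.

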
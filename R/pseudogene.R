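# Processed-pseudogene (PSD) calling: reciprocal cluster pairs whose
# distal mates land in exons of one source protein-coding gene, with
# retrotransposition hallmarks (poly(A), usually a TSD) confirmed at the
# breakpoints. Candidates without a poly(A) tail are discarded, which
# separates retrocopies from ordinary genomic duplications of coding loci.

#' Call somatic processed-pseudogene insertions
#'
#' For every reciprocal cluster pair, distal mate alignments are
#' intersected with exons; a PSD call is emitted when at least
#' `min_support` mates per side hit exons, at least `exon_frac` of each
#' side's distal mates hit exons of a single source gene, and a poly(A)
#' tract is present at the breakpoints. Mates spanning non-adjacent exons
#' of the source gene are counted as retrocopy (intron-loss) evidence.
#'
#' @param pairs data.frame from [pair_reciprocal()] (`pairs` element).
#' @param clusters the cluster table the pair ids refer to.
#' @param exons exon table (gene_id/chrom/start/end/strand/exon_number).
#' @param aln tumor alignment table (clipped-read rescue).
#' @param ref_seqs named contig sequences.
#' @param min_support minimum exon-hitting mates per side (default 3).
#' @param exon_frac minimum fraction of distal mates hitting exons of the
#'   source gene, per side (default 0.8).
#' @param sample_id sample label.
#' @return MEI call table rows with class "PSD" and `src_gene` set.
#' @export
call_processed_pseudogenes <- function(pairs, clusters, exons, aln, ref_seqs,
                                       min_support = 3L, exon_frac = 0.8,
                                       sample_id = "tumor") {
  out <- NULL
  if (is.null(pairs) || nrow(pairs) == 0) return(out)
  for (k in seq_len(nrow(pairs))) {
    plus <- clusters[clusters$cluster_id == pairs$plus_id[k], ]
    minus <- clusters[clusters$cluster_id == pairs$minus_id[k], ]
    gp <- side_gene_hits(plus$members[[1]], exons)
    gm <- side_gene_hits(minus$members[[1]], exons)
    if (is.null(gp) || is.null(gm)) next
    shared <- intersect(names(gp$per_gene), names(gm$per_gene))
    if (length(shared) == 0) next
    score <- vapply(shared, function(g) gp$per_gene[[g]]$n + gm$per_gene[[g]]$n,
                    numeric(1))
    top <- shared[score == max(score)]
    if (length(top) != 1) next  # ambiguous source gene: no call
    g <- top
    hp <- gp$per_gene[[g]]; hm <- gm$per_gene[[g]]
    if (hp$n < min_support || hm$n < min_support) next
    if (hp$n / gp$n_distal < exon_frac || hm$n / gm$n_distal < exon_frac) next

    region5 <- c(plus$end - 400L, minus$start + 200L)
    region3 <- c(plus$end - 200L, minus$start + 400L)
    cl5 <- clipped_in_region(aln, plus$chrom, region5[1], region5[2], "clip3")
    cl3 <- clipped_in_region(aln, plus$chrom, region3[1], region3[2], "clip5")
    bkp5 <- assemble_breakpoint(cl5$pos, cl5$seq, "start", fallback_pos = plus$end)
    bkp3 <- assemble_breakpoint(cl3$pos, cl3$seq, "end", fallback_pos = minus$start)
    bkp5$chrom <- plus$chrom; bkp3$chrom <- minus$chrom
    pa3 <- detect_polyA(bkp3$consensus_seq %||% "")
    pa5 <- if (!is.null(bkp5$consensus_seq) && nchar(bkp5$consensus_seq %||% ""))
      detect_polyA(revcomp(bkp5$consensus_seq)) else 0L
    polyA_len <- max(pa3, pa5)
    if (polyA_len == 0) next  # no poly(A): discard (genomic duplication decoy)

    tsd <- if (bkp5$precise && bkp3$precise)
      detect_tsd(bkp5, bkp3, ref_seqs)
    else list(tsd_len = NA_integer_, tsd_seq = NA_character_,
              deletion_at_target = NA_integer_)
    exon_hits <- sort(unique(c(hp$exons, hm$exons)))
    retrocopy_evidence <- length(exon_hits) >= 2

    out <- rbind(out, data.frame(
      sample_id = sample_id, class = "PSD", chrom = plus$chrom,
      pos = bkp5$pos, bkp5_pos = bkp5$pos, bkp5_precise = bkp5$precise,
      bkp3_pos = bkp3$pos, bkp3_precise = bkp3$precise,
      strand = if (pa5 > pa3) "-" else "+",
      inserted_len = NA_integer_, subfamily = NA_character_,
      polyA_len = as.integer(polyA_len),
      tsd_len = tsd$tsd_len, tsd_seq = tsd$tsd_seq,
      target_del_len = tsd$deletion_at_target,
      en_site = NA_character_, en_mismatch = NA_integer_,
      en_offset = NA_integer_, en_strand = NA_character_,
      src_id = NA_character_, td_chrom = NA_character_,
      td_start = NA_integer_, td_end = NA_integer_,
      src_gene = g,
      status = if (bkp5$precise && bkp3$precise) "precise" else "imprecise",
      support = plus$support + minus$support,
      support_clipped = bkp5$support_clipped + bkp3$support_clipped,
      plus_id = plus$cluster_id, minus_id = minus$cluster_id,
      stringsAsFactors = FALSE))
    attr(out, "retrocopy_evidence") <- retrocopy_evidence
  }
  out
}

# distal mates of one cluster side intersected with exons; per-gene counts
side_gene_hits <- function(members, exons) {
  d <- members[members$mate_kind == "distal", , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  per_gene <- list()
  for (i in seq_len(nrow(d))) {
    hit <- exons$chrom == d$mate_chrom[i] &
      exons$start < d$mate_end[i] & exons$end > d$mate_start[i]
    for (g in unique(exons$gene_id[hit])) {
      exn <- exons$exon_number[hit & exons$gene_id == g]
      if (is.null(per_gene[[g]])) per_gene[[g]] <- list(n = 0L, exons = integer())
      per_gene[[g]]$n <- per_gene[[g]]$n + 1L
      per_gene[[g]]$exons <- union(per_gene[[g]]$exons, exn)
    }
  }
  if (length(per_gene) == 0) return(NULL)
  list(per_gene = per_gene, n_distal = nrow(d))
}
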
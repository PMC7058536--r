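# Readers/writers for external formats. Internal coordinates are 0-based
# half-open everywhere; VCF/SAM emission converts to 1-based. BAM access
# goes through Rsamtools; SAM input is converted on the fly.

#' Read paired-end alignments into the internal record table
#'
#' Reads a coordinate-sorted BAM (or SAM, converted transparently) into
#' the alignment data.frame used by the caller. Secondary, supplementary,
#' duplicate-marked and QC-fail reads are excluded. Unmapped mates are
#' retained (their sequence carries the repeat evidence).
#'
#' @param path BAM or SAM file.
#' @param region optional data.frame/list with chrom, start, end (0-based
#'   half-open); requires an index.
#' @param sample_id sample label stored on every record.
#' @return alignment data.frame (two rows per pair when both ends are in
#'   range).
#' @export
read_alignments <- function(path, region = NULL, sample_id = "sample") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE, isNotPassingQualityControls = FALSE)
  what <- c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar",
            "seq", "mrnm", "mpos")
  if (!is.null(region)) {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)) &&
        !file.exists(paste0(path, ".csi")))
      stop("region query requires a BAM index (.bai/.csi) for ", path)
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    if (!region$chrom %in% names(hdr))
      return(empty_alignments(sample_id))
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start + 1L, region$end))
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, which = which)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flags, what = what)
  }
  res <- tryCatch(Rsamtools::scanBam(path, param = param),
                  error = function(e) stop("failed to read ", path, ": ",
                                           conditionMessage(e)))
  b <- res[[1]]
  if (length(res) > 1) {
    b <- lapply(names(res[[1]]), function(f)
      do.call(c, lapply(res, `[[`, f)))
    names(b) <- names(res[[1]])
  }
  n <- length(b$qname)
  if (n == 0) return(empty_alignments(sample_id))
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  mate_mapped <- bitwAnd(flag, 8L) == 0L
  clips <- cigar_clips(ifelse(is.na(b$cigar), "*", b$cigar))
  span <- cigar_ref_span(ifelse(is.na(b$cigar), "*", b$cigar))
  df <- data.frame(
    qname = b$qname,
    chrom = ifelse(mapped, as.character(b$rname), NA_character_),
    pos = ifelse(mapped, as.integer(b$pos) - 1L, NA_integer_),
    end = ifelse(mapped, as.integer(b$pos) - 1L + span, NA_integer_),
    strand = ifelse(bitwAnd(flag, 16L) == 0L, "+", "-"),
    mapq = as.integer(b$mapq),
    cigar = as.character(b$cigar),
    seq = as.character(b$seq),
    is_read1 = bitwAnd(flag, 64L) != 0L,
    mapped = mapped,
    clip5 = clips$clip5, clip3 = clips$clip3,
    mate_chrom = ifelse(mate_mapped, as.character(b$mrnm), NA_character_),
    mate_pos = ifelse(mate_mapped, as.integer(b$mpos) - 1L, NA_integer_),
    mate_strand = ifelse(bitwAnd(flag, 32L) == 0L, "+", "-"),
    mate_mapped = mate_mapped,
    is_proper = bitwAnd(flag, 2L) != 0L,
    sample_id = sample_id,
    stringsAsFactors = FALSE)
  df$mapq[!df$mapped] <- 0L
  df
}

empty_alignments <- function(sample_id = "sample") {
  data.frame(qname = character(), chrom = character(), pos = integer(),
             end = integer(), strand = character(), mapq = integer(),
             cigar = character(), seq = character(), is_read1 = logical(),
             mapped = logical(), clip5 = integer(), clip3 = integer(),
             mate_chrom = character(), mate_pos = integer(),
             mate_strand = character(), mate_mapped = logical(),
             is_proper = logical(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Write an alignment table as SAM
#'
#' Emits a coordinate-sorted SAM with proper flags; unmapped reads are
#' placed at their mate's coordinates per the SAM convention.
#'
#' @param aln alignment table.
#' @param contig_lengths named integer vector of reference contig lengths.
#' @param path output .sam path.
#' @return the path, invisibly.
#' @export
write_sam <- function(aln, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths))), con)
  flag <- ifelse(aln$is_read1, 64L, 128L) + 1L
  flag <- flag + ifelse(aln$mapped, 0L, 4L)
  flag <- flag + ifelse(aln$mate_mapped %in% FALSE, 8L, 0L)
  flag <- flag + ifelse(aln$strand == "-", 16L, 0L)
  flag <- flag + ifelse(!is.na(aln$mate_strand) & aln$mate_strand == "-", 32L, 0L)
  flag <- flag + ifelse(aln$is_proper, 2L, 0L)
  rname <- ifelse(aln$mapped, aln$chrom, ifelse(is.na(aln$mate_chrom), "*", aln$mate_chrom))
  pos1 <- ifelse(aln$mapped, aln$pos + 1L,
                 ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos + 1L))
  cig <- ifelse(aln$mapped, aln$cigar, "*")
  mrnm <- ifelse(is.na(aln$mate_chrom), "*",
                 ifelse(aln$mate_chrom == rname & rname != "*", "=", aln$mate_chrom))
  mpos1 <- ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos + 1L)
  o <- order(match(rname, c(names(contig_lengths), "*")), pos1)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                   aln$qname[o], flag[o], rname[o], pos1[o],
                   aln$mapq[o], cig[o], mrnm[o], mpos1[o], aln$seq[o])
  writeLines(lines, con)
  invisible(path)
}

MEI_INFO_KEYS <- c("MEITYPE", "SUBFAMILY", "POLYA_LEN", "TSD_LEN", "ENMOTIF_MM",
                   "SRCID", "TDCOORDS", "SRCGENE", "STATUS")

#' Write MEI calls as VCF 4.2
#'
#' One record per call; POS is the 1-based base left of the 3'-extreme
#' insertion breakpoint. INFO carries MEITYPE, SUBFAMILY, POLYA_LEN,
#' TSD_LEN, ENMOTIF_MM, SRCID, TDCOORDS, SRCGENE and STATUS
#' (precise/imprecise). Round-trip with [read_mei_vcf()] reproduces these
#' fields.
#'
#' @param calls MEI call table sorted by (chrom, pos).
#' @param ref_seqs named contig sequences (for the REF base and contigs).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mei_vcf <- function(calls, ref_seqs, path) {
  if (!is.null(calls) && nrow(calls)) {
    o <- order(match(calls$chrom, names(ref_seqs)), calls$bkp3_pos)
    if (any(o != seq_len(nrow(calls)))) stop("calls must be sorted by (chrom, pos)")
    if (any(!calls$chrom %in% names(ref_seqs)))
      stop("call on contig absent from reference: ",
           paste(setdiff(calls$chrom, names(ref_seqs)), collapse = ","))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(ref_seqs),
            vapply(ref_seqs, nchar, 1L)),
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    "##INFO=<ID=MEITYPE,Number=1,Type=String,Description=\"Insertion class\">",
    "##INFO=<ID=SUBFAMILY,Number=1,Type=String,Description=\"Element subfamily\">",
    "##INFO=<ID=POLYA_LEN,Number=1,Type=Integer,Description=\"Poly(A) tract length\">",
    "##INFO=<ID=TSD_LEN,Number=1,Type=Integer,Description=\"Target site duplication length\">",
    "##INFO=<ID=ENMOTIF_MM,Number=1,Type=Integer,Description=\"Endonuclease motif mismatches\">",
    "##INFO=<ID=SRCID,Number=1,Type=String,Description=\"Transduction source element\">",
    "##INFO=<ID=TDCOORDS,Number=1,Type=String,Description=\"Transduced interval chrom:start-end (0-based half-open)\">",
    "##INFO=<ID=SRCGENE,Number=1,Type=String,Description=\"Pseudogene source gene\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"precise or imprecise\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  if (!is.null(calls) && nrow(calls)) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      x <- calls[i, ]
      kv <- c(
        MEITYPE = x$class, SUBFAMILY = x$subfamily,
        POLYA_LEN = x$polyA_len, TSD_LEN = x$tsd_len,
        ENMOTIF_MM = x$en_mismatch, SRCID = x$src_id,
        TDCOORDS = if (!is.na(x$td_chrom))
          sprintf("%s:%d-%d", x$td_chrom, x$td_start, x$td_end) else NA,
        SRCGENE = x$src_gene, STATUS = x$status)
      kv <- kv[!is.na(kv)]
      paste(paste0(names(kv), "=", kv), collapse = ";")
    }, "")
    pos1 <- calls$bkp3_pos  # 0-based breakpoint == 1-based base to its left
    refbase <- substring(ref_seqs[calls$chrom], pos1, pos1)
    refbase[refbase == "" | is.na(refbase)] <- "N"
    lines <- sprintf("%s\t%d\t%s\t%s\t<INS:ME>\t.\tPASS\t%s",
                     calls$chrom, pos1, sprintf("MEI%04d", seq_len(nrow(calls))),
                     refbase, info)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an MEI VCF back into a call table
#'
#' Parses with VariantAnnotation and restores the INFO fields written by
#' [write_mei_vcf()].
#'
#' @param path VCF path.
#' @return data.frame with chrom, pos (0-based 3'-breakpoint), class and
#'   the INFO-derived columns.
#' @export
read_mei_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  gr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  getc <- function(k, as = as.character) {
    if (k %in% names(info)) {
      v <- info[[k]]
      as(ifelse(is.na(v), NA, v))
    } else rep(as(NA), n)
  }
  td <- getc("TDCOORDS")
  tdm <- regmatches(td, regexec("^(.+):([0-9]+)-([0-9]+)$", td))
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    bkp3_pos = BiocGenerics::start(gr),  # 1-based left base == 0-based bkp
    class = getc("MEITYPE"),
    subfamily = getc("SUBFAMILY"),
    polyA_len = getc("POLYA_LEN", as.integer),
    tsd_len = getc("TSD_LEN", as.integer),
    en_mismatch = getc("ENMOTIF_MM", as.integer),
    src_id = getc("SRCID"),
    td_chrom = vapply(tdm, function(m) if (length(m)) m[2] else NA_character_, ""),
    td_start = vapply(tdm, function(m) if (length(m)) as.integer(m[3]) else NA_integer_, 1L),
    td_end = vapply(tdm, function(m) if (length(m)) as.integer(m[4]) else NA_integer_, 1L),
    src_gene = getc("SRCGENE"),
    status = getc("STATUS"),
    stringsAsFactors = FALSE)
}

#' Read copy-number segments from TSV/BED
#'
#' Requires columns chrom, start, end plus either `logR` or
#' (`total_cn`, `minor_cn`). Segments are returned sorted; overlapping
#' segments on one chromosome are an error. logR-only input is flagged as
#' requiring the purity/ploidy transform.
#'
#' @param path TSV with a header line.
#' @return data.frame of segments with attribute `needs_transform`.
#' @export
read_cn_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("copy-number file must have columns chrom, start, end")
  has_logr <- "logR" %in% names(df)
  has_cn <- all(c("total_cn", "minor_cn") %in% names(df))
  if (!has_logr && !has_cn)
    stop("need either a logR column or total_cn + minor_cn columns")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    bad <- which(s$start[-1] < s$end[-nrow(s)])
    if (length(bad))
      stop("overlapping copy-number segments on ", ch, ": rows ",
           paste(bad, bad + 1L, sep = "/", collapse = ", "))
  }
  rownames(df) <- NULL
  attr(df, "needs_transform") <- has_logr && !has_cn
  df
}

#' Read gene models from GTF/GFF
#'
#' Imports exon features via rtracklayer and returns the exon table used
#' by the pseudogene caller (0-based half-open coordinates).
#'
#' @param path GTF/GFF3 file with exon features carrying gene_id.
#' @return exon data.frame (gene_id, chrom, start, end, strand,
#'   exon_number).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  df$exon_number <- stats::ave(df$start, df$gene_id, FUN = seq_along)
  df
}

#' Write a reference and annotation to disk
#'
#' FASTA (+ .fai via Rsamtools), gap BED, source-element BED and gene GTF
#' for a simulated reference.
#'
#' @param ref a `sim_reference`.
#' @param dir output directory (created).
#' @return named list of written paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  ss <- Biostrings::DNAStringSet(unlist(ref$seqs))
  names(ss) <- names(ref$seqs)
  Biostrings::writeXStringSet(ss, fa)
  Rsamtools::indexFa(fa)
  gaps <- file.path(dir, "gaps.bed")
  write.table(ref$gaps, gaps, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  src <- file.path(dir, "sources_l1.bed")
  write.table(ref$sources[, c("chrom", "start", "end", "id", "strand")],
              src, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  gtf <- file.path(dir, "genes.gtf")
  ex <- ref$exons
  lines <- sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; exon_number "%d";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$exon_number)
  writeLines(lines, gtf)
  list(fasta = fa, gaps = gaps, sources = src, genes = gtf)
}

#' Write read pairs as gzipped FASTQ
#'
#' @param frags fragment table from [generate_reads()].
#' @param prefix output prefix; writes `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz`.
#' @return character vector of the two paths.
#' @export
write_fastq <- function(frags, prefix) {
  p1 <- paste0(prefix, "_1.fastq.gz"); p2 <- paste0(prefix, "_2.fastq.gz")
  wr <- function(path, seqs, names) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    qual <- strrep("I", nchar(seqs[1]))
    writeLines(paste0("@", names, "\n", seqs, "\n+\n", qual), con)
  }
  wr(p1, frags$fseq1, frags$qname)
  wr(p2, revcomp(frags$fseq2), frags$qname)
  c(p1, p2)
}
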
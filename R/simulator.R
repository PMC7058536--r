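# Synthetic-genome simulation: a seeded mock reference with unsequenced
# gaps, embedded full-length L1 source elements and multi-exon genes;
# planted somatic/germline retrotransposition events of every supported
# class; paired-end read generation; a "perfect aligner" that places each
# read at its truth coordinates (soft-clipping across junctions, leaving
# repeat-derived reads unmapped with their sequence retained, and zeroing
# MAPQ inside annotated repeat loci); clonality mixing by read subsampling;
# and truth-registry precision/recall scoring.
#
# The haplotype is represented as an ordered "piece map": alternating
# reference-derived and inserted segments, each piece recording where (if
# anywhere) its sequence occurs in the reference. Read placement is exact
# interval arithmetic on that map -- no alignment is ever performed.

EVENT_CLASSES <- c("solo_L1", "L1_partnered_TD", "L1_orphan_TD", "Alu",
                   "SVA", "ERVK", "PSD", "deletion", "segdup")

rand_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Deterministic synthetic retroelement consensus library
#'
#' Pseudo-consensi with the documented structure of the real families: a
#' ~6-kb "L1" ending in an A-rich tail, a ~300-bp "Alu", a ~1.5-kb "SVA"
#' and a ~1-kb "ERVK". Real Repbase-style consensi are a drop-in
#' replacement via [read_consensus_library()].
#'
#' @param seed integer seed; the default yields the library used by the
#'   bundled simulations.
#' @return a [consensus_library()] data.frame.
#' @export
synthetic_consensus_library <- function(seed = 42L) {
  set.seed(child_seed(seed, "library"))
  mk <- function(n, tail_a = 12L) {
    body <- rand_dna(n - tail_a)
    paste0(body, strrep("A", tail_a))
  }
  lib <- consensus_library(
    class_name = c("L1", "Alu", "SVA", "ERVK"),
    subfamily = c("L1syn", "AluSyn", "SVAsyn", "ERVKsyn"),
    seq = c(mk(6019L), mk(300L), mk(1565L), mk(1000L, 0L)))
  lib
}

#' Build a synthetic reference genome
#'
#' Generates i.i.d. contig sequence with N-run gaps covering approximately
#' `gap_fraction` of each contig, embeds `n_sources` full-length L1 source
#' elements (each with a unique 10-kb downstream flank) and `n_genes`
#' synthetic multi-exon genes, and returns the sequence together with the
#' gap, source and gene annotation.
#'
#' @param n_contigs number of contigs.
#' @param contig_len length of each contig in bp (>= 1e5).
#' @param gap_fraction fraction of each contig covered by N gaps (< 1).
#' @param n_sources total embedded full-length L1 source elements.
#' @param n_genes total synthetic multi-exon genes.
#' @param seed integer seed; the build is fully deterministic given it.
#' @param library consensus library (defaults to the seeded synthetic one).
#' @return an object of class `sim_reference`: list with `seqs` (named
#'   character vector), `gaps`, `sources`, `genes`, `exons`, `library`,
#'   `seed`.
#' @export
make_reference <- function(n_contigs = 2L, contig_len = 1e6, gap_fraction = 0.01,
                           n_sources = 3L, n_genes = 4L, seed = 1L,
                           library = synthetic_consensus_library()) {
  if (gap_fraction >= 1) stop("gap_fraction must be < 1")
  if (contig_len < 1e5) stop("contig_len must be >= 100 kb")
  set.seed(child_seed(seed, "reference"))
  contig_len <- as.integer(contig_len)
  chroms <- paste0("chr", seq_len(n_contigs))
  seqs <- setNames(vapply(chroms, function(x) rand_dna(contig_len), ""), chroms)

  # N gaps: a few runs per contig totalling ~gap_fraction
  gaps <- NULL
  if (gap_fraction > 0) {
    for (ch in chroms) {
      total <- round(contig_len * gap_fraction)
      n_runs <- max(1L, min(3L, total %/% 5000L))
      lens <- as.integer(round(total * as.numeric(prop.table(runif(n_runs, 0.5, 1.5)))))
      starts <- sort(sample.int(contig_len - max(lens) - 20000L, n_runs) + 10000L)
      for (i in seq_len(n_runs)) {
        s <- starts[i]; e <- min(s + lens[i], contig_len)
        substr(seqs[[ch]], s + 1L, e) <- strrep("N", e - s)
        gaps <- rbind(gaps, data.frame(chrom = ch, start = s, end = e))
      }
    }
  } else gaps <- data.frame(chrom = character(), start = integer(), end = integer())

  occupied <- gaps  # intervals already taken (avoid overlap)
  take <- function(len, margin = 12000L) {
    # sample a free interval of length len, away from gaps/previous features
    for (try in 1:200) {
      ch <- sample(chroms, 1)
      s <- sample.int(contig_len - len - 2L * margin, 1) + margin
      cand <- data.frame(chrom = ch, start = s - margin %/% 2L,
                         end = s + len + margin)
      hit <- any(occupied$chrom == ch &
                 occupied$start < cand$end & occupied$end > cand$start)
      if (!hit) {
        occupied <<- rbind(occupied, cand[, c("chrom", "start", "end")])
        return(list(chrom = ch, start = s, end = s + len))
      }
    }
    stop("could not place feature; reference too crowded")
  }

  l1seq <- library$seq[library$class_name == "L1"][1]
  l1len <- nchar(l1seq)
  sources <- NULL
  for (i in seq_len(n_sources)) {
    loc <- take(l1len)
    strand <- sample(c("+", "-"), 1)
    emb <- if (strand == "+") l1seq else revcomp(l1seq)
    substr(seqs[[loc$chrom]], loc$start + 1L, loc$end) <- emb
    sources <- rbind(sources, data.frame(
      id = sprintf("SRC%02d", i), chrom = loc$chrom, start = loc$start,
      end = loc$end, strand = strand, origin = "reference_fulllength",
      stringsAsFactors = FALSE))
  }
  if (is.null(sources))
    sources <- data.frame(id = character(), chrom = character(), start = integer(),
                          end = integer(), strand = character(), origin = character())

  genes <- NULL; exons <- NULL
  for (g in seq_len(n_genes)) {
    n_ex <- sample(4:7, 1)
    ex_len <- sample(120:400, n_ex, replace = TRUE)
    intron <- sample(500:2000, n_ex - 1, replace = TRUE)
    span <- sum(ex_len) + sum(intron)
    loc <- take(span)
    strand <- sample(c("+", "-"), 1)
    pos <- loc$start
    gid <- sprintf("GENE%02d", g)
    for (e in seq_len(n_ex)) {
      exons <- rbind(exons, data.frame(
        gene_id = gid, chrom = loc$chrom, start = pos, end = pos + ex_len[e],
        strand = strand, exon_number = e, stringsAsFactors = FALSE))
      pos <- pos + ex_len[e] + if (e < n_ex) intron[e] else 0L
    }
    genes <- rbind(genes, data.frame(
      gene_id = gid, gene_name = gid, chrom = loc$chrom, start = loc$start,
      end = loc$end, strand = strand, stringsAsFactors = FALSE))
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), gene_name = character(),
                        chrom = character(), start = integer(), end = integer(),
                        strand = character())
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(), strand = character(),
                        exon_number = integer())
  }

  structure(list(seqs = seqs, contig_len = contig_len, gaps = gaps,
                 sources = sources, genes = genes, exons = exons,
                 library = library, seed = seed),
            class = "sim_reference")
}

# sequence of a reference interval (0-based half-open), strand-aware
ref_seq <- function(ref, chrom, start, end, strand = "+") {
  s <- substring(ref$seqs[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

# candidate insertion sites: outside gaps (with margin), minimum separation,
# away from sources and contig edges; optionally at L1-endonuclease motifs
sample_sites <- function(ref, n, en_frac = 0.8, margin = 300L, min_sep = 2000L,
                         edge = 5000L) {
  chroms <- names(ref$seqs)
  blocked <- rbind(
    ref$gaps[, c("chrom", "start", "end")],
    if (nrow(ref$sources)) data.frame(chrom = ref$sources$chrom,
                                      start = ref$sources$start - 1000L,
                                      end = ref$sources$end + 11000L))
  chosen <- data.frame(chrom = character(), pos = integer())
  is_free <- function(ch, p) {
    if (p < edge || p > ref$contig_len - edge) return(FALSE)
    if (any(blocked$chrom == ch & blocked$start - margin < p &
            blocked$end + margin > p)) return(FALSE)
    !any(chosen$chrom == ch & abs(chosen$pos - p) < min_sep)
  }
  # precompute EN-motif cleavage points (between TTTT and R) per contig
  en_sites <- lapply(ref$seqs, function(s) {
    m <- gregexpr("TTTT[AG]", s)[[1]]
    if (m[1] == -1) integer() else as.integer(m) + 3L  # 0-based cleavage point
  })
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:500) {
      ch <- sample(chroms, 1)
      if (runif(1) < en_frac && length(en_sites[[ch]]) > 0) {
        p <- sample(en_sites[[ch]], 1)
      } else {
        p <- sample.int(ref$contig_len - 2L * edge, 1) + edge
      }
      if (is_free(ch, p)) {
        chosen <- rbind(chosen, data.frame(chrom = ch, pos = as.integer(p)))
        placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place event ", i, "; genome too crowded")
  }
  chosen
}

# build the inserted-sequence parts for one event; returns a data.frame of
# parts in insertion (5'->3' element) orientation with reference-mapping info
event_parts <- function(ref, ev) {
  lib <- ref$library
  l1 <- lib[lib$class_name == "L1", ][1, ]
  parts <- NULL
  add <- function(seq, kind, ref_chrom = NA, ref_start = NA, ref_end = NA,
                  ref_strand = NA, class = NA) {
    rbind(parts, data.frame(seq = seq, kind = kind, ref_chrom = ref_chrom,
                            ref_start = ref_start, ref_end = ref_end,
                            ref_strand = ref_strand, class = class,
                            stringsAsFactors = FALSE))
  }
  cls <- ev$class
  if (cls %in% c("solo_L1", "Alu", "SVA", "ERVK", "deletion")) {
    el_class <- if (cls %in% c("solo_L1", "deletion")) "L1" else cls
    el <- lib[lib$class_name == el_class, ][1, ]
    seq <- substring(el$seq, ev$trunc + 1L)
    parts <- add(seq, "cons", class = el_class)
  } else if (cls == "L1_partnered_TD") {
    seq <- substring(l1$seq, ev$trunc + 1L)
    parts <- add(seq, "cons", class = "L1")
    src <- ref$sources[ref$sources$id == ev$src_id, ]
    td <- td_interval_for(src, ev$td_len)
    parts <- add(ref_seq(ref, td$chrom, td$start, td$end, src$strand), "flank",
                 td$chrom, td$start, td$end, src$strand)
  } else if (cls == "L1_orphan_TD") {
    src <- ref$sources[ref$sources$id == ev$src_id, ]
    td <- td_interval_for(src, ev$td_len)
    parts <- add(ref_seq(ref, td$chrom, td$start, td$end, src$strand), "flank",
                 td$chrom, td$start, td$end, src$strand)
  } else if (cls == "PSD") {
    ex <- ref$exons[ref$exons$gene_id == ev$src_gene, ]
    ex <- ex[order(ex$exon_number), ]
    ord <- if (ex$strand[1] == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    for (i in ord) {
      parts <- add(ref_seq(ref, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[1]),
                   "flank", ex$chrom[i], ex$start[i], ex$end[i], ex$strand[1])
    }
  } else if (cls == "segdup") {
    # genomic duplication decoy: the full genomic span of a gene (introns
    # included), no poly(A) -- what a retrocopy is NOT
    gn <- ref$genes[ref$genes$gene_id == ev$src_gene, ]
    parts <- add(ref_seq(ref, gn$chrom, gn$start, gn$end, "+"), "flank",
                 gn$chrom, gn$start, gn$end, "+")
    return(parts)
  } else stop("unknown event class: ", cls)
  parts <- add(strrep("A", ev$polyA_len), "polyA")
  parts
}

# the transduced interval: downstream of the source 3' end, strand-aware
td_interval_for <- function(src, td_len) {
  if (src$strand == "+") {
    list(chrom = src$chrom, start = src$end, end = src$end + td_len)
  } else {
    list(chrom = src$chrom, start = src$start - td_len, end = src$start)
  }
}

#' Plant somatic (and germline) retroelement events into a reference
#'
#' Samples insertion sites outside gaps (L1-machinery events preferentially
#' at endonuclease-motif cleavage points), draws per-event structure
#' (strand, 5' truncation, TSD 5-20 bp, poly(A) 10-60 bp, transduction
#' length, deletion span), and builds normal and tumor haplotype piece
#' maps. Germline events are present in both haplotypes; somatic events
#' only in the tumor. L1-mediated deletions replace the deleted interval
#' with a truncated L1 plus poly(A) and carry no TSD.
#'
#' @param ref a `sim_reference`.
#' @param counts named integer vector of somatic event counts by class
#'   (names among solo_L1, L1_partnered_TD, L1_orphan_TD, Alu, SVA, ERVK,
#'   PSD, deletion).
#' @param germline_counts named counts planted in both haplotypes.
#' @param seed integer seed.
#' @param trunc_prob probability a solo-L1 copy is 5'-truncated (default 0.9).
#' @param en_frac fraction of L1-machinery sites placed at endonuclease
#'   motifs (default 0.8).
#' @param td_len_range,polyA_range,tsd_range,del_len_range sampling ranges.
#' @param n_germline_fl_l1 number of germline full-length L1 insertions
#'   (non-reference polymorphic source candidates) included on top of
#'   `germline_counts`.
#' @return list with `truth` (one row per event), `tumor` and `normal`
#'   haplotypes (piece map + sequence), and the `ref` used.
#' @export
plant_events <- function(ref,
                         counts = c(solo_L1 = 50, L1_partnered_TD = 10,
                                    L1_orphan_TD = 10, Alu = 20, SVA = 8),
                         germline_counts = c(solo_L1 = 4, Alu = 4),
                         seed = 1L, trunc_prob = 0.9, en_frac = 0.8,
                         td_len_range = c(200L, 1500L),
                         polyA_range = c(10L, 60L), tsd_range = c(5L, 20L),
                         del_len_range = c(1500L, 6000L),
                         n_germline_fl_l1 = 1L) {
  set.seed(child_seed(seed, "plant"))
  counts <- counts[counts > 0]
  germline_counts <- germline_counts[germline_counts > 0]
  if (any(!names(counts) %in% EVENT_CLASSES) ||
      any(!names(germline_counts) %in% EVENT_CLASSES))
    stop("unknown event class in counts")
  lib <- ref$library
  l1len <- nchar(lib$seq[lib$class_name == "L1"][1])

  classes <- c(rep(names(counts), counts), rep(names(germline_counts), germline_counts))
  germline <- c(rep(FALSE, sum(counts)), rep(TRUE, sum(germline_counts)))
  if (n_germline_fl_l1 > 0) {
    classes <- c(classes, rep("solo_L1", n_germline_fl_l1))
    germline <- c(germline, rep(TRUE, n_germline_fl_l1))
  }
  full_length_gl <- c(rep(FALSE, length(classes) - n_germline_fl_l1),
                      rep(TRUE, n_germline_fl_l1))
  n <- length(classes)
  if (n == 0) stop("no events requested")
  sites <- sample_sites(ref, n, en_frac = en_frac)

  events <- data.frame(
    event_id = sprintf("EV%04d", seq_len(n)), class = classes,
    chrom = sites$chrom, pos = sites$pos,
    strand = sample(c("+", "-"), n, replace = TRUE),
    germline = germline, stringsAsFactors = FALSE)
  events$polyA_len <- sample(polyA_range[1]:polyA_range[2], n, replace = TRUE)
  events$tsd_len <- sample(tsd_range[1]:tsd_range[2], n, replace = TRUE)
  events$tsd_len[events$class == "deletion"] <- 0L
  events$del_len <- ifelse(events$class == "deletion",
                           sample(del_len_range[1]:del_len_range[2], n, replace = TRUE),
                           0L)
  # 5' truncation offsets (consensus start); full length = 0
  events$trunc <- 0L
  is_l1body <- events$class %in% c("solo_L1", "L1_partnered_TD", "deletion")
  tr <- rbinom(n, 1, trunc_prob) == 1 & is_l1body
  tr[full_length_gl] <- FALSE
  events$trunc[tr] <- vapply(which(tr), function(i)
    sample((l1len - 3600L):(l1len - 400L), 1), integer(1))
  events$td_len <- 0L
  is_td <- events$class %in% c("L1_partnered_TD", "L1_orphan_TD")
  events$td_len[is_td] <- sample(td_len_range[1]:td_len_range[2], sum(is_td),
                                 replace = TRUE)
  events$src_id <- NA_character_
  if (any(is_td)) {
    if (nrow(ref$sources) == 0) stop("transductions requested but reference has no sources")
    events$src_id[is_td] <- sample(ref$sources$id, sum(is_td), replace = TRUE)
  }
  events$src_gene <- NA_character_
  is_psd <- events$class %in% c("PSD", "segdup")
  if (any(is_psd)) {
    if (nrow(ref$genes) == 0) stop("PSDs requested but reference has no genes")
    events$src_gene[is_psd] <- sample(ref$genes$gene_id, sum(is_psd), replace = TRUE)
  }
  events$polyA_len[events$class == "segdup"] <- 0L
  # keep transductions on + element strand relative to insertion simple: the
  # element strand still varies; flank content is revcomp'd as a block when -.

  # assemble per-event inserted sequence and part maps
  ins <- vector("list", n)
  for (i in seq_len(n)) {
    p <- event_parts(ref, events[i, ])
    ins[[i]] <- p
  }
  events$inserted_len <- vapply(ins, function(p) sum(nchar(p$seq)), numeric(1))

  truth <- events
  truth$bkp5 <- truth$pos
  truth$bkp3 <- ifelse(truth$class == "deletion", truth$pos + truth$del_len,
                       truth$pos - truth$tsd_len)

  normal <- build_haplotype(ref, events[events$germline, , drop = FALSE],
                            ins[events$germline])
  tumor <- build_haplotype(ref, events, ins)
  list(truth = truth, tumor = tumor, normal = normal, ref = ref)
}

# build a haplotype (piece map + sequence) from the reference and an
# ordered set of events with their part lists
build_haplotype <- function(ref, events, ins_parts) {
  pieces <- NULL
  seqs <- list()
  for (ch in names(ref$seqs)) {
    idx <- which(events$chrom == ch)
    idx <- idx[order(events$pos[idx])]
    h <- 0L; r <- 0L
    chunks <- character(0)
    add_piece <- function(hlen, kind, rs, re, rstrand, event_id, class) {
      pieces <<- rbind(pieces, data.frame(
        contig = ch, hap_start = h, hap_end = h + hlen, kind = kind,
        ref_chrom = if (kind %in% c("ref", "flank")) rs$chrom else NA,
        ref_start = if (kind %in% c("ref", "flank")) rs$start else NA,
        ref_end = if (kind %in% c("ref", "flank")) rs$end else NA,
        ref_strand = rstrand, event_id = event_id, class = class,
        stringsAsFactors = FALSE))
      h <<- h + hlen
    }
    for (i in idx) {
      ev <- events[i, ]
      # reference piece up to the 5' breakpoint
      if (ev$pos > r) {
        chunks <- c(chunks, substring(ref$seqs[[ch]], r + 1L, ev$pos))
        add_piece(ev$pos - r, "ref", list(chrom = ch, start = r, end = ev$pos),
                  NULL, "+", NA, NA)
      }
      parts <- ins_parts[[i]]
      if (ev$strand == "-") {
        parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
        parts$seq <- revcomp(parts$seq)
        parts$ref_strand <- ifelse(is.na(parts$ref_strand), NA,
                                   ifelse(parts$ref_strand == "+", "-", "+"))
      }
      for (k in seq_len(nrow(parts))) {
        pk <- parts[k, ]
        chunks <- c(chunks, pk$seq)
        add_piece(nchar(pk$seq), pk$kind,
                  list(chrom = pk$ref_chrom, start = pk$ref_start, end = pk$ref_end),
                  NULL, if (is.na(pk$ref_strand)) "+" else pk$ref_strand,
                  ev$event_id, ev$class)
      }
      # resume reference: duplicated target site (insertions) or skip (deletion)
      r <- if (ev$class == "deletion") ev$pos + ev$del_len else ev$pos - ev$tsd_len
    }
    if (r < ref$contig_len) {
      chunks <- c(chunks, substring(ref$seqs[[ch]], r + 1L, ref$contig_len))
      add_piece(ref$contig_len - r, "ref",
                list(chrom = ch, start = r, end = ref$contig_len), NULL, "+", NA, NA)
    }
    seqs[[ch]] <- paste(chunks, collapse = "")
  }
  list(pieces = pieces, seqs = seqs)
}

#' Generate paired-end reads from a haplotype
#'
#' Uniform fragment sampling with Gaussian insert sizes and uniform
#' substitution errors. Read pairs are returned as haplotype intervals plus
#' forward-oriented sequences; [align_reads_perfect()] turns them into
#' alignment records.
#'
#' @param hap haplotype from [plant_events()] (or `haplotype_from_reference()`).
#' @param coverage mean sequence coverage (default 38).
#' @param read_len read length (default 100).
#' @param insert_mean,insert_sd fragment-size distribution (default 450/50).
#' @param err_rate per-base substitution error rate (default 0.002).
#' @param seed integer seed.
#' @param prefix read-name prefix.
#' @return data.frame of fragments: contig, start1/end1 (R1, haplotype
#'   coords), start2/end2 (R2), fseq1/fseq2 (haplotype-forward sequences).
#' @export
generate_reads <- function(hap, coverage = 38, read_len = 100L,
                           insert_mean = 450, insert_sd = 50,
                           err_rate = 0.002, seed = 1L, prefix = "frag") {
  if (coverage <= 0) stop("coverage must be positive")
  if (insert_mean < read_len) stop("insert_mean must be >= read_len")
  set.seed(child_seed(seed, paste0("reads_", prefix)))
  out <- NULL
  for (ch in names(hap$seqs)) {
    L <- nchar(hap$seqs[[ch]])
    nf <- as.integer(round(coverage * L / (2 * read_len)))
    flen <- as.integer(pmax(2L * read_len + 10L,
                            round(rnorm(nf, insert_mean, insert_sd))))
    start <- as.integer(floor(runif(nf, 0, pmax(1, L - flen))))
    flen <- pmin(flen, L - start)
    df <- data.frame(
      qname = sprintf("%s_%s_%07d", prefix, ch, seq_len(nf)),
      contig = ch,
      start1 = start, end1 = start + read_len,
      start2 = start + flen - read_len, end2 = start + flen,
      stringsAsFactors = FALSE)
    df$fseq1 <- substring(hap$seqs[[ch]], df$start1 + 1L, df$end1)
    df$fseq2 <- substring(hap$seqs[[ch]], df$start2 + 1L, df$end2)
    out <- rbind(out, df)
  }
  # substitution errors
  if (err_rate > 0) {
    for (col in c("fseq1", "fseq2")) {
      out[[col]] <- add_seq_errors(out[[col]], err_rate)
    }
  }
  out
}

# uniform substitution errors across a character vector of equal-ish reads
add_seq_errors <- function(seqs, err_rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1, total, err_rate)
  if (n_err == 0) return(seqs)
  pos <- sort(sample.int(total, n_err))
  cum <- cumsum(lens)
  ridx <- findInterval(pos - 1L, c(0L, cum), rightmost.closed = FALSE)
  off <- pos - c(0L, cum)[ridx]
  subs <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    i <- ridx[k]; j <- off[k]
    cur <- substr(seqs[i], j, j)
    alt <- sample(setdiff(subs, cur), 1)
    substr(seqs[i], j, j) <- alt
  }
  seqs
}

#' Place simulated reads at their truth coordinates ("perfect aligner")
#'
#' Each read interval is mapped through the haplotype piece map: reads
#' fully inside reference-derived (or transduced/retro-copied, i.e. unique)
#' segments are placed at the corresponding reference coordinates with
#' MAPQ 60 (MAPQ 0 when mostly inside an annotated reference L1 locus);
#' reads straddling a junction are soft-clipped at it when the unique
#' anchor is at least `min_anchor` bp; reads mostly inside repeat consensus
#' or poly(A) sequence are left unmapped with their sequence retained, as a
#' read aligner would with a multi-mapping repeat mate.
#'
#' @param hap haplotype (piece map + sequence).
#' @param frags fragment table from [generate_reads()].
#' @param ref the `sim_reference` (for repeat-locus MAPQ masking).
#' @param min_anchor minimum unique mapped prefix/suffix to place a clipped
#'   read (default 20 bp).
#' @param max_insert proper-pair insert ceiling (default 650).
#' @param sample_id sample label stored on every record.
#' @return alignment records: a data.frame with two rows per pair.
#' @export
align_reads_perfect <- function(hap, frags, ref, min_anchor = 20L,
                                max_insert = 650L, sample_id = "sample") {
  pieces <- hap$pieces
  res <- NULL
  for (ch in unique(frags$contig)) {
    pc <- pieces[pieces$contig == ch, , drop = FALSE]
    pc <- pc[order(pc$hap_start), , drop = FALSE]
    fr <- frags[frags$contig == ch, , drop = FALSE]
    for (endk in 1:2) {
      s <- fr[[paste0("start", endk)]]; e <- fr[[paste0("end", endk)]]
      fseq <- fr[[paste0("fseq", endk)]]
      m <- map_intervals(pc, s, e, fseq, min_anchor)
      m$qname <- fr$qname
      m$is_read1 <- endk == 1L
      res <- rbind(res, m)
    }
  }
  # read strand: R1 sequenced haplotype-forward, R2 haplotype-reverse;
  # flipped again when the piece maps to the reference minus strand
  hapdir <- ifelse(res$is_read1, "+", "-")
  flip <- !is.na(res$piece_strand) & res$piece_strand == "-"
  res$strand <- ifelse(xor(hapdir == "-", flip), "-", "+")
  # SAM-oriented sequence (reference forward for mapped; haplotype forward
  # for unmapped -- orientation is irrelevant downstream)
  res$seq <- res$fseq
  if (any(flip)) res$seq[flip] <- revcomp(res$fseq[flip])
  res$fseq <- NULL

  # MAPQ masking inside annotated reference repeat (source L1) loci
  res$mapq <- ifelse(res$mapped, 60L, 0L)
  if (nrow(ref$sources)) {
    for (i in seq_len(nrow(ref$sources))) {
      srci <- ref$sources[i, ]
      ov <- res$mapped & !is.na(res$chrom) & res$chrom == srci$chrom &
        (pmin(res$end, srci$end) - pmax(res$pos, srci$start)) >=
          0.5 * (res$end - res$pos)
      res$mapq[which(ov)] <- 0L
    }
  }

  # pair mate info
  o <- order(res$qname, !res$is_read1)
  res <- res[o, , drop = FALSE]
  i1 <- seq(1L, nrow(res), by = 2L); i2 <- i1 + 1L
  fill_mate <- function(a, b) {
    res$mate_chrom[a] <<- res$chrom[b]; res$mate_pos[a] <<- res$pos[b]
    res$mate_strand[a] <<- res$strand[b]; res$mate_mapped[a] <<- res$mapped[b]
  }
  res$mate_chrom <- NA_character_; res$mate_pos <- NA_integer_
  res$mate_strand <- NA_character_; res$mate_mapped <- NA
  fill_mate(i1, i2); fill_mate(i2, i1)
  # proper pair: both mapped, same chrom, FR orientation, sane insert
  lo <- pmin(res$pos[i1], res$pos[i2]); hi <- pmax(res$end[i1], res$end[i2])
  proper <- res$mapped[i1] & res$mapped[i2] &
    res$chrom[i1] == res$chrom[i2] &
    res$strand[i1] != res$strand[i2] &
    (hi - lo) <= max_insert &
    ifelse(res$pos[i1] <= res$pos[i2], res$strand[i1] == "+", res$strand[i2] == "+")
  proper[is.na(proper)] <- FALSE
  res$is_proper <- FALSE
  res$is_proper[i1] <- proper; res$is_proper[i2] <- proper
  res$sample_id <- sample_id
  res$piece_strand <- NULL
  rownames(res) <- NULL
  res
}

# vectorised interval mapping through a contig's piece table
map_intervals <- function(pc, s, e, fseq, min_anchor) {
  nb <- length(s)
  p1 <- findInterval(s, pc$hap_start)
  p2 <- findInterval(e - 1L, pc$hap_start)
  unique_kind <- pc$kind %in% c("ref", "flank")
  out <- data.frame(
    chrom = rep(NA_character_, nb), pos = NA_integer_, end = NA_integer_,
    mapped = FALSE, clip5 = 0L, clip3 = 0L, cigar = NA_character_,
    piece_strand = NA_character_, fseq = fseq, stringsAsFactors = FALSE)

  place <- function(rows, pidx, hs, he, c5, c3) {
    # hs/he: mapped haplotype subinterval; c5/c3 clips in haplotype orientation
    pp <- pc[pidx, , drop = FALSE]
    w <- he - hs
    off <- hs - pp$hap_start
    plus <- pp$ref_strand == "+"
    rs <- ifelse(plus, pp$ref_start + off, pp$ref_end - off - w)
    out$chrom[rows] <<- pp$ref_chrom
    out$pos[rows] <<- as.integer(rs)
    out$end[rows] <<- as.integer(rs + w)
    out$mapped[rows] <<- TRUE
    # clips flip with strand
    cc5 <- ifelse(plus, c5, c3); cc3 <- ifelse(plus, c3, c5)
    out$clip5[rows] <<- as.integer(cc5); out$clip3[rows] <<- as.integer(cc3)
    out$cigar[rows] <<- paste0(ifelse(cc5 > 0, paste0(cc5, "S"), ""),
                               w, "M",
                               ifelse(cc3 > 0, paste0(cc3, "S"), ""))
    out$piece_strand[rows] <<- pp$ref_strand
  }

  same <- p1 == p2
  ok <- same & unique_kind[p1]
  if (any(ok)) place(which(ok), p1[ok], s[ok], e[ok], 0L, 0L)

  span <- which(!same)
  if (length(span)) {
    len1 <- pc$hap_end[p1[span]] - s[span]          # unique-prefix candidate
    len2 <- e[span] - pc$hap_start[p2[span]]        # unique-suffix candidate
    u1 <- unique_kind[p1[span]]; u2 <- unique_kind[p2[span]]
    len1[!u1] <- -1L; len2[!u2] <- -1L
    use1 <- len1 >= min_anchor & len1 >= len2
    use2 <- !use1 & len2 >= min_anchor
    w <- span[use1]
    if (length(w)) place(w, p1[w], s[w], pc$hap_end[p1[w]],
                         0L, e[w] - pc$hap_end[p1[w]])
    w <- span[use2]
    if (length(w)) place(w, p2[w], pc$hap_start[p2[w]], e[w],
                         pc$hap_start[p2[w]] - s[w], 0L)
  }
  out
}

#' Mix tumor and normal read pairs to a target clonality
#'
#' Subsamples tumor-haplotype read pairs to `fraction` and tops up with
#' normal-haplotype pairs to `depth_target_pairs` total pairs (defaults to
#' the tumor pair count), emulating subclonal tumors by read mixing.
#' Operates on alignment-record tables (two rows per pair), so each read
#' set retains the placement of its own haplotype.
#'
#' @param tumor_aln,normal_aln alignment tables from [align_reads_perfect()].
#' @param fraction tumor fraction in (0, 1].
#' @param depth_target_pairs total pairs after mixing.
#' @param seed integer seed.
#' @return an alignment table.
#' @export
mix_clonality <- function(tumor_aln, normal_aln, fraction,
                          depth_target_pairs = length(unique(tumor_aln$qname)),
                          seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(child_seed(seed, paste0("mix", fraction)))
  tq <- unique(tumor_aln$qname)
  keep <- tq[runif(length(tq)) < fraction]
  tk <- tumor_aln[tumor_aln$qname %in% keep, , drop = FALSE]
  need <- max(0L, depth_target_pairs - length(keep))
  if (need > 0) {
    nq <- unique(normal_aln$qname)
    if (need > length(nq)) {
      warning("normal pair pool smaller than top-up; using all of it")
      need <- length(nq)
    }
    add <- normal_aln[normal_aln$qname %in% sample(nq, need), , drop = FALSE]
    add$qname <- paste0("mixn_", add$qname)
    tk <- rbind(tk, add)
  }
  rownames(tk) <- NULL
  tk
}

#' Score calls against the simulation truth registry
#'
#' Greedy one-to-one matching by class and breakpoint position within
#' `pos_tol`; each truth event is matched at most once, duplicate calls on
#' one event count as false positives.
#'
#' @param calls data.frame with columns `class`, `chrom`, `pos`.
#' @param truth truth registry from [plant_events()] (germline rows are
#'   ignored).
#' @param pos_tol matching tolerance in bp (default 150).
#' @param classes optional subset of truth classes to score against.
#' @return list with tp, fp, fn, precision, recall.
#' @export
evaluate_calls <- function(calls, truth, pos_tol = 150L, classes = NULL) {
  truth <- truth[!truth$germline, , drop = FALSE]
  if (!is.null(classes)) truth <- truth[truth$class %in% classes, , drop = FALSE]
  used <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  if (!is.null(calls) && nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      cand <- which(!used & truth$class == calls$class[i] &
                    truth$chrom == calls$chrom[i] &
                    abs(truth$pos - calls$pos[i]) <= pos_tol)
      if (length(cand)) {
        j <- cand[which.min(abs(truth$pos[cand] - calls$pos[i]))]
        used[j] <- TRUE; tp <- tp + 1L
      } else fp <- fp + 1L
    }
  }
  fn <- sum(!used)
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' A haplotype identical to the reference (no events)
#' @param ref a `sim_reference`.
#' @return haplotype list (piece map + sequences).
#' @export
haplotype_from_reference <- function(ref) {
  pieces <- do.call(rbind, lapply(names(ref$seqs), function(ch)
    data.frame(contig = ch, hap_start = 0L, hap_end = ref$contig_len,
               kind = "ref", ref_chrom = ch, ref_start = 0L,
               ref_end = ref$contig_len, ref_strand = "+",
               event_id = NA_character_, class = NA_character_,
               stringsAsFactors = FALSE)))
  list(pieces = pieces, seqs = as.list(ref$seqs))
}
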
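# Base-pair breakpoint resolution and insertion characterization: clipped
# read consensus, poly(A) tract, target-site duplication, L1-endonuclease
# motif, subfamily/length estimation, and the aggregation of a reciprocal
# cluster pair into a fully characterized insertion call.

#' Resolve a breakpoint from soft-clipped reads
#'
#' The modal clip position among soft-clipped reads becomes the breakpoint
#' (leftmost position on ties, for determinism), with a majority-vote
#' consensus of the clipped tails; with no clipped reads the cluster inner
#' edge is reported as an imprecise breakpoint.
#'
#' @param clip_pos integer vector of clip positions (0-based; for a 5'-side
#'   breakpoint these are read ends, for a 3'-side breakpoint read starts).
#' @param clip_seq character vector of clipped tail sequences, parallel to
#'   `clip_pos`.
#' @param anchor `"start"` when tails extend right from the junction (5'
#'   side), `"end"` when tails end at the junction (3' side).
#' @param fallback_pos cluster inner edge used when no clips are present.
#' @return list: `pos`, `precise`, `consensus_seq`, `support_clipped`.
#' @export
assemble_breakpoint <- function(clip_pos, clip_seq, anchor = c("start", "end"),
                                fallback_pos = NA_integer_) {
  anchor <- match.arg(anchor)
  if (length(clip_pos) == 0)
    return(list(pos = as.integer(fallback_pos), precise = FALSE,
                consensus_seq = NULL, support_clipped = 0L))
  tab <- table(clip_pos)
  modal <- as.integer(names(tab)[tab == max(tab)])
  pos <- min(modal)  # leftmost modal position
  sel <- clip_pos == pos
  cons <- consensus_vote(clip_seq[sel], anchor)
  list(pos = pos, precise = TRUE, consensus_seq = cons,
       support_clipped = sum(sel))
}

# majority-vote consensus of tails aligned at the junction
consensus_vote <- function(seqs, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0) return("")
  if (length(seqs) == 1) return(seqs)
  if (anchor == "end") {
    rev1 <- function(s) vapply(strsplit(s, ""), function(x)
      paste(rev(x), collapse = ""), "")
    return(rev1(consensus_vote(rev1(seqs), "start")))
  }
  L <- max(nchar(seqs))
  m <- vapply(seqs, function(s) {
    x <- strsplit(s, "")[[1]]
    c(x, rep(NA_character_, L - length(x)))
  }, character(L))
  if (is.null(dim(m))) m <- matrix(m, nrow = L)
  cons <- apply(m, 1, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    names(sort(table(col), decreasing = TRUE))[1]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Measure a terminal poly(A) tract
#'
#' Length of the longest terminal (3'-end) window with an A fraction of at
#' least `min_purity` and length at least `min_len`; 0 when none
#' qualifies. Case-insensitive; pass the reverse complement to measure a
#' poly(T) head.
#'
#' @param seq DNA string (the breakpoint consensus tail).
#' @param min_len minimum tract length (default 10).
#' @param min_purity minimum A fraction (default 0.8).
#' @return integer tract length.
#' @export
detect_polyA <- function(seq, min_len = 10L, min_purity = 0.8) {
  if (is.null(seq) || is.na(seq) || nchar(seq) == 0) return(0L)
  x <- rev(strsplit(toupper(seq), "")[[1]]) == "A"
  frac <- cumsum(x) / seq_along(x)
  # a tract starts at an A: windows opening on a non-A base are not tracts
  ok <- which(frac >= min_purity & seq_along(x) >= min_len & x)
  if (length(ok) == 0) 0L else max(ok)
}

#' Target-site duplication or target-site deletion between breakpoints
#'
#' When the 3'-side breakpoint lies `d` bp left of the 5'-side breakpoint
#' (d <= `max_tsd`) the target site was duplicated and the TSD sequence is
#' read from the reference; when it lies at or right of it the insertion
#' deleted (or bluntly joined, width 0) target sequence.
#'
#' @param bkp5,bkp3 breakpoint lists (need `chrom` and `pos`).
#' @param ref_seqs named character vector/list of reference contig
#'   sequences.
#' @param max_tsd maximum credible TSD length (default 50).
#' @return list with either `tsd_len`/`tsd_seq` or `deletion_at_target`.
#' @export
detect_tsd <- function(bkp5, bkp3, ref_seqs, max_tsd = 50L) {
  if (!identical(bkp5$chrom, bkp3$chrom))
    stop("breakpoints on different chromosomes: not a target-site question")
  d <- bkp5$pos - bkp3$pos
  if (d > 0 && d <= max_tsd) {
    seq <- substring(ref_seqs[[bkp5$chrom]], bkp3$pos + 1L, bkp5$pos)
    list(tsd_len = as.integer(d), tsd_seq = seq, deletion_at_target = NA_integer_)
  } else if (d <= 0) {
    list(tsd_len = NA_integer_, tsd_seq = NA_character_,
         deletion_at_target = as.integer(-d))
  } else {
    list(tsd_len = NA_integer_, tsd_seq = NA_character_,
         deletion_at_target = NA_integer_)  # unresolved (d > max_tsd)
  }
}

#' Match the L1-endonuclease cleavage motif near a breakpoint
#'
#' Scans `window` bp around the breakpoint for the best match to the
#' degenerate cleavage motif TTTT|R on the plus strand or Y|AAAA on the
#' minus strand (R = A/G, Y = C/T; "|" the cleavage point). Best = fewest
#' mismatches, then nearest to the breakpoint, then plus strand. The
#' mismatch count (0-5) is always computed; matches with more than
#' `max_mismatch` mismatches return NULL.
#'
#' @param ref_seqs named contig sequences.
#' @param chrom,pos breakpoint (0-based cleavage position).
#' @param window scan half-width in bp (default 10).
#' @param max_mismatch reporting threshold (default 3).
#' @return list(site_seq, mismatches, cleavage_offset, strand) or NULL.
#' @export
match_en_motif <- function(ref_seqs, chrom, pos, window = 10L, max_mismatch = 3L) {
  L <- nchar(ref_seqs[[chrom]])
  best <- NULL
  for (off in -window:window) {
    c0 <- pos + off
    # plus strand: TTTT | R  (5-mer = [c0-4, c0+1))
    if (c0 - 4 >= 0 && c0 + 1 <= L) {
      s <- substring(ref_seqs[[chrom]], c0 - 3L, c0 + 1L)
      mm <- motif_mismatches(s, "TTTTR")
      best <- en_better(best, list(site_seq = s, mismatches = mm,
                                   cleavage_offset = off, strand = "+"))
    }
    # minus strand: Y | AAAA (5-mer = [c0-1, c0+4))
    if (c0 - 1 >= 0 && c0 + 4 <= L) {
      s <- substring(ref_seqs[[chrom]], c0, c0 + 4L)
      mm <- motif_mismatches(s, "YAAAA")
      best <- en_better(best, list(site_seq = s, mismatches = mm,
                                   cleavage_offset = off, strand = "-"))
    }
  }
  if (is.null(best) || best$mismatches > max_mismatch) return(NULL)
  best
}

motif_mismatches <- function(s, motif) {
  s <- toupper(s)
  if (nchar(s) != 5) return(5L)
  pat <- switch(motif,
                TTTTR = list(c("T"), c("T"), c("T"), c("T"), c("A", "G")),
                YAAAA = list(c("C", "T"), c("A"), c("A"), c("A"), c("A")))
  x <- strsplit(s, "")[[1]]
  sum(vapply(1:5, function(i) !(x[i] %in% pat[[i]]), logical(1)))
}

en_better <- function(cur, new) {
  if (is.null(cur)) return(new)
  if (new$mismatches < cur$mismatches) return(new)
  if (new$mismatches == cur$mismatches &&
      abs(new$cleavage_offset) < abs(cur$cleavage_offset)) return(new)
  cur
}

# gather clipped reads near a junction search region
clipped_in_region <- function(aln, chrom, from, to, side = c("clip3", "clip5"),
                              min_clip = 5L) {
  side <- match.arg(side)
  if (side == "clip3") {
    sel <- aln$mapped & aln$chrom == chrom & aln$clip3 >= min_clip &
      aln$end >= from & aln$end <= to
    sel[is.na(sel)] <- FALSE
    rows <- aln[sel, , drop = FALSE]
    list(pos = rows$end,
         seq = substring(rows$seq, nchar(rows$seq) - rows$clip3 + 1L))
  } else {
    sel <- aln$mapped & aln$chrom == chrom & aln$clip5 >= min_clip &
      aln$pos >= from & aln$pos <= to
    sel[is.na(sel)] <- FALSE
    rows <- aln[sel, , drop = FALSE]
    list(pos = rows$pos, seq = substring(rows$seq, 1L, rows$clip5))
  }
}

# cluster distal mate intervals of a pair's members; returns the dominant
# distal interval or NULL
dominant_distal_interval <- function(members, exclude_chrom = NULL,
                                     exclude_pos = NULL, exclude_radius = 5000L,
                                     link = 2000L) {
  d <- members[members$mate_kind == "distal", , drop = FALSE]
  if (!is.null(exclude_chrom) && nrow(d)) {
    drop <- d$mate_chrom == exclude_chrom &
      abs((d$mate_start + d$mate_end) / 2 - exclude_pos) <= exclude_radius
    d <- d[!drop, , drop = FALSE]
  }
  if (nrow(d) == 0) return(NULL)
  best <- NULL
  for (ch in unique(d$mate_chrom)) {
    s <- d[d$mate_chrom == ch, , drop = FALSE]
    s <- s[order(s$mate_start), , drop = FALSE]
    grp <- c(0L, cumsum(diff(s$mate_start) > link))
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      if (is.null(best) || nrow(m) > best$support)
        best <- list(chrom = ch, start = min(m$mate_start),
                     end = max(m$mate_end), support = nrow(m))
    }
  }
  best
}

#' Characterize a reciprocal cluster pair as an insertion call
#'
#' Aggregates breakpoint assembly on both sides, poly(A)/poly(T)
#' measurement, target-site duplication, endonuclease-motif matching,
#' subfamily assignment (best consensus hit over supporting mates), length
#' estimation from consensus coverage, and solo/transduction
#' classification. Pairs whose two sides classify to conflicting element
#' classes are rejected (reason recorded in the `reject` attribute of the
#' NULL return).
#'
#' @param plus,minus one-row cluster data.frames (positive and negative).
#' @param aln tumor alignment table (for clipped-read rescue).
#' @param ref_seqs named contig sequences.
#' @param library consensus library.
#' @param registry source-element registry (may be NULL: no transduction
#'   tracing).
#' @param sample_id sample label.
#' @param en_window,max_tsd tuning of motif scan and TSD cap.
#' @return one-row `data.frame` MEI call, or an object of class
#'   `mei_reject` whose `reject` element names the reason.
#' @export
characterize_insertion <- function(plus, minus, aln, ref_seqs, library,
                                   registry = NULL, sample_id = "tumor",
                                   en_window = 10L, max_tsd = 50L) {
  mp <- plus$members[[1]]; mm <- minus$members[[1]]
  reject <- function(why) structure(list(reject = why), class = "mei_reject")

  cons_cls <- function(m) m$mate_class[!is.na(m$mate_class) &
                                       m$mate_class %in% MEI_CLASSES]
  cp <- cons_cls(mp); cm <- cons_cls(mm)
  maj <- function(x) if (length(x)) names(sort(table(x), decreasing = TRUE))[1] else NA
  if (length(cp) && length(cm) && maj(cp) != maj(cm))
    return(reject("class_conflict"))
  el_class <- maj(c(cp, cm))

  # breakpoints: 5' side from right-clipped reads near the positive cluster
  # inner edge, 3' side from left-clipped reads near the negative one
  region5 <- c(plus$end - 400L, minus$start + 200L)
  region3 <- c(plus$end - 200L, minus$start + 400L)
  cl5 <- clipped_in_region(aln, plus$chrom, region5[1], region5[2], "clip3")
  cl3 <- clipped_in_region(aln, plus$chrom, region3[1], region3[2], "clip5")
  bkp5 <- assemble_breakpoint(cl5$pos, cl5$seq, "start", fallback_pos = plus$end)
  bkp3 <- assemble_breakpoint(cl3$pos, cl3$seq, "end", fallback_pos = minus$start)
  bkp5$chrom <- plus$chrom; bkp3$chrom <- minus$chrom

  # poly(A) at the 3' junction (plus-strand element) or poly(T) at the 5'
  # junction (minus-strand element)
  pa3 <- detect_polyA(bkp3$consensus_seq %||% "")
  pa5 <- if (!is.null(bkp5$consensus_seq) && nchar(bkp5$consensus_seq))
    detect_polyA(revcomp(bkp5$consensus_seq)) else 0L
  polyA_len <- max(pa3, pa5)
  # mate poly(A) support as weak fallback evidence
  polyA_mates <- sum(c(mp$mate_class, mm$mate_class) == "polyA", na.rm = TRUE)

  # element strand: majority orientation of repeat-mate hits, else poly(A) side
  orients <- c(mp$mate_orient, mm$mate_orient)
  orients <- orients[!is.na(orients)]
  strand <- if (length(orients)) maj(orients)
            else if (pa5 > pa3) "-" else "+"

  tsd <- if (bkp5$precise && bkp3$precise)
    detect_tsd(bkp5, bkp3, ref_seqs, max_tsd = max_tsd)
  else list(tsd_len = NA_integer_, tsd_seq = NA_character_,
            deletion_at_target = NA_integer_)

  en <- if (bkp5$precise)
    match_en_motif(ref_seqs, bkp5$chrom, bkp5$pos, window = en_window)
  else NULL

  # distal unique mates -> candidate transduced interval
  mid <- (plus$end + minus$start) %/% 2L
  td <- dominant_distal_interval(rbind(mp, mm), exclude_chrom = plus$chrom,
                                 exclude_pos = mid)
  tdc <- identify_transductions(
    has_l1 = !is.na(el_class) && el_class == "L1",
    el_class = el_class, td = td, polyA_len = polyA_len,
    polyA_mates = polyA_mates, registry = registry)
  if (!is.null(tdc$reject)) return(reject(tdc$reject))

  # subfamily and length from consensus coverage of supporting mates
  cons_rows <- rbind(mp, mm)
  cons_rows <- cons_rows[!is.na(cons_rows$mate_class) &
                         cons_rows$mate_class %in% MEI_CLASSES, , drop = FALSE]
  subfamily <- maj(cons_rows$mate_subfamily)
  cons_span <- if (nrow(cons_rows))
    max(cons_rows$mate_ce) - min(cons_rows$mate_cs) else 0L
  td_len <- if (!is.null(td)) td$end - td$start else 0L
  inserted_len <- cons_span + td_len + polyA_len

  data.frame(
    sample_id = sample_id, class = tdc$class, chrom = plus$chrom,
    pos = bkp5$pos, bkp5_pos = bkp5$pos, bkp5_precise = bkp5$precise,
    bkp3_pos = bkp3$pos, bkp3_precise = bkp3$precise,
    strand = strand, inserted_len = as.integer(inserted_len),
    subfamily = subfamily, polyA_len = as.integer(polyA_len),
    tsd_len = tsd$tsd_len, tsd_seq = tsd$tsd_seq,
    target_del_len = tsd$deletion_at_target,
    en_site = if (is.null(en)) NA_character_ else en$site_seq,
    en_mismatch = if (is.null(en)) NA_integer_ else en$mismatches,
    en_offset = if (is.null(en)) NA_integer_ else en$cleavage_offset,
    en_strand = if (is.null(en)) NA_character_ else en$strand,
    src_id = tdc$src_id, td_chrom = tdc$td_chrom,
    td_start = tdc$td_start, td_end = tdc$td_end,
    src_gene = NA_character_,
    status = if (bkp5$precise && bkp3$precise) "precise" else "imprecise",
    support = plus$support + minus$support,
    support_clipped = bkp5$support_clipped + bkp3$support_clipped,
    plus_id = plus$cluster_id, minus_id = minus$cluster_id,
    stringsAsFactors = FALSE)
}
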
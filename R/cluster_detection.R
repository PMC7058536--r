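# Discordant read-pair selection, strand-oriented clustering, reciprocal
# pairing and matched-normal subtraction. A "positive" cluster is anchored
# on + strand reads upstream of the insertion point (supporting its 5'
# side); a "negative" cluster on - strand reads downstream. This convention
# is used by every downstream module.

#' Select discordant read-pair candidates
#'
#' Keeps read pairs that are not proper pairs and have one uniquely mapped
#' anchor (MAPQ >= `mapq_floor`). The mate is either unmapped with repeat
#' sequence content (classified against the consensus library; a >= 80%
#' A or T mate is labelled `polyA`) or uniquely mapped at a distal locus
#' (other chromosome, or farther than `max_insert`). The anchor strand sets
#' the cluster side.
#'
#' @param aln alignment table ([read_alignments()] / [align_reads_perfect()]).
#' @param library consensus library.
#' @param mapq_floor anchor mapping-quality floor (default 20).
#' @param max_insert distance beyond which a mapped mate counts as distal
#'   (default 1000).
#' @param min_identity,min_len classification thresholds (see
#'   [classify_read()]).
#' @return data.frame of candidates, one row per (anchor, mate) with
#'   columns chrom/start/end/strand/side/mate_kind/mate_class/... .
#' @export
select_discordant_pairs <- function(aln, library, mapq_floor = 20L,
                                    max_insert = 1000L,
                                    min_identity = 0.85, min_len = 30L) {
  o <- order(aln$qname, !aln$is_read1)
  aln <- aln[o, , drop = FALSE]
  n <- nrow(aln)
  if (n %% 2L != 0L) stop("alignment table must contain complete pairs")
  i1 <- seq(1L, n, by = 2L); i2 <- i1 + 1L
  if (any(aln$qname[i1] != aln$qname[i2])) stop("unpaired records in alignment table")

  cand_for <- function(a, b) {
    # a = anchor rows index, b = mate rows index (parallel)
    ok <- aln$mapped[a] & aln$mapq[a] >= mapq_floor & !aln$is_proper[a]
    a <- a[ok]; b <- b[ok]
    mate_unmapped <- !aln$mapped[b]
    distal <- aln$mapped[b] & aln$mapq[b] >= mapq_floor &
      (aln$chrom[b] != aln$chrom[a] |
         pmax(aln$pos[a], aln$pos[b]) - pmin(aln$end[a], aln$end[b]) > max_insert)
    keep <- mate_unmapped | distal
    a <- a[keep]; b <- b[keep]
    data.frame(
      qname = aln$qname[a], sample_id = aln$sample_id[a],
      chrom = aln$chrom[a], start = aln$pos[a], end = aln$end[a],
      strand = aln$strand[a],
      side = ifelse(aln$strand[a] == "+", "positive", "negative"),
      mate_kind = ifelse(aln$mapped[b], "distal", "repeat"),
      mate_seq = ifelse(aln$mapped[b], NA_character_, aln$seq[b]),
      mate_chrom = ifelse(aln$mapped[b], aln$chrom[b], NA_character_),
      mate_start = ifelse(aln$mapped[b], aln$pos[b], NA_integer_),
      mate_end = ifelse(aln$mapped[b], aln$end[b], NA_integer_),
      stringsAsFactors = FALSE)
  }
  cands <- rbind(cand_for(i1, i2), cand_for(i2, i1))
  nc <- nrow(cands)
  cands$mate_class <- rep(NA_character_, nc)
  cands$mate_subfamily <- rep(NA_character_, nc)
  cands$mate_identity <- rep(NA_real_, nc)
  cands$mate_cs <- rep(NA_integer_, nc)
  cands$mate_ce <- rep(NA_integer_, nc)
  cands$mate_orient <- rep(NA_character_, nc)

  rep_rows <- which(cands$mate_kind == "repeat")
  if (length(rep_rows)) {
    seqs <- cands$mate_seq[rep_rows]
    # quick poly(A)/poly(T) labelling before alignment-based classification
    base_frac <- function(s, b) {
      (nchar(s) - nchar(gsub(b, "", s, fixed = TRUE))) / pmax(1L, nchar(s))
    }
    pa <- base_frac(seqs, "A") >= 0.8 | base_frac(seqs, "T") >= 0.8
    hit <- classify_read(seqs[!pa], library, min_identity = min_identity,
                         min_len = min_len)
    cands$mate_class[rep_rows[pa]] <- "polyA"
    idx <- rep_rows[!pa]
    cands$mate_class[idx] <- hit$class_name
    cands$mate_subfamily[idx] <- hit$subfamily
    cands$mate_identity[idx] <- hit$identity
    cands$mate_cs[idx] <- hit$consensus_start
    cands$mate_ce[idx] <- hit$consensus_end
    cands$mate_orient[idx] <- hit$read_orientation
  }
  cands <- cands[order(cands$chrom, cands$start), , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Cluster discordant candidates by position and side
#'
#' Single-linkage clustering per (chromosome, side): consecutive anchor
#' starts at most `max_gap` apart join one cluster; clusters with fewer
#' than `min_support` candidates are discarded. The dominant class is the
#' majority mate class ("unique" when distal mates dominate).
#'
#' @param cands candidate table from [select_discordant_pairs()].
#' @param max_gap single-linkage gap in bp (default 400).
#' @param min_support minimum supporting read pairs (default 3).
#' @return data.frame of clusters with a `members` list-column.
#' @export
build_clusters <- function(cands, max_gap = 400L, min_support = 3L) {
  out <- NULL
  if (is.null(cands) || nrow(cands) == 0) return(empty_clusters())
  for (key in unique(paste(cands$chrom, cands$side))) {
    sub <- cands[paste(cands$chrom, cands$side) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    brk <- c(0L, cumsum(diff(sub$start) > max_gap))
    for (g in unique(brk)) {
      mem <- sub[brk == g, , drop = FALSE]
      if (nrow(mem) < min_support) next
      cls <- mem$mate_class[!is.na(mem$mate_class) & mem$mate_class != "polyA"]
      n_uni <- sum(mem$mate_kind == "distal")
      dominant <- if (length(cls) >= n_uni && length(cls) > 0)
        names(sort(table(cls), decreasing = TRUE))[1]
      else if (n_uni > 0) "unique" else NA_character_
      out <- rbind(out, data.frame(
        chrom = mem$chrom[1], start = min(mem$start), end = max(mem$end),
        side = mem$side[1], support = nrow(mem), dominant_class = dominant,
        normal_support = 0L, members = I(list(mem)), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(empty_clusters())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$cluster_id <- sprintf("CL%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_clusters <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             side = character(), support = integer(),
             dominant_class = character(), normal_support = integer(),
             members = I(list()), cluster_id = character(),
             stringsAsFactors = FALSE)
}

#' Pair reciprocal positive/negative clusters
#'
#' Greedy nearest-match pairing of positive clusters with adjacent negative
#' clusters within `reciprocal_window` bp (gap measured from the positive
#' cluster end to the negative cluster start; small negative gaps arise
#' from target-site duplications). Unpaired clusters are returned as
#' orphans, the inputs to L1-rearrangement detection.
#'
#' @param clusters cluster table from [build_clusters()].
#' @param reciprocal_window pairing window in bp (default 500).
#' @return list with `pairs` (data.frame with plus_id/minus_id/gap_bp) and
#'   `orphans` (cluster table).
#' @export
pair_reciprocal <- function(clusters, reciprocal_window = 500L) {
  if (nrow(clusters) == 0)
    return(list(pairs = data.frame(plus_id = character(), minus_id = character(),
                                   gap_bp = integer()), orphans = clusters))
  pos <- clusters[clusters$side == "positive", , drop = FALSE]
  neg <- clusters[clusters$side == "negative", , drop = FALSE]
  cand <- NULL
  for (i in seq_len(nrow(pos))) {
    j <- which(neg$chrom == pos$chrom[i] &
               abs(neg$start - pos$end[i]) <= reciprocal_window)
    if (length(j))
      cand <- rbind(cand, data.frame(
        pi = i, ni = j, gap = neg$start[j] - pos$end[i]))
  }
  pairs <- data.frame(plus_id = character(), minus_id = character(),
                      gap_bp = integer(), stringsAsFactors = FALSE)
  used_p <- logical(nrow(pos)); used_n <- logical(nrow(neg))
  if (!is.null(cand)) {
    cand <- cand[order(abs(cand$gap)), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      if (used_p[cand$pi[k]] || used_n[cand$ni[k]]) next
      used_p[cand$pi[k]] <- TRUE; used_n[cand$ni[k]] <- TRUE
      pairs <- rbind(pairs, data.frame(
        plus_id = pos$cluster_id[cand$pi[k]],
        minus_id = neg$cluster_id[cand$ni[k]],
        gap_bp = cand$gap[k], stringsAsFactors = FALSE))
    }
  }
  orphans <- rbind(pos[!used_p, , drop = FALSE], neg[!used_n, , drop = FALSE])
  rownames(orphans) <- NULL
  list(pairs = pairs, orphans = orphans)
}

#' Remove clusters with matched-normal support or panel overlap
#'
#' Counts normal-sample discordant candidates of the same side and
#' compatible mate class within the cluster interval extended by `window`,
#' stores the count, and removes clusters exceeding `max_normal_support`
#' (germline events) or overlapping a germline panel interval.
#'
#' @param clusters tumor cluster table.
#' @param normal_cands candidate table from the matched normal
#'   ([select_discordant_pairs()] on the normal alignments).
#' @param panel optional data.frame of germline panel intervals
#'   (chrom/start/end).
#' @param max_normal_support maximum tolerated normal support (default 0).
#' @param window interval extension in bp (default 200).
#' @return filtered cluster table with `normal_support` filled in.
#' @export
subtract_normal <- function(clusters, normal_cands, panel = NULL,
                            max_normal_support = 0L, window = 200L) {
  if (nrow(clusters) == 0) return(clusters)
  ns <- integer(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    if (is.null(normal_cands) || nrow(normal_cands) == 0) { ns[i] <- 0L; next }
    hit <- normal_cands$chrom == cl$chrom & normal_cands$side == cl$side &
      normal_cands$start >= cl$start - window &
      normal_cands$start <= cl$end + window
    if (!is.na(cl$dominant_class) && cl$dominant_class != "unique")
      hit <- hit & (!is.na(normal_cands$mate_class) &
                    normal_cands$mate_class %in% c(cl$dominant_class, "polyA"))
    ns[i] <- sum(hit)
  }
  clusters$normal_support <- ns
  keep <- ns <= max_normal_support
  if (!is.null(panel) && nrow(panel)) {
    for (i in seq_len(nrow(clusters))) {
      if (any(panel$chrom == clusters$chrom[i] &
              panel$start < clusters$end[i] + window &
              panel$end > clusters$start[i] - window))
        keep[i] <- FALSE
    }
  }
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
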
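# L1-mediated deletion detection and related rearrangement flagging.
# Two strategies: (1) copy-number matched -- loss segments whose breakpoints
# match independent (orphan) L1 clusters in the right orientations, and
# (2) read-depth drop for deletions under 100 kb -- a tumor/normal
# normalized depth ratio on both sides of each cluster, tested against an
# empirical null resampled from the genome and Benjamini-Hochberg
# adjusted, with tier 1 (both clusters P < 0.1) and tier 2 (one cluster).
# The "single L1 event" structural check is an explicit orientation/content
# rule table: 5' L1 (or transduction) content on the plus side, poly(A) on
# the minus side, consistent element identity, and no target-site
# duplication.

#' Per-base read-depth vectors from an alignment table
#'
#' @param aln alignment table (mapped primary reads).
#' @param contig_lengths named integer vector.
#' @return named list of integer depth vectors (Rle).
#' @export
depth_track <- function(aln, contig_lengths) {
  out <- list()
  for (ch in names(contig_lengths)) {
    sel <- !is.na(aln$chrom) & aln$chrom == ch & aln$mapped
    ir <- IRanges::IRanges(aln$pos[sel] + 1L, aln$end[sel])
    out[[ch]] <- IRanges::coverage(ir, width = contig_lengths[[ch]])
  }
  out
}

# mean depth in a 0-based half-open window from a coverage Rle (cumsum view)
window_depth <- function(cov, start, end) {
  start <- max(0L, start); end <- min(length(cov), end)
  if (end <= start) return(NA_real_)
  mean(S4Vectors::runValue(S4Vectors::runsum(cov[(start + 1L):end], end - start)))
}

# simpler exact mean via views
mean_depth <- function(cov, start, end) {
  start <- max(0L, as.integer(start)); end <- min(length(cov), as.integer(end))
  if (end <= start) return(NA_real_)
  as.numeric(sum(S4Vectors::window(cov, start + 1L, end))) / (end - start)
}

#' Tumor/normal read-depth drop ratio at a cluster edge
#'
#' Normalizes tumor depth by the matched normal on each side of the
#' cluster and returns the ratio (putative-deletion side over outer side).
#' Buffer regions of `buffer` bp adjacent to the cluster are omitted to
#' avoid artifacts from local repeats.
#'
#' @param cov_t,cov_n depth tracks ([depth_track()]) for tumor and normal.
#' @param chrom contig.
#' @param cluster one-row cluster (start/end/side).
#' @param inward `"right"` when the putative deletion extends right of the
#'   cluster (positive cluster), `"left"` otherwise.
#' @param window window size in bp (200-5000).
#' @param buffer omitted buffer adjacent to the cluster (default 300).
#' @return list(ratio, t_in, n_in, t_out, n_out) or NULL when a window has
#'   no normal depth.
#' @export
depth_ratio <- function(cov_t, cov_n, chrom, cluster, inward = "right",
                        window = 1000L, buffer = 300L) {
  if (window < 200L || window > 5000L) stop("window must be within 200-5000 bp")
  ct <- cov_t[[chrom]]; cn <- cov_n[[chrom]]
  if (inward == "right") {
    in_s <- cluster$end + buffer; in_e <- in_s + window
    out_e <- cluster$start - buffer; out_s <- out_e - window
  } else {
    in_e <- cluster$start - buffer; in_s <- in_e - window
    out_s <- cluster$end + buffer; out_e <- out_s + window
  }
  t_in <- mean_depth(ct, in_s, in_e); n_in <- mean_depth(cn, in_s, in_e)
  t_out <- mean_depth(ct, out_s, out_e); n_out <- mean_depth(cn, out_s, out_e)
  if (anyNA(c(t_in, n_in, t_out, n_out)) || n_in == 0 || n_out == 0 || t_out == 0)
    return(NULL)
  list(ratio = (t_in / n_in) / (t_out / n_out),
       t_in = t_in, n_in = n_in, t_out = t_out, n_out = n_out)
}

#' Empirical null distribution of read-depth ratios
#'
#' Ratios computed at randomly sampled genomic locations (drawn from the
#' provided segments, intended to be those at the sample's predominant
#' copy number), comparing normalized depth right vs left of each
#' location with the same windows/buffers as the observed tests.
#'
#' @param cov_t,cov_n depth tracks.
#' @param segments data.frame chrom/start/end to sample from.
#' @param n_locations number of sampled locations (default 1e5; use ~1e4
#'   for fast desk-scale runs).
#' @param window,buffer as in [depth_ratio()].
#' @param seed integer seed.
#' @return sorted numeric vector of null ratios (class `depth_null`).
#' @export
depth_drop_null <- function(cov_t, cov_n, segments, n_locations = 100000L,
                            window = 1000L, buffer = 300L, seed = 1L) {
  set.seed(child_seed(seed, "depthnull"))
  seglen <- segments$end - segments$start
  avail <- sum(pmax(0, seglen - 2 * (window + buffer)))
  if (avail <= 0) stop("segments too small for the chosen window/buffer")
  if (n_locations > avail) {
    warning("n_locations exceeds available positions; sampling with replacement")
  }
  segi <- sample.int(nrow(segments), n_locations, replace = TRUE,
                     prob = pmax(0, seglen - 2 * (window + buffer)))
  off <- floor(runif(n_locations) *
                 (seglen[segi] - 2 * (window + buffer))) + window + buffer
  pos <- segments$start[segi] + off
  ch <- segments$chrom[segi]
  ratios <- rep(NA_real_, n_locations)
  for (cc in unique(ch)) {
    idx <- which(ch == cc)
    ct <- cov_t[[cc]]; cn <- cov_n[[cc]]
    # vectorised window sums via cumulative coverage
    cum_t <- c(0, cumsum(as.numeric(ct)))
    cum_n <- c(0, cumsum(as.numeric(cn)))
    wsum <- function(cum, s, e) cum[pmin(length(cum), e + 1L)] - cum[pmax(1L, s + 1L)]
    p <- pos[idx]
    t_r <- wsum(cum_t, p + buffer, p + buffer + window)
    n_r <- wsum(cum_n, p + buffer, p + buffer + window)
    t_l <- wsum(cum_t, p - buffer - window, p - buffer)
    n_l <- wsum(cum_n, p - buffer - window, p - buffer)
    ok <- n_r > 0 & n_l > 0 & t_l > 0
    ratios[idx[ok]] <- (t_r[ok] / n_r[ok]) / (t_l[ok] / n_l[ok])
  }
  ratios <- sort(ratios[!is.na(ratios)])
  structure(ratios, class = "depth_null")
}

#' Left-tail empirical p-value against a depth-ratio null
#' @param null a `depth_null` vector.
#' @param ratio observed ratio(s).
#' @return p-value(s): fraction of null ratios <= observed (with the +1
#'   resampling correction).
#' @export
depth_drop_p <- function(null, ratio) {
  (findInterval(ratio, null) + 1) / (length(null) + 1)
}

# structural single-event check for a putative deletion bridged by an
# inserted element: plus-side content must be element body (L1 or a traced
# transduction), minus-side content must carry the poly(A) end, and the
# element identity must be consistent. Returns TRUE/FALSE.
single_event_check <- function(plus, minus) {
  mp <- plus$members[[1]]; mm <- minus$members[[1]]
  cls_p <- mp$mate_class[!is.na(mp$mate_class)]
  cls_m <- mm$mate_class[!is.na(mm$mate_class)]
  plus_l1 <- any(cls_p %in% c("L1")) || any(mp$mate_kind == "distal")
  minus_pa <- any(cls_m == "polyA") || any(cls_m == "L1") ||
    any(mm$mate_kind == "distal")
  el_p <- setdiff(unique(cls_p), "polyA"); el_m <- setdiff(unique(cls_m), "polyA")
  consistent <- length(intersect(el_p, el_m)) > 0 ||
    length(el_p) == 0 || length(el_m) == 0
  # orientation-inconsistent pattern: poly(A) dominating the plus side while
  # the minus side carries 5' element content only
  pa_plus <- sum(cls_p == "polyA"); l1_plus <- sum(cls_p == "L1")
  inverted <- pa_plus > l1_plus && any(cls_m == "L1") && !any(cls_m == "polyA")
  plus_l1 && minus_pa && consistent && !inverted
}

#' Match copy-number losses to orphan L1 clusters (long deletions)
#'
#' A loss segment becomes an L1-mediated deletion call when its upstream
#' breakpoint matches an independent cluster in positive orientation and
#' its downstream breakpoint an independent cluster in negative
#' orientation (each within `tol`), and the reconstructed intervening
#' insertion passes the single-event structural check.
#'
#' @param orphans orphan cluster table (from [pair_reciprocal()], after
#'   normal subtraction).
#' @param cn_losses data.frame of loss segments (chrom/start/end).
#' @param tol breakpoint matching tolerance (default 1000).
#' @return data.frame of deletion calls (strategy "cn_matched").
#' @export
match_deletions_to_cn <- function(orphans, cn_losses, tol = 1000L) {
  out <- NULL
  if (is.null(cn_losses) || nrow(cn_losses) == 0 || nrow(orphans) == 0)
    return(out)
  pos <- orphans[orphans$side == "positive", , drop = FALSE]
  neg <- orphans[orphans$side == "negative", , drop = FALSE]
  for (i in seq_len(nrow(cn_losses))) {
    seg <- cn_losses[i, ]
    pi <- which(pos$chrom == seg$chrom & abs(pos$end - seg$start) <= tol)
    ni <- which(neg$chrom == seg$chrom & abs(neg$start - seg$end) <= tol)
    if (length(pi) == 0 || length(ni) == 0) next
    pi <- pi[which.min(abs(pos$end[pi] - seg$start))]
    ni <- ni[which.min(abs(neg$start[ni] - seg$end))]
    if (!single_event_check(pos[pi, ], neg[ni, ])) next
    out <- rbind(out, data.frame(
      chrom = seg$chrom, del_start = pos$end[pi], del_end = neg$start[ni],
      strategy = "cn_matched", tier = NA_integer_,
      p_adj_left = NA_real_, p_adj_right = NA_real_,
      plus_id = pos$cluster_id[pi], minus_id = neg$cluster_id[ni],
      support = pos$support[pi] + neg$support[ni],
      stringsAsFactors = FALSE))
  }
  out
}

#' Detect short L1-mediated deletions by read-depth drop
#'
#' Tests every positive/negative orphan-cluster pair less than `max_span`
#' apart from both clusters (depth ratio toward the putative deletion),
#' converts ratios to empirical p-values against the resampled null,
#' adjusts with Benjamini-Hochberg across all tests in the sample, and
#' reports tier 1 (both adjusted P < `alpha`) or tier 2 (exactly one).
#' Span continuity is verified on non-overlapping 500-bp windows and the
#' single-event structural check must pass.
#'
#' @param orphans orphan cluster table.
#' @param cov_t,cov_n depth tracks.
#' @param null `depth_null` from [depth_drop_null()].
#' @param max_span maximum deletion span (default 1e5).
#' @param window,buffer depth windows (window auto-shrinks for deletions
#'   shorter than `window + buffer`).
#' @param alpha tier threshold on BH-adjusted p (default 0.1).
#' @param continuity_frac fraction of 500-bp spanning windows required to
#'   show a depressed ratio (default 0.6).
#' @return data.frame of deletion calls (strategy "depth_drop") with tiers.
#' @export
detect_short_deletions <- function(orphans, cov_t, cov_n, null,
                                   max_span = 100000L, window = 1000L,
                                   buffer = 300L, alpha = 0.1,
                                   continuity_frac = 0.6) {
  pos <- orphans[orphans$side == "positive", , drop = FALSE]
  neg <- orphans[orphans$side == "negative", , drop = FALSE]
  cand <- NULL
  for (i in seq_len(nrow(pos))) {
    j <- which(neg$chrom == pos$chrom[i] & neg$start > pos$end[i] &
               neg$start - pos$end[i] < max_span)
    if (length(j) == 0) next
    j <- j[which.min(neg$start[j] - pos$end[i])]
    cand <- rbind(cand, data.frame(pi = i, ni = j))
  }
  if (is.null(cand)) return(NULL)
  tests <- NULL
  for (k in seq_len(nrow(cand))) {
    p <- pos[cand$pi[k], ]; q <- neg[cand$ni[k], ]
    span <- q$start - p$end
    w <- max(200L, min(window, span - buffer - 50L, 5000L))
    rp <- depth_ratio(cov_t, cov_n, p$chrom, p, "right", window = w, buffer = buffer)
    rm_ <- depth_ratio(cov_t, cov_n, q$chrom, q, "left", window = w, buffer = buffer)
    if (is.null(rp) || is.null(rm_)) next
    tests <- rbind(tests, data.frame(
      k = k, ratio_left = rp$ratio, ratio_right = rm_$ratio,
      p_left = depth_drop_p(null, rp$ratio),
      p_right = depth_drop_p(null, rm_$ratio)))
  }
  if (is.null(tests)) return(NULL)
  adj <- p.adjust(c(tests$p_left, tests$p_right), method = "BH")
  nt <- nrow(tests)
  tests$p_adj_left <- adj[seq_len(nt)]
  tests$p_adj_right <- adj[nt + seq_len(nt)]
  out <- NULL
  for (r in seq_len(nrow(tests))) {
    k <- tests$k[r]
    p <- pos[cand$pi[k], ]; q <- neg[cand$ni[k], ]
    nsig <- (tests$p_adj_left[r] < alpha) + (tests$p_adj_right[r] < alpha)
    if (nsig == 0) next
    if (!single_event_check(p, q)) next
    if (!span_continuity(cov_t, cov_n, p$chrom, p$end + buffer, q$start - buffer,
                         frac = continuity_frac)) next
    out <- rbind(out, data.frame(
      chrom = p$chrom, del_start = p$end, del_end = q$start,
      strategy = "depth_drop", tier = if (nsig == 2L) 1L else 2L,
      p_adj_left = tests$p_adj_left[r], p_adj_right = tests$p_adj_right[r],
      plus_id = p$cluster_id, minus_id = q$cluster_id,
      support = p$support + q$support, stringsAsFactors = FALSE))
  }
  out
}

# continuity of the depth drop across the putative deletion: fraction of
# non-overlapping 500-bp windows with tumor/normal ratio below the local
# flank level
span_continuity <- function(cov_t, cov_n, chrom, from, to, win = 500L,
                            frac = 0.6, drop_level = 0.8) {
  if (to - from < win) return(TRUE)  # too short to window: depth test governs
  starts <- seq(from, to - win, by = win)
  flank_t <- mean_depth(cov_t[[chrom]], from - 2000L, from - 500L)
  flank_n <- mean_depth(cov_n[[chrom]], from - 2000L, from - 500L)
  if (is.na(flank_t) || is.na(flank_n) || flank_n == 0 || flank_t == 0) return(FALSE)
  flank <- flank_t / flank_n
  r <- vapply(starts, function(s) {
    t <- mean_depth(cov_t[[chrom]], s, s + win)
    n <- mean_depth(cov_n[[chrom]], s, s + win)
    if (is.na(t) || is.na(n) || n == 0) return(NA_real_)
    (t / n) / flank
  }, numeric(1))
  r <- r[!is.na(r)]
  if (length(r) == 0) return(FALSE)
  mean(r < drop_level) >= frac
}

#' Junction signature at a 5' breakpoint
#'
#' Longest exact overlap (>= 1 bp) between the reference suffix ending at
#' the junction and the 5' start of the inserted sequence is scored as
#' microhomology. When the expected element start is supplied (consensus
#' sequence at the truncation point), leading observed bases absent from
#' it are scored as untemplated insertion. Neither pattern is a blunt
#' joint (length 0).
#'
#' @param ref_seqs named contig sequences.
#' @param chrom,pos precise 5' breakpoint (0-based junction).
#' @param inserted_5prime_seq first bases of the inserted sequence (e.g.
#'   the clipped-tail consensus).
#' @param expected_element_start expected first bases of the inserted
#'   element, enabling untemplated-insertion detection (optional).
#' @param max_len maximum signature length scanned (default 40).
#' @return list(kind, length) with kind in microhomology/insertion/blunt,
#'   or NULL for an imprecise breakpoint.
#' @export
junction_signature <- function(ref_seqs, chrom, pos, inserted_5prime_seq,
                               expected_element_start = NULL, max_len = 40L) {
  if (is.na(pos) || is.null(inserted_5prime_seq) ||
      is.na(inserted_5prime_seq) || nchar(inserted_5prime_seq) == 0)
    return(NULL)
  ins <- toupper(inserted_5prime_seq)
  if (!is.null(expected_element_start)) {
    expected <- toupper(expected_element_start)
    probe0 <- substring(ins, 1L, min(nchar(ins), 12L))
    templated0 <- nchar(probe0) >= 8L && startsWith(expected, probe0)
    if (!templated0 && nchar(ins) > 8L) {
      # untemplated bases: smallest offset at which the observed insertion
      # resumes matching the expected element start (anchor of >= 8 bp)
      for (off in seq_len(min(max_len, nchar(ins) - 8L))) {
        probe <- substring(ins, off + 1L, min(nchar(ins), off + 12L))
        if (nchar(probe) >= 8L && startsWith(expected, probe))
          return(list(kind = "insertion", length = off))
      }
    }
  }
  mh <- 0L
  for (len in seq_len(min(max_len, pos, nchar(ins)))) {
    refk <- substring(ref_seqs[[chrom]], pos - len + 1L, pos)
    if (substring(ins, 1L, len) == refk) mh <- len
  }
  if (mh >= 1L) return(list(kind = "microhomology", length = mh))
  list(kind = "blunt", length = 0L)
}

#' Flag translocation/fold-back/telomeric-loss candidates
#'
#' Annotation-only records from single (orphan) clusters: an orphan whose
#' mates map to another chromosome at a copy-number breakpoint is an
#' interchromosomal-bridge candidate; two same-side clusters within 10 kb
#' at a copy-number step are a fold-back inversion candidate; a loss
#' running from an L1 cluster to the contig end is a telomeric-loss
#' candidate.
#'
#' @param orphans orphan cluster table.
#' @param cn_segments copy-number segments (chrom/start/end/total_cn).
#' @param contig_lengths named lengths.
#' @param cn_tol breakpoint matching tolerance (default 1000).
#' @return data.frame of flags (kind, chrom, start, end, partner fields).
#' @export
flag_bridge_candidates <- function(orphans, cn_segments, contig_lengths,
                                   cn_tol = 1000L) {
  out <- NULL
  if (nrow(orphans) == 0) return(out)
  cn_breaks <- NULL
  if (!is.null(cn_segments) && nrow(cn_segments) > 1) {
    for (ch in unique(cn_segments$chrom)) {
      s <- cn_segments[cn_segments$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) < 2) next
      step <- diff(s$total_cn)
      cn_breaks <- rbind(cn_breaks, data.frame(
        chrom = ch, pos = s$end[-nrow(s)], step = step))
    }
  }
  near_break <- function(ch, p) {
    !is.null(cn_breaks) && any(cn_breaks$chrom == ch & abs(cn_breaks$pos - p) <= cn_tol)
  }
  # interchromosomal bridges
  for (i in seq_len(nrow(orphans))) {
    o <- orphans[i, ]
    m <- o$members[[1]]
    d <- m[m$mate_kind == "distal" & !is.na(m$mate_chrom) &
           m$mate_chrom != o$chrom, , drop = FALSE]
    edge <- if (o$side == "positive") o$end else o$start
    if (nrow(d) >= 3 && near_break(o$chrom, edge)) {
      out <- rbind(out, data.frame(
        kind = "interchromosomal_bridge", chrom = o$chrom, start = o$start,
        end = o$end, partner_chrom = names(sort(table(d$mate_chrom),
                                                decreasing = TRUE))[1],
        cluster_id = o$cluster_id, stringsAsFactors = FALSE))
    }
  }
  # fold-back inversions: two same-side clusters < 10 kb apart at a CN step
  for (side in c("positive", "negative")) {
    s <- orphans[orphans$side == side, , drop = FALSE]
    if (nrow(s) < 2) next
    s <- s[order(s$chrom, s$start), , drop = FALSE]
    for (i in seq_len(nrow(s) - 1)) {
      if (s$chrom[i + 1] != s$chrom[i]) next
      gap <- s$start[i + 1] - s$end[i]
      mid <- (s$end[i] + s$start[i + 1]) %/% 2L
      if (gap > 0 && gap < 10000L && near_break(s$chrom[i], mid)) {
        out <- rbind(out, data.frame(
          kind = "foldback_inversion", chrom = s$chrom[i], start = s$start[i],
          end = s$end[i + 1], partner_chrom = NA_character_,
          cluster_id = paste(s$cluster_id[i], s$cluster_id[i + 1], sep = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  # telomeric losses: CN loss from a cluster edge to the contig end
  if (!is.null(cn_segments) && nrow(cn_segments)) {
    losses <- cn_segments[cn_segments$total_cn < 2, , drop = FALSE]
    for (i in seq_len(nrow(losses))) {
      seg <- losses[i, ]
      at_end <- abs(seg$end - contig_lengths[[seg$chrom]]) <= cn_tol ||
        seg$start <= cn_tol
      if (!at_end) next
      edge <- if (seg$start <= cn_tol) seg$end else seg$start
      hit <- orphans$chrom == seg$chrom &
        (abs(orphans$end - edge) <= cn_tol | abs(orphans$start - edge) <= cn_tol)
      for (j in which(hit)) {
        out <- rbind(out, data.frame(
          kind = "telomeric_loss", chrom = seg$chrom, start = seg$start,
          end = seg$end, partner_chrom = NA_character_,
          cluster_id = orphans$cluster_id[j], stringsAsFactors = FALSE))
      }
    }
  }
  out
}
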
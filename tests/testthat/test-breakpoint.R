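test_that("breakpoint assembly takes the leftmost modal clip position", {
  bp <- assemble_breakpoint(rep(10034L, 6), rep("ACGTACGT", 6), "start", 9000L)
  expect_equal(bp$pos, 10034L)
  expect_true(bp$precise)
  expect_equal(bp$consensus_seq, "ACGTACGT")
  expect_equal(bp$support_clipped, 6L)
  # tie between 10034 and 10036: leftmost wins
  bp2 <- assemble_breakpoint(c(rep(10034L, 3), rep(10036L, 3)),
                             rep("AAAA", 6), "start", 9000L)
  expect_equal(bp2$pos, 10034L)
  # no clips: imprecise at the cluster edge
  bp3 <- assemble_breakpoint(integer(0), character(0), "start", 9000L)
  expect_false(bp3$precise)
  expect_equal(bp3$pos, 9000L)
  expect_null(bp3$consensus_seq)
})

test_that("clipped-tail consensus votes out sequencing errors", {
  tails <- c("ACGTACGTAA", "ACGTACGTAA", "ACCTACGTAA", "ACGTACGT")
  expect_equal(consensus_vote(tails, "start"), "ACGTACGTAA")
  # end-anchored tails align at their right edge
  tails_e <- c("TTACGT", "TACGT", "TTACGT")
  expect_equal(consensus_vote(tails_e, "end"), "TTACGT")
})

test_that("poly(A) detection follows the purity-window rule", {
  expect_equal(detect_polyA(paste0(strrep("CGT", 7), strrep("A", 12))), 12L)
  # 11 A's and a G within the last 12: the full 12-window still qualifies
  expect_equal(detect_polyA("CCCCCCCCAAAAAAAAGAAA"), 12L)
  expect_equal(detect_polyA("ACGTACGTACGTACGTACGT"), 0L)
  expect_equal(detect_polyA(""), 0L)
  # case invariance and monotonicity under appended A's
  set.seed(3)
  s <- paste0(rdna(30), strrep("A", 15))
  expect_equal(detect_polyA(tolower(s)), detect_polyA(s))
  prev <- detect_polyA(s)
  for (k in 1:5) {
    s <- paste0(s, "A")
    cur <- detect_polyA(s)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("TSD detection distinguishes duplication, blunt and target deletion", {
  ref <- list(chr1 = paste(rep("ACGTT", 2000), collapse = ""))
  b5 <- list(chrom = "chr1", pos = 5015L)
  b3 <- list(chrom = "chr1", pos = 5000L)
  tsd <- detect_tsd(b5, b3, ref)
  expect_equal(tsd$tsd_len, 15L)
  expect_equal(tsd$tsd_seq, substring(ref$chr1, 5001, 5015))
  blunt <- detect_tsd(b5, list(chrom = "chr1", pos = 5015L), ref)
  expect_equal(blunt$deletion_at_target, 0L)
  del <- detect_tsd(b5, list(chrom = "chr1", pos = 9015L), ref)
  expect_equal(del$deletion_at_target, 4000L)
  expect_true(is.na(del$tsd_len))
  expect_error(detect_tsd(b5, list(chrom = "chr2", pos = 5000L), ref),
               "different chrom")
})

test_that("endonuclease motif matching handles both strands and mismatches", {
  # plus-strand site TTTT|AA at position 100 (0-based cleavage 100)
  ref <- list(chr1 = paste0(strrep("C", 96), "TTTTAA", strrep("C", 98)))
  en <- match_en_motif(ref, "chr1", 100L)
  expect_equal(en$mismatches, 0L)
  expect_equal(en$strand, "+")
  expect_equal(en$site_seq, "TTTTA")
  # TTGT|A: one mismatch to TTTTR
  ref2 <- list(chr1 = paste0(strrep("C", 96), "TTGTA", strrep("C", 99)))
  en2 <- match_en_motif(ref2, "chr1", 100L)
  expect_equal(en2$mismatches, 1L)
  # minus-strand site T|AAAA via Y|AAAA
  ref3 <- list(chr1 = paste0(strrep("C", 99), "TAAAA", strrep("C", 96)))
  en3 <- match_en_motif(ref3, "chr1", 100L)
  expect_equal(en3$mismatches, 0L)
  expect_equal(en3$strand, "-")
  # no motif anywhere: > 3 mismatches -> NULL
  ref4 <- list(chr1 = strrep("G", 200))
  expect_null(match_en_motif(ref4, "chr1", 100L))
})

test_that("motif matching is strand-symmetric under reverse complement", {
  set.seed(17)
  for (k in 1:5) {
    s <- paste0(rdna(90), "TTTT", sample(c("A", "G"), 1), rdna(90))
    L <- nchar(s)
    en_f <- match_en_motif(list(c = s), "c", 94L)
    en_r <- match_en_motif(list(c = revcomp(s)), "c", L - 94L)
    expect_equal(en_f$mismatches, en_r$mismatches)
    expect_false(identical(en_f$strand, en_r$strand))
  }
})

test_that("full-structure insertions are reproduced from the simulation", {
  fx <- small_sim()
  res <- small_call()
  truth <- fx$sim$truth
  calls <- res$calls
  matched <- 0L
  for (i in which(!truth$germline)) {
    tr <- truth[i, ]
    j <- which(calls$chrom == tr$chrom & abs(calls$pos - tr$pos) <= 150)
    if (length(j) != 1) next
    matched <- matched + 1L
    cl <- calls[j, ]
    expect_equal(cl$class, tr$class)
    expect_equal(cl$strand, tr$strand)
    if (cl$status == "precise") {
      expect_lte(abs(cl$pos - tr$pos), 5L)
      expect_equal(cl$tsd_len, tr$tsd_len)
      # poly(A) estimate: at least the planted tract; the consensus A-rich
      # tail (12 bp) merges with it and can extend the measurement
      expect_gte(cl$polyA_len, min(tr$polyA_len, 10L) - 2L)
      # the consensus A-rich tail (12 bp) merges with the planted tract and
      # purity tolerance can add a few more bases
      expect_lte(cl$polyA_len, tr$polyA_len + 35L)
    }
  }
  expect_gte(matched, sum(!truth$germline) * 0.9)
})

test_that("5'-truncated elements report insertion length from consensus coverage", {
  fx <- small_sim()
  res <- small_call()
  truth <- fx$sim$truth
  trunc <- truth[!truth$germline & truth$class == "solo_L1" & truth$trunc > 0, ]
  for (i in seq_len(nrow(trunc))) {
    j <- which(res$calls$chrom == trunc$chrom[i] &
               abs(res$calls$pos - trunc$pos[i]) <= 150 &
               res$calls$class == "solo_L1")
    if (length(j) != 1) next
    expect_lte(abs(res$calls$inserted_len[j] - trunc$inserted_len[i]), 150L)
  }
})

test_that("conflicting element classes on the two sides reject the pair", {
  lib <- synthetic_consensus_library()
  mkside <- function(start, side, cls) {
    cands <- do.call(rbind, lapply(seq(start, start + 200, 100), function(s) {
      c <- mk_cand(start = s, side = side, mate_class = cls)
      c$mate_orient <- "+"
      c
    }))
    cands
  }
  cl <- build_clusters(rbind(mkside(1000, "positive", "L1"),
                             mkside(1450, "negative", "Alu")),
                       max_gap = 300L, min_support = 3L)
  ref <- list(chr1 = rdna(5000))
  plus <- cl[cl$side == "positive", ]
  minus <- cl[cl$side == "negative", ]
  out <- characterize_insertion(plus, minus, empty_alignments(), ref, lib)
  expect_s3_class(out, "mei_reject")
  expect_equal(out$reject, "class_conflict")
})
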
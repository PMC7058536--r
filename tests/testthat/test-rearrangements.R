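# shared deletion simulation (memoised)
del_sim <- function() {
  fixture("del_sim", function() {
    ref <- make_reference(n_contigs = 1, contig_len = 5e5, n_sources = 2,
                          n_genes = 2, seed = 31)
    sim <- plant_events(ref, counts = c(solo_L1 = 5, deletion = 4),
                        germline_counts = c(), n_germline_fl_l1 = 0, seed = 31)
    t_frags <- generate_reads(sim$tumor, coverage = 38, seed = 32, prefix = "t")
    n_frags <- generate_reads(sim$normal, coverage = 30, seed = 33, prefix = "n")
    t_aln <- align_reads_perfect(sim$tumor, t_frags, ref, sample_id = "tumor")
    n_aln <- align_reads_perfect(sim$normal, n_frags, ref, sample_id = "normal")
    res <- run_call(t_aln, n_aln, ref$seqs, ref$library,
                    sources_l1 = ref$sources, exons = ref$exons)
    rr <- run_rearrange(res, t_aln, n_aln, vapply(ref$seqs, nchar, 1L),
                        fast = TRUE, seed = 35)
    list(ref = ref, sim = sim, t_aln = t_aln, n_aln = n_aln, res = res, rr = rr)
  })
}

test_that("depth ratio reflects constructed coverage exactly", {
  # flat normal 30x; tumor 40x outside, 20x inside a deletion at [5000, 8000)
  cov_n <- list(chr1 = S4Vectors::Rle(rep(30L, 20000)))
  tum <- rep(40L, 20000); tum[5001:8000] <- 20L
  cov_t <- list(chr1 = S4Vectors::Rle(tum))
  cl <- data.frame(start = 4600L, end = 4950L, side = "positive")
  r <- depth_ratio(cov_t, cov_n, "chr1", cl, "right", window = 1000L,
                   buffer = 300L)
  expect_equal(r$ratio, 0.5, tolerance = 1e-9)
  # no depth change anywhere: ratio 1
  cov_t2 <- list(chr1 = S4Vectors::Rle(rep(40L, 20000)))
  r2 <- depth_ratio(cov_t2, cov_n, "chr1", cl, "right", window = 1000L)
  expect_equal(r2$ratio, 1, tolerance = 1e-9)
  # a spike confined to the buffer does not affect the ratio
  tum3 <- rep(40L, 20000); tum3[4951:5250] <- 400L
  r3 <- depth_ratio(list(chr1 = S4Vectors::Rle(tum3)), cov_n, "chr1", cl,
                    "right", window = 1000L, buffer = 300L)
  expect_equal(r3$ratio, 1, tolerance = 1e-9)
  expect_error(depth_ratio(cov_t, cov_n, "chr1", cl, "right", window = 100L),
               "200-5000")
})

test_that("the resampled null is seeded, centred at 1, and extreme drops are rare", {
  set.seed(1)
  n <- 40000
  cov_t <- list(chr1 = S4Vectors::Rle(as.integer(rpois(n, 38))))
  cov_n <- list(chr1 = S4Vectors::Rle(as.integer(rpois(n, 30))))
  segs <- data.frame(chrom = "chr1", start = 0L, end = n)
  null1 <- depth_drop_null(cov_t, cov_n, segs, n_locations = 3000L,
                           window = 1000L, seed = 5)
  null2 <- depth_drop_null(cov_t, cov_n, segs, n_locations = 3000L,
                           window = 1000L, seed = 5)
  expect_identical(as.numeric(null1), as.numeric(null2))
  p_mid <- depth_drop_p(null1, 1.0)
  expect_gt(p_mid, 0.35); expect_lt(p_mid, 0.65)
  expect_lt(depth_drop_p(null1, 0.1), 0.001)
})

test_that("planted short deletions come out tier 1 with truth boundaries and no TSD", {
  fx <- del_sim()
  dels <- fx$rr$deletions
  truth <- fx$sim$truth[fx$sim$truth$class == "deletion", ]
  expect_equal(nrow(dels), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    j <- which(abs(dels$del_start - truth$pos[i]) <= 300)
    expect_length(j, 1)
    expect_equal(dels$strategy[j], "depth_drop")
    expect_equal(dels$tier[j], 1L)
    # deletion length within twice the breakpoint tolerance
    called_len <- dels$del_end[j] - dels$del_start[j]
    expect_lte(abs(called_len - truth$del_len[i]), 300L)
  }
  # the event bridging the deletion shows target-site loss, never a TSD:
  # its negative-side breakpoint lies del_len to the right
  expect_true(all(dels$del_end > dels$del_start))
})

test_that("tier assignment distinguishes clean from borderline drops", {
  # constructed coverage: deletion [10000, 12000); the right-side cluster sits
  # in a locally noisy region where the drop is masked on that side
  set.seed(8)
  n <- 30000
  base_n <- as.integer(rpois(n, 30))
  base_t <- as.integer(rpois(n, 38))
  tum <- base_t
  tum[10001:12000] <- as.integer(rpois(2000, 19))
  cov_n <- list(chr1 = S4Vectors::Rle(base_n))
  cov_t_clean <- list(chr1 = S4Vectors::Rle(tum))
  # borderline: restore the inside depth near the negative cluster so the
  # minus-side test sees no drop
  tum_b <- tum
  tum_b[10701:12000] <- base_t[10701:12000]
  cov_t_border <- list(chr1 = S4Vectors::Rle(tum_b))
  segs <- data.frame(chrom = "chr1", start = 0L, end = n)
  mkcl <- function(s, e, side) {
    cands <- do.call(rbind, lapply(seq(s, e - 100, length.out = 3), function(x) {
      c <- mk_cand(start = x, side = side, mate_class = if (side == "positive") "L1" else "polyA")
      c
    }))
    cands
  }
  cl <- build_clusters(rbind(mkcl(9600, 10000, "positive"),
                             mkcl(12000, 12400, "negative")),
                       max_gap = 400L, min_support = 3L)
  null_c <- depth_drop_null(cov_t_clean, cov_n, segs, n_locations = 3000L,
                            window = 500L, seed = 2)
  d_clean <- detect_short_deletions(cl, cov_t_clean, cov_n, null_c,
                                    window = 500L, continuity_frac = 0.5)
  expect_equal(nrow(d_clean), 1L)
  expect_equal(d_clean$tier, 1L)
  null_b <- depth_drop_null(cov_t_border, cov_n, segs, n_locations = 3000L,
                            window = 500L, seed = 2)
  d_border <- detect_short_deletions(cl, cov_t_border, cov_n, null_b,
                                     window = 500L, continuity_frac = 0.2)
  expect_equal(nrow(d_border), 1L)
  expect_equal(d_border$tier, 2L)
  # no depth change at all: no call
  cov_t_flat <- list(chr1 = S4Vectors::Rle(base_t))
  null_f <- depth_drop_null(cov_t_flat, cov_n, segs, n_locations = 3000L,
                            window = 500L, seed = 2)
  d_flat <- detect_short_deletions(cl, cov_t_flat, cov_n, null_f, window = 500L)
  expect_null(d_flat)
})

test_that("copy-number matched deletions require both flanking clusters", {
  fx <- del_sim()
  truth <- fx$sim$truth[fx$sim$truth$class == "deletion", ]
  losses <- data.frame(chrom = truth$chrom,
                       start = truth$pos + sample(-200:200, nrow(truth)),
                       end = truth$bkp3 + sample(-200:200, nrow(truth)),
                       total_cn = 1)
  cnd <- match_deletions_to_cn(fx$res$orphans, losses)
  expect_equal(nrow(cnd), nrow(truth))
  expect_true(all(cnd$strategy == "cn_matched"))
  # a loss with only the upstream cluster matched yields no call
  half <- data.frame(chrom = truth$chrom[1], start = truth$pos[1],
                     end = truth$bkp3[1] + 50000, total_cn = 1)
  expect_null(match_deletions_to_cn(fx$res$orphans, half))
  # orientation-inconsistent reconstruction is rejected by the rule table
  plus_bad <- fx$res$orphans[fx$res$orphans$side == "positive", ][1, ]
  minus_bad <- fx$res$orphans[fx$res$orphans$side == "negative", ][1, ]
  pm <- plus_bad$members[[1]]; mm <- minus_bad$members[[1]]
  pm$mate_class <- "polyA"; pm$mate_kind <- "repeat"
  mm$mate_class <- "L1"; mm$mate_kind <- "repeat"
  plus_bad$members <- I(list(pm)); minus_bad$members <- I(list(mm))
  expect_false(retrocall:::single_event_check(plus_bad, minus_bad))
})

test_that("junction signatures classify microhomology, insertion and blunt joints", {
  set.seed(6)
  body <- rdna(400)
  element_start <- "GATTACAGATTACAGGCGT"
  # 3-bp microhomology: reference ends with the insertion's first 3 bases
  ref_mh <- list(chr1 = paste0(body, substr(element_start, 1, 3)))
  js <- junction_signature(ref_mh, "chr1", nchar(ref_mh$chr1), element_start)
  expect_equal(js$kind, "microhomology")
  expect_equal(js$length, 3L)
  # 9 untemplated bases before the element start
  ref_bl <- list(chr1 = paste0(body, "CCCCC"))
  observed <- paste0("TTGCATGCA", element_start)
  js2 <- junction_signature(ref_bl, "chr1", nchar(ref_bl$chr1), observed,
                            expected_element_start = element_start)
  expect_equal(js2$kind, "insertion")
  expect_equal(js2$length, 9L)
  # exact abutment
  js3 <- junction_signature(ref_bl, "chr1", nchar(ref_bl$chr1), element_start,
                            expected_element_start = element_start)
  expect_equal(js3$kind, "blunt")
  expect_equal(js3$length, 0L)
  # imprecise breakpoint: NULL
  expect_null(junction_signature(ref_bl, "chr1", NA, element_start))
})

test_that("bridge, fold-back and telomeric-loss candidates are flagged", {
  contigs <- c(chr1 = 200000L, chr2 = 200000L)
  cn <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                   start = c(0L, 50000L, 120000L),
                   end = c(50000L, 120000L, 200000L),
                   total_cn = c(2, 4, 1))
  mkcl <- function(chrom, s, side, kind = "repeat", mchrom = NA, mstart = NA) {
    cands <- do.call(rbind, lapply(seq(s, s + 200, 100), function(x)
      mk_cand(chrom = chrom, start = x, side = side, mate_kind = kind,
              mate_class = if (kind == "repeat") "L1" else NA,
              mate_chrom = mchrom, mate_start = mstart,
              mate_end = if (is.na(mstart)) NA else mstart + 100L)))
    cands
  }
  # orphan at the chr1 CN break (50 kb) with mates on chr2 -> bridge
  cands <- rbind(mkcl("chr1", 49600, "positive", "distal", "chr2", 90000),
                 # two same-side clusters 5.5 kb apart at the 120 kb step
                 mkcl("chr1", 117000, "positive"),
                 mkcl("chr1", 122800, "positive"),
                 # isolated orphan with repeat-only mates: no flag
                 mkcl("chr2", 10000, "negative"))
  cl <- build_clusters(cands, max_gap = 400L, min_support = 3L)
  flags <- flag_bridge_candidates(cl, cn, contigs)
  expect_true("interchromosomal_bridge" %in% flags$kind)
  expect_true("foldback_inversion" %in% flags$kind)
  br <- flags[flags$kind == "interchromosomal_bridge", ]
  expect_equal(br$partner_chrom[1], "chr2")
  expect_false(any(flags$chrom == "chr2"))
  # telomeric loss: loss segment reaching the contig end from a cluster
  cn_tel <- data.frame(chrom = "chr2", start = c(0L, 9900L),
                       end = c(9900L, 200000L), total_cn = c(2, 1))
  flags2 <- flag_bridge_candidates(cl, cn_tel, contigs)
  expect_true("telomeric_loss" %in% flags2$kind)
})

test_that("BH adjustment is monotone and tiering is order-invariant", {
  fx <- del_sim()
  orphans <- fx$res$orphans
  rr <- fx$rr
  # permute orphan order: identical deletion calls
  set.seed(9)
  perm <- orphans[sample(nrow(orphans)), ]
  d2 <- detect_short_deletions(perm, rr$depth_t, rr$depth_n, rr$null)
  d1 <- rr$deletions[rr$deletions$strategy == "depth_drop", ]
  o1 <- d1[order(d1$del_start), c("del_start", "del_end", "tier")]
  o2 <- d2[order(d2$del_start), c("del_start", "del_end", "tier")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_true(all(d1$p_adj_left >= 0 & d1$p_adj_left <= 1))
})
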
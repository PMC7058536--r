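test_that("discordant selection keeps planted discordant pairs and drops proper ones", {
  lib <- synthetic_consensus_library()
  l1 <- lib$seq[lib$class_name == "L1"]
  set.seed(21)
  mk_pair <- function(i, proper, mate_repeat = FALSE, strand1 = "+") {
    pos <- 1000L + i * 500L
    r1 <- data.frame(qname = sprintf("p%04d", i), chrom = "chr1", pos = pos,
                     end = pos + 100L, strand = strand1, mapq = 60L,
                     cigar = "100M", seq = rdna(100), is_read1 = TRUE,
                     mapped = TRUE, clip5 = 0L, clip3 = 0L,
                     mate_chrom = "chr1", mate_pos = pos + 300L,
                     mate_strand = "-", mate_mapped = !mate_repeat,
                     is_proper = proper, sample_id = "s",
                     stringsAsFactors = FALSE)
    r2 <- r1
    r2$is_read1 <- FALSE
    r2$strand <- "-"
    if (mate_repeat) {
      r2$mapped <- FALSE; r2$chrom <- NA; r2$pos <- NA; r2$end <- NA
      r2$mapq <- 0L; r2$seq <- substr(l1, 2001, 2100)
      r1$mate_mapped <- FALSE
    } else {
      r2$pos <- pos + 300L; r2$end <- pos + 400L
    }
    rbind(r1, r2)
  }
  aln <- do.call(rbind, c(
    lapply(1:1000, function(i) mk_pair(i, proper = TRUE)),
    lapply(1001:1008, function(i) mk_pair(i, proper = FALSE, mate_repeat = TRUE))))
  cands <- select_discordant_pairs(aln, lib)
  expect_equal(nrow(cands), 8L)
  expect_true(all(cands$side == "positive"))
  expect_true(all(cands$mate_class == "L1"))
})

test_that("clustering equals the brute-force single-linkage oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    starts <- sort(sample.int(50000, n))
    cands <- do.call(rbind, lapply(starts, function(s) mk_cand(start = s)))
    cl <- build_clusters(cands, max_gap = 400L, min_support = 1L)
    oracle <- cluster_oracle(starts, 400L)
    expect_equal(nrow(cl), length(unique(oracle)))
    sizes_o <- sort(as.integer(table(oracle)))
    expect_equal(sort(cl$support), sizes_o)
    # every member lies inside its cluster interval; no candidate reused
    total <- 0L
    for (i in seq_len(nrow(cl))) {
      mem <- cl$members[[i]]
      total <- total + nrow(mem)
      expect_true(all(mem$start >= cl$start[i] & mem$start <= cl$end[i]))
    }
    expect_equal(total, n)
  }
})

test_that("clusters below min_support are discarded", {
  cands <- rbind(mk_cand(start = 100), mk_cand(start = 200))
  expect_equal(nrow(build_clusters(cands, min_support = 3L)), 0L)
  cands5 <- do.call(rbind, lapply(seq(1000, 1400, by = 100),
                                  function(s) mk_cand(start = s)))
  cl <- build_clusters(cands5, max_gap = 400L, min_support = 3L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 5L)
})

test_that("reciprocal pairing picks the nearer negative and leaves orphans", {
  mk_cl <- function(start, end, side) {
    cands <- do.call(rbind, lapply(seq(start, end - 100, length.out = 3),
                                   function(s) mk_cand(start = s, side = side)))
    cands
  }
  cands <- rbind(mk_cl(9600, 10000, "positive"),
                 mk_cl(10120, 10500, "negative"))
  cl <- build_clusters(cands, max_gap = 400L, min_support = 3L)
  pr <- pair_reciprocal(cl)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$gap_bp,
               cl$start[cl$side == "negative"] - cl$end[cl$side == "positive"])
  expect_equal(nrow(pr$orphans), 0L)

  # lone positive cluster stays an orphan
  cl2 <- build_clusters(mk_cl(5000, 5400, "positive"), min_support = 3L)
  pr2 <- pair_reciprocal(cl2)
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(nrow(pr2$orphans), 1L)

  # two negatives at 100 and 450 bp: the nearer one is chosen
  cands3 <- rbind(do.call(rbind, lapply(c(19850, 19920, 20000),
                                        function(s) mk_cand(start = s, side = "positive"))),
                  do.call(rbind, lapply(c(20100, 20150, 20200),
                                        function(s) mk_cand(start = s, side = "negative"))),
                  do.call(rbind, lapply(c(20450, 20500, 20550),
                                        function(s) mk_cand(start = s, side = "negative"))))
  cl3 <- build_clusters(cands3, max_gap = 100L, min_support = 3L)
  pr3 <- pair_reciprocal(cl3)
  expect_equal(nrow(pr3$pairs), 1L)
  neg_start <- cl3$start[cl3$cluster_id == pr3$pairs$minus_id]
  expect_equal(neg_start, 20100)
  # pairs + orphans partition the clusters
  expect_equal(nrow(pr3$pairs) * 2L + nrow(pr3$orphans), nrow(cl3))
})

test_that("normal subtraction removes germline-supported clusters monotonically", {
  cands <- do.call(rbind, lapply(seq(1000, 1400, 100),
                                 function(s) mk_cand(start = s)))
  cl <- build_clusters(cands, min_support = 3L)
  normal0 <- cands[0, ]
  expect_equal(nrow(subtract_normal(cl, normal0)), 1L)
  normal4 <- do.call(rbind, lapply(seq(1050, 1350, 100),
                                   function(s) mk_cand(start = s)))
  expect_equal(nrow(subtract_normal(cl, normal4, max_normal_support = 1L)), 0L)
  # monotone: raising the threshold never removes a retained cluster
  kept <- vapply(0:6, function(th)
    nrow(subtract_normal(cl, normal4, max_normal_support = th)), 1L)
  expect_true(all(diff(kept) >= 0))
  # panel overlap removes regardless of support
  panel <- data.frame(chrom = "chr1", start = 900L, end = 1600L)
  expect_equal(nrow(subtract_normal(cl, normal0, panel = panel)), 0L)
})

test_that("somatic events survive subtraction while germline events are removed", {
  fx <- small_sim()
  res <- small_call()
  truth <- fx$sim$truth
  som <- truth[!truth$germline, ]
  germ <- truth[truth$germline, ]
  calls <- res$calls
  # every somatic event recovered, no call at a germline site
  for (i in seq_len(nrow(germ)))
    expect_false(any(calls$chrom == germ$chrom[i] &
                     abs(calls$pos - germ$pos[i]) < 200))
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$fp, 0L)
  expect_gte(ev$recall, 0.9)
})
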
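test_that("reference generation is deterministic and respects gap fraction", {
  r1 <- make_reference(n_contigs = 1, contig_len = 2e5, gap_fraction = 0.1,
                       n_sources = 1, n_genes = 1, seed = 3)
  r2 <- make_reference(n_contigs = 1, contig_len = 2e5, gap_fraction = 0.1,
                       n_sources = 1, n_genes = 1, seed = 3)
  expect_identical(r1$seqs, r2$seqs)
  nN <- nchar(gsub("[^N]", "", r1$seqs[["chr1"]]))
  expect_lt(abs(nN / 2e5 - 0.1), 0.011)
  expect_error(make_reference(gap_fraction = 1), "gap_fraction")
  expect_error(make_reference(contig_len = 5e4), "100 kb")
  r0 <- make_reference(n_contigs = 1, contig_len = 2e5, n_sources = 0,
                       n_genes = 0, seed = 3)
  expect_equal(nrow(r0$sources), 0L)
})

test_that("planted events are booked once each with correct classes", {
  ref <- make_reference(n_contigs = 1, contig_len = 3e5, n_sources = 2,
                        n_genes = 2, seed = 5)
  sim <- plant_events(ref, counts = c(solo_L1 = 10, L1_orphan_TD = 3,
                                      deletion = 2),
                      germline_counts = c(), n_germline_fl_l1 = 0, seed = 5)
  expect_equal(nrow(sim$truth), 15L)
  expect_equal(sum(sim$truth$class == "solo_L1"), 10L)
  expect_equal(sum(sim$truth$class == "L1_orphan_TD"), 3L)
  expect_equal(sum(sim$truth$class == "deletion"), 2L)
  expect_equal(anyDuplicated(sim$truth$event_id), 0L)
  # deletions carry no TSD
  expect_true(all(sim$truth$tsd_len[sim$truth$class == "deletion"] == 0L))
})

test_that("haplotype length accounting matches planted events exactly", {
  ref <- make_reference(n_contigs = 1, contig_len = 3e5, n_sources = 2,
                        n_genes = 2, seed = 6)
  sim <- plant_events(ref, counts = c(solo_L1 = 5, deletion = 3),
                      germline_counts = c(), n_germline_fl_l1 = 0, seed = 6)
  tr <- sim$truth
  expected <- 3e5 + sum(tr$inserted_len) + sum(tr$tsd_len) - sum(tr$del_len)
  expect_equal(nchar(sim$tumor$seqs[["chr1"]]), expected)
  # the normal haplotype has no somatic events
  expect_equal(nchar(sim$normal$seqs[["chr1"]]), 3e5)
})

test_that("solo-L1 truncation rate follows the configured probability", {
  ref <- make_reference(n_contigs = 1, contig_len = 8e5, n_sources = 1,
                        n_genes = 1, seed = 8)
  sim <- plant_events(ref, counts = c(solo_L1 = 100), germline_counts = c(),
                      n_germline_fl_l1 = 0, trunc_prob = 0.9, seed = 8)
  frac <- mean(sim$truth$trunc > 0)
  expect_gt(frac, 0.8); expect_lt(frac, 0.98)  # binomial tolerance at n=100
})

test_that("read generation hits target coverage and is seed-deterministic", {
  ref <- make_reference(n_contigs = 1, contig_len = 2e5, n_sources = 0,
                        n_genes = 0, gap_fraction = 0, seed = 9)
  hap <- haplotype_from_reference(ref)
  fr <- generate_reads(hap, coverage = 38, read_len = 100, seed = 2)
  expect_equal(nrow(fr), round(38 * 2e5 / 200))
  fr2 <- generate_reads(hap, coverage = 38, read_len = 100, seed = 2)
  expect_identical(fr, fr2)
  # zero error rate: every read is an exact substring of the haplotype
  fr0 <- generate_reads(hap, coverage = 0.5, err_rate = 0, seed = 3)
  idx <- sample(nrow(fr0), 20)
  for (i in idx) {
    expect_identical(fr0$fseq1[i],
                     substring(hap$seqs[["chr1"]], fr0$start1[i] + 1, fr0$end1[i]))
  }
  expect_error(generate_reads(hap, insert_mean = 50), "insert_mean")
  expect_error(generate_reads(hap, coverage = 0), "coverage")
})

test_that("clonality mixing thins tumor support as a binomial expectation", {
  fx <- small_sim()
  mixed <- mix_clonality(fx$t_aln, fx$n_aln, 0.5, seed = 4)
  n_t <- length(unique(fx$t_aln$qname))
  n_kept <- length(unique(mixed$qname[!startsWith(mixed$qname, "mixn_")]))
  expect_lt(abs(n_kept / n_t - 0.5), 0.02)
  expect_equal(length(unique(mixed$qname)), n_t)
  expect_error(mix_clonality(fx$t_aln, fx$n_aln, 0), "fraction")
  full <- mix_clonality(fx$t_aln, fx$n_aln, 1, seed = 4)
  expect_equal(nrow(full), nrow(fx$t_aln))
})

test_that("precision/recall scoring implements one-to-one greedy matching", {
  truth <- data.frame(event_id = sprintf("E%02d", 1:10), class = "solo_L1",
                      chrom = "chr1", pos = seq(1000, 10000, by = 1000),
                      germline = FALSE, stringsAsFactors = FALSE)
  calls <- data.frame(class = "solo_L1", chrom = "chr1",
                      pos = c(seq(1000, 9000, by = 1000), 50000),
                      stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$tp, 9L); expect_equal(ev$fp, 1L); expect_equal(ev$fn, 1L)
  expect_equal(ev$precision, 0.9); expect_equal(ev$recall, 0.9)
  # perfect calls
  ev2 <- evaluate_calls(truth[, c("class", "chrom", "pos")], truth)
  expect_equal(ev2$precision, 1); expect_equal(ev2$recall, 1)
  # duplicate calls on one truth event: the second is a false positive
  dup <- truth[c(1, 1), c("class", "chrom", "pos")]
  ev3 <- evaluate_calls(dup, truth)
  expect_equal(ev3$tp, 1L); expect_equal(ev3$fp, 1L)
})

test_that("perfect alignment clips reads at junctions and leaves repeats unmapped", {
  fx <- small_sim()
  ta <- fx$t_aln
  expect_true(any(!ta$mapped))
  expect_true(any(ta$clip3 > 0) && any(ta$clip5 > 0))
  # unmapped reads keep their sequence
  expect_true(all(nchar(ta$seq[!ta$mapped]) == 100))
  # mapped intervals have SAM-consistent cigar spans
  m <- ta[ta$mapped, ][1:200, ]
  expect_equal(m$end - m$pos + m$clip5 + m$clip3, rep(100L, 200))
  # clip positions of right-clipped reads pile up at true junctions
  tr <- fx$sim$truth[!fx$sim$truth$germline, ]
  one <- tr[tr$class == "solo_L1", ][1, ]
  clips <- ta$end[ta$mapped & ta$clip3 >= 5 & !is.na(ta$chrom) &
                  ta$chrom == one$chrom &
                  abs(ta$end - one$pos) < 20]
  expect_gte(length(clips), 3)
  expect_equal(as.integer(names(sort(table(clips), decreasing = TRUE))[1]),
               one$pos)
})
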
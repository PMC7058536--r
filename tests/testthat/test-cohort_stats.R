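sim_zinb <- function(n, mu, theta, pi0, seed) {
  set.seed(seed)
  y <- rnbinom(n, size = theta, mu = mu)
  y[runif(n) < pi0] <- 0L
  y
}

test_that("ZINB recovers the sign and significance of a x5 rate effect", {
  y0 <- sim_zinb(200, mu = 8, theta = 1, pi0 = 0.4, seed = 101)
  y1 <- sim_zinb(200, mu = 40, theta = 1, pi0 = 0.4, seed = 102)
  counts <- data.frame(sample_id = sprintf("s%03d", 1:400),
                       group_label = rep(c("other", "target"), each = 200),
                       mei_count = c(y0, y1))
  res <- zinb_enrichment(counts, "target")
  expect_gt(res$z, 0)
  expect_lt(res$p, 0.01)
  expect_equal(res$direction, "enriched")
  # label swap flips the sign with equal magnitude
  res2 <- zinb_enrichment(counts, "other")
  expect_equal(res2$z, -res$z, tolerance = 1e-3)
  expect_equal(res2$direction, "depleted")
})

test_that("ZINB collapses to plain NB when data carry no zero inflation", {
  set.seed(103)
  y <- rnbinom(400, size = 2, mu = 20)  # virtually no structural zeros
  counts <- data.frame(sample_id = sprintf("s%03d", 1:400),
                       group_label = rep(c("a", "b"), each = 200),
                       mei_count = y)
  res <- zinb_enrichment(counts, "b")
  pi0 <- plogis(res$coefficients["zero_intercept"])
  expect_lt(unname(pi0), 0.05)
})

test_that("ZINB guards its preconditions", {
  counts <- data.frame(sample_id = letters[1:20],
                       group_label = c(rep("t", 5), rep("o", 15)),
                       mei_count = rpois(20, 3))
  expect_error(zinb_enrichment(counts, "t"), "fewer than")
  counts2 <- data.frame(sample_id = sprintf("s%d", 1:40),
                        group_label = rep(c("t", "o"), each = 20),
                        mei_count = c(rep(0L, 20), rpois(20, 3)))
  expect_error(zinb_enrichment(counts2, "t"), "all-zero")
})

test_that("motif bins agree with an exhaustive Hamming-distance oracle", {
  # every 5-mer, embedded in a neutral context
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases))
  set.seed(11)
  kmers <- sample(kmers, 120)  # a broad random sample of the 1024
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  pats <- c("TTTTA", "TTTTG", "CAAAA", "TAAAA")
  for (k in kmers) {
    track <- motif_track_from_reference(list(c = paste0("GG", k, "GG")))
    mm_oracle <- min(vapply(pats, ham, 1L, a = k))
    bin_oracle <- c(3L, 3L, 2L, 1L, 0L, 0L)[mm_oracle + 1L]
    expect_equal(track$bins$c[3], bin_oracle, info = k)
  }
  # canonical examples
  tr <- motif_track_from_reference(list(c = "GGTTTTAGG"))
  expect_equal(tr$bins$c[3], 3L)
  trG <- motif_track_from_reference(list(c = strrep("G", 50)))
  expect_true(all(trG$bins$c == 0L))
  # footprint covers every scanned position
  expect_equal(sum(trG$footprint_bp), 46L)
})

test_that("windowed insertion rates conserve totals and use half-open windows", {
  contigs <- c(chr1 = 3000000L, chr2 = 1500000L)
  ins <- data.frame(chrom = c(rep("chr1", 5), "chr1", "chr2"),
                    pos = c(rep(1500000L, 5), 1000000L, 10L))
  rw <- rate_per_window(ins, contigs)
  expect_equal(sum(rw$count), nrow(ins))
  # 5 insertions land in [1e6, 2e6); the boundary insertion at exactly 1e6
  # joins them (right window, half-open convention)
  expect_equal(rw$count[rw$chrom == "chr1" & rw$start == 1000000L], 6L)
  expect_equal(rw$count[rw$chrom == "chr1" & rw$start == 0L], 0L)
  # empty contig: all-zero track
  rw0 <- rate_per_window(ins[0, ], contigs)
  expect_true(all(rw0$count == 0L))
})

test_that("feature association pins bin 0 at 1 and covers a uniform null", {
  set.seed(12)
  ref <- list(chr1 = rdna(200000))
  track <- motif_track_from_reference(ref)
  ins <- data.frame(chrom = "chr1", pos = sample.int(200000, 60))
  fa <- suppressWarnings(feature_association(ins, track, window = 5000L,
                                             contig_lengths = c(chr1 = 200000L)))
  expect_equal(fa$enrichment[fa$bin == 0], 1)
  for (b in 1:3) {
    row <- fa[fa$bin == b, ]
    if (!is.na(row$enrichment))
      expect_true(row$ci_lo <= 1.6 && row$ci_hi >= 0.6)
  }
})

test_that("Mann-Whitney group test matches exact enumeration and BH dominates raw p", {
  counts <- data.frame(sample_id = sprintf("s%d", 1:6),
                       mei_count = c(1, 2, 3, 10, 11, 12))
  g <- list(sep = rep(c("lo", "hi"), each = 3))
  res <- group_test(counts, g)
  # exact two-sided minimum at n=3,3: 2/choose(6,3) = 0.1
  expect_equal(res$p, 0.1)
  expect_false(res$significant)
  # identical groups: p in the null region, never flagged
  counts2 <- data.frame(sample_id = sprintf("s%d", 1:8),
                        mei_count = rep(c(4, 7, 9, 2), 2))
  res2 <- group_test(counts2, list(same = rep(c("a", "b"), each = 4)))
  expect_gt(res2$p, 0.5)
  # BH never shrinks p-values
  set.seed(13)
  counts3 <- data.frame(sample_id = sprintf("s%d", 1:40),
                        mei_count = rpois(40, 5))
  gl <- lapply(1:20, function(i) sample(rep(c("x", "y"), each = 20)))
  names(gl) <- sprintf("t%02d", 1:20)
  res3 <- group_test(counts3, gl)
  expect_true(all(res3$q >= res3$p))
  expect_error(group_test(counts, list(bad = rep("a", 6))), "two non-empty")
})

test_that("Spearman correlation handles monotone, reversed and constant input", {
  counts <- data.frame(mei_count = 1:10, sv_count = (1:10)^2)
  expect_equal(sv_correlation(counts)$rho, 1)
  counts$sv_count <- rev(counts$sv_count)
  expect_equal(sv_correlation(counts)$rho, -1)
  constant <- data.frame(mei_count = rep(3, 10), sv_count = 1:10)
  expect_warning(r <- sv_correlation(constant), "constant")
  expect_null(r)
  expect_error(sv_correlation(data.frame(mei_count = 1:2, sv_count = 1:2)),
               "at least 3")
})
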
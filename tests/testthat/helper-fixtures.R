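# Shared fixtures, built in code and memoised for the session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small end-to-end simulation shared by io/pipeline/psd tests
small_sim <- function() {
  fixture("small_sim", function() {
    ref <- make_reference(n_contigs = 1L, contig_len = 3e5, n_sources = 2L,
                          n_genes = 3L, seed = 7L)
    sim <- plant_events(ref, counts = c(solo_L1 = 6, L1_partnered_TD = 2,
                                        L1_orphan_TD = 2, Alu = 4, SVA = 2),
                        seed = 7L)
    t_frags <- generate_reads(sim$tumor, coverage = 38, seed = 11L, prefix = "t")
    n_frags <- generate_reads(sim$normal, coverage = 30, seed = 12L, prefix = "n")
    t_aln <- align_reads_perfect(sim$tumor, t_frags, ref, sample_id = "tumor")
    n_aln <- align_reads_perfect(sim$normal, n_frags, ref, sample_id = "normal")
    list(ref = ref, sim = sim, t_aln = t_aln, n_aln = n_aln)
  })
}

small_call <- function() {
  fixture("small_call", function() {
    fx <- small_sim()
    res <- run_call(fx$t_aln, fx$n_aln, fx$ref$seqs, fx$ref$library,
                    sources_l1 = fx$ref$sources, exons = fx$ref$exons)
    res
  })
}

# independent quadratic-time local-alignment oracle (pure R, full matrix,
# match +1 / mismatch -1 / gap -2), reporting score, identity and subject
# span of the leftmost-best alignment
sw_oracle <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  A <- strsplit(toupper(a), "")[[1]]; B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    eq <- ifelse(A[i] == B, match, mismatch)
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(0L, H[i, j] + eq[j], H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
    }
  }
  sc <- max(H)
  if (sc == 0) return(list(score = 0L, identity = NA_real_, alen = 0L))
  # traceback from a best cell, preferring longer alignments on ties
  best <- NULL
  cells <- which(H == sc, arr.ind = TRUE)
  for (ci in seq_len(nrow(cells))) {
    i <- cells[ci, 1]; j <- cells[ci, 2]
    nm <- 0L; alen <- 0L
    while (i > 1L && j > 1L && H[i, j] > 0L) {
      eq <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      if (H[i, j] == H[i - 1L, j - 1L] + eq) {
        nm <- nm + (A[i - 1L] == B[j - 1L]); alen <- alen + 1L
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == H[i - 1L, j] + gap) {
        alen <- alen + 1L; i <- i - 1L
      } else {
        alen <- alen + 1L; j <- j - 1L
      }
    }
    cand <- list(score = sc, identity = nm / alen, alen = alen,
                 b_start = j - 1L, b_end = cells[ci, 2] - 1L)
    if (is.null(best) || cand$alen > best$alen) best <- cand
  }
  best
}

# brute-force single-linkage clustering oracle: connected components of
# the graph joining candidates on one (chrom, side) whose anchor starts
# differ by at most max_gap
cluster_oracle <- function(starts, max_gap) {
  n <- length(starts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(starts[i] - starts[j]) <= max_gap && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random DNA helper for tests
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# hand-built candidate row(s) for cluster-level tests
mk_cand <- function(chrom = "chr1", start, side = "positive",
                    mate_kind = "repeat", mate_class = "L1",
                    mate_chrom = NA, mate_start = NA, mate_end = NA) {
  data.frame(qname = sprintf("q%06.0f", start + runif(1) * 1e5),
             sample_id = "s", chrom = chrom, start = as.integer(start),
             end = as.integer(start + 100L), strand = if (side == "positive") "+" else "-",
             side = side, mate_kind = mate_kind,
             mate_seq = NA_character_, mate_chrom = mate_chrom,
             mate_start = mate_start, mate_end = mate_end,
             mate_class = mate_class, mate_subfamily = NA_character_,
             mate_identity = NA_real_, mate_cs = NA_integer_,
             mate_ce = NA_integer_, mate_orient = NA_character_,
             stringsAsFactors = FALSE)
}
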
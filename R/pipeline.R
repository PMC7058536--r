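# End-to-end orchestration: somatic MEI calling on a tumor/normal pair,
# rearrangement detection, and the self-contained in-silico validation
# experiment (simulate -> perfect-align -> call -> score at four tumor
# clonalities).

#' Default pipeline parameters
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
call_params <- function(...) {
  p <- list(
    mapq_floor = 20L, max_insert = 1000L, min_identity = 0.85, min_len = 30L,
    max_gap = 400L, min_support = 3L, reciprocal_window = 500L,
    max_normal_support = 0L, normal_window = 200L,
    en_window = 10L, max_tsd = 50L, element_len = 6019L,
    full_length_frac = 0.9)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Somatic MEI calling on a tumor/normal pair
#'
#' Runs the full detection chain: discordant-pair selection in tumor and
#' normal, strand-oriented clustering, matched-normal subtraction,
#' reciprocal pairing, breakpoint characterization, two-pass transduction
#' tracing (somatic full-length insertions join the source registry for
#' the second pass), and processed-pseudogene calling on pairs whose mates
#' land in exons.
#'
#' @param tumor,normal alignment tables (or BAM/SAM paths, read via
#'   [read_alignments()]).
#' @param ref_seqs named contig sequences (character).
#' @param library consensus library.
#' @param sources_l1 reference full-length L1 annotation
#'   (chrom/start/end/strand/id) or NULL.
#' @param exons exon table for PSD calling or NULL.
#' @param panel germline panel intervals or NULL.
#' @param sample_id tumor sample label.
#' @param call_germline also call germline MEIs from the normal (their
#'   full-length L1s become polymorphic source candidates).
#' @param params parameter list from [call_params()].
#' @return list with `calls`, `germline_calls`, `clusters`, `pairs`,
#'   `orphans`, `rejected`, `registry`, `normal_cands`.
#' @export
run_call <- function(tumor, normal, ref_seqs, library, sources_l1 = NULL,
                     exons = NULL, panel = NULL, sample_id = "tumor",
                     call_germline = TRUE, params = call_params()) {
  if (is.character(tumor)) tumor <- read_alignments(tumor, sample_id = sample_id)
  if (is.character(normal)) normal <- read_alignments(normal, sample_id = "normal")
  pr <- params
  t_cands <- select_discordant_pairs(tumor, library, pr$mapq_floor,
                                     pr$max_insert, pr$min_identity, pr$min_len)
  n_cands <- select_discordant_pairs(normal, library, pr$mapq_floor,
                                     pr$max_insert, pr$min_identity, pr$min_len)
  clusters <- build_clusters(t_cands, pr$max_gap, pr$min_support)
  clusters <- subtract_normal(clusters, n_cands, panel,
                              pr$max_normal_support, pr$normal_window)
  paired <- pair_reciprocal(clusters, pr$reciprocal_window)

  # germline calls from the normal sample (no subtraction): polymorphic
  # full-length L1 insertions act as transduction sources
  germline_calls <- NULL
  if (call_germline) {
    ncl <- build_clusters(n_cands, pr$max_gap, pr$min_support)
    npr <- pair_reciprocal(ncl, pr$reciprocal_window)
    germline_calls <- characterize_pairs(npr$pairs, ncl, normal, ref_seqs,
                                         library, registry = NULL,
                                         sample_id = "normal", pr)$calls
  }
  registry <- build_source_registry(sources_l1, normal_calls = germline_calls,
                                    element_len = pr$element_len,
                                    full_length_frac = pr$full_length_frac)

  pass1 <- characterize_pairs(paired$pairs, clusters, tumor, ref_seqs, library,
                              registry, sample_id, pr)
  # second pass: somatic full-length L1 calls join the registry
  registry2 <- build_source_registry(sources_l1, normal_calls = germline_calls,
                                     tumor_calls = pass1$calls,
                                     element_len = pr$element_len,
                                     full_length_frac = pr$full_length_frac)
  res <- if (nrow(registry2) > nrow(registry))
    characterize_pairs(paired$pairs, clusters, tumor, ref_seqs, library,
                       registry2, sample_id, pr)
  else pass1

  calls <- res$calls
  # PSD calling on pairs not already explained by an element class
  if (!is.null(exons) && nrow(res$unexplained_pairs)) {
    psd <- call_processed_pseudogenes(res$unexplained_pairs, clusters, exons,
                                      tumor, ref_seqs,
                                      min_support = pr$min_support,
                                      sample_id = sample_id)
    calls <- rbind(calls, psd)
  }
  if (!is.null(calls) && nrow(calls)) {
    calls <- calls[order(match(calls$chrom, names(ref_seqs)), calls$pos), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  list(calls = calls, germline_calls = germline_calls, clusters = clusters,
       pairs = paired$pairs, orphans = paired$orphans,
       rejected = res$rejected, registry = registry2, normal_cands = n_cands)
}

# characterize every reciprocal pair; collect calls, rejections and the
# pairs left unexplained (no element content) for the PSD caller
characterize_pairs <- function(pairs, clusters, aln, ref_seqs, library,
                               registry, sample_id, pr) {
  calls <- NULL; rejected <- NULL
  unexplained <- pairs[0, , drop = FALSE]
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      plus <- clusters[clusters$cluster_id == pairs$plus_id[k], , drop = FALSE]
      minus <- clusters[clusters$cluster_id == pairs$minus_id[k], , drop = FALSE]
      cl <- characterize_insertion(plus, minus, aln, ref_seqs, library,
                                   registry, sample_id,
                                   en_window = pr$en_window,
                                   max_tsd = pr$max_tsd)
      if (is.null(cl) || inherits(cl, "mei_reject")) {
        why <- if (inherits(cl, "mei_reject")) cl$reject else "unknown"
        rejected <- rbind(rejected, data.frame(
          plus_id = pairs$plus_id[k], minus_id = pairs$minus_id[k],
          reason = why, stringsAsFactors = FALSE))
        if (why %in% c("no_element_content", "polyA_only"))
          unexplained <- rbind(unexplained, pairs[k, , drop = FALSE])
      } else calls <- rbind(calls, cl)
    }
  }
  list(calls = calls, rejected = rejected, unexplained_pairs = unexplained)
}

#' Rearrangement detection on the outputs of [run_call()]
#'
#' Runs both L1-mediated deletion strategies (copy-number matching and the
#' depth-drop test with its resampled null) plus bridge/fold-back/telomere
#' flagging on the orphan clusters.
#'
#' @param callres result of [run_call()].
#' @param tumor,normal alignment tables.
#' @param contig_lengths named contig lengths.
#' @param cn_segments copy-number segments with total_cn (or logR plus
#'   `pp = list(rho, psi)` for the transform) or NULL.
#' @param pp purity/ploidy for logR input.
#' @param n_null null-sample size (default 1e5; the `fast` flag lowers it
#'   to 1e4).
#' @param fast logical.
#' @param seed integer seed for the null resampling.
#' @param window,buffer depth-test geometry.
#' @return list with `deletions`, `flags`, `null`, `depth_t`, `depth_n`.
#' @export
run_rearrange <- function(callres, tumor, normal, contig_lengths,
                          cn_segments = NULL, pp = NULL, n_null = 100000L,
                          fast = FALSE, seed = 1L, window = 1000L,
                          buffer = 300L) {
  if (fast) n_null <- min(n_null, 10000L)
  if (!is.null(cn_segments) && !"total_cn" %in% names(cn_segments)) {
    if (is.null(pp)) stop("logR-only copy-number input needs pp = list(rho, psi)")
    cn_segments$total_cn <- logr_to_cn(running_median(cn_segments$logR),
                                       pp$rho, pp$psi)
  }
  cov_t <- depth_track(tumor, contig_lengths)
  cov_n <- depth_track(normal, contig_lengths)
  # null locations drawn from predominant-copy-number segments: the modal
  # total copy number when CN is provided, else the whole genome
  segs <- if (!is.null(cn_segments) && nrow(cn_segments)) {
    cn_round <- round(cn_segments$total_cn)
    lens <- cn_segments$end - cn_segments$start
    mode_cn <- as.integer(names(sort(tapply(lens, cn_round, sum),
                                     decreasing = TRUE))[1])
    cn_segments[cn_round == mode_cn, c("chrom", "start", "end"), drop = FALSE]
  } else {
    data.frame(chrom = names(contig_lengths), start = 0L,
               end = as.integer(unname(unlist(contig_lengths))))
  }
  null <- depth_drop_null(cov_t, cov_n, segs, n_locations = n_null,
                          window = window, buffer = buffer, seed = seed)
  orphans <- callres$orphans
  dels <- detect_short_deletions(orphans, cov_t, cov_n, null,
                                 window = window, buffer = buffer)
  if (!is.null(cn_segments) && nrow(cn_segments)) {
    losses <- cn_segments[cn_segments$total_cn < 1.5, , drop = FALSE]
    cnd <- match_deletions_to_cn(orphans, losses)
    if (!is.null(cnd)) {
      # depth-drop calls take precedence for the same cluster pair
      if (!is.null(dels)) {
        dup <- paste(cnd$plus_id, cnd$minus_id) %in% paste(dels$plus_id, dels$minus_id)
        cnd <- cnd[!dup, , drop = FALSE]
      }
      dels <- rbind(dels, cnd)
    }
  }
  flags <- flag_bridge_candidates(orphans, cn_segments, contig_lengths)
  list(deletions = dels, flags = flags, null = null,
       depth_t = cov_t, depth_n = cov_n)
}

#' The in-silico validation experiment
#'
#' Self-contained: builds a seeded synthetic reference, plants the default
#' somatic event mix, generates tumor (38x) and normal (30x) reads plus a
#' diluent normal pool, mixes tumor clonalities by read subsampling, calls
#' MEIs for each tumor/normal pair, and scores precision/recall against
#' the truth registry.
#'
#' @param seed master seed.
#' @param clonalities tumor fractions to evaluate.
#' @param n_contigs,contig_len genome scale (default 2 x 1 Mb).
#' @param counts somatic event mix (default ~150 events).
#' @param coverage_t,coverage_n sequencing depths.
#' @param pos_tol truth-matching tolerance (default 150 bp).
#' @param params caller parameters.
#' @return list with `table` (one row per clonality: precision, recall,
#'   tp, fp, fn), `truth`, and the last call set.
#' @export
run_validation <- function(seed = 1L, clonalities = c(0.25, 0.5, 0.75, 1.0),
                           n_contigs = 2L, contig_len = 1e6,
                           counts = c(solo_L1 = 80, L1_partnered_TD = 15,
                                      L1_orphan_TD = 15, Alu = 30, SVA = 10),
                           coverage_t = 38, coverage_n = 30, pos_tol = 150L,
                           params = call_params()) {
  ref <- make_reference(n_contigs = n_contigs, contig_len = contig_len,
                        seed = seed)
  sim <- plant_events(ref, counts = counts, seed = seed)
  t_frags <- generate_reads(sim$tumor, coverage = coverage_t,
                            seed = child_seed(seed, "t"), prefix = "t")
  n_frags <- generate_reads(sim$normal, coverage = coverage_n,
                            seed = child_seed(seed, "n"), prefix = "n")
  d_frags <- generate_reads(sim$normal, coverage = coverage_t,
                            seed = child_seed(seed, "d"), prefix = "d")
  t_aln <- align_reads_perfect(sim$tumor, t_frags, ref, sample_id = "tumor")
  n_aln <- align_reads_perfect(sim$normal, n_frags, ref, sample_id = "normal")
  d_aln <- align_reads_perfect(sim$normal, d_frags, ref, sample_id = "diluent")
  rm(t_frags, n_frags, d_frags)

  tab <- NULL; last <- NULL
  for (fr in clonalities) {
    mixed <- if (fr >= 1) t_aln
    else mix_clonality(t_aln, d_aln, fr, seed = child_seed(seed, "mix"))
    res <- run_call(mixed, n_aln, ref$seqs, ref$library,
                    sources_l1 = ref$sources, exons = ref$exons,
                    sample_id = sprintf("tumor_c%d", round(fr * 100)),
                    params = params)
    ev <- evaluate_calls(res$calls, sim$truth, pos_tol = pos_tol)
    tab <- rbind(tab, data.frame(
      clonality = fr, tp = ev$tp, fp = ev$fp, fn = ev$fn,
      precision = ev$precision, recall = ev$recall))
    last <- res
  }
  list(table = tab, truth = sim$truth, ref = ref, last_call = last)
}
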
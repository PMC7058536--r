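# L1 3' transduction tracing: source-element registry construction
# (reference full-length loci, non-reference polymorphic elements from
# normals, tumor-only somatic sources), solo/partnered/orphan
# classification, source attribution via strand-aware 10-kb downstream
# windows, and per-source activity summaries.

#' Build the L1 source-element registry
#'
#' The registry is the union of (i) annotated reference full-length L1
#' loci, (ii) full-length non-reference insertions seen in any normal
#' sample (polymorphic sources, cohort-scoped), and (iii) full-length
#' somatic insertions seen only in a tumor (somatic sources, scoped to
#' that sample). Each entry carries its strand-aware 10-kb downstream
#' window, the interval transduced sequence must match.
#'
#' @param reference_l1 data.frame of reference full-length L1 loci
#'   (chrom/start/end/strand; an `id` column is honoured if present).
#' @param normal_calls,tumor_calls MEI call tables (may be NULL); only
#'   solo-L1 calls whose consensus coverage reaches `full_length_frac` of
#'   the element length qualify as sources.
#' @param element_len full-length consensus length used for the
#'   full-length test.
#' @param full_length_frac minimum covered fraction (default 0.9).
#' @param window_len downstream window length (fixed 10 kb).
#' @return data.frame registry with window coordinates.
#' @export
build_source_registry <- function(reference_l1, normal_calls = NULL,
                                  tumor_calls = NULL, element_len = 6019L,
                                  full_length_frac = 0.9, window_len = 10000L) {
  rows <- NULL
  add <- function(id, chrom, start, end, strand, origin, scope) {
    if (is.na(strand) || !strand %in% c("+", "-"))
      stop("L1 locus without strand: downstream window undefined (", id, ")")
    if (strand == "+") {
      ws <- end; we <- end + window_len
    } else {
      ws <- start - window_len; we <- start
    }
    rbind(rows, data.frame(id = id, chrom = chrom, start = start, end = end,
                           strand = strand, origin = origin,
                           sample_scope = scope,
                           window_start = as.integer(ws),
                           window_end = as.integer(we),
                           stringsAsFactors = FALSE))
  }
  if (!is.null(reference_l1) && nrow(reference_l1)) {
    ids <- if ("id" %in% names(reference_l1)) reference_l1$id
           else sprintf("REF_L1_%03d", seq_len(nrow(reference_l1)))
    for (i in seq_len(nrow(reference_l1)))
      rows <- add(ids[i], reference_l1$chrom[i], reference_l1$start[i],
                  reference_l1$end[i], reference_l1$strand[i],
                  "reference_fulllength", "cohort")
  }
  call_sources <- function(calls, origin, prefix) {
    if (is.null(calls) || nrow(calls) == 0) return(invisible())
    fl <- calls$class == "solo_L1" & !is.na(calls$inserted_len) &
      calls$inserted_len >= full_length_frac * element_len
    calls <- calls[fl, , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      # the inserted element occupies a point in reference space; its
      # downstream flank is the reference sequence beyond the insertion site
      p <- calls$pos[i]
      rows <<- add(sprintf("%s_%03d", prefix, i), calls$chrom[i], p, p,
                   calls$strand[i], origin,
                   if (origin == "somatic") calls$sample_id[i] else "cohort")
    }
  }
  call_sources(normal_calls, "nonref_polymorphic", "POLY_L1")
  call_sources(tumor_calls, "somatic", "SOM_L1")
  if (is.null(rows))
    rows <- data.frame(id = character(), chrom = character(), start = integer(),
                       end = integer(), strand = character(), origin = character(),
                       sample_scope = character(), window_start = integer(),
                       window_end = integer(), stringsAsFactors = FALSE)
  rows
}

#' Classify L1 evidence as solo, partnered or orphan transduction
#'
#' Decision rule over the evidence gathered for one reciprocal cluster
#' pair: a traced distal unique interval plus L1 consensus mates means a
#' partnered transduction; a traced distal interval with poly(A) evidence
#' and no L1 consensus means an orphan transduction; L1 consensus alone
#' means a solo insertion. Pairs with neither element content nor a traced
#' transduction are rejected.
#'
#' @param has_l1 TRUE when L1 consensus mates support the pair.
#' @param el_class majority consensus class of the repeat mates (NA when
#'   none).
#' @param td candidate transduced interval (list chrom/start/end/support)
#'   or NULL.
#' @param polyA_len detected poly(A)/poly(T) tract length at the junctions.
#' @param polyA_mates number of poly(A)-content mates.
#' @param registry source registry (NULL disables tracing).
#' @param sample_id sample for somatic-source scoping.
#' @return list with `class`, `src_id`, `td_chrom`/`td_start`/`td_end`, or
#'   a `reject` reason.
#' @export
identify_transductions <- function(has_l1, el_class, td, polyA_len,
                                   polyA_mates = 0L, registry = NULL,
                                   sample_id = NULL) {
  none <- list(class = NA_character_, src_id = NA_character_,
               td_chrom = NA_character_, td_start = NA_integer_,
               td_end = NA_integer_, reject = NULL)
  if (!is.na(el_class) && el_class %in% c("Alu", "SVA", "ERVK")) {
    none$class <- el_class
    return(none)
  }
  src <- if (!is.null(td) && !is.null(registry))
    trace_source(td, registry, sample_id = sample_id) else NA_character_
  if (!is.null(td) && !is.na(src)) {
    none$src_id <- src
    none$td_chrom <- td$chrom; none$td_start <- td$start; none$td_end <- td$end
    if (has_l1) { none$class <- "L1_partnered_TD"; return(none) }
    if (polyA_len > 0 || polyA_mates > 0) {
      none$class <- "L1_orphan_TD"; return(none)
    }
    none$src_id <- NA_character_
  }
  if (has_l1) { none$class <- "solo_L1"; return(none) }
  if (polyA_len > 0 || polyA_mates > 0) {
    none$reject <- "polyA_only"; return(none)
  }
  none$reject <- "no_element_content"
  none
}

#' Trace a transduced interval to its source element
#'
#' The source is the registry element whose 10-kb downstream window
#' contains at least `min_containment` of the transduced interval;
#' ambiguity (two or more candidate windows) yields NA with a warning.
#' Somatic-origin sources are only eligible for calls from their own
#' sample.
#'
#' @param td list/row with chrom, start, end.
#' @param registry from [build_source_registry()].
#' @param min_containment containment fraction threshold (default 0.8).
#' @param sample_id sample of the call (for somatic-source scoping); NULL
#'   matches cohort-scoped sources only.
#' @return source id or NA.
#' @export
trace_source <- function(td, registry, min_containment = 0.8, sample_id = NULL) {
  if (is.null(registry) || nrow(registry) == 0) return(NA_character_)
  eligible <- registry$sample_scope == "cohort" |
    (!is.null(sample_id) & registry$sample_scope == (sample_id %||% ""))
  reg <- registry[eligible, , drop = FALSE]
  if (nrow(reg) == 0) return(NA_character_)
  frac <- ifelse(reg$chrom == td$chrom,
                 containment_fraction(td$start, td$end,
                                      reg$window_start, reg$window_end),
                 0)
  hit <- which(frac >= min_containment)
  if (length(hit) == 0) return(NA_character_)
  if (length(hit) > 1) {
    warning("transduced interval matches ", length(hit),
            " source windows; ambiguous, returning NA")
    return(NA_character_)
  }
  reg$id[hit]
}

#' Per-source transduction activity across samples
#'
#' Counts traced transductions per source per sample; a source is active
#' in a sample when it promoted at least one transduction there.
#'
#' @param calls MEI call table (cohort); rows with a non-NA `src_id` are
#'   traced transductions.
#' @param registry source registry.
#' @return list with `activity` (source x sample counts, long format),
#'   `per_source_total`, `active_sources_per_sample`, and `untraced`
#'   (count of transduction calls without a source).
#' @export
summarize_activity <- function(calls, registry) {
  is_td <- calls$class %in% c("L1_partnered_TD", "L1_orphan_TD")
  traced <- calls[is_td & !is.na(calls$src_id), , drop = FALSE]
  untraced <- sum(is_td & is.na(calls$src_id))
  if (nrow(traced)) {
    activity <- aggregate(list(n_td = traced$pos),
                          by = list(source_id = traced$src_id,
                                    sample_id = traced$sample_id), FUN = length)
  } else {
    activity <- data.frame(source_id = character(), sample_id = character(),
                           n_td = integer())
  }
  per_source <- if (nrow(activity))
    aggregate(list(total_td = activity$n_td),
              by = list(source_id = activity$source_id), FUN = sum)
  else data.frame(source_id = character(), total_td = integer())
  per_sample <- if (nrow(activity))
    aggregate(list(active_sources = activity$source_id),
              by = list(sample_id = activity$sample_id),
              FUN = function(x) length(unique(x)))
  else data.frame(sample_id = character(), active_sources = integer())
  list(activity = activity, per_source_total = per_source,
       active_sources_per_sample = per_sample, untraced = untraced)
}
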
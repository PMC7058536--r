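# Retroelement consensus library handling and read classification. The
# classifier is a local (Smith-Waterman) aligner over both strands of every
# consensus (match +1, mismatch -1, gap -2), with an optional shared-k-mer
# screen to skip hopeless read/consensus pairs.

MEI_CLASSES <- c("L1", "Alu", "SVA", "ERVK")

#' Read a retroelement consensus library from multi-FASTA
#'
#' Headers follow `>CLASS|SUBFAMILY` (e.g. `>L1|L1HS`). Sequences are
#' uppercased; classes outside L1/Alu/SVA/ERVK are rejected.
#'
#' @param path multi-FASTA file.
#' @return a `data.frame` with columns `class_name`, `subfamily`, `seq`.
#' @export
read_consensus_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  cls <- vapply(parts, `[`, "", 1)
  sub <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], "")
  consensus_library(cls, sub, as.character(ss))
}

#' Construct a consensus library in memory
#'
#' @param class_name vector of element classes (L1, Alu, SVA, ERVK).
#' @param subfamily subfamily labels.
#' @param seq uppercase DNA consensus sequences.
#' @return a `data.frame` library usable by [classify_read()].
#' @export
consensus_library <- function(class_name, subfamily, seq) {
  seq <- toupper(seq)
  if (any(!class_name %in% MEI_CLASSES))
    stop("unknown element class: ", paste(setdiff(class_name, MEI_CLASSES), collapse = ", "))
  if (any(nchar(seq) == 0) || any(grepl("[^ACGT]", seq)))
    stop("consensus sequences must be non-empty ACGT")
  structure(data.frame(class_name = class_name, subfamily = subfamily,
                       seq = seq, stringsAsFactors = FALSE),
            class = c("consensus_library", "data.frame"))
}

#' Write a consensus library to multi-FASTA
#' @param library a consensus library data.frame.
#' @param path output file.
#' @export
write_consensus_library <- function(library, path) {
  ss <- Biostrings::DNAStringSet(library$seq)
  names(ss) <- paste(library$class_name, library$subfamily, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Classify read sequences against the consensus library
#'
#' Best local alignment across both strands of every consensus. A hit is
#' reported when the best alignment reaches `min_identity` over at least
#' `min_len` aligned columns; ties are broken by longer alignment, then
#' library order. Vectorised over reads.
#'
#' @param seq character vector of read sequences.
#' @param library consensus library ([consensus_library()]).
#' @param min_identity minimum alignment identity (matches / alignment
#'   columns), default 0.85.
#' @param min_len minimum alignment length in columns, default 30.
#' @param seed_k shared-k-mer screen length (0 disables the screen and
#'   forces the exhaustive search).
#' @return a `data.frame` with one row per read: `class_name`, `subfamily`,
#'   `identity`, `consensus_start`, `consensus_end` (0-based half-open on
#'   the forward consensus), `read_orientation`, `aligned_len`; `NA` rows
#'   mean no hit.
#' @export
classify_read <- function(seq, library, min_identity = 0.85, min_len = 30L,
                          seed_k = 12L) {
  if (nrow(library) == 0) stop("empty consensus library")
  seq <- toupper(seq)
  res <- .sw_classify(seq, library$seq, revcomp(library$seq),
                      as.numeric(min_identity), as.integer(min_len),
                      1L, -1L, -2L, as.integer(seed_k))
  data.frame(
    class_name = ifelse(is.na(res$lib_index), NA_character_,
                        library$class_name[res$lib_index]),
    subfamily = ifelse(is.na(res$lib_index), NA_character_,
                       library$subfamily[res$lib_index]),
    identity = res$identity,
    consensus_start = res$consensus_start,
    consensus_end = res$consensus_end,
    read_orientation = res$orientation,
    aligned_len = res$aligned_len,
    stringsAsFactors = FALSE)
}

#' 5' truncation assessment from a consensus hit
#'
#' An element copy is called 5'-truncated when its alignment to the
#' consensus starts beyond a slack from the consensus 5' end.
#'
#' @param consensus_start,consensus_end 0-based half-open consensus span of
#'   the hit (forward consensus coordinates).
#' @param element_length full consensus length.
#' @param slack5 allowed 5' slack in bp before calling truncation
#'   (default 100).
#' @return list with `is_5prime_truncated` and `covered_span` (c(start, end)).
#' @export
consensus_position <- function(consensus_start, consensus_end, element_length,
                               slack5 = 100L) {
  if (any(is.na(c(consensus_start, consensus_end)))) stop("hit is null")
  if (consensus_start < 0 || consensus_end > element_length)
    stop("hit span outside element length")
  list(is_5prime_truncated = consensus_start > slack5,
       covered_span = c(consensus_start, consensus_end))
}
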
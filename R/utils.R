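# Small shared helpers. Internal coordinates are 0-based half-open
# throughout; conversion to 1-based happens only at VCF/BED emission.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement; tolerates N and lower case (output is
#' upper case).
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
  unname(out)
}

# genome interval data.frame constructor (0-based half-open)
genome_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(all(start >= 0), all(start <= end))
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

# fraction of interval a contained in interval b (same chrom assumed checked)
containment_fraction <- function(a_start, a_end, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  len <- pmax(1L, a_end - a_start)
  ov / len
}

# derive a reproducible child seed from a base seed and a tag; stays < 2^31
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

# length of the 5' and 3' soft/hard clips of a cigar string
cigar_clips <- function(cigar) {
  n <- length(cigar)
  c5 <- integer(n); c3 <- integer(n)
  has5 <- grepl("^[0-9]+[SH]", cigar)
  c5[has5] <- as.integer(regmatches(cigar, regexpr("^[0-9]+(?=[SH])", cigar, perl = TRUE)))
  has3 <- grepl("[0-9]+[SH]$", cigar)
  c3[has3] <- as.integer(sub("[SH]$", "", regmatches(cigar, regexpr("[0-9]+[SH]$", cigar))))
  list(clip5 = c5, clip3 = c3)
}

# reference span consumed by a cigar (M/D/N/=/X)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
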
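# canonical telomeric hexamer and its reverse complement
T_TYPE_FWD <- "TTAGGG"
T_TYPE_REV <- "CCCTAA"

#' Common telomere variant repeats
#'
#' The four most common telomeric hexamers scanned by the TVR and TERRA
#' modules: the canonical t-type repeat TTAGGG and the variants TGAGGG,
#' TCAGGG and TTGGGG. All other hexamers of the NNNGGG type are pooled
#' under `"other"` by [tvr_profile()].
#'
#' @format Character vector of length 4.
#' @export
COMMON_TVRS <- c("TTAGGG", "TGAGGG", "TCAGGG", "TTGGGG")

.check_dna <- function(seq, what = "seq") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (other than N) in %d sequence(s)",
                 what, sum(bad)), call. = FALSE)
  }
  invisible(seq)
}

.revcomp <- function(seq) {
  out <- character(length(seq))
  ok <- !is.na(seq) & nzchar(seq)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[ok])))
  }
  out[!ok] <- seq[!ok]
  out
}

#' Count t-type repeats in read sequences
#'
#' Counts non-overlapping occurrences of the canonical telomeric repeat
#' `TTAGGG` plus non-overlapping occurrences of its reverse complement
#' `CCCTAA`, scanning each sequence left to right. A hexamer cannot overlap
#' itself, so the left-to-right scan is unambiguous.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N only).
#' @return Integer vector of repeat counts, one per sequence.
#' @examples
#' count_t_type_repeats(c(strrep("TTAGGG", 4), "CCCTAACCCTAA", "ACGTACGT"))
#' @export
count_t_type_repeats <- function(seq) {
  if (length(seq) == 0L) return(integer(0))
  seq <- toupper(as.character(seq))
  .check_dna(seq)
  x <- Biostrings::DNAStringSet(seq)
  Biostrings::vcountPattern(T_TYPE_FWD, x) +
    Biostrings::vcountPattern(T_TYPE_REV, x)
}

#' Classify reads as telomeric
#'
#' A read is telomeric when it contains at least `min_repeats` t-type
#' repeats (`TTAGGG` or its reverse complement, summed across both
#' orientations; see [count_t_type_repeats()]).
#'
#' @param seq Character vector of read sequences.
#' @param min_repeats Minimum number of t-type repeats (default 4).
#' @return Logical vector.
#' @export
is_telomeric_read <- function(seq, min_repeats = 4L) {
  if (!is.numeric(min_repeats) || length(min_repeats) != 1L || min_repeats < 1) {
    stop("min_repeats must be a single integer >= 1", call. = FALSE)
  }
  count_t_type_repeats(seq) >= min_repeats
}

#' Orient a sequence to the G-rich telomeric strand
#'
#' Returns the sequence unchanged when it carries at least as many `TTAGGG`
#' as `CCCTAA` occurrences (ties keep the forward orientation), otherwise
#' its reverse complement. TVR scanning operates on G-strand sequence only.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of G-strand oriented sequences.
#' @export
orient_to_g_strand <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  seq <- toupper(as.character(seq))
  .check_dna(seq)
  x <- Biostrings::DNAStringSet(seq)
  fwd <- Biostrings::vcountPattern(T_TYPE_FWD, x)
  rev <- Biostrings::vcountPattern(T_TYPE_REV, x)
  flip <- rev > fwd
  seq[flip] <- .revcomp(seq[flip])
  seq
}

# longest single-nucleotide run in a sequence
.max_homopolymer <- function(seq) {
  vapply(strsplit(seq, ""), function(ch) {
    if (length(ch) == 0L) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}
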
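#' Quantify TERRA expression from RNA-seq reads
#'
#' Counts reads containing at least `min_repeats` occurrences of each of
#' the four most common telomeric hexamers ([COMMON_TVRS]; either
#' orientation), normalizes each count by the total number of reads and
#' multiplies by `scale` (10^6 by default, reads per million). The total
#' TERRA expression of a sample is the sum of the four individual
#' values. A read may count toward several variants when it carries
#' enough repeats of each. Counting operates on read sequences, so
#' unaligned FASTQ input works directly.
#'
#' @param seq Character vector of RNA read sequences.
#' @param sample_id Sample identifier.
#' @param min_repeats Minimum repeat occurrences per read per variant.
#' @param scale Normalization scale (default `1e6`).
#' @return List of class `terra_profile` with elements `sample_id`,
#'   `per_tvr` (named numeric, reads per million per variant), `total`,
#'   `counts` (raw read counts) and `total_reads`.
#' @examples
#' reads <- c(rep(strrep("TTAGGG", 6), 3), rep("ACGTACGTACGTACGT", 97))
#' terra_profile(reads, "S1")
#' @export
terra_profile <- function(seq, sample_id = "sample", min_repeats = 4L,
                          scale = 1e6) {
  if (length(seq) == 0L) stop("empty RNA read set", call. = FALSE)
  seq <- toupper(as.character(seq))
  .check_dna(seq)
  x <- Biostrings::DNAStringSet(seq)
  counts <- vapply(COMMON_TVRS, function(v) {
    hits <- Biostrings::vcountPattern(v, x) +
      Biostrings::vcountPattern(.revcomp(v), x)
    sum(hits >= min_repeats)
  }, integer(1))
  per_tvr <- counts / length(seq) * scale
  out <- list(sample_id = sample_id, per_tvr = per_tvr,
              total = sum(per_tvr), counts = counts,
              total_reads = length(seq))
  class(out) <- "terra_profile"
  out
}

#' @export
print.terra_profile <- function(x, ...) {
  cat(sprintf("TERRA profile of %s (%d reads):\n", x$sample_id, x$total_reads))
  print(data.frame(variant = names(x$per_tvr),
                   reads = as.integer(x$counts),
                   reads_per_million = as.numeric(x$per_tvr)),
        row.names = FALSE)
  cat(sprintf("total TERRA: %.4g reads per million\n", x$total))
  invisible(x)
}
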
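#' Estimate normalized telomere content from read sequences
#'
#' Counts reads containing at least `min_repeats` t-type repeats
#' (TTAGGG or its reverse complement) and normalizes by the total read
#' count, scaled to reads per million by default.
#'
#' @param seq Character vector of read sequences for one sample
#'   (all reads, not only telomeric ones).
#' @param sample_id Sample identifier.
#' @param role `"tumor"` or `"normal"`.
#' @param min_repeats Minimum t-type repeats defining a telomeric read.
#' @param scale Normalization scale (default `1e6`, reads per million).
#' @return A one-row data frame of class `telomere_count` with columns
#'   `sample_id`, `role`, `telomeric_reads`, `total_reads`, `content`.
#' @examples
#' reads <- c(rep(strrep("TTAGGG", 6), 2), rep("ACGTACGTACGT", 98))
#' telomere_content(reads, "S1", "tumor")
#' @seealso [tc_ratio()], [read_alignments()]
#' @export
telomere_content <- function(seq, sample_id = "sample", role = c("tumor", "normal"),
                             min_repeats = 4L, scale = 1e6) {
  role <- match.arg(role)
  if (length(seq) == 0L) stop("empty read set: cannot compute telomere content",
                              call. = FALSE)
  telo <- sum(is_telomeric_read(seq, min_repeats))
  total <- length(seq)
  out <- data.frame(sample_id = sample_id, role = role,
                    telomeric_reads = telo, total_reads = total,
                    content = telo / total * scale,
                    stringsAsFactors = FALSE)
  class(out) <- c("telomere_count", "data.frame")
  out
}

#' Tumor/normal telomere content ratio
#'
#' The per-patient telomere content estimate: the ratio of the tumor
#' sample's normalized telomere content to its matched normal's. Values
#' well above 1 indicate telomere gain, characteristic of ALT-positive
#' tumors. When no matched normal is available, the tumor's normalized
#' content alone (tumor-only mode) ranks samples similarly.
#'
#' @param tumor,normal `telomere_count` rows from [telomere_content()].
#' @return A one-row data frame of class `telomere_content_ratio` with
#'   columns `sample_id` and `ratio`.
#' @export
tc_ratio <- function(tumor, normal) {
  stopifnot(is.data.frame(tumor), is.data.frame(normal))
  if (normal$content <= 0) {
    stop("normal telomere content is zero: ratio undefined; ",
         "use the tumor-only content (tumor$content) instead", call. = FALSE)
  }
  out <- data.frame(sample_id = tumor$sample_id,
                    ratio = tumor$content / normal$content,
                    stringsAsFactors = FALSE)
  class(out) <- c("telomere_content_ratio", "data.frame")
  out
}
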
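# Frame-anchored hexamer scan of one G-strand sequence.
# Anchors on every TTAGGG occurrence and walks outwards in 6-mer steps
# through contiguous NNNGGG-compatible hexamers; positions reached from
# several anchors are counted once. Returns 1-based start positions and
# the hexamers found there. Isolated GGG triplets outside a telomeric
# run are never visited.
.scan_tvr_frame <- function(seq) {
  n <- nchar(seq)
  empty <- data.frame(pos = integer(0), hexamer = character(0),
                      stringsAsFactors = FALSE)
  if (n < 6L) return(empty)
  m <- gregexpr(T_TYPE_FWD, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  anchors <- as.integer(m)
  compatible <- function(p) {
    p >= 1L && p + 5L <= n &&
      substr(seq, p + 3L, p + 5L) == "GGG" &&
      !grepl("[^ACGT]", substr(seq, p, p + 2L))
  }
  pos <- integer(0)
  for (a in anchors) {
    p <- a
    while (compatible(p)) {   # leftward walk includes the anchor itself
      pos <- c(pos, p)
      p <- p - 6L
    }
    p <- a + 6L
    while (compatible(p)) {
      pos <- c(pos, p)
      p <- p + 6L
    }
  }
  pos <- sort(unique(pos))
  data.frame(pos = pos, hexamer = substring(seq, pos, pos + 5L),
             stringsAsFactors = FALSE)
}

#' Count telomere variant repeat occurrences in one sequence
#'
#' Walks the sequence in the hexamer frame anchored on `TTAGGG`
#' occurrences and tallies every frame hexamer of the NNNGGG type under
#' its exact sequence. The input must already be G-strand oriented
#' (see [orient_to_g_strand()]).
#'
#' @param seq A single G-strand DNA sequence.
#' @return Named integer vector of hexamer counts (possibly empty).
#' @examples
#' count_tvr_occurrences(paste0(strrep("TTAGGG", 2), "TGAGGG", strrep("TTAGGG", 2)))
#' @export
count_tvr_occurrences <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(as.character(seq))
  .check_dna(seq)
  hits <- .scan_tvr_frame(seq)
  if (nrow(hits) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(hits$hexamer)
  setNames(as.integer(tab), names(tab))
}

#' Find TVR singletons in one sequence
#'
#' A TVR singleton is a variant hexamer of the NNNGGG type (not TTAGGG)
#' surrounded by at least three canonical t-type repeats on either side:
#' `(TTAGGG)3 - NNNGGG - (TTAGGG)3`. Flanking repeats may be shared
#' between adjacent singletons. The input must be G-strand oriented.
#'
#' @param seq A single G-strand DNA sequence.
#' @return Data frame with columns `variant` and `pos` (1-based start of
#'   the variant hexamer within `seq`).
#' @export
find_tvr_singletons <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(as.character(seq))
  .check_dna(seq)
  flank <- strrep(T_TYPE_FWD, 3L)
  hits <- .scan_tvr_frame(seq)
  hits <- hits[hits$hexamer != T_TYPE_FWD, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(variant = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  p <- hits$pos
  ok <- p >= 19L & p + 23L <= nchar(seq) &
    substring(seq, p - 18L, p - 1L) == flank &
    substring(seq, p + 6L, p + 23L) == flank
  data.frame(variant = hits$hexamer[ok], pos = p[ok],
             stringsAsFactors = FALSE)
}

#' TVR composition and singleton profile of a sample
#'
#' Screens the telomeric reads of a sample (reads passing
#' [is_telomeric_read()]) for telomere variant repeats and TVR
#' singletons. Reads are G-strand oriented before scanning. Occurrence
#' and singleton counts are reported for the four most common hexamers
#' ([COMMON_TVRS]) individually; all non-canonical NNNGGG variants are
#' additionally pooled under `"other"`.
#'
#' @param seq Character vector of all read sequences of the sample.
#' @param sample_id Sample identifier.
#' @param role `"tumor"` or `"normal"`.
#' @param min_repeats Telomeric-read threshold passed to
#'   [is_telomeric_read()].
#' @return List of class `tvr_profile` with elements `sample_id`, `role`,
#'   `tvr_counts` (named integer vector: the four common hexamers, any
#'   observed variant, and `other`), `singleton_counts` (same layout),
#'   `telomeric_reads` and `total_reads`.
#' @export
tvr_profile <- function(seq, sample_id = "sample", role = c("tumor", "normal"),
                        min_repeats = 4L) {
  role <- match.arg(role)
  seq <- toupper(as.character(seq))
  total <- length(seq)
  telo <- seq[is_telomeric_read(seq, min_repeats)]
  telo <- orient_to_g_strand(telo)

  tvr <- integer(0)
  singles <- integer(0)
  for (s in telo) {
    occ <- count_tvr_occurrences(s)
    for (v in names(occ)) tvr[v] <- (if (v %in% names(tvr)) tvr[[v]] else 0L) + occ[[v]]
    sg <- find_tvr_singletons(s)
    if (nrow(sg) > 0L) {
      st <- table(sg$variant)
      for (v in names(st)) {
        singles[v] <- (if (v %in% names(singles)) singles[[v]] else 0L) +
          as.integer(st[[v]])
      }
    }
  }
  pad <- function(x) {
    for (v in COMMON_TVRS) if (!v %in% names(x)) x[v] <- 0L
    noncanon <- setdiff(names(x), c(COMMON_TVRS, "other"))
    x["other"] <- sum(x[noncanon])
    x[c(COMMON_TVRS, noncanon, "other")]
  }
  out <- list(sample_id = sample_id, role = role,
              tvr_counts = pad(tvr), singleton_counts = pad(singles),
              telomeric_reads = length(telo), total_reads = total)
  class(out) <- "tvr_profile"
  out
}

#' @export
print.tvr_profile <- function(x, ...) {
  cat(sprintf("TVR profile of %s (%s): %d telomeric / %d reads\n",
              x$sample_id, x$role, x$telomeric_reads, x$total_reads))
  df <- data.frame(hexamer = names(x$tvr_counts),
                   occurrences = as.integer(x$tvr_counts),
                   singletons = as.integer(x$singleton_counts[names(x$tvr_counts)]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Telomere-content-normalized log2 singleton ratio
#'
#' Compares the per-read singleton rate of a variant between tumor and
#' normal, further divided by the tumor/normal telomere content ratio so
#' that subgroups with very different telomere content remain comparable:
#' `log2((tumor_singletons/tumor_reads) / (normal_singletons/normal_reads)
#' / tc_ratio)`. When either singleton count is zero, a pseudocount of
#' 0.5 is added to both and the result is flagged.
#'
#' @param tumor,normal `tvr_profile` objects.
#' @param tc Tumor/normal telomere content ratio: a number or a
#'   `telomere_content_ratio` row from [tc_ratio()].
#' @param variant Variant hexamer, e.g. `"TTTGGG"`.
#' @param pseudocount Value added to both counts when either is zero.
#' @return One-row data frame with `sample_id`, `variant`, `log2_ratio`
#'   and `pseudocount_used`.
#' @export
singleton_ratio <- function(tumor, normal, tc, variant, pseudocount = 0.5) {
  stopifnot(inherits(tumor, "tvr_profile"), inherits(normal, "tvr_profile"))
  if (is.data.frame(tc)) tc <- tc$ratio
  if (!is.finite(tc) || tc <= 0) stop("tc ratio must be positive", call. = FALSE)
  st <- if (variant %in% names(tumor$singleton_counts))
    tumor$singleton_counts[[variant]] else 0L
  sn <- if (variant %in% names(normal$singleton_counts))
    normal$singleton_counts[[variant]] else 0L
  flagged <- (st == 0L || sn == 0L)
  if (flagged) {
    if (pseudocount <= 0) {
      stop(sprintf("zero singleton count for %s and no pseudocount", variant),
           call. = FALSE)
    }
    st <- st + pseudocount
    sn <- sn + pseudocount
  }
  lr <- log2((st / tumor$total_reads) / (sn / normal$total_reads) / tc)
  data.frame(sample_id = tumor$sample_id, variant = variant,
             log2_ratio = lr, pseudocount_used = flagged,
             stringsAsFactors = FALSE)
}
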
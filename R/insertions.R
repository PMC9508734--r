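#' Insertion caller configuration
#'
#' Thresholds of the telomere-insertion screen. Defaults follow the
#' published detection scheme: the genome is tiled into 1 kb windows; a
#' window is a candidate when the tumor holds at least three
#' telomere-insertion read pairs and the matched normal none; breakpoint
#' refinement requires telomeric soft clips of at least 15 bp carrying at
#' least two t-type repeats that start at the same position (+/- 1 bp),
#' with at least two such reads per breakpoint.
#'
#' @param window_size Tiling window size in bp.
#' @param min_tumor_pairs Minimum tumor insertion pairs per window.
#' @param max_normal_pairs Maximum normal insertion pairs per window.
#' @param min_clip_len Minimum soft-clip length (bp).
#' @param min_clip_repeats Minimum t-type repeats within the clip.
#' @param clip_start_tolerance Clip start tolerance (bp).
#' @param min_clip_reads Minimum qualifying clipped reads per breakpoint.
#' @param pairing_distance Maximum distance (bp) for merging two opposite
#'   breakpoints into one two-sided insertion.
#' @param context_filter_window Half-width (bp) of the reference context
#'   checked around a breakpoint by the automated context filter.
#' @param min_repeats Telomeric-read rule for the pair screen
#'   (see [is_telomeric_read()]).
#' @return List of class `insertion_caller_config`.
#' @export
insertion_caller_config <- function(window_size = 1000L, min_tumor_pairs = 3L,
                                    max_normal_pairs = 0L, min_clip_len = 15L,
                                    min_clip_repeats = 2L,
                                    clip_start_tolerance = 1L,
                                    min_clip_reads = 2L,
                                    pairing_distance = 5000L,
                                    context_filter_window = 100L,
                                    min_repeats = 4L) {
  cfg <- list(window_size = as.integer(window_size),
              min_tumor_pairs = as.integer(min_tumor_pairs),
              max_normal_pairs = as.integer(max_normal_pairs),
              min_clip_len = as.integer(min_clip_len),
              min_clip_repeats = as.integer(min_clip_repeats),
              clip_start_tolerance = as.integer(clip_start_tolerance),
              min_clip_reads = as.integer(min_clip_reads),
              pairing_distance = as.integer(pairing_distance),
              context_filter_window = as.integer(context_filter_window),
              min_repeats = as.integer(min_repeats))
  if (any(unlist(cfg) < 0L)) stop("thresholds must be non-negative", call. = FALSE)
  class(cfg) <- "insertion_caller_config"
  cfg
}

# soft-clip geometry from CIGAR strings
.cigar_clips <- function(cigar, seq) {
  left <- right <- integer(length(cigar))
  has_l <- !is.na(cigar) & grepl("^\\d+S", cigar)
  left[has_l] <- as.integer(sub("^(\\d+)S.*", "\\1", cigar[has_l]))
  has_r <- !is.na(cigar) & grepl("\\d+S$", cigar)
  right[has_r] <- as.integer(sub(".*?(\\d+)S$", "\\1", cigar[has_r]))
  ref_span <- vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  nc <- nchar(seq)
  data.frame(left_len = left, right_len = right, ref_span = ref_span,
             left_seq = substring(seq, 1L, left),
             right_seq = substring(seq, nc - right + 1L, nc),
             stringsAsFactors = FALSE)
}

.point_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || length(regions) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  GenomicRanges::countOverlaps(gr, regions, ignore.strand = TRUE) > 0L
}

#' Collect telomere-insertion read-pair anchors
#'
#' Screens read pairs where exactly one mate is telomeric and the other
#' maps onto the genome outside the supplied telomeric/centromeric
#' exclusion regions. The anchor is the 5' mapping coordinate of the
#' non-telomeric mate.
#'
#' @param aln Alignment data frame (see [read_alignments()]); both mates
#'   of a pair share `read_id`.
#' @param excluded `GRanges` of excluded regions (or `NULL`).
#' @param min_repeats Telomeric-read threshold.
#' @return Data frame of anchors with columns `chrom` and `pos`.
#' @export
collect_insertion_pairs <- function(aln, excluded = NULL, min_repeats = 4L) {
  if (nrow(aln) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  paired <- bitwAnd(aln$flag, 1L) > 0L   # pair screen ignores unpaired records
  aln <- aln[paired, , drop = FALSE]
  if (nrow(aln) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  telo <- is_telomeric_read(aln$seq, min_repeats)
  n_mates <- table(aln$read_id)
  incomplete <- sum(n_mates != 2L)
  if (incomplete > 0L) {
    warning(sprintf("%d paired read id(s) without exactly two records skipped",
                    incomplete), call. = FALSE)
  }
  keep <- aln$read_id %in% names(n_mates)[n_mates == 2L]
  aln <- aln[keep, , drop = FALSE]
  telo <- telo[keep]

  sp <- split(seq_len(nrow(aln)), aln$read_id)
  anchors <- lapply(sp, function(idx) {
    t1 <- telo[idx]
    if (sum(t1) != 1L) return(NULL)          # need exactly one telomeric mate
    other <- idx[!t1]
    if (is.na(aln$chrom[other])) return(NULL)  # anchor mate must be mapped
    data.frame(chrom = aln$chrom[other], pos = aln$pos[other],
               stringsAsFactors = FALSE)
  })
  anchors <- do.call(rbind, anchors)
  if (is.null(anchors) || nrow(anchors) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  rownames(anchors) <- NULL
  drop <- .point_in_regions(anchors$chrom, anchors$pos, excluded)
  anchors[!drop, , drop = FALSE]
}

#' Screen fixed genomic windows for insertion candidates
#'
#' Tiles each chromosome into fixed, non-sliding windows (0-based
#' multiples of `window_size`, half-open) and keeps windows holding at
#' least `min_tumor_pairs` tumor anchors and at most `max_normal_pairs`
#' normal anchors (zero by default).
#'
#' @param tumor_anchors,normal_anchors Anchor data frames from
#'   [collect_insertion_pairs()].
#' @param cfg [insertion_caller_config()].
#' @return Data frame of candidate windows: `chrom`, `start`, `end`
#'   (1-based closed), `n_tumor`, `n_normal`.
#' @export
screen_windows <- function(tumor_anchors, normal_anchors = NULL,
                           cfg = insertion_caller_config()) {
  w <- cfg$window_size
  key <- function(a) {
    if (is.null(a) || nrow(a) == 0L) return(character(0))
    sprintf("%s:%d", a$chrom, (a$pos - 1L) %/% w)
  }
  tt <- table(key(tumor_anchors))
  nn <- table(key(normal_anchors))
  keep <- names(tt)[tt >= cfg$min_tumor_pairs]
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_tumor = integer(0),
                      n_normal = integer(0), stringsAsFactors = FALSE))
  }
  n_norm <- ifelse(keep %in% names(nn), as.integer(nn[keep]), 0L)
  ok <- n_norm <= cfg$max_normal_pairs
  keep <- keep[ok]
  n_norm <- n_norm[ok]
  chrom <- sub(":[^:]*$", "", keep)
  k <- as.integer(sub(".*:", "", keep))
  out <- data.frame(chrom = chrom, start = k * w + 1L, end = (k + 1L) * w,
                    n_tumor = as.integer(tt[keep]), n_normal = n_norm,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# automated context filter: reject breakpoints whose flanking reference
# sequence is itself telomere-like or a long homopolymer (the published
# scheme removed such calls by manual IGV review)
.context_ok <- function(chrom, pos, reference, half_width) {
  if (is.null(reference)) return(rep(TRUE, length(pos)))
  vapply(seq_along(pos), function(i) {
    if (!chrom[i] %in% names(reference)) return(TRUE)
    n <- Biostrings::width(reference[chrom[i]])
    lo <- max(1L, pos[i] - half_width)
    hi <- min(n, pos[i] + half_width)
    ctx <- as.character(Biostrings::subseq(reference[[chrom[i]]], lo, hi))
    count_t_type_repeats(ctx) < 2L && .max_homopolymer(ctx) < 20L
  }, logical(1))
}

#' Refine candidate windows into breakpoints
#'
#' Searches the tumor alignments of each candidate window for telomeric
#' soft-clipped reads: clip length at least `min_clip_len`, at least
#' `min_clip_repeats` t-type repeats within the clipped sequence, and
#' clip start positions within `clip_start_tolerance` of each other.
#' Same-direction clusters with at least `min_clip_reads` reads become
#' breakpoints; each breakpoint then passes the automated reference
#' context filter. For right clips the breakpoint is the reference
#' coordinate of the first clipped base; for left clips, the base
#' preceding the clip.
#'
#' @param windows Candidate windows from [screen_windows()].
#' @param tumor_aln Tumor alignment data frame.
#' @param cfg [insertion_caller_config()].
#' @param reference Optional [Biostrings::DNAStringSet] reference for the
#'   context filter (skipped when `NULL`).
#' @return Data frame of breakpoints: `chrom`, `pos` (1-based),
#'   `direction` (`right_clip`/`left_clip`), `n_clip_reads`,
#'   `n_support_pairs`, `window_start`, `window_end`.
#' @export
refine_breakpoints <- function(windows, tumor_aln,
                               cfg = insertion_caller_config(),
                               reference = NULL) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      direction = character(0), n_clip_reads = integer(0),
                      n_support_pairs = integer(0), window_start = integer(0),
                      window_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(windows) == 0L || nrow(tumor_aln) == 0L) return(empty)

  mapped <- !is.na(tumor_aln$chrom)
  aln <- tumor_aln[mapped, , drop = FALSE]
  clips <- .cigar_clips(aln$cigar, aln$seq)

  # candidate clip events: (chrom, clip start coordinate, breakpoint, dir)
  ev <- list()
  right_ok <- clips$right_len >= cfg$min_clip_len &
    count_t_type_repeats(clips$right_seq) >= cfg$min_clip_repeats
  if (any(right_ok)) {
    ev$right <- data.frame(chrom = aln$chrom[right_ok],
                           bp = aln$pos[right_ok] + clips$ref_span[right_ok],
                           direction = "right_clip", stringsAsFactors = FALSE)
  }
  left_ok <- clips$left_len >= cfg$min_clip_len &
    count_t_type_repeats(clips$left_seq) >= cfg$min_clip_repeats
  if (any(left_ok)) {
    ev$left <- data.frame(chrom = aln$chrom[left_ok],
                          bp = aln$pos[left_ok] - 1L,
                          direction = "left_clip", stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0L) return(empty)

  out <- list()
  for (i in seq_len(nrow(windows))) {
    win <- windows[i, ]
    for (dir in c("right_clip", "left_clip")) {
      e <- ev[ev$chrom == win$chrom & ev$direction == dir &
                ev$bp >= win$start & ev$bp <= win$end, , drop = FALSE]
      if (nrow(e) < cfg$min_clip_reads) next
      p <- sort(e$bp)
      # greedy clustering: all starts within +/- tolerance of a common position
      while (length(p) > 0L) {
        in_cl <- p <= p[1L] + 2L * cfg$clip_start_tolerance
        cl <- p[in_cl]
        p <- p[!in_cl]
        if (length(cl) < cfg$min_clip_reads) next
        tab <- table(cl)
        bp <- as.integer(names(tab)[which.max(tab)])   # modal start, lowest on tie
        out[[length(out) + 1L]] <- data.frame(
          chrom = win$chrom, pos = bp, direction = dir,
          n_clip_reads = length(cl), n_support_pairs = win$n_tumor,
          window_start = win$start, window_end = win$end,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  keep <- .context_ok(out$chrom, out$pos, reference, cfg$context_filter_window)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble breakpoints into telomere insertions
#'
#' Opposite-direction breakpoint pairs within `pairing_distance` on the
#' same chromosome merge into one two-sided insertion (nearest-first);
#' every remaining breakpoint is reported as a one-sided insertion, so
#' the insertion count equals the breakpoint count minus the number of
#' merges.
#'
#' @param breakpoints Breakpoint data frame from [refine_breakpoints()].
#' @param cfg [insertion_caller_config()].
#' @return Data frame of insertions: `chrom`, `start`, `end`,
#'   `sidedness`, `n_breakpoints`, `n_clip_reads`.
#' @export
assemble_insertions <- function(breakpoints, cfg = insertion_caller_config()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sidedness = character(0),
                      n_breakpoints = integer(0), n_clip_reads = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(breakpoints) == 0L) return(empty)
  bp <- breakpoints[order(breakpoints$chrom, breakpoints$pos), , drop = FALSE]
  used <- rep(FALSE, nrow(bp))
  out <- list()
  for (i in seq_len(nrow(bp))) {
    if (used[i]) next
    used[i] <- TRUE
    partner <- which(!used & bp$chrom == bp$chrom[i] &
                       bp$direction != bp$direction[i] &
                       abs(bp$pos - bp$pos[i]) <= cfg$pairing_distance)
    if (length(partner) > 0L) {
      j <- partner[which.min(abs(bp$pos[partner] - bp$pos[i]))]
      used[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        chrom = bp$chrom[i], start = min(bp$pos[c(i, j)]),
        end = max(bp$pos[c(i, j)]), sidedness = "two_sided",
        n_breakpoints = 2L,
        n_clip_reads = sum(bp$n_clip_reads[c(i, j)]),
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = bp$chrom[i], start = bp$pos[i], end = bp$pos[i],
        sidedness = "one_sided", n_breakpoints = 1L,
        n_clip_reads = bp$n_clip_reads[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call telomere insertions from paired tumor/normal alignments
#'
#' End-to-end insertion screen: telomere-insertion read-pair collection,
#' 1 kb window screening against the matched normal, soft-clip breakpoint
#' refinement with the automated context filter, and assembly into one-
#' or two-sided insertions. Running without a matched normal is supported
#' but flagged with a warning, since it inflates false positives.
#'
#' @param tumor_aln,normal_aln Alignment data frames; `normal_aln` may be
#'   `NULL` for tumor-only mode.
#' @param excluded `GRanges` of telomeric/centromeric exclusion regions.
#' @param reference Optional reference `DNAStringSet` for the context
#'   filter.
#' @param cfg [insertion_caller_config()].
#' @return List of class `telomere_insertions` with elements `windows`,
#'   `breakpoints`, `insertions` and `n_insertions`.
#' @export
call_insertions <- function(tumor_aln, normal_aln = NULL, excluded = NULL,
                            reference = NULL,
                            cfg = insertion_caller_config()) {
  if (is.null(normal_aln)) {
    warning("no matched normal supplied: tumor-only insertion calling ",
            "is prone to false positives", call. = FALSE)
  }
  t_anchors <- collect_insertion_pairs(tumor_aln, excluded, cfg$min_repeats)
  n_anchors <- if (is.null(normal_aln)) NULL else
    collect_insertion_pairs(normal_aln, excluded, cfg$min_repeats)
  windows <- screen_windows(t_anchors, n_anchors, cfg)
  breakpoints <- refine_breakpoints(windows, tumor_aln, cfg, reference)
  insertions <- assemble_insertions(breakpoints, cfg)
  out <- list(windows = windows, breakpoints = breakpoints,
              insertions = insertions, n_insertions = nrow(insertions))
  class(out) <- "telomere_insertions"
  out
}

#' @export
print.telomere_insertions <- function(x, ...) {
  cat(sprintf("telomere insertion screen: %d candidate window(s), %d breakpoint(s), %d insertion(s)\n",
              nrow(x$windows), nrow(x$breakpoints), x$n_insertions))
  if (x$n_insertions > 0L) print(x$insertions, row.names = FALSE)
  invisible(x)
}
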
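# Alignment tables
#
# All sequence-level operations consume a plain data frame of alignment
# records with columns:
#   read_id    character
#   flag       integer SAM flag
#   chrom      character or NA (NA = unmapped)
#   pos        integer, 1-based leftmost aligned position, NA if unmapped
#   cigar      character ("*" if unmapped)
#   seq        character read sequence
#   mate_chrom character or NA
#   mate_pos   integer or NA
# Positions are 1-based throughout the package (SAM/R convention);
# 0-based half-open coordinates appear only in BED files, converted at
# the I/O boundary by rtracklayer.

.aln_cols <- c("read_id", "flag", "chrom", "pos", "cigar", "seq",
               "mate_chrom", "mate_pos")

#' Read an alignment table from BAM or SAM
#'
#' Thin wrapper over [Rsamtools::scanBam()] returning the package's plain
#' alignment data frame. SAM input is converted to BAM in a temporary
#' file first. By default only primary alignments are kept so that a read
#' is never counted twice.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @param primary_only Drop secondary and supplementary records
#'   (default `TRUE`).
#' @return Data frame with columns `read_id`, `flag`, `chrom`, `pos`,
#'   `cigar`, `seq`, `mate_chrom`, `mate_pos`.
#' @export
read_alignments <- function(path, primary_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- if (primary_only) {
    Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE)
  } else Rsamtools::scanBamFlag()
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "mrnm", "mpos"),
    flag = flag)
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  df <- data.frame(
    read_id = b$qname,
    flag = b$flag,
    chrom = ifelse(unmapped, NA_character_, as.character(b$rname)),
    pos = ifelse(unmapped, NA_integer_, b$pos),
    cigar = ifelse(is.na(b$cigar), "*", b$cigar),
    seq = as.character(b$seq),
    mate_chrom = as.character(b$mrnm),
    mate_pos = b$mpos,
    stringsAsFactors = FALSE)
  df
}

#' Write an alignment table as SAM
#'
#' Emits a minimal valid SAM file (used by the simulators so that
#' downstream steps can be exercised through standard BAM tooling).
#' Unmapped records with a mapped mate are placed at the mate's
#' coordinate, following SAM convention.
#'
#' @param aln Alignment data frame (see [read_alignments()]).
#' @param path Output path (`.sam`).
#' @param seqlengths Named integer vector of reference contig lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlengths) {
  stopifnot(all(.aln_cols %in% names(aln)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(seqlengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths)[i],
                       as.integer(seqlengths[i])), con)
  }
  unmapped <- is.na(aln$chrom)
  rname <- ifelse(unmapped,
                  ifelse(is.na(aln$mate_chrom), "*", aln$mate_chrom),
                  aln$chrom)
  pos <- ifelse(unmapped,
                ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos),
                aln$pos)
  rnext <- ifelse(is.na(aln$mate_chrom), "*", aln$mate_chrom)
  pnext <- ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos)
  cigar <- ifelse(unmapped | is.na(aln$cigar), "*", aln$cigar)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                   aln$read_id, aln$flag, rname, pos,
                   ifelse(unmapped, 0L, 60L), cigar, rnext, pnext, aln$seq)
  writeLines(lines, con)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' @param path FASTQ/FASTA path (gzip allowed).
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  fmt <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE))
    "fasta" else "fastq"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Write sequences as FASTQ
#'
#' @param seq Character vector of sequences.
#' @param path Output path.
#' @param ids Read identifiers (default `read1..readN`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seq, path, ids = sprintf("read%d", seq_along(seq))) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read exclusion regions from a BED file
#'
#' Telomeric/centromeric exclusion intervals for the insertion caller.
#' BED is 0-based half-open on disk; the returned `GRanges` is 1-based.
#'
#' @param path BED path.
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_excluded_regions <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read / write a cohort marker table
#'
#' One row per sample with the marker panel feeding TMM classification.
#' Logical markers (`mna`, `tert_ra`, `atrx_mut`, `tert_expr_high`,
#' `telomerase_activity_high`, `apb`, `cca`) and numeric auxiliaries
#' (`tc_ratio`, `trf_kb`, `terra_total`, `tttggg_singleton_log2`,
#' `n_insertions`); missing values written as `NA`.
#'
#' @param path TSV path.
#' @return `read_cohort`: data frame of sample features.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, na.strings = c("NA", ""),
                   stringsAsFactors = FALSE)
  for (col in .logical_markers) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname read_cohort
#' @param features Sample feature data frame.
#' @return `write_cohort`: `path`, invisibly.
#' @export
write_cohort <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
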
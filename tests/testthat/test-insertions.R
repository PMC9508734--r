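telo_seq <- function(k = 17L) strrep("TTAGGG", k)

pair_rows <- function(id, anchor_chrom, anchor_pos, telomeric = TRUE) {
  mate_seq <- if (telomeric) telo_seq() else strrep("ACGT", 25)
  rbind(
    data.frame(read_id = id, flag = 137L, chrom = anchor_chrom,
               pos = anchor_pos, cigar = "100M", seq = strrep("ACGT", 25),
               mate_chrom = NA_character_, mate_pos = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(read_id = id, flag = 69L, chrom = NA_character_,
               pos = NA_integer_, cigar = "*", seq = mate_seq,
               mate_chrom = anchor_chrom, mate_pos = anchor_pos,
               stringsAsFactors = FALSE))
}

test_that("pair collection anchors on the mapped non-telomeric mate", {
  excl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  aln <- rbind(pair_rows("p1", "chr1", 10000L),
               pair_rows("p2", "chr1", 20000L, telomeric = FALSE),
               pair_rows("p3", "chr1", 500L))       # anchor inside exclusion
  anchors <- collect_insertion_pairs(aln, excl)
  expect_equal(anchors$pos, 10000L)
  expect_equal(anchors$chrom, "chr1")
})

test_that("window screening enforces tumor minimum and clean normal", {
  cfg <- insertion_caller_config()
  t3 <- data.frame(chrom = "chr1", pos = c(10100L, 10400L, 10900L))
  t2 <- data.frame(chrom = "chr2", pos = c(5100L, 5200L))
  n1 <- data.frame(chrom = "chr1", pos = 10500L)

  ok <- screen_windows(t3, NULL, cfg)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$start, 10001L)
  expect_equal(ok$end, 11000L)
  expect_equal(ok$n_tumor, 3L)

  expect_equal(nrow(screen_windows(t2, NULL, cfg)), 0L)
  expect_equal(nrow(screen_windows(t3, n1, cfg)), 0L)
})

test_that("breakpoint refinement demands long telomeric clips in a tight cluster", {
  cfg <- insertion_caller_config()
  win <- data.frame(chrom = "chr1", start = 10001L, end = 11000L,
                    n_tumor = 3L, n_normal = 0L)
  clip_read <- function(id, pos, cigar, seq) {
    data.frame(read_id = id, flag = 0L, chrom = "chr1", pos = pos,
               cigar = cigar, seq = seq, mate_chrom = NA_character_,
               mate_pos = NA_integer_, stringsAsFactors = FALSE)
  }
  body <- strrep("ACGT", 15)   # 60 bp aligned
  good <- paste0(body, strrep("TTAGGG", 4))   # 24 bp clip, 4 repeats

  two <- rbind(clip_read("c1", 10440L, "60M24S", good),
               clip_read("c2", 10440L, "60M24S", good))
  bp <- refine_breakpoints(win, two, cfg)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$pos, 10500L)
  expect_equal(bp$direction, "right_clip")
  expect_equal(bp$n_clip_reads, 2L)

  # 12 bp clip with 2 repeats: too short
  short <- rbind(clip_read("c1", 10440L, "60M12S",
                           paste0(body, strrep("TTAGGG", 2))),
                 clip_read("c2", 10440L, "60M12S",
                           paste0(body, strrep("TTAGGG", 2))))
  expect_equal(nrow(refine_breakpoints(win, short, cfg)), 0L)

  # a single qualifying read is below the cluster minimum
  expect_equal(nrow(refine_breakpoints(win, two[1, ], cfg)), 0L)

  # starts 3 bp apart do not cluster at tolerance 1
  spread <- rbind(clip_read("c1", 10440L, "60M24S", good),
                  clip_read("c2", 10443L, "60M24S", good))
  expect_equal(nrow(refine_breakpoints(win, spread, cfg)), 0L)
})

test_that("the context filter rejects telomere-like reference flanks", {
  cfg <- insertion_caller_config()
  win <- data.frame(chrom = "chrT", start = 1L, end = 1000L,
                    n_tumor = 3L, n_normal = 0L)
  body <- strrep("ACGT", 15)
  good <- paste0(body, strrep("TTAGGG", 4))
  reads <- data.frame(read_id = c("c1", "c2"), flag = 0L, chrom = "chrT",
                      pos = 440L, cigar = "60M24S", seq = good,
                      mate_chrom = NA_character_, mate_pos = NA_integer_,
                      stringsAsFactors = FALSE)
  telomeric_ref <- Biostrings::DNAStringSet(c(chrT = strrep("TTAGGG", 200)))
  expect_equal(nrow(refine_breakpoints(win, reads, cfg, telomeric_ref)), 0L)
  clean_ref <- Biostrings::DNAStringSet(c(chrT = strrep("ACGT", 300)))
  expect_equal(nrow(refine_breakpoints(win, reads, cfg, clean_ref)), 1L)
})

test_that("insertion assembly merges opposite breakpoints within range", {
  cfg <- insertion_caller_config()
  bp <- function(pos, dir) {
    data.frame(chrom = "chr1", pos = pos, direction = dir, n_clip_reads = 2L,
               n_support_pairs = 3L, window_start = 1L, window_end = 1000L,
               stringsAsFactors = FALSE)
  }
  one <- assemble_insertions(bp(500L, "right_clip"), cfg)
  expect_equal(one$sidedness, "one_sided")

  two <- assemble_insertions(rbind(bp(500L, "right_clip"),
                                   bp(800L, "left_clip")), cfg)
  expect_equal(nrow(two), 1L)
  expect_equal(two$sidedness, "two_sided")
  expect_equal(c(two$start, two$end), c(500L, 800L))

  far <- assemble_insertions(rbind(bp(500L, "right_clip"),
                                   bp(9000L, "left_clip")), cfg)
  expect_equal(nrow(far), 2L)
  expect_true(all(far$sidedness == "one_sided"))

  # many breakpoints, exactly one opposite pair in range: count drops by one
  set.seed(5)
  lots <- do.call(rbind, lapply(seq_len(132L), function(i)
    bp(20000L * i, "right_clip")))
  lots <- rbind(lots, bp(500L, "right_clip"), bp(800L, "left_clip"))
  res <- assemble_insertions(lots, cfg)
  expect_equal(nrow(res), 133L)
  expect_equal(sum(res$sidedness == "two_sided"), 1L)
})

test_that("planted insertions are recovered exactly and the null case is silent", {
  sites <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                      pos = c(12500L, 30499L, 22222L),
                      n_pairs = c(4L, 3L, 3L), n_clips = c(3L, 2L, 2L),
                      direction = c("right", "left", "right"))
  sim <- simulate_wgs_pair(seed = 77, n_reads = 6000L,
                           insertion_sites = sites)
  res <- call_insertions(sim$tumor, sim$normal, sim$excluded, sim$reference)
  expect_equal(res$n_insertions, 3L)
  found <- res$breakpoints[order(res$breakpoints$chrom), ]
  truth <- sites[order(sites$chrom), ]
  expect_true(all(abs(found$pos - truth$pos) <= 1L))
  # no calls anywhere else
  expect_true(all(found$chrom == truth$chrom))
  # tumor versus itself: nothing survives the clean-normal requirement
  null_res <- call_insertions(sim$tumor, sim$tumor, sim$excluded,
                              sim$reference)
  expect_equal(null_res$n_insertions, 0L)
  expect_equal(nrow(null_res$windows), 0L)
})

test_that("call counts never increase when thresholds are raised", {
  sites <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(12500L, 18700L, 25500L),
                      n_pairs = c(5L, 3L, 2L), n_clips = c(3L, 2L, 2L))
  sim <- simulate_wgs_pair(seed = 13, n_reads = 5000L,
                           insertion_sites = sites)
  n_calls <- function(min_pairs, min_clips) {
    cfg <- insertion_caller_config(min_tumor_pairs = min_pairs,
                                   min_clip_reads = min_clips)
    call_insertions(sim$tumor, sim$normal, sim$excluded, sim$reference,
                    cfg)$n_insertions
  }
  base <- n_calls(3L, 2L)
  expect_equal(base, 2L)   # the 2-pair site fails the window screen
  expect_lte(n_calls(4L, 2L), base)
  expect_lte(n_calls(3L, 3L), base)
  expect_lte(n_calls(6L, 4L), n_calls(4L, 2L))
})

test_that("tumor-only mode works but warns", {
  sites <- data.frame(chrom = "chr1", pos = 12500L, n_pairs = 3L, n_clips = 2L)
  sim <- simulate_wgs_pair(seed = 3, n_reads = 4000L,
                           insertion_sites = sites)
  expect_warning(res <- call_insertions(sim$tumor, NULL, sim$excluded,
                                        sim$reference), "tumor-only")
  expect_equal(res$n_insertions, 1L)
})
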
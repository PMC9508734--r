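test_that("TVR occurrence counting walks the hexamer frame", {
  counts <- count_tvr_occurrences(
    paste0(strrep("TTAGGG", 2), "TGAGGG", strrep("TTAGGG", 2)))
  expect_equal(counts[["TTAGGG"]], 4L)
  expect_equal(counts[["TGAGGG"]], 1L)

  counts <- count_tvr_occurrences(
    paste0(strrep("TTAGGG", 3), "TAAGGG", strrep("TTAGGG", 3)))
  expect_equal(counts[["TAAGGG"]], 1L)

  expect_length(count_tvr_occurrences("ACGTACGTACGTACGTAC"), 0)
  # an isolated GGG triplet outside any telomeric run is not a frame hit
  counts <- count_tvr_occurrences(paste0("AAAGGGACGTACGT", strrep("TTAGGG", 2)))
  expect_false("AAAGGG" %in% names(counts))
})

test_that("singleton finder requires three canonical flanks on both sides", {
  one <- find_tvr_singletons(paste0(strrep("TTAGGG", 3), "TTTGGG",
                                    strrep("TTAGGG", 3)))
  expect_equal(one$variant, "TTTGGG")
  expect_equal(one$pos, 19L)

  none <- find_tvr_singletons(paste0(strrep("TTAGGG", 2), "TTTGGG",
                                     strrep("TTAGGG", 3)))
  expect_equal(nrow(none), 0L)

  two <- find_tvr_singletons(paste0(strrep("TTAGGG", 3), "TTTGGG",
                                    strrep("TTAGGG", 3), "TGAGGG",
                                    strrep("TTAGGG", 3)))
  expect_equal(two$variant, c("TTTGGG", "TGAGGG"))
})

test_that("singleton finder agrees exactly with the overlap-tolerant oracle", {
  set.seed(1234)
  for (i in seq_len(1000)) {
    s <- random_telomere_seq(n_blocks = sample(8:20, 1))
    got <- find_tvr_singletons(s)
    want <- oracle_singletons(s)
    expect_identical(got$variant, want$variant)
    expect_identical(got$pos, want$pos)
  }
})

test_that("profiles keep singleton counts bounded by occurrence counts", {
  sim <- simulate_wgs_pair(seed = 21, n_reads = 4000L,
                           telomeric_fraction = 0.05, singleton_rate = 0.5)
  prof <- tvr_profile(sim$tumor$seq, "s", "tumor")
  expect_gt(prof$telomeric_reads, 0L)
  for (v in setdiff(names(prof$singleton_counts), "TTAGGG")) {
    expect_lte(prof$singleton_counts[[v]], prof$tvr_counts[[v]])
  }
  expect_true(all(prof$tvr_counts >= 0L))
})

test_that("singleton log2 ratio follows hand arithmetic and flags pseudocounts", {
  mk <- function(st, total, id = "s", role = "tumor") {
    p <- list(sample_id = id, role = role,
              tvr_counts = c(TTAGGG = 100L, TTTGGG = st + 5L),
              singleton_counts = c(TTAGGG = 0L, TTTGGG = st),
              telomeric_reads = 50L, total_reads = total)
    class(p) <- "tvr_profile"
    p
  }
  # identical profiles at tc ratio 1: log2(1) = 0
  expect_equal(singleton_ratio(mk(8L, 1000L), mk(8L, 1000L, role = "normal"),
                               1, "TTTGGG")$log2_ratio, 0)
  # tumor rate 2x the normal rate, tc ratio 4: log2(2/4) = -1
  r <- singleton_ratio(mk(16L, 1000L), mk(8L, 1000L, role = "normal"),
                       4, "TTTGGG")
  expect_equal(r$log2_ratio, -1)
  expect_false(r$pseudocount_used)
  # zero normal count: error without pseudocount, flagged with one
  expect_error(singleton_ratio(mk(4L, 1000L), mk(0L, 1000L, role = "normal"),
                               1, "TTTGGG", pseudocount = 0), "pseudocount")
  r0 <- singleton_ratio(mk(4L, 1000L), mk(0L, 1000L, role = "normal"),
                        1, "TTTGGG")
  expect_true(r0$pseudocount_used)
  expect_true(is.finite(r0$log2_ratio))
})

test_that("ALT-like simulations show depleted TTTGGG singleton ratios versus TEL-like", {
  # ALT-like: high telomere content, low planted TTTGGG singleton rate;
  # TEL-like: low content, common TTTGGG singletons
  alt_mix <- c(TTTGGG = 0.05, TGAGGG = 0.55, TCAGGG = 0.3, TTGGGG = 0.1)
  tel_mix <- c(TTTGGG = 0.7, TGAGGG = 0.15, TCAGGG = 0.1, TTGGGG = 0.05)
  ratio_for <- function(seed, tumor_mix, tumor_frac) {
    sim <- simulate_wgs_pair(seed = seed, n_reads = 6000L,
                             telomeric_fraction = c(tumor = tumor_frac,
                                                    normal = 0.01),
                             tvr_mix = list(tumor = tumor_mix,
                                            normal = tel_mix),
                             singleton_rate = 0.6)
    pt <- tvr_profile(sim$tumor$seq, "s", "tumor")
    pn <- tvr_profile(sim$normal$seq, "s", "normal")
    tc <- tc_ratio(telomere_content(sim$tumor$seq, "s", "tumor"),
                   telomere_content(sim$normal$seq, "s", "normal"))
    singleton_ratio(pt, pn, tc, "TTTGGG")$log2_ratio
  }
  alt <- vapply(1:4, function(s) ratio_for(400 + s, alt_mix, 0.08), numeric(1))
  tel <- vapply(1:4, function(s) ratio_for(500 + s, tel_mix, 0.012), numeric(1))
  expect_lt(mean(alt), mean(tel))
})
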
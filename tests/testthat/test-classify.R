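features_row <- function(...) {
  base <- list(sample_id = "s", mna = FALSE, tert_ra = FALSE,
               atrx_mut = FALSE, tert_expr_high = FALSE,
               telomerase_activity_high = NA, apb = FALSE, cca = FALSE,
               tc_ratio = NA_real_, trf_kb = NA_real_,
               terra_total = NA_real_, tttggg_singleton_log2 = NA_real_,
               n_insertions = NA_integer_)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

test_that("strict classification implements the three subgroup definitions", {
  expect_equal(strict_classify(features_row(mna = TRUE))$label, "TEL_pos")
  expect_equal(strict_classify(features_row(tert_expr_high = TRUE))$label,
               "TEL_pos")
  expect_equal(strict_classify(features_row(apb = TRUE, cca = TRUE))$label,
               "ALT_pos")
  expect_equal(strict_classify(features_row())$label, "TMM_neg")
  # telomerase markers alongside concordant ALT assays: ambiguous
  expect_equal(strict_classify(features_row(tert_expr_high = TRUE, apb = TRUE,
                                            cca = TRUE))$label, "ambiguous")
  # discordant assays: ambiguous
  expect_equal(strict_classify(features_row(apb = TRUE))$label, "ambiguous")
  # missing ALT assay: ambiguous
  expect_equal(strict_classify(features_row(apb = TRUE, cca = NA))$label,
               "ambiguous")
})

test_that("strict classification is total and single-labelled on complete features", {
  set.seed(99)
  labels <- c("TEL_pos", "ALT_pos", "TMM_neg", "ambiguous")
  for (i in 1:200) {
    f <- features_row(mna = sample(c(TRUE, FALSE), 1),
                      tert_ra = sample(c(TRUE, FALSE), 1),
                      tert_expr_high = sample(c(TRUE, FALSE), 1),
                      apb = sample(c(TRUE, FALSE), 1),
                      cca = sample(c(TRUE, FALSE), 1))
    a <- strict_classify(f)
    b <- strict_classify(f)
    expect_true(a$label %in% labels)
    expect_identical(a$label, b$label)
  }
})

test_that("feature preconditions are enforced by name", {
  bad <- features_row(mna = NA, tert_ra = NA, tert_expr_high = NA)
  expect_error(strict_classify(bad), "telomerase marker")
  expect_error(strict_classify(features_row()[, -1]), "sample_id")
})

test_that("ambiguous resolution reproduces the seven reference cases", {
  cfg <- classifier_config(singleton_alt_mean = -1.5)
  cohort <- example_ambiguous_cohort()
  strict <- strict_classify(cohort)
  expect_true(all(strict$label == "ambiguous"))
  res <- resolve_ambiguous(cohort, cfg)
  got <- setNames(res$label, res$sample_id)
  expect_equal(got[["NB05"]], "TEL_pos")
  expect_equal(got[["NB45"]], "TEL_pos")
  expect_equal(got[["NB43"]], "ALT_pos")
  expect_equal(got[["NB68"]], "ALT_pos")
  expect_equal(got[["NB46"]], "ALT_pos")
  expect_equal(got[["NB50"]], "ALT_pos")
  expect_equal(got[["NB54"]], "ALT_pos")
  expect_true(all(res$stage == "resolved"))
})

test_that("resolution handles missing auxiliary evidence honestly", {
  # discordant assays, no genomic lesion, nothing auxiliary: stays ambiguous
  f <- features_row(apb = TRUE)
  expect_equal(resolve_ambiguous(f)$label, "ambiguous")
  # same but TERT expression high: telomerase call
  f2 <- features_row(apb = TRUE, tert_expr_high = TRUE)
  expect_equal(resolve_ambiguous(f2)$label, "TEL_pos")
  # two auxiliary ALT markers suffice
  f3 <- features_row(apb = TRUE, tc_ratio = 5, n_insertions = 2L)
  expect_equal(resolve_ambiguous(f3)$label, "ALT_pos")
  # one is not enough without telomerase evidence
  f4 <- features_row(apb = TRUE, tc_ratio = 5)
  expect_equal(resolve_ambiguous(f4)$label, "ambiguous")
  # refusing non-ambiguous input
  expect_error(resolve_ambiguous(features_row(mna = TRUE)), "ambiguous")
})

test_that("cohort classification escalates only ambiguous samples", {
  cfg <- classifier_config(singleton_alt_mean = -1.5)
  cohort <- rbind(features_row(mna = TRUE),
                  features_row(apb = TRUE, cca = TRUE),
                  features_row(apb = TRUE, tc_ratio = 5, n_insertions = 2L))
  cohort$sample_id <- c("tel", "alt", "amb")
  calls <- tmm_classify(cohort, cfg)
  expect_equal(calls$label, c("TEL_pos", "ALT_pos", "ALT_pos"))
  expect_equal(calls$stage, c("strict", "strict", "resolved"))
  # auxiliary markers are never consulted for strict-classified samples:
  # blanking them changes nothing outside the ambiguous stratum
  blank <- cohort
  blank$tc_ratio <- NA_real_
  blank$n_insertions <- NA_integer_
  calls2 <- tmm_classify(blank, cfg)
  expect_equal(calls2$label[1:2], calls$label[1:2])
  expect_equal(calls2$stage[1:2], c("strict", "strict"))
})
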
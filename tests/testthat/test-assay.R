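test_that("mean TRF is the OD-weighted mean fragment length", {
  expect_equal(mean_trf(data.frame(length_kb = 8, od = 1)), 8)
  expect_equal(mean_trf(data.frame(length_kb = c(6, 10), od = c(1, 1))), 8)
  expect_equal(mean_trf(data.frame(length_kb = c(10, 6), od = c(1, 3))), 7)
  expect_error(mean_trf(data.frame(length_kb = c(6, 10), od = c(0, 0))),
               "zero")
  expect_error(mean_trf(data.frame(length_kb = c(6, 10, 8), od = c(1, 1, 1))),
               "monotone")
})

test_that("mean TRF scales with lengths and ignores OD rescaling", {
  prof <- data.frame(length_kb = c(4, 7, 12), od = c(0.2, 1.4, 0.3))
  m <- mean_trf(prof)
  expect_gte(m, min(prof$length_kb))
  expect_lte(m, max(prof$length_kb))
  expect_equal(mean_trf(data.frame(length_kb = 3 * prof$length_kb,
                                   od = prof$od)), 3 * m)
  expect_equal(mean_trf(data.frame(length_kb = prof$length_kb,
                                   od = 5 * prof$od)), m)
  expect_gte(trf_heterogeneity(prof), 0)
})

test_that("C-circle calls follow the two published thresholds", {
  expect_true(cca_call(5, 100, "th1"))          # exactly 5% is positive
  expect_false(cca_call(4.9, 100, "th1"))
  expect_false(cca_call(0, 100, "th1"))
  # 25% intensity but AUC ratio 3 fails the th2 polymerase clause
  expect_false(cca_call(25, 100, "th2",
                        with_polymerase_auc = 30, no_polymerase_auc = 10))
  expect_true(cca_call(20, 100, "th2",
                       with_polymerase_auc = 40, no_polymerase_auc = 10))
  expect_false(cca_call(19.9, 100, "th2",
                        with_polymerase_auc = 40, no_polymerase_auc = 10))
  expect_false(cca_call(0, 100, "th2",
                        with_polymerase_auc = 40, no_polymerase_auc = 10))
  expect_error(cca_call(5, 0, "th1"), "reference")
  expect_error(cca_call(5, 100, "th2"), "th2")
  # th2 positivity implies positivity under a 20% intensity-only rule
  sig <- runif(50, 0, 30)
  th2 <- cca_call(sig, 100, "th2", with_polymerase_auc = 50,
                  no_polymerase_auc = 10)
  expect_true(all(sig[th2] / 100 >= 0.20))
})

test_that("TERT dichotomization is strict at the threshold", {
  expect_equal(classify_tert_expression(12.1), "high")
  expect_equal(classify_tert_expression(6.0), "low")
  expect_equal(classify_tert_expression(7.58), "low")
  expect_equal(classify_tert_expression(7.59), "high")
})

test_that("mixture threshold recovers the analytic posterior crossing", {
  true_m <- c(6, 11); true_s <- c(0.5, 1); true_w <- c(0.6, 0.4)
  cohort <- simulate_expression_cohort(seed = 7, n = 2000L, means = true_m,
                                       sds = true_s, weights = true_w)
  fit <- fit_tert_threshold(cohort$values)
  analytic <- oracle_mixture_crossing(true_m, true_s, true_w)
  expect_lt(abs(fit$threshold - analytic), 0.15)
  expect_gt(fit$threshold, fit$means[1])
  expect_lt(fit$threshold, fit$means[2])
  # grid helper agrees with the analytic crossing at grid resolution
  expect_lt(abs(mixture_posterior_threshold(true_m, true_s, true_w) - analytic),
            0.011)
})

test_that("mixture threshold separates well-separated point-like components", {
  set.seed(11)
  x <- c(rnorm(100, 0, 0.01), rnorm(100, 10, 0.01))
  fit <- fit_tert_threshold(x)
  expect_gt(fit$threshold, 0)
  expect_lt(fit$threshold, 10)
  expect_error(fit_tert_threshold(x[1:10]), "at least 20")
})

test_that("increasing component separation stabilizes the threshold", {
  thr_for <- function(gap, seeds) {
    vapply(seeds, function(s) {
      v <- simulate_expression_cohort(seed = s, n = 1000L,
                                      means = c(6, 6 + gap))$values
      fit_tert_threshold(v)$threshold
    }, numeric(1))
  }
  narrow <- thr_for(2, 1:8)
  wide <- thr_for(8, 1:8)
  expect_lt(sd(wide), sd(narrow))
  mid_lo <- 6 + 0.25 * 8; mid_hi <- 6 + 0.75 * 8
  expect_true(all(wide > mid_lo & wide < mid_hi))
})

test_that("simulated densitometry reproduces the requested mean TRF", {
  prof <- simulate_densitometry(10.66, sd_kb = 1.2)
  expect_lt(abs(mean_trf(prof) - 10.66), 0.1)
  tight <- simulate_densitometry(8.39, sd_kb = 1e-4)
  # at vanishing spread the mass sits on the nearest ladder rung
  expect_lt(abs(mean_trf(tight) - 8.39),
            max(diff(tight$length_kb)))
  expect_error(simulate_densitometry(10, sd_kb = 0), "positive")
  expect_error(simulate_densitometry(50), "lane range")
  noisy1 <- simulate_densitometry(9, noise_sd = 0.1, seed = 5)
  noisy2 <- simulate_densitometry(9, noise_sd = 0.1, seed = 5)
  expect_identical(noisy1, noisy2)
})
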
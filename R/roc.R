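#' Empirical ROC curve
#'
#' Enumerates every observed score as a threshold (a sample is predicted
#' positive when its score is greater than or equal to the threshold),
#' computes sensitivity and specificity at each, and the trapezoidal area
#' under the curve. The trapezoidal AUC equals the concordance statistic:
#' the fraction of (positive, negative) pairs ranked concordantly, with
#' half credit for ties.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical class labels (`TRUE` = positive).
#' @return Object of class `tmm_roc` with elements `points` (data frame
#'   `threshold`, `sensitivity`, `specificity`; thresholds decreasing,
#'   bracketed by `Inf`/`-Inf`), `auc`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - pts$specificity
  auc <- sum(diff(fpr) * (head(pts$sensitivity, -1) +
                            pts$sensitivity[-1]) / 2)
  out <- list(points = pts, auc = auc,
              n_pos = sum(labels), n_neg = sum(!labels))
  class(out) <- "tmm_roc"
  out
}

#' @export
print.tmm_roc <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.tmm_roc <- function(x, ...) {
  plot(1 - x$points$specificity, x$points$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Propose a diagnostic threshold from a ROC curve
#'
#' Returns the observed threshold maximizing Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity, then toward the lower threshold.
#'
#' @param curve A `tmm_roc` object from [empirical_roc()].
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
propose_threshold <- function(curve) {
  stopifnot(inherits(curve, "tmm_roc"))
  pts <- curve$points[is.finite(curve$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) stop("degenerate ROC curve", call. = FALSE)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[pts$specificity[best] == max(pts$specificity[best])]
  }
  if (length(best) > 1L) {
    best <- best[which.min(pts$threshold[best])]
  }
  list(threshold = pts$threshold[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best],
       j = j[best])
}

#' Combine two predictors by logistic regression
#'
#' Maximum-likelihood binary logistic fit on two covariates; the fitted
#' per-sample probabilities feed [empirical_roc()] for a combined ROC
#' curve. Only complete cases are used. Perfect separation is flagged
#' with a warning and probabilities from the diverging fit are capped
#' away from 0/1.
#'
#' @param x1,x2 Numeric covariates.
#' @param labels Logical class labels.
#' @param eps Probability cap under separation.
#' @return List with `probabilities`, `coefficients`, `model`,
#'   `separated` and the row filter `complete`.
#' @export
combine_predictors <- function(x1, x2, labels, eps = 1e-8) {
  stopifnot(length(x1) == length(labels), length(x2) == length(labels))
  complete <- complete.cases(x1, x2, labels)
  d <- data.frame(y = as.logical(labels[complete]),
                  x1 = x1[complete], x2 = x2[complete])
  if (!any(d$y) || all(d$y)) stop("both classes must be present", call. = FALSE)
  if (sd(d$x1) == 0 && sd(d$x2) == 0) {
    stop("both covariates are constant", call. = FALSE)
  }
  r <- suppressWarnings(cor(d$x1, d$x2))
  if (is.finite(r) && abs(r) > 0.9999) {
    stop("covariates are collinear", call. = FALSE)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x1 + x2, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p <- fitted(fit)
  if (separated) {
    warning("perfect separation detected: probabilities capped", call. = FALSE)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  list(probabilities = as.numeric(p), coefficients = coef(fit), model = fit,
       separated = separated, complete = complete)
}

#' Dunn's post-hoc test of pairwise group differences
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis test, with
#' the standard tie correction and Bonferroni family-wise adjustment.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor.
#' @param p_adjust_method Passed to [stats::p.adjust()] (default
#'   `"bonferroni"`).
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least two groups", call. = FALSE)
  n <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  ni <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(lv, 2L)
  z <- apply(pairs, 2L, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(sigma2 * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
             p_adjusted = pmin(1, p.adjust(p, method = p_adjust_method)),
             stringsAsFactors = FALSE)
}

#' Compare a metric between TMM subgroups
#'
#' Kruskal-Wallis test across groups followed by Dunn's pairwise
#' comparisons with multiplicity adjustment; the standard subgroup
#' comparison of the workflow. Groups with fewer than two observations
#' are rejected.
#'
#' @inheritParams dunn_test
#' @return List of class `tmm_group_comparison` with `kruskal` (an
#'   `htest`), `dunn` (data frame) and `group_means`.
#' @export
group_compare <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  ni <- table(groups)
  if (length(ni) < 2L || any(ni < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  out <- list(kruskal = kruskal.test(values, groups),
              dunn = dunn_test(values, groups, p_adjust_method),
              group_means = tapply(values, groups, mean))
  class(out) <- "tmm_group_comparison"
  out
}

#' @export
print.tmm_group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g\n",
              unname(x$kruskal$statistic), unname(x$kruskal$parameter),
              x$kruskal$p.value))
  cat("group means:\n")
  print(round(x$group_means, 4))
  cat("Dunn pairwise comparisons:\n")
  print(x$dunn, row.names = FALSE)
  invisible(x)
}
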
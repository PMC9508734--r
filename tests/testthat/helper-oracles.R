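# Independent oracles used across the suite. These stay deliberately
# brute-force and must not share code paths with the implementation.

# regex count of t-type repeats (both orientations, non-overlapping)
oracle_t_type_count <- function(seq) {
  cnt <- function(p) {
    m <- gregexpr(p, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  cnt("TTAGGG") + cnt("CCCTAA")
}

# overlap-tolerant singleton scan: check the bracketed pattern at every
# offset of the sequence directly
oracle_singletons <- function(seq) {
  n <- nchar(seq)
  flank <- strrep("TTAGGG", 3)
  out <- list()
  if (n < 42L) {
    return(data.frame(variant = character(0), pos = integer(0)))
  }
  for (p in 19:(n - 23L)) {
    hex <- substr(seq, p, p + 5L)
    if (hex == "TTAGGG") next
    if (!grepl("^[ACGT]{3}GGG$", hex)) next
    if (substr(seq, p - 18L, p - 1L) == flank &&
        substr(seq, p + 6L, p + 23L) == flank) {
      out[[length(out) + 1L]] <- data.frame(variant = hex, pos = p,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(variant = character(0), pos = integer(0)))
  }
  do.call(rbind, out)
}

# O(n^2) concordance AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search with the stated tie-breaks
oracle_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && t < best$t)))) {
      best <- list(t = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# closed-form posterior-0.95 crossing of a known 2-component mixture
oracle_mixture_crossing <- function(means, sds, weights, level = 0.95) {
  post <- function(x) {
    d2 <- weights[2] * dnorm(x, means[2], sds[2])
    d1 <- weights[1] * dnorm(x, means[1], sds[1])
    d2 / (d1 + d2) - level
  }
  uniroot(post, c(means[1], means[2]), tol = 1e-9)$root
}

# random telomere-like test sequences: runs of canonical repeats,
# variants and junk in random order
random_telomere_seq <- function(n_blocks = 12L) {
  blocks <- sample(c("TTAGGG", "TTTGGG", "TGAGGG", "TCAGGG", "TAAGGG",
                     "ACGTAC", "GGGTTA"),
                   n_blocks, replace = TRUE,
                   prob = c(0.55, 0.1, 0.1, 0.05, 0.05, 0.1, 0.05))
  paste(blocks, collapse = "")
}
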
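# run expr under a local RNG state so generators are pure functions of
# their seed and leave the caller's RNG untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# remove chance t-type motifs from a sequence by breaking each occurrence
.scrub_t_type <- function(seq) {
  repeat {
    hit <- regexpr("TTAGGG|CCCTAA", seq)
    if (hit == -1L) return(seq)
    substr(seq, hit + 2L, hit + 2L) <- "T"  # TTAGGG->TTTGGG would stay GGG; break harder
    substr(seq, hit + 3L, hit + 3L) <- "A"
  }
}

#' Simulate a small reference genome with terminal telomeric tracts
#'
#' A few short contigs with telomere-free interiors and telomeric tracts
#' at both ends (C-strand repeats at the 5' end, G-strand at the 3'
#' end), plus the matching telomeric exclusion regions, so that
#' exclusion-interval logic can be exercised at desk scale.
#'
#' @param seed Integer seed.
#' @param n_contigs Number of contigs.
#' @param contig_length Contig length (bp).
#' @param telomere_length Length of each terminal telomeric tract (bp).
#' @return List with `reference` ([Biostrings::DNAStringSet]),
#'   `seqlengths` (named integer) and `excluded`
#'   ([GenomicRanges::GRanges] covering the telomeric tracts).
#' @export
simulate_reference <- function(seed = 1L, n_contigs = 3L,
                               contig_length = 50000L,
                               telomere_length = 2000L) {
  stopifnot(contig_length > 2L * telomere_length + 10000L)
  .with_seed(seed, {
    tracts <- telomere_length %/% 6L
    contigs <- vapply(seq_len(n_contigs), function(i) {
      interior <- .scrub_t_type(.random_dna(contig_length - 2L * 6L * tracts))
      paste0(strrep(T_TYPE_REV, tracts), interior, strrep(T_TYPE_FWD, tracts))
    }, character(1))
    names(contigs) <- sprintf("chr%d", seq_len(n_contigs))
    reference <- Biostrings::DNAStringSet(contigs)
    lens <- setNames(Biostrings::width(reference), names(contigs))
    tract_len <- 6L * tracts
    excluded <- GenomicRanges::GRanges(
      rep(names(lens), each = 2L),
      IRanges::IRanges(
        start = as.vector(rbind(1L, lens - tract_len + 1L)),
        end = as.vector(rbind(rep(tract_len, length(lens)), lens))))
    list(reference = reference, seqlengths = lens, excluded = excluded)
  })
}

# one telomeric read: mostly canonical repeats, optionally one planted
# variant singleton, randomly reverse-complemented
.telomeric_reads <- function(n, read_len, tvr_mix, singleton_rate) {
  if (n == 0L) return(character(0))
  k <- max(8L, read_len %/% 6L)
  vars <- names(tvr_mix)
  pv <- tvr_mix / sum(tvr_mix)
  vapply(seq_len(n), function(i) {
    hex <- rep(T_TYPE_FWD, k)
    if (runif(1) < singleton_rate) {
      slot <- sample(4:(k - 3L), 1L)
      hex[slot] <- sample(vars, 1L, prob = pv)
    }
    s <- paste(hex, collapse = "")
    if (runif(1) < 0.5) s <- .revcomp(s)
    s
  }, character(1))
}

.aln_row <- function(read_id, flag, chrom, pos, cigar, seq,
                     mate_chrom = NA_character_, mate_pos = NA_integer_) {
  data.frame(read_id = read_id, flag = as.integer(flag), chrom = chrom,
             pos = as.integer(pos), cigar = cigar, seq = seq,
             mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
             stringsAsFactors = FALSE)
}

# reads of one sample: mapped background pairs, unmapped telomeric pairs,
# and (tumor only) insertion-supporting discordant pairs and clipped reads
.simulate_sample_reads <- function(ref, n_reads, read_len, telomeric_fraction,
                                   tvr_mix, singleton_rate, insertion_sites,
                                   prefix) {
  lens <- ref$seqlengths
  margin <- 3000L
  n_telo <- rbinom(1L, n_reads, telomeric_fraction)
  n_bg <- n_reads - n_telo
  n_bg_pairs <- n_bg %/% 2L

  refstr <- setNames(as.character(ref$reference), names(lens))

  rows <- list()
  if (n_bg_pairs > 0L) {
    chrom <- sample(names(lens), n_bg_pairs, replace = TRUE)
    span <- lens[chrom] - 2L * margin - 2L * read_len - 300L
    pos1 <- margin + 1L + as.integer(floor(runif(n_bg_pairs) * span))
    pos2 <- pos1 + 200L
    seq1 <- substring(refstr[chrom], pos1, pos1 + read_len - 1L)
    seq2 <- substring(refstr[chrom], pos2, pos2 + read_len - 1L)
    ids <- sprintf("%s_bg%d", prefix, seq_len(n_bg_pairs))
    cig <- sprintf("%dM", read_len)
    rows$bg1 <- .aln_row(ids, 65L, chrom, pos1, cig, seq1, chrom, pos2)
    rows$bg2 <- .aln_row(ids, 129L, chrom, pos2, cig, seq2, chrom, pos1)
  }
  ts <- if (n_telo > 0L) {
    .telomeric_reads(n_telo, read_len, tvr_mix, singleton_rate)
  } else character(0)
  n_tp <- n_telo %/% 2L
  if (n_tp > 0L) {
    ids <- sprintf("%s_telo%d", prefix, seq_len(n_tp))
    rows$telo1 <- .aln_row(ids, 77L, NA_character_, NA_integer_, "*",
                           ts[seq_len(n_tp)])
    rows$telo2 <- .aln_row(ids, 141L, NA_character_, NA_integer_, "*",
                           ts[n_tp + seq_len(n_tp)])
  }
  # leftover singletons: pair the odd telomeric read with the odd
  # background read when both exist (keeps totals exact and all ids paired)
  telo_odd <- n_telo %% 2L == 1L
  bg_odd <- n_bg %% 2L == 1L
  if (telo_odd && bg_odd) {
    oid <- sprintf("%s_odd", prefix)
    rows$odd1 <- .aln_row(oid, 77L, NA_character_, NA_integer_, "*",
                          ts[n_telo])
    rows$odd2 <- .aln_row(oid, 141L, NA_character_, NA_integer_, "*",
                          .random_dna(read_len))
  } else if (telo_odd) {
    rows$odd1 <- .aln_row(sprintf("%s_odd", prefix), 4L, NA_character_,
                          NA_integer_, "*", ts[n_telo])
  } else if (bg_odd) {
    rows$odd1 <- .aln_row(sprintf("%s_odd", prefix), 4L, NA_character_,
                          NA_integer_, "*", .random_dna(read_len))
  }

  if (!is.null(insertion_sites) && nrow(insertion_sites) > 0L) {
    if (!"direction" %in% names(insertion_sites)) {
      insertion_sites$direction <- "right"
    }
    for (s in seq_len(nrow(insertion_sites))) {
      site <- insertion_sites[s, ]
      if (!site$chrom %in% names(lens) || site$pos < 200L ||
          site$pos > lens[[site$chrom]] - 200L) {
        stop(sprintf("insertion site %s:%d outside reference", site$chrom,
                     site$pos), call. = FALSE)
      }
      w <- 1000L
      win_start <- ((site$pos - 1L) %/% w) * w + 1L
      lo <- max(win_start, site$pos - 300L)
      hi <- min(win_start + w - 1L, site$pos - 30L)
      if (lo > hi) { lo <- win_start; hi <- win_start + w - 1L }
      if (site$n_pairs > 0L) {
        apos <- sample(lo:hi, site$n_pairs, replace = TRUE)
        aseq <- substring(refstr[[site$chrom]], apos, apos + read_len - 1L)
        ids <- sprintf("%s_ins%d_p%d", prefix, s, seq_len(site$n_pairs))
        rows[[paste0("insp", s, "a")]] <- .aln_row(
          ids, 137L, site$chrom, apos, sprintf("%dM", read_len), aseq)
        rows[[paste0("insp", s, "b")]] <- .aln_row(
          ids, 69L, NA_character_, NA_integer_, "*",
          strrep(T_TYPE_FWD, read_len %/% 6L),
          site$chrom, apos)
      }
      if (site$n_clips > 0L) {
        anchor_len <- 60L
        clip_len <- 42L
        clip_seq <- strrep(T_TYPE_FWD, clip_len %/% 6L)
        ids <- sprintf("%s_ins%d_c%d", prefix, s, seq_len(site$n_clips))
        if (site$direction == "right") {
          ap <- site$pos - anchor_len
          body <- as.character(Biostrings::subseq(
            ref$reference[[site$chrom]], ap, site$pos - 1L))
          rows[[paste0("insc", s)]] <- .aln_row(
            ids, 0L, site$chrom, rep(ap, site$n_clips),
            sprintf("%dM%dS", anchor_len, clip_len),
            rep(paste0(body, clip_seq), site$n_clips))
        } else {
          ap <- site$pos + 1L
          body <- as.character(Biostrings::subseq(
            ref$reference[[site$chrom]], ap, ap + anchor_len - 1L))
          rows[[paste0("insc", s)]] <- .aln_row(
            ids, 0L, site$chrom, rep(ap, site$n_clips),
            sprintf("%dS%dM", clip_len, anchor_len),
            rep(paste0(.revcomp(clip_seq), body), site$n_clips))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(aln = out, n_telomeric = n_telo)
}

#' Simulate a paired tumor/normal WGS read set
#'
#' Generates alignment tables for a matched tumor/normal pair on a small
#' synthetic reference: mapped background pairs from telomere-free
#' interiors, unmapped telomeric read pairs at a planted per-read
#' fraction with a controllable variant-repeat singleton composition,
#' and (tumor only) planted telomere insertions emitting discordant
#' pairs and telomeric soft-clipped reads at stated counts. The truth
#' record lists all planted quantities.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_reads Reads per sample.
#' @param read_len Read length (bp).
#' @param telomeric_fraction Planted per-read telomeric probability;
#'   scalar or named vector `c(tumor=, normal=)`.
#' @param tvr_mix Named probabilities over variant hexamers used for
#'   planted singletons; either one vector for both samples or
#'   `list(tumor =, normal =)`.
#' @param singleton_rate Fraction of telomeric reads carrying one planted
#'   variant singleton; scalar or named vector `c(tumor =, normal =)`.
#' @param insertion_sites `NULL` or data frame with columns `chrom`,
#'   `pos` (1-based breakpoint), `n_pairs`, `n_clips` and optional
#'   `direction` (`"right"`/`"left"`, default right).
#' @param reference Optional output of [simulate_reference()]; generated
#'   from `seed` when `NULL`.
#' @return List with `tumor` and `normal` alignment data frames,
#'   `reference`, `seqlengths`, `excluded` and `truth`.
#' @export
simulate_wgs_pair <- function(seed = 1L, n_reads = 20000L, read_len = 102L,
                              telomeric_fraction = c(tumor = 5e-4,
                                                     normal = 1e-4),
                              tvr_mix = c(TTTGGG = 0.4, TGAGGG = 0.3,
                                          TCAGGG = 0.2, TTGGGG = 0.1),
                              singleton_rate = 0.3,
                              insertion_sites = NULL,
                              reference = NULL) {
  if (length(telomeric_fraction) == 1L) {
    telomeric_fraction <- c(tumor = unname(telomeric_fraction),
                            normal = unname(telomeric_fraction))
  }
  if (!is.list(tvr_mix)) tvr_mix <- list(tumor = tvr_mix, normal = tvr_mix)
  if (length(singleton_rate) == 1L) {
    singleton_rate <- c(tumor = unname(singleton_rate),
                        normal = unname(singleton_rate))
  }
  if (is.null(reference)) reference <- simulate_reference(seed)
  .with_seed(seed + 1L, {
    tumor <- .simulate_sample_reads(reference, n_reads, read_len,
                                    telomeric_fraction[["tumor"]],
                                    tvr_mix$tumor,
                                    singleton_rate[["tumor"]],
                                    insertion_sites, "t")
    normal <- .simulate_sample_reads(reference, n_reads, read_len,
                                     telomeric_fraction[["normal"]],
                                     tvr_mix$normal,
                                     singleton_rate[["normal"]], NULL, "n")
    list(tumor = tumor$aln, normal = normal$aln,
         reference = reference$reference,
         seqlengths = reference$seqlengths, excluded = reference$excluded,
         truth = list(n_reads = n_reads,
                      telomeric_fraction = telomeric_fraction,
                      n_telomeric = c(tumor = tumor$n_telomeric,
                                      normal = normal$n_telomeric),
                      tvr_mix = tvr_mix, singleton_rate = singleton_rate,
                      insertion_sites = insertion_sites))
  })
}

#' Simulate an RNA-seq read set with planted TERRA content
#'
#' @param seed Integer seed.
#' @param n_reads Number of reads.
#' @param read_len Read length (bp).
#' @param terra_fractions Named per-read probabilities of being a TERRA
#'   read of each variant type (names from [COMMON_TVRS]).
#' @return List with `reads` (character vector) and `truth` (planted
#'   per-variant read counts).
#' @export
simulate_rna_reads <- function(seed = 1L, n_reads = 100000L, read_len = 102L,
                               terra_fractions = c(TTAGGG = 4e-4,
                                                   TGAGGG = 1e-4,
                                                   TCAGGG = 5e-5,
                                                   TTGGGG = 5e-5)) {
  stopifnot(all(names(terra_fractions) %in% COMMON_TVRS))
  .with_seed(seed, {
    counts <- setNames(rbinom(length(terra_fractions), n_reads,
                              terra_fractions), names(terra_fractions))
    n_terra <- sum(counts)
    if (n_terra > n_reads) stop("TERRA fractions too large", call. = FALSE)
    k <- read_len %/% 6L
    terra <- unlist(lapply(names(counts), function(v) {
      if (counts[[v]] == 0L) return(character(0))
      vapply(seq_len(counts[[v]]), function(i) {
        s <- strrep(v, k)
        if (runif(1) < 0.5) s <- .revcomp(s)
        s
      }, character(1))
    }))
    template <- .scrub_t_type(.random_dna(200000L))
    off <- sample.int(200000L - read_len, n_reads - n_terra, replace = TRUE)
    bg <- substring(template, off, off + read_len - 1L)
    reads <- sample(c(terra, bg))
    list(reads = reads, truth = list(n_reads = n_reads, counts = counts,
                                     fractions = terra_fractions))
  })
}

#' Simulate a bimodal log2 expression cohort
#'
#' Two-component Gaussian mixture, used to exercise the TERT expression
#' threshold fit. Defaults place a low (non-expressing) component at
#' log2 = 6 and a high component at log2 = 11.
#'
#' @param seed Integer seed.
#' @param n Cohort size.
#' @param means,sds,weights Component parameters (low component first).
#' @return List with `values` and `component` (1 = low, 2 = high).
#' @export
simulate_expression_cohort <- function(seed = 1L, n = 2000L,
                                       means = c(6, 11), sds = c(0.5, 1),
                                       weights = c(0.6, 0.4)) {
  stopifnot(length(means) == 2L, sds[1] > 0, sds[2] > 0,
            abs(sum(weights) - 1) < 1e-8)
  .with_seed(seed, {
    comp <- sample(1:2, n, replace = TRUE, prob = weights)
    list(values = rnorm(n, means[comp], sds[comp]), component = comp)
  })
}

#' Simulate a cohort marker table with TMM group structure
#'
#' Draws per-sample marker vectors for the three TMM subgroups with the
#' group means observed in neuroblastoma: tumor/normal telomere content
#' 0.87 / 6.39 / 0.96 and mean TRF 8.39 / 10.66 / 6.36 kb for
#' TMM-negative / ALT-positive / telomerase-positive tumors, and total
#' TERRA 0.004 / 0.011 / 0.002. Telomere content and TERRA are drawn
#' lognormally (non-negative, right-skewed), TRF normally. Binary
#' markers are consistent with the group label; a configurable
#' discordance rate flips one ALT assay per affected sample to create
#' ambiguous cases.
#'
#' @param seed Integer seed.
#' @param n_per_group Named sizes for `TMM_neg`, `ALT_pos`, `TEL_pos`.
#' @param tc_means,trf_means,terra_means Named group means.
#' @param tc_sdlog,trf_sd,terra_sdlog Dispersions.
#' @param singleton_means,singleton_sd Group means / sd of the TTTGGG
#'   log2 singleton ratio.
#' @param insertion_prevalence Per-group probability of carrying at
#'   least one telomere insertion.
#' @param discordance_rate Probability a sample's APB or CCA result is
#'   flipped.
#' @param trf_available Probability the TRF assay was run on a sample.
#' @return List with `features` (classifier-ready data frame) and
#'   `truth` (the planted group labels).
#' @export
simulate_cohort_table <- function(
    seed = 1L,
    n_per_group = c(TMM_neg = 17L, ALT_pos = 13L, TEL_pos = 31L),
    tc_means = c(TMM_neg = 0.87, ALT_pos = 6.39, TEL_pos = 0.96),
    trf_means = c(TMM_neg = 8.39, ALT_pos = 10.66, TEL_pos = 6.36),
    terra_means = c(TMM_neg = 0.004, ALT_pos = 0.011, TEL_pos = 0.002),
    tc_sdlog = 0.6, trf_sd = 1.3, terra_sdlog = 0.5,
    singleton_means = c(TMM_neg = 0, ALT_pos = -2.5, TEL_pos = 0),
    singleton_sd = 0.8,
    insertion_prevalence = c(TMM_neg = 0.06, ALT_pos = 0.77, TEL_pos = 0.32),
    discordance_rate = 0.10,
    trf_available = 0.57) {
  stopifnot(all(n_per_group >= 2L))
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  .with_seed(seed, {
    lmean <- function(m, sdlog) log(m) - sdlog^2 / 2  # arithmetic-mean match
    tc <- rlnorm(n, lmean(tc_means[groups], tc_sdlog), tc_sdlog)
    trf <- rnorm(n, trf_means[groups], trf_sd)
    terra <- rlnorm(n, lmean(terra_means[groups], terra_sdlog), terra_sdlog)
    singleton <- rnorm(n, singleton_means[groups], singleton_sd)
    n_ins <- rbinom(n, 1L, insertion_prevalence[groups]) * (1L + rpois(n, 1.5))

    is_tel <- groups == "TEL_pos"
    is_alt <- groups == "ALT_pos"
    driver <- ifelse(is_tel,
                     sample(c("mna", "tert_ra", "expr_only"), n, replace = TRUE,
                            prob = c(0.40, 0.35, 0.25)), "none")
    mna <- driver == "mna"
    tert_ra <- driver == "tert_ra"
    tert_expr_high <- is_tel & (driver == "expr_only" | runif(n) < 0.97)
    atrx_mut <- is_alt & runif(n) < 0.46
    apb <- is_alt
    cca <- is_alt
    measured <- runif(n) < 0.22
    telomerase_activity_high <- ifelse(measured, is_tel, NA)

    flip <- runif(n) < discordance_rate
    which_assay <- sample(c("apb", "cca"), n, replace = TRUE)
    apb <- ifelse(flip & which_assay == "apb", !apb, apb)
    cca <- ifelse(flip & which_assay == "cca", !cca, cca)

    features <- data.frame(
      sample_id = sprintf("SIM%03d", seq_len(n)),
      mna = mna, tert_ra = tert_ra, atrx_mut = atrx_mut,
      tert_expr_high = tert_expr_high,
      telomerase_activity_high = telomerase_activity_high,
      apb = apb, cca = cca,
      tc_ratio = tc,
      trf_kb = ifelse(runif(n) < trf_available, trf, NA_real_),
      terra_total = terra,
      tttggg_singleton_log2 = singleton,
      n_insertions = as.integer(n_ins),
      stringsAsFactors = FALSE)
    list(features = features,
         truth = data.frame(sample_id = features$sample_id, label = groups,
                            discordant = flip, stringsAsFactors = FALSE))
  })
}

#' Simulate a Southern-blot densitometry profile
#'
#' Gaussian optical-density profile over a log-spaced fragment-length
#' ladder, with OD proportional to the probability mass falling into
#' each ladder cell so that the OD-weighted mean recovers `mean_kb`.
#'
#' @param mean_kb Target mean fragment length (kb); must lie inside
#'   `lane_range`.
#' @param sd_kb Profile standard deviation (kb, > 0).
#' @param n_points Ladder positions.
#' @param lane_range Fragment-length range of the lane (kb).
#' @param noise_sd Multiplicative lognormal noise on OD (0 = none).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Data frame with columns `length_kb` and `od`.
#' @export
simulate_densitometry <- function(mean_kb, sd_kb = 1.0, n_points = 120L,
                                  lane_range = c(1.5, 21), noise_sd = 0,
                                  seed = 1L) {
  if (sd_kb <= 0) stop("sd_kb must be positive", call. = FALSE)
  if (mean_kb <= lane_range[1] || mean_kb >= lane_range[2]) {
    stop("mean_kb must lie inside the lane range", call. = FALSE)
  }
  L <- exp(seq(log(lane_range[1]), log(lane_range[2]), length.out = n_points))
  cellw <- c(diff(L)[1], diff(L))
  z <- -(L - mean_kb)^2 / (2 * sd_kb^2)
  od <- exp(z - max(z)) * cellw
  if (noise_sd > 0) {
    od <- .with_seed(seed, od * rlnorm(n_points, 0, noise_sd))
  }
  data.frame(length_kb = L, od = od)
}
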
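---
title: "Assessing telomere maintenance mechanisms with telotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing telomere maintenance mechanisms with telotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotype)
```

## The problem

Neuroblastoma spans the full clinical spectrum from spontaneous regression
to fatal progression, and much of that difference tracks whether the tumor
has activated a telomere maintenance mechanism (TMM): telomerase
(via *MYCN* amplification, *TERT* rearrangement or high *TERT* expression)
or the recombination-based ALT pathway. Neither of the two standard ALT
assays — the C-circle assay (CCA) and ALT-associated PML body (APB)
staining — is fully sensitive and specific, so a minority of tumors return
conflicting results. `telotype` implements the sequencing- and assay-derived
marker panel and a two-stage classifier: a strict rule set first, then an
evidence-weighted resolution for the ambiguous remainder.

## Sequence-level metrics

**Telomeric reads and telomere content.** A read is telomeric when it
contains at least `min_repeats = 4` t-type repeats, counting non-overlapping
occurrences of TTAGGG plus non-overlapping occurrences of its reverse
complement CCCTAA in a left-to-right scan. Both orientations are summed in
one read: a sequenced fragment is single-stranded and either motif
evidences telomeric origin. The hexamer cannot overlap itself, so the scan
is deterministic. Telomere content is telomeric reads per million total
reads; the per-patient estimate is the tumor/normal content ratio, and a
tumor-only mode (the tumor's normalized content alone) ranks cohorts
near-identically when matched normals are unavailable. Reads are counted
regardless of mapping status; for BAM input only primary alignments are
read, so no read is counted twice. The reads-per-million scale is a
package convention: it is stated for the RNA metric and adopted uniformly,
so absolute values of other conventions differ by a constant factor.

**TVR composition and singletons.** Telomere variant repeats (TVRs) are
hexamers of the NNNGGG type inside telomeric sequence. Scanning is
restricted to reads passing the telomeric-read rule, oriented to the
G-strand (reverse-complemented when CCCTAA occurrences outnumber TTAGGG;
ties keep the forward orientation). The scan is anchored on TTAGGG
occurrences and walks outward in 6-mer steps through contiguous
NNNGGG-compatible hexamers, so isolated GGG triplets in non-telomeric
context are never tallied. A TVR *singleton* is a variant flanked by at
least three canonical repeats on each side, (TTAGGG)₃–NNNGGG–(TTAGGG)₃;
flanking repeats may be shared between adjacent singletons, which makes the
definition overlap-tolerant and unambiguous against a brute-force scan.
Because singleton counts grow with telomere content, the tumor/normal
singleton-rate ratio is further divided by the telomere content ratio
before taking log₂. When either singleton count is zero a pseudocount of
0.5 is added to both counts and the value is flagged — this keeps sparse
simulated samples finite without silently shifting well-measured ones.

**Telomere insertions.** Intrachromosomal insertions of telomeric DNA are
called in four stages. (1) Read pairs where exactly one mate is telomeric
and the other maps outside user-supplied telomeric/centromeric exclusion
regions contribute an anchor at the mapped mate's 5′ coordinate (the
deterministic, order-independent choice). (2) Fixed, non-sliding 1 kb
windows (0-based multiples of 1000, half-open) with ≥ 3 tumor anchors and
0 normal anchors become candidates. (3) Within candidates, soft-clipped
reads with clips ≥ 15 bp containing ≥ 2 t-type repeats and clip starts
within ± 1 bp cluster into breakpoints when ≥ 2 reads agree; the breakpoint
is the first clipped base for right clips and the base preceding the clip
for left clips. (4) An automated context filter replaces manual inspection:
a breakpoint is rejected when the reference within ± 100 bp contains ≥ 2
t-type repeats or a homopolymer run ≥ 20 bp, the two local contexts that
generate spurious telomeric clips. Opposite-direction breakpoints within
5 kb merge into one two-sided insertion; 5 kb is large enough to bridge an
insertion locus and small enough not to join distant events (the maximum
pairing distance is not constrained by the detection scheme itself, so it
is exposed in `insertion_caller_config()`). Tumor-only calling works but
warns, since the clean-normal requirement is the main false-positive
control. Exclusion intervals are a required user input — there is no
universally agreed interval set, and the choice materially affects the
anchor screen.

**TERRA.** RNA-seq reads are screened for ≥ 4 occurrences of each of the
four most common telomeric hexamers (either orientation, threshold reused
from the WGS rule); per-variant counts are normalized to reads per million
and summed into the total. A read carrying enough repeats of several
variants counts toward each, since the per-variant definitions are
independent. Counting operates on sequences, so unaligned FASTQ is
accepted; a spliced alignment upstream is optional and does not change the
counts.

## Assay quantification

**Mean TRF** is the optical-density-weighted mean fragment length of a
Southern-blot lane, `mean TRF = Σ(ODᵢ·Lᵢ)/Σ(ODᵢ)` in kb, computed on the
lane as sampled (no interpolation or ladder smoothing — image processing is
upstream of this package). The OD-weighted standard deviation is exposed as
an optional heterogeneity measure; ALT lanes tend to be broader, but no
quantitative claim is attached to it.

**C-circle calls** implement both published thresholds against the
ALT-positive reference line: th₁ (sample/reference signal ≥ 0.05) and th₂
(ratio ≥ 0.20 and with-polymerase AUC ≥ 4× the polymerase-free AUC). Signal
units and background handling are deliberately out of scope; only the
ratio-to-reference contract is assumed.

**TERT expression threshold.** Cohort log₂ expression is bimodal: a
non-expressing and an expressing component. A two-component Gaussian
mixture with unequal variances is fitted (mclust's EM with
model-based hierarchical initialization, which is deterministic for a given
sample), and the threshold is the lowest grid point — step 0.01, searched
from the lower component mean to the observed maximum — whose posterior
probability under the higher-mean component reaches 0.95. Starting the grid
at the lower mean keeps the threshold between the component means even when
the upper component has the larger variance (whose heavier tails would
otherwise dominate far below the lower mode). Fits with collapsed
components, or grids that never reach the posterior level, raise errors
rather than returning a number. The shipped default of 7.58 for
`classify_tert_expression()` is the published cohort constant; "high" is a
strict inequality, so a value exactly at the threshold is low.

## Classification

`strict_classify()` is total and deterministic: TEL⁺ requires a telomerase
marker and both ALT assays negative; ALT⁺ requires concordant APB⁺ and
CCA⁺ without telomerase markers; TMM⁻ requires all five markers negative;
everything else — discordant assays, telomerase markers co-occurring with
ALT assay positivity, or a missing APB/CCA result — is ambiguous. Missing
markers are never imputed.

The resolution stage formalizes what is otherwise a narrative,
case-by-case argument. The rule was reverse-engineered so that every one
of the seven bundled reference cases reproduces its published call, and is
documented as such: (1) concordant APB⁺/CCA⁺ dominates (assay agreement
outranks expression markers); (2) otherwise a genomic telomerase lesion
(MNA or TERT rearrangement) dominates discordant assays; (3) otherwise the
sample is ALT⁺ when at least `min_aux_alt_markers = 2` of the available
auxiliary markers point to ALT — ATRX mutation, TC ratio ≥ 1.22, TRF ≥
9.01 kb, TERRA ≥ the ALT-group mean 0.011, TTTGGG singleton log₂ ratio ≤
the ALT-group mean, any telomere insertion — TEL⁺ when TERT expression or
telomerase activity is high, and ambiguous otherwise. Missing markers are
excluded from the score rather than imputed, so a sparsely measured sample
can honestly remain ambiguous. The singleton reference mean has no
published value; it defaults to `NA` (marker skipped) and must be computed
from cohort data or supplied. High telomerase activity likewise has no
numeric cutoff and enters as a user-supplied flag.

ROC support: `empirical_roc()` enumerates observed thresholds
(positive ⟺ score ≥ threshold) and integrates trapezoidally, which equals
the pairwise concordance statistic with half credit for ties;
`propose_threshold()` maximizes Youden's J with ties broken toward higher
specificity, then lower threshold (Youden is an assumption — the threshold
derivation is described only as based on the ROC coordinates);
`combine_predictors()` is a maximum-likelihood logistic fit whose fitted
probabilities feed a combined ROC, with perfect separation flagged and
capped. Subgroup comparisons use Kruskal–Wallis followed by Dunn's pairwise
z-tests with tie correction; the family-wise adjustment is Bonferroni,
since the post-hoc procedure is named without its adjustment.

## What the simulators emulate — and what they do not

The generators are pure functions of their seed and return truth records
sufficient to score every downstream stage.

- `simulate_reference()`: a few ~50 kb contigs with scrubbed (t-type-free)
  interiors and ~2 kb terminal telomeric tracts, so exclusion-BED logic is
  exercised at desk scale.
- `simulate_wgs_pair()`: mapped background pairs, unmapped telomeric read
  pairs at a planted binomial per-read fraction with controllable variant
  singleton composition, and planted insertion sites emitting the stated
  numbers of discordant pairs and telomeric soft clips.
- `simulate_rna_reads()`: background reads plus TERRA reads at planted
  per-variant fractions.
- `simulate_cohort_table()`: subgroup sizes 17/13/31 (TMM⁻/ALT⁺/TEL⁺, the
  unambiguously classified cohort), telomere content lognormal around
  means 0.87/6.39/0.96 (sdlog 0.6), TRF normal around 8.39/10.66/6.36 kb
  (sd 1.3 kb), TERRA lognormal around 0.004/0.011/0.002 (sdlog 0.5),
  TTTGGG singleton log₂ ratios centered at −2.5 in ALT⁺ versus 0 elsewhere,
  insertion prevalences 0.06/0.77/0.32, a TRF-availability rate of 0.57,
  and an assay discordance rate of 0.10 (≈ 7 ambiguous per 68). The group
  means and prevalences are the observed cohort values; the dispersions,
  the lognormal choice for non-negative right-skewed quantities, and the
  singleton centers are modeling choices fixed once to look like the
  published distributions and documented here as assumptions, not asserted
  facts.
- `simulate_expression_cohort()`: the bimodal log₂ mixture
  0.6·N(6, 0.5²) + 0.4·N(11, 1²).
- `simulate_densitometry()`: a Gaussian profile over a log-spaced ladder
  with OD proportional to per-cell probability mass, so the OD-weighted
  mean recovers the requested mean TRF to within the grid resolution.

None of the generators model sequencing error, GC or coverage bias,
subtelomeric sequence, karyotype instability, or locus-resolved TERRA.
Passing tests therefore demonstrate that the estimators recover what was
planted under the stated statistical structure — not that real tumor data
are free of the biases listed above.

## Numerical choices and degenerate inputs

- Positions are 1-based in memory (R/SAM convention); BED I/O converts at
  the boundary via rtracklayer.
- Clip-start clustering is greedy on sorted positions with all members
  within the ± 1 bp tolerance of a common start; the reported breakpoint is
  the modal start, lowest on ties.
- Zero normal telomere content makes the TC ratio undefined: an error
  directs the user to tumor-only mode rather than returning infinity.
- Empty read streams, all-zero densitometry lanes, non-monotone ladders,
  single-class ROC labels, collinear or doubly constant logistic
  covariates, and mixture fits with collapsed components all raise errors.
- The discordance-resolution and ROC code never consults auxiliary markers
  for strictly classified samples, keeping the stepwise workflow's
  step economy auditable from the per-sample provenance.

## Problem sizes

The test-suite and acceptance-script simulations run on one CPU in a few
minutes total: read-level checks use 3,000–200,000 reads (the largest for
the binomial content check), oracle sweeps 1,000 random sequences, mixture
fits n = 2,000, logistic recovery n = 5,000, and cohort-level rates are
estimated over 10 replicate cohorts of 61 samples. These sizes were chosen
to keep every statistical assertion comfortably powered at desk scale.

## Known limitations

- Telomere content uses a fixed repeat threshold; read-length-scaled
  thresholds (as in dedicated telomere-read callers) would shift absolute
  values on long or short reads.
- The TVR scan attributes variants only within TTAGGG-anchored runs;
  heavily diverged telomeric sequence with no canonical anchor is invisible.
- The insertion caller does not assemble the inserted sequence, classify
  its mechanism, or call structural variants generally.
- Somatic ATRX/TERT status enters as boolean annotation from an upstream
  pipeline; mutation calling is out of scope.
- The evidence-weighted resolution reproduces the seven published reference
  cases, but it is a formalization of a narrative rule and should be
  treated as a decision aid, not a validated clinical classifier.
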
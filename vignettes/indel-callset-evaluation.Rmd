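---
title: "Evaluating INDEL call sets: quality tiers, concordance, context and coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating INDEL call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelqc)
```

## The problem

Insertions and deletions (INDELs) are harder to call accurately than
SNVs: their error profile is dominated by library preparation (PCR
slippage in homopolymer runs), capture inefficiency in exome
sequencing, coverage non-uniformity, and representational ambiguity
inside repeats. `indelqc` bundles the analyses needed to characterize
an INDEL call set along these axes: a coverage-based quality
classification, concordance between call sets from different platforms,
sequence-context profiling, coverage-uniformity statistics, and a
downsampling sensitivity analysis. A synthetic-data generator makes
every analysis runnable at desk scale with known ground truth.

## The quality model

A micro-assembly caller reports, for each INDEL, the k-mer coverage of
the reference and alternate alleles, $C_o^{Ref}$ and $C_o^{Alt}$.
Under a balanced expectation $C_e = (C_o^{Ref} + C_o^{Alt})/2$ the
goodness-of-fit statistic

$$\chi^2 = \frac{(C_o^{Ref}-C_e)^2}{C_e} +
           \frac{(C_o^{Alt}-C_e)^2}{C_e}$$

measures allele imbalance. Validation of hundreds of loci by deep
amplicon resequencing shows that calls with low alternate-allele
coverage tolerate much less imbalance before becoming unreliable, so a
single $\chi^2$ cutoff is inappropriate. The three-tier classification
applies coverage-dependent cutoffs:

* **high**: $C_o^{Alt} > 10$ and $\chi^2 < 10.8$, or
  $5 < C_o^{Alt} \le 10$ and $\chi^2 \le 4.5$, or
  $C_o^{Alt} \le 5$ and $\chi^2 \le 2$ (validated error rate ~7%);
* **low**: $C_o^{Alt} \le 10$ and $\chi^2 > 10.8$ (validated error
  rate ~51%);
* **moderate**: everything else.

The boundary semantics are kept exactly as validated — strict `<` on
10.8 in the high tier, inclusive `<=` on 4.5 and 2 — so the point
`(cov_alt = 11, chi2 = 10.8)` is moderate, and a high-coverage call is
never classified low however imbalanced it is. Smoothing this apparent
asymmetry would silently change which calls pass published filters, so
fidelity won over elegance. The five constants are overridable via
`quality_thresholds()`; the package applies them but does not re-derive
them from new validation data.

```{r}
chi_square_score(10, 2)
classify_quality(c(11, 8, 8), c(10.0, 11.5, 5.0))
```

## Normalization and matching

Equivalent INDELs can be written at different positions inside repeats.
`normalize_calls()` produces the canonical representation: shared
trailing bases are trimmed (extending leftwards from the reference when
an allele empties), then shared leading bases are trimmed down to a
single anchor base. The result is maximally left-shifted and minimally
trimmed, verified in the tests against a brute-force oracle that
enumerates every candidate representation and compares the edited
haplotypes. Variants abutting position 1 of a contig are right-padded
instead (the VCF telomere convention).

Two match predicates compare normalized call sets: *position-match*
(same chromosome and position) and *exact-match* (additionally the same
allele strings). A third, *validation-match* (position plus the same
variation type), reproduces the rule used when scoring calls against
amplicon-resequencing truth, where an insertion is not validated by a
deletion at the same coordinate. `compare_callsets()` reports
intersection and set-specific counts as percentages of the union; under
position-match a locus shared by both sets counts once as concordant
and surplus signatures count as set-specific, so the three rates always
sum to 100. Per-locus depth floors (`{0, 1, 20, 40, 60, 80}` in
`concordance_table()`) exclude loci under-covered in either set before
the set algebra; depth is taken at the normalized anchor position, the
simplest defensible reading of per-locus "base coverage" (an
averaged-over-span alternative would need per-base depth everywhere and
changes little at these scales).

## Sequence context

Repeat context is assigned from the reference, not from the allele:
`find_homopolymers()` reports maximal single-base runs of length at
least 5 (the conventional threshold at which polymerase slippage
dominates), and `find_strs()` reports maximal perfect tandem tracts
with a primitive 2–6 bp motif, at least 3 copies and an 8 bp minimum
span. These detector gates are declared configuration defaults standing
in for an external STR-region catalogue; they make the method
self-contained but are approximations, not reproductions, of any
specific catalogue. A call is labelled `poly-A/C/G/T` when its variant
interval intersects or lies within 1 bp of a homopolymer tract of that
reference-strand base (A and T kept distinct, since they are reported
separately), `other-STR` for the remaining tract overlaps, else
`non-STR`. The 1 bp adjacency allowance covers inserted runs that
extend a tract from its boundary, where the insertion point sits
between the flank and the tract. Labelling is performed after
normalization and is invariant to the raw representation; the detectors
are tested against an exhaustive enumeration oracle on random windows
with planted, edge-spanning tracts.

## Coverage statistics

Coverage uniformity is summarized by the bias-corrected coefficient of
variation

$$\widehat{C_v}^{*} = \left(1 + \frac{1}{4n}\right)\frac{s}{\bar x},$$

reported as a percentage (1 decimal), and by the coverage fraction at
$X$ reads (default curve $X = 1..51$). For region sizes above ~10,000
bases the correction is numerically irrelevant and the estimator
approaches $s/\bar x$, which the tests confirm by Monte-Carlo at
$n = 10^6$. Depth input is a plain per-base TSV or bedGraph rather than
alignments, which keeps the statistics testable without BAM files;
bases absent from a depth table count as zero and are logged.

## Downsampling sensitivity

Re-running an assembler on downsampled alignments is out of scope for a
desk-scale toolkit. `sensitivity_curve()` instead applies a documented
call-level surrogate: allele coverages are thinned binomially at rate
`target_mean / full_mean` and a call is deemed detectable when its
thinned alternate coverage reaches `min_alt` (default 3, the usual
minimum k-mer support of a micro-assembly caller). Curves are averaged
over 25 seeded replicates with SD, stratified by zygosity. Because a
heterozygous call carries roughly `Binomial(depth, 0.5)` alternate
coverage while a homozygous call carries the full depth, the homozygous
curve dominates and reaches any sensitivity target at lower coverage —
the surrogate reproduces this ordering and the shape of the
coverage–sensitivity relationship, but absolute coverage requirements
from read-level experiments (e.g. "95% at 60X") are explicitly not
claimed reproducible by it.

## The synthetic-data generator

`generate_reference()` builds a background sequence scrubbed of
incidental repeats (any background tract passing the detector gates is
broken by a point substitution) and plants homopolymer/STR tracts at
recorded coordinates with flanks chosen so each tract is exactly
maximal; detector output on the finished sequence equals the planted
bookkeeping exactly, which several tests exploit.

`generate_truth_indels()` places INDELs with recorded zygosity and
context. Defaults are fixed once to the study conditions the package
emulates: sizes span 1–100 bp (90% small, capped at 5 bp; 10% uniform
6–100 bp — real germline sets are dominated by 1–2 bp events), the
heterozygous fraction is 0.61 (≈1.6-fold more heterozygous than
homozygous), and the context mix is 55% non-STR, 15% each poly-A/T, 2%
each poly-C/G, 11% other-STR, reflecting the A/T-heavy repeat landscape
of exonic sequence.

`generate_callset()` turns a truth set into a platform-flavoured call
set: capture dropout on 150 bp windows, an extra loss probability for
\>5 bp INDELs, negative-binomial locus depths matching the profile's
mean and CV (negative binomial because overdispersed counts reproduce
capture-induced skew), zygosity-dependent allele coverages
(heterozygous `Binomial(depth, 0.5)`, homozygous full depth), and
context-dependent false calls injected preferentially as one-unit
slippage signatures inside planted tracts with strongly unbalanced
coverages. Emission requires at least one alternate-supporting
observation; the stricter `min_alt = 3` detection rule is modelled
separately in the sensitivity module. Every emitted call carries a
hidden truth label.

The two built-in profiles encode the platform contrasts the package is
designed to measure: `wgs_profile()` (mean 71X, CV 39.4%, negligible
dropout, no large-INDEL penalty) and `wes_profile()` (mean 337X, CV
109.3%, 16% window dropout, 0.8 large-INDEL loss probability, poly-A/T
false-call rates of 0.40 against 0.15 for the WGS-like profile). The
dropout, CV and mean values are measured platform characteristics; the
large-INDEL penalty and per-context false-call rates are generator
choices fixed once to reproduce the observed direction and rough
magnitude of the large-INDEL deficit and poly-A/T error enrichment in
capture data.

What the generator does *not* emulate: read-level sequencing error,
alignment artifacts, GC-dependent coverage bias, interrupted/imperfect
repeats, and multi-sample structure. Passing tests on synthetic data
therefore demonstrate the correctness of the statistics and the
direction of platform contrasts, not absolute error rates on real data.

## Worked example

```{r, message = FALSE}
r   <- generate_reference(100000L, seed = 1)
tr  <- generate_truth_indels(r, n = 400, seed = 2)
wgs <- generate_callset(tr, wgs_profile(), r, seed = 3)
wes <- generate_callset(tr, wes_profile(), r, seed = 4)

# quality and context composition of the capture-like set
rep <- classify_report(wes, r$seq)
rep$class_table[, c("class", "n", "percent")]

# concordance across depth floors
concordance_table(wgs, wes, callset_depth_table(wgs),
                  callset_depth_table(wes))[, 1:4]
```

## Numerical choices and degenerate inputs

* `chi_square_score(0, 0)` returns 0 with a warning (no coverage, no
  evidence either way); negative inputs are an error.
* `ppv()` requires a positive denominator; percentages are rounded to
  one decimal only in the report layers, never internally.
* Duplicate records after normalization collapse keeping the maximum
  alternate coverage — set comparisons deduplicate implicitly, and the
  maximum is the least destructive summary of a representation clash.
* Region membership uses the normalized anchor position only; a
  deletion spanning a region boundary is attributed to its anchor.
* SNP/MNP records are excluded at construction with reported counts.
* Zygosity is read from a configurable INFO key and defaults to
  `"unknown"` (caller output formats differ); unknown calls are
  excluded from stratified sensitivity curves with a message.
* All simulation randomness is seeded; generator outputs are
  byte-identical across runs with the same seed.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline on a
200 kb synthetic reference with ~700 truth INDELs, 500 calls per
quality tier for error-rate recovery, 1,000 random fixtures each for
the normalization and repeat-detector oracles, and 25 thinning
replicates per coverage level — sizes chosen so the whole suite
completes in minutes on a laptop while keeping Monte-Carlo noise well
inside the asserted tolerances.

## Known limitations

* Haplotype-aware equivalence beyond left-normalization (variant
  decomposition/recomposition) is not attempted.
* Symbolic/structural alleles and genotype likelihoods are out of
  scope.
* The sensitivity surrogate calibrates orderings, not absolute
  coverage requirements.
* STR context uses perfect repeats only; interrupted tracts are
  labelled by their longest perfect core.
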
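#' k-mer Chi-Square allele-balance score
#'
#' Goodness-of-fit statistic on the observed reference and alternate
#' allele k-mer coverages against the balanced expectation. With observed
#' coverages \eqn{C_o^{Ref}} and \eqn{C_o^{Alt}} the expected coverage of
#' each allele is \eqn{C_e = (C_o^{Ref} + C_o^{Alt})/2} and
#' \deqn{\chi^2 = \frac{(C_o^{Ref}-C_e)^2}{C_e} +
#'               \frac{(C_o^{Alt}-C_e)^2}{C_e}.}
#' High values flag allele imbalance (for a heterozygous call both alleles
#' should be covered roughly equally). The degenerate case
#' `cov_ref + cov_alt == 0` returns 0 with a warning.
#'
#' @param cov_ref,cov_alt non-negative observed allele coverages
#'   (vectorized).
#' @return Non-negative numeric vector of scores.
#' @examples
#' chi_square_score(5, 5)    # 0
#' chi_square_score(10, 2)   # 5.333...
#' chi_square_score(0, 10)   # 10
#' @export
chi_square_score <- function(cov_ref, cov_alt) {
  if (any(is.na(cov_ref)) || any(is.na(cov_alt)) ||
      any(cov_ref < 0) || any(cov_alt < 0)) {
    stop("cov_ref and cov_alt must be non-negative")
  }
  total <- cov_ref + cov_alt
  expected <- total / 2
  out <- numeric(length(total))
  nz <- total > 0
  out[nz] <- (cov_ref[nz] - expected[nz])^2 / expected[nz] +
             (cov_alt[nz] - expected[nz])^2 / expected[nz]
  if (any(!nz)) {
    warning("degenerate record(s) with zero total coverage scored 0",
            call. = FALSE)
  }
  out
}

#' Quality-classification thresholds
#'
#' The five constants of the three-tier classification. Defaults are the
#' validated cutoffs: a call is *high* quality when
#' `cov_alt > 10 & chi2 < 10.8`, or `5 < cov_alt <= 10 & chi2 <= 4.5`, or
#' `cov_alt <= 5 & chi2 <= 2`; *low* quality when
#' `cov_alt <= 10 & chi2 > 10.8`; *moderate* otherwise. The boundary
#' semantics (strict `<` on 10.8 in the high tier, `<=` on 4.5 and 2) are
#' preserved exactly as validated, so e.g. `(cov_alt = 11, chi2 = 10.8)`
#' is moderate.
#'
#' @param hi_cov_chi2_max chi-square bound for the `cov_alt > cov_hi` tier.
#' @param mid_cov_chi2_max bound for the `cov_lo < cov_alt <= cov_hi` tier.
#' @param low_cov_chi2_max bound for the `cov_alt <= cov_lo` tier.
#' @param cov_hi,cov_lo coverage breakpoints.
#' @return A list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(hi_cov_chi2_max = 10.8,
                               mid_cov_chi2_max = 4.5,
                               low_cov_chi2_max = 2,
                               cov_hi = 10L, cov_lo = 5L) {
  stopifnot(hi_cov_chi2_max > 0, mid_cov_chi2_max > 0,
            low_cov_chi2_max > 0, cov_lo < cov_hi)
  structure(list(hi_cov_chi2_max = hi_cov_chi2_max,
                 mid_cov_chi2_max = mid_cov_chi2_max,
                 low_cov_chi2_max = low_cov_chi2_max,
                 cov_hi = cov_hi, cov_lo = cov_lo),
            class = "quality_thresholds")
}

#' Three-tier quality classification
#'
#' Classifies each call as `"high"`, `"moderate"` or `"low"` from its
#' alternate-allele coverage and chi-square score (see
#' [quality_thresholds()] for the rule). The classification is a total
#' partition: every `(cov_alt, chi2)` pair maps to exactly one class, and
#' for fixed `cov_alt` an increasing score never raises the class. Calls
#' with `cov_alt > cov_hi` are never low, only moderate, however large the
#' score.
#'
#' @param cov_alt alternate-allele coverage (vectorized).
#' @param chi2 chi-square score from [chi_square_score()].
#' @param thresholds a [quality_thresholds()] object.
#' @return Character vector in `c("high", "moderate", "low")`.
#' @examples
#' classify_quality(11, 10.0)  # "high"
#' classify_quality(8, 11.5)   # "low"
#' classify_quality(8, 5.0)    # "moderate"
#' @export
classify_quality <- function(cov_alt, chi2,
                             thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  t <- thresholds
  if (any(chi2 < 0, na.rm = TRUE)) stop("chi2 must be non-negative")
  high <- (cov_alt > t$cov_hi & chi2 < t$hi_cov_chi2_max) |
          (cov_alt > t$cov_lo & cov_alt <= t$cov_hi &
             chi2 <= t$mid_cov_chi2_max) |
          (cov_alt <= t$cov_lo & chi2 <= t$low_cov_chi2_max)
  low <- !high & cov_alt <= t$cov_hi & chi2 > t$hi_cov_chi2_max
  ifelse(high, "high", ifelse(low, "low", "moderate"))
}

#' Score and classify every call in a call set
#'
#' Computes the chi-square score from the stored allele coverages and
#' assigns the three-tier quality class.
#'
#' @param cs an `indel_callset`.
#' @param thresholds a [quality_thresholds()] object.
#' @return The call set with `chi2` and `quality_class` filled in.
#' @export
annotate_quality <- function(cs, thresholds = quality_thresholds()) {
  stopifnot(inherits(cs, "indel_callset"))
  if (nrow(cs$calls)) {
    cs$calls$chi2 <- suppressWarnings(
      chi_square_score(cs$calls$cov_ref, cs$calls$cov_alt))
    cs$calls$quality_class <- classify_quality(cs$calls$cov_alt,
                                               cs$calls$chi2, thresholds)
  }
  cs
}

#' Positive predictive value of a validated call set
#'
#' `PPV = 100 * TP / (TP + FP)`, i.e. the percentage of assayed loci that
#' validated as true calls.
#'
#' @param n_tested number of assayed loci (`TP + FP`), must be positive.
#' @param n_valid number of true-positive calls, `0 <= n_valid <= n_tested`.
#' @return PPV as a percentage (full precision; report layers round to one
#'   decimal).
#' @examples
#' ppv(160, 152)  # 95.0
#' ppv(145, 122)  # 84.1...
#' @export
ppv <- function(n_tested, n_valid) {
  if (any(n_tested <= 0)) stop("n_tested must be positive")
  if (any(n_valid < 0 | n_valid > n_tested)) {
    stop("need 0 <= n_valid <= n_tested")
  }
  100 * n_valid / n_tested
}

#' Quality-class composition of a call set
#'
#' Counts and proportions of high/moderate/low quality calls. All calls
#' must already be classified (see [annotate_quality()]).
#'
#' @param cs an `indel_callset`.
#' @return A data frame with one row per class (`high`, `moderate`,
#'   `low`): columns `class`, `n`, `proportion`.
#' @export
class_composition <- function(cs) {
  stopifnot(inherits(cs, "indel_callset"))
  cls <- cs$calls$quality_class
  if (any(cls == "unset")) {
    stop("call set contains unclassified calls; run annotate_quality() first")
  }
  levels <- c("high", "moderate", "low")
  n <- vapply(levels, function(l) sum(cls == l), integer(1L))
  data.frame(class = levels, n = unname(n),
             proportion = if (sum(n)) unname(n) / sum(n) else rep(0, 3L),
             stringsAsFactors = FALSE)
}

#' Fold enrichment between two counts
#'
#' Simple ratio `a / b`, reported to one decimal by the formatting layers
#' (e.g. 769 high-quality calls against 71 is a 10.8-fold enrichment).
#'
#' @param a,b positive counts (or rates).
#' @return Numeric ratio.
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be positive")
  a / b
}
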
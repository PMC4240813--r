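#' Sensitivity of a call set against a truth set
#'
#' The fraction of truth INDELs recovered in the called set under
#' exact-match: `|truth intersect called| / |truth|`. The canonical use is
#' measuring, after downsampling, how many of the INDELs confirmed at
#' full coverage are still discovered.
#'
#' @param truth,called normalized `indel_callset`s; `truth` must be
#'   non-empty.
#' @return Proportion in `[0, 1]`.
#' @export
sensitivity_at <- function(truth, called) {
  stopifnot(inherits(truth, "indel_callset"),
            inherits(called, "indel_callset"))
  if (!nrow(truth$calls)) stop("empty truth set")
  if ((nrow(truth$calls) && !all(truth$calls$normalized)) ||
      (nrow(called$calls) && !all(called$calls$normalized))) {
    stop("both call sets must be left-normalized")
  }
  mean(call_key(truth$calls) %in% call_key(called$calls))
}

#' Binomial thinning of allele coverages
#'
#' Emulates downsampling an alignment from mean coverage `full_mean` to
#' `target_mean` at the call level: each allele coverage is thinned
#' independently and binomially at rate `target_mean / full_mean`.
#' Deterministic for a given `seed`.
#'
#' @param cs an `indel_callset` with `cov_ref` / `cov_alt` set.
#' @param full_mean mean coverage the observed coverages correspond to.
#' @param target_mean desired mean coverage, `<= full_mean`.
#' @param seed integer seed; `NULL` to use the current RNG state.
#' @return The call set with thinned coverages.
#' @export
thin_coverages <- function(cs, full_mean, target_mean, seed = NULL) {
  stopifnot(inherits(cs, "indel_callset"),
            target_mean <= full_mean, full_mean > 0, target_mean >= 0)
  if (!is.null(seed)) set.seed(seed)
  rate <- target_mean / full_mean
  n <- nrow(cs$calls)
  if (n) {
    cs$calls$cov_ref <- stats::rbinom(n, cs$calls$cov_ref, rate)
    cs$calls$cov_alt <- stats::rbinom(n, cs$calls$cov_alt, rate)
  }
  cs
}

#' Call-level detection predicate
#'
#' A call is considered detectable when its alternate-allele coverage
#' meets the caller's minimum support (`min_alt`, default 3 — the usual
#' minimum k-mer coverage required to report a variant).
#'
#' @param cov_alt alternate-allele coverage (vectorized); or an
#'   `indel_callset`, in which case its `cov_alt` column is used.
#' @param min_alt minimum supporting coverage (default 3).
#' @return Logical vector.
#' @export
detectable <- function(cov_alt, min_alt = 3L) {
  if (inherits(cov_alt, "indel_callset")) cov_alt <- cov_alt$calls$cov_alt
  cov_alt >= min_alt
}

#' Downsampling sensitivity curves, stratified by zygosity
#'
#' For each target mean coverage, the truth calls' allele coverages are
#' binomially thinned from `full_mean` and the fraction of calls still
#' detectable (`cov_alt >= min_alt`) is recorded, averaged over
#' `replicates` thinning draws. The denominator is the set of truth calls
#' detectable at full coverage, so the curve is exactly 1 at
#' `full_mean`. With `strata = TRUE`, separate curves are produced for
#' heterozygous and homozygous calls (calls of unknown zygosity are
#' excluded from the stratified curves with a message); since a
#' heterozygous call carries roughly half the alternate-allele coverage
#' of a homozygous one at equal depth, the homozygous curve dominates and
#' reaches any sensitivity target at a lower coverage.
#'
#' This is a call-level surrogate for re-running an assembler on
#' downsampled alignments; it reproduces the shape and ordering of the
#' coverage-sensitivity relationship, not absolute coverage requirements.
#'
#' @param truth a normalized `indel_callset` with coverages at full depth.
#' @param full_mean the mean coverage the stored coverages correspond to.
#' @param levels target mean coverages (default `c(20, 32, 45, 57)`);
#'   `full_mean` is always appended.
#' @param min_alt detection threshold (default 3).
#' @param seed integer seed for the thinning draws.
#' @param strata produce per-zygosity curves as well?
#' @param replicates number of thinning replicates (default 25).
#' @return A data frame with columns `stratum`, `coverage`,
#'   `sensitivity`, `sd`, `truth_size`.
#' @export
sensitivity_curve <- function(truth, full_mean,
                              levels = c(20, 32, 45, 57),
                              min_alt = 3L, seed = 1L, strata = TRUE,
                              replicates = 25L) {
  stopifnot(inherits(truth, "indel_callset"), full_mean > 0,
            all(levels <= full_mean))
  calls <- truth$calls
  if (!nrow(calls)) stop("empty truth set")
  base <- detectable(calls$cov_alt, min_alt)
  groups <- list(all = rep(TRUE, nrow(calls)))
  if (strata) {
    unknown <- calls$zygosity == "unknown"
    if (any(unknown)) {
      message(sum(unknown), " call(s) of unknown zygosity excluded from ",
              "stratified curves")
    }
    groups$heterozygous <- calls$zygosity == "heterozygous"
    groups$homozygous <- calls$zygosity == "homozygous"
  }
  levels <- sort(unique(c(levels, full_mean)))
  set.seed(seed)
  out <- list()
  for (stratum in names(groups)) {
    in_g <- groups[[stratum]] & base
    denom <- sum(in_g)
    if (!denom) next
    cov0 <- calls$cov_alt[in_g]
    for (lv in levels) {
      rate <- lv / full_mean
      sens <- vapply(seq_len(replicates), function(r) {
        if (rate >= 1) return(1)
        mean(stats::rbinom(denom, cov0, rate) >= min_alt)
      }, numeric(1L))
      out[[length(out) + 1L]] <- data.frame(
        stratum = stratum, coverage = lv, sensitivity = mean(sens),
        sd = stats::sd(sens), truth_size = denom,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Coverage needed to reach a sensitivity target
#'
#' Linear interpolation of a sensitivity curve to the smallest coverage at
#' which the curve reaches `target` (default 0.95). Returns `NA` when the
#' curve never reaches the target.
#'
#' @param curve one stratum of a [sensitivity_curve()] result.
#' @param target sensitivity target in `(0, 1]`.
#' @return Interpolated coverage.
#' @export
coverage_for_sensitivity <- function(curve, target = 0.95) {
  stopifnot(is.data.frame(curve), target > 0, target <= 1)
  curve <- curve[order(curve$coverage), , drop = FALSE]
  s <- curve$sensitivity
  cv <- curve$coverage
  if (all(s < target)) return(NA_real_)
  i <- which(s >= target)[1L]
  if (i == 1L) return(cv[1L])
  cv[i - 1L] + (target - s[i - 1L]) * (cv[i] - cv[i - 1L]) /
    (s[i] - s[i - 1L])
}
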
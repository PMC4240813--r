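#' Match predicates between two INDEL calls
#'
#' Position-match: same chromosome and (normalized) position.
#' Exact-match: additionally the same reference and alternate alleles.
#' Validation-match: same chromosome, position and variation type
#' (insertion vs deletion) — the predicate used when scoring calls against
#' amplicon-resequencing truth data, where an insertion call is not
#' validated by a deletion at the same coordinate.
#'
#' Both calls must be left-normalized first (see [normalize_calls()]);
#' comparing raw representations is refused because equivalent INDELs can
#' be written at different coordinates inside repeats.
#'
#' @param a,b single-row call data frames (or single-call `indel_callset`s).
#' @return Logical scalar.
#' @export
match_exact <- function(a, b) {
  ab <- match_pair(a, b)
  ab$a$chrom == ab$b$chrom && ab$a$pos == ab$b$pos &&
    ab$a$ref == ab$b$ref && ab$a$alt == ab$b$alt
}

#' @rdname match_exact
#' @export
match_position <- function(a, b) {
  ab <- match_pair(a, b)
  ab$a$chrom == ab$b$chrom && ab$a$pos == ab$b$pos
}

#' @rdname match_exact
#' @export
match_validation <- function(a, b) {
  ab <- match_pair(a, b)
  ab$a$chrom == ab$b$chrom && ab$a$pos == ab$b$pos &&
    ab$a$itype == ab$b$itype
}

match_pair <- function(a, b) {
  one <- function(x) {
    if (inherits(x, "indel_callset")) x <- x$calls
    stopifnot(is.data.frame(x), nrow(x) == 1L)
    if (!isTRUE(x$normalized)) {
      stop("calls must be left-normalized before matching")
    }
    x
  }
  list(a = one(a), b = one(b))
}

#' Compare two call sets
#'
#' Computes intersection and set-specific counts between two normalized
#' call sets under exact-match (same chromosome, position and alleles) or
#' position-match (chromosome and position only), optionally after
#' excluding loci whose per-locus depth falls below `depth_floor` in
#' either set. The three rates are percentages of the union size
#' (`n_intersection + n_a_specific + n_b_specific`) and always sum to 100.
#'
#' Under position-match, a locus present in both sets counts once as
#' concordant; surplus distinct signatures at that locus count as specific
#' to the set carrying them, so the three counts remain a partition.
#'
#' @param a,b normalized `indel_callset`s.
#' @param mode `"exact"` or `"position"`.
#' @param depth_a,depth_b optional per-locus depth tables (data frames
#'   with `chrom`, `pos`, `depth`); required when `depth_floor > 0`. A
#'   locus absent from a table is treated as depth 0 (logged).
#' @param depth_floor minimum per-locus depth required in *both* sets
#'   (0 = no filtering). Depth is taken at the normalized anchor position.
#' @return A list of class `concordance_result`: counts
#'   `n_intersection`, `n_a_specific`, `n_b_specific`, rates
#'   `rate_concordant`, `rate_a_specific`, `rate_b_specific`
#'   (percentages), plus `mode` and `depth_floor`.
#' @export
compare_callsets <- function(a, b, mode = c("exact", "position"),
                             depth_a = NULL, depth_b = NULL,
                             depth_floor = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "indel_callset"), inherits(b, "indel_callset"))
  ca <- a$calls; cb <- b$calls
  if ((nrow(ca) && !all(ca$normalized)) ||
      (nrow(cb) && !all(cb$normalized))) {
    stop("both call sets must be left-normalized before comparison")
  }
  if (depth_floor > 0L) {
    ca <- ca[locus_depth(ca, depth_a) >= depth_floor &
             locus_depth(ca, depth_b) >= depth_floor, , drop = FALSE]
    cb <- cb[locus_depth(cb, depth_a) >= depth_floor &
             locus_depth(cb, depth_b) >= depth_floor, , drop = FALSE]
  }
  if (mode == "exact") {
    ka <- call_key(ca); kb <- call_key(cb)
    n_int <- sum(ka %in% kb)
    n_a <- sum(!(ka %in% kb))
    n_b <- sum(!(kb %in% ka))
  } else {
    la <- unique(locus_key(ca)); lb <- unique(locus_key(cb))
    shared <- intersect(la, lb)
    n_int <- length(shared)
    sig_a <- table(locus_key(ca)); sig_b <- table(locus_key(cb))
    # surplus signatures at shared loci are set-specific
    n_a <- sum(sig_a[setdiff(la, lb)]) +
      sum(sig_a[shared] - 1L)
    n_b <- sum(sig_b[setdiff(lb, la)]) +
      sum(sig_b[shared] - 1L)
  }
  union_n <- n_int + n_a + n_b
  rate <- function(x) if (union_n) 100 * x / union_n else NA_real_
  structure(list(n_intersection = as.integer(n_int),
                 n_a_specific = as.integer(n_a),
                 n_b_specific = as.integer(n_b),
                 rate_concordant = rate(n_int),
                 rate_a_specific = rate(n_a),
                 rate_b_specific = rate(n_b),
                 mode = mode, depth_floor = as.integer(depth_floor)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance (%s-match, depth floor %d): %.1f%% concordant, %.1f%% / %.1f%% set-specific (n = %d / %d / %d)\n",
    x$mode, x$depth_floor, x$rate_concordant, x$rate_a_specific,
    x$rate_b_specific, x$n_intersection, x$n_a_specific, x$n_b_specific))
  invisible(x)
}

# depth at each call's anchor locus; missing loci are depth 0 (logged once)
locus_depth <- function(calls, depth_table) {
  if (!nrow(calls)) return(integer(0))
  if (is.null(depth_table)) {
    message("no depth table supplied; loci treated as depth 0")
    return(rep(0L, nrow(calls)))
  }
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth_table)))
  key <- paste(depth_table$chrom, depth_table$pos, sep = "\r")
  idx <- match(locus_key(calls), key)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " locus/loci absent from depth table; ",
            "treated as depth 0")
  }
  out <- depth_table$depth[idx]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Mean and standard deviation of concordance rates across samples
#'
#' Unweighted per-cell mean and sample standard deviation of the rates of
#' several per-sample [compare_callsets()] results (one per sample). With
#' a single sample the SD is `NA` (flagged undefined).
#'
#' @param results list of `concordance_result` objects.
#' @return Data frame with rows `concordant`, `a_specific`, `b_specific`
#'   and columns `mean`, `sd`.
#' @examples
#' # two samples with concordance 52% and 54%: mean 53.0, SD 1.41
#' @export
mean_concordance <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1L),
                       "concordance_result")))
  mat <- vapply(results, function(r) {
    c(r$rate_concordant, r$rate_a_specific, r$rate_b_specific)
  }, numeric(3L))
  if (length(results) == 1L) {
    warning("single sample: SD undefined", call. = FALSE)
    sds <- rep(NA_real_, 3L)
  } else {
    sds <- apply(mat, 1L, stats::sd)
  }
  data.frame(cell = c("concordant", "a_specific", "b_specific"),
             mean = rowMeans(mat), sd = sds, stringsAsFactors = FALSE)
}

#' Multiple-signature loci in a (union) call set
#'
#' A genomic location carrying more than one distinct INDEL signature
#' (`(ref, alt)` pair). Assuming at most one signature can be the true
#' variant, every additional signature is a false-positive call, so the
#' per-context breakdown of these loci localizes error sources (they are
#' typically enriched in homopolymer A/T runs).
#'
#' @param cs a normalized, deduplicated `indel_callset` (typically the
#'   union of the sets under study, built with [union_callsets()]).
#' @return A data frame with one row per signature at multi-signature
#'   loci: `chrom`, `pos`, `ref`, `alt`, `context`, `n_signatures`.
#' @export
multiple_signatures <- function(cs) {
  stopifnot(inherits(cs, "indel_callset"))
  calls <- cs$calls
  if (!nrow(calls)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      context = character(), n_signatures = integer(),
                      stringsAsFactors = FALSE))
  }
  lk <- locus_key(calls)
  n_sig <- stats::ave(seq_along(lk), lk, FUN = length)
  out <- calls[n_sig >= 2L,
               c("chrom", "pos", "ref", "alt", "context"), drop = FALSE]
  out$n_signatures <- as.integer(n_sig[n_sig >= 2L])
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of call sets
#'
#' Deduplicated union of the calls of two or more call sets (maximum
#' `cov_alt` kept for records present in several sets).
#'
#' @param ... `indel_callset`s.
#' @param label label for the union set.
#' @return An `indel_callset`.
#' @export
union_callsets <- function(..., label = "union") {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "indel_callset")))
  calls <- do.call(rbind, lapply(sets, `[[`, "calls"))
  indel_callset(calls, label = label)
}
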
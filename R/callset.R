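#' Construct an INDEL call set
#'
#' An `indel_callset` is a named, deduplicated collection of INDEL calls,
#' optionally restricted to a set of target regions. Calls are held in a
#' data frame with one row per biallelic INDEL in the 1-based anchored VCF
#' representation (the first base of `ref` and `alt` is the shared anchor
#' base once calls are left-normalized).
#'
#' Records whose reference and alternate alleles have equal length (SNPs,
#' MNPs) are rejected: only true insertions and deletions are modelled.
#' Duplicate `(chrom, pos, ref, alt)` tuples are collapsed keeping the
#' maximum alternate-allele coverage.
#'
#' @param calls data frame with at least `chrom`, `pos`, `ref`, `alt`.
#'   Optional columns: `cov_ref`, `cov_alt` (non-negative integer allele
#'   k-mer coverages, default 0), `zygosity` (`"heterozygous"`,
#'   `"homozygous"` or `"unknown"`), `chi2`, `quality_class`, `context`,
#'   `normalized`, `truth` (logical truth label from the simulator).
#' @param label free-text label for the set (e.g. `"WGS"`, `"WES"`).
#' @param sample_id free-text sample identifier.
#' @param target_regions optional [GenomicRanges::GRanges] the calls are
#'   restricted to; calls outside are dropped with a message.
#' @return An object of class `indel_callset`: a list with elements
#'   `calls` (data frame), `label`, `sample_id`, `target_regions`.
#' @examples
#' cs <- indel_callset(data.frame(chrom = "chr1", pos = 10L,
#'                                ref = "AT", alt = "A",
#'                                cov_ref = 12L, cov_alt = 9L))
#' n_calls(cs)
#' @export
indel_callset <- function(calls, label = "", sample_id = "",
                          target_regions = NULL) {
  stopifnot(is.data.frame(calls))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols)) {
    stop("calls is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos)
  calls$ref <- toupper(as.character(calls$ref))
  calls$alt <- toupper(as.character(calls$alt))

  if (nrow(calls)) {
    if (any(is.na(calls$pos)) || any(calls$pos < 1L)) {
      stop("call positions must be positive 1-based integers")
    }
    bad_allele <- !grepl("^[ACGT]+$", calls$ref) | !grepl("^[ACGT]+$", calls$alt)
    if (any(bad_allele)) {
      stop("alleles must be non-empty A/C/G/T strings (record ",
           which(bad_allele)[1L], ")")
    }
    len_equal <- nchar(calls$ref) == nchar(calls$alt)
    if (any(len_equal)) {
      stop("non-INDEL record(s) (equal allele lengths) at row(s): ",
           paste(utils::head(which(len_equal), 5L), collapse = ", "))
    }
  }

  calls$size <- abs(nchar(calls$ref) - nchar(calls$alt))
  calls$itype <- ifelse(nchar(calls$alt) > nchar(calls$ref),
                        "insertion", "deletion")
  n <- nrow(calls)
  if (is.null(calls$cov_ref)) calls$cov_ref <- rep(0L, n)
  if (is.null(calls$cov_alt)) calls$cov_alt <- rep(0L, n)
  calls$cov_ref <- as.integer(calls$cov_ref)
  calls$cov_alt <- as.integer(calls$cov_alt)
  if (n && (any(is.na(calls$cov_ref)) || any(is.na(calls$cov_alt)) ||
            any(calls$cov_ref < 0L) || any(calls$cov_alt < 0L))) {
    stop("cov_ref / cov_alt must be non-negative integers")
  }
  if (is.null(calls$zygosity)) calls$zygosity <- rep("unknown", n)
  ok_zyg <- calls$zygosity %in% c("heterozygous", "homozygous", "unknown")
  if (!all(ok_zyg)) stop("zygosity must be heterozygous/homozygous/unknown")
  if (is.null(calls$chi2)) calls$chi2 <- rep(NA_real_, n)
  if (is.null(calls$quality_class)) calls$quality_class <- rep("unset", n)
  if (is.null(calls$context)) calls$context <- rep("unset", n)
  if (is.null(calls$normalized)) calls$normalized <- rep(FALSE, n)

  # collapse duplicate (chrom,pos,ref,alt) keeping max cov_alt
  key <- call_key(calls)
  if (anyDuplicated(key)) {
    ord <- order(key, -calls$cov_alt)
    calls <- calls[ord, , drop = FALSE]
    calls <- calls[!duplicated(call_key(calls)), , drop = FALSE]
  }
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt),
                 , drop = FALSE]
  rownames(calls) <- NULL

  cs <- structure(list(calls = calls, label = label, sample_id = sample_id,
                       target_regions = NULL),
                  class = "indel_callset")
  if (!is.null(target_regions)) {
    cs <- restrict_to_regions(cs, target_regions)
  }
  cs
}

# stable (chrom,pos,ref,alt) identity used for dedup and set algebra
call_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
}

# (chrom,pos) locus identity
locus_key <- function(calls) {
  paste(calls$chrom, calls$pos, sep = "\r")
}

#' Number of calls in a call set
#' @param cs an `indel_callset`.
#' @return Integer count of calls.
#' @export
n_calls <- function(cs) {
  stopifnot(inherits(cs, "indel_callset"))
  nrow(cs$calls)
}

#' @export
print.indel_callset <- function(x, ...) {
  cat("indel_callset", if (nzchar(x$label)) sQuote(x$label) else "",
      if (nzchar(x$sample_id)) paste0("[", x$sample_id, "]") else "",
      "with", nrow(x$calls), "call(s)\n")
  if (!is.null(x$target_regions)) {
    cat("  restricted to", length(x$target_regions), "target interval(s)\n")
  }
  cat("  insertions:", sum(x$calls$itype == "insertion"),
      " deletions:", sum(x$calls$itype == "deletion"),
      " large (>5 bp):", sum(x$calls$size > 5L), "\n")
  invisible(x)
}

#' INDEL size and the large-INDEL predicate
#'
#' The size of an INDEL is the absolute difference in allele lengths,
#' `|len(ref) - len(alt)|`. A "large" INDEL is one of size strictly greater
#' than 5 bp; large INDELs are markedly harder to detect, particularly for
#' alignment-based callers and capture-based (exome) libraries.
#'
#' @param ref,alt allele strings (vectorized).
#' @return `indel_size()`: integer vector of sizes; `is_large()`: logical.
#' @examples
#' indel_size("A", "ATTTTTT")   # 6
#' is_large("ACT", "A")         # FALSE (size 2)
#' is_large("ACTGCAT", "A")     # TRUE  (size 6)
#' @export
indel_size <- function(ref, alt) {
  abs(nchar(ref) - nchar(alt))
}

#' @rdname indel_size
#' @export
is_large <- function(ref, alt) {
  indel_size(ref, alt) > 5L
}

#' Restrict a call set to target regions
#'
#' Keeps calls whose (normalized) anchor position falls inside the given
#' regions; membership uses the anchored position only, not the full span of
#' a deletion. The number of removed calls is reported with a message.
#'
#' @param cs an `indel_callset`.
#' @param regions a [GenomicRanges::GRanges] of target intervals (they are
#'   merged with `reduce()` before use).
#' @return The restricted `indel_callset` with `target_regions` attached.
#' @export
restrict_to_regions <- function(cs, regions) {
  stopifnot(inherits(cs, "indel_callset"),
            methods::is(regions, "GRanges"))
  regions <- GenomicRanges::reduce(regions)
  if (nrow(cs$calls)) {
    pos_gr <- GenomicRanges::GRanges(
      cs$calls$chrom, IRanges::IRanges(cs$calls$pos, cs$calls$pos))
    inside <- IRanges::overlapsAny(pos_gr, regions)
    n_removed <- sum(!inside)
    if (n_removed > 0L) {
      message("restrict_to_regions: removed ", n_removed,
              " call(s) outside target regions")
    }
    cs$calls <- cs$calls[inside, , drop = FALSE]
    rownames(cs$calls) <- NULL
  }
  cs$target_regions <- regions
  cs
}

#' Filter a call set by an arbitrary predicate on its calls
#'
#' Convenience wrapper keeping the call-set metadata intact.
#'
#' @param cs an `indel_callset`.
#' @param keep logical vector of length `n_calls(cs)`.
#' @return The filtered `indel_callset`.
#' @export
filter_calls <- function(cs, keep) {
  stopifnot(inherits(cs, "indel_callset"), is.logical(keep),
            length(keep) == nrow(cs$calls))
  cs$calls <- cs$calls[keep & !is.na(keep), , drop = FALSE]
  rownames(cs$calls) <- NULL
  cs
}
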
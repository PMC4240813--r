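#' Left-normalize INDEL representations against a reference
#'
#' Different aligners and callers may report the same INDEL at different
#' positions inside a repeat, or with redundant flanking bases. Left
#' normalization produces the unique canonical representation: shared
#' trailing bases are trimmed (extending the alleles leftwards from the
#' reference when one would become empty), then shared leading bases are
#' trimmed down to a single anchor base. Applying the normalized edit to
#' the reference yields exactly the same alternate haplotype as the raw
#' edit, and the operation is idempotent.
#'
#' When a variant abuts position 1 of its contig and an allele would become
#' empty, the base *following* the reference allele is appended to both
#' alleles instead (the VCF convention for telomeric variants); such records
#' carry no left anchor base.
#'
#' @param cs an `indel_callset` (or a data frame of calls).
#' @param reference reference sequences: a [Biostrings::DNAStringSet] or a
#'   named character vector keyed by chromosome.
#' @return The call set with every call in canonical left-aligned form,
#'   `normalized = TRUE`, re-deduplicated (equivalent raw representations
#'   collapse onto one record, keeping the maximum `cov_alt`).
#' @examples
#' ref <- c(chr1 = "GGCACACATAG")
#' cs <- indel_callset(data.frame(chrom = "chr1", pos = 7L,
#'                                ref = "ACA", alt = "A"))
#' normalize_calls(cs, ref)$calls[, c("pos", "ref", "alt")]
#' @export
normalize_calls <- function(cs, reference) {
  as_df <- is.data.frame(cs)
  calls <- if (as_df) cs else cs$calls
  if (nrow(calls)) {
    norm <- vapply(seq_len(nrow(calls)), function(i) {
      v <- left_align_one(calls$chrom[i], calls$pos[i],
                          calls$ref[i], calls$alt[i], reference)
      c(as.character(v$pos), v$ref, v$alt)
    }, character(3L))
    calls$pos <- as.integer(norm[1L, ])
    calls$ref <- norm[2L, ]
    calls$alt <- norm[3L, ]
    calls$size <- abs(nchar(calls$ref) - nchar(calls$alt))
    calls$itype <- ifelse(nchar(calls$alt) > nchar(calls$ref),
                          "insertion", "deletion")
  }
  calls$normalized <- TRUE
  if (as_df) return(calls)
  out <- indel_callset(calls, label = cs$label, sample_id = cs$sample_id)
  out$target_regions <- cs$target_regions
  out
}

#' Left-normalize a single INDEL
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the anchor base.
#' @param ref,alt allele strings.
#' @param reference as in [normalize_calls()].
#' @return A list with elements `chrom`, `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(chrom, pos, ref, alt, reference) {
  left_align_one(chrom, pos, ref, alt, reference)
}

left_align_one <- function(chrom, pos, ref, alt, reference) {
  seq <- ref_chrom_seq(reference, chrom)
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  if (pos < 1L || pos + nchar(ref) - 1L > nchar(seq)) {
    stop("variant at ", chrom, ":", pos, " outside reference bounds")
  }
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop("ref allele mismatch with reference at ", chrom, ":", pos,
         " (expected ", substr(seq, pos, pos + nchar(ref) - 1L),
         ", got ", ref, ")")
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos == 1L) {
        # contig start: pad on the right instead of the left
        pad_at <- pos + nchar(ref)
        if (pad_at > nchar(seq)) {
          stop("variant spans the whole contig; cannot normalize")
        }
        b <- substr(seq, pad_at, pad_at)
        ref <- paste0(ref, b)
        alt <- paste0(alt, b)
        break
      }
      pos <- pos - 1L
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      break
    }
  }
  # trim shared leading bases down to one anchor
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Apply an INDEL edit to a sequence
#'
#' Replaces the reference allele at `pos` with the alternate allele and
#' returns the resulting haplotype string. Used to verify that two
#' representations of a variant are equivalent.
#'
#' @param seq reference sequence (character).
#' @param pos 1-based position of the edit.
#' @param ref,alt allele strings.
#' @return The edited sequence.
#' @export
apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}
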
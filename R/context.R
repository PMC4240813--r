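#' Find homopolymer tracts in a sequence
#'
#' Maximal single-base runs of length at least `min_len` (default 5, the
#' conventional minimum at which homopolymer slippage becomes a dominant
#' INDEL error mode). Runs of `N` are ignored.
#'
#' @param seq uppercase A/C/G/T/N sequence (character scalar).
#' @param min_len minimum run length (default 5).
#' @param chrom chromosome label attached to the output (default `"seq"`).
#' @return A repeat-tract data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `motif` (the base), `copies`, `kind = "homopolymer"`.
#' @examples
#' find_homopolymers("GGAAAAAC")  # one poly-A tract of length 5
#' @export
find_homopolymers <- function(seq, min_len = 5L, chrom = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 1L)
  seq <- toupper(seq)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  empty_tracts(chrom,
               start = starts[keep] - 1L, end = ends[keep],
               motif = r$values[keep],
               copies = as.numeric(r$lengths[keep]),
               kind = "homopolymer")
}

#' Find short tandem repeat tracts in a sequence
#'
#' Maximal perfect tandem tracts with a primitive motif of length
#' `motif_len` (2-6 bp by default), at least `min_copies` copies (the last
#' copy may be partial) and total span at least `min_span` bp. A motif is
#' primitive when it is not itself a repetition of a shorter motif, so a
#' poly-A run is never reported as an "AA" repeat, and a CA-repeat is not
#' re-reported with motif "CACA"; homopolymer runs therefore never appear
#' in the STR output and take precedence at the labelling stage.
#'
#' Detection is a vectorized period-k self-comparison: positions where
#' `seq[i] == seq[i + k]` form runs, and a maximal run of length m marks a
#' tandem tract of span m + k with copy number (m + k)/k.
#'
#' @param seq uppercase A/C/G/T/N sequence (character scalar).
#' @param motif_len integer vector of motif lengths to scan (default 2:6).
#' @param min_copies minimum copy number (default 3).
#' @param min_span minimum tract span in bp (default 8).
#' @param chrom chromosome label for the output.
#' @return A repeat-tract data frame (`kind = "other-STR"`), sorted by
#'   start; columns as in [find_homopolymers()].
#' @examples
#' find_strs("TTCACACACATT")  # one CA tract, 4 copies
#' @export
find_strs <- function(seq, motif_len = 2:6, min_copies = 3,
                      min_span = 8L, chrom = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L,
            all(motif_len >= 2L), all(motif_len <= 6L))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  out <- list()
  for (k in sort(unique(as.integer(motif_len)))) {
    if (n < 2L * k) next
    eq <- chars[seq_len(n - k)] == chars[(k + 1L):n] &
      valid[seq_len(n - k)] & valid[(k + 1L):n]
    r <- rle(eq)
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    hit <- which(r$values)
    for (j in hit) {
      m <- r$lengths[j]
      span <- m + k
      copies <- span / k
      if (span < min_span || copies < min_copies) next
      s <- run_starts[j]                      # 1-based tract start
      motif <- substr(seq, s, s + k - 1L)
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <-
        data.frame(chrom = chrom, start = s - 1L, end = s + span - 1L,
                   motif = motif, copies = copies, kind = "other-STR",
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_tracts(chrom))
  tracts <- do.call(rbind, out)
  # homopolymer precedence holds by construction: a primitive motif of
  # length >= 2 contains two distinct bases, so a pure single-base run can
  # only ever be reported by find_homopolymers(); labelling order in
  # annotate_context() handles partial overlaps.
  tracts <- tracts[order(tracts$start, tracts$end, tracts$motif),
                   , drop = FALSE]
  rownames(tracts) <- NULL
  tracts
}

empty_tracts <- function(chrom = character(0), start = integer(0),
                         end = integer(0), motif = character(0),
                         copies = numeric(0), kind = character(0)) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), motif = motif, copies = copies,
             kind = rep_len(kind, n), stringsAsFactors = FALSE)
}

# a motif is primitive iff it is not a whole number of copies of a
# shorter prefix
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k <= 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, k %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Annotate calls with their sequence-context class
#'
#' Partitions INDELs by the repeat composition of their locus into six
#' classes: `poly-A`, `poly-C`, `poly-G`, `poly-T` (the variant interval
#' intersects or lies within 1 bp of a homopolymer tract of that
#' reference-strand base, length >= `min_hp_len`), `other-STR`
#' (intersects/abuts a short tandem repeat tract), or `non-STR`. The
#' variant interval is the deleted bases for a deletion and the two bases
#' flanking the insertion point for an insertion; the 1 bp adjacency
#' allowance covers inserted runs that extend a tract from its boundary.
#' When several homopolymer tracts qualify, the nearest (then longest)
#' wins. Tracts are detected on a +/- `window` bp window around each call
#' (truncated at contig edges).
#'
#' Calls must be normalized first: context is then invariant under the
#' original raw representation of the variant.
#'
#' @param cs an `indel_callset` (or data frame of calls).
#' @param reference reference sequences ([Biostrings::DNAStringSet] or
#'   named character).
#' @param min_hp_len minimum homopolymer length (default 5).
#' @param str_params list of [find_strs()] parameters.
#' @param window half-width of the sequence window examined per call.
#' @return The call set with the `context` column filled in.
#' @export
annotate_context <- function(cs, reference, min_hp_len = 5L,
                             str_params = list(motif_len = 2:6,
                                               min_copies = 3,
                                               min_span = 8L),
                             window = 50L) {
  as_df <- is.data.frame(cs)
  calls <- if (as_df) cs else cs$calls
  if (nrow(calls)) {
    if (!all(calls$normalized)) {
      stop("normalize calls before annotating context")
    }
    calls$context <- vapply(seq_len(nrow(calls)), function(i) {
      context_one(calls$chrom[i], calls$pos[i], calls$ref[i],
                  calls$alt[i], reference, min_hp_len, str_params, window)
    }, character(1L))
  }
  if (as_df) return(calls)
  cs$calls <- calls
  cs
}

context_one <- function(chrom, pos, ref, alt, reference, min_hp_len,
                        str_params, window) {
  seq <- ref_chrom_seq(reference, chrom)
  n <- nchar(seq)
  # variant interval, 1-based closed on the reference
  if (nchar(ref) > nchar(alt)) {          # deletion: the deleted bases
    v_start <- pos + 1L
    v_end <- pos + (nchar(ref) - nchar(alt))
  } else {                                 # insertion: flanking base pair
    v_start <- pos
    v_end <- min(pos + 1L, n)
  }
  w_start <- max(1L, pos - window)
  w_end <- min(n, v_end + window)
  win <- substr(seq, w_start, w_end)

  hp <- find_homopolymers(win, min_len = min_hp_len, chrom = chrom)
  lab <- pick_tract_label(hp, w_start, v_start, v_end,
                          label = function(t) paste0("poly-", t$motif))
  if (!is.na(lab)) return(lab)
  str <- do.call(find_strs, c(list(seq = win, chrom = chrom), str_params))
  lab <- pick_tract_label(str, w_start, v_start, v_end,
                          label = function(t) "other-STR")
  if (!is.na(lab)) return(lab)
  "non-STR"
}

# choose the qualifying tract (gap <= 1 bp from the variant interval)
# nearest to the variant, breaking ties by tract length
pick_tract_label <- function(tracts, w_start, v_start, v_end, label) {
  if (!nrow(tracts)) return(NA_character_)
  t_start <- tracts$start + w_start          # 1-based closed coords
  t_end <- tracts$end + w_start - 1L
  gap <- pmax(t_start - v_end, v_start - t_end, 0L)
  ok <- gap <= 1L
  if (!any(ok)) return(NA_character_)
  cand <- which(ok)
  cand <- cand[order(gap[cand], -(t_end[cand] - t_start[cand]))]
  label(tracts[cand[1L], , drop = FALSE])
}

#' Sequence-context composition of a call set
#'
#' Proportions of the six context labels, optionally within one quality
#' stratum, plus the aggregated poly-A/T share (homopolymer A and T
#' INDELs behave alike and are reported together as the dominant
#' error-prone class).
#'
#' @param cs an `indel_callset` with contexts annotated.
#' @param stratum `"all"` or one of `"high"`, `"moderate"`, `"low"` to
#'   restrict to a quality class.
#' @return A data frame with one row per context label (`poly-A`,
#'   `poly-C`, `poly-G`, `poly-T`, `other-STR`, `non-STR`): columns
#'   `context`, `n`, `proportion`; the poly-A/T aggregate is attached as
#'   attribute `poly_at` (list with `n` and `proportion`).
#' @export
context_composition <- function(cs, stratum = "all") {
  stopifnot(inherits(cs, "indel_callset"))
  calls <- cs$calls
  if (!identical(stratum, "all")) {
    stopifnot(stratum %in% c("high", "moderate", "low"))
    calls <- calls[calls$quality_class == stratum, , drop = FALSE]
  }
  if (any(calls$context == "unset")) {
    stop("call set contains calls without context; ",
         "run annotate_context() first")
  }
  labels <- c("poly-A", "poly-C", "poly-G", "poly-T", "other-STR",
              "non-STR")
  n <- vapply(labels, function(l) sum(calls$context == l), integer(1L))
  total <- sum(n)
  out <- data.frame(context = labels, n = unname(n),
                    proportion = if (total) unname(n) / total
                                 else rep(0, length(labels)),
                    stringsAsFactors = FALSE)
  at <- sum(n[c("poly-A", "poly-T")])
  attr(out, "poly_at") <- list(n = at,
                               proportion = if (total) at / total else 0)
  out
}
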
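#' Platform profile for the call-set simulator
#'
#' Bundles the knobs that distinguish sequencing platforms and library
#' preparations in the simulator: target mean depth and coverage
#' dispersion, capture dropout, context-dependent false-call rates, and
#' the extra loss of large INDELs seen with hybridization capture.
#'
#' @param label free-text platform label.
#' @param mean_depth target mean depth (> 0).
#' @param cv_target target coefficient of variation of depth, as a
#'   percentage.
#' @param dropout_frac fraction of target windows with zero recovery.
#' @param fdr_by_context named vector of false-call rates per context
#'   label (fraction of emitted calls in that context that are false);
#'   names from `poly-A`, `poly-C`, `poly-G`, `poly-T`, `other-STR`,
#'   `non-STR`.
#' @param large_indel_capture_penalty probability that a size > 5 bp
#'   truth INDEL is lost to capture inefficiency.
#' @return A list of class `platform_profile`.
#' @export
platform_profile <- function(label, mean_depth, cv_target,
                             dropout_frac = 0,
                             fdr_by_context = c("poly-A" = 0.1,
                                                "poly-C" = 0.05,
                                                "poly-G" = 0.05,
                                                "poly-T" = 0.1,
                                                "other-STR" = 0.05,
                                                "non-STR" = 0.03),
                             large_indel_capture_penalty = 0) {
  stopifnot(mean_depth > 0, cv_target >= 0,
            dropout_frac >= 0, dropout_frac <= 1,
            all(fdr_by_context >= 0), all(fdr_by_context < 1),
            large_indel_capture_penalty >= 0,
            large_indel_capture_penalty <= 1)
  structure(list(label = label, mean_depth = mean_depth,
                 cv_target = cv_target, dropout_frac = dropout_frac,
                 fdr_by_context = fdr_by_context,
                 large_indel_capture_penalty =
                   large_indel_capture_penalty),
            class = "platform_profile")
}

#' Built-in platform profiles
#'
#' `wgs_profile()` emulates PCR-amplified whole-genome sequencing of
#' exonic regions: mean depth 71X, depth CV 39.4%, essentially no
#' dropout, no large-INDEL penalty, mildly elevated false-call rates in
#' homopolymer A/T runs. `wes_profile()` emulates hybridization-capture
#' exome sequencing: mean depth 337X but CV 109.3%, 16% of target windows
#' unrecovered, a strong loss of INDELs larger than 5 bp, and strongly
#' inflated poly-A/T false-call rates.
#'
#' @return A [platform_profile()].
#' @export
wgs_profile <- function() {
  platform_profile(
    label = "WGS-like", mean_depth = 71, cv_target = 39.4,
    dropout_frac = 0.001,
    fdr_by_context = c("poly-A" = 0.15, "poly-C" = 0.05,
                       "poly-G" = 0.05, "poly-T" = 0.15,
                       "other-STR" = 0.06, "non-STR" = 0.03),
    large_indel_capture_penalty = 0)
}

#' @rdname wgs_profile
#' @export
wes_profile <- function() {
  platform_profile(
    label = "WES-like", mean_depth = 337, cv_target = 109.3,
    dropout_frac = 0.16,
    fdr_by_context = c("poly-A" = 0.40, "poly-C" = 0.10,
                       "poly-G" = 0.10, "poly-T" = 0.40,
                       "other-STR" = 0.12, "non-STR" = 0.05),
    large_indel_capture_penalty = 0.8)
}

#' Default repeat-tract specification
#'
#' One row per planted tract family: `motif` (1-6 bp), `n` tracts per
#' 100 kb and `len` span in bp. The default plants abundant A/T
#' homopolymers, fewer C/G homopolymers, and a mix of
#' dinucleotide/trinucleotide repeats, roughly mirroring the repeat
#' landscape of exonic sequence. [generate_reference()] scales the
#' counts with the requested sequence length.
#'
#' @return Data frame with columns `motif`, `n`, `len`.
#' @export
default_tract_spec <- function() {
  data.frame(
    motif = c("A", "T", "A", "T", "C", "G", "CA", "TG", "AT",
              "AAT", "AGC"),
    n = c(48L, 48L, 26L, 26L, 16L, 16L, 18L, 12L, 10L, 10L, 8L),
    len = c(8L, 8L, 6L, 6L, 6L, 6L, 12L, 12L, 10L, 12L, 12L),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic reference with planted repeat tracts
#'
#' Builds a uniform-composition background sequence that is *free* of
#' incidental repeat tracts (any background homopolymer of length >=
#' `min_hp_len` or STR passing the detector thresholds is broken by a
#' point substitution), then plants the requested tracts at recorded,
#' non-overlapping coordinates with flanking bases chosen so each tract
#' is exactly maximal. The planted coordinates therefore coincide exactly
#' with the detector output on the finished sequence.
#'
#' @param length sequence length in bp.
#' @param tract_spec data frame (`motif`, `n`, `len`) as in
#'   [default_tract_spec()], with `n` counted per 100 kb and scaled to
#'   `length`; use a zero-row frame for no tracts.
#' @param seed integer seed.
#' @param chrom chromosome name for the synthetic contig.
#' @param min_hp_len homopolymer threshold used for the background
#'   cleanup (default 5).
#' @return A list of class `sim_reference`: `seq` (named character),
#'   `tracts` (repeat-tract data frame, 0-based half-open), `length`,
#'   `chrom`, `seed`.
#' @export
generate_reference <- function(length = 100000L,
                               tract_spec = default_tract_spec(),
                               seed = 1L, chrom = "chr_sim",
                               min_hp_len = 5L) {
  stopifnot(length >= 1000L)
  set.seed(seed)
  if (nrow(tract_spec)) {
    tract_spec$n <- pmax(1L, as.integer(round(tract_spec$n *
                                                length / 1e5)))
  }
  if (sum(tract_spec$n * (tract_spec$len + 12L)) > length / 2) {
    stop("requested tracts overflow the sequence length")
  }
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, length, replace = TRUE)

  scrub <- function(chars, protect = integer(0)) {
    # break incidental tracts outside protected positions
    for (iter in 1:50) {
      s <- paste(chars, collapse = "")
      found <- rbind(find_homopolymers(s, min_len = min_hp_len),
                     find_strs(s))
      if (nrow(found) == 0L) return(chars)
      fixed_any <- FALSE
      for (i in seq_len(nrow(found))) {
        span <- (found$start[i] + 1L):found$end[i]   # 1-based
        free <- setdiff(span, protect)
        if (!base::length(free)) next
        p <- free[ceiling(base::length(free) / 2)]
        chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        fixed_any <- TRUE
      }
      if (!fixed_any) break
    }
    chars
  }
  chars <- scrub(chars)

  tracts <- empty_tracts()
  occupied <- logical(length)
  if (nrow(tract_spec)) {
    for (row in seq_len(nrow(tract_spec))) {
      motif <- toupper(tract_spec$motif[row])
      k <- nchar(motif)
      span <- as.integer(tract_spec$len[row])
      stopifnot(span >= k)
      tract_chars <- strsplit(strrep(motif, ceiling(span / k)),
                              "")[[1L]][seq_len(span)]
      for (j in seq_len(tract_spec$n[row])) {
        placed <- FALSE
        for (try in 1:200) {
          s0 <- sample.int(length - span - 20L, 1L) + 10L  # 1-based start
          zone <- (s0 - 8L):(s0 + span + 7L)
          if (any(occupied[zone])) next
          chars[s0:(s0 + span - 1L)] <- tract_chars
          # flanks must not extend the tract's period (nor match the
          # run base for homopolymers)
          left_bad <- unique(c(tract_chars[k], tract_chars[1L]))
          right_bad <- unique(c(tract_chars[span - k + 1L],
                                tract_chars[span]))
          chars[s0 - 1L] <- sample(setdiff(bases, left_bad), 1L)
          chars[s0 + span] <- sample(setdiff(bases, right_bad), 1L)
          occupied[zone] <- TRUE
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place tract ", motif, " x", span,
                          "; sequence too crowded")
        tracts <- rbind(tracts, empty_tracts(
          chrom = chrom, start = s0 - 1L, end = s0 + span - 1L,
          motif = motif, copies = span / k,
          kind = if (k == 1L) "homopolymer" else "other-STR"))
      }
    }
    # planting may have created new junctions; scrub outside tract zones
    protect <- unlist(lapply(seq_len(nrow(tracts)), function(i) {
      (tracts$start[i]):(tracts$end[i] + 1L)    # tract + 1bp flanks
    }), use.names = FALSE)
    chars <- scrub_keep_planted(chars, tracts, protect, min_hp_len, bases)
  }
  tracts <- tracts[order(tracts$start), , drop = FALSE]
  rownames(tracts) <- NULL
  seq <- paste(chars, collapse = "")
  structure(list(seq = stats::setNames(seq, chrom), tracts = tracts,
                 length = length, chrom = chrom, seed = seed),
            class = "sim_reference")
}

# break tracts that the detector reports but that were not planted,
# mutating only unprotected positions
scrub_keep_planted <- function(chars, tracts, protect, min_hp_len,
                               bases) {
  planted_key <- paste(tracts$start, tracts$end, tracts$motif)
  for (iter in 1:50) {
    s <- paste(chars, collapse = "")
    found <- rbind(find_homopolymers(s, min_len = min_hp_len),
                   find_strs(s))
    extra <- found[!(paste(found$start, found$end, found$motif) %in%
                       planted_key), , drop = FALSE]
    if (nrow(extra) == 0L) return(chars)
    fixed_any <- FALSE
    for (i in seq_len(nrow(extra))) {
      span <- (extra$start[i] + 1L):extra$end[i]
      free <- setdiff(span, protect)
      if (!length(free)) next
      p <- free[ceiling(length(free) / 2)]
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      fixed_any <- TRUE
    }
    if (!fixed_any) break
  }
  chars
}

#' Default size distribution of truth INDELs
#'
#' Returns a sampler over 1-100 bp: 90% of draws are small
#' (1 + geometric, capped at 5 bp) and 10% are uniform over 6-100 bp, so
#' the truth set spans the full size range while remaining dominated by
#' 1-2 bp events, as real germline call sets are.
#'
#' @return A function `f(n)` returning `n` integer sizes.
#' @export
default_size_dist <- function() {
  function(n) {
    small <- pmin(1L + stats::rgeom(n, 0.55), 5L)
    large <- sample(6:100, n, replace = TRUE)
    ifelse(stats::runif(n) < 0.9, small, large)
  }
}

#' Generate a truth INDEL set on a synthetic reference
#'
#' Places `n` INDELs with recorded zygosity and sequence context. Calls
#' in a `poly-N` context insert or delete copies of the run base at a
#' planted homopolymer tract of base N; `other-STR` calls insert or
#' delete whole motif units at a planted STR tract; `non-STR` calls are
#' placed away from every planted tract (8 bp exclusion zone). All calls
#' are emitted left-normalized at unique positions; the planted label is
#' kept in both `context` and `context_planted`.
#'
#' @param reference a `sim_reference` from [generate_reference()].
#' @param n number of truth INDELs.
#' @param size_dist a sampler `f(n)` over 1-100 bp, e.g.
#'   [default_size_dist()]. Deletion sizes are capped by the available
#'   repeat tract (repeat contexts) or by the reference (non-STR).
#' @param het_frac fraction of heterozygous calls (default 0.61, i.e.
#'   roughly 1.6-fold more heterozygous than homozygous calls).
#' @param context_mix named probabilities over the six context labels.
#' @param seed integer seed.
#' @return An `indel_callset` (label `"truth"`) with `zygosity`,
#'   `context`, `context_planted` columns, normalized.
#' @export
generate_truth_indels <- function(reference, n,
                                  size_dist = default_size_dist(),
                                  het_frac = 0.61,
                                  context_mix = c("poly-A" = 0.15,
                                                  "poly-C" = 0.02,
                                                  "poly-G" = 0.02,
                                                  "poly-T" = 0.15,
                                                  "other-STR" = 0.11,
                                                  "non-STR" = 0.55),
                                  seed = 1L) {
  stopifnot(inherits(reference, "sim_reference"), n >= 1L,
            het_frac >= 0, het_frac <= 1,
            abs(sum(context_mix) - 1) < 1e-8)
  set.seed(seed)
  seq <- unname(reference$seq)
  slen <- nchar(seq)
  chrom <- reference$chrom
  tracts <- reference$tracts
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]

  # exclusion map: planted tracts +/- 8 bp (non-STR placements must avoid)
  near_tract <- logical(slen)
  if (nrow(tracts)) {
    for (i in seq_len(nrow(tracts))) {
      z <- max(1L, tracts$start[i] - 7L):min(slen, tracts$end[i] + 8L)
      near_tract[z] <- TRUE
    }
  }
  used_pos <- logical(slen)     # block re-use of anchor positions
  tract_used <- rep(FALSE, nrow(tracts))

  contexts <- sample(names(context_mix), n, replace = TRUE,
                     prob = context_mix)
  sizes <- size_dist(n)
  stopifnot(all(sizes >= 1L), all(sizes <= 100L))
  is_ins <- stats::runif(n) < 0.5
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- contexts[i]
    made <- NULL
    if (ctx %in% c("poly-A", "poly-C", "poly-G", "poly-T")) {
      base_n <- sub("poly-", "", ctx)
      cand <- which(tracts$kind == "homopolymer" &
                      tracts$motif == base_n & !tract_used)
      if (!length(cand)) {
        stop("not enough planted ", ctx,
             " tracts for the requested truth set")
      }
      t_i <- cand[sample.int(length(cand), 1L)]
      tract_used[t_i] <- TRUE
      anchor <- tracts$start[t_i]          # 1-based base before tract
      run_len <- tracts$end[t_i] - tracts$start[t_i]
      if (anchor < 1L || used_pos[anchor]) next
      s <- if (is_ins[i]) sizes[i] else min(sizes[i], run_len)
      if (is_ins[i]) {
        made <- list(pos = anchor, ref = chars[anchor],
                     alt = paste0(chars[anchor], strrep(base_n, s)))
      } else {
        made <- list(pos = anchor,
                     ref = paste0(chars[anchor], strrep(base_n, s)),
                     alt = chars[anchor])
      }
      used_pos[anchor] <- TRUE
    } else if (ctx == "other-STR") {
      cand <- which(tracts$kind == "other-STR" & !tract_used)
      if (!length(cand)) {
        stop("not enough planted STR tracts for the requested truth set")
      }
      t_i <- cand[sample.int(length(cand), 1L)]
      tract_used[t_i] <- TRUE
      k <- nchar(tracts$motif[t_i])
      span <- tracts$end[t_i] - tracts$start[t_i]
      anchor <- tracts$start[t_i]
      if (anchor < 1L || used_pos[anchor]) next
      # requested size, capped by the tract span for deletions; partial
      # motif copies are allowed so small sizes stay exact
      s <- if (is_ins[i]) sizes[i] else min(sizes[i], span)
      frag <- substr(strrep(tracts$motif[t_i], ceiling(s / k) + 1L),
                     1L, s)
      if (is_ins[i]) {
        made <- list(pos = anchor, ref = chars[anchor],
                     alt = paste0(chars[anchor], frag))
      } else {
        made <- list(pos = anchor,
                     ref = substr(seq, anchor, anchor + s),
                     alt = chars[anchor])
      }
      used_pos[anchor] <- TRUE
    } else {  # non-STR
      for (try in 1:200) {
        p <- sample.int(slen - 110L, 1L) + 4L
        s <- sizes[i]
        span <- p:min(slen, p + s + 1L)
        if (any(near_tract[span]) || any(used_pos[p])) next
        if (is_ins[i]) {
          ins <- paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                       collapse = "")
          made <- list(pos = p, ref = chars[p],
                       alt = paste0(chars[p], ins))
        } else {
          made <- list(pos = p,
                       ref = substr(seq, p, p + s),
                       alt = chars[p])
        }
        used_pos[p] <- TRUE
        break
      }
      if (is.null(made)) {
        stop("could not place non-STR INDEL ", i,
             "; reference too crowded")
      }
    }
    if (!is.null(made)) {
      rows[[i]] <- data.frame(
        chrom = chrom, pos = made$pos, ref = made$ref, alt = made$alt,
        zygosity = if (stats::runif(1) < het_frac) "heterozygous"
                   else "homozygous",
        context = ctx, context_planted = ctx, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no truth INDELs could be placed")
  df <- do.call(rbind, rows)
  cs <- indel_callset(df, label = "truth")
  cs <- normalize_calls(cs, reference$seq)
  # positions must be unique after normalization
  cs$calls <- cs$calls[!duplicated(locus_key(cs$calls)), , drop = FALSE]
  rownames(cs$calls) <- NULL
  cs
}

# negative-binomial depth draws with target mean and CV (percent)
draw_depths <- function(n, mean_depth, cv_percent) {
  cv <- cv_percent / 100
  v <- (cv * mean_depth)^2
  if (v > mean_depth) {
    size <- mean_depth^2 / (v - mean_depth)
    stats::rnbinom(n, size = size, mu = mean_depth)
  } else {
    stats::rpois(n, mean_depth)
  }
}

#' Simulate a platform-flavoured call set from a truth set
#'
#' Emulates what a micro-assembly caller would report from one platform:
#' truth calls falling in dropped-out capture windows are lost; large
#' (> 5 bp) truth calls are additionally lost with probability
#' `large_indel_capture_penalty`; surviving calls draw a locus depth from
#' a negative binomial matching the profile's mean and CV, and allele
#' coverages from the zygosity model (heterozygous: `cov_alt ~
#' Binomial(depth, 0.5)`, `cov_ref` the remainder; homozygous:
#' `cov_alt = depth`, `cov_ref = 0`); calls with no alternate-allele
#' support (`cov_alt == 0`) are not emitted. False calls are then
#' injected per context at the profile's `fdr_by_context` rates,
#' preferentially as 1-unit slippage events inside planted poly-A/T (and
#' other) tracts, with strongly unbalanced coverages that inflate the
#' chi-square score. Every emitted call carries a hidden logical `truth`
#' label.
#'
#' @param truth an `indel_callset` from [generate_truth_indels()].
#' @param profile a [platform_profile()].
#' @param reference the `sim_reference` the truth set was built on.
#' @param seed integer seed.
#' @param window_size capture-window size in bp used for dropout
#'   (default 150).
#' @return An `indel_callset` (label = `profile$label`) whose calls carry
#'   `truth` (logical) and `context_planted` columns.
#' @export
generate_callset <- function(truth, profile, reference, seed = 1L,
                             window_size = 150L) {
  stopifnot(inherits(truth, "indel_callset"),
            inherits(profile, "platform_profile"),
            inherits(reference, "sim_reference"))
  set.seed(seed)
  calls <- truth$calls
  slen <- reference$length

  # capture dropout on tiled windows
  n_win <- ceiling(slen / window_size)
  dropped_win <- stats::runif(n_win) < profile$dropout_frac
  win_of <- function(pos) pmin(((pos - 1L) %/% window_size) + 1L, n_win)
  keep <- !dropped_win[win_of(calls$pos)]
  # capture loss of large INDELs
  keep <- keep & !(calls$size > 5L &
                     stats::runif(nrow(calls)) <
                       profile$large_indel_capture_penalty)
  calls <- calls[keep, , drop = FALSE]

  n <- nrow(calls)
  depth <- draw_depths(n, profile$mean_depth, profile$cv_target)
  het <- calls$zygosity == "heterozygous"
  cov_alt <- integer(n)
  cov_alt[het] <- stats::rbinom(sum(het), depth[het], 0.5)
  cov_alt[!het] <- depth[!het]
  cov_ref <- ifelse(het, depth - cov_alt, 0L)
  calls$cov_ref <- as.integer(cov_ref)
  calls$cov_alt <- as.integer(cov_alt)
  calls <- calls[calls$cov_alt >= 1L, , drop = FALSE]
  calls$truth <- TRUE

  # context-dependent false calls
  false_rows <- list()
  tracts <- reference$tracts
  chars <- strsplit(unname(reference$seq), "", fixed = TRUE)[[1L]]
  taken <- unique(calls$pos)
  for (ctx in names(profile$fdr_by_context)) {
    f <- profile$fdr_by_context[[ctx]]
    n_true_ctx <- sum(calls$context_planted == ctx)
    n_false <- round(f / (1 - f) * n_true_ctx)
    if (n_false < 1L) next
    if (ctx %in% c("poly-A", "poly-C", "poly-G", "poly-T")) {
      base_n <- sub("poly-", "", ctx)
      cand <- which(tracts$kind == "homopolymer" & tracts$motif == base_n)
    } else if (ctx == "other-STR") {
      cand <- which(tracts$kind == "other-STR")
    } else {
      cand <- integer(0)
    }
    for (j in seq_len(n_false)) {
      if (length(cand)) {
        t_i <- cand[sample.int(length(cand), 1L)]
        anchor <- tracts$start[t_i]
        unit <- if (tracts$kind[t_i] == "homopolymer")
                  tracts$motif[t_i] else tracts$motif[t_i]
        # 1-unit slippage signature; insertion/deletion at random
        if (stats::runif(1) < 0.5) {
          rec <- list(pos = anchor, ref = chars[anchor],
                      alt = paste0(chars[anchor], unit))
        } else {
          rec <- list(pos = anchor,
                      ref = paste0(chars[anchor], unit),
                      alt = chars[anchor])
        }
      } else {
        for (try in 1:100) {
          p <- sample.int(slen - 20L, 1L) + 4L
          if (!(p %in% taken)) break
        }
        if (stats::runif(1) < 0.5) {
          rec <- list(pos = p, ref = chars[p],
                      alt = paste0(chars[p],
                                   sample(c("A", "C", "G", "T"), 1L)))
        } else {
          rec <- list(pos = p, ref = substr(unname(reference$seq), p,
                                            p + 1L),
                      alt = chars[p])
        }
      }
      d <- draw_depths(1L, profile$mean_depth, profile$cv_target)
      ca <- sample.int(5L, 1L)
      false_rows[[length(false_rows) + 1L]] <- data.frame(
        chrom = reference$chrom, pos = rec$pos, ref = rec$ref,
        alt = rec$alt, zygosity = "unknown",
        cov_ref = as.integer(max(d, ca + 1L)), cov_alt = ca,
        context = ctx, context_planted = ctx, truth = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(false_rows)) {
    fr <- do.call(rbind, false_rows)
    # a false call duplicating a true signature exactly would collapse in
    # deduplication and corrupt the truth labels; keep distinct ones only
    fr <- fr[!(paste(fr$chrom, fr$pos, fr$ref, fr$alt, sep = "\r") %in%
                 call_key(calls)), , drop = FALSE]
    fr <- fr[!duplicated(paste(fr$chrom, fr$pos, fr$ref, fr$alt,
                               sep = "\r")), , drop = FALSE]
    calls <- rbind(calls[, names(fr)], fr)
  } else {
    calls <- calls[, c("chrom", "pos", "ref", "alt", "zygosity",
                       "cov_ref", "cov_alt", "context",
                       "context_planted", "truth")]
  }
  out <- indel_callset(calls, label = profile$label,
                       sample_id = truth$sample_id)
  out <- normalize_calls(out, reference$seq)
  out
}

#' Per-locus depth table of a call set
#'
#' Depth at each call's anchor position, taken as `cov_ref + cov_alt`.
#' Suitable as the `depth_a` / `depth_b` argument of
#' [compare_callsets()].
#'
#' @param cs an `indel_callset`.
#' @return Data frame with `chrom`, `pos`, `depth`.
#' @export
callset_depth_table <- function(cs) {
  stopifnot(inherits(cs, "indel_callset"))
  data.frame(chrom = cs$calls$chrom, pos = cs$calls$pos,
             depth = cs$calls$cov_ref + cs$calls$cov_alt,
             stringsAsFactors = FALSE)
}

#' Simulate a per-base depth table over regions
#'
#' Draws independent negative-binomial per-base depths matching a
#' platform profile's mean and CV over the given regions; used to
#' exercise the coverage-profile statistics.
#'
#' @param regions a [GenomicRanges::GRanges].
#' @param profile a [platform_profile()].
#' @param seed integer seed.
#' @return Data frame with `chrom`, `pos`, `depth`.
#' @export
generate_depth_table <- function(regions, profile, seed = 1L) {
  stopifnot(methods::is(regions, "GRanges"),
            inherits(profile, "platform_profile"))
  set.seed(seed)
  regions <- GenomicRanges::reduce(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  starts <- GenomicRanges::start(regions)
  ends <- GenomicRanges::end(regions)
  pos <- unlist(lapply(seq_along(starts), function(i) {
    seq.int(starts[i], ends[i])
  }), use.names = FALSE)
  chrom <- rep(chroms, ends - starts + 1L)
  data.frame(chrom = chrom, pos = pos,
             depth = draw_depths(length(pos), profile$mean_depth,
                                 profile$cv_target),
             stringsAsFactors = FALSE)
}

#' Generate validation-style calls with planted per-class error rates
#'
#' Draws calls whose coverage/score pairs land in the high and low
#' quality tiers by construction, each with a planted Bernoulli validity:
#' high-tier calls are false with probability `err_high` (default 7%),
#' low-tier calls with probability `err_low` (default 51%). Scoring the
#' result with [annotate_quality()] and computing per-class PPV recovers
#' `100 * (1 - err)` up to binomial noise, which is how the three-tier
#' scheme's error separation is exercised end to end.
#'
#' @param n_high,n_low calls per tier.
#' @param err_high,err_low planted error rates.
#' @param seed integer seed.
#' @return Data frame with `cov_ref`, `cov_alt`, `chi2`,
#'   `quality_class`, `valid`.
#' @export
generate_validation_calls <- function(n_high = 500L, n_low = 500L,
                                      err_high = 0.07, err_low = 0.51,
                                      seed = 1L) {
  set.seed(seed)
  draw_tier <- function(n, tier) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        if (tier == "high") {
          branch <- sample.int(3L, 1L)
          if (branch == 1L) {        # cov_alt > 10, chi2 < 10.8
            ca <- sample(11:60, 1L)
            cr <- stats::rbinom(1L, 2L * ca, 0.5)
          } else if (branch == 2L) { # 5 < cov_alt <= 10, chi2 <= 4.5
            ca <- sample(6:10, 1L)
            cr <- ca + sample(-2:2, 1L)
            cr <- max(cr, 0L)
          } else {                   # cov_alt <= 5, chi2 <= 2
            ca <- sample(1:5, 1L)
            cr <- ca + sample(-1:1, 1L)
            cr <- max(cr, 0L)
          }
        } else {                     # cov_alt <= 10, chi2 > 10.8
          ca <- sample(0:10, 1L)
          cr <- ca + sample(25:80, 1L)
        }
        chi2 <- suppressWarnings(chi_square_score(cr, ca))
        if (classify_quality(ca, chi2) == tier) break
      }
      out[[i]] <- data.frame(cov_ref = cr, cov_alt = ca, chi2 = chi2,
                             quality_class = tier,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  hi <- draw_tier(n_high, "high")
  lo <- draw_tier(n_low, "low")
  hi$valid <- stats::runif(n_high) >= err_high
  lo$valid <- stats::runif(n_low) >= err_low
  rbind(hi, lo)
}
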
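# Independent brute-force oracles used to check the fast implementations.

# Leftmost anchored representation of an INDEL, found by enumerating every
# candidate anchor position and testing haplotype equality directly.
oracle_leftmost <- function(seq, pos, ref, alt) {
  hap <- apply_edit(seq, pos, ref, alt)
  k <- abs(nchar(ref) - nchar(alt))
  is_del <- nchar(ref) > nchar(alt)
  n <- nchar(seq)
  for (p in seq_len(n)) {
    if (is_del) {
      if (p + k > n) break
      cand_ref <- substr(seq, p, p + k)
      cand_alt <- substr(seq, p, p)
    } else {
      if (p > nchar(hap) - k) break
      cand_ref <- substr(seq, p, p)
      cand_alt <- substr(hap, p, p + k)
    }
    if (substr(cand_ref, 1L, 1L) != substr(cand_alt, 1L, 1L)) next
    ok <- tryCatch(apply_edit(seq, p, cand_ref, cand_alt) == hap,
                   error = function(e) FALSE)
    if (ok) {
      return(list(pos = p, ref = cand_ref, alt = cand_alt))
    }
  }
  stop("oracle found no representation")
}

# Exhaustive repeat-tract enumeration on a window: maximal single-base runs
# and maximal period-k tandem runs found by direct character comparison.
oracle_tracts <- function(seq, min_hp_len = 5L, motif_len = 2:6,
                          min_copies = 3, min_span = 8L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  hp <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && chars[j + 1L] == chars[i]) j <- j + 1L
    if (valid[i] && j - i + 1L >= min_hp_len) {
      hp[[length(hp) + 1L]] <- data.frame(
        start = i - 1L, end = j, motif = chars[i],
        copies = as.numeric(j - i + 1L), kind = "homopolymer",
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  str <- list()
  for (k in motif_len) {
    s <- 1L
    while (s + k <= n) {
      # left-maximality at period k
      if (s > 1L && valid[s - 1L] && valid[s - 1L + k] &&
          chars[s - 1L] == chars[s - 1L + k]) {
        s <- s + 1L
        next
      }
      e <- s
      while (e + k <= n && valid[e] && valid[e + k] &&
             chars[e] == chars[e + k]) {
        e <- e + 1L
      }
      if (e > s) {
        span <- (e - s) + k
        copies <- span / k
        motif <- paste(chars[s:(s + k - 1L)], collapse = "")
        if (span >= min_span && copies >= min_copies &&
            all(valid[s:(s + span - 1L)]) &&
            oracle_primitive(motif)) {
          str[[length(str) + 1L]] <- data.frame(
            start = s - 1L, end = s + span - 1L, motif = motif,
            copies = copies, kind = "other-STR",
            stringsAsFactors = FALSE)
        }
      }
      s <- s + 1L
    }
  }
  out <- do.call(rbind, c(hp, str))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      motif = character(), copies = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$kind, out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(motif, 1L, d), k / d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# O(n*m) all-pairs comparison of two call data frames, independent of the
# keyed implementation in compare_callsets().
oracle_compare <- function(ca, cb, mode = "exact") {
  if (mode == "exact") {
    hit_a <- vapply(seq_len(nrow(ca)), function(i) {
      any(cb$chrom == ca$chrom[i] & cb$pos == ca$pos[i] &
            cb$ref == ca$ref[i] & cb$alt == ca$alt[i])
    }, logical(1L))
    hit_b <- vapply(seq_len(nrow(cb)), function(i) {
      any(ca$chrom == cb$chrom[i] & ca$pos == cb$pos[i] &
            ca$ref == cb$ref[i] & ca$alt == cb$alt[i])
    }, logical(1L))
    list(n_intersection = sum(hit_a), n_a_specific = sum(!hit_a),
         n_b_specific = sum(!hit_b))
  } else {
    la <- unique(paste(ca$chrom, ca$pos))
    lb <- unique(paste(cb$chrom, cb$pos))
    shared <- intersect(la, lb)
    n_a <- 0L
    for (l in la) {
      n_here <- sum(paste(ca$chrom, ca$pos) == l)
      n_a <- n_a + if (l %in% shared) n_here - 1L else n_here
    }
    n_b <- 0L
    for (l in lb) {
      n_here <- sum(paste(cb$chrom, cb$pos) == l)
      n_b <- n_b + if (l %in% shared) n_here - 1L else n_here
    }
    list(n_intersection = length(shared), n_a_specific = n_a,
         n_b_specific = n_b)
  }
}
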
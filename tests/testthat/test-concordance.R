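test_that("match predicates separate position, exact and validation matching", {
  a <- norm_call(pos = 10L, ref = "AT", alt = "A")   # 1-bp deletion
  b <- norm_call(pos = 10L, ref = "A", alt = "AT")   # 1-bp insertion
  expect_true(match_exact(a, a))
  expect_true(match_position(a, a))
  expect_true(match_position(a, b))
  expect_false(match_exact(a, b))
  expect_false(match_validation(a, b))  # same locus, different type
  expect_true(match_validation(a, norm_call(pos = 10L, ref = "ATT",
                                            alt = "A")))
  # un-normalized input is refused
  raw <- a; raw$normalized <- FALSE
  expect_error(match_exact(raw, a), "normalized")
})

test_that("two raw representations of one repeat deletion exact-match after normalization", {
  seq <- paste0("GGTC", strrep("CA", 5L), "TGGA")
  rs <- c(chr1 = seq)
  r1 <- normalize_calls(indel_callset(
    data.frame(chrom = "chr1", pos = 5L, ref = "CAC", alt = "C")), rs)
  r2 <- normalize_calls(indel_callset(
    data.frame(chrom = "chr1", pos = 11L, ref = "CAC", alt = "C")), rs)
  expect_true(match_exact(r1, r2))
})

test_that("compare_callsets covers the definitional examples", {
  mk <- function(n, offset = 0L) {
    as_normalized_callset(data.frame(
      chrom = "chr1", pos = (seq_len(n) + offset) * 10L,
      ref = "AT", alt = "A"))
  }
  a <- mk(20L)
  ident <- compare_callsets(a, a, mode = "exact")
  expect_equal(ident$rate_concordant, 100)
  expect_equal(ident$n_a_specific, 0L)
  expect_equal(ident$n_b_specific, 0L)
  disjoint <- compare_callsets(mk(10L), mk(10L, offset = 50L))
  expect_equal(disjoint$rate_concordant, 0)
  # |intersection| = 50, a-only = 30, b-only = 20 -> 50/30/20 percent
  a_only <- as_normalized_callset(data.frame(
    chrom = "chr1", pos = 10000L + seq_len(30L), ref = "AT", alt = "A"))
  b_only <- as_normalized_callset(data.frame(
    chrom = "chr1", pos = 20000L + seq_len(20L), ref = "AT", alt = "A"))
  shared <- mk(50L)
  A <- union_callsets(shared, a_only)
  B <- union_callsets(shared, b_only)
  r <- compare_callsets(A, B, mode = "exact")
  expect_equal(r$n_intersection, 50L)
  expect_equal(r$n_a_specific, 30L)
  expect_equal(r$n_b_specific, 20L)
  expect_equal(r$rate_concordant, 50)
  expect_equal(r$rate_a_specific, 30)
  expect_equal(r$rate_b_specific, 20)
  expect_equal(r$rate_concordant + r$rate_a_specific +
                 r$rate_b_specific, 100)
})

test_that("compare_callsets agrees with a brute-force all-pairs matcher", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:50, 1L); m <- sample(5:50, 1L)
    mk_random <- function(k) {
      df <- data.frame(
        chrom = sample(c("chr1", "chr2"), k, TRUE),
        pos = sample(1:40, k, TRUE) * 3L,
        ref = sample(c("AT", "A", "ACGT"), k, TRUE),
        alt = "G")
      # make ref/alt a legal indel pair
      df$alt <- ifelse(nchar(df$ref) == 1L, paste0(df$ref, "TG"),
                       substr(df$ref, 1L, 1L))
      df$normalized <- TRUE
      indel_callset(df)
    }
    a <- mk_random(n); b <- mk_random(m)
    for (mode in c("exact", "position")) {
      r <- compare_callsets(a, b, mode = mode)
      o <- oracle_compare(a$calls, b$calls, mode = mode)
      expect_equal(r$n_intersection, o$n_intersection)
      expect_equal(r$n_a_specific, o$n_a_specific)
      expect_equal(r$n_b_specific, o$n_b_specific)
      expect_equal(r$rate_concordant + r$rate_a_specific +
                     r$rate_b_specific, 100)
    }
    # exact-match intersection can never exceed position-match
    expect_lte(compare_callsets(a, b, "exact")$n_intersection,
               compare_callsets(a, b, "position")$n_intersection)
  }
})

test_that("depth floors exclude low-depth loci and raise concordance", {
  # discordance planted exclusively at loci with depth 0 in set b
  shared <- data.frame(chrom = "chr1", pos = seq_len(60L) * 10L,
                       ref = "AT", alt = "A")
  a_extra <- data.frame(chrom = "chr1", pos = 5000L + seq_len(40L) * 10L,
                        ref = "AT", alt = "A")
  a <- as_normalized_callset(rbind(shared, a_extra))
  b <- as_normalized_callset(shared)
  depth_a <- data.frame(chrom = a$calls$chrom, pos = a$calls$pos,
                        depth = 50L)
  depth_b <- data.frame(chrom = b$calls$chrom, pos = b$calls$pos,
                        depth = 50L)   # a_extra loci absent -> depth 0
  r0 <- compare_callsets(a, b, "exact", depth_a, depth_b,
                         depth_floor = 0L)
  suppressMessages(
    r1 <- compare_callsets(a, b, "exact", depth_a, depth_b,
                           depth_floor = 1L))
  expect_equal(r0$rate_concordant, 60)
  expect_equal(r1$rate_concordant, 100)
  expect_gt(r1$rate_concordant, r0$rate_concordant)
})

test_that("mean concordance across samples gives per-cell mean and SD", {
  mk_res <- function(conc) {
    structure(list(n_intersection = 0L, n_a_specific = 0L,
                   n_b_specific = 0L, rate_concordant = conc,
                   rate_a_specific = (100 - conc) / 2,
                   rate_b_specific = (100 - conc) / 2,
                   mode = "exact", depth_floor = 0L),
              class = "concordance_result")
  }
  m <- mean_concordance(list(mk_res(52), mk_res(54)))
  expect_equal(m$mean[m$cell == "concordant"], 53.0)
  expect_equal(round(m$sd[m$cell == "concordant"], 2), 1.41)
  # identical samples -> SD 0
  m2 <- mean_concordance(list(mk_res(60), mk_res(60), mk_res(60)))
  expect_equal(m2$sd, rep(0, 3L))
  # single sample -> SD flagged undefined
  expect_warning(m1 <- mean_concordance(list(mk_res(52))), "SD undefined")
  expect_true(all(is.na(m1$sd)))
  expect_equal(m1$mean[1L], 52)
})

test_that("multiple-signature loci are detected and counted exactly", {
  none <- as_normalized_callset(data.frame(
    chrom = "chr1", pos = c(10L, 20L), ref = "AT", alt = "A"))
  expect_equal(nrow(multiple_signatures(none)), 0L)
  two <- as_normalized_callset(data.frame(
    chrom = "chr1", pos = c(10L, 10L, 30L),
    ref = c("AT", "A", "GC"), alt = c("A", "AT", "G")))
  sig <- multiple_signatures(two)
  expect_equal(nrow(sig), 2L)
  expect_equal(unique(sig$pos), 10L)
  expect_equal(unique(sig$n_signatures), 2L)
  # planted k multi-signature loci recovered exactly
  set.seed(11)
  k <- 7L
  rows <- lapply(seq_len(k), function(i) {
    data.frame(chrom = "chr2", pos = i * 100L,
               ref = c("AT", "A", "ATT"), alt = c("A", "ACG", "A"))
  })
  singles <- data.frame(chrom = "chr2", pos = 9000L + seq_len(25L),
                        ref = "AT", alt = "A")
  u <- as_normalized_callset(rbind(do.call(rbind, rows), singles))
  sig2 <- multiple_signatures(u)
  expect_equal(length(unique(sig2$pos)), k)
  expect_equal(unique(sig2$n_signatures), 3L)
})
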
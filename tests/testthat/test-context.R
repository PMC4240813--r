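test_that("homopolymer detection finds maximal runs of length >= 5", {
  expect_equal(nrow(find_homopolymers("ACGTACGT")), 0L)
  hp <- find_homopolymers("GGAAAAAC")
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$motif, "A")
  expect_equal(hp$start, 2L)   # 0-based half-open
  expect_equal(hp$end, 7L)
  expect_equal(hp$copies, 5)
  # N never forms or joins a run
  expect_equal(nrow(find_homopolymers("AANNNNNAA")), 0L)
  expect_equal(nrow(find_homopolymers("AAAANAAAA")), 0L)
  hp2 <- find_homopolymers("AAAAANAAAAA")
  expect_equal(nrow(hp2), 2L)
  # threshold is configurable
  expect_equal(nrow(find_homopolymers("AAAA", min_len = 4L)), 1L)
})

test_that("STR detection finds primitive tandem tracts with the default gates", {
  s <- find_strs("TTCACACACATT")
  expect_equal(nrow(s), 1L)
  expect_equal(s$motif, "CA")
  expect_equal(s$copies, 4)
  expect_equal(s$start, 2L)
  expect_equal(s$end, 10L)
  # a homopolymer run is never reported as a dinucleotide repeat
  expect_equal(nrow(find_strs("AAAAAAAAAA")), 0L)
  # span below 8 bp or fewer than 3 copies is ignored
  expect_equal(nrow(find_strs("GGCACACAGG")), 0L)       # span 6
  expect_equal(nrow(find_strs("GGCATGCATGGG")), 0L)     # 2 copies of CATG
  # trinucleotide tract passes
  s3 <- find_strs("GGACTACTACTGG")
  expect_equal(s3$motif, "ACT")
  expect_equal(s3$copies, 3)
})

test_that("tract detectors equal the exhaustive oracle on random windows", {
  set.seed(13)
  for (i in 1:120) {
    # random window with occasionally planted tracts, including at edges
    chars <- sample(c("A", "C", "G", "T", "N"), 200L, TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    if (i %% 3L == 0L) {
      unit <- sample(c("A", "T", "CA", "GAT"), 1L)
      run <- strrep(unit, sample(3:8, 1L))
      at <- sample(c(1L, sample(2:150, 1L),
                     201L - nchar(run)), 1L)
      substr_chars <- strsplit(run, "")[[1L]]
      chars[at:(at + length(substr_chars) - 1L)] <- substr_chars
    }
    seq <- paste(chars, collapse = "")
    got <- rbind(
      find_homopolymers(seq)[, c("start", "end", "motif", "copies",
                                 "kind")],
      find_strs(seq)[, c("start", "end", "motif", "copies", "kind")])
    got <- got[order(got$kind, got$start, got$motif), , drop = FALSE]
    rownames(got) <- NULL
    expect_equal(got, oracle_tracts(seq))
  }
})

test_that("context annotation assigns exactly one of the six labels", {
  # poly-A: 1-bp deletion of A inside a length-5 A run
  seq1 <- "GGTTAAAAAGCTGACGGATCGA"
  rs1 <- c(chr1 = seq1)
  del_a <- normalize_calls(indel_callset(
    data.frame(chrom = "chr1", pos = 5L, ref = "AA", alt = "A")), rs1)
  expect_equal(annotate_context(del_a, rs1)$calls$context, "poly-A")
  # other-STR: CA deletion inside a CACACACA tract (no homopolymer >= 5)
  seq2 <- "GGTTCACACACATCGGATGGCC"
  rs2 <- c(chr1 = seq2)
  del_ca <- normalize_calls(indel_callset(
    data.frame(chrom = "chr1", pos = 4L, ref = "TCA", alt = "T")), rs2)
  expect_equal(annotate_context(del_ca, rs2)$calls$context, "other-STR")
  # non-STR: isolated 3-bp insertion in a non-repetitive flank
  seq3 <- "GGTACGTTAGCATGCCATGAGT"
  rs3 <- c(chr1 = seq3)
  ins <- normalize_calls(indel_callset(
    data.frame(chrom = "chr1", pos = 10L, ref = "G", alt = "GCTG")), rs3)
  expect_equal(annotate_context(ins, rs3)$calls$context, "non-STR")
  # un-normalized input refused
  raw <- indel_callset(data.frame(chrom = "chr1", pos = 10L, ref = "G",
                                  alt = "GCTG"))
  expect_error(annotate_context(raw, rs3), "normalize")
  labels <- c("poly-A", "poly-C", "poly-G", "poly-T", "other-STR",
              "non-STR")
  expect_true(annotate_context(ins, rs3)$calls$context %in% labels)
})

test_that("an inserted run abutting a tract inherits the tract context", {
  # insertion of AA immediately left of an AAAAA run (1 bp adjacency)
  seq <- "GGTTCAAAAAGCTGACGGATCG"
  rs <- c(chr1 = seq)
  ins <- normalize_calls(indel_callset(
    data.frame(chrom = "chr1", pos = 5L, ref = "C", alt = "CAA")), rs)
  expect_equal(annotate_context(ins, rs)$calls$context, "poly-A")
})

test_that("context is invariant under equivalent raw representations", {
  set.seed(21)
  for (i in 1:50) {
    fx <- random_repeat_indel()
    rs <- c(chr1 = fx$seq)
    raw <- indel_callset(data.frame(chrom = "chr1", pos = fx$pos,
                                    ref = fx$ref, alt = fx$alt))
    norm <- normalize_calls(raw, rs)
    ctx1 <- annotate_context(norm, rs)$calls$context
    # same variant, built directly from the normalized representation
    rebuilt <- normalize_calls(indel_callset(norm$calls[
      , c("chrom", "pos", "ref", "alt")]), rs)
    ctx2 <- annotate_context(rebuilt, rs)$calls$context
    expect_equal(ctx1, ctx2)
  }
})

test_that("region expansion and flanks follow the padded-and-merged rule", {
  # exon at BED (100, 200), pad 20 -> BED (80, 220)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 200L))
  ex <- expand_regions(gr, 20L)
  expect_equal(GenomicRanges::start(ex), 81L)
  expect_equal(GenomicRanges::end(ex), 220L)
  # pad 0 is the identity up to merging
  expect_equal(expand_regions(gr, 0L), GenomicRanges::reduce(gr))
  # two calls 30 bp apart with 25 bp flanks merge into one interval
  cs <- as_normalized_callset(data.frame(
    chrom = "chr1", pos = c(500L, 530L), ref = "AT", alt = "A"))
  fl <- flank_regions(cs, 25L)
  expect_equal(length(fl), 1L)
  expect_equal(GenomicRanges::start(fl), 475L)
  expect_equal(GenomicRanges::end(fl), 555L)
  # clamped at the contig start
  cs2 <- as_normalized_callset(data.frame(chrom = "chr1", pos = 10L,
                                          ref = "AT", alt = "A"))
  expect_equal(GenomicRanges::start(flank_regions(cs2, 25L)), 1L)
})

test_that("context composition recovers a planted mixture and the poly-A/T aggregate", {
  df <- data.frame(chrom = "chr1", pos = seq_len(50L) * 10L, ref = "AT",
                   alt = "A",
                   context = rep(c("poly-A", "poly-T", "non-STR",
                                   "other-STR"),
                                 c(12L, 15L, 18L, 5L)))
  cs <- indel_callset(df)
  comp <- context_composition(cs)
  expect_equal(comp$n[comp$context == "poly-A"], 12L)
  expect_equal(comp$n[comp$context == "poly-T"], 15L)
  expect_equal(sum(comp$proportion), 1)
  at <- attr(comp, "poly_at")
  expect_equal(at$n, 27L)
  expect_equal(at$proportion, 27 / 50)
  # all non-STR case
  df2 <- df; df2$context <- "non-STR"
  comp2 <- context_composition(indel_callset(df2))
  expect_equal(comp2$proportion,
               c(0, 0, 0, 0, 0, 1))
  # unset contexts are a hard error
  df3 <- df; df3$context[1L] <- "unset"
  expect_error(context_composition(indel_callset(df3)), "context")
})
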
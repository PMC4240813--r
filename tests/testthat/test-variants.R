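test_that("call-set construction enforces the INDEL data model", {
  # SNP (equal allele lengths) refused
  expect_error(indel_callset(data.frame(chrom = "chr1", pos = 5L,
                                        ref = "A", alt = "C")),
               "non-INDEL")
  # negative coverage refused
  expect_error(indel_callset(data.frame(chrom = "chr1", pos = 5L,
                                        ref = "AT", alt = "A",
                                        cov_ref = -1L, cov_alt = 3L)),
               "non-negative")
  # duplicates collapse keeping the maximum cov_alt
  cs <- indel_callset(data.frame(
    chrom = "chr1", pos = c(5L, 5L), ref = "AT", alt = "A",
    cov_ref = c(10L, 10L), cov_alt = c(3L, 9L)))
  expect_equal(n_calls(cs), 1L)
  expect_equal(cs$calls$cov_alt, 9L)
  # derived fields
  cs2 <- indel_callset(data.frame(chrom = "chr1", pos = 5L,
                                  ref = "A", alt = "ATTT"))
  expect_equal(cs2$calls$size, 3L)
  expect_equal(cs2$calls$itype, "insertion")
})

test_that("indel size and the large-INDEL predicate follow the strict >5 bp rule", {
  expect_equal(indel_size("A", "ATTTTTT"), 6L)
  expect_true(is_large("A", "ATTTTTT"))
  expect_equal(indel_size("ACT", "A"), 2L)
  expect_false(is_large("ACT", "A"))
  expect_false(is_large("ACTGCA", "A"))  # size 5 is not large
  expect_true(is_large("ACTGCAT", "A")) # size 6 is
})

test_that("read_indel_vcf drops SNPs, splits multi-allelics, passes coverages", {
  vcf <- tempfile(fileext = ".vcf")
  write_test_vcf(vcf, c(
    "chr1\t10\t.\tA\tATT\t.\tPASS\tCOVREF=10;COVALT=2;ZYG=het",
    "chr1\t20\t.\tC\tG\t.\tPASS\tCOVREF=5;COVALT=5",          # SNP
    "chr1\t30\t.\tA\tAT,ATT\t.\tPASS\tCOVREF=9;COVALT=4,6;ZYG=hom"))
  expect_message(cs <- read_indel_vcf(vcf), "dropped 1 non-INDEL")
  expect_equal(n_calls(cs), 3L)
  first <- cs$calls[cs$calls$pos == 10L, ]
  expect_equal(first$cov_ref, 10L)
  expect_equal(first$cov_alt, 2L)
  expect_equal(first$zygosity, "heterozygous")
  multi <- cs$calls[cs$calls$pos == 30L, ]
  expect_equal(nrow(multi), 2L)
  expect_setequal(multi$alt, c("AT", "ATT"))
  expect_setequal(multi$cov_alt, c(4L, 6L))
  expect_equal(unique(multi$zygosity), "homozygous")
})

test_that("missing coverage keys warn and fall back to zero", {
  vcf <- tempfile(fileext = ".vcf")
  write_test_vcf(vcf, "chr1\t10\t.\tA\tATT\t.\tPASS\tZYG=het")
  expect_warning(cs <- read_indel_vcf(vcf), "missing coverage")
  expect_equal(cs$calls$cov_ref, 0L)
  expect_equal(cs$calls$cov_alt, 0L)
})

test_that("VCF write -> read round trip is loss-free on the core fields", {
  df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   pos = c(10L, 30L, 7L),
                   ref = c("AT", "A", "GCCA"),
                   alt = c("A", "ATTT", "G"),
                   cov_ref = c(10L, 0L, 33L),
                   cov_alt = c(2L, 17L, 4L),
                   zygosity = c("heterozygous", "homozygous", "unknown"))
  cs <- indel_callset(df, label = "rt")
  path <- tempfile(fileext = ".vcf.gz")
  write_indel_vcf(cs, path)
  back <- read_indel_vcf(path)
  cols <- c("chrom", "pos", "ref", "alt", "cov_ref", "cov_alt",
            "zygosity")
  expect_equal(back$calls[, cols], cs$calls[, cols])
})

test_that("left normalization matches the haplotype-enumeration oracle", {
  # deletion of CA at the right end of a CACACA run shifts leftmost
  seq <- "GGTGCACACATAG"
  ref_set <- c(chr1 = seq)
  v <- left_normalize("chr1", 8L, "ACA", "A", ref_set)
  o <- oracle_leftmost(seq, 8L, "ACA", "A")
  expect_equal(v$pos, o$pos)
  expect_equal(v$ref, o$ref)
  expect_equal(v$alt, o$alt)
  # random repeat-context INDELs: haplotype equality, oracle agreement,
  # idempotence
  set.seed(42)
  for (i in 1:200) {
    fx <- random_repeat_indel()
    rs <- c(chr1 = fx$seq)
    v <- left_normalize("chr1", fx$pos, fx$ref, fx$alt, rs)
    expect_equal(apply_edit(fx$seq, v$pos, v$ref, v$alt),
                 apply_edit(fx$seq, fx$pos, fx$ref, fx$alt))
    o <- oracle_leftmost(fx$seq, fx$pos, fx$ref, fx$alt)
    expect_equal(v$pos, o$pos)
    v2 <- left_normalize("chr1", v$pos, v$ref, v$alt, rs)
    expect_identical(v2, v)
  }
})

test_that("normalization refuses corrupt input and handles contig start", {
  ref_set <- c(chr1 = "AAAAGTC")
  expect_error(left_normalize("chr1", 2L, "GG", "G", ref_set),
               "mismatch")
  # deletion abutting position 1: right-padded representation
  v <- left_normalize("chr1", 1L, "AA", "A", ref_set)
  expect_equal(v$pos, 1L)
  expect_equal(apply_edit("AAAAGTC", v$pos, v$ref, v$alt),
               apply_edit("AAAAGTC", 1L, "AA", "A"))
})

test_that("normalize_calls collapses equivalent raw representations", {
  seq <- paste0("TTGC", strrep("CA", 6L), "GTTAGC")
  rs <- c(chr1 = seq)
  # same 2-bp deletion written at two different offsets in the run
  df <- data.frame(chrom = "chr1",
                   pos = c(5L, 9L),
                   ref = c("CAC", "CAC"),
                   alt = c("C", "C"),
                   cov_ref = c(5L, 5L), cov_alt = c(3L, 8L))
  cs <- normalize_calls(indel_callset(df), rs)
  expect_equal(n_calls(cs), 1L)
  expect_equal(cs$calls$cov_alt, 8L)  # max coverage kept
  expect_true(all(cs$calls$normalized))
})

test_that("restrict_to_regions honours the half-open BED convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)  # 0-based half-open = 1-based 11..20
  regions <- read_bed_regions(bed)
  df <- data.frame(chrom = "chr1", pos = c(10L, 11L, 20L, 21L),
                   ref = "AT", alt = "A")
  cs <- indel_callset(df)
  expect_message(r <- restrict_to_regions(cs, regions), "removed 2")
  expect_equal(r$calls$pos, c(11L, 20L))
  # brute-force membership check
  manual <- df$pos[df$pos >= 11L & df$pos <= 20L]
  expect_equal(r$calls$pos, manual)
  # empty region set removes everything
  empty <- GenomicRanges::GRanges()
  expect_equal(n_calls(restrict_to_regions(cs, empty)), 0L)
  # all inside is the identity
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 100L))
  expect_equal(n_calls(restrict_to_regions(cs, wide)), 4L)
})
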
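# Programmatic fixtures shared across the test files.

# Minimal VCF writer for test inputs (plain text, VCF 4.2).
write_test_vcf <- function(path, records,
                           info_defs = c("COVREF", "COVALT", "ZYG")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"x\">",
            info_defs),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, records), path)
  path
}

# A repeat-rich random reference plus one equivalent raw/shifted INDEL
# representation pair inside a planted repeat run.
random_repeat_indel <- function() {
  unit <- sample(c("A", "T", "CA", "AT", "ACG"), 1L)
  copies <- sample(4:8, 1L)
  left <- paste(sample(c("G", "C", "T", "A"), 12L, TRUE), collapse = "")
  run <- strrep(unit, copies)
  right <- paste(sample(c("G", "C", "T", "A"), 12L, TRUE), collapse = "")
  seq <- paste0(left, run, right)
  k <- nchar(unit)
  run_start <- nchar(left) + 1L
  # raw representation: delete or insert one unit at a random offset
  # inside the run (often not left-aligned)
  offset <- sample.int(copies - 1L, 1L)
  p <- run_start + offset * k - 1L
  if (stats::runif(1) < 0.5) {
    rec <- list(pos = p, ref = substr(seq, p, p + k),
                alt = substr(seq, p, p))
  } else {
    rec <- list(pos = p, ref = substr(seq, p, p),
                alt = paste0(substr(seq, p, p), unit))
  }
  list(seq = seq, pos = rec$pos, ref = rec$ref, alt = rec$alt)
}

# Normalized single-call data frame (bypassing the reference) for
# match-predicate tests.
norm_call <- function(chrom = "chr1", pos = 10L, ref = "AT", alt = "A",
                      ...) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, ..., stringsAsFactors = FALSE)
  df$size <- abs(nchar(df$ref) - nchar(df$alt))
  df$itype <- ifelse(nchar(df$alt) > nchar(df$ref), "insertion",
                     "deletion")
  df$normalized <- TRUE
  df
}

# Call set marked normalized without touching a reference (positions and
# alleles are already canonical by construction in the tests using this).
as_normalized_callset <- function(df, label = "") {
  df$normalized <- TRUE
  indel_callset(df, label = label)
}
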
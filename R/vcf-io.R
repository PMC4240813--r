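#' Read an INDEL call set from a VCF file
#'
#' Reads a VCF 4.x file, keeps only true insertions/deletions, splits
#' multi-allelic records into biallelic ones, and pulls the per-allele
#' k-mer coverages from configurable INFO keys. The defaults match
#' micro-assembly caller output that reports reference/alternate k-mer
#' coverage per call (`COVREF`/`COVALT`); callers exposing AD-style raw
#' read counts can be read by pointing the keys at those fields.
#'
#' Records with equal-length alleles (SNPs/MNPs) are dropped and their
#' count reported. Records whose coverage keys are absent get coverage 0
#' and a single warning with the affected count. Zygosity is read from an
#' optional INFO key (`het`/`hom` or the full words); anything else maps
#' to `"unknown"`.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param cov_ref_key,cov_alt_key INFO keys holding the reference and
#'   alternate allele coverages.
#' @param zyg_key optional INFO key holding zygosity; `NULL` to skip.
#' @param label,sample_id passed to [indel_callset()].
#' @return An `indel_callset` with unset `chi2`, `quality_class`, `context`.
#' @export
read_indel_vcf <- function(path, cov_ref_key = "COVREF",
                           cov_alt_key = "COVALT", zyg_key = "ZYG",
                           label = "", sample_id = "") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(indel_callset(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      label = label, sample_id = sample_id))
  }
  cov_ref_raw <- suppressWarnings(vcfR::extract.info(v, cov_ref_key))
  cov_alt_raw <- suppressWarnings(vcfR::extract.info(v, cov_alt_key))
  zyg_raw <- if (!is.null(zyg_key)) {
    suppressWarnings(vcfR::extract.info(v, zyg_key))
  } else {
    rep(NA_character_, nrow(fix))
  }

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(as.character(fix[, "REF"]))
  alt_field <- as.character(fix[, "ALT"])
  if (any(is.na(pos)) || any(is.na(ref)) || any(is.na(alt_field)) ||
      any(!nzchar(ref)) || any(!nzchar(alt_field))) {
    bad <- which(is.na(pos) | is.na(ref) | is.na(alt_field))[1L]
    stop("malformed VCF record at data line ", bad, " of ", path)
  }

  # split multi-allelic records; per-allele coverages may be comma lists
  alts <- strsplit(alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_along(alts), n_alt)
  allele_no <- sequence(n_alt)
  alt <- toupper(unlist(alts, use.names = FALSE))

  pick_cov <- function(raw, rec, k) {
    val <- raw[rec]
    if (is.na(val)) return(NA_integer_)
    parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
    out <- suppressWarnings(as.integer(parts[min(k, length(parts))]))
    out
  }
  cov_ref <- mapply(pick_cov, rec = idx, k = 1L,
                    MoreArgs = list(raw = cov_ref_raw))
  cov_alt <- mapply(pick_cov, rec = idx, k = allele_no,
                    MoreArgs = list(raw = cov_alt_raw))
  n_nocov <- sum(is.na(cov_ref) | is.na(cov_alt))
  if (n_nocov > 0L) {
    warning(n_nocov, " record(s) missing coverage key(s) ",
            cov_ref_key, "/", cov_alt_key, "; coverages set to 0",
            call. = FALSE)
    cov_ref[is.na(cov_ref)] <- 0L
    cov_alt[is.na(cov_alt)] <- 0L
  }

  zyg <- tolower(zyg_raw[idx])
  zyg <- ifelse(zyg %in% c("het", "heterozygous"), "heterozygous",
         ifelse(zyg %in% c("hom", "homozygous"), "homozygous", "unknown"))

  df <- data.frame(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
                   alt = alt, cov_ref = cov_ref, cov_alt = cov_alt,
                   zygosity = zyg, stringsAsFactors = FALSE)
  keep <- nchar(df$ref) != nchar(df$alt)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("read_indel_vcf: dropped ", n_dropped,
            " non-INDEL (SNP/MNP) record(s)")
  }
  df <- df[keep, , drop = FALSE]
  indel_callset(df, label = label, sample_id = sample_id)
}

#' Write an INDEL call set to VCF
#'
#' Writes calls with their allele coverages (and, when set, chi-square
#' score, quality class, context and zygosity) as INFO fields. Output is
#' bgzip-style gzipped VCF as produced by [vcfR::write.vcf()].
#'
#' @param cs an `indel_callset`.
#' @param path output path (conventionally ending in `.vcf.gz`).
#' @param cov_ref_key,cov_alt_key,zyg_key INFO keys to write.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(cs, path, cov_ref_key = "COVREF",
                            cov_alt_key = "COVALT", zyg_key = "ZYG") {
  stopifnot(inherits(cs, "indel_callset"))
  calls <- cs$calls
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=indelqc",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Reference allele k-mer coverage\">", cov_ref_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Alternate allele k-mer coverage\">", cov_alt_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Zygosity\">", zyg_key),
    "##INFO=<ID=CHI2,Number=1,Type=Float,Description=\"k-mer Chi-Square allele balance score\">",
    "##INFO=<ID=QCLASS,Number=1,Type=String,Description=\"Quality class: high/moderate/low\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Sequence context label\">"
  )
  info <- sprintf("%s=%d;%s=%d;%s=%s", cov_ref_key, calls$cov_ref,
                  cov_alt_key, calls$cov_alt, zyg_key,
                  ifelse(calls$zygosity == "heterozygous", "het",
                  ifelse(calls$zygosity == "homozygous", "hom", "unknown")))
  extra <- character(nrow(calls))
  has_chi2 <- !is.na(calls$chi2)
  extra[has_chi2] <- sprintf(";CHI2=%.4f", calls$chi2[has_chi2])
  has_class <- calls$quality_class != "unset"
  extra[has_class] <- paste0(extra[has_class], ";QCLASS=",
                             calls$quality_class[has_class])
  has_ctx <- calls$context != "unset"
  extra[has_ctx] <- paste0(extra[has_ctx], ";CTX=", calls$context[has_ctx])
  info <- paste0(info, extra)
  fix <- cbind(CHROM = calls$chrom, POS = as.character(calls$pos),
               ID = NA_character_, REF = calls$ref, ALT = calls$alt,
               QUAL = NA_character_, FILTER = "PASS", INFO = info)
  if (nrow(calls) == 0L) {
    fix <- matrix(character(0), nrow = 0, ncol = 8,
                  dimnames = list(NULL, c("CHROM", "POS", "ID", "REF",
                                          "ALT", "QUAL", "FILTER", "INFO")))
  }
  v <- methods::new("vcfR", meta = meta, fix = fix,
                    gt = matrix(character(0), nrow = 0, ncol = 0))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
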
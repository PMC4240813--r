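#' Load a reference sequence set from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases the
#' sequences and trims FASTA description lines down to the sequence name.
#'
#' @param path path to a (plain-text) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

# Resolve a reference argument (DNAStringSet, named character vector, or a
# single unnamed sequence) to the plain uppercase character sequence of one
# chromosome. Centralizing this keeps every consumer tolerant of either
# representation.
ref_chrom_seq <- function(reference, chrom) {
  if (methods::is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference)) {
      stop("chromosome ", sQuote(chrom), " not present in reference")
    }
    return(toupper(as.character(reference[[chrom]])))
  }
  if (methods::is(reference, "DNAString")) {
    return(toupper(as.character(reference)))
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) {
      if (length(reference) != 1L) {
        stop("unnamed character reference must be a single sequence")
      }
      return(toupper(reference))
    }
    if (!chrom %in% names(reference)) {
      stop("chromosome ", sQuote(chrom), " not present in reference")
    }
    return(toupper(unname(reference[[chrom]])))
  }
  stop("unsupported reference type: ", class(reference)[1L])
}
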
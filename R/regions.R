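#' Read a region set from a BED file
#'
#' Regions are represented internally as merged (reduced)
#' [GenomicRanges::GRanges] in R's 1-based closed convention;
#' [rtracklayer::import()] performs the conversion from BED's 0-based
#' half-open convention, keeping the coordinate translation in one place.
#'
#' @param path path to a BED file.
#' @return A merged `GRanges`.
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Write regions or repeat tracts to BED
#'
#' @param x a `GRanges`, or a repeat-tract data frame as returned by
#'   [find_homopolymers()] / [find_strs()] (columns `chrom`, `start`,
#'   `end` in 0-based half-open coordinates, plus `motif` and `kind`).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(x, path) {
  if (is.data.frame(x)) {
    gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1L, x$end))
    if (!is.null(x$motif)) {
      S4Vectors::mcols(gr)$name <- paste0(x$kind, ":", x$motif)
    }
    x <- gr
  }
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Expand regions symmetrically and merge
#'
#' Pads each interval by `pad` bases on both sides (clamped at the contig
#' start), then merges overlapping intervals. With the default `pad = 20`
#' this turns a set of exons into the exonic targeted regions that include
#' splice sites.
#'
#' @param regions a `GRanges`.
#' @param pad non-negative pad in bp (default 20).
#' @return A merged `GRanges`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' expand_regions(gr, 20)
#' @export
expand_regions <- function(regions, pad = 20L) {
  stopifnot(methods::is(regions, "GRanges"), pad >= 0L)
  GenomicRanges::start(regions) <-
    pmax(GenomicRanges::start(regions) - pad, 1L)
  GenomicRanges::end(regions) <- GenomicRanges::end(regions) + pad
  GenomicRanges::reduce(regions)
}

#' Build flanking regions around call loci
#'
#' Creates a `(pos - pad, pos + pad)` window around the anchor position of
#' every call and merges the result. The default 25 bp flank is the window
#' used when profiling coverage around INDEL loci.
#'
#' @param cs an `indel_callset`.
#' @param pad flank size in bp (default 25).
#' @return A merged `GRanges`.
#' @export
flank_regions <- function(cs, pad = 25L) {
  stopifnot(inherits(cs, "indel_callset"), pad >= 0L)
  if (!nrow(cs$calls)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    cs$calls$chrom,
    IRanges::IRanges(pmax(cs$calls$pos - pad, 1L), cs$calls$pos + pad))
  GenomicRanges::reduce(gr)
}
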
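#' Export strand-sites as BED6
#'
#' One BED line per strand-site, 0-based half-open over the motif footprint,
#' with the motif in the name column and the strand in column 6.
#'
#' @param loci A `motif_loci` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_loci_bed <- function(loci, path) {
  sites <- strand_sites(loci)
  width <- attr(loci, "motif_width") %||% 4L
  ref <- attr(loci, "genome_id") %||% "ref"
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   ref, sites$start, sites$start + width,
                   sites$motif, sites$locus_id, sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Export loci as TSV
#'
#' @param loci A `motif_loci` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_loci_tsv <- function(loci, path) {
  data.table::fwrite(as.data.frame(loci), path, sep = "\t")
  invisible(path)
}

#' Export an annotated region report as TSV
#'
#' @param regions A (possibly gene-annotated) `region_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_region_report <- function(regions, path) {
  data.table::fwrite(as.data.frame(regions), path, sep = "\t")
  invisible(path)
}

#' Export palindrome records as TSV
#'
#' @param palindromes A `palindrome_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_palindromes_tsv <- function(palindromes, path) {
  data.table::fwrite(as.data.frame(palindromes), path, sep = "\t")
  invisible(path)
}
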
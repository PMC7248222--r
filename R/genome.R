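#' Read a genome from a FASTA file
#'
#' Reads a single-record (or named multi-record) FASTA file and returns a
#' `genome_seq` object carrying the uppercased sequence together with its
#' composition statistics. Only the alphabet `{A, C, G, T, N}` is accepted;
#' `N` bases are excluded from the GC-fraction denominator because they carry
#' no compositional information.
#'
#' @param path Path to a FASTA file.
#' @param record Optional record name; required when the file holds more than
#'   one record.
#' @return A `genome_seq` object: a list with elements `id`, `seq` (a single
#'   character string), `length`, `gc_fraction`, `base_counts` (named counts
#'   of A, C, G, T, N), `a_count_fwd` and `t_count_fwd`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGTACGT"), fa)
#' g <- read_genome_fasta(fa)
#' g$gc_fraction  # 0.5
#' @export
read_genome_fasta <- function(path, record = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in ", path)
  }
  if (is.null(record)) {
    if (length(set) > 1L) {
      stop("multiple FASTA records in ", path,
           "; pass `record` to pick one of: ",
           paste(names(set), collapse = ", "))
    }
    record <- names(set)[1L]
  } else if (!record %in% names(set)) {
    stop("record '", record, "' not found in ", path)
  }
  id <- sub("\\s.*$", "", record)
  seq <- toupper(as.character(set[[record]]))
  if (nchar(seq) == 0L) {
    stop("FASTA record '", id, "' is empty")
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("invalid character '", substr(seq, bad, bad),
         "' at position ", bad, " of record '", id, "'")
  }
  genome_seq(id, seq)
}

#' Construct a genome_seq object from an in-memory sequence
#'
#' @param id Identifier (accession-like string).
#' @param seq Character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @return A `genome_seq` object (see [read_genome_fasta()]).
#' @export
genome_seq <- function(id, seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("invalid character '", substr(seq, bad, bad),
         "' at position ", bad)
  }
  counts <- base_counts(seq)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  structure(
    list(
      id          = as.character(id),
      seq         = seq,
      length      = nchar(seq),
      gc_fraction = if (acgt > 0) (counts[["G"]] + counts[["C"]]) / acgt else NA_real_,
      base_counts = counts,
      a_count_fwd = counts[["A"]],
      t_count_fwd = counts[["T"]]
    ),
    class = "genome_seq"
  )
}

base_counts <- function(seq) {
  raw <- charToRaw(seq)
  vapply(c(A = "A", C = "C", G = "G", T = "T", N = "N"),
         function(b) sum(raw == charToRaw(b)), integer(1))
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp, GC %.1f%%\n",
              x$id, format(x$length, big.mark = ","),
              100 * x$gc_fraction))
  invisible(x)
}

#' Write a genome_seq to FASTA
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  starts <- seq(1L, genome$length, by = width)
  lines <- substring(genome$seq, starts, pmin(starts + width - 1L, genome$length))
  writeLines(c(paste0(">", genome$id), lines), path)
  invisible(path)
}
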
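#' Scan a genome for palindromic motifs
#'
#' Finds every occurrence of the given reverse-complement-palindromic motifs
#' (by default the two m6A restriction-modification targets GATC and CATG).
#' Because the motifs are palindromes, one forward-strand occurrence implies
#' an identical occurrence on the reverse strand at the same start, so each
#' occurrence is a two-strand *locus*. Overlapping occurrences are all
#' reported (step-1 scan) and `N` bases never match.
#'
#' @param genome A `genome_seq` (see [read_genome_fasta()]).
#' @param motifs Character vector of palindromic motifs; non-palindromic
#'   motifs are rejected because strand pairing would be undefined.
#' @return A `motif_loci` data.frame with columns `locus_id`, `motif` and
#'   `start` (0-based forward-strand position of the motif's first base),
#'   sorted by `start`, with attributes `genome_length` and `genome_id`.
#' @examples
#' g <- genome_seq("toy", "AAGATCAACATGAA")
#' scan_motifs(g)$start  # 2 8
#' @export
scan_motifs <- function(genome, motifs = c("GATC", "CATG")) {
  stopifnot(inherits(genome, "genome_seq"))
  motifs <- toupper(motifs)
  for (m in motifs) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    if (rc != m) {
      stop("motif '", m, "' is not a reverse-complement palindrome; ",
           "strand pairing is undefined")
    }
  }
  subject <- Biostrings::DNAString(genome$seq)
  hits <- lapply(motifs, function(m) {
    v <- Biostrings::matchPattern(m, subject, fixed = TRUE)
    data.frame(motif = rep(m, length(v)),
               start = BiocGenerics::start(v) - 1L)
  })
  loci <- do.call(rbind, hits)
  loci <- loci[order(loci$start, loci$motif), , drop = FALSE]
  rownames(loci) <- NULL
  loci <- cbind(locus_id = seq_len(nrow(loci)), loci)
  attr(loci, "genome_length") <- genome$length
  attr(loci, "genome_id") <- genome$id
  attr(loci, "motif_width") <- unique(nchar(motifs))
  class(loci) <- c("motif_loci", "data.frame")
  loci
}

#' Expand palindromic loci into strand-resolved sites
#'
#' Each palindromic locus carries one target adenine per strand: for both
#' GATC and CATG the forward-strand adenine is the motif's second base
#' (`start + 1`) and the reverse-strand adenine pairs with the forward-strand
#' thymine at `start + 2` (reported at that forward coordinate with strand
#' `-`). This strand resolution is what makes hemimethylation observable.
#'
#' @param loci A `motif_loci` data.frame from [scan_motifs()].
#' @return A data.frame with one row per strand-site (2 per locus): columns
#'   `locus_id`, `motif`, `start`, `strand` and `adenine_pos` (0-based
#'   forward coordinate of the target adenine on that strand).
#' @export
strand_sites <- function(loci) {
  stopifnot(is.data.frame(loci))
  if (nrow(loci) == 0L) {
    return(data.frame(locus_id = integer(), motif = character(),
                      start = integer(), strand = character(),
                      adenine_pos = integer()))
  }
  a_off <- vapply(loci$motif, function(m) {
    i <- regexpr("A", m)
    if (i < 1L) stop("motif '", m, "' contains no adenine")
    as.integer(i) - 1L
  }, integer(1), USE.NAMES = FALSE)
  # reverse-strand adenine pairs with the forward T, symmetric in a palindrome
  t_off <- nchar(loci$motif) - 1L - a_off
  out <- data.frame(
    locus_id    = rep(loci$locus_id, each = 2L),
    motif       = rep(loci$motif, each = 2L),
    start       = rep(loci$start, each = 2L),
    strand      = rep(c("+", "-"), nrow(loci)),
    adenine_pos = as.integer(rbind(loci$start + a_off, loci$start + t_off))
  )
  rownames(out) <- NULL
  out
}

#' Spacing and dispersion statistics for one motif
#'
#' The mean recurrence interval is `genome length / locus count`, matching
#' the "once every X bp" convention; the index of dispersion is the
#' variance-to-mean ratio of the successive inter-start distances
#' (population variance: the gap set is complete, not a sample). Values well
#' above the mean indicate clustering relative to random placement.
#'
#' @param loci A `motif_loci` data.frame.
#' @param genome A `genome_seq`, or `NULL` to use the loci's
#'   `genome_length` attribute.
#' @param motif Motif to restrict to (default: all loci).
#' @return A `spacing_stats` list: `motif`, `locus_count`, `mean_interval`,
#'   `gaps`, `gap_mean`, `gap_variance`, `dispersion_index`. With fewer than
#'   two loci the gap-based fields are `NA` (undefined, not an error).
#' @export
spacing_stats <- function(loci, genome = NULL, motif = NULL) {
  glen <- if (!is.null(genome)) genome$length else attr(loci, "genome_length")
  if (is.null(glen)) stop("genome length unknown; pass `genome`")
  if (!is.null(motif)) loci <- loci[loci$motif == toupper(motif), , drop = FALSE]
  starts <- sort(loci$start)
  n <- length(starts)
  if (n < 2L) {
    return(structure(list(
      motif = motif %||% "all", locus_count = n,
      mean_interval = if (n > 0) glen / n else NA_real_,
      gaps = integer(), gap_mean = NA_real_, gap_variance = NA_real_,
      dispersion_index = NA_real_
    ), class = "spacing_stats"))
  }
  gaps <- diff(starts)
  gm <- mean(gaps)
  gv <- mean((gaps - gm)^2)  # population variance
  structure(list(
    motif = motif %||% "all",
    locus_count = n,
    mean_interval = glen / n,
    gaps = gaps,
    gap_mean = gm,
    gap_variance = gv,
    dispersion_index = gv / gm
  ), class = "spacing_stats")
}

#' @export
print.spacing_stats <- function(x, ...) {
  cat(sprintf("<spacing_stats> %s: %d loci, once every %.0f bp, dispersion %s\n",
              x$motif, x$locus_count, x$mean_interval,
              if (is.na(x$dispersion_index)) "undefined"
              else sprintf("%.0f", x$dispersion_index)))
  invisible(x)
}

#' Motif-free gaps of a genome
#'
#' Computes the maximal intervals containing no base of any motif occurrence.
#' Motif footprints are merged first (overlapping occurrences do not
#' double-count), a gap runs from the end of one footprint (`start + width`)
#' to the start of the next, and the terminal segments before the first and
#' after the last footprint are included as candidate gaps. With zero loci
#' the whole genome is one gap.
#'
#' @param loci A `motif_loci` data.frame (all motifs merged).
#' @param genome A `genome_seq`, or `NULL` to use attributes of `loci`.
#' @return A data.frame of `gap_record`s with 0-based half-open columns
#'   `start`, `end`, `length`, sorted by `start`. Zero-length gaps (adjacent
#'   footprints) are omitted.
#' @export
motif_free_gaps <- function(loci, genome = NULL) {
  glen <- if (!is.null(genome)) genome$length else attr(loci, "genome_length")
  if (is.null(glen)) stop("genome length unknown; pass `genome`")
  width <- attr(loci, "motif_width") %||% 4L
  if (nrow(loci) == 0L) {
    return(data.frame(start = 0L, end = glen, length = glen))
  }
  fp <- IRanges::reduce(IRanges::IRanges(start = loci$start + 1L, width = width))
  gaps <- IRanges::gaps(fp, start = 1L, end = glen)
  out <- data.frame(start = BiocGenerics::start(gaps) - 1L,
                    end = BiocGenerics::end(gaps),
                    length = BiocGenerics::width(gaps))
  out <- out[out$length > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Longest motif-free gap
#'
#' @inheritParams motif_free_gaps
#' @return A one-row data.frame (`start`, `end`, `length`) for the longest
#'   gap, with the full gap list sorted by decreasing length attached as
#'   attribute `all_gaps`. Ties broken by leftmost start.
#' @export
longest_motif_free_gap <- function(loci, genome = NULL) {
  gaps <- motif_free_gaps(loci, genome)
  if (nrow(gaps) == 0L) {
    glen <- if (!is.null(genome)) genome$length else attr(loci, "genome_length")
    longest <- data.frame(start = NA_integer_, end = NA_integer_, length = 0L)
    attr(longest, "all_gaps") <- gaps
    return(longest)
  }
  ord <- order(-gaps$length, gaps$start)
  sorted <- gaps[ord, , drop = FALSE]
  rownames(sorted) <- NULL
  longest <- sorted[1L, , drop = FALSE]
  attr(longest, "all_gaps") <- sorted
  longest
}

#' Expected motif recurrence interval under an i.i.d. composition model
#'
#' Under independent bases with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`, a fixed k-mer occurs at a given position with
#' probability equal to the product of its per-base probabilities, and is
#' expected once every `1 / probability` bp. At 40% GC a motif with two
#' strong (G/C) and two weak (A/T) bases such as GATC recurs about every
#' 278 bp (1 / (0.2^2 * 0.3^2)).
#'
#' @param gc_fraction GC content in (0, 1).
#' @param motif Motif string over `{A,C,G,T}`.
#' @return An `expected_frequency_model` list: `p_S`, `p_W`,
#'   `motif_probability`, `expected_interval` (bp).
#' @export
expected_interval <- function(gc_fraction, motif = "GATC") {
  stopifnot(is.numeric(gc_fraction), length(gc_fraction) == 1L)
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}: ", motif)
  p_S <- gc_fraction / 2
  p_W <- (1 - gc_fraction) / 2
  bases <- strsplit(motif, "")[[1]]
  is_S <- bases %in% c("G", "C")
  if (gc_fraction <= 0 && any(is_S)) {
    stop("gc_fraction 0 but motif requires G/C: undefined")
  }
  if (gc_fraction >= 1 && any(!is_S)) {
    stop("gc_fraction 1 but motif requires A/T: undefined")
  }
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction outside [0,1]")
  prob <- prod(ifelse(is_S, p_S, p_W))
  structure(list(
    motif = motif,
    p_S = p_S,
    p_W = p_W,
    motif_probability = prob,
    expected_interval = 1 / prob
  ), class = "expected_frequency_model")
}

#' @export
print.expected_frequency_model <- function(x, ...) {
  cat(sprintf("<expected_frequency_model> %s: p = %.4g, once every %.0f bp\n",
              x$motif, x$motif_probability, x$expected_interval))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
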
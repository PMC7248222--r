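#' Sliding-window motif enrichment (ME score)
#'
#' Slides a window (default 278 bp, the expected motif recurrence interval
#' at 40% GC) along the genome with step 1 and scores each window by fold
#' enrichment: the number of palindromic loci (not strand-sites) whose
#' k-mer lies wholly inside the window, divided by the expected count
#' (default 2: one expected occurrence of each motif per window).
#'
#' @param genome A `genome_seq`.
#' @param loci A `motif_loci` data.frame from [scan_motifs()].
#' @param window Window size in bp; must be at least the motif width.
#' @param expected Expected locus count per window.
#' @return A data.frame with one row per window start: 0-based half-open
#'   `start`, `end`, per-motif counts `n_gatc`, `n_catg` (generic motifs are
#'   summed into `n_gatc` order-free via dedicated columns), and `me`.
#' @export
window_enrichment <- function(genome, loci, window = 278L, expected = 2) {
  stopifnot(inherits(genome, "genome_seq"))
  width <- attr(loci, "motif_width") %||% 4L
  if (window < width) stop("window smaller than motif width")
  if (window > genome$length) stop("window larger than genome")
  glen <- genome$length
  n_win <- glen - window + 1L
  # prefix sums over start-position indicators, one per motif
  count_for <- function(starts) {
    ind <- integer(glen)
    if (length(starts)) {
      tab <- table(starts)
      ind[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    pre <- c(0L, cumsum(ind))
    # starts s .. s + window - width fit wholly; s is 0-based
    s <- 0:(n_win - 1L)
    pre[s + window - width + 2L] - pre[s + 1L]
  }
  n_gatc <- count_for(loci$start[loci$motif == "GATC"])
  n_catg <- count_for(loci$start[loci$motif == "CATG"])
  n_other <- count_for(loci$start[!loci$motif %in% c("GATC", "CATG")])
  total <- n_gatc + n_catg + n_other
  out <- data.frame(
    start = 0:(n_win - 1L),
    end = window:glen,
    n_gatc = n_gatc,
    n_catg = n_catg,
    me = total / expected
  )
  attr(out, "window") <- as.integer(window)
  attr(out, "expected") <- expected
  out
}

#' Merge significant enrichment windows into regions
#'
#' Windows at or above the ME threshold are merged when they overlap; the
#' region score is the maximum member ME and, when `loci` are supplied,
#' per-motif counts are recounted over the merged span. Merging is
#' idempotent: applying it to its own output changes nothing.
#'
#' @param scores Output of [window_enrichment()] (or a previous merge),
#'   sorted by start.
#' @param me_threshold Minimum ME for a window to qualify (default 3.5).
#' @param loci Optional `motif_loci` for recounting within merged spans.
#' @return A `region_report` data.frame (`start`, `end`, `n_gatc`, `n_catg`,
#'   `me`), sorted by ME descending then start; zero rows when nothing
#'   qualifies.
#' @export
merge_significant_windows <- function(scores, me_threshold = 3.5, loci = NULL) {
  keep <- scores[!is.na(scores$me) & scores$me >= me_threshold, , drop = FALSE]
  if (nrow(keep) == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      n_gatc = integer(), n_catg = integer(), me = numeric())
    class(out) <- c("region_report", "data.frame")
    return(out)
  }
  ir <- IRanges::IRanges(start = keep$start + 1L, end = keep$end)
  merged <- IRanges::reduce(ir)
  hit <- IRanges::findOverlaps(ir, merged)
  me_max <- tapply(keep$me[S4Vectors_from(hit)], S4Vectors_to(hit), max)
  out <- data.frame(
    start = BiocGenerics::start(merged) - 1L,
    end = BiocGenerics::end(merged),
    n_gatc = NA_integer_,
    n_catg = NA_integer_,
    me = as.numeric(me_max[as.character(seq_along(merged))])
  )
  width <- attr(loci, "motif_width") %||% 4L
  if (!is.null(loci)) {
    for (i in seq_len(nrow(out))) {
      inside <- loci$start >= out$start[i] & loci$start + width <= out$end[i]
      out$n_gatc[i] <- sum(inside & loci$motif == "GATC")
      out$n_catg[i] <- sum(inside & loci$motif == "CATG")
    }
  } else if (all(c("n_gatc", "n_catg") %in% names(scores))) {
    # carry counts through for already-merged input (idempotence)
    for (i in seq_len(nrow(out))) {
      member <- keep$start >= out$start[i] & keep$end <= out$end[i]
      if (any(member)) {
        best <- which(member)[which.max(keep$me[member])]
        out$n_gatc[i] <- keep$n_gatc[best]
        out$n_catg[i] <- keep$n_catg[best]
      }
    }
  }
  out <- out[order(-out$me, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_report", "data.frame")
  out
}

# helpers to avoid importing S4Vectors wholesale
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

#' Fold-depletion score for motif-free gaps
#'
#' For each motif-free gap the expected number of loci it should contain is
#' `expected * length / window` (default 2 per 278 bp); the fold score is
#' its reciprocal, so `fold < 1` flags depletion. A gap of exactly
#' `window / expected` bp (139 bp at the defaults) scores 1.
#'
#' @param gaps Gap data.frame from [motif_free_gaps()].
#' @param window Window size in bp (default 278).
#' @param expected Expected loci per window (default 2).
#' @return A data.frame with the gap columns plus `expected_in_gap` and
#'   `fold`; zero-length gaps are omitted.
#' @export
depletion_scan <- function(gaps, window = 278, expected = 2) {
  gaps <- gaps[gaps$length > 0L, , drop = FALSE]
  gaps$expected_in_gap <- expected * gaps$length / window
  gaps$fold <- 1 / gaps$expected_in_gap
  rownames(gaps) <- NULL
  gaps
}

#' Read gene annotations from GFF3
#'
#' A slim GFF3 reader for gene features. Malformed lines (fewer than nine
#' tab-separated fields, or non-numeric coordinates) are skipped with a
#' warning rather than aborting the file.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (default `"gene"`).
#' @return A data.frame with columns `gene_id`, `start` (0-based), `end`
#'   (half-open), `strand`, `txn_class`, `annotation`.
#' @export
read_gene_annotations <- function(path, types = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  n_bad <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) { n_bad <- n_bad + 1L; next }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      n_bad <- n_bad + 1L
      next
    }
    if (!f[3] %in% types) next
    attrs <- gff3_attributes(f[9])
    id <- attrs[["ID"]] %||% attrs[["Name"]] %||%
      attrs[["locus_tag"]] %||% attrs[["gene"]] %||% NA_character_
    rows[[i]] <- data.frame(
      gene_id = id,
      start = start - 1L,
      end = end,
      strand = f[7],
      txn_class = attrs[["txn_class"]] %||% attrs[["transcription_class"]] %||%
        NA_character_,
      annotation = attrs[["product"]] %||% attrs[["Note"]] %||% NA_character_
    )
  }
  if (n_bad > 0L) warning(n_bad, " malformed GFF3 line(s) skipped in ", path)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      txn_class = character(), annotation = character())
  }
  rownames(out) <- NULL
  out
}

gff3_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) utils::URLdecode(trimws(paste(p[-1], collapse = "="))))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals
}

#' Annotate enriched regions with overlapping genes
#'
#' Joins each region to every gene it overlaps by at least one bp. Regions
#' may list multiple genes and a gene may recur across regions.
#'
#' @param regions A `region_report` from [merge_significant_windows()].
#' @param genes Gene table from [read_gene_annotations()].
#' @return The region report with added columns `genes`, `classes` and
#'   `annotations` (comma-separated; empty string when no overlap).
#' @export
annotate_regions <- function(regions, genes) {
  regions$genes <- ""
  regions$classes <- ""
  regions$annotations <- ""
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(regions)
  r_ir <- IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  g_ir <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  hits <- IRanges::findOverlaps(r_ir, g_ir)
  for (i in seq_len(nrow(regions))) {
    gi <- S4Vectors_to(hits)[S4Vectors_from(hits) == i]
    if (length(gi)) {
      regions$genes[i] <- paste(genes$gene_id[gi], collapse = ",")
      regions$classes[i] <- paste(genes$txn_class[gi], collapse = ",")
      regions$annotations[i] <- paste(genes$annotation[gi], collapse = ",")
    }
  }
  regions
}

#' Correlation of per-gene motif density with transcription class
#'
#' Computes, per motif, the Pearson correlation between size-normalised
#' per-gene locus counts (loci wholly inside the gene span, divided by gene
#' length) and a numeric transcription-class code. The default ordinal
#' mapping is Early = 0, Early-Late = 1, Late = 2; genes with an unmapped or
#' missing class (e.g. "Unknown") are excluded.
#'
#' @param genes Gene table with `txn_class` (or supply `class_table`).
#' @param loci A `motif_loci` data.frame.
#' @param class_table Optional data.frame (`gene_id`, `txn_class`) overriding
#'   the classes carried in `genes`.
#' @param class_codes Named numeric vector mapping class labels to codes.
#' @return Named numeric vector of Pearson R, one element per motif present
#'   in `loci`. Fewer than three classed genes yields `NA` with a warning.
#' @export
gene_motif_density_correlation <- function(genes, loci, class_table = NULL,
                                           class_codes = c(Early = 0,
                                                           `Early-Late` = 1,
                                                           Late = 2)) {
  if (!is.null(class_table)) {
    genes$txn_class <- class_table$txn_class[
      match(genes$gene_id, class_table$gene_id)]
  }
  genes$code <- unname(class_codes[genes$txn_class])
  genes <- genes[!is.na(genes$code), , drop = FALSE]
  motifs <- sort(unique(loci$motif))
  out <- setNames(rep(NA_real_, length(motifs)), motifs)
  if (nrow(genes) < 3L) {
    warning("fewer than 3 genes with a mapped transcription class; ",
            "correlation undefined")
    return(out)
  }
  width <- attr(loci, "motif_width") %||% 4L
  for (m in motifs) {
    st <- loci$start[loci$motif == m]
    dens <- vapply(seq_len(nrow(genes)), function(i) {
      sum(st >= genes$start[i] & st + width <= genes$end[i]) /
        (genes$end[i] - genes$start[i])
    }, numeric(1))
    if (stats::sd(dens) == 0 || stats::sd(genes$code) == 0) {
      out[m] <- 0
    } else {
      out[m] <- stats::cor(dens, genes$code)
    }
  }
  out
}
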
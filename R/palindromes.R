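#' Classify palindromic loci into two-strand methylation states
#'
#' Applies the conventional 75%-of-reads rule to the cross-replicate mean
#' methylFrac of each strand of a palindrome: *fully methylated* when both
#' strand means strictly exceed the threshold, *hemimethylated* when
#' exactly one does, *stochastic* otherwise. The inequality is strict, so a
#' strand mean of exactly 0.75 does not count as methylated. Loci whose
#' replicate-level fractions are all exactly zero on both strands are
#' additionally flagged stably non-methylated (a subset of stochastic).
#'
#' @param records A `stability_records` data.frame from
#'   [combine_replicates()]; both strand records must exist per locus.
#' @param threshold Per-strand mean-frac threshold (default 0.75).
#' @return A `palindrome_records` data.frame: `locus_id`, `motif`, `start`,
#'   `fwd_mean_frac`, `rev_mean_frac`, `state` (factor: fully_methylated,
#'   hemimethylated, stochastic), `stably_nonmethylated`. State counts are
#'   attached as attribute `state_counts` and always partition the loci.
#' @export
classify_palindromes <- function(records, threshold = 0.75) {
  stopifnot(inherits(records, "stability_records"))
  n_rep <- attr(records, "n_replicates")
  fwd <- records[records$strand == "+", , drop = FALSE]
  rev <- records[records$strand == "-", , drop = FALSE]
  if (!setequal(fwd$locus_id, rev$locus_id) ||
      nrow(fwd) != nrow(rev)) {
    missing_ids <- c(setdiff(fwd$locus_id, rev$locus_id),
                     setdiff(rev$locus_id, fwd$locus_id))
    stop("loci missing a strand record: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  rev <- rev[match(fwd$locus_id, rev$locus_id), , drop = FALSE]
  fwd_hi <- fwd$mean_frac > threshold
  rev_hi <- rev$mean_frac > threshold
  state <- ifelse(fwd_hi & rev_hi, "fully_methylated",
                  ifelse(xor(fwd_hi, rev_hi), "hemimethylated", "stochastic"))
  frac_cols <- paste0("frac_", seq_len(n_rep))
  all_zero <- rowSums(fwd[, frac_cols, drop = FALSE] != 0) == 0 &
    rowSums(rev[, frac_cols, drop = FALSE] != 0) == 0
  out <- data.frame(
    locus_id = fwd$locus_id,
    motif = fwd$motif,
    start = fwd$start,
    fwd_mean_frac = fwd$mean_frac,
    rev_mean_frac = rev$mean_frac,
    state = factor(state, levels = c("fully_methylated", "hemimethylated",
                                     "stochastic")),
    stably_nonmethylated = all_zero
  )
  out <- out[order(out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "state_counts") <- table(out$state)
  class(out) <- c("palindrome_records", "data.frame")
  out
}

#' State counts and fractions of a palindrome classification
#'
#' @param palindromes A `palindrome_records` data.frame.
#' @return A list with `counts`, `fractions` and `total` over the three
#'   two-strand states.
#' @export
palindrome_state_summary <- function(palindromes) {
  counts <- table(palindromes$state)
  list(counts = counts,
       fractions = counts / nrow(palindromes),
       total = nrow(palindromes))
}

#' Stably non-methylated palindromes
#'
#' Loci with zero methylated reads on both strands in every replicate —
#' the strongest possible non-methylation signal, and in a genome under an
#' active restriction-modification system a short and biologically
#' interesting list.
#'
#' @param palindromes A `palindrome_records` data.frame.
#' @return The subset of rows with `stably_nonmethylated == TRUE`.
#' @export
stably_nonmethylated_loci <- function(palindromes) {
  out <- palindromes[palindromes$stably_nonmethylated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene palindrome methylation report
#'
#' Lists, for each requested gene, the palindromic loci whose k-mer lies
#' wholly within the gene span (a motif straddling a gene boundary is not
#' "within" the gene), with both strand means and the two-strand state,
#' ordered by position.
#'
#' @param palindromes A `palindrome_records` data.frame.
#' @param genes Gene table from [read_gene_annotations()].
#' @param gene_ids Genes to report; unknown ids raise an error listing the
#'   known ones.
#' @param motif_width Motif width in bp (default 4).
#' @return A data.frame: `gene_id`, `locus_id`, `motif`, `start`,
#'   `fwd_mean_frac`, `rev_mean_frac`, `state`. A gene containing no locus
#'   contributes no rows (not an error).
#' @export
gene_palindrome_report <- function(palindromes, genes, gene_ids,
                                   motif_width = 4L) {
  unknown <- setdiff(gene_ids, genes$gene_id)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         "; known ids: ", paste(genes$gene_id, collapse = ", "))
  }
  rows <- lapply(gene_ids, function(gid) {
    g <- genes[genes$gene_id == gid, , drop = FALSE][1L, ]
    inside <- palindromes$start >= g$start &
      palindromes$start + motif_width <= g$end
    sub <- palindromes[inside, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(gene_id = gid,
               sub[order(sub$start),
                   c("locus_id", "motif", "start", "fwd_mean_frac",
                     "rev_mean_frac", "state")])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), locus_id = integer(),
                      motif = character(), start = integer(),
                      fwd_mean_frac = numeric(), rev_mean_frac = numeric(),
                      state = character())
  }
  rownames(out) <- NULL
  out
}
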
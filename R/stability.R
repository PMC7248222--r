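#' Combine replicate methylFrac values per motif strand-site
#'
#' For every strand-site (two per palindromic locus) the methylated-read
#' fraction is looked up in each replicate at the site's target adenine.
#' A site with no call in a replicate contributes a fraction of 0 for that
#' replicate: at this stage, absence of a modification call is evidence of
#' non-methylation (the per-position table covers the whole genome). The
#' cross-replicate mean and population standard deviation are computed, and
#' each site is binarised per replicate at `binarize` (a fraction of exactly
#' 0.5 counts as methylated); the count `k` of methylated replicates maps
#' bijectively to the stability class.
#'
#' @param replicates List of `mod_set` objects (at least two, same genome
#'   length where known).
#' @param loci A `motif_loci` data.frame.
#' @param binarize Per-replicate binarisation threshold (default 0.5).
#' @return A `stability_records` data.frame with one row per strand-site:
#'   `locus_id`, `motif`, `start`, `strand`, `frac_1..frac_n`, `mean_frac`,
#'   `sd_frac`, `k_methylated`, `stability_class`. The number of replicates
#'   is stored in attribute `n_replicates`.
#' @export
combine_replicates <- function(replicates, loci, binarize = 0.5) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  lens <- vapply(replicates, function(r) r$genome_length, integer(1))
  lens <- lens[!is.na(lens)]
  if (length(unique(lens)) > 1L) {
    stop("replicate genome lengths differ: ", paste(unique(lens), collapse = ", "))
  }
  sites <- strand_sites(loci)
  n_rep <- length(replicates)
  fr <- matrix(0, nrow = nrow(sites), ncol = n_rep)
  site_key <- paste(sites$adenine_pos, sites$strand)
  for (j in seq_len(n_rep)) {
    calls <- replicates[[j]]$calls
    idx <- match(site_key, paste(calls$position, calls$strand))
    f <- calls$methyl_frac[idx]
    f[is.na(f)] <- 0  # absent call or absent frac => non-methylated here
    fr[, j] <- f
  }
  colnames(fr) <- paste0("frac_", seq_len(n_rep))
  mean_frac <- rowMeans(fr)
  sd_frac <- sqrt(rowMeans((fr - mean_frac)^2))  # population SD
  k <- as.integer(rowSums(fr >= binarize))
  out <- cbind(sites[, c("locus_id", "motif", "start", "strand")],
               as.data.frame(fr),
               data.frame(mean_frac = mean_frac, sd_frac = sd_frac,
                          k_methylated = k,
                          stability_class = stability_class_label(k, n_rep)))
  out <- out[order(out$locus_id, out$strand == "-"), , drop = FALSE]  # + first
  rownames(out) <- NULL
  attr(out, "n_replicates") <- n_rep
  attr(out, "binarize") <- binarize
  class(out) <- c("stability_records", "data.frame")
  out
}

stability_class_levels <- function(n_rep) {
  if (n_rep == 3L) {
    c("stable_nonmethylated", "methylated_in_one", "methylated_in_two",
      "stable_methylated")
  } else {
    c("stable_nonmethylated",
      paste0("methylated_in_", seq_len(n_rep - 1L)),
      "stable_methylated")
  }
}

stability_class_label <- function(k, n_rep) {
  factor(stability_class_levels(n_rep)[k + 1L],
         levels = stability_class_levels(n_rep))
}

#' Summarise stability classes over all strand-sites
#'
#' @param records A `stability_records` data.frame from
#'   [combine_replicates()].
#' @return A `stability_summary` list: per-class `counts` and `fractions`
#'   (ordered stable_methylated first), `variably_methylated_fraction`
#'   (sites methylated in some but not all replicates), and
#'   `motif_composition` (per class, percentage of each motif).
#' @export
classify_stability <- function(records) {
  stopifnot(inherits(records, "stability_records"))
  n_rep <- attr(records, "n_replicates")
  lv <- rev(stability_class_levels(n_rep))  # stable_methylated first
  cls <- factor(as.character(records$stability_class), levels = lv)
  counts <- table(cls)
  total <- nrow(records)
  fractions <- counts / total
  variably <- sum(records$k_methylated > 0L & records$k_methylated < n_rep) / total
  comp <- lapply(lv, function(l) {
    sub <- records$motif[cls == l]
    if (!length(sub)) return(setNames(numeric(0), character(0)))
    100 * table(sub) / length(sub)
  })
  names(comp) <- lv
  structure(list(
    counts = counts,
    fractions = fractions,
    total = total,
    variably_methylated_fraction = variably,
    motif_composition = comp
  ), class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat("<stability_summary>", x$total, "strand-sites\n")
  for (l in names(x$counts)) {
    cat(sprintf("  %-22s %5d (%.1f%%)\n", l, x$counts[[l]],
                100 * x$fractions[[l]]))
  }
  cat(sprintf("  variably methylated: %.1f%%\n",
              100 * x$variably_methylated_fraction))
  invisible(x)
}

#' Class fractions from printed class counts
#'
#' Convenience for cross-checking published per-class counts: converts a
#' vector of counts to percentages of their total, rounded to one decimal.
#'
#' @param counts Numeric vector of class counts.
#' @return Percentages (one decimal place), same names as `counts`.
#' @export
class_percentages <- function(counts) {
  round(100 * counts / sum(counts), 1)
}

#' Export the per-site stability table
#'
#' Writes the per-strand-site mean/SD scatter that underlies the standard
#' stability plot (mean methylFrac vs cross-replicate SD), ordered by
#' `(locus_id, strand)` with `+` before `-`.
#'
#' @param records A `stability_records` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_stability_table <- function(records, path) {
  stopifnot(inherits(records, "stability_records"))
  cols <- c("locus_id", "strand", "mean_frac", "sd_frac", "motif",
            "stability_class")
  out <- records[order(records$locus_id, records$strand == "-"), cols,
                 drop = FALSE]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
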
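#' Construct a replicate modification-call set
#'
#' Container for one sequencing replicate's per-site base-modification
#' evidence: a table keyed by `(position, strand)` holding ipdRatio,
#' Phred-scaled ModificationQV, read coverage and (when estimated) the
#' methylated-read fraction with its 95% CI.
#'
#' @param calls data.frame with columns `position` (0-based forward-strand
#'   coordinate), `strand` (`+`/`-`), `base`, `ipd_ratio`, `mod_qv`,
#'   `coverage`, `methyl_frac`, `frac_low`, `frac_up`, `mod_type`.
#'   Missing optional columns are filled with `NA`.
#' @param replicate_id Identifier for the replicate.
#' @param genome_length Genome length in bp, or `NA` if unknown.
#' @param ref_id Reference sequence name (used when writing files).
#' @return A `mod_set` object.
#' @export
mod_set <- function(calls, replicate_id = "rep", genome_length = NA_integer_,
                    ref_id = "ref") {
  na_like <- list(
    position = NA_integer_, strand = NA_character_, base = NA_character_,
    ipd_ratio = NA_real_, mod_qv = NA_real_, coverage = NA_integer_,
    methyl_frac = NA_real_, frac_low = NA_real_, frac_up = NA_real_,
    mod_type = NA_character_
  )
  calls <- as.data.frame(calls)
  for (col in names(na_like)) {
    if (!col %in% names(calls)) calls[[col]] <- rep(na_like[[col]], nrow(calls))
  }
  calls <- calls[, names(na_like), drop = FALSE]
  key <- paste(calls$position, calls$strand)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (position, strand) key in call set: ", dup)
  }
  if (!is.na(genome_length) && nrow(calls) > 0 &&
      any(calls$position < 0L | calls$position >= genome_length)) {
    stop("call positions outside [0, genome_length)")
  }
  structure(list(replicate_id = replicate_id,
                 calls = calls,
                 genome_length = as.integer(genome_length),
                 ref_id = ref_id),
            class = "mod_set")
}

#' @export
print.mod_set <- function(x, ...) {
  cat(sprintf("<mod_set> %s: %d strand-position calls, genome %s bp\n",
              x$replicate_id, nrow(x$calls),
              ifelse(is.na(x$genome_length), "?",
                     format(x$genome_length, big.mark = ","))))
  invisible(x)
}

#' Read a PacBio-style modifications GFF3 file
#'
#' Parses the base-modification GFF3 dialect written by SMRT kinetics
#' software: one feature per called strand-position, type `m6A`, `m4C` or
#' `modified_base`, score column carrying the ModificationQV, and
#' `coverage`, `context`, `IPDRatio`, `frac`, `fracLow`, `fracUp`
#' attributes (the `frac*` trio is optional and is preserved as missing,
#' never invented as 0). Coordinates are converted from 1-based inclusive
#' to 0-based. Unknown feature types are kept as `modified_base` with a
#' warning; lines with bad coordinates are rejected with a warning.
#'
#' @param path Path to the GFF3 file.
#' @param replicate_id Replicate identifier (default: file basename).
#' @param genome_length Optional genome length for validation.
#' @return A `mod_set`.
#' @export
read_modifications_gff <- function(path, replicate_id = NULL,
                                   genome_length = NA_integer_) {
  if (!file.exists(path)) stop("modifications GFF not found: ", path)
  replicate_id <- replicate_id %||% sub("\\.gff3?$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  known <- c("m6A", "m4C", "modified_base")
  n_bad <- 0L; n_unknown <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) { n_bad <- n_bad + 1L; next }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      n_bad <- n_bad + 1L; next
    }
    type <- f[3]
    if (!type %in% known) { n_unknown <- n_unknown + 1L; type <- "modified_base" }
    attrs <- gff3_attributes(f[9])
    ctx <- attrs[["context"]]
    rows[[i]] <- data.frame(
      position = start - 1L,
      strand = f[7],
      base = if (!is.null(ctx)) substr(ctx, (nchar(ctx) + 1L) %/% 2L,
                                       (nchar(ctx) + 1L) %/% 2L)
             else if (type == "m6A") "A" else NA_character_,
      ipd_ratio = as.numeric(attrs[["IPDRatio"]] %||% NA),
      mod_qv = suppressWarnings(as.numeric(f[6])),
      coverage = as.integer(attrs[["coverage"]] %||% NA),
      methyl_frac = as.numeric(attrs[["frac"]] %||% NA),
      frac_low = as.numeric(attrs[["fracLow"]] %||% NA),
      frac_up = as.numeric(attrs[["fracUp"]] %||% NA),
      mod_type = type
    )
  }
  if (n_bad > 0L) warning(n_bad, " line(s) with bad coordinates rejected in ", path)
  if (n_unknown > 0L) warning(n_unknown, " feature(s) of unknown type kept as modified_base in ", path)
  kept <- rows[!vapply(rows, is.null, logical(1))]
  calls <- do.call(rbind, kept)
  ref_id <- if (length(kept)) {
    strsplit(lines[which(!vapply(rows, is.null, logical(1)))[1]], "\t")[[1]][1]
  } else "ref"
  if (is.null(calls)) calls <- data.frame()
  mod_set(calls, replicate_id, genome_length, ref_id = ref_id)
}

csv_required_cols <- c("refName", "tpl", "strand", "base", "score",
                       "ipdRatio", "coverage")

#' Read a PacBio-style per-position modifications CSV
#'
#' Parses the per-strand-position kinetics table: columns `refName`, `tpl`
#' (1-based template position), `strand` (0 = forward, 1 = reverse),
#' `base`, `score` (ModificationQV), `ipdRatio` and `coverage`. Unlike the
#' GFF, the CSV covers every strand-position, called or not. Duplicate
#' `(tpl, strand)` rows are rejected.
#'
#' @inheritParams read_modifications_gff
#' @return A `mod_set` (no `methyl_frac`: the CSV does not estimate it).
#' @export
read_modifications_csv <- function(path, replicate_id = NULL,
                                   genome_length = NA_integer_) {
  if (!file.exists(path)) stop("modifications CSV not found: ", path)
  replicate_id <- replicate_id %||% sub("\\.csv$", "", basename(path))
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = "refName"))
  missing_cols <- setdiff(csv_required_cols, names(dt))
  if (length(missing_cols)) {
    stop("CSV header mismatch in ", path, ": missing {",
         paste(missing_cols, collapse = ", "), "}; found {",
         paste(names(dt), collapse = ", "), "}")
  }
  calls <- data.frame(
    position = as.integer(dt$tpl) - 1L,
    strand = ifelse(dt$strand == 0L, "+", "-"),
    base = as.character(dt$base),
    ipd_ratio = as.numeric(dt$ipdRatio),
    mod_qv = as.numeric(dt$score),
    coverage = as.integer(dt$coverage),
    mod_type = "none"
  )
  mod_set(calls, replicate_id, genome_length,
          ref_id = if (nrow(dt)) as.character(dt$refName[1]) else "ref")
}

#' Combine GFF calls with per-position CSV kinetics for one replicate
#'
#' The CSV supplies ipdRatio/coverage for every strand-position; the GFF
#' overlays ModificationQV, methylated-read fraction and modification type
#' at the subset of called positions. GFF-only positions (absent from the
#' CSV) are appended.
#'
#' @param gff,csv `mod_set` objects for the same replicate, either `NULL`.
#' @return A merged `mod_set`.
#' @export
merge_mod_sets <- function(gff = NULL, csv = NULL) {
  if (is.null(csv)) return(gff)
  if (is.null(gff)) return(csv)
  glen <- csv$genome_length
  if (is.na(glen)) glen <- gff$genome_length
  out <- csv$calls
  key_out <- paste(out$position, out$strand)
  key_gff <- paste(gff$calls$position, gff$calls$strand)
  idx <- match(key_gff, key_out)
  hit <- !is.na(idx)
  for (col in c("mod_qv", "methyl_frac", "frac_low", "frac_up", "mod_type")) {
    out[[col]][idx[hit]] <- gff$calls[[col]][hit]
  }
  if (any(!hit)) out <- rbind(out, gff$calls[!hit, names(out), drop = FALSE])
  mod_set(out, csv$replicate_id, glen, ref_id = csv$ref_id %||% gff$ref_id)
}

#' Genome-wide high-ipdRatio summary
#'
#' Counts strand-positions whose ipdRatio strictly exceeds the threshold
#' (default 2, the conventional modification-evidence cut) and expresses
#' them as a fraction of all `2 * genome_length` strand-positions. When
#' `loci` are supplied the count is also expressed as a fold excess over
#' the motif target adenines (one per strand-site).
#'
#' @param modset A `mod_set` with per-position ipdRatio (CSV-sourced).
#' @param threshold ipdRatio threshold; strictly greater-than counts.
#' @param loci Optional `motif_loci` for the fold-excess denominator.
#' @return A `mod_summary` list: `high_ipd_count`, `strand_positions`,
#'   `high_ipd_fraction`, `motif_adenine_count`, `fold_excess`.
#' @export
high_ipd_summary <- function(modset, threshold = 2, loci = NULL) {
  stopifnot(inherits(modset, "mod_set"))
  if (is.na(modset$genome_length)) {
    stop("genome_length unknown; high-ipd fraction undefined")
  }
  n_high <- sum(modset$calls$ipd_ratio > threshold, na.rm = TRUE)
  strand_positions <- 2L * modset$genome_length
  n_motif_a <- if (!is.null(loci)) nrow(strand_sites(loci)) else NA_integer_
  structure(list(
    high_ipd_count = n_high,
    strand_positions = strand_positions,
    high_ipd_fraction = n_high / strand_positions,
    motif_adenine_count = n_motif_a,
    fold_excess = if (!is.null(loci)) fold_excess(n_high, n_motif_a) else NA_real_
  ), class = "mod_summary")
}

#' @export
print.mod_summary <- function(x, ...) {
  cat(sprintf("<mod_summary> %s strand-positions with ipdRatio above threshold (%.1f%% of genome, both strands)\n",
              format(x$high_ipd_count, big.mark = ","),
              100 * x$high_ipd_fraction))
  if (!is.na(x$fold_excess)) {
    cat(sprintf("  %.1fx more than the %s motif target adenines\n",
                x$fold_excess, format(x$motif_adenine_count, big.mark = ",")))
  }
  invisible(x)
}

#' Fold excess of high-ipdRatio sites over motif adenines
#'
#' @param high_count Number of strand-positions above the ipdRatio cut.
#' @param motif_adenine_count Number of motif target adenines (strand-sites).
#' @return The ratio; `NA` when the denominator is zero (undefined).
#' @export
fold_excess <- function(high_count, motif_adenine_count) {
  if (is.na(motif_adenine_count) || motif_adenine_count == 0) return(NA_real_)
  high_count / motif_adenine_count
}

#' Convert between ModificationQV and p-value
#'
#' ModificationQV is Phred-scaled: `QV = -10 * log10(p)`, so the default
#' calling threshold of QV 30 corresponds to p = 0.001.
#'
#' @param qv Phred-scaled quality, `>= 0`.
#' @return `qv_to_pvalue`: the p-value `10^(-qv / 10)`.
#' @export
qv_to_pvalue <- function(qv) {
  stopifnot(all(qv >= 0))
  10^(-qv / 10)
}

#' @rdname qv_to_pvalue
#' @param p p-value in (0, 1].
#' @return `pvalue_to_qv`: the Phred-scaled quality `-10 * log10(p)`.
#' @export
pvalue_to_qv <- function(p) {
  if (any(p <= 0)) stop("p-value must be positive")
  stopifnot(all(p <= 1))
  -10 * log10(p)
}

#' Per-motif methylation call fractions at a QV threshold
#'
#' A motif strand-site is called methylated when a modification call exists
#' at its target adenine (same strand) with ModificationQV at or above the
#' threshold. Calls at non-adenine motif bases never count. Returns the
#' called fraction per motif and, when a genome is supplied, the percentage
#' of the total adenine pool (forward A count + forward T count, i.e. one
#' adenine per strand-position pair) that is methylated.
#'
#' @param modset A `mod_set` carrying `mod_qv` at called positions.
#' @param loci A `motif_loci` data.frame.
#' @param qv_threshold Minimum ModificationQV (default 30, p = 0.001).
#' @param genome Optional `genome_seq` for the adenine-pool denominator.
#' @return A list: `per_site` (strand-site table with logical `methylated`),
#'   `fraction_by_motif` (named), `n_methylated`, `pct_adenines_methylated`.
#' @export
motif_methylation_calls <- function(modset, loci, qv_threshold = 30,
                                    genome = NULL) {
  sites <- strand_sites(loci)
  if (!is.na(modset$genome_length) && nrow(sites) > 0 &&
      any(sites$adenine_pos >= modset$genome_length)) {
    stop("locus adenine position outside the modification set's genome")
  }
  calls <- modset$calls
  ok <- !is.na(calls$mod_qv) & calls$mod_qv >= qv_threshold &
    (is.na(calls$base) | calls$base == "A")
  key_called <- paste(calls$position[ok], calls$strand[ok])
  sites$methylated <- paste(sites$adenine_pos, sites$strand) %in% key_called
  frac <- tapply(sites$methylated, sites$motif, mean)
  pct_adenines <- NA_real_
  if (!is.null(genome)) {
    pool <- genome$a_count_fwd + genome$t_count_fwd
    pct_adenines <- 100 * sum(sites$methylated) / pool
  }
  list(per_site = sites,
       fraction_by_motif = frac[sort(names(frac))],
       n_methylated = sum(sites$methylated),
       pct_adenines_methylated = pct_adenines)
}
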
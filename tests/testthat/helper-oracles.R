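# Independent oracles and fixture builders shared across test files.

# Naive position-by-position motif scan, independent of scan_motifs():
# returns sorted 0-based starts of every occurrence of `motif` in `seq`.
brute_force_starts <- function(seq, motif) {
  n <- nchar(seq)
  k <- nchar(motif)
  if (n < k) return(integer())
  starts <- 1:(n - k + 1)
  which(substring(seq, starts, starts + k - 1) == motif) - 1L
}

# Pearson correlation from raw sums (textbook formula), independent of cor().
pearson_from_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Random {A,C,G,T} sequence (test-local, independent of simulate_genome()).
random_seq <- function(n, gc = 0.4) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# Hand-built motif_loci table for fixtures where the sequence is irrelevant.
toy_loci <- function(starts, motifs = "GATC", genome_length = NULL) {
  loci <- data.frame(locus_id = seq_along(starts),
                     motif = rep_len(motifs, length(starts)),
                     start = as.integer(starts))
  attr(loci, "genome_length") <- genome_length
  attr(loci, "motif_width") <- 4L
  class(loci) <- c("motif_loci", "data.frame")
  loci
}

# Minimal mod_set carrying methyl_frac/mod_qv at given strand-positions.
toy_mod_set <- function(position, strand, methyl_frac = NA_real_,
                        mod_qv = 40, base = "A", ipd_ratio = 4,
                        coverage = 30, genome_length = NA_integer_,
                        replicate_id = "toy") {
  mod_set(data.frame(position = as.integer(position), strand = strand,
                     base = base, ipd_ratio = ipd_ratio,
                     mod_qv = as.numeric(mod_qv),
                     coverage = as.integer(coverage),
                     methyl_frac = methyl_frac,
                     mod_type = ifelse(mod_qv >= 30, "m6A", "none")),
          replicate_id = replicate_id, genome_length = genome_length)
}

# Replicate set in which each strand-site i has the given frac per replicate.
# fracs: matrix with one row per strand-site (ordered as strand_sites(loci)).
mod_sets_from_fracs <- function(loci, fracs, genome_length = 10000L) {
  sites <- strand_sites(loci)
  lapply(seq_len(ncol(fracs)), function(j) {
    toy_mod_set(sites$adenine_pos, sites$strand,
                methyl_frac = fracs[, j],
                genome_length = genome_length,
                replicate_id = paste0("rep", j))
  })
}

# Three-gene toy annotation GFF3 written to a temp file.
write_toy_gff3 <- function(path, genes) {
  lines <- c("##gff-version 3",
             sprintf("toy\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s;txn_class=%s",
                     genes$start + 1L, genes$end, genes$gene_id,
                     genes$txn_class))
  writeLines(lines, path)
  path
}
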
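#' Simulation configuration for the synthetic methylome generator
#'
#' Bundles and validates every knob of the synthetic world. The defaults
#' describe a PBCV-1-like chlorovirus genome and its m6A landscape: a
#' 330,611 bp genome at 40% GC; three biological replicates at 30-fold
#' coverage; palindrome two-strand states drawn with probabilities
#' (fully 0.619, hemi 0.31, stochastic 0.071); strand-site stability
#' classes (for strand-level planting) at (k=3: 0.807, k=2: 0.131,
#' k=1: 0.041, k=0: 0.021); per-read methylation probabilities 0.97 for a
#' methylated strand-site and 0.02 for a non-methylated one; and a 9%
#' background rate of spuriously high ipdRatio at non-motif positions.
#'
#' @param genome_length Genome length in bp.
#' @param gc GC fraction of the i.i.d. composition model.
#' @param seed Integer seed; every stochastic step derives from it.
#' @param n_replicates Number of biological replicates.
#' @param coverage Reads per strand-position.
#' @param palindrome_state_proportions Named numeric (fully, hemi,
#'   stochastic), summing to 1.
#' @param strand_stability_proportions Numeric of length `n_replicates + 1`
#'   for k = n..0 methylated replicates, summing to 1.
#' @param pi_meth,pi_un Per-read methylation probability for methylated /
#'   non-methylated latent states; `0 <= pi_un < pi_meth <= 1`.
#' @param background_high_ipd_prob Probability that a non-motif
#'   strand-position shows ipdRatio in (2, 6) by chance.
#' @param planted_gap_length,planted_gap_start Optional motif-free gap to
#'   plant (0-based start of the gap interior).
#' @param planted_window Optional list `(start, k)`: plant `k` loci within a
#'   `window_size` window starting there.
#' @param window_size Window for the planted enrichment feature (bp).
#' @param qv_meth_offset,qv_meth_geom_prob ModificationQV of a methylated
#'   draw is `offset + Geometric(prob)`; offset 30 guarantees the call
#'   clears the default threshold.
#' @param qv_un_max Non-methylated QV is uniform on `0..qv_un_max`.
#' @param ipd_meth_mean,ipd_meth_sd Methylated ipdRatio is Normal, truncated
#'   below at 2.
#' @param ipd_bg_mean,ipd_bg_sd Background ipdRatio is Normal, truncated
#'   below at 0.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(genome_length = 330611L,
                              gc = 0.4,
                              seed = 1L,
                              n_replicates = 3L,
                              coverage = 30L,
                              palindrome_state_proportions =
                                c(fully = 0.619, hemi = 0.31, stochastic = 0.071),
                              strand_stability_proportions =
                                c(0.807, 0.131, 0.041, 0.021),
                              pi_meth = 0.97,
                              pi_un = 0.02,
                              background_high_ipd_prob = 0.09,
                              planted_gap_length = NULL,
                              planted_gap_start = 62000L,
                              planted_window = NULL,
                              window_size = 278L,
                              qv_meth_offset = 30L,
                              qv_meth_geom_prob = 0.1,
                              qv_un_max = 20L,
                              ipd_meth_mean = 4.0,
                              ipd_meth_sd = 0.8,
                              ipd_bg_mean = 1.0,
                              ipd_bg_sd = 0.25) {
  stopifnot(genome_length > 0, gc >= 0, gc <= 1,
            n_replicates >= 2L, coverage >= 1L)
  if (abs(sum(palindrome_state_proportions) - 1) > 1e-9) {
    stop("palindrome_state_proportions must sum to 1")
  }
  if (length(strand_stability_proportions) != n_replicates + 1L) {
    stop("strand_stability_proportions needs length n_replicates + 1 (k = n..0)")
  }
  if (abs(sum(strand_stability_proportions) - 1) > 1e-9) {
    stop("strand_stability_proportions must sum to 1")
  }
  if (!(pi_un >= 0 && pi_un < pi_meth && pi_meth <= 1)) {
    stop("need 0 <= pi_un < pi_meth <= 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# positions (0-based starts) of any motif occurrence within chars[lo:hi] (1-based)
find_motif_starts <- function(chars, lo, hi, motifs = c("GATC", "CATG")) {
  lo <- max(1L, lo); hi <- min(length(chars), hi)
  if (hi - lo + 1L < 4L) return(integer())
  s <- paste(chars[lo:hi], collapse = "")
  starts <- integer()
  for (m in motifs) {
    p <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
    if (p[1] != -1L) starts <- c(starts, lo - 1L + p - 1L)  # to 0-based abs
  }
  sort(starts)
}

# destroy motif occurrences by setting their middle two bases to "AA";
# neither GATC nor CATG contains "AA", starts with A or ends with A, so the
# patch cannot seed a new occurrence, and occurrences overlapping a kept
# motif by <= 1 base have their middle bases outside it.
scrub_motifs <- function(chars, lo, hi, keep_starts = integer()) {
  repeat {
    found <- setdiff(find_motif_starts(chars, lo, hi), keep_starts)
    if (!length(found)) break
    for (p in found) chars[(p + 2L):(p + 3L)] <- "A"
  }
  chars
}

#' Simulate a genome with optional planted motif landscape features
#'
#' Draws an i.i.d. base sequence with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`, then optionally plants (i) a motif-free gap
#' of exactly the requested length, delimited by anchor motifs and scrubbed
#' of interior GATC/CATG occurrences, and (ii) an enriched window holding
#' exactly `k` evenly spaced loci. Deterministic under the seed.
#'
#' @param config A `sim_config` (see [simulation_config()]).
#' @param seed Seed override (default `config$seed`).
#' @return A list: `genome` (a `genome_seq` with id
#'   `"synthetic_<seed>"`), `truth` (planted gap/window coordinates).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  L <- config$genome_length
  p <- c(G = config$gc / 2, C = config$gc / 2,
         A = (1 - config$gc) / 2, T = (1 - config$gc) / 2)
  chars <- sample(names(p), L, replace = TRUE, prob = p)
  truth <- list(gap = NULL, window = NULL)

  if (!is.null(config$planted_gap_length)) {
    len <- as.integer(config$planted_gap_length)
    g0 <- as.integer(config$planted_gap_start)
    if (g0 < 4L || g0 + len + 4L > L) {
      stop("planted gap [", g0, ", ", g0 + len, ") + anchors exceeds genome")
    }
    chars[(g0 - 3L):g0] <- c("G", "A", "T", "C")           # anchor ends at g0
    chars[(g0 + len + 1L):(g0 + len + 4L)] <- c("C", "A", "T", "G")
    chars <- scrub_motifs(chars, g0 - 7L, g0 + len + 8L,
                          keep_starts = c(g0 - 4L, g0 + len))
    truth$gap <- list(start = g0, end = g0 + len, length = len)
  }

  if (!is.null(config$planted_window)) {
    w0 <- as.integer(config$planted_window$start)
    k <- as.integer(config$planted_window$k)
    w <- as.integer(config$window_size)
    if (w0 < 0L || w0 + w > L) stop("planted window exceeds genome")
    if (k > (w - 4L) %/% 4L + 1L) stop("cannot fit ", k, " loci in ", w, " bp")
    offs <- if (k == 1L) (w - 4L) %/% 2L
            else floor((w - 4L) * (seq_len(k) - 1L) / (k - 1L))
    planted <- w0 + as.integer(offs)
    motifs <- rep(c("GATC", "CATG"), length.out = k)
    chars <- scrub_motifs(chars, w0 - 3L, w0 + w + 3L)  # clear first
    for (i in seq_len(k)) {
      chars[(planted[i] + 1L):(planted[i] + 4L)] <- strsplit(motifs[i], "")[[1]]
    }
    chars <- scrub_motifs(chars, w0 - 3L, w0 + w + 3L, keep_starts = planted)
    truth$window <- list(start = w0, end = w0 + w, k = k,
                         planted_starts = planted, motifs = motifs)
  }

  genome <- genome_seq(paste0("synthetic_", seed), paste(chars, collapse = ""))
  list(genome = genome, truth = truth)
}

rtnorm_lower <- function(n, mean, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate replicate modification-call sets with planted ground truth
#'
#' Assigns a latent per-replicate methylation indicator to every motif
#' strand-site, then emits per-site evidence under a binomial read-sampling
#' model: `methylFrac ~ Binomial(coverage, pi) / coverage` with
#' `pi = pi_meth` or `pi_un` by the latent state; ModificationQV is
#' `30 + Geometric` jitter for methylated draws (always callable) and
#' uniform on 0..20 otherwise; ipdRatio is drawn from the methylated or
#' background truncated normal. Two planting modes are supported:
#'
#' * `"locus"` (default, the palindrome-state model): each locus draws
#'   fully/hemi/stochastic; fully methylates both strands in all
#'   replicates, hemi methylates one strand (chosen at random) in all
#'   replicates, stochastic flips a fair coin per strand-site and
#'   replicate.
#' * `"strand"`: each strand-site draws its stability class directly from
#'   `strand_stability_proportions` (k methylated replicates, chosen
#'   uniformly).
#'
#' With `background = TRUE`, every non-motif strand-position also receives
#' a row (high ipdRatio, uniform in (2, 6), with probability
#' `background_high_ipd_prob`), emulating the full per-position kinetics
#' CSV.
#'
#' @param genome A `genome_seq` (normally from [simulate_genome()]).
#' @param loci `motif_loci` scanned from that genome.
#' @param config A `sim_config`.
#' @param mode Planting mode, `"locus"` or `"strand"`.
#' @param background Emit non-motif strand-positions too (costly; off by
#'   default).
#' @param seed Seed override (default `config$seed + 1`, so genome and
#'   replicate draws are decoupled but both derive from the config seed).
#' @return A `methylome_sim` list: `replicates` (list of `mod_set`),
#'   `truth` (`sites`: per strand-site drawn/latent classes; `loci`:
#'   per-locus drawn and realized palindrome states), `config`, `mode`.
#' @export
simulate_replicates <- function(genome, loci, config,
                                mode = c("locus", "strand"),
                                background = FALSE,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (config$coverage < 1L) stop("coverage must be positive")
  set.seed(seed)
  sites <- strand_sites(loci)
  n_sites <- nrow(sites)
  n_rep <- config$n_replicates
  n_loci <- nrow(loci)

  latent <- matrix(0L, n_sites, n_rep)
  drawn_locus_state <- rep(NA_character_, n_loci)
  drawn_site_k <- rep(NA_integer_, n_sites)
  if (mode == "locus") {
    drawn_locus_state <- sample(names(config$palindrome_state_proportions),
                                n_loci, replace = TRUE,
                                prob = config$palindrome_state_proportions)
    hemi_strand <- sample(c("+", "-"), n_loci, replace = TRUE)
    # strand_sites() emits the two strands of locus i as rows 2i-1, 2i
    state_site <- rep(drawn_locus_state, each = 2L)
    hemi_meth <- rep(hemi_strand, each = 2L) == sites$strand
    latent[state_site == "fully", ] <- 1L
    latent[state_site == "hemi" & hemi_meth, ] <- 1L
    sto <- state_site == "stochastic"
    latent[sto, ] <- matrix(stats::rbinom(sum(sto) * n_rep, 1L, 0.5),
                            nrow = sum(sto))
  } else {
    drawn_site_k <- sample(n_rep:0, n_sites, replace = TRUE,
                           prob = config$strand_stability_proportions)
    for (i in seq_len(n_sites)) {
      if (drawn_site_k[i] > 0L) {
        latent[i, sample.int(n_rep, drawn_site_k[i])] <- 1L
      }
    }
  }

  cov <- config$coverage
  replicates <- vector("list", n_rep)
  for (j in seq_len(n_rep)) {
    meth <- latent[, j] == 1L
    pi <- ifelse(meth, config$pi_meth, config$pi_un)
    frac <- stats::rbinom(n_sites, cov, pi) / cov
    frac <- as.numeric(sprintf("%.4f", frac))
    half <- 1.96 * sqrt(pmax(frac * (1 - frac), 0) / cov)
    qv <- ifelse(meth,
                 config$qv_meth_offset +
                   stats::rgeom(n_sites, config$qv_meth_geom_prob),
                 sample(0:config$qv_un_max, n_sites, replace = TRUE))
    ipd <- ifelse(meth,
                  rtnorm_lower(n_sites, config$ipd_meth_mean,
                               config$ipd_meth_sd, 2),
                  rtnorm_lower(n_sites, config$ipd_bg_mean,
                               config$ipd_bg_sd, 0))
    calls <- data.frame(
      position = sites$adenine_pos,
      strand = sites$strand,
      base = "A",
      ipd_ratio = as.numeric(sprintf("%.2f", ipd)),
      mod_qv = as.numeric(qv),
      coverage = cov,
      methyl_frac = frac,
      frac_low = as.numeric(sprintf("%.4f", pmax(0, frac - half))),
      frac_up = as.numeric(sprintf("%.4f", pmin(1, frac + half))),
      mod_type = ifelse(qv >= 30, "m6A", "none")
    )
    if (background) {
      calls <- rbind(calls, background_calls(genome, sites, config))
    }
    replicates[[j]] <- mod_set(calls, paste0("rep", j), genome$length,
                               ref_id = genome$id)
  }

  site_k <- as.integer(rowSums(latent))
  truth_sites <- cbind(
    sites[, c("locus_id", "motif", "start", "strand", "adenine_pos")],
    as.data.frame(`colnames<-`(latent, paste0("latent_", seq_len(n_rep)))),
    data.frame(latent_k = site_k,
               drawn_k = drawn_site_k,
               realized_class = as.character(stability_class_label(site_k, n_rep)))
  )
  fwd_k <- site_k[sites$strand == "+"][match(loci$locus_id,
                                             sites$locus_id[sites$strand == "+"])]
  rev_k <- site_k[sites$strand == "-"][match(loci$locus_id,
                                             sites$locus_id[sites$strand == "-"])]
  fwd_hi <- fwd_k / n_rep > 0.75
  rev_hi <- rev_k / n_rep > 0.75
  truth_loci <- data.frame(
    locus_id = loci$locus_id, motif = loci$motif, start = loci$start,
    drawn_state = drawn_locus_state,
    realized_state = ifelse(fwd_hi & rev_hi, "fully_methylated",
                            ifelse(xor(fwd_hi, rev_hi), "hemimethylated",
                                   "stochastic"))
  )
  structure(list(replicates = replicates,
                 truth = list(sites = truth_sites, loci = truth_loci),
                 config = config, mode = mode),
            class = "methylome_sim")
}

background_calls <- function(genome, sites, config) {
  L <- genome$length
  pos <- rep(0:(L - 1L), 2L)
  strand <- rep(c("+", "-"), each = L)
  key_site <- paste(sites$adenine_pos, sites$strand)
  keep <- !(paste(pos, strand) %in% key_site)
  pos <- pos[keep]; strand <- strand[keep]
  n <- length(pos)
  fwd_base <- strsplit(genome$seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  base <- ifelse(strand == "+", fwd_base[pos + 1L],
                 comp[fwd_base[pos + 1L]])
  high <- stats::runif(n) < config$background_high_ipd_prob
  ipd <- ifelse(high, stats::runif(n, 2, 6),
                rtnorm_lower(n, config$ipd_bg_mean, config$ipd_bg_sd, 0))
  data.frame(
    position = pos, strand = strand, base = unname(base),
    ipd_ratio = as.numeric(sprintf("%.2f", ipd)),
    mod_qv = as.numeric(sample(0:config$qv_un_max, n, replace = TRUE)),
    coverage = config$coverage,
    methyl_frac = NA_real_, frac_low = NA_real_, frac_up = NA_real_,
    mod_type = "none"
  )
}

#' One-call synthetic methylome
#'
#' Runs [simulate_genome()], scans the emitted genome, and runs
#' [simulate_replicates()], so that the loci fed to the replicate
#' simulator are exactly what the scanner sees.
#'
#' @inheritParams simulate_replicates
#' @param config A `sim_config`.
#' @return The `methylome_sim` with `genome`, `loci` and `genome_truth`
#'   added.
#' @export
simulate_methylome <- function(config, mode = c("locus", "strand"),
                               background = FALSE) {
  g <- simulate_genome(config)
  loci <- scan_motifs(g$genome)
  sim <- simulate_replicates(g$genome, loci, config, mode = mode,
                             background = background)
  sim$genome <- g$genome
  sim$genome_truth <- g$truth
  sim$loci <- loci
  sim
}

#' Write a modification-call set in the PacBio GFF3 dialect
#'
#' Emits one feature line per call at or above the QV threshold (the GFF
#' conventionally holds only positive calls), with `coverage`, `context`,
#' `IPDRatio` and — when present — `frac`/`fracLow`/`fracUp` attributes.
#'
#' @param modset A `mod_set`.
#' @param path Output path.
#' @param qv_threshold Minimum ModificationQV for a line (default 30).
#' @return `path`, invisibly.
#' @export
write_pacbio_gff <- function(modset, path, qv_threshold = 30) {
  calls <- modset$calls
  calls <- calls[!is.na(calls$mod_qv) & calls$mod_qv >= qv_threshold, ,
                 drop = FALSE]
  ref <- modset$ref_id %||% "ref"
  lines <- c("##gff-version 3",
             paste0("##source methylstab ", utils::packageVersion("methylstab")))
  if (nrow(calls)) {
    attrs <- sprintf("coverage=%d;context=%s;IPDRatio=%.2f",
                     calls$coverage,
                     ifelse(is.na(calls$base), "N", calls$base),
                     calls$ipd_ratio)
    has_frac <- !is.na(calls$methyl_frac)
    attrs[has_frac] <- sprintf("%s;frac=%.4f;fracLow=%.4f;fracUp=%.4f",
                               attrs[has_frac],
                               calls$methyl_frac[has_frac],
                               calls$frac_low[has_frac],
                               calls$frac_up[has_frac])
    lines <- c(lines, sprintf(
      "%s\tkinModCall\t%s\t%d\t%d\t%d\t%s\t.\t%s",
      ref,
      ifelse(calls$mod_type == "none", "modified_base", calls$mod_type),
      calls$position + 1L, calls$position + 1L,
      as.integer(calls$mod_qv), calls$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a modification-call set in the PacBio per-position CSV dialect
#'
#' @param modset A `mod_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modifications_csv <- function(modset, path) {
  calls <- modset$calls
  dt <- data.table::data.table(
    refName = modset$ref_id %||% "ref",
    tpl = calls$position + 1L,
    strand = ifelse(calls$strand == "+", 0L, 1L),
    base = calls$base,
    score = calls$mod_qv,
    ipdRatio = calls$ipd_ratio,
    coverage = calls$coverage
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write a full simulation to disk
#'
#' Emits `genome.fa`, `rep<i>.modifications.gff` / `.csv` for each
#' replicate, and the ground-truth tables `truth_sites.tsv` /
#' `truth_loci.tsv`.
#'
#' @param sim A `methylome_sim` from [simulate_methylome()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "methylome_sim"), !is.null(sim$genome))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"))
  write_genome_fasta(sim$genome, paths[["genome"]])
  for (j in seq_along(sim$replicates)) {
    gff <- file.path(outdir, sprintf("rep%d.modifications.gff", j))
    csv <- file.path(outdir, sprintf("rep%d.modifications.csv", j))
    write_pacbio_gff(sim$replicates[[j]], gff)
    write_modifications_csv(sim$replicates[[j]], csv)
    paths[[sprintf("rep%d_gff", j)]] <- gff
    paths[[sprintf("rep%d_csv", j)]] <- csv
  }
  ts <- file.path(outdir, "truth_sites.tsv")
  tl <- file.path(outdir, "truth_loci.tsv")
  data.table::fwrite(sim$truth$sites, ts, sep = "\t")
  data.table::fwrite(sim$truth$loci, tl, sep = "\t")
  paths[["truth_sites"]] <- ts
  paths[["truth_loci"]] <- tl
  invisible(paths)
}
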
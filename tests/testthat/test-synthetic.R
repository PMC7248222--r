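test_that("config validation enforces the stated world", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(palindrome_state_proportions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(simulation_config(strand_stability_proportions = c(0.9, 0.1)),
               "length")
  expect_error(simulation_config(pi_meth = 0.5, pi_un = 0.6), "pi_un")
  expect_error(simulation_config(coverage = 0L), "coverage")
})

test_that("the same seed yields byte-identical outputs", {
  cfg <- simulation_config(genome_length = 8000L, seed = 19,
                           planted_gap_length = 500L,
                           planted_gap_start = 3000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_methylome(cfg), d1)
  p2 <- write_simulation(simulate_methylome(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("genome composition tracks the configured GC content", {
  cfg <- simulation_config(genome_length = 330611L, gc = 0.4, seed = 7)
  g <- simulate_genome(cfg)$genome
  expect_equal(g$length, 330611L)
  expect_lt(abs(g$gc_fraction - 0.4), 0.005)  # binomial concentration bound
  # gc = 1: motifs need A/T, so no loci at all
  g1 <- simulate_genome(simulation_config(genome_length = 5000L, gc = 1,
                                          seed = 7))$genome
  expect_equal(nrow(scan_motifs(g1)), 0L)
})

test_that("a planted gap is recovered exactly by the scanner", {
  cfg <- simulation_config(genome_length = 60000L, seed = 23,
                           planted_gap_length = 3617L,
                           planted_gap_start = 20000L)
  sim <- simulate_genome(cfg)
  loci <- scan_motifs(sim$genome)
  top <- longest_motif_free_gap(loci, sim$genome)
  expect_equal(top$length, 3617L)
  expect_equal(top$start, 20000L)
  expect_equal(top$end, 23617L)
  expect_error(simulate_genome(simulation_config(genome_length = 1000L,
                                                 planted_gap_length = 2000L)),
               "exceeds genome")
})

test_that("a planted window holds exactly k loci", {
  cfg <- simulation_config(genome_length = 20000L, seed = 29,
                           planted_window = list(start = 5000L, k = 9L))
  sim <- simulate_genome(cfg)
  loci <- scan_motifs(sim$genome)
  inside <- loci$start >= 5000L & loci$start + 4L <= 5278L
  expect_equal(sum(inside), 9L)
  expect_setequal(loci$start[inside], sim$truth$window$planted_starts)
  sc <- window_enrichment(sim$genome, loci, window = 278L)
  expect_equal(sc$me[sc$start == 5000L], 4.5)
})

test_that("emitted GFF calls are a subset of CSV positions", {
  cfg <- simulation_config(genome_length = 6000L, seed = 5)
  sim <- simulate_methylome(cfg, background = TRUE)
  d <- withr::local_tempdir()
  p <- write_simulation(sim, d)
  gff <- read_modifications_gff(p[["rep2_gff"]], genome_length = 6000L)
  csv <- read_modifications_csv(p[["rep2_csv"]], genome_length = 6000L)
  key <- function(x) paste(x$calls$position, x$calls$strand)
  expect_true(all(key(gff) %in% key(csv)))
  expect_true(all(gff$calls$mod_qv >= 30))
  # background CSV covers every strand-position
  expect_equal(nrow(csv$calls), 2L * 6000L)
})

test_that("write/read round-trips preserve records on both dialects", {
  set.seed(77)
  n <- 10000L
  qv <- sample(0:60, n, replace = TRUE)
  frac <- as.numeric(sprintf("%.4f", runif(n)))
  calls <- data.frame(
    position = sample.int(5e5, n) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    base = "A",
    ipd_ratio = as.numeric(sprintf("%.2f", runif(n, 0, 8))),
    mod_qv = as.numeric(qv),
    coverage = sample(10:60, n, replace = TRUE),
    methyl_frac = frac,
    frac_low = as.numeric(sprintf("%.4f", pmax(0, frac - 0.05))),
    frac_up = as.numeric(sprintf("%.4f", pmin(1, frac + 0.05))),
    mod_type = ifelse(qv >= 30, "m6A", "none"))
  ms <- mod_set(calls, "rt", 5e5, ref_id = "refX")

  gff <- withr::local_tempfile(fileext = ".gff")
  write_pacbio_gff(ms, gff)
  back <- read_modifications_gff(gff, genome_length = 5e5)
  sub <- calls[calls$mod_qv >= 30, , drop = FALSE]
  rownames(sub) <- NULL
  expect_identical(back$calls, sub)
  expect_equal(back$ref_id, "refX")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_modifications_csv(ms, csv)
  back2 <- read_modifications_csv(csv, genome_length = 5e5)
  cols <- c("position", "strand", "base", "ipd_ratio", "mod_qv", "coverage")
  expect_identical(back2$calls[, cols], calls[, cols])

  # single call: one feature line plus headers
  one <- mod_set(calls[1, ], "one", 5e5)
  write_pacbio_gff(one, gff, qv_threshold = 0)
  expect_equal(sum(!grepl("^#", readLines(gff))), 1L)
})

test_that("noiseless simulation is recovered perfectly end to end", {
  cfg <- simulation_config(genome_length = 30000L, seed = 13,
                           pi_meth = 1, pi_un = 0,
                           background_high_ipd_prob = 0)
  for (mode in c("locus", "strand")) {
    sim <- simulate_methylome(cfg, mode = mode)
    rec <- combine_replicates(sim$replicates, sim$loci)
    expect_identical(as.character(rec$stability_class),
                     sim$truth$sites$realized_class)
    pal <- classify_palindromes(rec)
    expect_identical(as.character(pal$state),
                     sim$truth$loci$realized_state)
    # in strand mode the drawn k IS the realized k (no coin flips)
    if (mode == "strand") {
      expect_identical(rec$k_methylated, sim$truth$sites$drawn_k)
    }
  }
})

test_that("strand-mode planting recovers planted class counts exactly when noiseless", {
  cfg <- simulation_config(genome_length = 40000L, seed = 41,
                           pi_meth = 1, pi_un = 0,
                           background_high_ipd_prob = 0)
  sim <- simulate_methylome(cfg, mode = "strand")
  s <- classify_stability(combine_replicates(sim$replicates, sim$loci))
  planted <- table(factor(sim$truth$sites$drawn_k, levels = 3:0))
  expect_equal(unname(unclass(s$counts)), unname(unclass(planted)))
})

test_that("background high-ipd fraction sits in the expected band", {
  cfg <- simulation_config(genome_length = 50000L, seed = 3)
  sim <- simulate_methylome(cfg, background = TRUE)
  hs <- high_ipd_summary(sim$replicates[[1]], 2, loci = sim$loci)
  # b * (1 - motif density) + methylated motif adenines
  expect_gte(hs$high_ipd_fraction, 0.09)
  expect_lte(hs$high_ipd_fraction, 0.13)
})

test_that("the simulate CLI writes a readable bundle", {
  d <- withr::local_tempdir()
  expect_message(
    methylstab_cli(c("simulate", "--outdir", d, "--seed", "4",
                     "--length", "5000", "--noiseless")),
    "wrote")
  expect_true(file.exists(file.path(d, "genome.fa")))
  g <- read_genome_fasta(file.path(d, "genome.fa"))
  expect_equal(g$length, 5000L)
  bed <- file.path(d, "loci.bed")
  expect_message(
    methylstab_cli(c("scan", "--fasta", file.path(d, "genome.fa"),
                     "--out", bed)),
    "strand-sites")
  expect_true(file.exists(bed))
})
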
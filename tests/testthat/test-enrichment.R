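make_enrichment_fixture <- function() {
  # 1000 bp genome, motifs planted far enough apart to count by eye
  set.seed(7)
  cfg <- simulation_config(genome_length = 1000L, gc = 1, seed = 7,
                           planted_window = list(start = 100L, k = 5L),
                           planted_gap_start = NULL)
  sim <- simulate_genome(cfg)
  g <- sim$genome
  list(genome = g, loci = scan_motifs(g), truth = sim$truth)
}

test_that("window ME is observed loci over expected", {
  fx <- make_enrichment_fixture()
  expect_equal(nrow(fx$loci), 5L)  # gc = 1 background: only planted loci
  sc <- window_enrichment(fx$genome, fx$loci, window = 278L, expected = 2)
  # the planted 278-bp window holds exactly the 5 loci -> ME 2.5
  w <- sc[sc$start == 100L, ]
  expect_equal(w$n_gatc + w$n_catg, 5L)
  expect_equal(w$me, 2.5)
  # a window holding exactly 2 loci scores 1.0
  expect_true(any(sc$me == 1))
  # whole-genome consistency identity
  expect_equal(mean(sc$me),
               sum(sc$n_gatc + sc$n_catg) / (2 * nrow(sc)),
               tolerance = 1e-9)
  expect_error(window_enrichment(fx$genome, fx$loci, window = 3), "width")
})

test_that("significant windows merge into regions, idempotently", {
  scores <- data.frame(
    start = c(100L, 150L, 600L),
    end = c(378L, 428L, 878L),
    n_gatc = c(8L, 9L, 7L), n_catg = c(0L, 0L, 0L),
    me = c(4.0, 4.5, 3.5))
  reg <- merge_significant_windows(scores, me_threshold = 3.5)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(100L, 600L))
  expect_equal(reg$end, c(428L, 878L))
  expect_equal(reg$me, c(4.5, 3.5))       # max member ME, sorted by ME desc
  # idempotence
  reg2 <- merge_significant_windows(reg, me_threshold = 3.5)
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
  expect_equal(reg2$me, reg$me)
  # nothing qualifies -> empty
  expect_equal(nrow(merge_significant_windows(scores, me_threshold = 10)), 0L)
})

test_that("disjoint qualifying windows sort like a brute-force re-sort", {
  set.seed(1)
  scores <- data.frame(start = c(0L, 500L, 1000L),
                       end = c(278L, 778L, 1278L),
                       n_gatc = c(7L, 9L, 8L), n_catg = 0L,
                       me = c(3.5, 4.5, 4.0))
  reg <- merge_significant_windows(scores, 3.5)
  oracle <- scores[order(-scores$me, scores$start), ]
  expect_equal(reg$start, oracle$start)
  expect_equal(reg$me, oracle$me)
})

test_that("region counts come from loci wholly inside the merged span", {
  fx <- make_enrichment_fixture()
  sc <- window_enrichment(fx$genome, fx$loci, window = 278L)
  reg <- merge_significant_windows(sc, me_threshold = 2.5, loci = fx$loci)
  expect_gte(nrow(reg), 1L)
  expect_equal(reg$n_gatc[1] + reg$n_catg[1], 5L)
  expect_equal(reg$n_gatc[1], 3L)  # planted motifs alternate GATC/CATG
  expect_equal(reg$n_catg[1], 2L)
})

test_that("depletion fold is the reciprocal of the expected count", {
  gaps <- data.frame(start = c(0L, 500L, 1000L, 5000L),
                     end = c(139L, 778L, 4617L, 5000L),
                     length = c(139L, 278L, 3617L, 0L))
  dep <- depletion_scan(gaps)
  expect_equal(nrow(dep), 3L)               # zero-length gap omitted
  expect_equal(dep$fold[1], 1.0)            # 139 bp boundary
  expect_equal(dep$expected_in_gap[2], 2)
  expect_equal(dep$fold[2], 0.5)
  expect_equal(dep$expected_in_gap[3], 2 * 3617 / 278, tolerance = 1e-12)
  expect_equal(dep$fold[3], 139 / 3617, tolerance = 1e-12)
  # exact reciprocal identity
  expect_equal(dep$fold * dep$expected_in_gap, rep(1, 3))
  # fold monotone decreasing in length
  expect_true(all(diff(dep$fold[order(dep$length)]) < 0))
})

test_that("regions annotate with every gene they touch", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      start = c(0L, 200L, 400L), end = c(150L, 350L, 550L),
                      strand = "+", txn_class = c("Early", "Late", "Early"),
                      annotation = c("a", "b", "c"))
  regions <- merge_significant_windows(
    data.frame(start = c(100L, 380L), end = c(378L, 450L),
               n_gatc = 7L, n_catg = 0L, me = c(4, 4)), 3.5)
  ann <- annotate_regions(regions, genes)
  expect_equal(sort(strsplit(ann$genes[ann$start == 100], ",")[[1]]),
               c("g1", "g2"))
  expect_equal(ann$genes[ann$start == 380], "g3")
  # region with no gene overlap -> empty string
  none <- annotate_regions(
    merge_significant_windows(
      data.frame(start = 600L, end = 700L, n_gatc = 7L, n_catg = 0L, me = 4),
      3.5),
    genes)
  expect_equal(none$genes, "")
})

test_that("gene/class correlation matches the direct Pearson formula", {
  # identical density in all classes -> no relationship
  loci <- toy_loci(c(10, 110, 210, 310), genome_length = 400L)
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      start = c(0L, 100L, 200L, 300L),
                      end = c(100L, 200L, 300L, 400L),
                      strand = "+",
                      txn_class = c("Early", "Early-Late", "Late", "Early"),
                      annotation = NA)
  expect_equal(unname(gene_motif_density_correlation(genes, loci)["GATC"]), 0)

  # density perfectly ordered by class code -> R = 1
  loci2 <- toy_loci(c(10, 110, 120, 210, 220, 230), genome_length = 400L)
  genes2 <- genes[1:3, ]
  expect_equal(unname(gene_motif_density_correlation(genes2, loci2)["GATC"]), 1)

  # random fixture vs sum-formula oracle
  set.seed(5)
  starts <- sort(sample(0:9996, 60))
  loci3 <- toy_loci(starts, genome_length = 10000L)
  genes3 <- data.frame(gene_id = paste0("g", 1:10),
                       start = seq(0L, 9000L, by = 1000L),
                       end = seq(1000L, 10000L, by = 1000L),
                       strand = "+",
                       txn_class = sample(c("Early", "Early-Late", "Late"),
                                          10, replace = TRUE),
                       annotation = NA)
  r <- unname(gene_motif_density_correlation(genes3, loci3)["GATC"])
  dens <- vapply(1:10, function(i) {
    sum(starts >= genes3$start[i] & starts + 4 <= genes3$end[i]) / 1000
  }, numeric(1))
  code <- c(Early = 0, `Early-Late` = 1, Late = 2)[genes3$txn_class]
  expect_equal(r, pearson_from_sums(dens, unname(code)), tolerance = 1e-12)

  # fewer than 3 classed genes -> undefined
  expect_warning(
    r2 <- gene_motif_density_correlation(genes3[1:2, ], loci3),
    "undefined")
  expect_true(is.na(r2[["GATC"]]))
})

test_that("gene annotation reader skips malformed lines with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "toy\tx\tgene\t10\t50\t.\t+\t.\tID=gA;txn_class=Early",
               "this line is broken",
               "toy\tx\tgene\tNaN\t60\t.\t+\t.\tID=gBad",
               "toy\tx\tgene\t60\t90\t.\t-\t.\tID=gB;product=thing"),
             gff)
  expect_warning(genes <- read_gene_annotations(gff), "malformed")
  expect_equal(genes$gene_id, c("gA", "gB"))
  expect_equal(genes$start, c(9L, 59L))   # 1-based inclusive -> 0-based
  expect_equal(genes$end, c(50L, 90L))
  expect_equal(genes$annotation[2], "thing")
})
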
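test_that("toy genome plants motifs exactly where recorded", {
  g <- make_toy_genome(n_chrom = 2, chrom_len = 20000, n_genes = 8,
                       motif_plan = c("0" = 2, "1" = 3, "2" = 1), seed = 42)
  expect_equal(as.integer(table(factor(g$motifs$grade, levels = 0:2))),
               c(2L, 3L, 1L))
  for (i in seq_len(nrow(g$motifs))) {
    site <- substr(g$chromosomes[[g$motifs$chrom[i]]],
                   g$motifs$pos[i], g$motifs$pos[i] + 5L)
    expect_equal(sum(strsplit(site, "")[[1]] !=
                       strsplit("CACGTG", "")[[1]]),
                 g$motifs$grade[i])
  }
  expect_false(anyDuplicated(g$genes$gene_id) > 0)
})

test_that("promoter of a single planted consensus holds exactly one exact hit", {
  g <- make_toy_genome(n_chrom = 1, chrom_len = 12000, n_genes = 3,
                       motif_plan = c("0" = 1), seed = 5)
  m <- g$motifs[1, ]
  gene <- g$genes[g$genes$gene_id == m$gene_id, ]
  pr_start <- if (gene$strand == "+") gene$tss - g$promoter_len else gene$tss + 1
  prom <- substr(g$chromosomes[[m$chrom]], pr_start,
                 pr_start + g$promoter_len - 1)
  hits <- oracle_scan(prom, max_mm = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(pr_start + hits$start - 1L, m$pos)
})

test_that("planted 1-mismatch sites are recovered by exhaustive promoter scan", {
  g <- make_toy_genome(n_chrom = 1, chrom_len = 14000, n_genes = 5,
                       motif_plan = c("1" = 3), seed = 9)
  prom <- pho4cycle:::promoter_interval(g$genes, g$promoter_len)
  n0 <- 0; n1_at_planted <- 0
  for (i in seq_len(nrow(prom))) {
    s <- substr(g$chromosomes[[prom$chrom[i]]], prom$start[i], prom$end[i])
    h <- oracle_scan(s, max_mm = 1)
    n0 <- n0 + sum(h$mismatches == 0)
    abs_pos <- prom$start[i] + h$start - 1L
    n1_at_planted <- n1_at_planted +
      sum(abs_pos %in% g$motifs$pos & h$mismatches == 1)
  }
  expect_equal(n0, 0)
  expect_equal(n1_at_planted, 3)
})

test_that("identical seeds give byte-identical generator output", {
  d1 <- tempfile(); d2 <- tempfile()
  make_toy_genome(n_chrom = 1, chrom_len = 9000, n_genes = 2,
                  motif_plan = c("0" = 1), seed = 3, out_dir = d1)
  make_toy_genome(n_chrom = 1, chrom_len = 9000, n_genes = 2,
                  motif_plan = c("0" = 1), seed = 3, out_dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                   unname(tools::md5sum(file.path(d2, "genome.fa"))))

  cl <- c(chrA = 4000)
  ct <- make_chip_truth(cl, n_peaks = 2, n_cobound = 1, n_dependent = 0,
                        min_spacing = 500, seed = 8)
  t1 <- simulate_chip_tracks(cl, ct, noise_sd = 0.3, seed = 8)
  t2 <- simulate_chip_tracks(cl, ct, noise_sd = 0.3, seed = 8)
  expect_identical(t1$tf_co$values, t2$tf_co$values)

  tr <- make_expression_truth(n_genes = 50, seed = 2)
  s1 <- simulate_counts(tr, seed = 6)
  s2 <- simulate_counts(tr, seed = 6)
  expect_identical(s1$counts, s2$counts)
})

test_that("infeasible gene placement fails loudly", {
  expect_error(
    make_toy_genome(n_chrom = 1, chrom_len = 3000, n_genes = 5, seed = 1),
    "placement"
  )
})

test_that("null genes with zero dispersion vary only by Poisson noise", {
  tr <- make_expression_truth(n_genes = 100, frac_induced = 0,
                              dispersion = 0, seed = 1)
  sim <- simulate_counts(tr, n_rep = 50, lib_sizes = 1e6, seed = 2)
  m <- sapply(genotype_levels(), function(g) {
    rowMeans(sim$counts[, sim$samples$genotype == g])
  })
  # expected counts identical across genotypes; observed means agree
  # within a few Poisson standard errors
  rel <- (m - rowMeans(m)) / sqrt(rowMeans(m) / 50)
  expect_lt(max(abs(rel)), 5)
})

test_that("a pure TF main effect multiplies counts 8-fold regardless of cofactor", {
  tr <- make_expression_truth(n_genes = 400, frac_induced = 0, seed = 3)
  tr$pho4[1] <- 3  # planted (3, 0, 0)
  sim <- simulate_counts(tr, n_rep = 40, lib_sizes = 2e6, seed = 4)
  mg <- vapply(genotype_levels(), function(g) {
    mean(sim$counts[1, sim$samples$genotype == g])
  }, numeric(1))
  expect_equal(mg[["PHO4.pho2d"]] / mg[["pho4d.pho2d"]], 8, tolerance = 0.1)
  expect_equal(mg[["PHO4.PHO2"]] / mg[["pho4d.PHO2"]], 8, tolerance = 0.1)
})

test_that("naive mean-of-log estimates recover planted components at high n", {
  tr <- make_expression_truth(n_genes = 200, frac_induced = 0.2,
                              dispersion = 0.05, seed = 11)
  sim <- simulate_counts(tr, n_rep = 50, lib_sizes = 2e6, seed = 12)
  lc <- log2(sim$counts + 0.5)
  m <- sapply(genotype_levels(), function(g) {
    rowMeans(lc[, sim$samples$genotype == g])
  })
  pho4_hat <- m[, "PHO4.pho2d"] - m[, "pho4d.pho2d"]
  # counts are proportions of the library, so induced mass shifts every
  # gene by a common per-genotype composition offset (what TMM corrects
  # downstream); remove it via the null genes before comparing
  offset <- stats::median((pho4_hat - tr$pho4)[tr$class == "null"])
  keep <- tr$baseline_log2cpm > log2(20)
  expect_lt(mean(abs(pho4_hat - offset - tr$pho4)[keep]), 0.1)
})

test_that("noise-free tracks hit planted summit values exactly", {
  cl <- c(chrA = 6000)
  ct <- data.frame(peak_id = "pk1", chrom = "chrA", summit = 3000L,
                   sigma = 50, height = 10, alpha = 0.4, cobound = TRUE,
                   stringsAsFactors = FALSE)
  tk <- simulate_chip_tracks(cl, ct, noise_sd = 0, seed = 1)
  expect_equal(tk$tf_co$values$chrA[3000], 11)
  expect_equal(tk$tf_noco$values$chrA[3000], 1 + 0.4 * 10)
  expect_true(all(tk$mock$values$chrA == 1))
})

test_that("isolated peak integrates to height * sigma * sqrt(2 pi)", {
  cl <- c(chrA = 10000)
  ct <- data.frame(peak_id = "pk1", chrom = "chrA", summit = 5000L,
                   sigma = 50, height = 8, alpha = 1, cobound = FALSE,
                   stringsAsFactors = FALSE)
  tk <- simulate_chip_tracks(cl, ct, noise_sd = 0, seed = 1)
  area <- sum(tk$tf_co$values$chrA - 1)
  expect_equal(area, 8 * 50 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("overlapping planted peaks warn and sum", {
  cl <- c(chrA = 4000)
  ct <- data.frame(peak_id = c("a", "b"), chrom = "chrA",
                   summit = c(2000L, 2050L), sigma = 50,
                   height = c(5, 5), alpha = 1, cobound = FALSE,
                   stringsAsFactors = FALSE)
  expect_warning(tk <- simulate_chip_tracks(cl, ct, noise_sd = 0, seed = 1),
                 "summed")
  expect_gt(max(tk$tf_co$values$chrA), 1 + 5)
})

test_that("generator files round-trip through the package readers", {
  d <- tempfile()
  g <- make_toy_genome(n_chrom = 2, chrom_len = 12000, n_genes = 4,
                       motif_plan = c("0" = 2), seed = 21, out_dir = d)
  expect_identical(read_genome_fasta(file.path(d, "genome.fa")),
                   g$chromosomes)
  rg <- read_gene_bed(file.path(d, "genes.bed"))
  expect_identical(rg[, c("gene_id", "chrom", "tss", "strand")],
                   g$genes[, c("gene_id", "chrom", "tss", "strand")])

  tr <- make_expression_truth(n_genes = 30, seed = 1)
  sim <- simulate_counts(tr, seed = 2)
  write_counts(sim, d)
  back <- read_counts(file.path(d, "counts.tsv"),
                      file.path(d, "samples.tsv"))
  expect_identical(back$counts, sim$counts)
  expect_identical(back$samples, sim$samples)

  ct <- make_chip_truth(g, n_peaks = 3, n_cobound = 2, n_dependent = 1,
                        min_spacing = 1000, seed = 3)
  tk <- simulate_chip_tracks(g, ct, noise_sd = 0.25, seed = 4)
  p <- file.path(d, "tf.bedgraph")
  write_bedgraph(tk$tf_co, p)
  rt <- read_bedgraph(p)
  expect_identical(rt$values, tk$tf_co$values)
})
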
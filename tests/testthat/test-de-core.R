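sheet_for <- function(counts, n_rep = 2) {
  data.frame(sample_id = colnames(counts),
             genotype = rep(genotype_levels(), each = n_rep),
             replicate = rep(seq_len(n_rep), 4),
             stringsAsFactors = FALSE)
}

test_that("low-expression filter applies the CPM rule literally", {
  set.seed(1)
  counts <- matrix(rnbinom(20 * 8, mu = 30, size = 10), 20, 8,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%d", 1:8)))
  counts[1, ] <- 0                      # zero everywhere -> removed
  counts[2, ] <- pmax(counts[2, ], 60)  # comfortably above 1 CPM everywhere
  kept <- filter_low_expression(counts)
  expect_false("g01" %in% rownames(kept))
  expect_true("g02" %in% rownames(kept))

  # brute-force re-evaluation of the rule
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  expected <- rownames(counts)[rowSums(cpm < 1) < 3]
  expect_identical(rownames(kept), expected)
  expect_error(
    filter_low_expression(matrix(0L, 3, 8,
                                 dimnames = list(letters[1:3],
                                                 sprintf("s%d", 1:8)))),
    "all genes"
  )
})

test_that("TMM is 1 for identical or purely depth-scaled libraries", {
  set.seed(2)
  a <- rnbinom(50, mu = 100, size = 5) + 1L
  same <- cbind(s1 = a, s2 = a)
  expect_equal(tmm_factors(same)$factor, c(1, 1))
  doubled <- cbind(s1 = a, s2 = 2L * a)
  expect_equal(tmm_factors(doubled)$factor, c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the step-by-step trimmed weighted mean oracle", {
  counts <- cbind(
    s1 = c(100L, 200L, 300L, 400L, 500L, 10000L),
    s2 = c(120L, 180L, 330L, 380L, 520L, 30000L)
  )
  rownames(counts) <- sprintf("g%d", 1:6)
  expect_equal(tmm_factors(counts)$factor, oracle_tmm(counts),
               tolerance = 1e-9)

  set.seed(3)
  r <- matrix(rnbinom(40 * 4, mu = 200, size = 2) + 1L, 40, 4,
              dimnames = list(NULL, sprintf("s%d", 1:4)))
  expect_equal(tmm_factors(r)$factor, oracle_tmm(r), tolerance = 1e-9)
})

test_that("TMM factors have geometric mean 1 and follow sample permutations", {
  set.seed(4)
  counts <- matrix(rnbinom(60 * 6, mu = 150, size = 3) + 1L, 60, 6,
                   dimnames = list(NULL, sprintf("s%d", 1:6)))
  nf <- tmm_factors(counts)
  expect_equal(exp(mean(log(nf$factor))), 1, tolerance = 1e-12)
  perm <- c(4, 1, 6, 2, 5, 3)
  nf_p <- tmm_factors(counts[, perm])
  expect_equal(nf_p$factor, nf$factor[perm], tolerance = 1e-12)
})

test_that("log-CPM equals the closed form", {
  counts <- matrix(0L, 1, 1, dimnames = list("g", "s1"))
  nf <- data.frame(sample_id = "s1", lib_size = 1e6, factor = 1)
  expect_equal(log_cpm(counts, nf)[1, 1],
               log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-3)

  set.seed(5)
  counts <- matrix(rnbinom(25 * 4, mu = 500, size = 5), 25, 4,
                   dimnames = list(sprintf("g%02d", 1:25),
                                   sprintf("s%d", 1:4)))
  nf <- tmm_factors(counts)
  lc <- log_cpm(counts, nf)
  cells <- cbind(sample(25, 100, TRUE), sample(4, 100, TRUE))
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    eff <- nf$lib_size[j] * nf$factor[j]
    expect_equal(lc[i, j],
                 log2((counts[i, j] + 0.5) / (eff + 1) * 1e6))
  }
  # doubling a large count adds ~1
  expect_equal(log2((2000 + 0.5)) - log2((1000 + 0.5)), 1, tolerance = 1e-3)
})

test_that("genotype-mean fit matches an OLS oracle", {
  set.seed(6)
  lc <- matrix(rnorm(30 * 8, mean = 6), 30, 8,
               dimnames = list(sprintf("g%02d", 1:30),
                               paste0("s", 1:8)))
  sheet <- sheet_for(lc)
  fit <- fit_genotype_means(lc, sheet)
  g <- factor(sheet$genotype, levels = genotype_levels())
  for (i in c(1, 7, 30)) {
    ols <- lm(lc[i, ] ~ 0 + g)
    expect_equal(unname(fit$coefficients[i, ]), unname(coef(ols)),
                 tolerance = 1e-12)
    expect_equal(unname(fit$sigma2[i]), summary(ols)$sigma^2, tolerance = 1e-12)
  }
  expect_equal(fit$df, 4)

  # two identical replicates: beta is the value, s2 = 0; (4, 6) -> 5
  lc2 <- matrix(rep(c(4, 6), 4)[c(1, 1, 1, 2, 1, 2, 1, 2)], 1, 8)
  lc2 <- matrix(c(3, 3, 4, 6, 4, 6, 4, 6), 1, 8,
                dimnames = list("g1", paste0("s", 1:8)))
  fit2 <- fit_genotype_means(lc2, sheet)
  expect_equal(unname(fit2$coefficients[1, ]), c(3, 5, 5, 5))
  expect_equal(fit2$sigma2[1], (0 + 2 + 2 + 2) / 4)  # pooled over 4 df
})

test_that("variance moderation recovers a planted scaled-F prior", {
  set.seed(7)
  n <- 5000; d0 <- 4; s0 <- 0.04; d <- 4
  true_var <- s0 * d0 / rchisq(n, d0)
  s2 <- true_var * rchisq(n, d) / d
  fit <- make_fit(matrix(rnorm(n * 4), n, 4))
  fit$sigma2 <- s2
  fit$df <- d
  fit$s2_post <- NULL
  mod <- moderate_variances(fit)
  expect_equal(mod$df_prior, d0, tolerance = 0.3)
  expect_equal(mod$s2_prior, s0, tolerance = 0.15)
  expect_equal(mod$s2_post,
               (mod$df_prior * mod$s2_prior + d * s2) / (mod$df_prior + d),
               tolerance = 1e-12)
})

test_that("infinite prior df squeezes every variance to the prior", {
  fit <- make_fit(matrix(rnorm(400), 100, 4))
  fit$sigma2 <- rep(0.2, 100)  # all equal -> d0 = Inf path
  fit$df <- 4
  fit$s2_post <- NULL
  mod <- moderate_variances(fit)
  expect_true(is.infinite(mod$df_prior))
  expect_equal(unname(mod$s2_post), rep(0.2, 100))
})

test_that("TREAT reduces to the moderated t at lfc = 0 and matches limma", {
  set.seed(8)
  lc <- matrix(rnorm(200 * 8, mean = 6, sd = 0.4), 200, 8,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  lc[1:20, 7:8] <- lc[1:20, 7:8] + 3  # induced in PHO4.PHO2
  sheet <- sheet_for(lc)
  fit <- moderate_variances(fit_genotype_means(lc, sheet))
  tt <- treat_test(fit, c("PHO4.PHO2", "pho4d.PHO2"), lfc = 1)

  design <- stats::model.matrix(~ 0 + factor(sheet$genotype,
                                             levels = genotype_levels()))
  colnames(design) <- genotype_levels()
  lfit <- limma::lmFit(lc, design)
  ctr <- limma::makeContrasts(PHO4.PHO2 - pho4d.PHO2, levels = design)
  lfit2 <- limma::treat(limma::contrasts.fit(lfit, ctr), lfc = 1)
  expect_equal(tt$p, as.numeric(lfit2$p.value), tolerance = 1e-9)
  expect_equal(tt$logFC, as.numeric(lfit2$coefficients), tolerance = 1e-12)

  # lfc = 0 reduction to the ordinary two-sided moderated t
  t0 <- treat_test(fit, c("PHO4.PHO2", "pho4d.PHO2"), lfc = 0)
  tstat <- t0$logFC / t0$se
  expect_equal(t0$p, 2 * pt(abs(tstat), df = fit$df_total,
                            lower.tail = FALSE), tolerance = 1e-12)
})

test_that("TREAT p at the boundary |logFC| = lfc lies in (0.5, 1]", {
  fit <- make_fit(matrix(c(0, 0, 0, 1), 1, 4), s2_post = 0.04)
  tt <- treat_test(fit, c("PHO4.PHO2", "pho4d.pho2d"), lfc = 1)
  expect_gt(tt$p, 0.5)
  expect_lte(tt$p, 1)
})

test_that("global BH matches the textbook step-up and pools contrasts", {
  expect_equal(
    bh_adjust_global(list(a = data.frame(gene = "g", logFC = 2,
                                         p = 0.01)))$a$q, 0.01)
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  out <- bh_adjust_global(list(a = data.frame(gene = paste0("g", 1:4),
                                              logFC = 2, p = p4)))
  expect_equal(out$a$q, rep(0.04, 4))

  set.seed(9)
  pa <- runif(50); pb <- runif(30)
  res <- bh_adjust_global(list(
    a = data.frame(gene = paste0("a", 1:50), logFC = 2, p = pa),
    b = data.frame(gene = paste0("b", 1:30), logFC = 2, p = pb)
  ))
  expect_equal(c(res$a$q, res$b$q), oracle_bh(c(pa, pb)), tolerance = 1e-12)
  # monotone in p within the pooled set
  pooled <- rbind(res$a, res$b)
  expect_true(all(diff(pooled$q[order(pooled$p)]) >= -1e-15))
})

test_that("contrast logFCs are additive across genotype chains", {
  set.seed(10)
  fit <- make_fit(matrix(rnorm(40), 10, 4), s2_post = 0.1)
  ab <- treat_test(fit, c("PHO4.PHO2", "PHO4.pho2d"))$logFC
  bc <- treat_test(fit, c("PHO4.pho2d", "pho4d.pho2d"))$logFC
  ac <- treat_test(fit, c("PHO4.PHO2", "pho4d.pho2d"))$logFC
  expect_equal(ac, ab + bc, tolerance = 1e-12)
})

test_that("the pipeline recovers strongly induced genes with controlled FDR", {
  hits <- 0; total <- 0; false <- 0; flagged <- 0
  for (seed in 1:5) {
    tr <- make_expression_truth(n_genes = 1000, seed = seed)
    sim <- simulate_counts(tr, n_rep = 2, lib_sizes = 1e6, seed = seed + 100)
    de <- de_pipeline(sim$counts, sim$samples)
    tab <- de$tables$with_cofactor
    m <- match(tab$gene, tr$gene_id)
    planted_lfc <- (tr$pho4 + tr$co)[m]  # with-cofactor induction
    strong <- planted_lfc >= 2
    hits <- hits + sum(tab$induced & strong)
    total <- total + sum(strong)
    false <- false + sum(tab$induced & planted_lfc <= 1)
    flagged <- flagged + sum(tab$induced)
  }
  expect_gt(hits / total, 0.9)
  expect_lt(false / max(1, flagged), 0.10)
})
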
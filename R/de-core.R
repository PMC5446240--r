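#' Remove genes with too little evidence of expression
#'
#' A gene is dropped iff the number of samples in which its CPM (computed
#' on raw library sizes, before any between-sample normalization) falls
#' below `min_cpm` is at least `min_low_samples`. Gene order is preserved.
#'
#' @param counts integer gene x sample matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_low_samples minimum number of below-threshold samples that
#'   triggers removal (default 3).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_low_samples = 3) {
  stop_if_not(is.matrix(counts) && !anyNA(counts),
              "counts must be a complete numeric matrix")
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  cpm[is.nan(cpm)] <- 0  # empty library: everything is below threshold
  low <- rowSums(cpm < min_cpm)
  keep <- low < min_low_samples
  if (!any(keep)) {
    stop("all genes removed by the low-expression filter", call. = FALSE)
  }
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors computed by the TMM method: for each
#' sample, a weighted trimmed mean of gene-wise log2 ratios (M) against a
#' reference sample, doubly trimmed by M (default 30%) and by average
#' log intensity A (default 5%), with inverse-asymptotic-variance
#' weights; factors are rescaled to geometric mean 1. Delegates to
#' edgeR's implementation; the reference sample is the column whose
#' CPM upper quartile is closest to the mean upper quartile.
#'
#' @param counts integer gene x sample matrix (>= 2 samples).
#' @param trim_M,trim_A trim fractions for the log-ratios and average
#'   intensities.
#' @return data.frame of class `norm_factors`: `sample_id`, `lib_size`,
#'   `factor`.
#' @export
tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  stop_if_not(ncol(counts) >= 2, "TMM needs at least two samples")
  lib <- colSums(counts)
  stop_if_not(all(lib > 0), "library sizes must be positive")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  if (any(!is.finite(f))) {
    warning("sample(s) with no overlap with the reference; factor set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  structure(data.frame(
    sample_id = colnames(counts), lib_size = as.numeric(lib), factor = f,
    stringsAsFactors = FALSE
  ), class = c("norm_factors", "data.frame"))
}

#' Normalized log2 counts-per-million
#'
#' `log2((count + pseudocount) / (lib_size * factor + 1) * 1e6)`, the
#' unweighted log-CPM transform feeding the linear model.
#'
#' @param counts integer gene x sample matrix.
#' @param nf `norm_factors` for the same samples.
#' @param pseudocount added to counts before the log (default 0.5).
#' @return gene x sample numeric matrix of log2 CPM.
#' @export
log_cpm <- function(counts, nf, pseudocount = 0.5) {
  stop_if_not(setequal(colnames(counts), nf$sample_id),
              "normalization factors must cover every sample")
  nf <- nf[match(colnames(counts), nf$sample_id), ]
  eff <- nf$lib_size * nf$factor
  log2(sweep(counts + pseudocount, 2, eff + 1, "/") * 1e6)
}

#' Fit per-gene genotype means
#'
#' Ordinary least squares on the genotype-indicator design
#' `y_ijk = beta_ij + eps_ijk`: the coefficient for each genotype is the
#' mean over its replicates, with a pooled residual variance on
#' `n_samples - n_genotypes` degrees of freedom. Delegates to
#' limma::lmFit.
#'
#' @param logcpm gene x sample log2-CPM matrix.
#' @param samples sample sheet with `sample_id` and `genotype`
#'   (values among [genotype_levels()]).
#' @return object of class `de_fit`: list with `coefficients` (gene x
#'   genotype matrix), `sigma2` (residual variances), `df` (residual
#'   df), `n_per_group`, and `genes`.
#' @export
fit_genotype_means <- function(logcpm, samples) {
  stop_if_not(setequal(colnames(logcpm), samples$sample_id),
              "sample sheet must cover every column")
  samples <- samples[match(colnames(logcpm), samples$sample_id), ]
  gl <- genotype_levels()
  stop_if_not(all(gl %in% samples$genotype),
              "every genotype must have at least one sample")
  g <- factor(samples$genotype, levels = gl)
  design <- stats::model.matrix(~ 0 + g)
  colnames(design) <- gl
  fit <- limma::lmFit(logcpm, design)
  df <- fit$df.residual[1]
  structure(list(
    coefficients = fit$coefficients,
    sigma2 = if (df >= 1) fit$sigma^2 else rep(NA_real_, nrow(logcpm)),
    df = df,
    n_per_group = table(g),
    genes = rownames(logcpm)
  ), class = "de_fit")
}

#' Empirical-Bayes moderation of residual variances
#'
#' Squeezes the gene-wise residual variances toward a common prior by
#' fitting a scaled-F (inverse chi-square) prior to the observed s^2 by
#' moment matching on log s^2 (trigamma inversion), then forming
#' `s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)`. `d0` may be infinite,
#' in which case every posterior variance equals the prior. Delegates
#' to limma::squeezeVar.
#'
#' @param fit a `de_fit` with residual variances on >= 1 df.
#' @param min_genes minimum number of finite variances required for a
#'   stable prior fit.
#' @return the fit, extended with `df_prior`, `s2_prior`, `s2_post` and
#'   `df_total`.
#' @export
moderate_variances <- function(fit, min_genes = 50) {
  stop_if_not(inherits(fit, "de_fit"), "fit must come from fit_genotype_means")
  stop_if_not(fit$df >= 1 && sum(is.finite(fit$sigma2)) >= min_genes,
              paste("variance moderation needs residual df >= 1 and at",
                    "least", min_genes, "genes with finite variances"))
  sv <- limma::squeezeVar(fit$sigma2, df = fit$df)
  fit$df_prior <- sv$df.prior
  fit$s2_prior <- sv$var.prior
  fit$s2_post <- sv$var.post
  # total df capped at the pooled residual df: the information in the
  # prior cannot exceed what the data set as a whole carries
  fit$df_total <- min(fit$df + sv$df.prior,
                      fit$df * sum(is.finite(fit$sigma2)))
  fit
}

contrast_leverage <- function(fit, contrast) {
  stop_if_not(all(contrast %in% colnames(fit$coefficients)),
              paste("unknown genotype in contrast:",
                    paste(setdiff(contrast, colnames(fit$coefficients)),
                          collapse = ", ")))
  n <- fit$n_per_group
  1 / n[[contrast[1]]] + 1 / n[[contrast[2]]]
}

#' Threshold fold-change (TREAT) test for one contrast
#'
#' Tests each gene against the composite null |true logFC| <= `lfc`
#' using the moderated t framework: with `t_r = (|logFC| - lfc)/se` and
#' `t_l = (|logFC| + lfc)/se`, the p-value is
#' `P(T > t_r) + P(T > t_l)` on `df_total` degrees of freedom. With
#' `lfc = 0` this reduces to the ordinary two-sided moderated t-test.
#'
#' @param fit a moderated `de_fit` (see [moderate_variances()]).
#' @param contrast character vector `c(a, b)` of genotype names; the
#'   reported logFC is `beta_a - beta_b`.
#' @param lfc log2 fold-change threshold of the null (default 1, i.e.
#'   fold change <= 2).
#' @return data.frame: `gene`, `logFC`, `se`, `p`.
#' @export
treat_test <- function(fit, contrast, lfc = 1) {
  stop_if_not(!is.null(fit$s2_post),
              "run moderate_variances() before treat_test()")
  lev <- contrast_leverage(fit, contrast)
  logFC <- fit$coefficients[, contrast[1]] - fit$coefficients[, contrast[2]]
  se <- sqrt(fit$s2_post * lev)
  df <- fit$df_total
  p <- ifelse(
    se == 0,
    as.numeric(!(abs(logFC) > lfc)),  # 0 if beyond threshold, else 1
    stats::pt((abs(logFC) - lfc) / se, df = df, lower.tail = FALSE) +
      stats::pt((abs(logFC) + lfc) / se, df = df, lower.tail = FALSE)
  )
  data.frame(gene = fit$genes, logFC = as.numeric(logFC),
             se = as.numeric(se), p = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Globally pooled Benjamini-Hochberg adjustment and induction calls
#'
#' Pools the raw p-values of every contrast into one vector before the
#' BH step-up, so the implied raw-p cutoff is identical across
#' contrasts, then flags a gene as induced in a contrast when q < `fdr`
#' and its logFC exceeds `lfc` (induction, not repression).
#'
#' @param tests named list of data.frames from [treat_test()].
#' @param fdr FDR level (default 0.05).
#' @param lfc the threshold used in the tests (induced requires
#'   logFC > lfc).
#' @return the input list with columns `q` and `induced` added to each
#'   element.
#' @export
bh_adjust_global <- function(tests, fdr = 0.05, lfc = 1) {
  stop_if_not(length(tests) >= 1, "need at least one contrast")
  p_all <- unlist(lapply(tests, `[[`, "p"), use.names = FALSE)
  q_all <- stats::p.adjust(p_all, method = "BH")
  at <- 0
  for (nm in names(tests)) {
    n <- nrow(tests[[nm]])
    tests[[nm]]$q <- q_all[at + seq_len(n)]
    tests[[nm]]$induced <- tests[[nm]]$q < fdr & tests[[nm]]$logFC > lfc
    at <- at + n
  }
  tests
}

#' One-call differential-induction pipeline
#'
#' Filter, TMM, log-CPM, genotype-mean fit, variance moderation, TREAT
#' per contrast, global BH.
#'
#' @param counts integer gene x sample matrix.
#' @param samples sample sheet (`sample_id`, `genotype`, `replicate`).
#' @param contrasts named list of genotype pairs; defaults to induction
#'   with and without the cofactor.
#' @param lfc,fdr test threshold and FDR level.
#' @param min_cpm,min_low_samples filter parameters.
#' @return list with `fit` (moderated `de_fit`), `norm` (factors) and
#'   `tables` (per-contrast data.frames with q and induced flags).
#' @export
de_pipeline <- function(counts, samples,
                        contrasts = list(
                          with_cofactor = c("PHO4.PHO2", "pho4d.PHO2"),
                          without_cofactor = c("PHO4.pho2d", "pho4d.pho2d")
                        ),
                        lfc = 1, fdr = 0.05,
                        min_cpm = 1, min_low_samples = 3) {
  counts <- filter_low_expression(counts, min_cpm, min_low_samples)
  nf <- tmm_factors(counts)
  lc <- log_cpm(counts, nf)
  fit <- fit_genotype_means(lc, samples)
  fit <- moderate_variances(fit)
  tables <- lapply(contrasts, function(ct) treat_test(fit, ct, lfc = lfc))
  tables <- bh_adjust_global(tables, fdr = fdr, lfc = lfc)
  list(fit = fit, norm = nf, tables = tables)
}

#' Induction calls in the shape the integration stage consumes
#'
#' @param tables the `tables` element of [de_pipeline()] output, with
#'   `with_cofactor` and `without_cofactor` entries.
#' @return data.frame: `gene`, `logFC_with`, `q_with`, `induced_with`,
#'   `logFC_without`, `q_without`, `induced_without`.
#' @export
induction_calls <- function(tables) {
  w <- tables$with_cofactor
  wo <- tables$without_cofactor
  stop_if_not(!is.null(w) && !is.null(wo) && identical(w$gene, wo$gene),
              "tables must contain with_cofactor / without_cofactor on the same genes")
  data.frame(
    gene = w$gene,
    logFC_with = w$logFC, q_with = w$q, induced_with = w$induced,
    logFC_without = wo$logFC, q_without = wo$q, induced_without = wo$induced,
    stringsAsFactors = FALSE
  )
}
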
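#' Generate per-gene expression truth for the factorial design
#'
#' Draws a planted truth table for the additive component model: the
#' expected log2 expression of gene i in genotype g is
#' `baseline + X_Pho4 * [TF present] + X_Pho2 * [cofactor present] +
#' CO * [both present]`. Non-null genes are split into three classes
#' mirroring the expression classes of the factorial analysis:
#' class I is dominated by the TF main effect, class II by the
#' collaborative (interaction) component, class III is a weakly induced
#' mix of the two.
#'
#' @param n_genes number of genes.
#' @param frac_induced fraction of genes given non-zero components.
#' @param class_props proportions of induced genes in classes I/II/III
#'   (normalized internally).
#' @param baseline_mean,baseline_sd normal parameters of the baseline
#'   log2-CPM distribution.
#' @param dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2) applied to every gene.
#' @param seed integer seed.
#' @return data.frame of class `expression_truth` with columns `gene_id`,
#'   `baseline_log2cpm`, `pho4`, `pho2`, `co` (log2 units), `class`
#'   (factor: I, II, III, null) and `dispersion`.
#' @export
make_expression_truth <- function(n_genes = 2000, frac_induced = 0.1,
                                  class_props = c(I = 0.6, II = 0.2, III = 0.2),
                                  baseline_mean = 5, baseline_sd = 1.5,
                                  dispersion = 0.05, seed = 1) {
  stop_if_not(dispersion >= 0, "dispersion must be >= 0")
  set.seed(seed)
  n_ind <- round(n_genes * frac_induced)
  props <- class_props / sum(class_props)
  n_cls <- stats::setNames(round(n_ind * props), names(props))
  n_cls[1] <- n_ind - sum(n_cls[-1])
  cls <- c(rep(names(n_cls), times = n_cls),
           rep("null", n_genes - n_ind))
  cls <- sample(cls)

  pho4 <- pho2 <- co <- numeric(n_genes)
  i1 <- cls == "I"; i2 <- cls == "II"; i3 <- cls == "III"
  pho4[i1] <- stats::runif(sum(i1), 2, 4)
  pho2[i1] <- stats::runif(sum(i1), 0, 0.5)
  co[i1]   <- stats::runif(sum(i1), 0, 0.5)
  pho4[i2] <- stats::runif(sum(i2), 0, 0.5)
  co[i2]   <- stats::runif(sum(i2), 2, 4)
  pho4[i3] <- stats::runif(sum(i3), 0.75, 1.25)
  co[i3]   <- stats::runif(sum(i3), 0.75, 1.25)

  structure(data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    baseline_log2cpm = stats::rnorm(n_genes, baseline_mean, baseline_sd),
    pho4 = pho4, pho2 = pho2, co = co,
    class = factor(cls, levels = c("I", "II", "III", "null")),
    dispersion = dispersion,
    stringsAsFactors = FALSE
  ), class = c("expression_truth", "data.frame"))
}

#' Expected log2 expression matrix under the component model
#'
#' @param truth an `expression_truth` data.frame.
#' @return genes x 4 matrix of expected log2 expression, columns in
#'   [genotype_levels()] order.
#' @export
expected_log2_expression <- function(truth) {
  d <- genotype_design()
  m <- sapply(seq_len(nrow(d)), function(j) {
    truth$baseline_log2cpm +
      truth$pho4 * d$has_tf[j] +
      truth$pho2 * d$has_cofactor[j] +
      truth$co * (d$has_tf[j] & d$has_cofactor[j])
  })
  dimnames(m) <- list(truth$gene_id, d$genotype)
  m
}

#' Simulate a factorial RNA-seq count matrix from planted truth
#'
#' Counts for sample s, gene i are negative binomial with mean
#' `lib_size[s] * p[i, g(s)]` where `p[, g]` renormalizes
#' `2^expected log2 expression` to proportions within genotype g, and NB
#' size `1/dispersion` (Poisson when dispersion is 0).
#'
#' @param truth an `expression_truth` data.frame.
#' @param n_rep replicates per genotype (>= 1).
#' @param lib_sizes per-sample library sizes; a scalar is recycled, a
#'   vector must have length `4 * n_rep` (genotype-major sample order).
#' @param seed integer seed.
#' @return list of class `sim_counts` with `counts` (integer gene x
#'   sample matrix), `samples` (sample sheet: `sample_id`, `genotype`,
#'   `replicate`) and `truth`.
#' @export
simulate_counts <- function(truth, n_rep = 2, lib_sizes = 2e6, seed = 1) {
  stop_if_not(n_rep >= 1, "need at least one replicate per genotype")
  stop_if_not(all(truth$dispersion >= 0), "dispersions must be >= 0")
  set.seed(seed)
  gl <- genotype_levels()
  samples <- data.frame(
    sample_id = paste0(rep(gl, each = n_rep), ".r", rep(seq_len(n_rep), 4)),
    genotype = rep(gl, each = n_rep),
    replicate = rep(seq_len(n_rep), 4),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(samples)
  if (length(lib_sizes) == 1) lib_sizes <- rep(lib_sizes, n_s)
  stop_if_not(length(lib_sizes) == n_s,
              "lib_sizes must be scalar or one per sample")

  e <- 2^expected_log2_expression(truth)
  p <- sweep(e, 2, colSums(e), "/")
  counts <- matrix(0L, nrow(truth), n_s,
                   dimnames = list(truth$gene_id, samples$sample_id))
  for (s in seq_len(n_s)) {
    mu <- lib_sizes[s] * p[, samples$genotype[s]]
    phi <- truth$dispersion
    x <- numeric(length(mu))
    pois <- phi == 0
    if (any(pois)) x[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) {
      x[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                 size = 1 / phi[!pois])
    }
    counts[, s] <- as.integer(x)
  }
  structure(list(counts = counts, samples = samples, truth = truth),
            class = "sim_counts")
}

#' Write / read a count matrix with its sample sheet
#'
#' The count TSV carries a `gene_id` column followed by one column per
#' sample; the sample sheet TSV has columns `sample_id`, `genotype`,
#' `replicate`.
#'
#' @param sim a `sim_counts` object (or a list with `counts` and
#'   `samples`).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_counts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, cp)
  sp <- file.path(dir, "samples.tsv")
  write_tsv(sim$samples, sp)
  tp <- NULL
  if (!is.null(sim$truth)) {
    tp <- file.path(dir, "expression_truth.tsv")
    write_tsv(sim$truth, tp)
  }
  invisible(c(counts = cp, samples = sp, truth = tp))
}

#' @rdname write_counts
#' @param counts_path,samples_path paths to the two TSVs.
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  samples <- read_tsv(samples_path)
  stop_if_not(setequal(samples$sample_id, colnames(m)) &&
                !anyDuplicated(samples$sample_id),
              "sample sheet IDs must be bijective with count columns")
  m <- m[, samples$sample_id, drop = FALSE]
  structure(list(counts = m, samples = samples), class = "sim_counts")
}
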
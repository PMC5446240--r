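default_config <- function() {
  list(
    mode = "simulate",
    out_dir = "pho4cycle_run",
    seed = 1,
    thresholds = list(lfc = 1, fdr = 0.05, min_fe = 3, fold_cut = 2,
                      max_mm = 2),
    simulate = list(n_chrom = 2, chrom_len = 25000, n_genome_genes = 16,
                    n_genes = 500, n_rep = 2, lib_size = 1e6,
                    dispersion = 0.05, noise_sd = 0.1),
    paths = list(counts = NULL, samples = NULL, fasta = NULL,
                 genes_bed = NULL, tf_co = NULL, tf_noco = NULL,
                 cofactor = NULL, mock = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' YAML document whose keys override the packaged defaults; see
#' [run_all()] for the recognized fields. In `files` mode every
#' referenced input path must exist at validation time.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- merge_config(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  stop_if_not(all(unlist(th) > 0), "thresholds must be positive")
  stop_if_not(cfg$mode %in% c("simulate", "files"),
              "mode must be 'simulate' or 'files'")
  if (cfg$mode == "files") {
    need <- c("counts", "samples", "fasta", "genes_bed", "tf_co",
              "tf_noco", "cofactor", "mock")
    for (nm in need) {
      p <- cfg$paths[[nm]]
      stop_if_not(!is.null(p) && file.exists(p),
                  paste0("missing input file for '", nm, "'"))
    }
  }
  cfg
}

#' Run the full pipeline
#'
#' Executes synthetic-data generation (in `simulate` mode) or loads the
#' declared input files, then the differential-induction engine, the
#' mutant-cycle decomposition and clustering, ChIP normalization, peak
#' calling and dependence classification, motif grading, and the
#' ChIP x expression integration. Every stage writes its outputs under
#' `out_dir` and a manifest records the seed, parameters and md5
#' checksums of all files, so a fixed-seed run is reproducible
#' file-by-file.
#'
#' @param config a config list (see [read_run_config()]) or the path to
#'   a YAML config.
#' @return invisibly, a list with the main stage outputs (`de`,
#'   `components`, `classes`, `dependence`, `motif_census`, `targets`,
#'   `summary`, `manifest`).
#' @export
run_all <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_config(merge_config(default_config(), config))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  sm <- cfg$simulate

  if (cfg$mode == "simulate") {
    data_dir <- file.path(out, "data")
    genome <- make_toy_genome(
      n_chrom = sm$n_chrom, chrom_len = sm$chrom_len,
      n_genes = sm$n_genome_genes,
      motif_plan = c("0" = sm$n_genome_genes), strands = "plus",
      seed = cfg$seed, out_dir = data_dir
    )
    truth <- variant_expression_truth(
      n_genes = sm$n_genes, genome_genes = genome$genes$gene_id,
      variant = "independent", dispersion = sm$dispersion,
      seed = cfg$seed + 1
    )
    sim <- simulate_counts(truth, n_rep = sm$n_rep,
                           lib_sizes = sm$lib_size, seed = cfg$seed + 2)
    write_counts(sim, data_dir)
    ct <- make_chip_truth(
      genome, n_peaks = nrow(genome$motifs),
      n_cobound = round(0.75 * nrow(genome$motifs)), n_dependent = 2,
      summits = data.frame(chrom = genome$motifs$chrom,
                           pos = genome$motifs$pos + 2L),
      seed = cfg$seed + 3
    )
    write_tsv(ct, file.path(data_dir, "chip_truth.tsv"))
    tracks <- simulate_chip_tracks(genome, ct, noise_sd = sm$noise_sd,
                                   seed = cfg$seed + 4)
    for (nm in names(tracks)) {
      write_bedgraph(tracks[[nm]], file.path(data_dir, paste0(nm, ".bedgraph")))
    }
    cfg$paths <- list(
      counts = file.path(data_dir, "counts.tsv"),
      samples = file.path(data_dir, "samples.tsv"),
      fasta = file.path(data_dir, "genome.fa"),
      genes_bed = file.path(data_dir, "genes.bed"),
      tf_co = file.path(data_dir, "tf_co.bedgraph"),
      tf_noco = file.path(data_dir, "tf_noco.bedgraph"),
      cofactor = file.path(data_dir, "cofactor.bedgraph"),
      mock = file.path(data_dir, "mock.bedgraph")
    )
  }

  # every stage consumes the declared files, not in-memory state
  cm <- read_counts(cfg$paths$counts, cfg$paths$samples)
  genome_seq <- read_genome_fasta(cfg$paths$fasta)
  genes <- read_gene_bed(cfg$paths$genes_bed)
  chrom_lengths <- vapply(genome_seq, nchar, integer(1))
  tr <- lapply(cfg$paths[c("tf_co", "tf_noco", "cofactor", "mock")],
               read_bedgraph, chrom_lengths = chrom_lengths)

  de_dir <- file.path(out, "de")
  dir.create(de_dir, showWarnings = FALSE)
  de <- de_pipeline(cm$counts, cm$samples, lfc = th$lfc, fdr = th$fdr)
  for (nm in names(de$tables)) {
    write_tsv(de$tables[[nm]], file.path(de_dir, paste0(nm, ".tsv")))
  }
  write_tsv(de$norm, file.path(de_dir, "normalization.tsv"))

  cyc_dir <- file.path(out, "cycle")
  dir.create(cyc_dir, showWarnings = FALSE)
  comp <- decompose_induction(de$fit)
  classes <- cluster_classes(comp, k = 3)
  comp_out <- data.frame(comp, class = classes$labels,
                         stringsAsFactors = FALSE)
  write_tsv(comp_out, file.path(cyc_dir, "components.tsv"))

  chip_dir <- file.path(out, "chip")
  dir.create(chip_dir, showWarnings = FALSE)
  tf_co <- normalize_track(tr$tf_co)
  tf_noco <- normalize_track(tr$tf_noco)
  cof <- normalize_track(tr$cofactor)
  mock <- normalize_track(tr$mock)
  peaks <- call_peaks_simple(tf_co, mock, min_fe = th$min_fe)
  cof_peaks <- call_peaks_simple(cof, mock, min_fe = th$min_fe,
                                 factor = "cofactor")
  ratios <- occupancy_ratio(peaks, tf_noco, tf_co)
  dep <- classify_dependence(peaks, cof_peaks, ratios,
                             fold_cut = th$fold_cut)
  write_peaks_bed(dep$table, file.path(chip_dir, "tf_peaks.bed"))
  write_peaks_bed(cof_peaks, file.path(chip_dir, "cofactor_peaks.bed"))
  write_tsv(data.frame(category = names(dep$counts),
                       n = as.integer(dep$counts)),
            file.path(chip_dir, "dependence_counts.tsv"))

  motif_dir <- file.path(out, "motif")
  dir.create(motif_dir, showWarnings = FALSE)
  mot <- best_motif_per_peak(peaks, genome_seq, max_mm = th$max_mm)
  write_tsv(mot$per_peak, file.path(motif_dir, "peak_motifs.tsv"))
  write_tsv(data.frame(grade = names(mot$census),
                       n = as.integer(mot$census)),
            file.path(motif_dir, "motif_census.tsv"))

  int_dir <- file.path(out, "integrate")
  dir.create(int_dir, showWarnings = FALSE)
  tt <- assign_peaks_to_genes(peaks, genes)
  calls <- induction_calls(de$tables)
  tgt <- call_direct_targets(tt, calls)
  write_tsv(tgt$assignments, file.path(int_dir, "targets.tsv"))
  scored <- sum(!is.na(tgt$per_peak$category))
  functional <- sum(tgt$per_peak$category != "non-functional",
                    na.rm = TRUE)
  summary <- list(
    n_peaks = nrow(peaks),
    n_assigned_peaks = length(unique(tt$peak_id)),
    n_direct_targets = length(tgt$direct_targets),
    percent_activated = if (scored > 0)
      percent_activated(scored, functional) else NA,
    category_counts = as.list(tgt$category_counts),
    dependence_counts = as.list(dep$counts),
    motif_census = as.list(mot$census),
    class_sizes = as.list(table(classes$labels))
  )
  jsonlite::write_json(summary, file.path(int_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pho4cycle")),
    seed = cfg$seed,
    thresholds = th,
    simulate = if (cfg$mode == "simulate") sm else NULL,
    checksums = as.list(tools::md5sum(sort(files)))
  )
  rel <- substring(names(manifest$checksums), nchar(out) + 2)
  names(manifest$checksums) <- rel
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(de = de, components = comp_out, classes = classes,
                 dependence = dep, motif_census = mot$census,
                 targets = tgt, summary = summary, manifest = manifest))
}

#' Expression truth for a TF variant differing in cofactor dependence
#'
#' Builds the planted truth used by the two-variant comparison: the
#' genes carrying a binding site (`genome_genes`) are induced mostly
#' through the TF main effect for the cofactor-`independent` variant
#' (so induction survives cofactor loss) and only through the
#' collaborative component for the `dependent` variant (induction
#' requires the cofactor); a fraction of bound genes stays uninduced in
#' both, giving non-functional peaks. All other genes are null filler.
#'
#' @param n_genes total genes in the count matrix.
#' @param genome_genes gene ids carrying a peak (must be the first ids
#'   of the truth table's genome).
#' @param variant `"independent"` or `"dependent"`.
#' @param frac_functional fraction of bound genes that are induced
#'   (defaults: 0.8 for independent, 0.4 for dependent).
#' @param dispersion NB dispersion.
#' @param seed integer seed.
#' @return an `expression_truth` data.frame.
#' @export
variant_expression_truth <- function(n_genes, genome_genes,
                                     variant = c("independent", "dependent"),
                                     frac_functional = NULL,
                                     dispersion = 0.05, seed = 1) {
  variant <- match.arg(variant)
  if (is.null(frac_functional)) {
    frac_functional <- if (variant == "independent") 0.8 else 0.4
  }
  set.seed(seed)
  nb <- length(genome_genes)
  stop_if_not(nb <= n_genes, "more bound genes than total genes")
  filler_ids <- sprintf("f%04d", seq_len(n_genes - nb))
  gene_id <- c(genome_genes, filler_ids)

  pho4 <- pho2 <- co <- numeric(n_genes)
  cls <- rep("null", n_genes)
  n_fun <- round(frac_functional * nb)
  fun <- sample(nb, n_fun)
  if (variant == "independent") {
    pho4[fun] <- stats::runif(n_fun, 2.5, 4)
    cls[fun] <- "I"
  } else {
    co[fun] <- stats::runif(n_fun, 2.5, 4)
    cls[fun] <- "II"
  }
  baseline <- stats::rnorm(n_genes, 5, 1.2)
  baseline[seq_len(nb)] <- stats::rnorm(nb, 6, 0.8)  # bound genes well covered

  structure(data.frame(
    gene_id = gene_id, baseline_log2cpm = baseline,
    pho4 = pho4, pho2 = pho2, co = co,
    class = factor(cls, levels = c("I", "II", "III", "null")),
    dispersion = dispersion, stringsAsFactors = FALSE
  ), class = c("expression_truth", "data.frame"))
}

#' End-to-end comparison of a cofactor-dependent vs independent TF
#'
#' Runs the full synthetic pipeline twice — once for a TF variant whose
#' bound genes are induced through the TF main effect (cofactor
#' independent) and once for a variant inducing only through the
#' collaborative component (cofactor dependent) — and summarizes, per
#' variant, the percentage of scored peaks whose downstream gene is
#' induced and the per-peak functional category counts.
#'
#' @param seed integer seed.
#' @param n_genes genes in each count matrix.
#' @param n_genome_genes bound genes (= peaks) per variant.
#' @param n_rep replicates per genotype.
#' @param noise_sd ChIP track noise.
#' @return list with one element per variant (`percent_activated`,
#'   `category_counts`, `n_scored`) plus `direction_ok`: TRUE when the
#'   independent variant shows the higher percent activated and its
#'   functional peaks are dominated by induction with or without the
#'   cofactor while the dependent variant's are dominated by
#'   cofactor-requiring induction.
#' @export
run_variant_comparison <- function(seed = 1, n_genes = 300,
                                   n_genome_genes = 16, n_rep = 2,
                                   noise_sd = 0.1) {
  one <- function(variant, off) {
    genome <- make_toy_genome(
      n_chrom = 2, chrom_len = 25000, n_genes = n_genome_genes,
      motif_plan = c("0" = n_genome_genes), strands = "plus",
      seed = seed + off
    )
    truth <- variant_expression_truth(
      n_genes, genome$genes$gene_id, variant = variant,
      seed = seed + off + 1
    )
    sim <- simulate_counts(truth, n_rep = n_rep, lib_sizes = 1e6,
                           seed = seed + off + 2)
    de <- de_pipeline(sim$counts, sim$samples)
    calls <- induction_calls(de$tables)

    ct <- make_chip_truth(
      genome, n_peaks = nrow(genome$motifs),
      n_cobound = nrow(genome$motifs), n_dependent = 0,
      summits = data.frame(chrom = genome$motifs$chrom,
                           pos = genome$motifs$pos + 2L),
      seed = seed + off + 3
    )
    tracks <- simulate_chip_tracks(genome, ct, noise_sd = noise_sd,
                                   seed = seed + off + 4)
    tf <- normalize_track(tracks$tf_co)
    mock <- normalize_track(tracks$mock)
    peaks <- call_peaks_simple(tf, mock)
    tt <- assign_peaks_to_genes(peaks, genome$genes)
    tgt <- call_direct_targets(tt, calls)
    scored <- sum(!is.na(tgt$per_peak$category))
    functional <- sum(tgt$per_peak$category != "non-functional",
                      na.rm = TRUE)
    list(
      percent_activated = percent_activated(scored, functional),
      category_counts = tgt$category_counts,
      n_scored = scored
    )
  }
  ind <- one("independent", 0)
  dep <- one("dependent", 1000)
  direction_ok <-
    ind$percent_activated > dep$percent_activated &&
    ind$category_counts[["induced-with-or-without"]] >
      ind$category_counts[["induced-only-with-cofactor"]] &&
    dep$category_counts[["induced-only-with-cofactor"]] >
      dep$category_counts[["induced-with-or-without"]]
  list(independent = ind, dependent = dep, direction_ok = direction_ok)
}
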
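#' Scale a coverage track to mean 1
#'
#' Divides every per-bp value by the genome-wide mean so the average
#' coverage per base pair is exactly 1; idempotent, and preserves all
#' ratios between positions.
#'
#' @param track a `coverage_track`.
#' @return the normalized track (`normalized` flag set).
#' @export
normalize_track <- function(track) {
  tot <- sum(vapply(track$values, sum, numeric(1)))
  len <- sum(vapply(track$values, length, numeric(1)))
  stop_if_not(tot > 0, "cannot normalize an all-zero track")
  m <- tot / len
  track$values <- lapply(track$values, function(v) v / m)
  track$normalized <- TRUE
  track
}

#' Simple fold-enrichment peak caller for synthetic tracks
#'
#' Computes per-bp fold enrichment `FE = (tf + eps) / (mock + eps)`,
#' takes maximal runs with `FE >= min_fe`, merges runs separated by at
#' most `merge_gap` bp, drops merged runs shorter than `min_width`, and
#' records for each surviving peak the summit (leftmost argmax of FE)
#' and height (max FE). Coordinates are 1-based inclusive; use
#' [write_peaks_bed()] for 0-based BED output.
#'
#' @param tf,mock normalized `coverage_track`s over the same genome.
#' @param min_fe fold-enrichment threshold (default 3).
#' @param min_width minimum peak width in bp (default 50).
#' @param merge_gap maximum gap merged between runs (default 100).
#' @param eps pseudo-enrichment floor avoiding division by zero.
#' @param factor,condition labels stamped on the output.
#' @return data.frame of class `peak_set`: `peak_id`, `chrom`, `start`,
#'   `end`, `summit`, `height`, `factor`, `condition`.
#' @export
call_peaks_simple <- function(tf, mock, min_fe = 3, min_width = 50,
                              merge_gap = 100, eps = 1e-3,
                              factor = tf$sample, condition = tf$condition) {
  stop_if_not(identical(names(tf$values), names(mock$values)) &&
                all(vapply(tf$values, length, integer(1)) ==
                      vapply(mock$values, length, integer(1))),
              "tf and mock tracks must cover identical chromosomes")
  peaks <- list()
  for (ch in names(tf$values)) {
    fe <- (tf$values[[ch]] + eps) / (mock$values[[ch]] + eps)
    above <- fe >= min_fe
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by small gaps
    if (nrow(runs) > 1) {
      keep_open <- runs$start[-1] - runs$end[-nrow(runs)] - 1 <= merge_gap
      grp <- cumsum(c(TRUE, !keep_open))
      runs <- data.frame(
        start = tapply(runs$start, grp, min),
        end = tapply(runs$end, grp, max)
      )
    }
    # width counts above-threshold bases, so sparse noise spikes bridged
    # by merge_gap cannot masquerade as a wide peak
    covered <- vapply(seq_len(nrow(runs)), function(i) {
      sum(above[runs$start[i]:runs$end[i]])
    }, numeric(1))
    runs <- runs[covered >= min_width, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      w <- runs$start[i]:runs$end[i]
      peak_fe <- fe[w]
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, start = runs$start[i], end = runs$end[i],
        summit = w[which.max(peak_fe)], height = max(peak_fe),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(peaks) == 0) {
    out <- data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), height = numeric(0),
                      factor = character(0), condition = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, peaks)
    out <- data.frame(peak_id = sprintf("peak%04d", seq_len(nrow(out))),
                      out, factor = factor, condition = condition,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("peak_set", "data.frame")
  out
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start, end = peaks$end)
  )
}

#' Overlap two peak sets
#'
#' A peak of `a` is shared iff it overlaps some peak of `b` by at least
#' one bp (and vice versa); counts are reported Venn-style.
#'
#' @param a,b `peak_set` data.frames on the same genome.
#' @return list with logical vectors `shared_a`, `shared_b` and a named
#'   `counts` vector (`shared_a`, `specific_a`, `shared_b`,
#'   `specific_b`).
#' @export
peak_overlap <- function(a, b) {
  shared_a <- rep(FALSE, nrow(a))
  shared_b <- rep(FALSE, nrow(b))
  if (nrow(a) > 0 && nrow(b) > 0) {
    # disjoint chromosome sets are legitimate input (all peaks specific)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(peaks_granges(a), peaks_granges(b))
    )
    shared_a[unique(S4Vectors::queryHits(hits))] <- TRUE
    shared_b[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  list(shared_a = shared_a, shared_b = shared_b,
       counts = c(shared_a = sum(shared_a),
                  specific_a = sum(!shared_a),
                  shared_b = sum(shared_b),
                  specific_b = sum(!shared_b)))
}

#' Occupancy ratio of a TF across cofactor conditions
#'
#' For each peak interval, the ratio of the maximum normalized coverage
#' without the cofactor to the maximum with it, reported on the log2
#' scale; a floor of `eps` is added to both maxima.
#'
#' @param peaks a `peak_set`.
#' @param track_noco,track_co normalized `coverage_track`s for the TF
#'   without and with the cofactor.
#' @param eps pseudo-enrichment floor (default 1e-3).
#' @return numeric vector of per-peak log2 ratios, named by `peak_id`.
#' @export
occupancy_ratio <- function(peaks, track_noco, track_co, eps = 1e-3) {
  stop_if_not(all(peaks$chrom %in% names(track_co$values)),
              "peak outside the coverage tracks")
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    len <- length(track_co$values[[ch]])
    stop_if_not(peaks$start[i] >= 1 && peaks$end[i] <= len,
                "peak outside the coverage tracks")
    w <- peaks$start[i]:peaks$end[i]
    log2((max(track_noco$values[[ch]][w]) + eps) /
           (max(track_co$values[[ch]][w]) + eps))
  }, numeric(1))
  stats::setNames(out, peaks$peak_id)
}

#' Classify TF peaks by cofactor co-binding and dependence
#'
#' A TF peak is co-bound when it overlaps a cofactor peak; a co-bound
#' peak is cofactor-dependent when its height drops by more than
#' `fold_cut`-fold without the cofactor, i.e. its log2 occupancy ratio
#' is below `-log2(fold_cut)`.
#'
#' @param peaks TF `peak_set`.
#' @param cofactor_peaks cofactor `peak_set`.
#' @param ratios per-peak log2 occupancy ratios ([occupancy_ratio()]),
#'   aligned with `peaks`.
#' @param fold_cut dependence fold threshold (default 2).
#' @return list with `table` (peaks plus `cobound`, `log2_ratio`,
#'   `category`) and `counts` (dependent / independent / not-cobound).
#' @export
classify_dependence <- function(peaks, cofactor_peaks, ratios,
                                fold_cut = 2) {
  stop_if_not(length(ratios) == nrow(peaks),
              "one ratio per TF peak required")
  cobound <- peak_overlap(peaks, cofactor_peaks)$shared_a
  dependent <- cobound & ratios < -log2(fold_cut)
  category <- ifelse(!cobound, "not-cobound",
                     ifelse(dependent, "dependent", "independent"))
  tab <- data.frame(peaks, cobound = cobound,
                    log2_ratio = as.numeric(ratios),
                    category = category, stringsAsFactors = FALSE)
  counts <- c(dependent = sum(category == "dependent"),
              independent = sum(category == "independent"),
              `not-cobound` = sum(category == "not-cobound"))
  list(table = tab, counts = counts)
}

#' Bootstrap confidence intervals for group means
#'
#' Percentile bootstrap of the mean within each group.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @param B bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame: `group`, `n`, `mean`, `lower`, `upper` (CI
#'   bounds are NA for singleton groups).
#' @export
group_mean_bootstrap <- function(values, groups, B = 10000, seed = 1,
                                 conf = 0.95) {
  set.seed(seed)
  a <- (1 - conf) / 2
  grs <- unique(groups)
  out <- lapply(grs, function(g) {
    v <- values[groups == g]
    n <- length(v)
    if (n < 2) {
      return(data.frame(group = g, n = n, mean = mean(v),
                        lower = NA_real_, upper = NA_real_,
                        stringsAsFactors = FALSE))
    }
    bm <- rowMeans(matrix(sample(v, n * B, replace = TRUE), nrow = B))
    ci <- stats::quantile(bm, c(a, 1 - a), names = FALSE)
    data.frame(group = g, n = n, mean = mean(v),
               lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sample t-test on group means
#'
#' Pooled-variance Student's t-test (or Welch under
#' `variant = "welch"`), two-sided. Degenerate zero-variance input with
#' equal means yields t = 0, p = 1 rather than an error.
#'
#' @param values numeric vector.
#' @param groups labels with exactly two levels, aligned with `values`.
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @return list with `t`, `df`, `p`, `means` (named group means).
#' @export
group_ttest <- function(values, groups, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  grs <- unique(groups)
  stop_if_not(length(grs) == 2, "exactly two groups required")
  x <- values[groups == grs[1]]
  y <- values[groups == grs[2]]
  stop_if_not(length(x) >= 2 && length(y) >= 2,
              "each group needs at least two values")
  means <- stats::setNames(c(mean(x), mean(y)), as.character(grs))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (means[1] == means[2]) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  means = means))
    }
    return(list(t = sign(means[1] - means[2]) * Inf,
                df = length(x) + length(y) - 2, p = 0, means = means))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, means = means)
}

#' Write peaks as BED6+ / read them back
#'
#' BED columns: chrom, start (0-based), end, name `factor:condition`,
#' score `trunc(height * 100)`, strand `.`, then summit (0-based),
#' height, and any extra columns present (`log2_ratio`, `category`).
#'
#' @param peaks a `peak_set` (optionally with classification columns).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  extra <- intersect(c("log2_ratio", "category"), names(peaks))
  df <- data.frame(
    peaks$chrom, peaks$start - 1L, peaks$end,
    paste0(peaks$factor, ":", peaks$condition),
    trunc(peaks$height * 100), ".",
    peaks$summit - 1L, peaks$height,
    stringsAsFactors = FALSE
  )
  for (cn in extra) df[[cn]] <- peaks[[cn]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(b) >= 8, "expected the BED6+ layout of write_peaks_bed")
  name <- strsplit(b[[4]], ":", fixed = TRUE)
  out <- data.frame(
    peak_id = sprintf("peak%04d", seq_len(nrow(b))),
    chrom = b[[1]], start = b[[2]] + 1L, end = b[[3]],
    summit = b[[7]] + 1L, height = b[[8]],
    factor = vapply(name, `[`, character(1), 1),
    condition = vapply(name, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  if (ncol(b) >= 9) out$log2_ratio <- b[[9]]
  if (ncol(b) >= 10) out$category <- b[[10]]
  class(out) <- c("peak_set", "data.frame")
  out
}
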
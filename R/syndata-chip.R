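#' Generate planted ChIP peak truth
#'
#' Draws a set of TF binding peaks with Gaussian shape parameters, a
#' cofactor co-binding flag and, for co-bound peaks, an attenuation
#' factor alpha applied to the peak height when the cofactor is absent.
#' Dependent peaks (alpha < 0.5, i.e. more than a twofold height drop)
#' and independent co-bound peaks draw alpha from well-separated ranges
#' so the planted dichotomy survives the baseline and normalization of
#' realistic tracks. Peaks not co-bound keep alpha = 1.
#'
#' @param chrom_lengths named integer vector of chromosome lengths, or a
#'   `toy_genome` (its chromosome lengths are used).
#' @param n_peaks total number of TF peaks.
#' @param n_cobound how many of them are co-bound by the cofactor.
#' @param n_dependent how many of the co-bound peaks are
#'   cofactor-dependent (alpha drawn from `alpha_dependent`).
#' @param height_range uniform range of peak heights (fold enrichment
#'   over the baseline of 1).
#' @param sigma Gaussian width parameter in bp.
#' @param alpha_dependent,alpha_independent uniform alpha ranges for
#'   dependent and independent co-bound peaks.
#' @param min_spacing minimum distance between summits in bp.
#' @param summits optional data.frame (`chrom`, `pos`) pinning summit
#'   locations (e.g. to planted motifs); overrides random placement.
#' @param seed integer seed.
#' @return data.frame of class `chip_truth`: `peak_id`, `chrom`,
#'   `summit`, `sigma`, `height`, `alpha`, `cobound`.
#' @export
make_chip_truth <- function(chrom_lengths, n_peaks = 20, n_cobound = 15,
                            n_dependent = 3, height_range = c(8, 20),
                            sigma = 50, alpha_dependent = c(0.1, 0.4),
                            alpha_independent = c(0.65, 1),
                            min_spacing = 2000, summits = NULL, seed = 1) {
  if (inherits(chrom_lengths, "toy_genome")) {
    chrom_lengths <- vapply(chrom_lengths$chromosomes, nchar, integer(1))
  }
  stop_if_not(n_cobound <= n_peaks, "n_cobound must be <= n_peaks")
  stop_if_not(n_dependent <= n_cobound, "n_dependent must be <= n_cobound")
  set.seed(seed)

  if (is.null(summits)) {
    # evenly spread candidate summits, then jitter within half the spacing
    per <- ceiling(n_peaks / length(chrom_lengths))
    cand <- do.call(rbind, lapply(seq_along(chrom_lengths), function(i) {
      len <- chrom_lengths[i]
      usable <- len - 2 * (4 * sigma)
      stop_if_not(usable > per * min_spacing,
                  "chromosomes too short for requested peak count/spacing")
      at <- round(seq(4 * sigma, len - 4 * sigma, length.out = per + 2))
      at <- at[2:(per + 1)]
      data.frame(chrom = names(chrom_lengths)[i], pos = at,
                 stringsAsFactors = FALSE)
    }))
    cand <- cand[seq_len(n_peaks), , drop = FALSE]
    jit <- round(stats::runif(n_peaks, -min_spacing / 5, min_spacing / 5))
    summits <- data.frame(chrom = cand$chrom, pos = cand$pos + jit,
                          stringsAsFactors = FALSE)
  }
  stop_if_not(nrow(summits) >= n_peaks, "not enough summit positions")
  summits <- summits[seq_len(n_peaks), , drop = FALSE]
  stop_if_not(all(summits$pos >= 1 &
                    summits$pos <= chrom_lengths[summits$chrom]),
              "peak summits must lie within chromosome bounds")

  cobound <- c(rep(TRUE, n_cobound), rep(FALSE, n_peaks - n_cobound))
  alpha <- rep(1, n_peaks)
  dep_idx <- seq_len(n_dependent)
  ind_idx <- setdiff(which(cobound), dep_idx)
  alpha[dep_idx] <- stats::runif(n_dependent, alpha_dependent[1],
                                 alpha_dependent[2])
  alpha[ind_idx] <- stats::runif(length(ind_idx), alpha_independent[1],
                                 alpha_independent[2])

  ord <- sample(n_peaks)  # decouple planted order from genomic order
  structure(data.frame(
    peak_id = sprintf("pk%03d", seq_len(n_peaks)),
    chrom = summits$chrom[ord], summit = as.integer(summits$pos[ord]),
    sigma = sigma,
    height = stats::runif(n_peaks, height_range[1], height_range[2]),
    alpha = alpha[ord], cobound = cobound[ord],
    stringsAsFactors = FALSE
  ), class = c("chip_truth", "data.frame"))
}

new_coverage_track <- function(values, sample, condition,
                               normalized = FALSE) {
  structure(list(values = values, sample = sample, condition = condition,
                 normalized = normalized),
            class = "coverage_track")
}

#' Simulate ChIP coverage tracks from planted peak truth
#'
#' Produces four per-bp tracks over the given chromosomes: the TF with
#' the cofactor present (`tf_co`), the TF without the cofactor
#' (`tf_noco`, peak heights multiplied by each peak's alpha), the
#' cofactor itself (`cofactor`, bumps only at co-bound peaks) and a
#' `mock` control. Each peak contributes a Gaussian bump
#' `height * exp(-(x - summit)^2 / (2 sigma^2))` on a baseline of 1;
#' i.i.d. normal noise of sd `noise_sd` is added and values are clipped
#' at 0. Overlapping planted bumps (summits closer than 4 sigma on one
#' track) sum and raise a warning.
#'
#' @param genome a `toy_genome` or named integer vector of chromosome
#'   lengths.
#' @param chip_truth a `chip_truth` data.frame.
#' @param noise_sd noise standard deviation in enrichment units.
#' @param seed integer seed.
#' @return named list of four `coverage_track` objects.
#' @export
simulate_chip_tracks <- function(genome, chip_truth, noise_sd = 0.2,
                                 seed = 1) {
  chrom_lengths <- if (inherits(genome, "toy_genome")) {
    vapply(genome$chromosomes, nchar, integer(1))
  } else genome
  stop_if_not(all(chip_truth$summit >= 1 &
                    chip_truth$summit <= chrom_lengths[chip_truth$chrom]),
              "peaks must lie within chromosome bounds")
  set.seed(seed)

  close_pairs <- unlist(lapply(split(chip_truth, chip_truth$chrom),
                               function(d) {
    s <- sort(d$summit)
    diff(s) < 4 * d$sigma[1]
  }))
  if (any(close_pairs)) {
    warning("overlapping planted peaks on one track; signals are summed")
  }

  bump_field <- function(height_of) {
    lapply(stats::setNames(names(chrom_lengths), names(chrom_lengths)),
           function(ch) {
      len <- chrom_lengths[[ch]]
      v <- rep(1, len)
      d <- chip_truth[chip_truth$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        h <- height_of(d[i, ])
        if (h == 0) next
        lo <- max(1L, d$summit[i] - as.integer(6 * d$sigma[i]))
        hi <- min(len, d$summit[i] + as.integer(6 * d$sigma[i]))
        x <- lo:hi
        v[x] <- v[x] + h * exp(-(x - d$summit[i])^2 / (2 * d$sigma[i]^2))
      }
      v
    })
  }

  add_noise <- function(values) {
    if (noise_sd == 0) return(values)
    lapply(values, function(v) pmax(0, v + stats::rnorm(length(v), 0,
                                                        noise_sd)))
  }

  list(
    tf_co = new_coverage_track(
      add_noise(bump_field(function(p) p$height)), "tf", "with_cofactor"),
    tf_noco = new_coverage_track(
      add_noise(bump_field(function(p) p$alpha * p$height)),
      "tf", "without_cofactor"),
    cofactor = new_coverage_track(
      add_noise(bump_field(function(p) if (p$cobound) p$height else 0)),
      "cofactor", "with_cofactor"),
    mock = new_coverage_track(
      add_noise(lapply(chrom_lengths, function(len) rep(1, len))),
      "mock", "control")
  )
}

#' bedGraph output for a coverage track
#'
#' Runs of equal value are collapsed; coordinates are 0-based half-open
#' per the bedGraph convention. Values are printed with 17 significant
#' digits so a read/write cycle is lossless.
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, start, end, r$values), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_lengths optional named lengths used to validate and pad
#'   the parsed track; inferred from the file when omitted.
#' @param sample,condition metadata attached to the returned track.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL, sample = NA_character_,
                          condition = NA_character_) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "value"))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(b$end, b$chrom, max)
    chrom_lengths <- chrom_lengths[unique(b$chrom)]  # keep file order
  }
  values <- lapply(stats::setNames(names(chrom_lengths),
                                   names(chrom_lengths)), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    d <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      v[(d$start[i] + 1):d$end[i]] <- d$value[i]
    }
    v
  })
  new_coverage_track(values, sample, condition)
}
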
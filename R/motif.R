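#' Scan a sequence for the E-box consensus with mismatch grading
#'
#' Slides a 6-bp window over the forward strand and reports every window
#' within `max_mm` mismatches of `CACGTG`, with its exact Hamming
#' distance. Because the consensus is its own reverse complement, the
#' distance of a window equals the distance of its reverse complement,
#' so the forward scan covers both strands and each site is counted
#' once. `N` (or any non-ACGT character) counts as a mismatch.
#'
#' @param seq nucleotide string (A/C/G/T/N, case-insensitive).
#' @param max_mm maximum mismatches reported: 0, 1 or 2.
#' @return data.frame: `start` (1-based window start), `match` (the
#'   6-mer) and `mismatches`.
#' @export
scan_ebox <- function(seq, max_mm = 2) {
  stop_if_not(max_mm %in% 0:2, "max_mm must be 0, 1 or 2")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6) {
    return(data.frame(start = integer(0), match = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  consensus <- strsplit(EBOX, "", fixed = TRUE)[[1]]
  starts <- seq_len(n - 5L)
  mm <- integer(length(starts))
  for (k in 1:6) {
    mm <- mm + (chars[starts + k - 1L] != consensus[k])
  }
  hit <- which(mm <= max_mm)
  if (length(hit) == 0) {
    return(data.frame(start = integer(0), match = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(
    start = starts[hit],
    match = substring(seq, starts[hit], starts[hit] + 5L),
    mismatches = mm[hit],
    stringsAsFactors = FALSE
  )
}

#' Best motif grade under each peak
#'
#' Extracts the sequence under each peak interval and records the
#' minimal-mismatch E-box hit (grade 0, 1 or 2), or `NA` when no window
#' is within `max_mm` mismatches. Also returns the grade census whose
#' rows sum to the number of peaks.
#'
#' @param peaks a `peak_set` (1-based inclusive `start`/`end`).
#' @param genome named character vector of chromosome sequences, a
#'   `toy_genome`, or a path to a FASTA file.
#' @param max_mm maximum mismatches considered (default 2).
#' @return list with `per_peak` (data.frame: `peak_id`, `grade`,
#'   `motif_start`, `motif`) and `census` (named counts for grades
#'   `0`, `1`, `2` and `none`).
#' @export
best_motif_per_peak <- function(peaks, genome, max_mm = 2) {
  if (inherits(genome, "toy_genome")) genome <- genome$chromosomes
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  stop_if_not(all(peaks$chrom %in% names(genome)),
              "peak chromosome missing from the genome")
  per_peak <- lapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    stop_if_not(peaks$start[i] >= 1 &&
                  peaks$end[i] <= nchar(genome[[ch]]),
                "peak extends beyond the chromosome end")
    sub <- substr(genome[[ch]], peaks$start[i], peaks$end[i])
    hits <- scan_ebox(sub, max_mm = max_mm)
    if (nrow(hits) == 0) {
      return(data.frame(peak_id = peaks$peak_id[i], grade = NA_integer_,
                        motif_start = NA_integer_, motif = NA_character_,
                        stringsAsFactors = FALSE))
    }
    best <- hits[which.min(hits$mismatches), ]
    data.frame(peak_id = peaks$peak_id[i], grade = best$mismatches,
               motif_start = peaks$start[i] + best$start - 1L,
               motif = best$match, stringsAsFactors = FALSE)
  })
  per_peak <- do.call(rbind, per_peak)
  census <- c(
    `0` = sum(per_peak$grade == 0, na.rm = TRUE),
    `1` = sum(per_peak$grade == 1, na.rm = TRUE),
    `2` = sum(per_peak$grade == 2, na.rm = TRUE),
    none = sum(is.na(per_peak$grade))
  )
  list(per_peak = per_peak, census = census)
}
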
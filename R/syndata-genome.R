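EBOX <- "CACGTG"
DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

hamming6 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Generate a toy genome with planted E-box motifs
#'
#' Builds random chromosomes, places genes with non-overlapping promoters
#' (1 kb upstream of the TSS on the gene's strand), and plants one E-box
#' (`CACGTG`) site of a requested mismatch grade in the promoter of
#' distinct genes. Background promoter sequence is scrubbed so that
#' scanning recovers exactly the planted sites: promoters contain no
#' accidental exact consensus, and a window of `scrub_flank` bp around each
#' planted site of grade g contains no window closer than g mismatches.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome in bp.
#' @param n_genes total number of genes to place.
#' @param motif_plan named integer vector with names in `c("0","1","2")`
#'   giving how many planted sites of each mismatch grade to create. The
#'   total must not exceed `n_genes`.
#' @param seed integer seed; all randomness in the call derives from it.
#' @param promoter_len promoter length in bp (motifs are planted here).
#' @param gene_spacing distance between consecutive TSSs on a chromosome.
#' @param cds_len CDS length for every gene.
#' @param strands `"alternate"` (default), `"plus"` or `"minus"`; strand
#'   assignment pattern for the placed genes.
#' @param scrub_flank half-width of the region around each planted motif
#'   cleared of better-or-equal-grade windows.
#' @param out_dir optional directory; when given, the genome FASTA, BED6
#'   gene table and motif truth TSV are written there.
#' @return an object of class `toy_genome`: a list with `chromosomes`
#'   (named character vector of sequences), `genes` (data.frame with
#'   `gene_id`, `chrom`, `tss`, `strand`, `cds_start`, `cds_end`; 1-based
#'   inclusive coordinates), `motifs` (data.frame with `chrom`, `pos`
#'   (1-based start of the 6-mer), `grade`, `gene_id`) and `promoter_len`.
#' @export
make_toy_genome <- function(n_chrom = 2, chrom_len = 20000, n_genes = 8,
                            motif_plan = c("0" = 2, "1" = 2, "2" = 1),
                            seed = 1, promoter_len = 1000,
                            gene_spacing = 2000, cds_len = 500,
                            strands = c("alternate", "plus", "minus"),
                            scrub_flank = 200, out_dir = NULL) {
  strands <- match.arg(strands)
  stop_if_not(all(names(motif_plan) %in% c("0", "1", "2")),
              "motif_plan names must be among '0', '1', '2'")
  n_motifs <- sum(motif_plan)
  stop_if_not(n_motifs <= n_genes,
              "motif_plan requests more planted sites than genes")
  set.seed(seed)

  per_chrom <- ceiling(n_genes / n_chrom)
  # each gene occupies a promoter + CDS block laid on the strand-aware
  # side of the TSS; consecutive blocks are gene_spacing apart, which
  # keeps promoters non-overlapping as long as the block fits the spacing
  block <- promoter_len + cds_len
  stop_if_not(gene_spacing >= block + 100,
              "gene_spacing too small for promoter_len + cds_len")
  lead <- 100
  span_needed <- lead + (per_chrom - 1) * gene_spacing + block + 100
  if (span_needed > chrom_len) {
    stop("placement failure: chrom_len ", chrom_len, " too short for ",
         per_chrom, " genes per chromosome (need >= ", span_needed, ")",
         call. = FALSE)
  }

  chroms <- stats::setNames(
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(DNA_BASES, chrom_len, replace = TRUE), collapse = "")
    }, character(1)),
    paste0("chr", seq_len(n_chrom))
  )

  # gene layout: round-robin over chromosomes, evenly spaced loci
  idx <- seq_len(n_genes)
  chrom_of <- paste0("chr", ((idx - 1) %% n_chrom) + 1)
  slot <- ((idx - 1) %/% n_chrom)
  strand_of <- switch(strands,
    plus = rep("+", n_genes),
    minus = rep("-", n_genes),
    alternate = rep(c("+", "-"), length.out = n_genes)
  )
  block_start <- lead + slot * gene_spacing
  # "+" gene: [promoter | CDS ->]; "-" gene: [<- CDS | promoter]
  cds_start <- ifelse(strand_of == "+", block_start + promoter_len,
                      block_start)
  genes <- data.frame(
    gene_id = sprintf("g%03d", idx),
    chrom = chrom_of,
    tss = as.integer(ifelse(strand_of == "+", cds_start,
                            cds_start + cds_len - 1)),
    strand = strand_of,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_start + cds_len - 1),
    stringsAsFactors = FALSE
  )

  prom <- promoter_interval(genes, promoter_len)

  # remove every exact consensus from all promoters
  for (i in seq_len(nrow(prom))) {
    chroms[prom$chrom[i]] <- scrub_interval(
      chroms[[prom$chrom[i]]], prom$start[i], prom$end[i],
      max_grade = 0, keep = NULL
    )
  }

  # plant motifs in the central band of distinct promoters
  grades <- rep(as.integer(names(motif_plan)), times = motif_plan)
  owners <- sample(seq_len(n_genes), n_motifs)
  motifs <- data.frame(chrom = character(0), pos = integer(0),
                       grade = integer(0), gene_id = character(0))
  for (j in seq_along(grades)) {
    gi <- owners[j]
    g <- grades[j]
    lo <- prom$start[gi] + round(0.25 * promoter_len)
    hi <- prom$end[gi] - round(0.25 * promoter_len) - 6
    pos <- sample(lo:hi, 1)
    site <- mutate_consensus(g)
    ch <- genes$chrom[gi]
    substr(chroms[ch], pos, pos + 5) <- site
    # clear the neighbourhood of windows at distance < g (and of extra
    # exact sites for g = 0) so the planted grade is the best one locally
    chroms[ch] <- scrub_interval(
      chroms[[ch]],
      max(1, pos - scrub_flank), min(nchar(chroms[[ch]]), pos + 5 + scrub_flank),
      max_grade = max(0L, g - 1L), keep = c(pos, pos + 5)
    )
    motifs <- rbind(motifs, data.frame(
      chrom = ch, pos = pos, grade = g, gene_id = genes$gene_id[gi],
      stringsAsFactors = FALSE
    ))
  }

  genome <- structure(
    list(chromosomes = chroms, genes = genes, motifs = motifs,
         promoter_len = promoter_len),
    class = "toy_genome"
  )
  if (!is.null(out_dir)) write_toy_genome(genome, out_dir)
  genome
}

# promoter interval (1-based inclusive) for each gene, clipped to chromosome
promoter_interval <- function(genes, promoter_len) {
  start <- ifelse(genes$strand == "+", genes$tss - promoter_len, genes$tss + 1)
  end <- ifelse(genes$strand == "+", genes$tss - 1, genes$tss + promoter_len)
  data.frame(chrom = genes$chrom, start = pmax(1L, as.integer(start)),
             end = as.integer(end), gene_id = genes$gene_id,
             strand = genes$strand, stringsAsFactors = FALSE)
}

# a random 6-mer at Hamming distance exactly `g` from the consensus
mutate_consensus <- function(g) {
  s <- strsplit(EBOX, "")[[1]]
  if (g > 0) {
    at <- sample(6, g)
    for (p in at) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
  }
  paste(s, collapse = "")
}

# Mutate bases inside [start, end] of `seq` until no 6-mer window whose
# start lies in the interval is within `max_grade` mismatches of the
# consensus, excluding windows fully inside the planted site `keep`
# (c(start, end) of the planted 6-mer); bases within `keep` are never
# touched. Hamming distance to the palindromic consensus is strand
# symmetric, so the forward scan suffices.
scrub_interval <- function(seq, start, end, max_grade = 0, keep = NULL,
                           max_iter = 400) {
  consensus <- strsplit(EBOX, "")[[1]]
  for (iter in seq_len(max_iter)) {
    lo <- max(1L, start - 5L)
    hi <- min(nchar(seq) - 5L, end)
    if (hi < lo) return(seq)
    win_start <- lo:hi
    chars <- strsplit(substr(seq, lo, hi + 5L), "")[[1]]
    mm <- integer(length(win_start))
    for (k in 1:6) {
      mm <- mm + (chars[seq_along(win_start) + k - 1L] != consensus[k])
    }
    bad <- win_start[mm <= max_grade]
    if (!is.null(keep)) bad <- setdiff(bad, keep[1])
    if (length(bad) == 0) return(seq)
    w <- bad[1]
    cand <- w:(w + 5L)
    if (!is.null(keep)) cand <- cand[cand < keep[1] | cand > keep[2]]
    if (length(cand) == 0) next
    p <- sample(cand, 1)
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(DNA_BASES, old), 1)
  }
  stop("placement failure: could not scrub interval of near-consensus sites",
       call. = FALSE)
}

#' Write a toy genome to disk
#'
#' Emits `genome.fa` (FASTA), `genes.bed` (BED6: chrom, start, end,
#' gene_id, score 0, strand; 0-based half-open over the CDS) and
#' `motifs.tsv` (planted motif truth, 1-based start positions).
#'
#' @param genome a `toy_genome` object.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_toy_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  dss <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dss, fa, width = 80)
  bed <- file.path(dir, "genes.bed")
  g <- genome$genes
  utils::write.table(
    data.frame(g$chrom, g$cds_start - 1L, g$cds_end, g$gene_id, 0L, g$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  mt <- file.path(dir, "motifs.tsv")
  write_tsv(genome$motifs, mt)
  gt <- file.path(dir, "gene_table.tsv")
  write_tsv(g, gt)
  invisible(c(fasta = fa, genes_bed = bed, motifs = mt, gene_table = gt))
}

#' Read a BED6 gene table
#'
#' Inverse of the BED6 written by [write_toy_genome()]; converts back to
#' 1-based inclusive CDS coordinates. The TSS is the strand-aware 5' end.
#'
#' @param path BED6 file.
#' @return data.frame with `gene_id`, `chrom`, `tss`, `strand`,
#'   `cds_start`, `cds_end`.
#' @export
read_gene_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(b) >= 6, "expected a BED6 file with 6 columns")
  names(b)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  data.frame(
    gene_id = b$gene_id, chrom = b$chrom,
    tss = ifelse(b$strand == "+", b$start + 1L, b$end),
    strand = b$strand,
    cds_start = b$start + 1L, cds_end = b$end,
    stringsAsFactors = FALSE
  )
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(dss)),
                  sub("\\s.*$", "", names(dss)))
}
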
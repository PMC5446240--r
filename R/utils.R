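#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for printed percentages so that
#' e.g. 56.5 becomes 57 rather than R's banker's rounding to 56.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' The four genotypes of the factorial TF x cofactor design
#'
#' Level order is fixed: double deletion, cofactor only, TF only, full
#' genotype. All model fitting and decomposition code indexes genotype
#' means by these names.
#'
#' @return character vector of length 4.
#' @export
#' @examples
#' genotype_levels()
genotype_levels <- function() {
  c("pho4d.pho2d", "pho4d.PHO2", "PHO4.pho2d", "PHO4.PHO2")
}

# presence indicators for the TF / cofactor in each genotype, in level order
genotype_design <- function() {
  g <- genotype_levels()
  data.frame(
    genotype = g,
    has_tf = g %in% c("PHO4.pho2d", "PHO4.PHO2"),
    has_cofactor = g %in% c("pho4d.PHO2", "PHO4.PHO2"),
    stringsAsFactors = FALSE
  )
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# write a data.frame as plain TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
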
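#' Double-mutant-cycle decomposition of induction
#'
#' Decomposes each gene's log2 induction over the 2x2 genotype design
#' into the TF acting alone, the cofactor acting alone, and their
#' collaborative (interaction) component:
#' \deqn{X_{Pho4} = \beta_{PHO4.pho2\Delta} - \beta_{pho4\Delta.pho2\Delta}}
#' \deqn{X_{Pho2} = \beta_{pho4\Delta.PHO2} - \beta_{pho4\Delta.pho2\Delta}}
#' \deqn{CO = (\beta_{PHO4.PHO2} - \beta_{pho4\Delta.PHO2}) -
#'            (\beta_{PHO4.pho2\Delta} - \beta_{pho4\Delta.pho2\Delta})}
#' so that `X_Pho4 + X_Pho2 + CO` equals the full induction
#' `beta_full - beta_double_null` exactly. Standard errors derive from
#' the moderated variance of the fit; each component is tested two-sided
#' on the moderated t distribution.
#'
#' @param fit a moderated `de_fit` (see [moderate_variances()]) holding
#'   all four genotype means.
#' @return data.frame of class `cycle_components`: `gene`, `pho4`,
#'   `pho2`, `co`, their `se_*`, `t_*` and `p_*` columns.
#' @export
decompose_induction <- function(fit) {
  stop_if_not(inherits(fit, "de_fit"), "fit must come from fit_genotype_means")
  stop_if_not(!is.null(fit$s2_post),
              "run moderate_variances() before decompose_induction()")
  gl <- genotype_levels()
  missing_g <- setdiff(gl, colnames(fit$coefficients))
  if (length(missing_g) > 0) {
    stop("missing genotype mean(s): ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  b <- fit$coefficients
  pho4 <- b[, "PHO4.pho2d"] - b[, "pho4d.pho2d"]
  pho2 <- b[, "pho4d.PHO2"] - b[, "pho4d.pho2d"]
  co <- (b[, "PHO4.PHO2"] - b[, "pho4d.PHO2"]) -
    (b[, "PHO4.pho2d"] - b[, "pho4d.pho2d"])

  n <- fit$n_per_group
  s <- sqrt(fit$s2_post)
  se_pho4 <- s * sqrt(1 / n[["PHO4.pho2d"]] + 1 / n[["pho4d.pho2d"]])
  se_pho2 <- s * sqrt(1 / n[["pho4d.PHO2"]] + 1 / n[["pho4d.pho2d"]])
  se_co <- s * sqrt(sum(1 / unclass(n)))
  df <- fit$df_total
  two_sided <- function(t) 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)

  out <- data.frame(
    gene = fit$genes,
    pho4 = as.numeric(pho4), pho2 = as.numeric(pho2), co = as.numeric(co),
    se_pho4 = as.numeric(se_pho4), se_pho2 = as.numeric(se_pho2),
    se_co = as.numeric(se_co),
    stringsAsFactors = FALSE
  )
  out$t_pho4 <- out$pho4 / out$se_pho4
  out$t_pho2 <- out$pho2 / out$se_pho2
  out$t_co <- out$co / out$se_co
  out$p_pho4 <- two_sided(out$t_pho4)
  out$p_pho2 <- two_sided(out$t_pho2)
  out$p_co <- two_sided(out$t_co)
  class(out) <- c("cycle_components", "data.frame")
  out
}

#' Ward clustering of genes by expression components
#'
#' Hierarchically clusters genes on the Euclidean distance over the
#' unstandardized `(X_Pho4, X_Pho2, CO)` estimates with Ward's
#' minimum-variance linkage, cuts the tree at `k`, and (for k = 3)
#' labels clusters by their centroids: class I is the cluster whose
#' centroid maximizes `X_Pho4 - |CO|` (TF main effect dominant), class
#' II the one maximizing `CO - X_Pho4` (collaborative), class III the
#' remainder.
#'
#' @param cc a `cycle_components` data.frame (or any data.frame with
#'   `pho4`, `pho2`, `co`).
#' @param k number of clusters (default 3).
#' @return list with `labels` (character vector, named by gene when
#'   gene ids are present), `cluster` (integer cut), `hclust` (the
#'   dendrogram object).
#' @export
cluster_classes <- function(cc, k = 3) {
  X <- as.matrix(cc[, c("pho4", "pho2", "co")])
  stop_if_not(nrow(X) >= k, "k must not exceed the number of genes")
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  if (k == 3) {
    cent <- apply(X, 2, function(col) tapply(col, cl, mean))
    class_I <- which.max(cent[, "pho4"] - abs(cent[, "co"]))
    rest <- setdiff(seq_len(3), class_I)
    class_II <- rest[which.max((cent[, "co"] - cent[, "pho4"])[rest])]
    class_III <- setdiff(rest, class_II)
    map <- character(3)
    map[class_I] <- "I"; map[class_II] <- "II"; map[class_III] <- "III"
    labels <- map[cl]
  } else if (k == 1) {
    labels <- rep("I", nrow(X))
  } else {
    labels <- paste0("C", cl)
  }
  if (!is.null(cc$gene)) names(labels) <- cc$gene
  list(labels = labels, cluster = cl, hclust = hc)
}

#' Display-clipped component table
#'
#' Clips component estimates to `[cap_lo, cap_hi]` for heat-map display
#' and produces the companion `-log10 p` table. The returned `stored`
#' element keeps the unclipped estimates.
#'
#' @param cc a `cycle_components` data.frame.
#' @param cap_hi,cap_lo display caps (defaults 3 and -2).
#' @return list with `display` (clipped estimates), `neglog10p`
#'   (matching -log10 p-values) and `stored` (unclipped estimates).
#' @export
component_heat_table <- function(cc, cap_hi = 3, cap_lo = -2) {
  est <- as.matrix(cc[, c("pho4", "pho2", "co")])
  rownames(est) <- cc$gene
  display <- pmin(pmax(est, cap_lo), cap_hi)
  nlp <- -log10(as.matrix(cc[, c("p_pho4", "p_pho2", "p_co")]))
  rownames(nlp) <- cc$gene
  colnames(nlp) <- c("pho4", "pho2", "co")
  list(display = display, neglog10p = nlp, stored = est)
}
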
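#' Assign ChIP peaks to candidate target genes
#'
#' For each peak, the nearest gene TSS on each side (relative to the
#' peak summit) is a candidate; a candidate is kept iff the peak lies on
#' the gene's 5' side of its TSS — for a `+` gene the peak must start
#' before the TSS, for a `-` gene it must end after it — and, when
#' `max_dist` is set, within that distance of the TSS. A peak between
#' divergent genes can therefore be assigned to both. Peaks overlapping
#' any CDS are dropped unless `allow_cds`, in which case they are kept
#' and flagged.
#'
#' @param peaks a `peak_set`.
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `strand`,
#'   `cds_start`, `cds_end`), as from a `toy_genome` or
#'   [read_gene_bed()].
#' @param allow_cds keep CDS-overlapping peaks (default FALSE).
#' @param max_dist optional cap on summit-to-TSS distance in bp.
#' @return data.frame of class `target_table`: `peak_id`, `gene_id`,
#'   `distance` (summit to TSS, bp), `in_cds`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, allow_cds = FALSE,
                                  max_dist = NULL) {
  stop_if_not(nrow(genes) > 0, "empty gene table")
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    in_cds <- any(peaks$start[i] <= g$cds_end & peaks$end[i] >= g$cds_start)
    if (in_cds && !allow_cds) next
    s <- peaks$summit[i]
    left <- g[g$tss < s, , drop = FALSE]
    right <- g[g$tss >= s, , drop = FALSE]
    cand <- rbind(
      if (nrow(left) > 0) left[which.max(left$tss), ],
      if (nrow(right) > 0) right[which.min(right$tss), ]
    )
    for (j in seq_len(nrow(cand))) {
      upstream <- if (cand$strand[j] == "+") {
        peaks$start[i] <= cand$tss[j]
      } else {
        peaks$end[i] >= cand$tss[j]
      }
      if (!upstream) next
      d <- abs(cand$tss[j] - s)
      if (!is.null(max_dist) && d > max_dist) next
      rows[[length(rows) + 1]] <- data.frame(
        peak_id = peaks$peak_id[i], gene_id = cand$gene_id[j],
        distance = d, in_cds = in_cds, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(peak_id = character(0), gene_id = character(0),
               distance = integer(0), in_cds = logical(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("target_table", "data.frame")
  out
}

FUNCTIONAL_CATEGORIES <- c("induced-with-or-without",
                           "induced-only-with-cofactor",
                           "non-functional")

#' Call direct targets and per-peak functional categories
#'
#' Joins peak-to-gene assignments with induction calls. Each assignment
#' is categorized as `induced-with-or-without` (induced in both
#' cofactor states), `induced-only-with-cofactor`, or `non-functional`;
#' genes missing from the calls (e.g. filtered out) get `NA` and are
#' excluded from denominators. A peak assigned to two genes takes its
#' most functional category. Direct targets are the genes with at least
#' one functional (non-`non-functional`) assigned peak.
#'
#' @param tt a `target_table` from [assign_peaks_to_genes()].
#' @param calls induction calls from [induction_calls()].
#' @return list with `assignments` (tt plus `category`), `per_peak`
#'   (best category per peak), `category_counts` (per-peak counts over
#'   the three categories plus `NA`), and `direct_targets` (character
#'   vector of gene ids).
#' @export
call_direct_targets <- function(tt, calls) {
  m <- match(tt$gene_id, calls$gene)
  cat_of <- function(iw, iwo) {
    ifelse(is.na(iw) | is.na(iwo), NA_character_,
           ifelse(iw & iwo, "induced-with-or-without",
                  ifelse(iw, "induced-only-with-cofactor",
                         "non-functional")))
  }
  category <- cat_of(calls$induced_with[m], calls$induced_without[m])
  assignments <- data.frame(tt, category = category,
                            stringsAsFactors = FALSE)

  rank_of <- function(x) match(x, FUNCTIONAL_CATEGORIES)  # 1 = most functional
  per_peak <- do.call(rbind, lapply(split(assignments, assignments$peak_id),
                                    function(d) {
    r <- rank_of(d$category)
    best <- if (all(is.na(r))) NA_character_ else
      FUNCTIONAL_CATEGORIES[min(r, na.rm = TRUE)]
    data.frame(peak_id = d$peak_id[1], category = best,
               stringsAsFactors = FALSE)
  }))
  rownames(per_peak) <- NULL

  category_counts <- c(
    stats::setNames(vapply(FUNCTIONAL_CATEGORIES, function(cc) {
      sum(per_peak$category == cc, na.rm = TRUE)
    }, numeric(1)), FUNCTIONAL_CATEGORIES),
    `NA` = sum(is.na(per_peak$category))
  )
  functional <- assignments$category %in%
    c("induced-with-or-without", "induced-only-with-cofactor")
  list(assignments = assignments, per_peak = per_peak,
       category_counts = category_counts,
       direct_targets = sort(unique(assignments$gene_id[functional])))
}

#' Percentage of bound genes activated upon binding
#'
#' `100 * induced / bound`, rounded half-up to `digits`.
#'
#' @param bound number of genes bound (> 0).
#' @param induced number of those induced (0 <= induced <= bound).
#' @param digits decimal places kept (0 or 2).
#' @return the percentage.
#' @export
#' @examples
#' percent_activated(115, 64)      # 56
#' percent_activated(74, 20)       # 29
#' percent_activated(64, 60, 2)    # 93.75
percent_activated <- function(bound, induced, digits = 0) {
  stop_if_not(bound > 0, "percentage undefined when nothing is bound")
  stop_if_not(induced >= 0 && induced <= bound,
              "induced must lie in [0, bound]")
  round_half_up(100 * induced / bound, digits)
}

#' Cofactor-dependence ratios over shared target genes
#'
#' For each shared gene, the ratio of its linear-scale induction fold
#' change without the cofactor to that with it; summarized by the mean
#' over shared genes plus boxplot-ready quantiles.
#'
#' @param fc_noco,fc_co named per-gene linear fold changes (> 0 for
#'   `fc_co`).
#' @param shared_genes genes over which to compute the ratios (must be
#'   present in both vectors).
#' @return list with `ratios` (named), `mean`, and `quartiles`
#'   (25/50/75%).
#' @export
dependence_ratio <- function(fc_noco, fc_co, shared_genes) {
  stop_if_not(all(shared_genes %in% names(fc_noco)) &&
                all(shared_genes %in% names(fc_co)),
              "shared genes must have fold changes in both conditions")
  fco <- fc_co[shared_genes]
  stop_if_not(all(fco > 0), "fold changes must be positive on the linear scale")
  r <- fc_noco[shared_genes] / fco
  list(ratios = r, mean = mean(r),
       quartiles = stats::quantile(r, c(0.25, 0.5, 0.75)))
}

#' Cofactor-dependence percentage from phosphatase activities
#'
#' Reproduces the reporter-assay arithmetic: the TF shows noticeable
#' activity only when its with-cofactor measurement exceeds
#' `floor_factor` times the no-TF blank, in which case the dependence
#' percentage is `100 * (act_noco - blank_noco) / (act_co - blank_co)`
#' with the numerator clamped at 0 (a blank-level no-cofactor reading
#' reports 0% rather than a negative value); otherwise the result is
#' "no activity".
#'
#' @param act_noco,act_co activities (OD420/OD600) without and with the
#'   cofactor.
#' @param blank_noco,blank_co matching no-TF control activities.
#' @param floor_factor activity floor as a multiple of the blank
#'   (default 2).
#' @param digits decimal places kept.
#' @return list with `percent` (NA when either condition has no
#'   activity) and `status` (`"ok"` or `"no activity"`).
#' @export
phosphatase_dependence_percent <- function(act_noco, act_co, blank_noco,
                                           blank_co, floor_factor = 2,
                                           digits = 0) {
  stop_if_not(all(c(act_noco, act_co, blank_noco, blank_co) >= 0),
              "activities must be non-negative")
  if (act_co <= floor_factor * blank_co || (act_co - blank_co) <= 0) {
    return(list(percent = NA_real_, status = "no activity"))
  }
  list(percent = round_half_up(
    100 * max(0, act_noco - blank_noco) / (act_co - blank_co), digits
  ), status = "ok")
}

#' Compare per-site scores between binding groups
#'
#' Given a motif-site inventory with one score per site (e.g. prior
#' nucleosome occupancy or competitor enrichment) and per-site binding
#' groups, reports bootstrap means with CIs and the two-sided t-test
#' between two chosen groups. Optionally restricts to the most
#' accessible quartile (lowest `accessibility_score`) first, keeping
#' `ceiling(0.25 * n)` sites.
#'
#' @param scores numeric per-site scores.
#' @param groups per-site group labels.
#' @param test_groups the two group labels to t-test (defaults to the
#'   first two distinct labels).
#' @param accessibility_score optional per-site values; when given, only
#'   the lowest quartile is analyzed.
#' @param B,seed bootstrap parameters.
#' @return list with `means` ([group_mean_bootstrap()] output), `test`
#'   ([group_ttest()] output or NULL if a test group is empty) and
#'   `n_used`.
#' @export
motif_site_score_compare <- function(scores, groups, test_groups = NULL,
                                     accessibility_score = NULL,
                                     B = 10000, seed = 1) {
  if (!is.null(accessibility_score)) {
    k <- ceiling(0.25 * length(scores))
    keep <- order(accessibility_score)[seq_len(k)]
    scores <- scores[keep]
    groups <- groups[keep]
  }
  present <- table(groups)
  empty <- setdiff(unique(groups), names(present)[present > 0])
  if (length(empty) > 0) warning("empty group(s) omitted: ",
                                 paste(empty, collapse = ", "))
  means <- group_mean_bootstrap(scores, groups, B = B, seed = seed)
  if (is.null(test_groups)) test_groups <- utils::head(unique(groups), 2)
  test <- NULL
  if (length(test_groups) == 2 &&
      all(test_groups %in% groups) &&
      all(table(factor(groups, levels = test_groups)) >= 2)) {
    sel <- groups %in% test_groups
    test <- group_ttest(scores[sel], groups[sel])
  }
  list(means = means, test = test, n_used = length(scores))
}
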
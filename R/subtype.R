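#' Subtype-specific differentially methylated enhancers
#'
#' Two-sided t-test per enhancer between basal and non-basal tumor samples,
#' with the direction (hyper/hypo in basal) labelled for significant
#' enhancers.
#'
#' @param enh_track `meth_track` (or matrix) of enhancer methylation.
#' @param subtype Factor-like vector over the track's samples with values
#'   `basal` / `non_basal` (samples with other/missing values are dropped).
#' @param alpha Significance threshold (default 0.05).
#' @param var_equal Pooled-variance test instead of Welch.
#' @return data.frame per enhancer with group means (`mean_non_basal`,
#'   `mean_basal`), `t`, `p`, `p_adj` and `direction` (hyper/hypo in basal,
#'   `none` when not significant).
#' @export
find_ssedmr <- function(enh_track, subtype, alpha = 0.05, var_equal = FALSE) {
  m <- if (inherits(enh_track, "meth_track")) enh_track$values else enh_track
  subtype <- as.character(subtype)
  keep <- subtype %in% c("basal", "non_basal")
  m <- m[, keep, drop = FALSE]
  grp <- factor(subtype[keep], levels = c("non_basal", "basal"))
  if (min(table(grp)) < 2) stop("need >= 2 samples per subtype group")
  out <- differential_test(m, grp, alpha = alpha, var_equal = var_equal)
  names(out)[names(out) == "unit_id"] <- "enhancer_id"
  names(out)[names(out) == "mean_ref"] <- "mean_non_basal"
  names(out)[names(out) == "mean_alt"] <- "mean_basal"
  out
}

#' Hierarchical clustering of samples on enhancer methylation
#'
#' Agglomerative clustering of samples (Euclidean distance on the
#' methylation vectors, average linkage by default), cut into two groups,
#' with the adjusted Rand index against known labels when provided.
#'
#' @param track `meth_track` (or matrix), typically restricted to sseDMRs.
#' @param labels Optional true sample labels for the agreement score.
#' @param k Number of groups to cut (default 2).
#' @param method Linkage (default "average").
#' @return List with the `hclust` tree, the `assignments` vector and
#'   `adjusted_rand` (NA when no labels given).
#' @export
cluster_samples_by_methylation <- function(track, labels = NULL, k = 2,
                                           method = "average") {
  m <- if (inherits(track, "meth_track")) track$values else track
  if (nrow(m) < 2) stop("need >= 2 regions to cluster on")
  if (ncol(m) < 2) stop("need >= 2 samples to cluster")
  hc <- stats::hclust(stats::dist(t(m)), method = method)
  cl <- stats::cutree(hc, k = k)
  ari <- NA_real_
  if (!is.null(labels)) {
    labels <- labels[colnames(m)]
    ari <- mclust::adjustedRandIndex(cl, as.character(labels))
  }
  list(hclust = hc, assignments = cl, adjusted_rand = ari)
}

#' Cross-tabulate enhancer methylation direction against target expression
#'
#' Joins subtype-specific enhancer calls with basal-vs-non-basal expression
#' calls over the enhancer-target pairs and counts the four combinations
#' (enhancer hyper/hypo in basal x target low/high in basal). A one-sided
#' binomial test asks whether hypermethylated enhancers preferentially have
#' low-expressed targets.
#'
#' @param ssedmr Output of [find_ssedmr()].
#' @param deg Output of [differential_test()] on expression, basal vs
#'   non-basal (reference level `non_basal`, so `direction = "hypo"` means
#'   low in basal).
#' @param pairs Pair data.frame.
#' @return List with the 2x2 `counts` table, the number of classified pairs
#'   `n_pairs`, and `p_tendency` (binomial test that hyper enhancers have
#'   low targets more often than not).
#' @export
target_direction_summary <- function(ssedmr, deg, pairs) {
  e_dir <- setNames(ssedmr$direction, ssedmr$enhancer_id)
  g_dir <- setNames(deg$direction, deg$unit_id)
  pe <- e_dir[pairs$enhancer_id]
  pg <- g_dir[pairs$gene_id]
  keep <- !is.na(pe) & !is.na(pg) & pe != "none" & pg != "none"
  pe <- pe[keep]; pg <- pg[keep]
  counts <- table(
    enhancer = factor(pe, levels = c("hyper", "hypo")),
    target = factor(ifelse(pg == "hypo", "low_in_basal", "high_in_basal"),
                    levels = c("low_in_basal", "high_in_basal"))
  )
  n_hyper <- sum(counts["hyper", ])
  p_tend <- if (n_hyper > 0) {
    stats::binom.test(counts["hyper", "low_in_basal"], n_hyper,
                      p = 0.5, alternative = "greater")$p.value
  } else NA_real_
  list(counts = counts, n_pairs = sum(keep), p_tendency = p_tend)
}
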
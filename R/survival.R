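#' Log-rank test between two patient groups
#'
#' Thin wrapper around [survival::survdiff()] returning the chi-square
#' statistic and p-value, with the degenerate cases resolved explicitly:
#' no events at all gives statistic 0 and p = 1; a single nonempty group is
#' an error.
#'
#' @param time,event Survival time and event indicator (1 = event).
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `p` and the two group sizes.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need two nonempty groups")
  if (sum(event) == 0)
    return(list(chisq = 0, p = 1, n = as.vector(table(group))))
  # a singular information matrix means the table carries no contrast
  # (zero log-rank variance): statistic 0 by convention
  sd_ <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ group),
                  error = function(e) NULL)
  if (is.null(sd_) || !is.finite(sd_$chisq))
    return(list(chisq = 0, p = 1, n = as.vector(table(group))))
  list(chisq = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(table(group)))
}

#' Per-enhancer Kaplan-Meier scan
#'
#' For every enhancer, patients are split at the median methylation value
#' (ties go to the low group) and the two groups compared with a log-rank
#' test. Enhancers with a degenerate split are skipped and listed in the
#' `skipped` attribute.
#'
#' @param track `meth_track` (or matrix) of region methylation.
#' @param clinical Clinical data.frame (`sample_id`, `os_time`, `os_event`);
#'   rows with missing time or event are dropped.
#' @param alpha Significance threshold recorded with the scan (default 0.05).
#' @param min_patients Minimum analyzable patients (default 10).
#' @return data.frame per enhancer: `enhancer_id`, `n_low`, `n_high`,
#'   `chisq`, `p`, `significant`.
#' @export
km_scan <- function(track, clinical, alpha = 0.05, min_patients = 10) {
  m <- if (inherits(track, "meth_track")) track$values else track
  cl <- clinical[is.finite(clinical$os_time) & is.finite(clinical$os_event), ]
  ids <- intersect(colnames(m), cl$sample_id)
  if (length(ids) < min_patients)
    stop("need at least ", min_patients, " patients with survival data")
  cl <- cl[match(ids, cl$sample_id), ]
  m <- m[, ids, drop = FALSE]
  skipped <- character(0)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    grp <- v > stats::median(v)   # FALSE = low (ties to low), TRUE = high
    if (length(unique(grp)) < 2) {
      skipped <<- c(skipped, rownames(m)[i])
      return(NULL)
    }
    lr <- logrank_test(cl$os_time, cl$os_event, grp)
    data.frame(enhancer_id = rownames(m)[i], n_low = sum(!grp),
               n_high = sum(grp), chisq = lr$chisq, p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(enhancer_id = character(0), n_low = integer(0),
                      n_high = integer(0), chisq = numeric(0), p = numeric(0))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  out
}

.empirical_p <- function(null_counts, observed) {
  (1 + sum(null_counts >= observed)) / (1 + length(null_counts))
}

#' Null scan over random probe-centred fragments
#'
#' Each replicate samples `n_regions` probes from the manifest, extends each
#' position by `half_extend` bp on both sides (`[pos - half_extend,
#' pos + half_extend + 1)`), aggregates methylation over the fragments and
#' runs the Kaplan-Meier scan, recording the number of significant
#' fragments. The observed real count is compared with this null.
#'
#' @param probes Probe manifest data.frame.
#' @param beta Probe beta matrix.
#' @param clinical Clinical data.frame.
#' @param observed Observed significant-enhancer count from the real scan.
#' @param n_regions Fragments per replicate (default 3067).
#' @param half_extend Extension in bp (default 500).
#' @param replicates Number of replicates (default 100).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @return List of class `null_distribution`: `counts` per replicate,
#'   `observed`, and the add-one `empirical_p`.
#' @export
random_region_null <- function(probes, beta, clinical, observed,
                               n_regions = 3067, half_extend = 500,
                               replicates = 100, alpha = 0.05, seed = 1) {
  if (nrow(probes) == 0) stop("probe manifest is empty")
  set.seed(seed)
  counts <- vapply(seq_len(replicates), function(r) {
    idx <- sample(nrow(probes), n_regions,
                  replace = n_regions > nrow(probes))
    frag <- data.frame(
      chrom = probes$chrom[idx],
      start = pmax(0L, as.integer(probes$pos[idx] - half_extend)),
      end = as.integer(probes$pos[idx] + half_extend + 1L),
      stringsAsFactors = FALSE
    )
    frag$region_id <- sprintf("frag%05d_%s", seq_len(nrow(frag)),
                              .coord_id(frag$chrom, frag$start, frag$end))
    track <- aggregate_region_methylation(frag, probes, beta)
    scan <- km_scan(track, clinical, alpha = alpha)
    sum(scan$significant)
  }, numeric(1))
  structure(list(counts = counts, observed = observed,
                 empirical_p = .empirical_p(counts, observed)),
            class = "null_distribution")
}

#' Null scan under patient-label perturbation
#'
#' Each replicate permutes the (time, event) rows jointly across patients,
#' reruns the Kaplan-Meier scan on the same methylation track and records
#' the significant count.
#'
#' @param track `meth_track` (or matrix) of enhancer methylation.
#' @param clinical Clinical data.frame.
#' @param observed Observed significant count from the real scan (computed
#'   from the unpermuted data when omitted).
#' @param replicates Number of permutations (default 100).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @return `null_distribution` list as in [random_region_null()].
#' @export
sample_perturbation_null <- function(track, clinical, observed = NULL,
                                     replicates = 100, alpha = 0.05,
                                     seed = 1) {
  if (is.null(observed))
    observed <- sum(km_scan(track, clinical, alpha = alpha)$significant)
  cl <- clinical[is.finite(clinical$os_time) & is.finite(clinical$os_event), ]
  set.seed(seed)
  counts <- vapply(seq_len(replicates), function(r) {
    idx <- sample(nrow(cl))
    perm <- cl
    perm$os_time <- cl$os_time[idx]
    perm$os_event <- cl$os_event[idx]
    sum(km_scan(track, perm, alpha = alpha)$significant)
  }, numeric(1))
  structure(list(counts = counts, observed = observed,
                 empirical_p = .empirical_p(counts, observed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d replicates, observed %d, empirical p = %.4g\n",
              length(x$counts), x$observed, x$empirical_p))
  invisible(x)
}

#' Univariate Cox selection of risk genes
#'
#' Fits one univariate Cox proportional-hazards model per gene on
#' z-standardized expression (Efron tie handling), adjusts the Wald
#' p-values with Benjamini-Hochberg, and selects genes with FDR below the
#' threshold. Non-convergent fits are flagged and excluded from selection.
#'
#' @param expr Expression matrix (genes x samples) of the candidate genes.
#' @param clinical Clinical data.frame.
#' @param fdr Selection threshold on BH-adjusted p (default 0.05).
#' @param min_patients Minimum patients (default 20).
#' @return List of class `risk_model`: per-gene `table` (beta, se, p, fdr,
#'   converged, selected), `selected` gene ids, and the standardization
#'   `center`/`scale` used (for scoring).
#' @export
cox_select_risk_genes <- function(expr, clinical, fdr = 0.05,
                                  min_patients = 20) {
  cl <- clinical[is.finite(clinical$os_time) & is.finite(clinical$os_event), ]
  ids <- intersect(colnames(expr), cl$sample_id)
  if (length(ids) < min_patients)
    stop("need at least ", min_patients, " patients with survival data")
  cl <- cl[match(ids, cl$sample_id), ]
  if (sum(cl$os_event) < 1) stop("need at least one event")
  e <- expr[, ids, drop = FALSE]
  ctr <- rowMeans(e)
  scl <- apply(e, 1, stats::sd)
  surv <- survival::Surv(cl$os_time, cl$os_event)
  rows <- lapply(rownames(e), function(g) {
    if (scl[g] == 0)
      return(data.frame(gene_id = g, beta = NA_real_, se = NA_real_,
                        p = NA_real_, converged = FALSE))
    z <- (e[g, ] - ctr[g]) / scl[g]
    fit <- tryCatch({
      f <- survival::coxph(surv ~ z, ties = "efron")
      ok <- is.finite(coef(f)) && is.finite(sqrt(diag(f$var)[1]))
      list(f = f, ok = ok)
    }, error = function(e) list(f = NULL, ok = FALSE),
       warning = function(w) {
         f <- suppressWarnings(survival::coxph(surv ~ z, ties = "efron"))
         list(f = f, ok = is.finite(coef(f)) && abs(coef(f)) < 15)
       })
    if (!fit$ok || is.null(fit$f))
      return(data.frame(gene_id = g, beta = NA_real_, se = NA_real_,
                        p = NA_real_, converged = FALSE))
    sm <- summary(fit$f)
    data.frame(gene_id = g, beta = unname(coef(fit$f)),
               se = sm$coefficients[1, "se(coef)"],
               p = sm$coefficients[1, "Pr(>|z|)"], converged = TRUE,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- NA_real_
  tab$fdr[tab$converged] <- stats::p.adjust(tab$p[tab$converged], "BH")
  tab$selected <- tab$converged & tab$fdr < fdr
  rownames(tab) <- NULL
  structure(list(table = tab,
                 selected = tab$gene_id[tab$selected],
                 center = ctr, scale = scl, fdr = fdr),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d genes tested, %d selected at FDR < %g\n",
              nrow(x$table), length(x$selected), x$fdr))
  invisible(x)
}

#' Combined coefficient-weighted risk score
#'
#' Per-patient score `sum_i beta_i * z_i` over the model's genes, where
#' `z_i` is the gene's expression standardized exactly as in the Cox fits.
#' Patients with score > 0 form the high-risk group; the two groups are
#' compared with a log-rank test.
#'
#' @param model `risk_model` from [cox_select_risk_genes()].
#' @param expr Expression matrix containing the model genes.
#' @param clinical Clinical data.frame.
#' @param genes Subset of model genes to combine (default: all selected).
#' @return List with `scores` (named per patient), `group`
#'   (high/low), `p` and `chisq` of the log-rank comparison; `p` is NA with
#'   a `degenerate` flag when all patients fall on one side.
#' @export
risk_score <- function(model, expr, clinical, genes = NULL) {
  if (is.null(genes)) genes <- model$selected
  if (length(genes) == 0) stop("no genes selected for the score")
  if (!all(genes %in% rownames(expr))) stop("model genes missing in expr")
  cl <- clinical[is.finite(clinical$os_time) & is.finite(clinical$os_event), ]
  ids <- intersect(colnames(expr), cl$sample_id)
  cl <- cl[match(ids, cl$sample_id), ]
  betas <- setNames(model$table$beta, model$table$gene_id)[genes]
  z <- (expr[genes, ids, drop = FALSE] - model$center[genes]) /
    model$scale[genes]
  scores <- as.vector(crossprod(z, betas))
  names(scores) <- ids
  grp <- ifelse(scores > 0, "high", "low")
  if (length(unique(grp)) < 2) {
    return(list(scores = scores, group = grp, chisq = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  lr <- logrank_test(cl$os_time, cl$os_event, grp)
  list(scores = scores, group = grp, chisq = lr$chisq, p = lr$p,
       degenerate = FALSE)
}

#' Exhaustive subset scan of risk-gene combinations
#'
#' Computes the combined risk score and its log-rank p for every nonempty
#' subset of the selected genes, reporting the best subset per size and
#' overall. Refuses more than `max_genes` genes (2^k enumeration guard).
#'
#' @param model `risk_model`.
#' @param expr Expression matrix.
#' @param clinical Clinical data.frame.
#' @param max_genes Enumeration guard (default 20).
#' @return List with the full `table` (subset, size, p), `best_per_size`
#'   and `best` overall.
#' @export
combination_scan <- function(model, expr, clinical, max_genes = 20) {
  genes <- model$selected
  k <- length(genes)
  if (k == 0) stop("no selected genes")
  if (k > max_genes)
    stop("refusing exhaustive enumeration over ", k,
         " genes; reduce the selection or raise max_genes explicitly")
  subsets <- unlist(lapply(seq_len(k), function(s)
    utils::combn(genes, s, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(gs) {
    rs <- risk_score(model, expr, clinical, genes = gs)
    data.frame(subset = paste(gs, collapse = ","), size = length(gs),
               p = rs$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$p)
  best_per_size <- do.call(rbind, lapply(split(tab[ok, ], tab$size[ok]),
    function(d) d[which.min(d$p), ]))
  rownames(best_per_size) <- NULL
  list(table = tab, best_per_size = best_per_size,
       best = tab[ok, ][which.min(tab$p[ok]), ])
}
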
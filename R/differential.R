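#' Two-group differential test per unit
#'
#' Row-wise two-sided t-test (Welch by default) between two sample groups,
#' with a direction label relative to the first factor level (the reference,
#' e.g. normal): `hyper` when the second-level mean is larger and p < alpha,
#' `hypo` when smaller, `none` otherwise.
#'
#' Degenerate rows are resolved without NaN propagation: when both groups
#' have zero variance the p-value is 1 (direction `none`) if the means are
#' equal, 0 with the sign of the difference otherwise. Rows with fewer than
#' two finite values in either group are skipped and reported in the
#' `skipped` attribute.
#'
#' @param x Numeric matrix, units x samples.
#' @param groups Factor (or coercible) of length `ncol(x)` with two levels;
#'   the first level is the reference.
#' @param alpha Significance level for the direction label (default 0.05).
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @param log2p1 Apply `log2(x + 1)` before testing (used for expression).
#' @return data.frame with `unit_id`, group means, `t`, `p`, `p_adj`
#'   (Benjamini-Hochberg) and `direction`.
#' @export
differential_test <- function(x, groups, alpha = 0.05, var_equal = FALSE,
                              log2p1 = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != ncol(x)) stop("groups length must match ncol(x)")
  if (log2p1) x <- log2(x + 1)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  skipped <- character(0)
  res <- lapply(seq_len(nrow(x)), function(i) {
    a <- x[i, ia]; b <- x[i, ib]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
      return(data.frame(unit_id = rownames(x)[i], mean_ref = mean(a),
                        mean_alt = mean(b), t = NA_real_, p = p))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(unit_id = rownames(x)[i], mean_ref = mean(a),
               mean_alt = mean(b), t = unname(tt$statistic), p = tt$p.value)
  })
  keep <- !vapply(res, is.null, logical(1))
  skipped <- rownames(x)[!keep]
  out <- do.call(rbind, res[keep])
  if (is.null(out))
    out <- data.frame(unit_id = character(0), mean_ref = numeric(0),
                      mean_alt = numeric(0), t = numeric(0), p = numeric(0))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$p < alpha,
                          ifelse(out$mean_alt > out$mean_ref, "hyper", "hypo"),
                          "none")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of drawing at least `k` successes in `n` draws without
#' replacement from a population of size `N` containing `K` successes. The
#' default is the inclusive tail `P(X >= k)`; `tail = "gt"` gives the strict
#' exceedance probability `P(X > k)` for compatibility with analyses that
#' evaluate the survivor function at the observed count.
#'
#' @param k Observed overlap.
#' @param n Draw (query) size.
#' @param K Successes in the background.
#' @param N Background size.
#' @param tail `"geq"` (default) or `"gt"`.
#' @return List with the four counts and the p-value `p`.
#' @export
hypergeom_enrichment <- function(k, n, K, N, tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(n, K)) stop("k cannot exceed min(n, K)")
  if (k < 0) stop("k must be nonnegative")
  q <- if (tail == "geq") k - 1 else k
  p <- stats::phyper(q, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, tail = tail, p = p)
}

#' Coefficient of variation
#'
#' `CV = sigma / mu` with `sigma` the sample standard deviation and `mu` the
#' mean across samples. Undefined for zero mean.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return The coefficient of variation.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least two finite values")
  mu <- mean(values)
  if (mu == 0) stop("CV undefined: mean is zero")
  stats::sd(values) / mu
}

#' Hypergeometric set enrichment over a gene-set collection
#'
#' One upper-tail hypergeometric test per set: overlap of the query with the
#' set, against a background universe. Sets are ranked by p-value.
#'
#' @param query Character vector of gene ids (must be within `background`).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector, the gene universe.
#' @param alpha Significance flag threshold (default 0.05).
#' @return data.frame ranked by `p` with per-set counts and a `significant`
#'   flag.
#' @export
gene_set_enrichment <- function(query, gene_sets, background, alpha = 0.05) {
  if (length(background) == 0) stop("empty background")
  background <- unique(background)
  query <- unique(intersect(query, background))
  res <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], background)
    k <- length(intersect(query, set))
    data.frame(set = s, k = k, set_size = length(set),
               query_size = length(query), background_size = length(background),
               p = hypergeom_enrichment(k, length(query), length(set),
                                        length(background))$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, -out$k), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
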
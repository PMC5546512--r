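#' Spearman rank correlation with small-sample exact p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value uses
#' full permutation enumeration for n < 10 (proportion of permutations with
#' `|rho|` at least as extreme) and the t approximation on
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho`, `p`, `n` and the `method` used.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- pracma::perms(seq_len(n))
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_all <- (matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 2 / factorial(min(n, 170))  # beyond-tie exact bound; effectively 0
      p <- min(p, 1)
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t_approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Correlate enhancer and promoter methylation with target expression
#'
#' For each enhancer-promoter pair, Spearman correlation between (i) the
#' enhancer's region methylation and the gene's expression and (ii) the
#' promoter's methylation and the same expression, on complete cases over
#' the requested samples. Pairs with fewer than `min_samples` complete
#' observations, or with a constant methylation/expression vector, are
#' skipped and listed in the `skipped` attribute.
#'
#' @param pairs Pair data.frame (`enhancer_id`, `gene_id`, `promoter_id`).
#' @param enh_track,prom_track `meth_track` objects (or plain matrices) for
#'   enhancers and promoters.
#' @param expr Expression matrix, genes x samples.
#' @param samples Character vector of sample ids to use (default: all shared).
#' @param alpha Significance threshold used downstream (stored; default 0.05).
#' @param min_samples Minimum complete observations per pair (default 10).
#' @return data.frame of regulation calls: per pair `rho_enh`, `p_enh`,
#'   `rho_prom`, `p_prom`, `ratio` (`|rho_enh| / |rho_prom|`), `sign`
#'   (sign of `rho_enh`), and significance flags.
#' @export
correlate_pairs <- function(pairs, enh_track, prom_track, expr,
                            samples = NULL, alpha = 0.05, min_samples = 10) {
  emat <- if (inherits(enh_track, "meth_track")) enh_track$values else enh_track
  pmat <- if (inherits(prom_track, "meth_track")) prom_track$values else prom_track
  if (is.null(samples))
    samples <- Reduce(intersect, list(colnames(emat), colnames(pmat),
                                      colnames(expr)))
  skipped <- list()
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    e <- pairs$enhancer_id[i]; g <- pairs$gene_id[i]; pr <- pairs$promoter_id[i]
    if (!e %in% rownames(emat) || !pr %in% rownames(pmat) ||
        !g %in% rownames(expr)) {
      skipped[[length(skipped) + 1]] <<- list(pair = i, reason = "missing_unit")
      return(NULL)
    }
    me <- emat[e, samples]; mp <- pmat[pr, samples]; ex <- expr[g, samples]
    ok <- is.finite(me) & is.finite(mp) & is.finite(ex)
    if (sum(ok) < min_samples) {
      skipped[[length(skipped) + 1]] <<- list(pair = i, reason = "few_samples")
      return(NULL)
    }
    if (sd(me[ok]) == 0 || sd(mp[ok]) == 0 || sd(ex[ok]) == 0) {
      skipped[[length(skipped) + 1]] <<- list(pair = i, reason = "constant_input")
      return(NULL)
    }
    se <- spearman_cor(me[ok], ex[ok])
    sp <- spearman_cor(mp[ok], ex[ok])
    data.frame(
      enhancer_id = e, gene_id = g, promoter_id = pr,
      n = sum(ok),
      rho_enh = se$rho, p_enh = se$p,
      rho_prom = sp$rho, p_prom = sp$p,
      ratio = abs(se$rho) / abs(sp$rho),
      sign = if (se$rho < 0) "negative" else "positive",
      sig_enh = se$p < alpha, sig_prom = sp$p < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(enhancer_id = character(0), gene_id = character(0),
                      promoter_id = character(0), n = integer(0),
                      rho_enh = numeric(0), p_enh = numeric(0),
                      rho_prom = numeric(0), p_prom = numeric(0),
                      ratio = numeric(0), sign = character(0),
                      sig_enh = logical(0), sig_prom = logical(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  out
}

#' Enhancer/promoter dominance from the correlation ratio
#'
#' The ratio `|rho_enh| / |rho_prom|` decides which element dominates the
#' gene's expression: `enhancer` when the ratio exceeds `cutoff` and the
#' enhancer correlation is significant, `promoter` when the ratio is below
#' `1/cutoff` and the promoter correlation is significant, `neither`
#' otherwise. A zero promoter correlation yields an infinite ratio.
#'
#' @param calls Regulation-call data.frame from [correlate_pairs()] (or any
#'   data.frame with `rho_enh`, `p_enh`, `rho_prom`, `p_prom`).
#' @param cutoff Dominance cutoff on the ratio (default 2).
#' @param alpha Significance threshold (default 0.05).
#' @return The input with columns `ratio` and `dominant` added/updated.
#' @export
dominance_ratio <- function(calls, cutoff = 2, alpha = 0.05) {
  ratio <- abs(calls$rho_enh) / abs(calls$rho_prom)
  dominant <- rep("neither", nrow(calls))
  dominant[ratio > cutoff & calls$p_enh < alpha] <- "enhancer"
  dominant[ratio < 1 / cutoff & calls$p_prom < alpha] <- "promoter"
  calls$ratio <- ratio
  calls$dominant <- dominant
  calls
}

#' Classify genes as enhancer- or promoter-regulated
#'
#' A gene is an eRG if any linked enhancer's methylation correlates
#' significantly with its expression, a pRG if its promoter methylation
#' does; genes satisfying both are `both`, the rest `neither`.
#'
#' @param calls Regulation calls from [correlate_pairs()].
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Also compute labels from BH-adjusted p-values.
#' @return data.frame with `gene_id`, `label` and (optionally) `label_adj`.
#' @export
classify_regulated_genes <- function(calls, alpha = 0.05,
                                     use_adjusted = TRUE) {
  lab_from <- function(pe, pp) {
    by_gene <- split(seq_len(nrow(calls)), calls$gene_id)
    vapply(by_gene, function(idx) {
      e <- any(pe[idx] < alpha)
      p <- any(pp[idx] < alpha)
      if (e && p) "both" else if (e) "eRG" else if (p) "pRG" else "neither"
    }, character(1))
  }
  lab <- lab_from(calls$p_enh, calls$p_prom)
  out <- data.frame(gene_id = names(lab), label = unname(lab),
                    stringsAsFactors = FALSE)
  if (use_adjusted) {
    lab2 <- lab_from(stats::p.adjust(calls$p_enh, "BH"),
                     stats::p.adjust(calls$p_prom, "BH"))
    out$label_adj <- unname(lab2)
  }
  rownames(out) <- NULL
  out
}

#' Null distribution of enhancer-random gene correlations
#'
#' For each enhancer, draws `n_draws` genes at random (without replacement)
#' from the expression matrix and computes the Spearman correlation between
#' the enhancer's methylation and each random gene's expression.
#'
#' @param enh_track `meth_track` (or matrix) of enhancer methylation.
#' @param expr Expression matrix, genes x samples.
#' @param n_draws Random targets per enhancer (default 10).
#' @param samples Sample ids to use (default: shared columns).
#' @param seed Integer seed; draws are reproducible.
#' @return List with the vector of null correlations `rho`, their `mean` and
#'   `quantiles`, and the draw table `draws`.
#' @export
random_target_null <- function(enh_track, expr, n_draws = 10, samples = NULL,
                               seed = 1) {
  emat <- if (inherits(enh_track, "meth_track")) enh_track$values else enh_track
  if (is.null(samples)) samples <- intersect(colnames(emat), colnames(expr))
  pool <- rownames(expr)
  if (length(pool) <= n_draws) stop("gene pool must exceed n_draws")
  set.seed(seed)
  draws <- lapply(rownames(emat), function(e) {
    gs <- sample(pool, n_draws)
    rho <- vapply(gs, function(g) {
      ex <- expr[g, samples]; me <- emat[e, samples]
      ok <- is.finite(ex) & is.finite(me)
      if (sd(ex[ok]) == 0 || sd(me[ok]) == 0) return(NA_real_)
      spearman_cor(me[ok], ex[ok])$rho
    }, numeric(1))
    data.frame(enhancer_id = e, gene_id = gs, rho = rho,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, draws)
  rownames(tab) <- NULL
  rho <- tab$rho[is.finite(tab$rho)]
  list(rho = rho, mean = mean(rho),
       quantiles = stats::quantile(rho, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       draws = tab)
}

#' Johnson relative weights for predictor importance
#'
#' Decomposes the model R-squared of a multiple regression into nonnegative
#' per-predictor weights: predictors are orthogonalized through the
#' symmetric square root of their correlation matrix, the response is
#' regressed on the orthogonal variables, and squared coefficients are
#' distributed back through the squared loadings. Weights sum to R-squared.
#'
#' @param y Response vector.
#' @param predictors Numeric matrix (n x p), standardized internally.
#' @return List with `weights` (named, summing to `r_squared`) and
#'   `r_squared`.
#' @export
relative_weights <- function(y, predictors) {
  X <- as.matrix(predictors)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("need n > number of predictors + 2")
  X <- scale(X); yz <- as.vector(scale(y))
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) stop("predictors are (near-)collinear")
  lambda <- ev$vectors %*% diag(sqrt(ev$values), p) %*% t(ev$vectors)
  lambda_inv <- ev$vectors %*% diag(1 / sqrt(ev$values), p) %*% t(ev$vectors)
  r_xy <- as.vector(stats::cor(X, yz))
  b <- as.vector(lambda_inv %*% r_xy)   # coefficients on orthogonal vars
  eps <- as.vector((lambda^2) %*% (b^2))
  names(eps) <- colnames(predictors) %||% paste0("x", seq_len(p))
  list(weights = eps, r_squared = sum(eps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
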
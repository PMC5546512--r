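# Independent brute-force oracles. These deliberately avoid the package's
# code paths (GRanges, pracma, survdiff) so that agreement is informative.

# half-open interval overlap
ov <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

oracle_filter_peaks <- function(peaks, genes, half) {
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(TRUE)
    !any(vapply(seq_len(nrow(g)), function(j) {
      ov(peaks$start[i], peaks$end[i],
         max(0, g$tss[j] - half), g$tss[j] + half)
    }, logical(1)))
  }, logical(1))
  peaks[keep, , drop = FALSE]
}

oracle_region_means <- function(regions, probes, beta) {
  out <- matrix(NA_real_, nrow(regions), ncol(beta),
                dimnames = list(regions$region_id, colnames(beta)))
  for (i in seq_len(nrow(regions))) {
    inside <- probes$chrom == regions$chrom[i] &
      probes$pos >= regions$start[i] & probes$pos < regions$end[i]
    if (!any(inside)) next
    out[i, ] <- colMeans(beta[probes$probe_id[inside], , drop = FALSE])
  }
  out[rowSums(is.na(out)) < ncol(out), , drop = FALSE]
}

oracle_ep_pairs <- function(inter, enhancers, promoters) {
  res <- list()
  for (r in seq_len(nrow(inter))) {
    if (inter$chrom1[r] != inter$chrom2[r]) next
    for (i in seq_len(nrow(enhancers))) {
      for (j in seq_len(nrow(promoters))) {
        if (enhancers$chrom[i] != inter$chrom1[r] ||
            promoters$chrom[j] != inter$chrom1[r]) next
        hitA_e <- ov(inter$start1[r], inter$end1[r],
                     enhancers$start[i], enhancers$end[i])
        hitB_p <- ov(inter$start2[r], inter$end2[r],
                     promoters$start[j], promoters$end[j])
        hitB_e <- ov(inter$start2[r], inter$end2[r],
                     enhancers$start[i], enhancers$end[i])
        hitA_p <- ov(inter$start1[r], inter$end1[r],
                     promoters$start[j], promoters$end[j])
        if ((hitA_e && hitB_p) || (hitB_e && hitA_p)) {
          res[[length(res) + 1]] <- paste(enhancers$region_id[i],
                                          promoters$gene_id[j])
        }
      }
    }
  }
  out <- unlist(res)
  if (is.null(out)) character(0) else sort(unique(out))
}

oracle_nearest <- function(enhancers, genes) {
  vapply(seq_len(nrow(enhancers)), function(i) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    mid <- floor((enhancers$start[i] + enhancers$end[i]) / 2)
    d <- abs(g$tss - mid)
    cand <- sort(g$gene_id[d == min(d)])
    cand[1]
  }, character(1))
}

oracle_hyper_geq <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# recursive permutation enumeration (independent of pracma::perms)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- list()
  for (i in seq_along(v)) {
    rest <- oracle_perms(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  P <- oracle_perms(seq_along(y))
  rhos <- apply(P, 1, function(p) cor(rx, ry[p]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# two-group log-rank by direct risk-set enumeration
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group)) == 1
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V == 0) 0 else (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Johnson weights for exactly two predictors, closed form: the 2x2
# correlation matrix has eigenvectors (1,1)/sqrt2 and (1,-1)/sqrt2.
oracle_relweights2 <- function(y, x1, x2) {
  r <- cor(x1, x2)
  ev1 <- 1 + r; ev2 <- 1 - r
  P <- cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2))
  L <- P %*% diag(sqrt(c(ev1, ev2))) %*% t(P)
  Linv <- P %*% diag(1 / sqrt(c(ev1, ev2))) %*% t(P)
  rxy <- c(cor(x1, y), cor(x2, y))
  bb <- as.vector(Linv %*% rxy)
  as.vector((L^2) %*% (bb^2))
}

rand_regions <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000,
                         max_len = 800) {
  start <- sample(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
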
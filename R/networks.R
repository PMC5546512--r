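#' Build the bipartite enhancer-target network
#'
#' Enhancer nodes on one side, gene nodes on the other; one edge per unique
#' enhancer-gene pair.
#'
#' @param pairs Pair data.frame (`enhancer_id`, `gene_id`).
#' @return An `igraph` bipartite graph with vertex attribute `type`
#'   (FALSE = enhancer, TRUE = gene).
#' @export
build_network <- function(pairs) {
  edges <- unique(pairs[, c("enhancer_id", "gene_id")])
  enh <- unique(edges$enhancer_id)
  gen <- unique(edges$gene_id)
  if (length(intersect(enh, gen)) > 0)
    stop("enhancer and gene identifiers overlap")
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = c(enh, gen),
                          type = c(rep(FALSE, length(enh)),
                                   rep(TRUE, length(gen))))
  )
  g
}

#' Degree table of a bipartite network
#' @param network Graph from [build_network()].
#' @return data.frame with `node`, `side` (enhancer/gene) and `degree`.
#' @export
network_degrees <- function(network) {
  d <- igraph::degree(network)
  data.frame(node = names(d),
             side = ifelse(igraph::V(network)$type, "gene", "enhancer"),
             degree = unname(d),
             stringsAsFactors = FALSE)
}

#' Enhancers with at least k targets
#' @param network Graph from [build_network()].
#' @param min_targets Minimum target count (default 4).
#' @return Character vector of enhancer node names.
#' @export
multi_target_enhancers <- function(network, min_targets = 4) {
  d <- network_degrees(network)
  d$node[d$side == "enhancer" & d$degree >= min_targets]
}

#' Discrete power-law fit of a degree distribution
#'
#' Maximum-likelihood exponent of a discrete power law with `xmin` fixed at
#' 1, plus the Kolmogorov-Smirnov distance between the empirical and fitted
#' distributions. Whether the fit is adequate is left to the caller; a
#' degenerate input (all degrees identical) is flagged instead of fitted.
#'
#' @param degrees Integer vector of node degrees (>= 1).
#' @param xmin Lower cutoff (default 1).
#' @return List with `alpha`, `ks_distance`, `n` and `degenerate`.
#' @export
degree_powerlaw_fit <- function(degrees, xmin = 1) {
  degrees <- degrees[degrees >= xmin]
  if (length(degrees) < 10) stop("need at least 10 nodes")
  if (length(unique(degrees)) == 1)
    return(list(alpha = NA_real_, ks_distance = NA_real_,
                n = length(degrees), degenerate = TRUE))
  fit <- igraph::fit_power_law(degrees, xmin = xmin, implementation = "plfit",
                               force.continuous = FALSE)
  list(alpha = fit$alpha, ks_distance = fit$KS.stat, n = length(degrees),
       degenerate = FALSE)
}

#' Co-expression of genes sharing an enhancer
#'
#' Pearson correlation of expression across samples for all genes targeted
#' by the selected enhancers, with the mean pairwise correlation within an
#' enhancer's target set and between different sets, and an average-linkage
#' hierarchical clustering on `1 - r`.
#'
#' @param pairs Pair data.frame.
#' @param expr Expression matrix, genes x samples.
#' @param enhancers Enhancer ids to analyse (default: all with >= 2 targets).
#' @param samples Sample ids (default: all columns).
#' @return List with the correlation matrix `cor`, `within_mean`,
#'   `between_mean`, the per-enhancer target list and the `hclust` tree.
#' @export
coexpression_of_targets <- function(pairs, expr, enhancers = NULL,
                                    samples = NULL) {
  tgt <- split(pairs$gene_id, pairs$enhancer_id)
  tgt <- lapply(tgt, unique)
  if (is.null(enhancers)) {
    tgt <- tgt[vapply(tgt, length, integer(1)) >= 2]
  } else {
    tgt <- tgt[enhancers]
    if (any(vapply(tgt, length, integer(1)) < 2))
      stop("each selected enhancer needs >= 2 targets")
  }
  if (length(tgt) == 0) stop("no enhancer with >= 2 targets")
  genes <- unique(unlist(tgt))
  genes <- intersect(genes, rownames(expr))
  if (is.null(samples)) samples <- colnames(expr)
  r <- stats::cor(t(expr[genes, samples, drop = FALSE]))
  membership <- lapply(tgt, function(g) intersect(g, genes))
  same <- matrix(FALSE, length(genes), length(genes),
                 dimnames = list(genes, genes))
  for (g in membership) same[g, g] <- TRUE
  off <- upper.tri(r)
  within_mean <- mean(r[off & same])
  between_mean <- if (any(off & !same)) mean(r[off & !same]) else NA_real_
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(cor = r, within_mean = within_mean, between_mean = between_mean,
       targets = membership, hclust = hc)
}

#' Functional coherence of enhancer target sets
#'
#' An enhancer is called coherent when at least `share_min` of its targets
#' belong to one common gene set. Also reports, per enhancer and set, the
#' fraction of targets overlapping the set.
#'
#' @param pairs Pair data.frame.
#' @param gene_sets Named list of gene sets.
#' @param min_targets Only enhancers with at least this many targets are
#'   assessed (default 3).
#' @param share_min Targets that must share one set (default 2).
#' @return List with the per-enhancer table `coherence` (`enhancer_id`,
#'   `n_targets`, `coherent`, `best_set`, `best_overlap`), the count
#'   `n_coherent`, and the long-format `overlap_fractions` table.
#' @export
functional_coherence <- function(pairs, gene_sets, min_targets = 3,
                                 share_min = 2) {
  if (length(gene_sets) == 0) stop("gene_sets must be nonempty")
  tgt <- lapply(split(pairs$gene_id, pairs$enhancer_id), unique)
  tgt <- tgt[vapply(tgt, length, integer(1)) >= min_targets]
  rows <- lapply(names(tgt), function(e) {
    ov <- vapply(gene_sets, function(s) length(intersect(tgt[[e]], s)),
                 integer(1))
    best <- which.max(ov)
    data.frame(enhancer_id = e, n_targets = length(tgt[[e]]),
               coherent = max(ov) >= share_min,
               best_set = names(gene_sets)[best],
               best_overlap = ov[best] / length(tgt[[e]]),
               stringsAsFactors = FALSE)
  })
  coh <- do.call(rbind, rows)
  if (is.null(coh))
    coh <- data.frame(enhancer_id = character(0), n_targets = integer(0),
                      coherent = logical(0), best_set = character(0),
                      best_overlap = numeric(0))
  fr <- do.call(rbind, lapply(names(tgt), function(e) {
    data.frame(enhancer_id = e, set = names(gene_sets),
               overlap_fraction = vapply(gene_sets, function(s)
                 length(intersect(tgt[[e]], s)) / length(tgt[[e]]),
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(coh) <- NULL
  list(coherence = coh, n_coherent = sum(coh$coherent),
       overlap_fractions = fr)
}

#' Random target sets emulating enhancer subnetworks
#'
#' Draws `n_networks` random gene sets whose sizes are uniform on
#' `[size_min, size_max]`, sampling genes without replacement within a set.
#' Used as the null for the coherence analysis.
#'
#' @param n_networks Number of random sets.
#' @param gene_pool Character vector to sample from.
#' @param size_min,size_max Size bounds (defaults 2 and 16).
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
random_subnetworks <- function(n_networks, gene_pool, size_min = 2,
                               size_max = 16, seed = 1) {
  if (length(gene_pool) < size_max) stop("gene pool smaller than size_max")
  set.seed(seed)
  size_range <- seq(size_min, size_max)
  sizes <- size_range[sample.int(length(size_range), n_networks,
                                 replace = TRUE)]
  lapply(sizes, function(s) sample(gene_pool, s))
}

#' Coherence of random subnetworks
#'
#' Applies the coherence rule of [functional_coherence()] to random target
#' sets, giving the null count of coherent "enhancers".
#'
#' @param subnetworks List of gene-id vectors from [random_subnetworks()].
#' @param gene_sets Named list of gene sets.
#' @param share_min Shared-set threshold (default 2).
#' @return Logical vector, one flag per subnetwork.
#' @export
subnetwork_coherence <- function(subnetworks, gene_sets, share_min = 2) {
  vapply(subnetworks, function(g) {
    any(vapply(gene_sets, function(s) length(intersect(g, s)),
               integer(1)) >= share_min)
  }, logical(1))
}
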
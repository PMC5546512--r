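#' Define promoter windows around transcription start sites
#'
#' A promoter is a fixed window centred on the TSS, `[tss - half_window,
#' tss + half_window)`, clipped at the chromosome start.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @param half_window Half width in bp (default 2000, i.e. a 4 kb window).
#' @return data.frame of promoter regions with columns `chrom`, `start`,
#'   `end`, `region_id`, `kind`, `gene_id`, `tss`.
#' @export
define_promoters <- function(genes, half_window = 2000) {
  stopifnot(half_window > 0)
  if (any(genes$tss < 0)) stop("gene with negative tss")
  data.frame(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$tss - half_window)),
    end = as.integer(genes$tss + half_window),
    region_id = paste0("prom:", genes$gene_id),
    kind = "promoter",
    gene_id = genes$gene_id,
    tss = genes$tss,
    stringsAsFactors = FALSE
  )
}

#' Filter peaks down to candidate enhancers
#'
#' Removes every peak that overlaps a TSS-proximal exclusion window
#' `[tss - exclusion_half_window, tss + exclusion_half_window)`; surviving
#' peaks keep their original coordinates (whole peaks are dropped, never
#' trimmed). Overlapping input peaks are merged first.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param genes Gene annotation data.frame.
#' @param exclusion_half_window Half width of the exclusion zone in bp
#'   (default 2500).
#' @return data.frame of enhancer regions with `region_id` of the form
#'   `chrom:start-end` and `kind = "enhancer"`.
#' @export
define_enhancers <- function(peaks, genes, exclusion_half_window = 2500) {
  if (any(peaks$start >= peaks$end)) stop("malformed peak interval")
  pk_gr <- GenomicRanges::reduce(.regions_gr(peaks))
  pk <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(pk_gr)),
    start = GenomicRanges::start(pk_gr) - 1L,
    end = GenomicRanges::end(pk_gr),
    stringsAsFactors = FALSE
  )
  excl <- data.frame(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$tss - exclusion_half_window)),
    end = as.integer(genes$tss + exclusion_half_window)
  )
  hits <- GenomicRanges::findOverlaps(.regions_gr(pk), .regions_gr(excl))
  drop <- unique(S4Vectors::queryHits(hits))
  keep <- pk[setdiff(seq_len(nrow(pk)), drop), , drop = FALSE]
  if (nrow(keep) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = keep$chrom, start = keep$start, end = keep$end,
    region_id = .coord_id(keep$chrom, keep$start, keep$end),
    kind = "enhancer",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Aggregate probe beta values into per-region methylation
#'
#' For every region and sample, the summary (arithmetic mean by default) of
#' beta values over probes with `start <= pos < end`. Regions covered by no
#' probe are omitted and reported in the coverage slot.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `region_id`.
#' @param probes Probe manifest data.frame (`probe_id`, `chrom`, `pos`).
#' @param beta Numeric matrix probes x samples, beta values in \[0, 1\].
#' @param fun Aggregation: `"mean"` (default) or `"median"`.
#' @return List of class `meth_track` with `values` (covered regions x
#'   samples matrix), `probes` (list of covering probe ids per region) and
#'   `coverage` (counts plus ids of uncovered regions).
#' @export
aggregate_region_methylation <- function(regions, probes, beta,
                                         fun = c("mean", "median")) {
  fun <- match.arg(fun)
  probes <- probes[probes$probe_id %in% rownames(beta), , drop = FALSE]
  beta <- beta[probes$probe_id, , drop = FALSE]
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value outside [0,1] for probe %s, sample %s",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  }
  hits <- GenomicRanges::findOverlaps(
    .points_gr(probes$chrom, probes$pos), .regions_gr(regions))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  covered <- sort(unique(sh))
  if (length(covered) == 0) {
    values <- matrix(numeric(0), nrow = 0, ncol = ncol(beta),
                     dimnames = list(NULL, colnames(beta)))
  } else if (fun == "mean") {
    sums <- rowsum(beta[qh, , drop = FALSE], group = sh)
    counts <- as.vector(table(sh))
    values <- sums / counts
    rownames(values) <- regions$region_id[covered]
  } else {
    values <- t(vapply(covered, function(r) {
      apply(beta[qh[sh == r], , drop = FALSE], 2, stats::median)
    }, numeric(ncol(beta))))
    rownames(values) <- regions$region_id[covered]
  }
  probe_list <- split(probes$probe_id[qh], regions$region_id[sh])
  structure(list(
    values = values,
    probes = probe_list,
    coverage = list(
      n_regions = nrow(regions),
      n_covered = length(covered),
      uncovered_ids = regions$region_id[setdiff(seq_len(nrow(regions)),
                                                covered)]
    )
  ), class = "meth_track")
}

#' @export
print.meth_track <- function(x, ...) {
  cat(sprintf("<meth_track> %d/%d regions covered, %d samples\n",
              x$coverage$n_covered, x$coverage$n_regions,
              ncol(x$values)))
  invisible(x)
}

#' Map chromatin-interaction anchors to enhancer-promoter pairs
#'
#' A pair (enhancer E, gene g) is emitted when one anchor of an
#' intra-chromosomal interaction overlaps E and the other overlaps the
#' promoter of g; both anchor orientations are checked and duplicate pairs
#' collapsed. Inter-chromosomal records are skipped and counted.
#'
#' @param interactions BEDPE data.frame (`chrom1,start1,end1,chrom2,start2,end2`).
#' @param enhancers Enhancer regions (from [define_enhancers()]).
#' @param promoters Promoter regions (from [define_promoters()]), carrying
#'   `gene_id` and `tss`.
#' @param min_overlap Minimum anchor overlap in bp (default 1).
#' @return data.frame of pairs: `enhancer_id`, `gene_id`, `promoter_id`,
#'   `distance` (enhancer midpoint to TSS), `support = "chia_pet"`. The
#'   number of skipped inter-chromosomal records is in attribute
#'   `n_interchrom`.
#' @export
map_anchors_to_pairs <- function(interactions, enhancers, promoters,
                                 min_overlap = 1) {
  intra <- interactions$chrom1 == interactions$chrom2
  n_skip <- sum(!intra)
  inter <- interactions[intra, , drop = FALSE]

  a1 <- data.frame(chrom = inter$chrom1, start = inter$start1,
                   end = inter$end1)
  a2 <- data.frame(chrom = inter$chrom2, start = inter$start2,
                   end = inter$end2)
  hit_tab <- function(anch, regions) {
    # disjoint seqlevels (no shared chromosome) is a valid empty-overlap
    # case, not a problem worth a GenomeInfoDb warning
    h <- suppressWarnings(
      GenomicRanges::findOverlaps(.regions_gr(anch), .regions_gr(regions),
                                  minoverlap = min_overlap))
    data.frame(rec = S4Vectors::queryHits(h), reg = S4Vectors::subjectHits(h))
  }
  one_side <- function(enh_anchor, prom_anchor) {
    eh <- hit_tab(enh_anchor, enhancers)
    ph <- hit_tab(prom_anchor, promoters)
    m <- merge(eh, ph, by = "rec", suffixes = c("_e", "_p"))
    if (nrow(m) == 0) return(NULL)
    data.frame(enh = m$reg_e, prom = m$reg_p)
  }
  both <- rbind(one_side(a1, a2), one_side(a2, a1))
  if (is.null(both) || nrow(both) == 0) {
    out <- data.frame(enhancer_id = character(0), gene_id = character(0),
                      promoter_id = character(0), distance = numeric(0),
                      support = character(0), stringsAsFactors = FALSE)
    attr(out, "n_interchrom") <- n_skip
    return(out)
  }
  both <- unique(both)
  mid <- .midpoint(enhancers$start[both$enh], enhancers$end[both$enh])
  out <- data.frame(
    enhancer_id = enhancers$region_id[both$enh],
    gene_id = promoters$gene_id[both$prom],
    promoter_id = promoters$region_id[both$prom],
    distance = abs(mid - promoters$tss[both$prom]),
    support = "chia_pet",
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$enhancer_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_interchrom") <- n_skip
  out
}

#' Assign each enhancer to its nearest gene
#'
#' Baseline pairing: each enhancer is linked to the gene whose TSS is closest
#' to the enhancer midpoint, with ties broken by the lexicographically
#' smaller `gene_id`. Enhancers on chromosomes without genes are flagged in
#' attribute `unpaired` and produce no pair.
#'
#' @param enhancers Enhancer regions.
#' @param genes Gene annotation data.frame.
#' @return data.frame of pairs with `support = "nearest_gene"`.
#' @export
nearest_gene_pairs <- function(enhancers, genes) {
  res <- vector("list", nrow(enhancers))
  unpaired <- character(0)
  for (i in seq_len(nrow(enhancers))) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      unpaired <- c(unpaired, enhancers$region_id[i])
      next
    }
    mid <- .midpoint(enhancers$start[i], enhancers$end[i])
    d <- abs(g$tss - mid)
    cand <- g[d == min(d), , drop = FALSE]
    pick <- cand[order(cand$gene_id)[1], ]
    res[[i]] <- data.frame(
      enhancer_id = enhancers$region_id[i],
      gene_id = pick$gene_id,
      promoter_id = paste0("prom:", pick$gene_id),
      distance = abs(pick$tss - mid),
      support = "nearest_gene",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(enhancer_id = character(0), gene_id = character(0),
                      promoter_id = character(0), distance = numeric(0),
                      support = character(0))
  rownames(out) <- NULL
  attr(out, "unpaired") <- unpaired
  out
}

#' Partition pairs into short- and long-range sets
#'
#' @param pairs Pair data.frame with a `distance` column.
#' @param threshold Distance cutoff in bp (default 100 kb); pairs at exactly
#'   the threshold fall into the short-range set.
#' @return List with elements `short` (distance <= threshold) and `long`.
#' @export
stratify_pairs_by_distance <- function(pairs, threshold = 100000) {
  list(
    short = pairs[pairs$distance <= threshold, , drop = FALSE],
    long = pairs[pairs$distance > threshold, , drop = FALSE]
  )
}
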
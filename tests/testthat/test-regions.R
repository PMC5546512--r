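test_that("promoter windows are TSS-centred and clipped at zero", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr2"),
                      strand = c("+", "-", "+"),
                      tss = c(10000, 500, 30000))
  pr <- define_promoters(genes)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$start[pr$gene_id == "g1"], 8000)
  expect_equal(pr$end[pr$gene_id == "g1"], 12000)
  expect_equal(pr$start[pr$gene_id == "g2"], 0)
  expect_equal(pr$end[pr$gene_id == "g2"], 2500)
  expect_true(all(grepl("^prom:g", pr$region_id)))
  expect_error(define_promoters(transform(genes, tss = c(-5, 1, 2))),
               "negative")
})

test_that("TSS-proximal peaks are removed whole, distal peaks kept", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 10000)
  peaks <- data.frame(chrom = "chr1",
                      start = c(9000, 20000), end = c(9500, 21000))
  enh <- define_enhancers(peaks, genes)
  expect_equal(nrow(enh), 1)
  expect_equal(enh$start, 20000)
  expect_equal(enh$end, 21000)  # original coordinates retained
})

test_that("enhancer filtering matches the all-pairs overlap oracle", {
  set.seed(31)
  for (rep in 1:25) {
    peaks <- rand_regions(10)
    peaks <- peaks[order(peaks$chrom, peaks$start), ]
    genes <- data.frame(gene_id = sprintf("g%02d", 1:5),
                        chrom = sample(c("chrA", "chrB"), 5, replace = TRUE),
                        strand = "+",
                        tss = sample(10000, 5))
    # pre-merge so coordinates survive the reduce step unchanged
    gr <- GenomicRanges::reduce(enhmeth:::.regions_gr(peaks))
    peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr))
    got <- define_enhancers(peaks, genes)
    want <- oracle_filter_peaks(peaks, genes, 2500)
    expect_equal(got[, c("chrom", "start", "end")],
                 want[, c("chrom", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("region methylation aggregates probe betas correctly", {
  regions <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 200),
                        region_id = c("r1", "r2"))
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       chrom = "chr1", pos = c(10, 120, 150))
  beta <- matrix(c(0.7, 0.2, 0.4), 3, 1,
                 dimnames = list(c("p1", "p2", "p3"), "s1"))
  tr <- aggregate_region_methylation(regions, probes, beta)
  expect_equal(tr$values["r1", "s1"], 0.7)       # singleton mean
  expect_equal(tr$values["r2", "s1"], 0.3)       # mean of 0.2 and 0.4
  expect_equal(tr$coverage$n_covered, 2)
  beta[1, 1] <- 1.2
  expect_error(aggregate_region_methylation(regions, probes, beta),
               "p1.*s1")
})

test_that("aggregation matches the nested-loop oracle and commutes with subsetting", {
  set.seed(42)
  regions <- rand_regions(20)
  regions$region_id <- sprintf("r%02d", 1:20)
  probes <- data.frame(probe_id = sprintf("p%02d", 1:15),
                       chrom = sample(c("chrA", "chrB"), 15, replace = TRUE),
                       pos = sample(10500, 15))
  beta <- matrix(runif(15 * 4), 15, 4,
                 dimnames = list(probes$probe_id, paste0("s", 1:4)))
  got <- aggregate_region_methylation(regions, probes, beta)
  want <- oracle_region_means(regions, probes, beta)
  expect_equal(got$values[rownames(want), ], want)
  # sample subsetting commutes
  sub <- aggregate_region_methylation(regions, probes,
                                      beta[, c("s2", "s4")])
  expect_equal(sub$values, got$values[, c("s2", "s4")])
})

test_that("anchor mapping emits exactly the enhancer-promoter overlaps", {
  enhancers <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                          region_id = "E1", kind = "enhancer")
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(50000, 90000))
  promoters <- define_promoters(genes)
  inter <- data.frame(chrom1 = "chr1", start1 = 900, end1 = 2100,
                      chrom2 = "chr1", start2 = 49500, end2 = 50500)
  p <- map_anchors_to_pairs(inter, enhancers, promoters)
  expect_equal(p$enhancer_id, "E1")
  expect_equal(p$gene_id, "g1")
  expect_equal(p$distance, abs(1500 - 50000))
  # both anchors on promoters -> no pair
  inter2 <- data.frame(chrom1 = "chr1", start1 = 49500, end1 = 50500,
                       chrom2 = "chr1", start2 = 89500, end2 = 90500)
  expect_equal(nrow(map_anchors_to_pairs(inter2, enhancers, promoters)), 0)
  # inter-chromosomal records are skipped and counted
  inter3 <- rbind(inter, data.frame(chrom1 = "chr1", start1 = 900,
                                    end1 = 2100, chrom2 = "chr2",
                                    start2 = 49500, end2 = 50500))
  p3 <- map_anchors_to_pairs(inter3, enhancers, promoters)
  expect_equal(attr(p3, "n_interchrom"), 1)
})

test_that("anchor mapping is symmetric in anchor order and matches the oracle", {
  set.seed(17)
  for (rep in 1:10) {
    enhancers <- rand_regions(10)
    enhancers$region_id <- sprintf("E%02d", 1:10)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                        chrom = sample(c("chrA", "chrB"), 10, replace = TRUE),
                        strand = "+", tss = sample(9000, 10))
    promoters <- define_promoters(genes, half_window = 400)
    inter <- cbind(rand_regions(30), rand_regions(30))
    names(inter) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
    got <- map_anchors_to_pairs(inter, enhancers, promoters)
    want <- oracle_ep_pairs(inter, enhancers, promoters)
    expect_equal(sort(paste(got$enhancer_id, got$gene_id)), want)
    swapped <- inter[, c(4, 5, 6, 1, 2, 3)]
    names(swapped) <- names(inter)
    got_sw <- map_anchors_to_pairs(swapped, enhancers, promoters)
    expect_equal(got[, 1:4], got_sw[, 1:4], ignore_attr = TRUE)
  }
})

test_that("nearest-gene pairing minimizes distance with lexicographic ties", {
  enhancers <- data.frame(chrom = "chr1", start = 4500, end = 5500,
                          region_id = "E1")
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
                      tss = c(4000, 9000))
  p <- nearest_gene_pairs(enhancers, genes)
  expect_equal(p$gene_id, "gB")     # mid 5000, distances 1000 vs 4000
  genes2 <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
                       tss = c(4000, 6000))
  p2 <- nearest_gene_pairs(enhancers, genes2)
  expect_equal(p2$gene_id, "gA")    # equidistant -> smaller gene_id
  # enhancer on a chromosome with no genes is flagged, not paired
  enh2 <- rbind(enhancers,
                data.frame(chrom = "chrX", start = 0, end = 100,
                           region_id = "E2"))
  p3 <- nearest_gene_pairs(enh2, genes)
  expect_equal(attr(p3, "unpaired"), "E2")
  expect_equal(nrow(p3), 1)
})

test_that("nearest-gene pairing matches the brute-force oracle", {
  set.seed(5)
  enhancers <- rand_regions(50)
  enhancers$region_id <- sprintf("E%02d", 1:50)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40),
                      chrom = sample(c("chrA", "chrB"), 40, replace = TRUE),
                      strand = "+", tss = sample(11000, 40))
  got <- nearest_gene_pairs(enhancers, genes)
  want <- oracle_nearest(enhancers, genes)
  expect_equal(got$gene_id, want[!is.na(want)])
})

test_that("distance stratification partitions pairs at the threshold", {
  pairs <- data.frame(enhancer_id = paste0("E", 1:10), gene_id = "g",
                      distance = c(150000, 100000, seq(1000, 80000,
                                                       length.out = 8)))
  s <- stratify_pairs_by_distance(pairs)
  expect_equal(nrow(s$long), 1)                       # only 150 kb
  expect_true(100000 %in% s$short$distance)           # boundary goes short
  expect_equal(nrow(s$short) + nrow(s$long), 10)
})
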
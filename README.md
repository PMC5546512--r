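# enhmeth

Enhancer methylation, target-gene regulation, and survival risk analysis.

Distal enhancers are cis-regulatory elements whose DNA methylation is
increasingly recognized as a driver of aberrant gene expression in cancer,
yet most methylation analyses still focus on promoters. `enhmeth` is an R
package for the integrated analysis that links the three layers of evidence
needed to study enhancer methylation in patient cohorts:

* **Where are the enhancers and which genes do they control?**
  H3K27ac peaks filtered away from transcription start sites define
  candidate enhancers; chromatin-interaction anchors (ChIA-PET style BEDPE
  records) connect an enhancer to a gene when one anchor overlaps the
  enhancer and the other overlaps the gene's promoter window (TSS ± 2 kb),
  with a nearest-gene baseline for comparison.
* **Does enhancer methylation matter for expression?**
  Region methylation is aggregated from array-style CpG probe beta values
  (mean beta over probes inside the region). Per enhancer–promoter pair the
  package computes Spearman correlations of enhancer methylation vs
  expression (ρ_E) and promoter methylation vs expression (ρ_P), and the
  dominance ratio |ρ_E| / |ρ_P|: a gene is *enhancer-dominant* when the
  ratio exceeds 2 with a significant enhancer correlation. Genes are
  classified as enhancer-regulated (eRG) or promoter-regulated (pRG),
  bipartite enhancer–target networks are characterized (degree power-law
  fit, co-expression of shared targets, functional coherence against gene
  sets), and subtype-specific differentially methylated enhancers
  (basal vs non-basal) are scanned.
* **Does it matter for patients?**
  A genome-scale Kaplan–Meier scan splits patients at each enhancer's
  median methylation and tests the two survival curves by log-rank, with
  two constructed nulls (random probe-centred ±500 bp fragments; joint
  permutation of survival times). Targets of survival-associated enhancers
  are ranked by univariate Cox regression on z-standardized expression and
  selected at Benjamini–Hochberg FDR < 0.05, then combined into a
  per-patient risk score

  `Riskscore = Σᵢ βᵢ · Exp_gene(i)`

  with patients split at score 0 and compared by log-rank; an exhaustive
  subset scan finds the best-prognostic gene combination.

Because cohort-scale data are large and access-controlled, the package
ships a first-class synthetic-data module (`simulate_study()`) that plants
known eDMRs, regulatory links, subtype shifts and survival effects with a
machine-readable ground truth, so every stage of the pipeline is verifiable
by parameter recovery.

## Worked example

```r
library(enhmeth)

bundle    <- simulate_study(sim_config(seed = 1))
enhancers <- define_enhancers(bundle$peaks, bundle$genes)
promoters <- define_promoters(bundle$genes)
enh_track  <- aggregate_region_methylation(enhancers, bundle$probes, bundle$meth)
prom_track <- aggregate_region_methylation(promoters, bundle$probes, bundle$meth)
pairs <- map_anchors_to_pairs(bundle$interactions, enhancers, promoters)
tumor <- bundle$clinical$sample_id[bundle$clinical$group == "tumor"]
group <- factor(bundle$clinical$group, levels = c("normal", "tumor"))

edmr   <- differential_test(enh_track$values, group)
calls  <- dominance_ratio(correlate_pairs(pairs, enh_track, prom_track,
                                          bundle$expr, samples = tumor))
labels <- classify_regulated_genes(calls)

cat("E-P pairs:", nrow(pairs), "\n")
cat("eDMRs:", sum(edmr$direction != "none"),
    "( hypo:", sum(edmr$direction == "hypo"), ")\n")
cat("eRGs:", sum(labels$label %in% c("eRG", "both")),
    "  pRGs:", sum(labels$label %in% c("pRG", "both")), "\n")
cat("enhancer-dominant pairs:", sum(calls$dominant == "enhancer"),
    "of", nrow(calls), "\n")
```

prints

```
E-P pairs: 158
eDMRs: 62 ( hypo: 60 )
eRGs: 119   pRGs: 46
enhancer-dominant pairs: 113 of 158
```

The default simulation plants 60 hypomethylated tumor enhancers driving 118
genes: the eDMR scan recovers them (62 calls, 60 hypo, 2 false positives at
the 5% level), the correlation stage labels the driven genes eRG, and most
driven pairs are enhancer-dominant. The full pipeline — including the
subtype scan, survival scan, permutation nulls, Cox selection, risk score
and combination scan — runs from a single config with `run_all()`:

```r
dir <- tempfile(); write_study_bundle(bundle, dir)
report <- run_all(default_run_config(dir, file.path(dir, "out")))
```

Every stage writes plain TSV/JSON tables (`pairs.tsv`, `edmr.tsv`,
`regulation_calls.tsv`, `ssedmr.tsv`, `survival_scan.tsv`,
`risk_model.json`, `combinations.tsv`, `report.json`, ...) under the output
directory.

## Documentation

The methods vignette (`vignettes/enhmeth-methods.Rmd`) describes the models
and statistics, every tunable parameter with its default and rationale,
what the simulator does and does not emulate, and known limitations.
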
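# Shared simulated bundles, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

# small planted bundle used across module tests
planted_bundle <- function() {
  fixture("planted", function() {
    simulate_study(sim_config(n_genes = 80, n_enhancers = 40,
                              n_normal = 40, n_tumor = 60,
                              n_risk_genes = 3, seed = 101))
  })
}

# matching analysis products for the planted bundle
planted_analysis <- function() {
  fixture("planted_analysis", function() {
    b <- planted_bundle()
    enhancers <- define_enhancers(b$peaks, b$genes)
    promoters <- define_promoters(b$genes)
    enh_track <- aggregate_region_methylation(enhancers, b$probes, b$meth)
    prom_track <- aggregate_region_methylation(promoters, b$probes, b$meth)
    pairs <- map_anchors_to_pairs(b$interactions, enhancers, promoters)
    tumor <- b$clinical$sample_id[b$clinical$group == "tumor"]
    calls <- correlate_pairs(pairs, enh_track, prom_track, b$expr,
                             samples = tumor)
    list(bundle = b, enhancers = enhancers, promoters = promoters,
         enh_track = enh_track, prom_track = prom_track, pairs = pairs,
         tumor = tumor, calls = calls)
  })
}

surv_single_bundle <- function() {
  fixture("surv_single", function() {
    simulate_study(sim_config(n_genes = 40, n_enhancers = 20,
                              frac_eRG = 0.25, frac_pRG = 0.1,
                              n_normal = 10, n_tumor = 300,
                              n_risk_genes = 1, hazard_betas = 0.7,
                              seed = 55))
  })
}

surv_combo_bundle <- function() {
  fixture("surv_combo", function() {
    simulate_study(sim_config(n_genes = 30, n_enhancers = 15, frac_eRG = 0.4,
                              frac_pRG = 0.1, frac_null = 0.5, n_normal = 10,
                              n_tumor = 200, n_risk_genes = 5, seed = 56))
  })
}

pure_null_bundle <- function() {
  fixture("pure_null_small", function() {
    simulate_study(sim_config(n_genes = 60, n_enhancers = 30,
                              n_normal = 30, n_tumor = 40,
                              effect_meth_shift = 0, effect_expr_slope = 0,
                              n_risk_genes = 2, hazard_betas = c(0, 0),
                              seed = 202))
  })
}
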
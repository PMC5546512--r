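#' Default pipeline configuration
#'
#' Returns the full parameter template for [run_all()]. Input paths point
#' into `input_dir` using the file names written by [write_study_bundle()].
#'
#' @param input_dir Directory holding the input files.
#' @param output_dir Directory for the result tables.
#' @return Named list of paths and stage parameters.
#' @export
default_run_config <- function(input_dir, output_dir) {
  list(
    inputs = list(
      genes = file.path(input_dir, "genes.tsv"),
      peaks = file.path(input_dir, "peaks.bed"),
      probes = file.path(input_dir, "probes.tsv"),
      meth = file.path(input_dir, "meth.tsv"),
      expr = file.path(input_dir, "expr.tsv"),
      interactions = file.path(input_dir, "interactions.bedpe"),
      clinical = file.path(input_dir, "clinical.tsv"),
      gene_sets = file.path(input_dir, "gene_sets.gmt")
    ),
    output_dir = output_dir,
    promoter_half_window = 2000,
    tss_exclusion = 2500,
    min_overlap = 1,
    alpha = 0.05,
    ratio_cutoff = 2,
    distance_threshold = 100000,
    min_targets_coherence = 3,
    coherence_share_min = 2,
    null_replicates = 100,
    run_region_null = TRUE,
    cox_fdr = 0.05,
    max_combination_genes = 20,
    seed = 1
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing fields are filled from [default_run_config()] (whose input paths
#' are resolved relative to the YAML's `input_dir`, when given).
#'
#' @param path Path to a YAML file.
#' @return Configuration list for [run_all()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- default_run_config(y$input_dir %||% ".", y$output_dir %||% "out")
  for (nm in setdiff(names(y), c("input_dir", "output_dir")))
    base[[nm]] <- y[[nm]]
  base
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: region definition and
#' enhancer-promoter pairing; differential methylation and expression;
#' methylation-expression regulation calls; network characterization;
#' subtype scan; survival scan, permutation nulls and risk modelling.
#' Every stage writes its tables under `config$output_dir` and the run
#' report is serialized as `report.json`.
#'
#' @param config Configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @return The run report (named list of per-stage counts and parameters),
#'   invisibly.
#' @export
run_all <- function(config) {
  cfg <- config
  for (f in names(cfg$inputs))
    if (!file.exists(cfg$inputs[[f]]))
      stop("configuration error: input file missing: ", f, " (",
           cfg$inputs[[f]], ")")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  wt <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## inputs
  genes <- read_genes(cfg$inputs$genes)
  peaks <- read_bed(cfg$inputs$peaks)
  probes <- read_probes(cfg$inputs$probes)
  meth <- read_matrix_tsv(cfg$inputs$meth)
  expr <- read_matrix_tsv(cfg$inputs$expr)
  interactions <- read_bedpe(cfg$inputs$interactions)
  clinical <- read_clinical(cfg$inputs$clinical)
  gene_sets <- read_gmt(cfg$inputs$gene_sets)

  group <- factor(clinical$group, levels = c("normal", "tumor"))
  names(group) <- clinical$sample_id
  tumor_ids <- clinical$sample_id[clinical$group == "tumor"]

  ## stage: pairing ---------------------------------------------------------
  pairing <- stage("pairs", {
    promoters <- define_promoters(genes, cfg$promoter_half_window)
    enhancers <- define_enhancers(peaks, genes, cfg$tss_exclusion)
    enh_track <- aggregate_region_methylation(enhancers, probes, meth)
    prom_track <- aggregate_region_methylation(promoters, probes, meth)
    pairs <- map_anchors_to_pairs(interactions, enhancers, promoters,
                                  cfg$min_overlap)
    nearest <- nearest_gene_pairs(enhancers, genes)
    wt(pairs, "pairs.tsv")
    wt(nearest, "nearest_pairs.tsv")
    jsonlite::write_json(list(
      enhancers = enh_track$coverage, promoters = prom_track$coverage,
      interchrom_skipped = attr(pairs, "n_interchrom")),
      out("coverage_report.json"), auto_unbox = TRUE, pretty = TRUE)
    list(promoters = promoters, enhancers = enhancers,
         enh_track = enh_track, prom_track = prom_track, pairs = pairs,
         nearest = nearest)
  })

  ## stage: differential ----------------------------------------------------
  covered_pairs <- pairing$pairs[
    pairing$pairs$enhancer_id %in% rownames(pairing$enh_track$values) &
    pairing$pairs$promoter_id %in% rownames(pairing$prom_track$values) &
    pairing$pairs$gene_id %in% rownames(expr), , drop = FALSE]
  dmr <- stage("dmr", {
    grp <- group[colnames(pairing$enh_track$values)]
    edmr <- differential_test(pairing$enh_track$values, grp,
                              alpha = cfg$alpha)
    names(edmr)[names(edmr) == "unit_id"] <- "enhancer_id"
    deg <- differential_test(expr[, names(group), drop = FALSE], group,
                             alpha = cfg$alpha, log2p1 = TRUE)
    names(deg)[names(deg) == "unit_id"] <- "gene_id"
    cv <- data.frame(
      unit_id = c(rownames(pairing$enh_track$values),
                  rownames(pairing$prom_track$values)),
      kind = rep(c("enhancer", "promoter"),
                 c(nrow(pairing$enh_track$values),
                   nrow(pairing$prom_track$values))),
      cv = c(apply(pairing$enh_track$values[, tumor_ids, drop = FALSE], 1,
                   coefficient_of_variation),
             apply(pairing$prom_track$values[, tumor_ids, drop = FALSE], 1,
                   coefficient_of_variation)),
      stringsAsFactors = FALSE)
    wt(edmr, "edmr.tsv"); wt(deg, "deg.tsv"); wt(cv, "cv.tsv")
    list(edmr = edmr, deg = deg, cv = cv)
  })

  ## stage: regulation --------------------------------------------------------
  reg <- stage("regulate", {
    calls <- correlate_pairs(covered_pairs, pairing$enh_track,
                             pairing$prom_track, expr, samples = tumor_ids,
                             alpha = cfg$alpha)
    calls <- dominance_ratio(calls, cutoff = cfg$ratio_cutoff,
                             alpha = cfg$alpha)
    labels <- classify_regulated_genes(calls, alpha = cfg$alpha)
    wt(calls, "regulation_calls.tsv")
    wt(labels, "gene_labels.tsv")
    list(calls = calls, labels = labels)
  })

  ## stage: network -----------------------------------------------------------
  net <- stage("network", {
    network <- build_network(covered_pairs)
    degrees <- network_degrees(network)
    coh <- functional_coherence(covered_pairs, gene_sets,
                                min_targets = cfg$min_targets_coherence,
                                share_min = cfg$coherence_share_min)
    wt(unique(covered_pairs[, c("enhancer_id", "gene_id")]), "network.tsv")
    wt(degrees, "degrees.tsv")
    wt(coh$coherence, "coherence.tsv")
    list(network = network, degrees = degrees, coherence = coh)
  })

  ## stage: subtype -----------------------------------------------------------
  sub <- stage("subtype", {
    subtype <- setNames(clinical$subtype, clinical$sample_id)
    tum_track <- pairing$enh_track$values[, tumor_ids, drop = FALSE]
    ssedmr <- find_ssedmr(tum_track, subtype[tumor_ids], alpha = cfg$alpha)
    sig <- ssedmr$enhancer_id[ssedmr$direction != "none"]
    clust <- if (length(sig) >= 2) {
      cluster_samples_by_methylation(tum_track[sig, , drop = FALSE],
                                     labels = subtype[tumor_ids])
    } else NULL
    basal_grp <- factor(subtype[tumor_ids], levels = c("non_basal", "basal"))
    deg_basal <- differential_test(expr[, tumor_ids, drop = FALSE],
                                   basal_grp, alpha = cfg$alpha,
                                   log2p1 = TRUE)
    dirsum <- target_direction_summary(ssedmr, deg_basal, covered_pairs)
    wt(ssedmr, "ssedmr.tsv")
    if (!is.null(clust))
      wt(data.frame(sample_id = names(clust$assignments),
                    cluster = unname(clust$assignments)),
         "cluster_assignments.tsv")
    wt(as.data.frame(dirsum$counts), "direction_counts.tsv")
    list(ssedmr = ssedmr, clust = clust, dirsum = dirsum)
  })

  ## stage: survival ----------------------------------------------------------
  surv <- stage("survival", {
    scan <- km_scan(pairing$enh_track, clinical, alpha = cfg$alpha)
    observed <- sum(scan$significant)
    perturb <- sample_perturbation_null(pairing$enh_track, clinical,
                                        observed = observed,
                                        replicates = cfg$null_replicates,
                                        alpha = cfg$alpha,
                                        seed = cfg$seed + 1)
    region_null <- if (isTRUE(cfg$run_region_null)) {
      random_region_null(probes, meth, clinical, observed = observed,
                         n_regions = nrow(pairing$enhancers),
                         replicates = cfg$null_replicates,
                         alpha = cfg$alpha, seed = cfg$seed + 2)
    } else NULL
    sig_enh <- scan$enhancer_id[scan$significant]
    targets <- unique(covered_pairs$gene_id[
      covered_pairs$enhancer_id %in% sig_enh])
    targets <- intersect(targets, rownames(expr))
    model <- if (length(targets) > 0) {
      cox_select_risk_genes(expr[targets, , drop = FALSE], clinical,
                            fdr = cfg$cox_fdr)
    } else NULL
    scores <- combos <- NULL
    if (!is.null(model) && length(model$selected) > 0) {
      scores <- risk_score(model, expr, clinical)
      if (length(model$selected) <= cfg$max_combination_genes)
        combos <- combination_scan(model, expr, clinical,
                                   max_genes = cfg$max_combination_genes)
    }
    wt(scan, "survival_scan.tsv")
    nulls <- data.frame(replicate = seq_along(perturb$counts),
                        perturbation = perturb$counts)
    if (!is.null(region_null)) nulls$random_region <- region_null$counts
    wt(nulls, "null_counts.tsv")
    if (!is.null(model)) {
      jsonlite::write_json(list(table = model$table,
                                selected = model$selected,
                                fdr = model$fdr),
                           out("risk_model.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA,
                           dataframe = "columns")
    }
    if (!is.null(scores))
      wt(data.frame(sample_id = names(scores$scores),
                    score = unname(scores$scores),
                    group = unname(scores$group)), "risk_scores.tsv")
    if (!is.null(combos)) wt(combos$table, "combinations.tsv")
    list(scan = scan, perturb = perturb, region_null = region_null,
         model = model, scores = scores, combos = combos)
  })

  ## report -------------------------------------------------------------------
  report <- list(
    counts = list(
      enhancers_defined = nrow(pairing$enhancers),
      enhancers_covered = pairing$enh_track$coverage$n_covered,
      promoters_covered = pairing$prom_track$coverage$n_covered,
      ep_pairs = nrow(pairing$pairs),
      ep_pairs_analyzable = nrow(covered_pairs),
      edmr = sum(dmr$edmr$direction != "none"),
      deg = sum(dmr$deg$direction != "none"),
      regulation_calls = nrow(reg$calls),
      erg_genes = sum(reg$labels$label %in% c("eRG", "both")),
      prg_genes = sum(reg$labels$label %in% c("pRG", "both")),
      ssedmr = sum(sub$ssedmr$direction != "none"),
      survival_enhancers = sum(surv$scan$significant),
      risk_genes = if (is.null(surv$model)) 0L
                   else length(surv$model$selected),
      combined_score_p = if (is.null(surv$scores)) NA else surv$scores$p
    ),
    parameters = cfg[setdiff(names(cfg), c("inputs", "output_dir"))],
    perturbation_empirical_p = surv$perturb$empirical_p,
    region_null_empirical_p = if (is.null(surv$region_null)) NULL
                              else surv$region_null$empirical_p
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), out("run_timestamp.txt"))
  invisible(report)
}
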
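#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_study()]. The
#' defaults define the package's reference toy study: two sample groups
#' (normal/tumor) with hypomethylated tumor enhancers, genes whose
#' expression decreases with the methylation of their regulating region,
#' subtype-dependent enhancer methylation within the tumor group, and
#' exponential survival whose log-hazard is a weighted sum of standardized
#' risk-gene expression.
#'
#' @param n_chromosomes Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 5e6).
#' @param n_genes Number of genes (default 200).
#' @param n_enhancers Number of enhancers (default 100); must not exceed
#'   `n_genes`.
#' @param probes_per_region CpG probes placed in each enhancer/promoter
#'   (default 3).
#' @param n_normal,n_tumor Sample counts (defaults 50, 50).
#' @param frac_basal Fraction of tumor samples of the basal subtype
#'   (default 0.4).
#' @param effect_meth_shift Beta-value difference planted for eDMRs (tumor
#'   vs normal) and for subtype-specific enhancers (basal vs non-basal);
#'   default 0.3. Zero plants no methylation signal.
#' @param effect_expr_slope Expression change per unit methylation of the
#'   regulating region (default -4). Zero plants no regulatory signal.
#' @param noise_sd_meth Per-sample methylation dispersion on the beta scale
#'   (default 0.2).
#' @param noise_sd_expr Expression noise standard deviation (default 0.8).
#' @param frac_eRG,frac_pRG,frac_null Fractions of genes planted as
#'   enhancer-regulated, promoter-regulated, and unregulated (defaults 0.3,
#'   0.2, 0.5; must sum to <= 1 and the implied eRG + pRG count must fit
#'   within `n_enhancers` so every regulated gene takes part in a pair).
#' @param frac_sse Fraction of enhancers planted with a basal/non-basal
#'   shift (default 0.3; drawn from the enhancer-regulated ones).
#' @param n_risk_genes Number of planted survival risk genes (default 5;
#'   drawn from the eRG genes).
#' @param hazard_betas Per-risk-gene log-hazard coefficients on standardized
#'   expression (default `log(2)` each). All-zero betas plant no survival
#'   signal.
#' @param censor_rate Expected fraction of censored patients (default 0.3).
#' @param seed Integer seed; fully determines the bundle.
#' @return Validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 5e6, n_genes = 200,
                       n_enhancers = 100, probes_per_region = 3,
                       n_normal = 50, n_tumor = 50, frac_basal = 0.4,
                       effect_meth_shift = 0.3, effect_expr_slope = -4,
                       noise_sd_meth = 0.2, noise_sd_expr = 0.8,
                       frac_eRG = 0.3, frac_pRG = 0.2, frac_null = 0.5,
                       frac_sse = 0.3, n_risk_genes = 5,
                       hazard_betas = rep(log(2), n_risk_genes),
                       censor_rate = 0.3, seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_genes = n_genes, n_enhancers = n_enhancers,
              probes_per_region = probes_per_region, n_normal = n_normal,
              n_tumor = n_tumor, frac_basal = frac_basal,
              effect_meth_shift = effect_meth_shift,
              effect_expr_slope = effect_expr_slope,
              noise_sd_meth = noise_sd_meth, noise_sd_expr = noise_sd_expr,
              frac_eRG = frac_eRG, frac_pRG = frac_pRG,
              frac_null = frac_null, frac_sse = frac_sse,
              n_risk_genes = n_risk_genes, hazard_betas = hazard_betas,
              censor_rate = censor_rate, seed = seed)
  cfg_err <- function(field, msg) stop("invalid config: ", field, " ", msg)
  for (f in c("n_chromosomes", "chrom_length", "n_genes", "n_enhancers",
              "probes_per_region", "n_normal", "n_tumor"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) cfg_err(f, "must be positive")
  for (f in c("frac_basal", "frac_eRG", "frac_pRG", "frac_null", "frac_sse",
              "censor_rate", "effect_meth_shift"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) cfg_err(f, "must be in [0, 1]")
  if (frac_eRG + frac_pRG + frac_null > 1 + 1e-9)
    cfg_err("frac_eRG+frac_pRG+frac_null", "must sum to <= 1")
  if (noise_sd_meth <= 0 || noise_sd_meth >= 0.25)
    cfg_err("noise_sd_meth", "must be in (0, 0.25)")
  if (noise_sd_expr < 0) cfg_err("noise_sd_expr", "must be nonnegative")
  if (n_enhancers > n_genes)
    cfg_err("n_enhancers", "must not exceed n_genes")
  n_erg <- round(frac_eRG * n_genes)
  n_prg <- round(frac_pRG * n_genes)
  if (n_erg > n_enhancers)
    cfg_err("frac_eRG", "implies more eRG genes than enhancers")
  if (n_erg + n_prg > n_enhancers)
    cfg_err("frac_pRG", "implies more regulated genes than enhancers can pair")
  if (n_risk_genes < 0 || (n_risk_genes > 0 && n_risk_genes > max(n_erg, 1)))
    cfg_err("n_risk_genes", "must not exceed the number of eRG genes")
  if (length(hazard_betas) != n_risk_genes)
    cfg_err("hazard_betas", "length must equal n_risk_genes")
  if (round(frac_sse * n_enhancers) > max(n_erg, 0) && effect_meth_shift > 0 &&
      frac_sse > 0)
    cfg_err("frac_sse", "implies more subtype enhancers than eRG enhancers")
  if (!is.numeric(seed) || seed != round(seed)) cfg_err("seed", "must be integer")
  gene_spacing <- floor(chrom_length / (ceiling(n_genes / n_chromosomes) + 1))
  if (gene_spacing < 12000)
    cfg_err("chrom_length", "too small for n_genes (gene spacing < 12 kb)")
  cfg$gene_spacing <- gene_spacing
  structure(cfg, class = "sim_config")
}

# Latent-Gaussian methylation: beta = plogis(latent). Find the latent mean
# whose squashed expectation equals the target beta mean (corrects the
# shrink-to-0.5 bias of the logistic squashing).
.latent_mean_for <- function(target, sigma) {
  if (sigma == 0) return(stats::qlogis(target))
  z <- seq(-6, 6, length.out = 201)
  w <- stats::dnorm(z); w <- w / sum(w)
  f <- function(mu) sum(stats::plogis(mu + sigma * z) * w) - target
  stats::uniroot(f, c(stats::qlogis(target) - 4, stats::qlogis(target) + 4))$root
}

.latent_cache <- function() {
  cache <- new.env(parent = emptyenv())
  function(target, sigma) {
    key <- paste(format(target, digits = 12), format(sigma, digits = 12))
    if (is.null(cache[[key]])) cache[[key]] <- .latent_mean_for(target, sigma)
    cache[[key]]
  }
}

#' Simulate a complete toy study bundle
#'
#' Generates an internally consistent study: gene annotation, enhancer
#' peaks, a CpG probe manifest, probe-level methylation, gene expression,
#' chromatin interactions linking enhancers to the promoters of their
#' target genes, clinical metadata with survival, gene sets, and a
#' machine-readable ground-truth record of everything planted.
#'
#' Methylation is a latent Gaussian per region and sample squashed to
#' \[0, 1\] with the logistic function (latent means bias-corrected so
#' planted beta-value shifts land on `effect_meth_shift`); probes add small
#' latent noise around their region. Expression is
#' `baseline + slope * methylation + Gaussian noise`, floored at 0.
#' Survival times are exponential with log-hazard
#' `sum(hazard_betas * z(risk-gene expression))` and independent
#' exponential censoring.
#'
#' @param config A [sim_config()] object.
#' @return List of class `study_bundle` with elements `genes`, `peaks`,
#'   `probes`, `meth`, `expr`, `interactions`, `clinical`, `gene_sets`,
#'   `truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  lat_mu <- .latent_cache()

  ## ---- layout -------------------------------------------------------------
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  gi <- seq_len(cfg$n_genes)
  chrom <- sprintf("chr%d", ((gi - 1) %/% per_chrom) + 1)
  slot <- ((gi - 1) %% per_chrom) + 1
  tss <- slot * cfg$gene_spacing
  genes <- data.frame(
    gene_id = sprintf("G%04d", gi), chrom = chrom,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE), tss = tss,
    stringsAsFactors = FALSE
  )

  ei <- sort(sample(cfg$n_genes, cfg$n_enhancers))
  enh <- data.frame(
    chrom = genes$chrom[ei],
    start = genes$tss[ei] + 6000L,
    end = genes$tss[ei] + 7000L,
    primary_gene = genes$gene_id[ei],
    stringsAsFactors = FALSE
  )
  enh$enhancer_id <- .coord_id(enh$chrom, enh$start, enh$end)

  ## ---- roles --------------------------------------------------------------
  n_erg <- round(cfg$frac_eRG * cfg$n_genes)
  n_prg <- round(cfg$frac_pRG * cfg$n_genes)
  enh_order <- sample(cfg$n_enhancers)
  active_enh <- sort(enh_order[seq_len(n_erg)])          # drive their genes
  inactive_enh <- sort(enh_order[seq(n_erg + 1, length.out = cfg$n_enhancers - n_erg)])
  prg_enh <- inactive_enh[seq_len(min(n_prg, length(inactive_enh)))]
  erg_primary <- enh$primary_gene[active_enh]
  prg_genes <- enh$primary_gene[prg_enh]

  # extra targets: active enhancers may co-drive additional unassigned genes
  driver_of <- setNames(rep(NA_character_, cfg$n_genes), genes$gene_id)
  driver_of[erg_primary] <- enh$enhancer_id[active_enh]
  free <- setdiff(genes$gene_id, c(enh$primary_gene))    # genes with no enhancer
  links <- data.frame(enhancer_id = enh$enhancer_id,
                      gene_id = enh$primary_gene,
                      stringsAsFactors = FALSE)
  for (j in active_enh) {
    m_extra <- sample(0:3, 1, prob = c(0.6, 0.2, 0.12, 0.08))
    if (m_extra == 0) next
    cand <- free[genes$chrom[match(free, genes$gene_id)] == enh$chrom[j]]
    cand <- cand[is.na(driver_of[cand])]
    if (length(cand) == 0) next
    extra <- sample(cand, min(m_extra, length(cand)))
    driver_of[extra] <- enh$enhancer_id[j]
    links <- rbind(links, data.frame(enhancer_id = enh$enhancer_id[j],
                                     gene_id = extra))
  }
  erg_genes <- names(driver_of)[!is.na(driver_of)]

  # subtype-shifted enhancers (from the active set) and risk genes
  n_sse <- round(cfg$frac_sse * cfg$n_enhancers)
  sse_enh <- if (n_sse > 0 && length(active_enh) > 0)
    sort(active_enh[sample.int(length(active_enh),
                               min(n_sse, length(active_enh)))]) else integer(0)
  sse_dir <- if (length(sse_enh) > 0)
    sample(rep(c("hyper", "hypo"), length.out = length(sse_enh))) else character(0)
  risk_genes <- if (cfg$n_risk_genes > 0)
    sort(sample(erg_primary, cfg$n_risk_genes)) else character(0)
  risk_enh <- enh$enhancer_id[match(risk_genes, enh$primary_gene)]

  ## ---- samples ------------------------------------------------------------
  n_basal <- round(cfg$frac_basal * cfg$n_tumor)
  samples <- data.frame(
    sample_id = c(sprintf("N%03d", seq_len(cfg$n_normal)),
                  sprintf("T%03d", seq_len(cfg$n_tumor))),
    group = rep(c("normal", "tumor"), c(cfg$n_normal, cfg$n_tumor)),
    stringsAsFactors = FALSE
  )
  subtype <- rep(NA_character_, nrow(samples))
  tumor_idx <- which(samples$group == "tumor")
  basal_idx <- sample(tumor_idx, n_basal)
  subtype[basal_idx] <- "basal"
  subtype[setdiff(tumor_idx, basal_idx)] <- "non_basal"
  samples$subtype <- subtype

  ## ---- region-level methylation -------------------------------------------
  shift <- cfg$effect_meth_shift
  fb <- cfg$frac_basal
  sclass <- ifelse(samples$group == "normal", "normal",
                   ifelse(samples$subtype == "basal", "basal", "non_basal"))
  n_s <- nrow(samples)

  region_means <- function(base, sig) {
    # returns function(class_targets) -> latent means per sample
    function(m_normal, m_basal, m_nonbasal) {
      mu <- c(normal = lat_mu(m_normal, sig),
              basal = lat_mu(m_basal, sig),
              non_basal = lat_mu(m_nonbasal, sig))
      mu[sclass]
    }
  }

  sig_enh <- cfg$noise_sd_meth / 0.25            # latent scale at beta ~ 0.5
  sig_prom_var <- cfg$noise_sd_meth / (0.3 * 0.7)
  sig_prom_stable <- 0.3 * cfg$noise_sd_meth / (0.3 * 0.7)

  enh_latent <- matrix(NA_real_, cfg$n_enhancers, n_s,
                       dimnames = list(enh$enhancer_id, samples$sample_id))
  is_sse <- setNames(rep(NA_character_, cfg$n_enhancers), enh$enhancer_id)
  if (length(sse_enh) > 0) is_sse[sse_enh] <- sse_dir
  for (j in seq_len(cfg$n_enhancers)) {
    planted <- (j %in% active_enh) && shift > 0
    m_norm <- if (planted) 0.5 + shift / 2 else 0.5
    m_tum <- if (planted) 0.5 - shift / 2 else 0.5
    dirn <- is_sse[j]
    if (!is.na(dirn) && shift > 0) {
      d <- if (dirn == "hyper") 1 else -1
      m_bas <- m_tum + d * shift * (1 - fb)
      m_non <- m_tum - d * shift * fb
    } else {
      m_bas <- m_tum; m_non <- m_tum
    }
    mu <- region_means(0.5, sig_enh)(m_norm, m_bas, m_non)
    enh_latent[j, ] <- mu + sig_enh * rnorm(n_s)
  }
  enh_beta <- stats::plogis(enh_latent)

  prom <- define_promoters(genes)
  prom_latent <- matrix(NA_real_, cfg$n_genes, n_s,
                        dimnames = list(prom$region_id, samples$sample_id))
  for (i in seq_len(cfg$n_genes)) {
    variable <- genes$gene_id[i] %in% prg_genes
    sig <- if (variable) sig_prom_var else sig_prom_stable
    mu <- lat_mu(0.3, sig)
    prom_latent[i, ] <- mu + sig * rnorm(n_s)
  }
  prom_beta <- stats::plogis(prom_latent)

  ## ---- probes -------------------------------------------------------------
  regions <- rbind(
    data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
               region_id = enh$enhancer_id, stringsAsFactors = FALSE),
    data.frame(chrom = prom$chrom, start = prom$start, end = prom$end,
               region_id = prom$region_id, stringsAsFactors = FALSE)
  )
  ppr <- cfg$probes_per_region
  probe_pos <- unlist(lapply(seq_len(nrow(regions)), function(r) {
    sort(sample(seq(regions$start[r], regions$end[r] - 1L), ppr))
  }))
  n_bg <- max(20L, round(0.2 * nrow(regions) * ppr))
  bg_chrom <- sprintf("chr%d", sample(cfg$n_chromosomes, n_bg, replace = TRUE))
  bg_pos <- sample.int(cfg$chrom_length, n_bg) - 1L
  probes <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(nrow(regions) * ppr + n_bg)),
    chrom = c(rep(regions$chrom, each = ppr), bg_chrom),
    pos = c(probe_pos, bg_pos),
    stringsAsFactors = FALSE
  )

  region_latent <- rbind(enh_latent, prom_latent)
  probe_sigma <- 0.15                      # latent-scale probe-to-probe noise
  reg_idx <- rep(seq_len(nrow(regions)), each = ppr)
  probe_latent <- region_latent[reg_idx, , drop = FALSE] +
    matrix(rnorm(length(reg_idx) * n_s, 0, probe_sigma),
           length(reg_idx), n_s)
  bg_mu <- lat_mu(0.5, sig_prom_stable)
  bg_latent <- matrix(bg_mu + sig_prom_stable * rnorm(n_bg * n_s), n_bg, n_s)
  meth <- stats::plogis(rbind(probe_latent, bg_latent))
  dimnames(meth) <- list(probes$probe_id, samples$sample_id)

  ## ---- expression ---------------------------------------------------------
  slope <- cfg$effect_expr_slope
  baseline <- runif(cfg$n_genes, 7, 10)
  expr <- matrix(rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd_expr),
                 cfg$n_genes, n_s,
                 dimnames = list(genes$gene_id, samples$sample_id))
  expr <- expr + baseline
  if (slope != 0) {
    for (g in erg_genes)
      expr[g, ] <- expr[g, ] + slope * enh_beta[driver_of[g], ]
    for (g in prg_genes)
      expr[g, ] <- expr[g, ] + slope * prom_beta[paste0("prom:", g), ]
  }
  expr[expr < 0] <- 0

  ## ---- survival -----------------------------------------------------------
  lambda0 <- 0.1
  os_time <- rep(NA_real_, n_s)
  os_event <- rep(NA_integer_, n_s)
  tum <- samples$group == "tumor"
  lp <- rep(0, sum(tum))
  if (cfg$n_risk_genes > 0 && any(cfg$hazard_betas != 0)) {
    zt <- t(scale(t(expr[risk_genes, tum, drop = FALSE])))
    lp <- as.vector(t(zt) %*% cfg$hazard_betas)
  }
  t_event <- rexp(sum(tum), rate = lambda0 * exp(lp))
  if (cfg$censor_rate > 0) {
    rate_c <- lambda0 * cfg$censor_rate / (1 - cfg$censor_rate)
    t_cens <- rexp(sum(tum), rate = rate_c)
  } else {
    t_cens <- rep(Inf, sum(tum))
  }
  os_time[tum] <- pmin(t_event, t_cens)
  os_event[tum] <- as.integer(t_event <= t_cens)
  clinical <- data.frame(samples, os_time = os_time, os_event = os_event,
                         stringsAsFactors = FALSE)

  ## ---- interactions -------------------------------------------------------
  link_enh <- match(links$enhancer_id, enh$enhancer_id)
  link_tss <- genes$tss[match(links$gene_id, genes$gene_id)]
  a_enh <- data.frame(chrom = enh$chrom[link_enh],
                      start = enh$start[link_enh] - 200L,
                      end = enh$end[link_enh] + 200L)
  a_prom <- data.frame(chrom = enh$chrom[link_enh],
                       start = link_tss - 800L, end = link_tss + 800L)
  swap <- sample(c(TRUE, FALSE), nrow(links), replace = TRUE)
  inter <- data.frame(
    chrom1 = ifelse(swap, a_prom$chrom, a_enh$chrom),
    start1 = ifelse(swap, a_prom$start, a_enh$start),
    end1 = ifelse(swap, a_prom$end, a_enh$end),
    chrom2 = ifelse(swap, a_enh$chrom, a_prom$chrom),
    start2 = ifelse(swap, a_enh$start, a_prom$start),
    end2 = ifelse(swap, a_enh$end, a_prom$end),
    stringsAsFactors = FALSE
  )
  # decoy promoter-promoter contacts
  n_pp <- max(3L, round(0.15 * nrow(links)))
  pp_i <- sample(cfg$n_genes, n_pp, replace = TRUE)
  pp_j <- vapply(pp_i, function(i) {
    same <- setdiff(which(genes$chrom == genes$chrom[i]), i)
    if (length(same) == 0) i else same[sample.int(length(same), 1)]
  }, integer(1))
  decoy <- data.frame(
    chrom1 = genes$chrom[pp_i], start1 = genes$tss[pp_i] - 800L,
    end1 = genes$tss[pp_i] + 800L,
    chrom2 = genes$chrom[pp_j], start2 = genes$tss[pp_j] - 800L,
    end2 = genes$tss[pp_j] + 800L, stringsAsFactors = FALSE
  )
  inter <- rbind(inter, decoy)
  if (cfg$n_chromosomes >= 2) {   # a couple of inter-chromosomal records
    inter <- rbind(inter, data.frame(
      chrom1 = "chr1", start1 = c(100L, 500L), end1 = c(400L, 900L),
      chrom2 = "chr2", start2 = c(100L, 500L), end2 = c(400L, 900L)
    ))
  }
  inter$name <- sprintf("pet%04d", seq_len(nrow(inter)))
  inter$score <- 2L

  ## ---- gene sets ----------------------------------------------------------
  tgt <- split(links$gene_id, links$enhancer_id)
  multi <- tgt[vapply(tgt, length, integer(1)) >= 2]
  gene_sets <- list()
  for (e in names(multi)) {
    pad <- sample(setdiff(genes$gene_id, multi[[e]]),
                  max(0, 8 - length(multi[[e]])))
    gene_sets[[paste0("COREG_", e)]] <- sort(c(multi[[e]], pad))
  }
  for (d in seq_len(10)) {
    gene_sets[[sprintf("DECOY_%02d", d)]] <- sort(sample(genes$gene_id, 10))
  }

  ## ---- ground truth -------------------------------------------------------
  has_meth_fx <- shift > 0
  has_expr_fx <- slope != 0
  has_surv_fx <- cfg$n_risk_genes > 0 && any(cfg$hazard_betas != 0)
  truth <- list(
    edmr = if (has_meth_fx) data.frame(
      enhancer_id = enh$enhancer_id[active_enh], direction = "hypo",
      stringsAsFactors = FALSE) else
        data.frame(enhancer_id = character(0), direction = character(0)),
    erg_genes = if (has_expr_fx) sort(erg_genes) else character(0),
    prg_genes = if (has_expr_fx) sort(prg_genes) else character(0),
    links = if (has_expr_fx) data.frame(
      enhancer_id = unname(driver_of[erg_genes]), gene_id = erg_genes,
      stringsAsFactors = FALSE, row.names = NULL) else
        data.frame(enhancer_id = character(0), gene_id = character(0)),
    ssedmr = if (has_meth_fx && length(sse_enh) > 0) data.frame(
      enhancer_id = enh$enhancer_id[sse_enh], direction = sse_dir,
      stringsAsFactors = FALSE) else
        data.frame(enhancer_id = character(0), direction = character(0)),
    survival_enhancers = if (has_surv_fx) risk_enh else character(0),
    risk = if (has_surv_fx) data.frame(
      gene_id = risk_genes,
      beta = cfg$hazard_betas,
      stringsAsFactors = FALSE) else
        data.frame(gene_id = character(0), beta = numeric(0))
  )

  structure(list(
    genes = genes,
    peaks = .simulated_peaks(enh, genes, cfg),
    probes = probes,
    meth = meth,
    expr = expr,
    interactions = inter,
    clinical = clinical,
    gene_sets = gene_sets,
    truth = truth,
    config = cfg
  ), class = "study_bundle")
}

# enhancer intervals plus a few TSS-proximal decoy peaks that the enhancer
# filter must remove
.simulated_peaks <- function(enh, genes, cfg) {
  peaks <- data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                      stringsAsFactors = FALSE)
  n_prox <- max(2L, round(0.05 * cfg$n_enhancers))
  gi <- sample(nrow(genes), n_prox)
  prox <- data.frame(chrom = genes$chrom[gi],
                     start = genes$tss[gi] + 1000L,
                     end = genes$tss[gi] + 1800L)
  out <- rbind(peaks, prox)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0("<study_bundle> %d genes, %d enhancer peaks, %d probes, ",
                     "%d samples, %d interactions\n"),
              nrow(x$genes), nrow(x$peaks), nrow(x$probes),
              nrow(x$clinical), nrow(x$interactions)))
  invisible(x)
}

#' Write a study bundle to disk
#'
#' Serializes all parts of the bundle as plain-text files: `genes.tsv`,
#' `peaks.bed` (BED3), `probes.tsv`, `meth.tsv`, `expr.tsv`,
#' `interactions.bedpe`, `clinical.tsv`, `gene_sets.gmt` and `truth.json`.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  utils::write.table(bundle$genes, fp("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(bundle$peaks, fp("peaks.bed"))
  utils::write.table(bundle$probes, fp("probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(round(bundle$meth, 6), fp("meth.tsv"), id_col = "probe_id")
  write_matrix_tsv(round(bundle$expr, 6), fp("expr.tsv"), id_col = "gene_id")
  write_bedpe(bundle$interactions, fp("interactions.bedpe"))
  cl <- bundle$clinical
  cl$os_time <- round(cl$os_time, 6)
  utils::write.table(cl, fp("clinical.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(bundle$gene_sets, fp("gene_sets.gmt"))
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return A `study_bundle` (without the original `config`).
#' @export
read_study_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  structure(list(
    genes = read_genes(fp("genes.tsv")),
    peaks = read_bed(fp("peaks.bed")),
    probes = read_probes(fp("probes.tsv")),
    meth = read_matrix_tsv(fp("meth.tsv")),
    expr = read_matrix_tsv(fp("expr.tsv")),
    interactions = read_bedpe(fp("interactions.bedpe")),
    clinical = read_clinical(fp("clinical.tsv")),
    gene_sets = read_gmt(fp("gene_sets.gmt")),
    truth = truth,
    config = NULL
  ), class = "study_bundle")
}
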
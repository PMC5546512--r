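test_that("log-rank test matches direct risk-set enumeration on small tables", {
  set.seed(19)
  for (rep in 1:20) {
    time <- sample(10, 6, replace = TRUE)
    event <- sample(0:1, 6, replace = TRUE)
    group <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    got <- logrank_test(time, event, group)
    want <- oracle_logrank(time, event, group)
    expect_equal(got$chisq, want$chisq, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # invariant to patient ordering
    o <- sample(6)
    got2 <- logrank_test(time[o], event[o], group[o])
    expect_equal(got2$chisq, got$chisq, tolerance = 1e-10)
  }
  # event-free data: statistic 0, p 1
  expect_equal(logrank_test(1:6, rep(0, 6), rep(c("a", "b"), 3))$p, 1)
})

test_that("km scan splits at the median with ties to the low group", {
  meth <- rbind(e1 = c(0.1, 0.2, 0.3, 0.3, 0.8, 0.9),
                e2 = rep(0.5, 6))
  colnames(meth) <- paste0("p", 1:6)
  cl <- data.frame(sample_id = paste0("p", 1:6), group = "tumor",
                   subtype = "basal", os_time = c(5, 6, 7, 1, 2, 3),
                   os_event = 1)
  scan <- km_scan(meth, cl, min_patients = 6)
  expect_equal(scan$enhancer_id, "e1")
  expect_equal(scan$n_low, 4)   # median .3; ties at the median go low
  expect_equal(scan$n_high, 2)
  expect_equal(attr(scan, "skipped"), "e2")  # degenerate split skipped
})

test_that("perturbation null preserves the survival-time multiset and calibrates", {
  an <- planted_analysis()
  b <- an$bundle
  scan <- km_scan(an$enh_track, b$clinical)
  observed <- sum(scan$significant)
  null1 <- sample_perturbation_null(an$enh_track, b$clinical,
                                    observed = observed, replicates = 10,
                                    seed = 11)
  null2 <- sample_perturbation_null(an$enh_track, b$clinical,
                                    observed = observed, replicates = 10,
                                    seed = 11)
  expect_identical(null1$counts, null2$counts)
  expect_equal(null1$empirical_p,
               (1 + sum(null1$counts >= observed)) / 11)
  expect_gt(null1$empirical_p, 0)  # add-one correction keeps p positive
})

test_that("random fragments extend probes by 500 bp on each side", {
  probes <- data.frame(probe_id = paste0("cg", 1:3), chrom = "chr1",
                       pos = c(10000, 20000, 30000))
  beta <- matrix(runif(3 * 12), 3, 12,
                 dimnames = list(probes$probe_id, paste0("s", 1:12)))
  cl <- data.frame(sample_id = paste0("s", 1:12), group = "tumor",
                   subtype = NA, os_time = rexp(12) + 0.1,
                   os_event = rep(1, 12))
  null <- random_region_null(probes, beta, cl, observed = 0, n_regions = 3,
                             replicates = 2, seed = 2)
  expect_length(null$counts, 2)
  # fragment arithmetic: [pos - 500, pos + 501), length 1001
  frag_start <- 10000 - 500; frag_end <- 10000 + 501
  expect_equal(frag_end - frag_start, 1001)
})

test_that("univariate Cox recovers a single planted log-hazard", {
  b <- surv_single_bundle()
  fit <- cox_select_risk_genes(b$expr[b$truth$risk$gene_id, , drop = FALSE],
                               b$clinical)
  expect_true(fit$table$converged)
  expect_lt(abs(fit$table$beta - 0.7), 0.25)
  expect_true(fit$table$gene_id %in% fit$selected)
})

test_that("pure-noise genes are almost never selected at FDR 0.05", {
  set.seed(66)
  n <- 150
  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:n)))
  cl <- data.frame(sample_id = paste0("s", 1:n), group = "tumor",
                   subtype = NA, os_time = rexp(n, 0.1),
                   os_event = rbinom(n, 1, 0.7))
  fit <- cox_select_risk_genes(expr, cl)
  expect_lte(length(fit$selected), 1)
  # BH monotonicity: adding a high-p gene never removes a selected gene
  expr2 <- rbind(expr, null_gene = rnorm(n))
  fit2 <- cox_select_risk_genes(expr2, cl)
  expect_true(all(fit$selected %in% fit2$selected))
})

test_that("risk score is linear, order-invariant, and degenerates cleanly", {
  b <- surv_single_bundle()
  fit <- cox_select_risk_genes(b$expr[b$truth$risk$gene_id, , drop = FALSE],
                               b$clinical)
  rs <- risk_score(fit, b$expr, b$clinical)
  # single gene with beta: score equals beta * standardized expression
  ids <- names(rs$scores)
  g <- fit$table$gene_id
  z <- (b$expr[g, ids] - fit$center[g]) / fit$scale[g]
  expect_equal(unname(rs$scores), unname(fit$table$beta * z))
  # all-zero betas give a single group and a degenerate-split signal
  fit0 <- fit
  fit0$table$beta <- 0
  rs0 <- risk_score(fit0, b$expr, b$clinical)
  expect_true(rs0$degenerate)
  expect_true(all(rs0$scores == 0))
})

test_that("combination scan enumerates all subsets and matches single genes", {
  b <- surv_combo_bundle()
  model <- cox_select_risk_genes(b$expr[b$truth$risk$gene_id, , drop = FALSE],
                                 b$clinical)
  expect_gte(length(model$selected), 2)
  combos <- combination_scan(model, b$expr, b$clinical)
  k <- length(model$selected)
  expect_equal(nrow(combos$table), 2^k - 1)
  singles <- combos$table[combos$table$size == 1, ]
  for (i in seq_len(nrow(singles))) {
    rs <- risk_score(model, b$expr, b$clinical, genes = singles$subset[i])
    expect_equal(singles$p[i], rs$p)
  }
  # score additivity over disjoint gene sets
  gs <- model$selected
  rs_all <- risk_score(model, b$expr, b$clinical, genes = gs)
  rs_a <- risk_score(model, b$expr, b$clinical, genes = gs[1])
  rs_b <- risk_score(model, b$expr, b$clinical, genes = gs[-1])
  expect_equal(rs_all$scores, rs_a$scores + rs_b$scores)
  # enumeration guard
  model_big <- model
  model_big$selected <- sprintf("g%02d", 1:25)
  expect_error(combination_scan(model_big, b$expr, b$clinical),
               "refusing exhaustive")
})
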
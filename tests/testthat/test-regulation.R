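test_that("spearman correlation is invariant under monotone transforms", {
  x <- c(0.1, 0.5, 0.9, 1.4, 2.0, 3.3, 4.1, 5.0, 6.2, 7.7)
  r1 <- spearman_cor(x, exp(x))
  expect_equal(r1$rho, 1)
  r2 <- spearman_cor(x, rev(exp(x)))
  expect_equal(r2$rho, -1)
  set.seed(3)
  y <- rnorm(12)
  expect_equal(spearman_cor(x[1:12 %% 12 + 1], y)$rho,
               spearman_cor(x[1:12 %% 12 + 1], y^3 + 5 * y)$rho)
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "constant")
})

test_that("small-sample p equals full permutation enumeration", {
  set.seed(13)
  for (rep in 1:6) {
    x <- rnorm(7); y <- rnorm(7)
    got <- spearman_cor(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho)
    expect_equal(got$p, want$p)   # over all 5040 permutations
    expect_equal(got$method, "exact_permutation")
  }
  # ties handled through average ranks in both routes
  x <- c(1, 2, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 4, 3, 6, 5)
  expect_equal(spearman_cor(x, y)$p, oracle_spearman(x, y)$p)
})

test_that("dominance follows the correlation-ratio rule", {
  calls <- data.frame(
    rho_enh = c(-0.6, -0.3, -0.1, 0), p_enh = c(0.001, 0.2, 0.3, 0.9),
    rho_prom = c(-0.2, -0.3, -0.5, 0.4), p_prom = c(0.5, 0.2, 0.001, 0.5))
  d <- dominance_ratio(calls)
  expect_equal(d$ratio, c(3, 1, 0.2, 0))
  expect_equal(d$dominant, c("enhancer", "neither", "promoter", "neither"))
  # zero promoter correlation: infinite ratio, enhancer iff significant
  calls2 <- data.frame(rho_enh = c(-0.5, -0.5), p_enh = c(0.01, 0.5),
                       rho_prom = c(0, 0), p_prom = c(0.5, 0.5))
  d2 <- dominance_ratio(calls2)
  expect_true(all(is.infinite(d2$ratio)))
  expect_equal(d2$dominant, c("enhancer", "neither"))
  # swapping enhancer and promoter inverts the ratio and the label
  swapped <- data.frame(rho_enh = calls$rho_prom, p_enh = calls$p_prom,
                        rho_prom = calls$rho_enh, p_prom = calls$p_enh)
  dsw <- dominance_ratio(swapped)
  expect_equal(dsw$ratio, 1 / d$ratio)
  swap_lab <- c(enhancer = "promoter", promoter = "enhancer",
                neither = "neither")
  expect_equal(unname(swap_lab[d$dominant]), dsw$dominant)
})

test_that("gene classification applies the any-link rule", {
  calls <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    p_enh = c(0.5, 0.01, 0.5, 0.01),
    p_prom = c(0.5, 0.5, 0.6, 0.02))
  lab <- classify_regulated_genes(calls, use_adjusted = FALSE)
  expect_equal(setNames(lab$label, lab$gene_id),
               c(g1 = "eRG", g2 = "neither", g3 = "both"))
})

test_that("planted regulatory structure is recovered from correlation calls", {
  an <- planted_analysis()
  b <- an$bundle
  calls <- dominance_ratio(an$calls)
  labels <- classify_regulated_genes(calls)
  called_erg <- labels$gene_id[labels$label %in% c("eRG", "both")]
  sens <- mean(b$truth$erg_genes %in% called_erg)
  expect_gte(sens, 0.85)
  # enhancer-driven genes are predominantly enhancer-dominant
  driven <- calls[paste(calls$enhancer_id, calls$gene_id) %in%
                    paste(b$truth$links$enhancer_id, b$truth$links$gene_id), ]
  expect_gte(mean(driven$dominant == "enhancer"), 0.85)
  # a constant-expression gene is skipped with a reason
  expr2 <- b$expr
  expr2[an$pairs$gene_id[1], ] <- 1
  calls2 <- correlate_pairs(an$pairs[1, , drop = FALSE], an$enh_track,
                            an$prom_track, expr2, samples = an$tumor)
  expect_equal(nrow(calls2), 0)
  expect_equal(attr(calls2, "skipped")[[1]]$reason, "constant_input")
})

test_that("random-target null is centred at zero and reproducible", {
  an <- planted_analysis()
  b <- an$bundle
  null1 <- random_target_null(an$enh_track$values[1:10, ], b$expr,
                              n_draws = 20, samples = an$tumor, seed = 5)
  null2 <- random_target_null(an$enh_track$values[1:10, ], b$expr,
                              n_draws = 20, samples = an$tumor, seed = 5)
  expect_identical(null1$draws, null2$draws)
  expect_lt(abs(null1$mean), 0.1)
  # real planted pairs dominate the null distribution
  real <- abs(an$calls$rho_enh[paste(an$calls$enhancer_id,
                                     an$calls$gene_id) %in%
              paste(b$truth$links$enhancer_id, b$truth$links$gene_id)])
  expect_lt(wilcox.test(real, abs(null1$rho),
                        alternative = "greater")$p.value, 0.01)
})

test_that("relative weights decompose R-squared", {
  set.seed(21)
  n <- 200
  # orthogonal predictors: weights equal squared simple correlations
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- residuals(lm(x2 ~ x1))          # exactly uncorrelated in-sample
  y <- 0.8 * x1 - 0.4 * x2 + rnorm(n)
  rw <- relative_weights(y, cbind(a = x1, b = x2))
  expect_equal(unname(rw$weights),
               c(cor(x1, y)^2, cor(x2, y)^2), tolerance = 1e-6)
  expect_equal(sum(rw$weights), summary(lm(scale(y) ~ scale(x1) +
                                             scale(x2)))$r.squared,
               tolerance = 1e-6)
  # single predictor: weight equals R-squared
  rw1 <- relative_weights(y, cbind(a = x1))
  expect_equal(unname(rw1$weights), cor(x1, y)^2, tolerance = 1e-10)
  # correlated predictors match the closed-form two-predictor decomposition
  z1 <- rnorm(n); z2 <- 0.6 * z1 + 0.8 * rnorm(n)
  yy <- z1 + 0.5 * z2 + rnorm(n)
  rw2 <- relative_weights(yy, cbind(p = z1, q = z2))
  expect_equal(unname(rw2$weights), oracle_relweights2(yy, z1, z2),
               tolerance = 1e-10)
  expect_error(relative_weights(y, cbind(x1, x1)), "collinear")
})
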
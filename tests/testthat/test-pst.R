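test_that("variance components handle degenerate inputs exactly", {
  meta <- balanced_meta(3)
  # identical constant values in both species: no variance anywhere
  # (the REML fit degenerates and falls back to the ANOVA estimator)
  est <- suppressWarnings(estimate_variance_components(rep(1, 6), meta))
  expect_equal(est$sigma2_b, 0)
  expect_equal(est$sigma2_w, 0)
  # perfect species separation, no noise
  est2 <- estimate_variance_components(rep(c(0, 2), each = 3), meta,
                                       sex_adjust = "none")
  expect_lt(est2$sigma2_w, 1e-6)
  expect_gt(est2$sigma2_b, 0)
  # one species absent
  meta_one <- meta; meta_one$species <- "A"
  expect_error(estimate_variance_components(rnorm(6), meta_one),
               "two species")
})

test_that("REML equals the hand-computed ANOVA oracle on balanced designs", {
  withr::local_seed(101)
  meta <- balanced_meta(10)
  for (i in 1:50) {
    y <- rep(rnorm(2, 0, 1), each = 10) + rnorm(20)
    reml <- estimate_variance_components(y, meta, engine = "reml",
                                         sex_adjust = "none")
    # independent oracle: expected mean squares, by hand
    ga <- y[1:10]; gb <- y[11:20]
    msb <- 10 * (mean(ga) - mean(y))^2 + 10 * (mean(gb) - mean(y))^2
    msw <- (sum((ga - mean(ga))^2) + sum((gb - mean(gb))^2)) / 18
    if (msb > msw) {
      expect_equal(reml$sigma2_b, (msb - msw) / 10, tolerance = 1e-9)
      expect_equal(reml$sigma2_w, msw, tolerance = 1e-9)
    } else {
      expect_equal(reml$sigma2_b, 0)
      expect_equal(reml$sigma2_w, sum((y - mean(y))^2) / 19,
                   tolerance = 1e-9)
    }
  }
})

test_that("REML agrees with lme4 on unbalanced, sex-adjusted designs", {
  skip_if_not_installed("lme4")
  withr::local_seed(55)
  for (i in 1:8) {
    n_a <- 8; n_b <- 12
    meta <- tibble::tibble(
      sample_id = paste0("s", 1:(n_a + n_b)),
      individual_id = paste0("i", 1:(n_a + n_b)),
      species = rep(c("A", "B"), c(n_a, n_b)),
      organ = "liver",
      sex = sample(c("F", "M"), n_a + n_b, replace = TRUE)
    )
    y <- rep(rnorm(2, 0, 1), c(n_a, n_b)) +
      0.5 * (meta$sex == "M") + rnorm(n_a + n_b)
    mine <- estimate_variance_components(y, meta, engine = "reml")
    fit <- lme4::lmer(
      y ~ sex + (1 | species), data = cbind(as.data.frame(meta), y = y),
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    expect_equal(mine$sigma2_b, vc$vcov[1], tolerance = 1e-4)
    expect_equal(mine$sigma2_w, vc$vcov[2], tolerance = 1e-4)
  }
})

test_that("P_ST statistic follows its closed form and stays in [0, 1]", {
  expect_equal(pst_statistic(0, 1), 0)
  expect_equal(pst_statistic(1, 1), 1 / 3)
  expect_equal(pst_statistic(2, 1), 0.5)
  expect_equal(pst_statistic(1, 1, scaling_ratio = 2), 0.5)
  expect_warning(out <- pst_statistic(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(pst_statistic(-1, 1), "non-negative")

  # monotonicity: increasing in sigma2_b, decreasing in sigma2_w
  b_grid <- pst_statistic(seq(0, 5, by = 0.25), 1)
  expect_true(all(diff(b_grid) > 0))
  w_grid <- pst_statistic(1, seq(0.1, 5, by = 0.25))
  expect_true(all(diff(w_grid) < 0))
  expect_true(all(b_grid >= 0 & b_grid <= 1))
})

test_that("resampling p-value correction follows (b+1)/(m+1)", {
  expect_equal(phipson_smyth_p(0, 1000), 1 / 1001)
  expect_equal(phipson_smyth_p(49, 999), 0.05)
  expect_equal(phipson_smyth_p(1000, 1000), 1)
  expect_error(phipson_smyth_p(5, 4), "\\[0, m\\]")
  expect_error(phipson_smyth_p(-1, 10), "\\[0, m\\]")
  # never exactly zero
  expect_gt(phipson_smyth_p(0, 1e6), 0)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0, 0.5)), "\\(0, 1\\]")
  # monotone in the raw p-values
  withr::local_seed(2)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("permutation null is deterministic and exact for P_ST = 0", {
  withr::local_seed(9)
  meta <- balanced_meta(5)
  y <- rnorm(10)
  cfg <- pst_config(n_permutations = 50, seed = 123)
  a <- suppressWarnings(permutation_null(y, meta, cfg))
  b <- suppressWarnings(permutation_null(y, meta, cfg))
  expect_identical(a$b_exceed, b$b_exceed)

  # observed P_ST = 0: every null value reaches it
  y0 <- rep(c(1, 2, 3, 4, 5), 2)   # species means identical
  r <- suppressWarnings(permutation_null(y0, meta, cfg))
  expect_equal(r$observed, 0)
  expect_equal(r$b_exceed, r$m)
})

test_that("few distinct assignments are enumerated exhaustively", {
  meta <- balanced_meta(3)
  y <- rnorm(6)
  expect_warning(
    r <- permutation_null(y, meta, pst_config(n_permutations = 1000)),
    "distinct"
  )
  expect_equal(r$m, choose(6, 3))
})

test_that("the scan is invariant under species relabelling", {
  sim <- simulate_expression_study(
    sim_config(n_genes = 120, organs = "liver"), seed = 19)
  z <- zfpkm_transform(sim$study, min_expressed_genes = 30)
  cfg <- pst_config(n_permutations = 60, seed = 4)
  scan1 <- run_pst_scan(z, "liver", cfg)

  z2 <- z
  z2$samples$species <- ifelse(z$samples$species == "A", "B", "A")
  scan2 <- run_pst_scan(z2, "liver", cfg)
  expect_equal(scan2$pst, scan1$pst)
  expect_equal(scan2$sigma2_b, scan1$sigma2_b)
  expect_equal(scan2$b_exceed, scan1$b_exceed)
})

test_that("scan results do not depend on gene processing order", {
  sim <- simulate_expression_study(
    sim_config(n_genes = 100, organs = "liver"), seed = 23)
  z <- zfpkm_transform(sim$study, min_expressed_genes = 30)
  genes <- pst_gene_filter(z, "liver")
  cfg <- pst_config(n_permutations = 40, seed = 6)
  full <- run_pst_scan(z, "liver", cfg, genes = genes)
  sub <- run_pst_scan(z, "liver", cfg, genes = genes[c(3, 1)])
  expect_equal(sub$b_exceed,
               full$b_exceed[match(genes[c(3, 1)], full$gene_id)])
})

test_that("REML and ANOVA engines agree on the balanced scan", {
  sim <- simulate_expression_study(
    sim_config(n_genes = 80, organs = c("brain", "liver")), seed = 29)
  z <- zfpkm_transform(sim$study, min_expressed_genes = 30)
  genes <- head(pst_gene_filter(z, "brain"), 15)
  a <- run_pst_scan(z, "brain", pst_config(n_permutations = 30, seed = 2,
                                           engine = "anova"), genes = genes)
  r <- run_pst_scan(z, "brain", pst_config(n_permutations = 30, seed = 2,
                                           engine = "reml"), genes = genes)
  expect_equal(a$pst, r$pst, tolerance = 1e-8)
})

test_that("directional genes separate from stabilizing genes in P_ST", {
  cfg_sim <- sim_config(
    n_genes = 600, organs = "kidney",
    regime_proportions = c(stabilizing = 0.7, neutral = 0,
                           directional = 0.3, balancing = 0),
    sigma_b = c(stabilizing = 0, neutral = 0, directional = 0,
                balancing = 0),
    species_shift = 1.2, n_unique_a = 0, n_unique_b = 0
  )
  sim <- simulate_expression_study(cfg_sim, seed = 37)
  z <- zfpkm_transform(sim$study)
  scan <- run_pst_scan(z, "kidney", pst_config(n_permutations = 100,
                                               seed = 37))
  tr <- sim$truth[match(scan$gene_id, sim$truth$gene_id), ]
  expect_gt(median(scan$pst[tr$regime == "directional"]),
            median(scan$pst[tr$regime == "stabilizing"]))
  expect_true(all(scan$p_raw >= 1 / (scan$m + 1)))
  expect_true(all(scan$p_adj >= scan$p_raw))
})
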
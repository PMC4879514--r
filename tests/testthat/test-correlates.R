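test_that("substitution-rate filter applies both exclusion rules", {
  cov <- tibble::tibble(
    gene_id = c("keep", "ds_high", "ratio_high", "ds_zero", "missing"),
    dn = c(0.1, 0.1, 3.5, 0.2, NA),
    ds = c(1.0, 2.5, 1.0, 0.0, 1.0)
  )
  kept <- dnds_filter(cov)
  expect_setequal(kept, c("keep", "ds_zero"))
})

test_that("reported correlations reproduce rank-then-Pearson to 1e-12", {
  withr::local_seed(47)
  n <- 200
  scan <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), organ = "kidney",
    sigma2_b = rexp(n), sigma2_w = rexp(n),
    pst = runif(n), p_raw = runif(n), p_adj = runif(n), de = FALSE
  )
  class(scan) <- c("pst_scan", class(scan))
  cov <- tibble::tibble(gene_id = scan$gene_id,
                        interactions_metabolic = rpois(n, 8))
  grid <- spearman_grid(scan, cov, targets = "interactions_metabolic")
  for (rs in c("pst", "sigma2_b", "sigma2_w")) {
    brute <- cor(rank(cov$interactions_metabolic), rank(scan[[rs]]))
    expect_equal(grid$rho[grid$response == rs], brute, tolerance = 1e-12)
  }
  expect_true(all(grid$n == n))
})

test_that("planted pleiotropy-variance correlation shows the sign pattern", {
  cfg <- sim_config(n_genes = 5000, organs = "kidney",
                    n_unique_a = 0, n_unique_b = 0)
  sim <- simulate_expression_study(cfg, seed = 51)
  cov <- simulate_covariates(cfg, sim$truth, rho_interactivity = -0.3,
                             seed = 51)
  z <- zfpkm_transform(sim$study)
  scan <- run_pst_scan(z, "kidney", pst_config(n_permutations = 30,
                                               seed = 51))
  grid <- spearman_grid(scan, cov,
                        targets = c("interactions_metabolic",
                                    "interactions_complex"))
  sw <- grid[grid$response == "sigma2_w", ]
  expect_true(all(sw$rho < -0.1))
  # the induced P_ST correlation is non-negative (less within-variance
  # means proportionally more between-variance)
  ps <- grid[grid$response == "pst", ]
  expect_true(all(ps$rho > -0.05))
})

test_that("null covariates give near-zero correlations and valid BH", {
  cfg <- sim_config(n_genes = 4000, organs = "kidney",
                    n_unique_a = 0, n_unique_b = 0)
  sim <- simulate_expression_study(cfg, seed = 53)
  cov <- simulate_covariates(cfg, sim$truth, rho_interactivity = 0,
                             rho_fst = 0, seed = 53)
  z <- zfpkm_transform(sim$study)
  scan <- run_pst_scan(z, "kidney", pst_config(n_permutations = 30,
                                               seed = 53))
  grid <- spearman_grid(scan, cov, targets = c("fst_upstream", "dnds"))
  expect_true(all(abs(grid$rho) < 0.08, na.rm = TRUE))
  ok <- !is.na(grid$p)
  expect_true(all(grid$p_adj[ok] >= grid$p[ok]))
})

test_that("duplicate gene rows in a scan table are rejected", {
  scan <- tibble::tibble(
    gene_id = c("g1", "g1"), organ = "kidney", sigma2_b = 1, sigma2_w = 1,
    pst = 0.3, p_raw = 0.5, p_adj = 0.5, de = FALSE
  )
  class(scan) <- c("pst_scan", class(scan))
  cov <- tibble::tibble(gene_id = "g1", interactions_metabolic = 3)
  expect_error(spearman_grid(scan, cov, targets = "interactions_metabolic"),
               "Duplicated")
})

test_that("high-F_ST contrasts behave under null and boundary cutoffs", {
  withr::local_seed(57)
  n <- 2000
  scan <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n), organ = "kidney",
    sigma2_b = rexp(n), sigma2_w = rexp(n), pst = runif(n),
    p_raw = runif(n), p_adj = runif(n), de = FALSE
  )
  class(scan) <- c("pst_scan", class(scan))
  cov <- tibble::tibble(gene_id = scan$gene_id, fst_upstream = runif(n))
  rep <- high_fst_contrast(scan, cov)
  mwu <- rep[rep$test == "mann_whitney", ]
  expect_equal(nrow(mwu), 6)
  expect_true(all(mwu$p > 0.001))      # no signal planted
  enr <- rep[rep$test == "chisq_enrichment", ]
  expect_true(abs(median(enr$odds_ratio) - 1) < 0.4)

  # cutoff above the maximum F_ST: stratum empty, skipped with warning
  expect_warning(
    rep2 <- high_fst_contrast(scan, cov, fst_cutoffs = c(0.5, 1.5)),
    "Empty"
  )
  expect_true(all(rep2$fst_cutoff <= 0.5))

  # planted association is detected
  cov3 <- cov
  cov3$fst_upstream <- pmin(1, pmax(0, scan$pst * 0.6 + runif(n, 0, 0.3)))
  rep3 <- high_fst_contrast(scan, cov3, fst_cutoffs = 0.5)
  expect_lt(rep3$p[rep3$test == "mann_whitney"], 1e-6)
})

test_that("positional enrichment detects planted sex-linked DE excess", {
  withr::local_seed(59)
  n <- 3000
  chr <- sample(c(paste0("chr", 1:20), "chrZ"), n, replace = TRUE)
  scan <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n), organ = "kidney",
    sigma2_b = 1, sigma2_w = 1, pst = 0.5, p_raw = 0.5, p_adj = 0.5,
    de = runif(n) < 0.05
  )
  class(scan) <- c("pst_scan", class(scan))
  cov <- tibble::tibble(gene_id = scan$gene_id, chromosome = chr,
                        start = 1L, end = sample.int(1e6, n))
  # null: uniform DE
  res <- positional_enrichment(scan, cov)
  expect_gt(res$sex_chromosome_test$p, 0.01)
  # planted: DE only on chrZ
  scan2 <- scan
  scan2$de <- chr == "chrZ" & runif(n) < 0.5
  res2 <- positional_enrichment(scan2, cov)
  expect_lt(res2$sex_chromosome_test$p, 1e-10)
  expect_gt(res2$sex_chromosome_test$prop_de_sex_chromosome,
            res2$sex_chromosome_test$prop_de_autosomes)

  # exactly proportional 2x2 table: chi-square 0
  scan3 <- scan[1:1100, ]
  cov3 <- cov[1:1100, ]
  cov3$chromosome <- rep(c("chrZ", "chr1"), c(100, 1000))
  scan3$de <- c(rep(c(TRUE, FALSE), c(10, 90)),
                rep(c(TRUE, FALSE), c(100, 900)))
  res3 <- positional_enrichment(scan3, cov3)
  expect_equal(res3$sex_chromosome_test$chisq, 0, tolerance = 1e-12)

  cov_one <- cov; cov_one$chromosome <- "chr1"
  expect_error(positional_enrichment(scan, cov_one), "one chromosome")
})
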
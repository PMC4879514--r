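test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 60)
  a <- simulate_expression_study(cfg, seed = 7)
  b <- simulate_expression_study(cfg, seed = 7)
  expect_identical(a$study$fpkm, b$study$fpkm)
  expect_identical(a$truth, b$truth)
  c <- simulate_expression_study(cfg, seed = 8)
  expect_false(identical(a$study$fpkm, c$study$fpkm))
})

test_that("degenerate noise gives identical individuals per gene and organ", {
  cfg <- sim_config(
    n_genes = 30, n_individuals_per_species = 4,
    organs = c("brain", "liver"),
    regime_proportions = c(stabilizing = 1, neutral = 0, directional = 0,
                           balancing = 0),
    sigma_w = c(stabilizing = 0, neutral = 1, directional = 0.4,
                balancing = 1.2),
    sigma_b = c(stabilizing = 0, neutral = 1, directional = 1.2,
                balancing = 0.1),
    sigma_jitter_sdlog = 0, n_unique_a = 0, n_unique_b = 0
  )
  sim <- simulate_expression_study(cfg, seed = 3)
  meta <- sim$study$samples
  for (o in c("brain", "liver")) {
    for (s in c("A", "B")) {
      cols <- meta$organ == o & meta$species == s
      spread <- apply(sim$study$fpkm[, cols], 1, function(x) diff(range(x)))
      expect_equal(max(spread), 0)
    }
  }
})

test_that("planted directional genes carry the configured species shift", {
  cfg <- sim_config(
    n_genes = 1000, organs = "kidney",
    regime_proportions = c(stabilizing = 0.9, neutral = 0, directional = 0.1,
                           balancing = 0),
    sigma_b = c(stabilizing = 0, neutral = 1, directional = 0, balancing = 0),
    species_shift = 2, n_unique_a = 0, n_unique_b = 0
  )
  sim <- simulate_expression_study(cfg, seed = 11)
  n_dir <- sum(sim$truth$regime == "directional")
  expect_gt(n_dir, 70)
  expect_lt(n_dir, 130)

  meta <- sim$study$samples
  clean <- rowSums(sim$study$fpkm == 0) == 0   # no detection-floor zeros
  log2m <- log2(sim$study$fpkm[clean, ])
  shift_hat <- rowMeans(log2m[, meta$species == "B"]) -
    rowMeans(log2m[, meta$species == "A"])
  tr <- sim$truth[clean, ]
  dir <- tr$regime == "directional"
  expect_gt(sum(dir), 50)
  # per-gene empirical shift matches the signed planted delta within ~3 SE
  se <- sqrt(2 * tr$sigma2_w_true[dir] / 10)
  expect_gt(mean(abs(shift_hat[dir] - tr$species_shift[dir]) < 3.5 * se),
            0.99)
  expect_equal(sort(unique(abs(tr$species_shift[dir]))), 2)
})

test_that("regime variance structure is recovered by method of moments", {
  cfg <- sim_config(
    n_genes = 1500, organs = "kidney", n_individuals_per_species = 10,
    regime_proportions = c(stabilizing = 0.25, neutral = 0.25,
                           directional = 0.25, balancing = 0.25),
    sigma_jitter_sdlog = 0, n_unique_a = 0, n_unique_b = 0
  )
  sim <- simulate_expression_study(cfg, seed = 5)
  meta <- sim$study$samples
  clean <- rowSums(sim$study$fpkm == 0) == 0   # no detection-floor zeros
  log2m <- log2(sim$study$fpkm[clean, ])
  tr <- sim$truth[clean, ]
  for (rg in c("stabilizing", "neutral", "balancing")) {
    rows <- tr$regime == rg
    within_var <- (apply(log2m[rows, meta$species == "A"], 1, var) +
                     apply(log2m[rows, meta$species == "B"], 1, var)) / 2
    truth_w <- tr$sigma2_w_true[rows][1]
    expect_lt(abs(mean(within_var) - truth_w), 0.15 * max(truth_w, 0.3))
  }
})

test_that("planted unique genes are exactly zero in the other species", {
  cfg <- sim_config(n_genes = 200, n_unique_a = 4, n_unique_b = 6)
  sim <- simulate_expression_study(cfg, seed = 9)
  meta <- sim$study$samples
  for (i in which(sim$truth$unique_to != "none")) {
    other <- setdiff(c("A", "B"), sim$truth$unique_to[i])
    expect_true(all(sim$study$fpkm[i, meta$species == other] == 0))
    expect_gt(max(sim$study$fpkm[i, meta$species != other]), 0)
  }
})

test_that("gonads are sampled single-sex at half the sample size", {
  sim <- simulate_expression_study(sim_config(n_genes = 30), seed = 1)
  meta <- sim$study$samples
  expect_setequal(unique(meta$sex[meta$organ == "testis"]), "M")
  expect_setequal(unique(meta$sex[meta$organ == "ovary"]), "F")
  expect_equal(sum(meta$organ == "testis" & meta$species == "A"), 5)
  expect_equal(sum(meta$organ == "brain" & meta$species == "A"), 10)
})

test_that("generator rejects impossible configurations", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(organs = character(0)), "empty")
  expect_error(sim_config(n_individuals_per_species = 0), "individual")
  expect_error(sim_config(regime_proportions = c(stabilizing = 0.5,
                                                 neutral = 0.5,
                                                 directional = 0.5,
                                                 balancing = 0)), "sum")
  expect_error(sim_config(n_genes = 5, n_unique_a = 4, n_unique_b = 4),
               "unique")
})

test_that("covariate generator plants the requested rank correlation", {
  cfg <- sim_config(n_genes = 5000)
  sim <- simulate_expression_study(cfg, seed = 13)
  # null case: no planted correlation
  cov0 <- simulate_covariates(cfg, sim$truth, rho_interactivity = 0,
                              seed = 13)
  ok <- !is.na(cov0$interactions_metabolic)
  rho0 <- cor(cov0$interactions_metabolic[ok],
              sim$truth$sigma2_w_true[ok], method = "spearman")
  expect_lt(abs(rho0), 0.05)
  # planted case
  cov <- simulate_covariates(cfg, sim$truth, rho_interactivity = -0.3,
                             seed = 13)
  for (col in c("interactions_metabolic", "interactions_complex",
                "interactions_signalling")) {
    ok <- !is.na(cov[[col]])
    rho <- cor(cov[[col]][ok], sim$truth$sigma2_w_true[ok],
               method = "spearman")
    expect_gt(rho, -0.38)
    expect_lt(rho, -0.22)
  }
  # degenerate anchor: constant truth still yields covariates
  truth2 <- sim$truth
  truth2$sigma2_w_true <- 1
  cov2 <- simulate_covariates(cfg, truth2, rho_interactivity = -0.3,
                              seed = 1)
  expect_equal(nrow(cov2), 5000)
})

test_that("simulated coverage has the planted deletion and ~15x depth", {
  cfg <- sim_config()
  cov <- simulate_coverage(cfg, seed = 21)
  tr <- attr(cov, "truth")
  expect_equal(tr$deletion_length, 20000L)
  in_del <- cov$windows$start >= tr$deletion_start &
    cov$windows$end <= tr$deletion_end
  del_rows <- cov$individual_species == tr$species_deleted
  expect_true(all(cov$depth[del_rows, in_del] == 0))
  expect_true(all(cov$depth[!del_rows, in_del] > 0))
  out_del <- !in_del & cov$windows$start < 80000  # outside planted gap too
  expect_lt(abs(mean(cov$depth[!del_rows, out_del]) - 15), 1)
  expect_error(simulate_coverage(cfg, deletion_start = -5), "inside")
  expect_error(simulate_coverage(cfg, deletion_end = 2e5), "inside")
})
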
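#' Configure the synthetic expression study generator
#'
#' The generator emulates a two-species, multi-organ population RNA-seq
#' design: two closely related species, nine organs (gonads single-sex),
#' five to ten individuals per species, and four expression-evolution
#' regimes in the within/between variance framework of Whitehead & Crawford:
#' stabilizing (both variances small), neutral (both large), directional
#' (between large, within small, plus a fixed species shift) and balancing
#' (within large, between small).
#'
#' Expression is simulated on the log2 scale as
#' `mu_g + a_go + delta_g * I(species B) + beta_sex,g * I(male) + b_gs + eps`,
#' with `b_gs ~ N(0, sigma_b^2)` a gene x species effect shared across organs,
#' `eps ~ N(0, sigma_w^2)` per sample, and then exponentiated to FPKM.
#' Per-gene `sigma_w`/`sigma_b` get mild lognormal jitter (sdlog
#' `sigma_jitter_sdlog`) around their regime value so genes are heterogeneous,
#' as in real data. Values below `detection_floor_log2` give FPKM 0.
#'
#' @param n_genes Number of genes.
#' @param n_individuals_per_species Individuals per species (half F, half M).
#'   Gonads are sampled only in the matching sex, so testis/ovary have half
#'   this sample size.
#' @param organs Organ labels; `"testis"`/`"ovary"` are recognized as
#'   single-sex.
#' @param regime_proportions Named proportions over
#'   stabilizing/neutral/directional/balancing; must sum to 1.
#' @param base_log2_mean Length-2 vector (location, scale) of the per-gene
#'   baseline log2 expression.
#' @param organ_effect_sd SD of gene x organ effects (log2 units).
#' @param sigma_w,sigma_b Named per-regime SDs (log2 units) of the
#'   within-species (among-individual) and between-species effects.
#' @param species_shift Fixed species shift delta (log2 units) added to
#'   species B for directional genes.
#' @param sex_effect_sd SD of per-gene additive sex effects; applied to a
#'   fraction `sex_gene_fraction` of genes (0 disables).
#' @param sex_gene_fraction Fraction of genes with a sex effect.
#' @param n_unique_a,n_unique_b Number of genes expressed uniquely in species
#'   A / species B (zero FPKM in the other species, all organs).
#' @param detection_floor_log2 log2-FPKM below which the simulated FPKM is 0.
#' @param sigma_jitter_sdlog Lognormal sdlog of per-gene jitter on the regime
#'   sigmas (0 disables).
#' @param rho_sigma_bw Correlation of the per-gene log-jitters on `sigma_b`
#'   and `sigma_w` (default 0.5): genes that vary more within species also
#'   diverge more between them, the pattern expected under stabilizing
#'   selection and neutral drift.
#' @param species_labels Length-2 character vector of species names.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_individuals_per_species = 10,
                       organs = c("brain", "embryo", "kidney", "liver",
                                  "lung", "muscle", "ovary", "skin",
                                  "testis"),
                       regime_proportions = c(stabilizing = 0.70,
                                              neutral = 0.20,
                                              directional = 0.05,
                                              balancing = 0.05),
                       base_log2_mean = c(location = 4, scale = 2),
                       organ_effect_sd = 2,
                       sigma_w = c(stabilizing = 0.4, neutral = 1.0,
                                   directional = 0.4, balancing = 1.2),
                       sigma_b = c(stabilizing = 0.4, neutral = 1.0,
                                   directional = 1.2, balancing = 0.1),
                       species_shift = 1.2,
                       sex_effect_sd = 0,
                       sex_gene_fraction = 0.1,
                       n_unique_a = 5,
                       n_unique_b = 11,
                       detection_floor_log2 = -4,
                       sigma_jitter_sdlog = 0.25,
                       rho_sigma_bw = 0.5,
                       species_labels = c("A", "B")) {
  regimes <- c("stabilizing", "neutral", "directional", "balancing")
  assert_that(n_genes >= 1, "`n_genes` must be positive.")
  assert_that(n_individuals_per_species >= 1,
              "Need at least one individual per species.")
  assert_that(length(organs) >= 1, "Organ list must not be empty.")
  assert_that(length(species_labels) == 2 &&
                !anyDuplicated(species_labels),
              "Exactly two distinct species labels required.")
  assert_that(setequal(names(regime_proportions), regimes),
              "regime_proportions must be named by the four regimes.")
  assert_that(abs(sum(regime_proportions) - 1) < 1e-8,
              "regime_proportions must sum to 1.")
  assert_that(all(sigma_w >= 0) && all(sigma_b >= 0),
              "Regime sigmas must be non-negative.")
  assert_that(n_unique_a + n_unique_b <= n_genes,
              "More unique genes requested than genes simulated.")
  structure(
    list(n_genes = n_genes,
         n_individuals_per_species = n_individuals_per_species,
         organs = organs,
         regime_proportions = regime_proportions[regimes],
         base_log2_mean = base_log2_mean,
         organ_effect_sd = organ_effect_sd,
         sigma_w = sigma_w[regimes], sigma_b = sigma_b[regimes],
         species_shift = species_shift,
         sex_effect_sd = sex_effect_sd,
         sex_gene_fraction = sex_gene_fraction,
         n_unique_a = n_unique_a, n_unique_b = n_unique_b,
         detection_floor_log2 = detection_floor_log2,
         sigma_jitter_sdlog = sigma_jitter_sdlog,
         rho_sigma_bw = rho_sigma_bw,
         species_labels = species_labels),
    class = "sim_config"
  )
}

sim_sample_sheet <- function(config) {
  sp <- config$species_labels
  n <- config$n_individuals_per_species
  inds <- purrr::map_dfr(sp, function(s) {
    tibble::tibble(
      individual_id = sprintf("%s_ind%02d", s, seq_len(n)),
      species = s,
      sex = rep(c("F", "M"), length.out = n)
    )
  })
  purrr::map_dfr(config$organs, function(o) {
    keep <- switch(o, testis = inds$sex == "M", ovary = inds$sex == "F",
                   rep(TRUE, nrow(inds)))
    out <- inds[keep, , drop = FALSE]
    out$organ <- o
    out$sample_id <- paste(out$individual_id, o, sep = ".")
    out[, c("sample_id", "individual_id", "species", "organ", "sex")]
  })
}

sim_fpkm_matrix <- function(log2_expr, off_species, species_idx, floor_log2) {
  fpkm <- 2^log2_expr
  fpkm[log2_expr < floor_log2] <- 0
  for (s_i in 1:2) {
    off <- off_species == s_i
    if (any(off)) fpkm[off, species_idx == s_i] <- 0
  }
  fpkm
}

# audit one realization's expressed calls against the planted ground truth;
# returns a per-gene log2 lift (0 where the realization is consistent)
sim_presence_repair <- function(zc, sheet, unique_to, off_species,
                                species_idx) {
  G <- nrow(zc$z)
  cutoff <- zc$cutoff
  sigma_bar <- mean(zc$fits$sigma)
  calls <- zc$z >= cutoff
  lift <- numeric(G)
  target <- cutoff + 0.2

  ind_expressing <- function(cols) {
    apply(calls[, cols, drop = FALSE], 1, function(row) {
      length(unique(sheet$individual_id[cols][row]))
    })
  }
  n_ind <- cbind(ind_expressing(species_idx == 1),
                 ind_expressing(species_idx == 2))

  for (s_i in 1:2) {
    other <- 3 - s_i
    other_cols <- species_idx == other
    absent_other <- rowSums(calls[, other_cols, drop = FALSE]) == 0
    spurious <- unique_to == "none" & n_ind[, s_i] >= 5 & absent_other
    if (any(spurious)) {
      zmax <- apply(zc$z[spurious, other_cols, drop = FALSE], 1, max)
      lift[spurious] <- pmax(
        lift[spurious],
        ifelse(is.finite(zmax), (target - zmax) * sigma_bar, 3)
      )
    }
  }
  planted <- which(unique_to != "none")
  for (g in planted) {
    own_cols <- species_idx == (3 - off_species[g])
    zg <- zc$z[g, own_cols]
    per_ind <- tapply(zg, sheet$individual_id[own_cols], max)
    v5 <- sort(per_ind, decreasing = TRUE)[min(5, length(per_ind))]
    if (!is.finite(v5) || v5 < cutoff + 0.1) {
      lift[g] <- max(lift[g],
                     if (is.finite(v5)) (target - v5) * sigma_bar else 3)
    }
  }
  lift
}

#' Simulate an expression study with known ground truth
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `study` (an [expression_study()]) and `truth`, a
#'   tibble with per-gene `gene_id`, `regime`, `species_shift` (log2),
#'   `sigma2_w_true`, `sigma2_b_true`, `sex_effect`, `unique_to`
#'   (`"none"`/`"A"`-label/`"B"`-label) and `in_deletion`.
#' @examples
#' sim <- simulate_expression_study(sim_config(n_genes = 50), seed = 1)
#' sim$study
#' dplyr::count(sim$truth, regime)
#' @export
simulate_expression_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  G <- config$n_genes
  regimes <- names(config$regime_proportions)
  regime <- sample(regimes, G, replace = TRUE,
                   prob = config$regime_proportions)
  # correlated lognormal jitter on the regime sigmas: a shared component
  # makes within-species variance and between-species divergence positively
  # related across genes, as observed under stabilizing selection and drift
  if (config$sigma_jitter_sdlog > 0) {
    rho_j <- config$rho_sigma_bw
    shared <- rnorm(G)
    jit_w <- exp(config$sigma_jitter_sdlog *
                   (sqrt(rho_j) * shared + sqrt(1 - rho_j) * rnorm(G)))
    jit_b <- exp(config$sigma_jitter_sdlog *
                   (sqrt(rho_j) * shared + sqrt(1 - rho_j) * rnorm(G)))
  } else {
    jit_w <- jit_b <- rep(1, G)
  }
  sd_w <- unname(config$sigma_w[regime]) * jit_w
  sd_b <- unname(config$sigma_b[regime]) * jit_b
  # random sign: directional selection pushes different genes in different
  # directions, and a net one-sided shift would be absorbed by the
  # density-peak anchoring of the zFPKM normalization anyway
  delta <- ifelse(regime == "directional",
                  config$species_shift * sample(c(-1, 1), G, replace = TRUE),
                  0)
  mu <- rnorm(G, config$base_log2_mean[["location"]],
              config$base_log2_mean[["scale"]])

  sex_effect <- rep(0, G)
  if (config$sex_effect_sd > 0) {
    hit <- runif(G) < config$sex_gene_fraction
    sex_effect[hit] <- rnorm(sum(hit), 0, config$sex_effect_sd)
  }

  unique_to <- rep("none", G)
  gene_pool <- sample.int(G, config$n_unique_a + config$n_unique_b)
  sp <- config$species_labels
  if (config$n_unique_a > 0) {
    unique_to[gene_pool[seq_len(config$n_unique_a)]] <- sp[1]
  }
  if (config$n_unique_b > 0) {
    unique_to[gene_pool[config$n_unique_a + seq_len(config$n_unique_b)]] <-
      sp[2]
  }

  sheet <- sim_sample_sheet(config)
  S <- nrow(sheet)
  organ_idx <- match(sheet$organ, config$organs)
  species_idx <- match(sheet$species, sp)
  male <- as.numeric(sheet$sex == "M")

  organ_eff <- matrix(rnorm(G * length(config$organs), 0,
                            config$organ_effect_sd),
                      nrow = G)
  species_eff <- matrix(rnorm(G * 2, 0, sd_b), nrow = G)

  # planted unique genes start comfortably expressed in their own species
  mu[unique_to != "none"] <- pmax(mu[unique_to != "none"], 6)

  log2_expr <- mu +
    organ_eff[, organ_idx, drop = FALSE] +
    species_eff[, species_idx, drop = FALSE] +
    outer(delta, as.numeric(species_idx == 2)) +
    outer(sex_effect, male) +
    matrix(rnorm(G * S, 0, sd_w), nrow = G, ncol = S)

  gene_ids <- sprintf("gene%05d", seq_len(G))
  off_species <- rep(0L, G)  # 1 or 2: species where the gene is planted off
  for (s_i in 1:2) {
    off_species[unique_to == sp[3 - s_i]] <- s_i
  }
  fpkm <- sim_fpkm_matrix(log2_expr, off_species, species_idx,
                          config$detection_floor_log2)
  dimnames(fpkm) <- list(gene_ids, sheet$sample_id)

  # The presence/absence ground truth must be exact: only planted genes may
  # be fully absent (zero expressed calls) in one species under the default
  # 0.125 zFPKM call, and each planted gene must be expressed in at least 5
  # individuals of its own species. Because the call threshold is relative
  # to the realized density mode, this cannot be guaranteed analytically;
  # instead the generator audits its own realization with the package's
  # zFPKM calls and lifts offending genes clear of the boundary, iterating
  # to a fixed point (gene-level lifts shift both species equally, so
  # species differences in expression level are preserved).
  min_pos <- max(50, min(1000, floor(G / 4)))
  for (iter in 1:8) {
    zc <- tryCatch(
      zfpkm_transform(expression_study(fpkm, sheet),
                      min_expressed_genes = min_pos),
      error = function(e) NULL
    )
    if (is.null(zc)) break
    repair <- sim_presence_repair(zc, sheet, unique_to, off_species,
                                  species_idx)
    if (all(repair == 0)) break
    log2_expr <- log2_expr + repair
    fpkm <- sim_fpkm_matrix(log2_expr, off_species, species_idx,
                            config$detection_floor_log2)
    dimnames(fpkm) <- list(gene_ids, sheet$sample_id)
  }

  truth <- tibble::tibble(
    gene_id = gene_ids,
    regime = regime,
    species_shift = delta,
    sigma2_w_true = sd_w^2,
    sigma2_b_true = sd_b^2,
    sex_effect = sex_effect,
    unique_to = unique_to,
    in_deletion = FALSE
  )
  list(study = expression_study(fpkm, sheet), truth = truth)
}

#' Simulate per-gene covariates, optionally rank-correlated with the truth
#'
#' Covariates mimic the inputs of the correlate analyses: three
#' protein-interaction counts (pleiotropy proxies), upstream-window F_ST,
#' lineage dN and dS, gene length, GC and genomic position. A Gaussian copula
#' couples `log(1 + interactions)` to the true within-species variance at
#' rank correlation `rho_interactivity` (negative: highly interactive genes
#' vary less, the pleiotropy-constraint pattern), and F_ST to the true
#' between-species variance at `rho_fst` (default 0: regulatory and
#' expression divergence unrelated).
#'
#' @param config A [sim_config()].
#' @param truth Truth tibble from [simulate_expression_study()].
#' @param rho_interactivity Target Spearman correlation between interaction
#'   counts and true within-species variance (0 disables planting).
#' @param rho_fst Target Spearman correlation between upstream F_ST and true
#'   between-species variance.
#' @param seed Integer seed.
#' @return A tibble of gene covariates (see [read_gene_covariates()] for
#'   columns). A small fraction of F_ST/dN/dS entries is missing, as in real
#'   ortholog-limited tables.
#' @export
simulate_covariates <- function(config, truth, rho_interactivity = -0.3,
                                rho_fst = 0, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  G <- nrow(truth)

  copula_from <- function(anchor, rho_s) {
    # normal scores of the anchor (midranks for ties), plus independent noise
    # calibrated so the latent Pearson correlation matches the target
    # Spearman: rho_p = 2 sin(pi * rho_s / 6)
    if (rho_s == 0 || length(unique(anchor)) < 2) return(rnorm(G))
    rho_p <- 2 * sin(pi * rho_s / 6)
    z <- stats::qnorm((rank(anchor, ties.method = "average") - 0.5) / G)
    z <- z / sd(z)
    rho_p * z + sqrt(1 - rho_p^2) * rnorm(G)
  }
  count_from_latent <- function(latent, mu, size) {
    qnbinom(pnorm(latent), mu = mu, size = size)
  }

  interactions <- purrr::map(
    c(metabolic = 10, complex = 6, signalling = 4),
    function(mu) {
      count_from_latent(copula_from(truth$sigma2_w_true, rho_interactivity),
                        mu = mu, size = 1.2)
    }
  )

  fst_latent <- copula_from(truth$sigma2_b_true, rho_fst)
  fst <- qbeta(pnorm(fst_latent), 1.3, 3.7)   # marginal mean 0.26

  ds <- qgamma(runif(G), shape = 2, rate = 8)
  dn <- ds * qgamma(runif(G), shape = 1.2, rate = 6)

  n_chr <- 30
  chr_sizes <- sort(round(exp(seq(log(2e8), log(5e6),
                                  length.out = n_chr))), decreasing = TRUE)
  chr_names <- c(paste0("chr", seq_len(n_chr - 1)), "chrZ")
  chromosome <- sample(chr_names, G, replace = TRUE,
                       prob = chr_sizes / sum(chr_sizes))
  gene_length <- pmax(200L, as.integer(round(qlnorm(runif(G), log(2000),
                                                    0.8))))
  start <- as.integer(floor(runif(G, 0,
                                  chr_sizes[match(chromosome, chr_names)] -
                                    gene_length - 1)))
  miss <- function(x, p) { x[runif(G) < p] <- NA; x }

  tibble::tibble(
    gene_id = truth$gene_id,
    fst_upstream = miss(fst, 0.05),
    dn = miss(dn, 0.1),
    ds = miss(ds, 0.1),
    interactions_metabolic = miss(interactions$metabolic, 0.2),
    interactions_complex = miss(interactions$complex, 0.2),
    interactions_signalling = miss(interactions$signalling, 0.2),
    gene_length = gene_length,
    gc = qbeta(runif(G), 20, 25),
    chromosome = chromosome,
    start = start,
    end = start + gene_length
  )
}

#' Simulate a resequencing coverage track with a planted fixed deletion
#'
#' Per-individual window depths are Poisson with mean `mean_depth`
#' (default 15, i.e. ~15x genome coverage). Inside the planted deletion,
#' depth is exactly 0 for every individual of the deleted species. A gene
#' model of `n_exons` exons is placed so that `exons_in_deletion` of them lie
#' inside the deletion. Optionally an assembly gap (zero depth in all
#' individuals of both species) is planted as a negative control for the
#' screen's gap exclusion.
#'
#' @param config A [sim_config()] (provides species labels).
#' @param scaffold_length,window_size Scaffold extent and window width (bp).
#' @param deletion_start,deletion_end Planted deletion (0-based half-open);
#'   defaults give the ~20-kb case. Must lie inside the scaffold.
#' @param species_deleted Label of the species carrying the deletion.
#' @param n_individuals Individuals per species in the resequencing panel.
#' @param mean_depth Poisson mean depth per window.
#' @param n_exons,exons_in_deletion Gene model shape.
#' @param gap Optional length-2 vector: an assembly-gap interval with zero
#'   depth in everyone; `NULL` for none.
#' @param seed Integer seed.
#' @return A [coverage_study()] with attribute `truth`, a one-row tibble
#'   recording the planted interval.
#' @export
simulate_coverage <- function(config = sim_config(),
                              scaffold_length = 100000L,
                              window_size = 200L,
                              deletion_start = 30000L,
                              deletion_end = 50000L,
                              species_deleted = config$species_labels[2],
                              n_individuals = 10L,
                              mean_depth = 15,
                              n_exons = 13L,
                              exons_in_deletion = 11L,
                              gap = c(80000L, 81000L),
                              seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(deletion_start >= 0 && deletion_end <= scaffold_length &&
                deletion_end > deletion_start,
              "Deletion interval must lie inside the scaffold.")
  assert_that(species_deleted %in% config$species_labels,
              "`species_deleted` must be one of the study species.")
  withr::local_seed(seed)
  sp <- config$species_labels
  starts <- seq(0L, scaffold_length - window_size, by = window_size)
  n_win <- length(starts)
  inds <- paste0(rep(sp, each = n_individuals), "_reseq",
                 sprintf("%02d", rep(seq_len(n_individuals), 2)))
  species_of <- setNames(rep(sp, each = n_individuals), inds)
  depth <- matrix(rpois(length(inds) * n_win, mean_depth),
                  nrow = length(inds), dimnames = list(inds, NULL))
  in_del <- starts >= deletion_start & starts + window_size <= deletion_end
  depth[species_of == species_deleted, in_del] <- 0
  # Poisson zeros in the non-deleted species inside the deletion would mimic
  # loss; at 15x they are vanishingly rare, but keep the planted contrast
  # clean in the other species
  depth[species_of != species_deleted, in_del][
    depth[species_of != species_deleted, in_del] == 0] <- 1
  if (!is.null(gap)) {
    in_gap <- starts >= gap[1] & starts + window_size <= gap[2]
    depth[, in_gap] <- 0
  }

  # exon model: `exons_in_deletion` exons inside the deletion, the rest
  # downstream; exon width adapts so the model fits any geometry
  spread_exons <- function(from, to, k, w_max = 300L) {
    if (k == 0) return(integer(0))
    span <- to - from
    w <- max(1L, min(w_max, as.integer(floor(span / (2 * k)))))
    starts <- from + as.integer(floor((seq_len(k) - 1) * span / k))
    attr(starts, "w") <- w
    starts
  }
  inside <- spread_exons(deletion_start, deletion_end, exons_in_deletion)
  out_to <- min(scaffold_length, deletion_end + 15000L)
  outside <- spread_exons(deletion_end, out_to,
                          n_exons - exons_in_deletion)
  gene_model <- tibble::tibble(
    start = c(as.integer(inside), as.integer(outside)),
    end = c(as.integer(inside) + attr(inside, "w") %||% 0L,
            as.integer(outside) + attr(outside, "w") %||% 0L),
    coding = c(FALSE, rep(TRUE, n_exons - 2), FALSE)
  )
  cov <- coverage_study(depth, tibble::tibble(start = starts,
                                              end = starts + window_size),
                        species_of, scaffold = "scaffold_syn1",
                        gene_model = gene_model)
  attr(cov, "truth") <- tibble::tibble(
    scaffold = "scaffold_syn1",
    deletion_start = as.integer(deletion_start),
    deletion_end = as.integer(deletion_end),
    deletion_length = as.integer(deletion_end - deletion_start),
    species_deleted = species_deleted,
    exons_in_deletion = as.integer(exons_in_deletion),
    n_exons = as.integer(n_exons)
  )
  cov
}
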
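#' Configuration for the expression P_ST scan
#'
#' @param n_permutations Number of resampled replicates per organ (default
#'   1000).
#' @param scaling_ratio The c/h^2 multiplier on the between-species component
#'   in the P_ST formula (default 1; exposed because the P_ST literature
#'   varies in how additive the trait is assumed to be).
#' @param alpha Significance level for the DE call on adjusted p-values.
#' @param seed Master seed; per-gene permutation streams are derived from it
#'   deterministically, so results do not depend on gene processing order.
#' @param engine Variance-component estimator used throughout the scan:
#'   `"anova"` (method-of-moments from mean squares; identical to constrained
#'   REML on balanced designs and fast enough for permutation loops) or
#'   `"reml"` (profiled-likelihood REML, per gene).
#' @param sex_adjust How sex enters the model: `"fixed"` (default; a fixed
#'   covariate — with only two sex levels a random effect is weakly
#'   identifiable), `"random"` (literal random-effects fit, REML engine
#'   only) or `"none"`. Single-sex organs drop the term automatically.
#' @return A list of class `pst_config`.
#' @export
pst_config <- function(n_permutations = 1000, scaling_ratio = 1,
                       alpha = 0.05, seed = 1,
                       engine = c("anova", "reml"),
                       sex_adjust = c("fixed", "random", "none")) {
  assert_that(n_permutations >= 1, "Need at least one permutation.")
  assert_that(scaling_ratio > 0, "`scaling_ratio` must be positive.")
  structure(
    list(n_permutations = as.integer(n_permutations),
         scaling_ratio = scaling_ratio, alpha = alpha,
         seed = as.integer(seed), engine = match.arg(engine),
         sex_adjust = match.arg(sex_adjust)),
    class = "pst_config"
  )
}

# fixed-effect design for the nuisance part of the model (intercept + sex)
sex_design <- function(sex, sex_adjust) {
  n <- length(sex)
  if (sex_adjust == "none" || length(unique(sex)) < 2) {
    matrix(1, n, 1)
  } else {
    model.matrix(~ factor(sex))
  }
}

# method-of-moments (ANOVA) estimator for one gene: expected mean squares of
# the species term after projecting out the nuisance design X0. Boundary
# convention: a negative between-species component is set to 0 and the
# within component re-estimated under the species-free model, which makes the
# constrained estimator coincide with boundary REML on balanced designs.
mom_components <- function(y, species_ind, X0) {
  n <- length(y)
  p0 <- qr(X0)$rank
  Q0 <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  y_t <- drop(Q0 %*% y)
  s_t <- drop(Q0 %*% species_ind)
  ss_den <- sum(s_t^2)
  rss0 <- sum(y_t^2)
  if (ss_den < 1e-12) abort("Species is confounded with the sex design.")
  ss_sp <- sum(y_t * s_t)^2 / ss_den
  df_w <- n - p0 - 1
  ms_w <- (rss0 - ss_sp) / df_w
  n_a <- sum(species_ind == 1)
  n_b <- n - n_a
  n0 <- (n - (n_a^2 + n_b^2) / n)  # k - 1 = 1
  sigma2_b <- (ss_sp - ms_w) / n0
  if (sigma2_b < 0) {
    c(sigma2_b = 0, sigma2_w = rss0 / (n - p0))
  } else {
    c(sigma2_b = sigma2_b, sigma2_w = ms_w)
  }
}

# profiled REML for y = X0 beta + Z u + e with one random factor
# (u ~ N(0, sigma2_w * lambda), species indicator Z). The block structure of
# V = I + lambda ZZ' gives closed-form algebra for everything; the single
# variance ratio lambda is found by root-solving the REML score equation
#   tr(P ZZ') = (n - p) * y'P ZZ' P y / (y'P y)
# which localizes the optimum far more precisely than value-based search
# (the profiled likelihood is flat near its maximum).
reml_components <- function(y, species, X0) {
  n <- length(y)
  groups <- split(seq_len(n), species)
  p <- qr(X0)$rank

  pieces <- function(lambda) {
    XtViX <- crossprod(X0)
    XtViy <- crossprod(X0, y)
    for (g in groups) {
      w <- lambda / (1 + lambda * length(g))
      cs_x <- colSums(X0[g, , drop = FALSE])
      XtViX <- XtViX - w * tcrossprod(cs_x)
      XtViy <- XtViy - w * cs_x * sum(y[g])
    }
    A_inv <- solve(XtViX)
    beta <- A_inv %*% XtViy
    r <- drop(y - X0 %*% beta)
    rVr <- sum(r^2)
    quad_z <- 0     # y'P ZZ' P y
    tr_pz <- 0      # tr(P ZZ')
    for (g in groups) {
      n_g <- length(g)
      w <- lambda / (1 + lambda * n_g)
      rVr <- rVr - w * sum(r[g])^2
      # (V^-1 r) summed over the group
      sum_pr <- sum(r[g]) / (1 + lambda * n_g)
      quad_z <- quad_z + sum_pr^2
      xv1 <- colSums(X0[g, , drop = FALSE]) / (1 + lambda * n_g)
      tr_pz <- tr_pz + n_g / (1 + lambda * n_g) -
        drop(t(xv1) %*% A_inv %*% xv1)
    }
    list(rVr = rVr, score = tr_pz - (n - p) * quad_z / rVr)
  }

  at0 <- pieces(0)
  if (at0$score >= 0) {          # criterion increasing at 0: boundary
    return(c(sigma2_b = 0, sigma2_w = at0$rVr / (n - p)))
  }
  hi <- 1
  while (pieces(hi)$score < 0 && hi < 1e8) hi <- hi * 4
  if (pieces(hi)$score < 0) {
    lambda <- hi
  } else {
    lambda <- exp(uniroot(function(t) pieces(exp(t))$score,
                          c(log(1e-12), log(hi)), tol = 1e-13)$root)
  }
  s2w <- pieces(lambda)$rVr / (n - p)
  c(sigma2_b = lambda * s2w, sigma2_w = s2w)
}

# literal random-effects treatment of sex: both species and sex random,
# iterated profiling (species profiled by reml_components given the sex BLUP
# removed). Kept simple; available behind sex_adjust = "random".
reml_components_random_sex <- function(y, species, sex) {
  # absorb sex by its REML BLUP first (random intercept per sex level),
  # then estimate species components on the partial residuals
  sex_fit <- reml_components(y, sex, matrix(1, length(y), 1))
  if (sex_fit[["sigma2_b"]] > 0) {
    lambda <- sex_fit[["sigma2_b"]] / sex_fit[["sigma2_w"]]
    for (lev in unique(sex)) {
      idx <- sex == lev
      shrink <- lambda * sum(idx) / (1 + lambda * sum(idx))
      y[idx] <- y[idx] - shrink * mean(y[idx] - mean(y))
    }
  }
  reml_components(y, species, matrix(1, length(y), 1))
}

#' Estimate between- and within-species variance components for one gene
#'
#' Decomposes one gene's expression in one organ into a between-species
#' component `sigma2_b` and a within-species among-individual component
#' `sigma2_w`, after adjusting for sex. The default estimator is REML
#' (profiled likelihood, species as the random factor); `engine = "anova"`
#' gives the method-of-moments estimator from the ANOVA mean squares. On
#' balanced designs the two coincide. Negative estimates are truncated at
#' zero (with the within component re-estimated under the reduced model).
#'
#' @param values Numeric vector of expression values (zFPKM), one per
#'   individual.
#' @param meta Data frame with `species` and `sex` matching `values`.
#' @param engine `"reml"` (default) or `"anova"`.
#' @param sex_adjust `"fixed"`, `"random"` or `"none"`.
#' @return Tibble with `sigma2_b`, `sigma2_w`, `method`.
#' @export
estimate_variance_components <- function(values, meta,
                                         engine = c("reml", "anova"),
                                         sex_adjust = c("fixed", "random",
                                                        "none")) {
  engine <- match.arg(engine)
  sex_adjust <- match.arg(sex_adjust)
  species <- as.character(meta$species)
  tab <- table(species)
  if (length(tab) != 2) {
    abort("Variance components need exactly two species present.")
  }
  if (any(tab < 2)) abort("Need >= 2 individuals per species.")
  sex <- if ("sex" %in% names(meta)) as.character(meta$sex) else
    rep("unknown", length(values))
  X0 <- sex_design(sex, if (sex_adjust == "none") "none" else "fixed")
  s_ind <- as.numeric(species == sort(unique(species))[2])
  est <- if (engine == "anova") {
    mom_components(values, s_ind, X0)
  } else if (sex_adjust == "random" && length(unique(sex)) > 1) {
    reml_components_random_sex(values, species, sex)
  } else {
    res <- tryCatch(reml_components(values, species, X0),
                    error = function(e) NULL)
    if (is.null(res)) {
      warn("REML fit failed; falling back to the ANOVA estimator.")
      mom_components(values, s_ind, X0)
    } else res
  }
  tibble::tibble(sigma2_b = unname(est[["sigma2_b"]]),
                 sigma2_w = unname(est[["sigma2_w"]]),
                 method = engine)
}

#' The expression P_ST statistic
#'
#' `P_ST = c * sigma2_b / (c * sigma2_b + 2 * sigma2_w)` with `c` the
#' scaling ratio (c/h^2, default 1) — the phenotypic analogue of Q_ST applied
#' to expression traits. Returns 0 when `sigma2_b` is 0 and `NA` (with a
#' warning) when both components are 0.
#'
#' @param sigma2_b,sigma2_w Non-negative variance components (vectorized).
#' @param scaling_ratio Positive multiplier on the between component.
#' @return P_ST values in `[0, 1]`.
#' @examples
#' pst_statistic(1, 1)   # 1/3
#' pst_statistic(2, 1)   # 0.5
#' @export
pst_statistic <- function(sigma2_b, sigma2_w, scaling_ratio = 1) {
  assert_that(scaling_ratio > 0, "`scaling_ratio` must be positive.")
  if (any(sigma2_b < 0 | sigma2_w < 0, na.rm = TRUE)) {
    abort("Variance components must be non-negative.")
  }
  den <- scaling_ratio * sigma2_b + 2 * sigma2_w
  out <- ifelse(den > 0, scaling_ratio * sigma2_b / den,
                NA_real_)
  out[sigma2_b == 0 & sigma2_w > 0] <- 0
  if (any(is.na(out) & !is.na(sigma2_b))) {
    warn("P_ST undefined where both variance components are zero.")
  }
  out
}

#' Resampling-corrected permutation p-value
#'
#' `p = (b + 1) / (m + 1)` where `b` of `m` resampled statistics reach the
#' observed one. The +1 correction guarantees `p >= 1/(m+1)` and never
#' exactly zero, giving valid (slightly conservative) p-values from a finite
#' number of random permutations.
#'
#' @param b_exceed Count of null statistics >= observed (vectorized).
#' @param m Number of permutations.
#' @return p-values in `[1/(m+1), 1]`.
#' @examples
#' phipson_smyth_p(0, 1000)  # 1/1001
#' phipson_smyth_p(49, 999)  # 0.05
#' @export
phipson_smyth_p <- function(b_exceed, m) {
  assert_that(all(m >= 1), "`m` must be at least 1.")
  if (any(b_exceed < 0 | b_exceed > m, na.rm = TRUE)) {
    abort("`b_exceed` must lie in [0, m].")
  }
  (b_exceed + 1) / (m + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

# draw m species-label permutations over individuals; if fewer distinct
# assignments exist, enumerate them all. Returns an n x m indicator matrix.
permutation_assignments <- function(species_ind, m) {
  n <- length(species_ind)
  n_b <- sum(species_ind == 1)
  n_distinct <- choose(n, n_b)
  if (n_distinct <= m) {
    warn(paste0("Only ", n_distinct, " distinct species assignments; ",
                "enumerating all of them."))
    sets <- combn(n, n_b)
    out <- matrix(0, n, ncol(sets))
    out[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n_b))] <- 1
    out
  } else {
    replicate(m, species_ind[sample.int(n)])
  }
}

# vectorized (over permutations) MoM components and P_ST for one gene
null_pst_for_gene <- function(y_t, Q0, perms, n, p0, scaling_ratio) {
  S_t <- Q0 %*% perms
  ss_den <- colSums(S_t^2)
  cross <- drop(crossprod(S_t, y_t))
  ss_sp <- cross^2 / ss_den
  rss0 <- sum(y_t^2)
  df_w <- n - p0 - 1
  ms_w <- (rss0 - ss_sp) / df_w
  n_b <- colSums(perms)
  n0 <- n - (n_b^2 + (n - n_b)^2) / n
  s2b <- pmax(0, (ss_sp - ms_w) / n0)
  s2w <- ifelse(s2b > 0, ms_w, rss0 / (n - p0))
  den <- scaling_ratio * s2b + 2 * s2w
  ifelse(den > 0, scaling_ratio * s2b / den, NA_real_)
}

#' Permutation null of P_ST for one gene
#'
#' Permutes species labels across the individuals of the organ (each
#' individual keeps its sex), re-estimates the variance components and P_ST
#' per replicate, and counts how many null statistics reach the observed one.
#' If fewer distinct label assignments exist than requested replicates, all
#' assignments are enumerated instead.
#'
#' @param values Expression values, one per individual.
#' @param meta Data frame with `species` and `sex`.
#' @param config A [pst_config()].
#' @return A list with `b_exceed`, `m`, `observed` (P_ST) and `null`
#'   (the null P_ST values).
#' @export
permutation_null <- function(values, meta, config = pst_config()) {
  species <- as.character(meta$species)
  sex <- if ("sex" %in% names(meta)) as.character(meta$sex) else
    rep("unknown", length(values))
  n <- length(values)
  X0 <- sex_design(sex, config$sex_adjust)
  p0 <- qr(X0)$rank
  Q0 <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  s_ind <- as.numeric(species == sort(unique(species))[2])
  obs <- mom_components(values, s_ind, X0)
  obs_pst <- pst_statistic(obs[["sigma2_b"]], obs[["sigma2_w"]],
                           config$scaling_ratio)
  withr::local_seed(config$seed)
  perms <- permutation_assignments(s_ind, config$n_permutations)
  nulls <- null_pst_for_gene(drop(Q0 %*% values), Q0, perms, n, p0,
                             config$scaling_ratio)
  list(b_exceed = sum(nulls >= obs_pst, na.rm = TRUE), m = ncol(perms),
       observed = obs_pst, null = nulls)
}

#' Scan one organ for differentially expressed genes with expression P_ST
#'
#' For every gene expressed in all samples of the organ: estimate the
#' between/within-species variance components (sex-adjusted), form P_ST,
#' build a permutation null by reassigning species labels across individuals
#' (per-gene deterministic substreams derived from the master seed),
#' resampling-correct the p-values and Benjamini-Hochberg adjust them across
#' genes. A gene is called DE when its adjusted p-value falls below
#' `config$alpha`.
#'
#' @param z A [zfpkm_transform()] result.
#' @param organ Organ label.
#' @param config A [pst_config()].
#' @param genes Gene ids to scan; defaults to [pst_gene_filter()] output.
#' @return A tibble of class `pst_scan` with columns `gene_id`, `organ`,
#'   `sigma2_b`, `sigma2_w`, `pst`, `b_exceed`, `m`, `p_raw`, `p_adj`, `de`
#'   (and `de_raw`, the call on unadjusted p-values). Attributes carry the
#'   config and organ.
#' @examples
#' sim <- simulate_expression_study(
#'   sim_config(n_genes = 60, organs = "liver"), seed = 1)
#' z <- zfpkm_transform(sim$study, min_expressed_genes = 20)
#' scan <- run_pst_scan(z, "liver", pst_config(n_permutations = 99))
#' dplyr::arrange(scan, p_raw)
#' @export
run_pst_scan <- function(z, organ, config = pst_config(), genes = NULL) {
  stopifnot(inherits(z, "zfpkm_matrix"), inherits(config, "pst_config"))
  if (is.null(genes)) genes <- pst_gene_filter(z, organ)
  assert_that(length(genes) >= 1, "No genes pass the expressed-in-all filter.")
  keep <- z$samples$organ == organ
  meta <- z$samples[keep, , drop = FALSE]
  species_levels <- sort(unique(meta$species))
  assert_that(length(species_levels) == 2,
              "The P_ST scan needs exactly two species.")
  Y <- z$z[genes, keep, drop = FALSE]

  n <- nrow(meta)
  X0 <- sex_design(meta$sex, config$sex_adjust)
  p0 <- qr(X0)$rank
  Q0 <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  s_ind <- as.numeric(meta$species == species_levels[2])

  # observed components, all genes at once (MoM) or per gene (REML)
  if (config$engine == "anova") {
    Yt <- Y %*% t(Q0)
    s_t <- drop(Q0 %*% s_ind)
    ss_den <- sum(s_t^2)
    ss_sp <- drop(Yt %*% s_t)^2 / ss_den
    rss0 <- rowSums(Yt^2)
    df_w <- n - p0 - 1
    ms_w <- (rss0 - ss_sp) / df_w
    n_b <- sum(s_ind)
    n0 <- n - (n_b^2 + (n - n_b)^2) / n
    s2b <- pmax(0, (ss_sp - ms_w) / n0)
    s2w <- ifelse(s2b > 0, ms_w, rss0 / (n - p0))
  } else {
    comp <- purrr::map(seq_along(genes), function(g) {
      reml_components(Y[g, ], meta$species, X0)
    })
    s2b <- purrr::map_dbl(comp, "sigma2_b")
    s2w <- purrr::map_dbl(comp, "sigma2_w")
  }
  obs_pst <- pst_statistic(s2b, s2w, config$scaling_ratio)

  organ_stream <- sum(utf8ToInt(organ))
  gene_index <- match(genes, rownames(z$z))  # stable across gene subsets
  perm_stats <- purrr::map(seq_along(genes), function(g) {
    withr::local_seed(derive_seed(config$seed, organ_stream, gene_index[g]))
    perms <- suppressWarnings(permutation_assignments(
      s_ind, config$n_permutations))
    nulls <- null_pst_for_gene(drop(Q0 %*% Y[g, ]), Q0, perms, n, p0,
                               config$scaling_ratio)
    c(b = sum(nulls >= obs_pst[g], na.rm = TRUE), m = ncol(perms))
  })
  b_exceed <- purrr::map_dbl(perm_stats, "b")
  m <- purrr::map_dbl(perm_stats, "m")
  if (any(m < config$n_permutations)) {
    warn(paste0("Fewer distinct species assignments (", min(m), ") than ",
                "requested permutations; all were enumerated."))
  }
  p_raw <- phipson_smyth_p(b_exceed, m)
  p_adj <- bh_adjust(p_raw)
  out <- tibble::tibble(
    gene_id = genes, organ = organ,
    sigma2_b = s2b, sigma2_w = s2w, pst = obs_pst,
    b_exceed = as.integer(b_exceed), m = as.integer(m),
    p_raw = p_raw, p_adj = p_adj,
    de = p_adj < config$alpha, de_raw = p_raw < config$alpha
  )
  class(out) <- c("pst_scan", class(out))
  attr(out, "config") <- config
  attr(out, "organ") <- organ
  out
}
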
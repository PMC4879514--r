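#' Spearman correlation grid of P_ST and its components against covariates
#'
#' For each organ scan and each target covariate (the three protein
#' interaction counts, organ specificity tau, dN/dS, upstream-window F_ST),
#' computes Spearman rank correlations with three responses: P_ST, the
#' between-species component and the within-species component. P-values come
#' from [stats::cor.test()] (t-approximation, exact for small n without
#' ties) and are Benjamini-Hochberg adjusted across the whole grid, which is
#' treated as one multiple-testing family.
#'
#' Genes with a missing value for a target are dropped pairwise for that
#' target only. dN/dS is formed as `dn/ds` where `ds > 0`, after the
#' saturation filter of [dnds_filter()].
#'
#' @param pst_tables A `pst_scan` tibble or list of them (one per organ).
#' @param covariates Gene covariate tibble.
#' @param tau_tables Optional [tau_table()] output; tau is averaged over
#'   species per gene before correlating.
#' @param targets Covariate columns to correlate; defaults to interactions,
#'   tau (if given), dN/dS and F_ST.
#' @return Tibble with `organ`, `target`, `response`, `rho`, `p`, `n`,
#'   `p_adj`.
#' @export
spearman_grid <- function(pst_tables, covariates, tau_tables = NULL,
                          targets = NULL) {
  if (inherits(pst_tables, "pst_scan")) pst_tables <- list(pst_tables)
  cov <- validate_gene_covariates(covariates)
  if (all(c("dn", "ds") %in% names(cov))) {
    keep <- dnds_filter(cov)
    cov$dnds <- ifelse(cov$gene_id %in% keep & !is.na(cov$ds) & cov$ds > 0,
                       cov$dn / cov$ds, NA_real_)
  }
  if (!is.null(tau_tables)) {
    tau_mean <- dplyr::summarise(dplyr::group_by(tau_tables, .data$gene_id),
                                 tau = mean(.data$tau, na.rm = TRUE))
    cov <- dplyr::left_join(cov, tau_mean, by = "gene_id")
  }
  if (is.null(targets)) {
    targets <- intersect(
      c("interactions_metabolic", "interactions_complex",
        "interactions_signalling", "tau", "dnds", "fst_upstream"),
      names(cov)
    )
  }
  responses <- c("pst", "sigma2_b", "sigma2_w")
  grid <- purrr::map_dfr(pst_tables, function(scan) {
    if (anyDuplicated(scan$gene_id)) {
      abort("Duplicated gene rows in a P_ST table.")
    }
    joined <- dplyr::inner_join(scan, cov, by = "gene_id")
    purrr::map_dfr(targets, function(tg) {
      purrr::map_dfr(responses, function(rs) {
        x <- joined[[tg]]
        y <- joined[[rs]]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        if (n < 10 || length(unique(x[ok])) < 2 ||
            length(unique(y[ok])) < 2) {
          warn(paste0("Constant or too-small input for ", tg, " ~ ", rs,
                      " in ", scan$organ[1], "; rho set NA."))
          return(tibble::tibble(organ = scan$organ[1], target = tg,
                                response = rs, rho = NA_real_,
                                p = NA_real_, n = n))
        }
        ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
        tibble::tibble(organ = scan$organ[1], target = tg, response = rs,
                       rho = unname(ct$estimate), p = ct$p.value, n = n)
      })
    })
  })
  grid$p_adj <- NA_real_
  ok <- !is.na(grid$p)
  grid$p_adj[ok] <- bh_adjust(grid$p[ok])
  grid
}

#' Filter genes with unreliable substitution-rate estimates
#'
#' Drops genes with `ds > 2` (synonymous saturation / alignment error) or
#' `dn/ds > 3`. Genes with missing `dn` or `ds` are dropped as incomplete for
#' rate-based analyses.
#'
#' @param covariates Gene covariate tibble with `dn`, `ds`.
#' @return Character vector of retained gene ids.
#' @examples
#' cov <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                       dn = c(0.1, 0.1, 3.5), ds = c(1.0, 2.5, 1.0))
#' dnds_filter(cov)  # only "a"
#' @export
dnds_filter <- function(covariates) {
  cov <- tibble::as_tibble(covariates)
  assert_that(all(c("dn", "ds") %in% names(cov)),
              "`dn` and `ds` columns required.")
  ok <- !is.na(cov$dn) & !is.na(cov$ds) & cov$ds <= 2 &
    (cov$ds == 0 | cov$dn / cov$ds <= 3)
  cov$gene_id[ok]
}

#' Contrast P_ST against high-F_ST genomic background
#'
#' For each F_ST cutoff: a Mann-Whitney U test comparing P_ST of genes whose
#' upstream window exceeds the cutoff against the rest, and, for each P_ST
#' cutoff, a chi-square test of enrichment of high-P_ST ("DE-like") genes in
#' the high-F_ST stratum. Empty strata are skipped with a warning.
#'
#' @param pst_table A `pst_scan` tibble.
#' @param covariates Gene covariate tibble with `fst_upstream`.
#' @param fst_cutoffs F_ST thresholds (default 0.3 to 0.8).
#' @param pst_cutoffs P_ST thresholds defining "high-P_ST" genes
#'   (default 0.05 to 0.3).
#' @return Tibble with one row per (fst_cutoff, pst_cutoff) combination
#'   (`pst_cutoff = NA` rows hold the Mann-Whitney contrast): `organ`,
#'   `fst_cutoff`, `pst_cutoff`, `test`, `n_high`, `n_rest`, `statistic`,
#'   `p`, `odds_ratio`.
#' @export
high_fst_contrast <- function(pst_table, covariates,
                              fst_cutoffs = seq(0.3, 0.8, by = 0.1),
                              pst_cutoffs = c(0.05, 0.1, 0.2, 0.3)) {
  joined <- dplyr::inner_join(pst_table,
                              dplyr::select(covariates, "gene_id",
                                            "fst_upstream"),
                              by = "gene_id")
  joined <- dplyr::filter(joined, !is.na(.data$fst_upstream),
                          !is.na(.data$pst))
  purrr::map_dfr(fst_cutoffs, function(fc) {
    high <- joined$fst_upstream > fc
    if (!any(high) || all(high)) {
      warn(paste0("Empty F_ST stratum at cutoff ", fc, "; skipped."))
      return(tibble::tibble())
    }
    mwu <- suppressWarnings(wilcox.test(joined$pst[high],
                                        joined$pst[!high]))
    mwu_row <- tibble::tibble(
      organ = joined$organ[1], fst_cutoff = fc, pst_cutoff = NA_real_,
      test = "mann_whitney", n_high = sum(high), n_rest = sum(!high),
      statistic = unname(mwu$statistic), p = mwu$p.value,
      odds_ratio = NA_real_
    )
    enr <- purrr::map_dfr(pst_cutoffs, function(pc) {
      de_like <- joined$pst > pc
      tab <- table(factor(high, c(FALSE, TRUE)),
                   factor(de_like, c(FALSE, TRUE)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        return(tibble::tibble())
      }
      cs <- suppressWarnings(chisq.test(tab))
      or <- (tab[2, 2] * tab[1, 1]) / max(1e-12, tab[2, 1] * tab[1, 2])
      tibble::tibble(
        organ = joined$organ[1], fst_cutoff = fc, pst_cutoff = pc,
        test = "chisq_enrichment", n_high = sum(high), n_rest = sum(!high),
        statistic = unname(cs$statistic), p = cs$p.value, odds_ratio = or
      )
    })
    dplyr::bind_rows(mwu_row, enr)
  })
}

#' Positional enrichment of differentially expressed genes
#'
#' Chi-square test of the DE proportion on the sex chromosome versus the
#' autosomes, and Spearman correlation of the per-chromosome DE proportion
#' with chromosome length (approximated by the largest annotated gene end
#' per chromosome, or supplied directly).
#'
#' @param pst_table A `pst_scan` tibble with a `de` column.
#' @param covariates Gene covariate tibble with `chromosome`, `start`, `end`.
#' @param sex_chromosome Label of the sex chromosome (default `"chrZ"`).
#' @param chromosome_lengths Optional named vector of chromosome lengths.
#' @return A list with `sex_chromosome_test` (tibble: proportions, chi-square
#'   statistic, p) and `size_correlation` (tibble: rho, p, n chromosomes).
#' @export
positional_enrichment <- function(pst_table, covariates,
                                  sex_chromosome = "chrZ",
                                  chromosome_lengths = NULL) {
  joined <- dplyr::inner_join(pst_table,
                              dplyr::select(covariates, "gene_id",
                                            "chromosome", "end"),
                              by = "gene_id")
  joined <- dplyr::filter(joined, !is.na(.data$chromosome))
  chrs <- unique(joined$chromosome)
  assert_that(length(chrs) >= 2, "Need more than one chromosome.")
  on_z <- joined$chromosome == sex_chromosome
  tab <- table(factor(on_z, c(FALSE, TRUE)),
               factor(joined$de, c(FALSE, TRUE)))
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  sex_test <- tibble::tibble(
    prop_de_sex_chromosome = mean(joined$de[on_z]),
    prop_de_autosomes = mean(joined$de[!on_z]),
    chisq = unname(cs$statistic), p = cs$p.value,
    n_sex_chromosome = sum(on_z), n_autosomes = sum(!on_z)
  )
  per_chr <- dplyr::summarise(
    dplyr::group_by(joined, .data$chromosome),
    prop_de = mean(.data$de), n_genes = dplyr::n(),
    max_end = max(.data$end, na.rm = TRUE), .groups = "drop"
  )
  per_chr$length <- if (!is.null(chromosome_lengths)) {
    unname(chromosome_lengths[per_chr$chromosome])
  } else per_chr$max_end
  ct <- suppressWarnings(cor.test(per_chr$prop_de, per_chr$length,
                                  method = "spearman"))
  list(
    sex_chromosome_test = sex_test,
    size_correlation = tibble::tibble(rho = unname(ct$estimate),
                                      p = ct$p.value,
                                      n_chromosomes = nrow(per_chr)),
    per_chromosome = per_chr
  )
}
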
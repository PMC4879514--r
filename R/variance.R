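#' Per-gene expression variance by organ and species
#'
#' Unbiased sample variance of zFPKM across the individuals of each
#' (organ, species) cell, one row per gene x organ x species, together with
#' the cell's mean expression (used later to control variance for expression
#' level). Cells with a single individual give `NA` with a warning. Genes
#' with an FPKM = 0 sentinel in a cell give `NA` for that cell.
#'
#' @param z A [zfpkm_transform()] result.
#' @param genes Optional gene ids to restrict to (default: all).
#' @return Tibble with `gene_id`, `organ`, `species`, `n`, `mean_z`,
#'   `variance`.
#' @export
expression_variance <- function(z, genes = NULL) {
  stopifnot(inherits(z, "zfpkm_matrix"))
  zmat <- z$z
  if (!is.null(genes)) zmat <- zmat[genes, , drop = FALSE]
  zmat[!is.finite(zmat)] <- NA
  cells <- dplyr::distinct(z$samples, .data$organ, .data$species)
  singleton <- FALSE
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    keep <- z$samples$organ == cells$organ[i] &
      z$samples$species == cells$species[i]
    m <- zmat[, keep, drop = FALSE]
    n_cell <- ncol(m)
    if (n_cell < 2) singleton <<- TRUE
    tibble::tibble(
      gene_id = rownames(m),
      organ = cells$organ[i],
      species = cells$species[i],
      n = n_cell,
      mean_z = unname(rowMeans(m)),
      variance = if (n_cell >= 2) unname(apply(m, 1, var)) else NA_real_
    )
  })
  if (singleton) {
    warn("Some (organ, species) cells have a single individual; variance NA.")
  }
  out
}

#' Between-species expression divergence per gene in one organ
#'
#' Absolute difference of the two species' mean log2-scale (zFPKM)
#' expression, over genes expressed in every sample of the organ.
#'
#' @param z A [zfpkm_transform()] result.
#' @param organ Organ label.
#' @param genes Gene ids to use; defaults to [pst_gene_filter()] output.
#' @return Tibble with `gene_id`, `organ`, `mean_a`, `mean_b`, `divergence`
#'   (= `|mean_a - mean_b|`); `mean_a` refers to the alphabetically first
#'   species label.
#' @export
expression_divergence <- function(z, organ, genes = NULL) {
  stopifnot(inherits(z, "zfpkm_matrix"))
  if (is.null(genes)) genes <- pst_gene_filter(z, organ)
  keep <- z$samples$organ == organ
  if (!any(keep)) abort(paste0("No samples for organ `", organ, "`."))
  species <- sort(unique(z$samples$species[keep]))
  assert_that(length(species) == 2,
              "Divergence needs exactly two species in the organ.")
  m <- z$z[genes, keep, drop = FALSE]
  sp <- z$samples$species[keep]
  mean_a <- unname(rowMeans(m[, sp == species[1], drop = FALSE]))
  mean_b <- unname(rowMeans(m[, sp == species[2], drop = FALSE]))
  tibble::tibble(gene_id = genes, organ = organ,
                 mean_a = mean_a, mean_b = mean_b,
                 divergence = abs(mean_a - mean_b))
}

#' Residualize expression variance on technical and genomic covariates
#'
#' Rank-transforms the per-gene variance and regresses the ranks on the
#' ranks of mean expression level, gene length and GC content plus the
#' design factors present in the table (organ, species, and sex if
#' supplied), then returns residuals plus lower/upper decile group flags
#' computed on the residuals. The rank-rank regression removes any monotone
#' covariate effect, not just a linear one.
#' Collinear (aliased) covariates are dropped with a warning. Genes with
#' missing covariates are dropped for this analysis only.
#'
#' @param variance_table Output of [expression_variance()] (or any tibble
#'   with `gene_id`, `variance`, `mean_z` and optional factor columns
#'   `organ`, `species`, `sex`).
#' @param covariates Gene covariate tibble with `gene_id`, `gene_length`,
#'   `gc`.
#' @param percentile Decile width for the extreme-variance groups
#'   (default 0.10).
#' @return The joined table with `resid_rank` (residual of the variance rank)
#'   and `variance_group` (`"low"`, `"mid"`, `"high"`); the low and high
#'   groups each hold `floor(percentile * n)` rows.
#' @export
residualize_variance <- function(variance_table, covariates,
                                 percentile = 0.10) {
  tab <- dplyr::inner_join(
    dplyr::filter(variance_table, !is.na(.data$variance)),
    dplyr::select(covariates, "gene_id", "gene_length", "gc"),
    by = "gene_id"
  )
  tab <- tab[complete.cases(tab[c("variance", "mean_z", "gene_length",
                                  "gc")]), , drop = FALSE]
  assert_that(nrow(tab) >= 10, "Too few complete rows to residualize.")
  tab$.rank <- rank(tab$variance)
  tab$.r_expr <- rank(tab$mean_z)
  tab$.r_len <- rank(tab$gene_length)
  tab$.r_gc <- rank(tab$gc)
  terms <- c(".r_expr", ".r_len", ".r_gc")
  for (f in c("organ", "species", "sex")) {
    if (f %in% names(tab) && length(unique(tab[[f]])) > 1) {
      terms <- c(terms, f)
    }
  }
  fit <- lm(stats::reformulate(terms, response = ".rank"), data = tab)
  if (anyNA(coef(fit))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    warn(paste0("Collinear covariate term(s) dropped: ",
                paste(dropped, collapse = ", ")))
  }
  tab$resid_rank <- residuals(fit)
  k <- floor(percentile * nrow(tab))
  ord <- order(tab$resid_rank)
  group <- rep("mid", nrow(tab))
  if (k > 0) {
    group[ord[seq_len(k)]] <- "low"
    group[ord[seq(nrow(tab) - k + 1, nrow(tab))]] <- "high"
  }
  tab$variance_group <- group
  tab[c(".rank", ".r_expr", ".r_len", ".r_gc")] <- NULL
  tibble::as_tibble(tab)
}
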
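#' Run the full expression-divergence pipeline on one study
#'
#' Chains the stages end to end: zFPKM normalization and expressed calls,
#' the per-organ P_ST scan, organ specificity, the correlate grid (when
#' covariates are supplied), NMDS ordination with per-axis ANOVA,
#' species-unique gene detection, and (when coverage is supplied) the
#' deletion screen. Every stage's table is written as TSV under `out_dir`
#' with a provenance header line (`# exprdiverge <version> seed=<seed>`),
#' and all randomness derives from the one seed, so reruns are reproducible.
#'
#' @param study An [expression_study()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param covariates Optional gene covariate tibble.
#' @param coverage Optional [coverage_study()] for the deletion screen.
#' @param config A [pst_config()].
#' @param cutoff Expressed-gene cutoff (zFPKM).
#' @param nmds_k Ordination dimensionality.
#' @param organs Organs to scan (default: all with both species and >= 2
#'   individuals per species).
#' @param min_expressed_genes Passed to [zfpkm_transform()].
#' @return A list with elements `zfpkm`, `scans` (list per organ),
#'   `de_summary` (DE counts per organ), `tau`, `correlates`, `nmds`,
#'   `axis_anova`, `unique_genes`, `deletions`.
#' @export
run_pipeline <- function(study, out_dir = NULL, covariates = NULL,
                         coverage = NULL, config = pst_config(),
                         cutoff = 0.125, nmds_k = 3, organs = NULL,
                         min_expressed_genes = 100) {
  stopifnot(inherits(study, "expression_study"))
  z <- zfpkm_transform(study, cutoff = cutoff,
                       min_expressed_genes = min_expressed_genes)
  calls <- call_expressed(z)

  meta <- z$samples
  if (is.null(organs)) {
    counts <- dplyr::count(meta, .data$organ, .data$species)
    ok <- dplyr::summarise(dplyr::group_by(counts, .data$organ),
                           ok = dplyr::n() == 2 && all(.data$n >= 2),
                           .groups = "drop")
    organs <- ok$organ[ok$ok]
  }
  scans <- purrr::map(organs, function(o) run_pst_scan(z, o, config))
  names(scans) <- organs
  de_summary <- purrr::map_dfr(scans, function(s) {
    tibble::tibble(organ = s$organ[1], n_genes = nrow(s),
                   n_de = sum(s$de), prop_de = mean(s$de),
                   n_de_raw = sum(s$de_raw))
  })

  tau_tab <- if (length(unique(meta$organ)) >= 2) tau_table(z) else NULL
  correlates <- if (!is.null(covariates) && length(scans) > 0) {
    spearman_grid(scans, covariates, tau_tab)
  } else NULL

  ord <- nmds(distance_matrix(z), k = nmds_k, seed = config$seed)
  axis_anova <- anova_on_axes(ord, meta)

  uniques <- species_unique_genes(calls, meta)
  deletions <- if (!is.null(coverage)) deletion_screen(coverage) else NULL

  res <- list(zfpkm = z, scans = scans, de_summary = de_summary,
              tau = tau_tab, correlates = correlates, nmds = ord,
              axis_anova = axis_anova, unique_genes = uniques,
              deletions = deletions)
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir, config)
  invisible(res)
}

write_pipeline_report <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- paste0("# exprdiverge ",
                   as.character(utils::packageVersion("exprdiverge")),
                   " seed=", config$seed)
  emit <- function(tab, name) {
    if (is.null(tab) || nrow(tab) == 0) return(invisible(NULL))
    tab <- dplyr::select(tab, dplyr::where(~ !is.list(.x)))
    path <- file.path(out_dir, name)
    writeLines(header, path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  emit(res$zfpkm$fits, "zfpkm_fits.tsv")
  emit(dplyr::bind_rows(res$scans), "pst_scan.tsv")
  emit(res$de_summary, "de_summary.tsv")
  emit(res$tau, "tau.tsv")
  emit(res$correlates, "correlates.tsv")
  emit(tibble::as_tibble(res$nmds$points, rownames = "sample_id"),
       "nmds_configuration.tsv")
  emit(res$axis_anova, "nmds_anova.tsv")
  emit(res$unique_genes, "unique_genes.tsv")
  emit(res$deletions, "deletions.tsv")
  invisible(out_dir)
}
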
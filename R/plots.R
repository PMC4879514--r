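#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an NMDS ordination
#'
#' Samples on two ordination axes, colored by organ and shaped by species.
#'
#' @param object An [nmds()] result.
#' @param meta Sample metadata (matched by `sample_id`).
#' @param axes Length-2 integer vector of axes to display.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.nmds_result <- function(object, meta, axes = c(1, 2), ...) {
  dat <- tibble::as_tibble(object$points, rownames = "sample_id")
  dat <- dplyr::left_join(dat, tibble::as_tibble(meta), by = "sample_id")
  ax <- paste0("axis", axes)
  ggplot2::ggplot(dat, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                    colour = .data$organ,
                                    shape = .data$species)) +
    ggplot2::geom_point(size = 2, alpha = 0.9) +
    ggplot2::labs(
      title = sprintf("NMDS (k = %d, stress = %.3f)", object$k,
                      object$stress),
      x = ax[1], y = ax[2]
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot of NMDS stress against dimensionality
#'
#' @param scree_table Output of [scree()].
#' @return A ggplot object.
#' @export
plot_scree <- function(scree_table) {
  ggplot2::ggplot(scree_table, ggplot2::aes(.data$k, .data$stress)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$elbow), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = scree_table$k) +
    ggplot2::labs(x = "dimensions (k)", y = "Kruskal stress-1") +
    ggplot2::theme_minimal()
}

#' Variance components of DE versus non-DE genes
#'
#' Side-by-side distributions of the log between- and within-species
#' variance components, split by DE status — a check that high P_ST is not
#' driven by one component alone.
#'
#' @param object A `pst_scan` tibble from [run_pst_scan()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pst_scan <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "gene_id", "de",
                  "sigma2_b", "sigma2_w"),
    c("sigma2_b", "sigma2_w"),
    names_to = "component", values_to = "value"
  )
  dat$de <- ifelse(dat$de, "DE", "not DE")
  ggplot2::ggplot(dat, ggplot2::aes(.data$de, log10(.data$value + 1e-6),
                                    fill = .data$de)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log10 variance component") +
    ggplot2::theme_minimal()
}

#' Coverage track with gene model, per species
#'
#' Mean window depth per species along the scaffold, with the gene's exons
#' underneath — the visual check for a fixed deletion (one species' depth
#' dropping to zero over part of the gene).
#'
#' @param cov A [coverage_study()].
#' @param calls Optional [deletion_screen()] output to highlight.
#' @return A ggplot object.
#' @export
plot_coverage <- function(cov, calls = NULL) {
  stopifnot(inherits(cov, "coverage_study"))
  long <- purrr::map_dfr(sort(unique(cov$individual_species)), function(s) {
    rows <- cov$individual_species == s
    tibble::tibble(
      species = s,
      pos = (cov$windows$start + cov$windows$end) / 2,
      depth = colMeans(cov$depth[rows, , drop = FALSE])
    )
  })
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$pos, .data$depth,
                                          colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(cov$scaffold, " position (bp)"),
                  y = "mean depth") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = calls$start, xmax = calls$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  if (!is.null(cov$gene_model)) {
    p <- p + ggplot2::geom_rect(
      data = cov$gene_model,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -2, ymax = -0.5),
      inherit.aes = FALSE, fill = "black"
    )
  }
  p
}
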
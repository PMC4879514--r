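#' Euclidean distances between samples on zFPKM values
#'
#' Distances over genes with finite zFPKM in every sample (genes carrying an
#' FPKM = 0 sentinel anywhere are dropped listwise, so all samples are
#' compared on the same gene set).
#'
#' @param z A [zfpkm_transform()] result.
#' @return A [stats::dist] object over samples.
#' @export
distance_matrix <- function(z) {
  stopifnot(inherits(z, "zfpkm_matrix"))
  assert_that(ncol(z$z) >= 3, "Need at least 3 samples for ordination.")
  keep <- rowSums(!is.finite(z$z)) == 0
  assert_that(sum(keep) >= 2,
              "No genes with finite zFPKM in all samples.")
  dist(t(z$z[keep, , drop = FALSE]))
}

#' Nonmetric multidimensional scaling of a sample distance matrix
#'
#' Kruskal NMDS: starting from the classical (metric) MDS configuration, the
#' layout is iteratively adjusted to minimize stress-1 between configuration
#' distances and dissimilarity ranks until the stress improvement falls below
#' the tolerance. Only distance ranks matter, so any monotone transform of
#' the input leaves the result (and final stress) unchanged.
#'
#' @param dist_obj A [stats::dist] or symmetric matrix of dissimilarities.
#' @param k Number of ordination axes.
#' @param max_iter Maximum isotonic-regression/update iterations.
#' @param tol Convergence tolerance on the stress change.
#' @param seed Seed used only to break exact ties in the input distances by
#'   infinitesimal jitter (exact ties are rare on real data).
#' @return An object of class `nmds_result`: `points` (samples x k, centered),
#'   `stress` (Kruskal stress-1, on `[0, 1]`), `k`, `converged`.
#' @export
nmds <- function(dist_obj, k = 2, max_iter = 200, tol = 1e-4, seed = 1) {
  d <- as.dist(dist_obj)
  n <- attr(d, "Size")
  assert_that(k >= 1 && k < n, "Need 1 <= k < number of samples.")
  dv <- as.vector(d)
  if (anyDuplicated(dv)) {
    withr::local_seed(seed)
    eps <- min(diff(sort(unique(dv)))) * 1e-8
    d <- d + runif(length(dv), 0, eps)
  }
  init <- cmdscale(d, k = k)
  if (ncol(init) < k) {     # degenerate spectra: pad with tiny jitter
    withr::local_seed(seed)
    init <- cbind(init, matrix(rnorm(n * (k - ncol(init)), 0, 1e-6), n))
  }
  fit <- MASS::isoMDS(d, y = init, k = k, maxit = max_iter, trace = FALSE,
                      tol = tol)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(
    list(points = pts, stress = fit$stress / 100, k = k,
         converged = TRUE),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("<nmds_result> ", nrow(x$points), " samples, k = ", x$k,
      ", stress-1 = ", signif(x$stress, 4), "\n", sep = "")
  invisible(x)
}

#' Stress per dimensionality (scree table)
#'
#' Runs [nmds()] over a range of dimensionalities and reports stress per k,
#' plus an automatic elbow suggestion (largest second difference of the
#' stress curve). The suggestion is advisory: pick k from the scree curve.
#'
#' @param dist_obj Dissimilarities as for [nmds()].
#' @param k_range Integer vector of dimensionalities.
#' @param ... Passed to [nmds()].
#' @return Tibble with `k`, `stress`, `elbow` (logical flag on the suggested
#'   k).
#' @export
scree <- function(dist_obj, k_range = 1:5, ...) {
  out <- tibble::tibble(
    k = as.integer(k_range),
    stress = purrr::map_dbl(k_range, function(k) nmds(dist_obj, k,
                                                      ...)$stress)
  )
  out$elbow <- FALSE
  if (nrow(out) >= 3) {
    d2 <- diff(diff(out$stress))
    out$elbow[which.max(d2) + 1] <- TRUE
  }
  out
}

#' ANOVA of design factors on ordination axes
#'
#' Per axis: type-II ANOVA of `axis ~ organ * sex * species` (factors and
#' their interactions), with constant factors dropped and interaction terms
#' removed (with a warning) when the design aliases them — e.g. single-sex
#' organs alias organ x sex cells.
#'
#' @param result An [nmds()] result.
#' @param meta Sample metadata matching the configuration rows (by
#'   `sample_id`).
#' @return Tibble with `axis`, `term`, `sum_sq`, `df`, `statistic` (F), `p`.
#' @export
anova_on_axes <- function(result, meta) {
  stopifnot(inherits(result, "nmds_result"))
  meta <- tibble::as_tibble(meta)
  meta <- meta[match(rownames(result$points), meta$sample_id), , drop = FALSE]
  assert_that(!anyNA(meta$sample_id),
              "Metadata must cover every ordinated sample.")
  factors <- c("organ", "sex", "species")
  factors <- factors[purrr::map_lgl(factors,
                                    ~ length(unique(meta[[.x]])) > 1)]
  assert_that(length(factors) >= 1, "All design factors are constant.")
  dat <- as.data.frame(lapply(meta[factors], factor))
  purrr::map_dfr(seq_len(result$k), function(ax) {
    dat$.y <- result$points[, ax]
    form <- stats::reformulate(paste(factors, collapse = " * "),
                               response = ".y")
    fit <- lm(form, data = dat)
    if (anyNA(coef(fit))) {
      warn("Aliased design cells; interaction terms dropped.")
      form <- stats::reformulate(paste(factors, collapse = " + "),
                                 response = ".y")
      fit <- lm(form, data = dat)
    }
    a <- car::Anova(fit, type = 2)
    tibble::tibble(
      axis = ax, term = rownames(a),
      sum_sq = a[["Sum Sq"]], df = a[["Df"]],
      statistic = a[["F value"]], p = a[["Pr(>F)"]]
    )
  })
}

#' Mean silhouette width of a grouping on an ordination
#'
#' Measures how tightly samples cluster by a metadata factor in the
#' configuration space: the mean silhouette width of the grouping under
#' Euclidean distance on the ordination axes. Comparing the width by organ
#' with the width by species quantifies the "samples cluster by organ, not
#' by species" pattern.
#'
#' @param result An [nmds()] result.
#' @param meta Sample metadata (matched by `sample_id`).
#' @param group Metadata column to group by.
#' @return Mean silhouette width (scalar).
#' @export
silhouette_by <- function(result, meta, group) {
  stopifnot(inherits(result, "nmds_result"))
  meta <- meta[match(rownames(result$points), meta$sample_id), , drop = FALSE]
  g <- as.integer(factor(meta[[group]]))
  assert_that(length(unique(g)) >= 2, "Grouping must have >= 2 levels.")
  sil <- cluster::silhouette(g, dist(result$points))
  mean(sil[, "sil_width"])
}
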
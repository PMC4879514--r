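#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an NMDS result into a per-sample tibble
#'
#' @param x An [nmds()] result.
#' @param ... Ignored.
#' @return Tibble with `sample_id` and one column per axis.
#' @export
tidy.nmds_result <- function(x, ...) {
  tibble::as_tibble(x$points, rownames = "sample_id")
}

#' One-row summary of an NMDS fit
#'
#' @param x An [nmds()] result.
#' @param ... Ignored.
#' @return Tibble with `k`, `stress`, `n_samples`, `converged`.
#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(k = x$k, stress = x$stress,
                 n_samples = nrow(x$points), converged = x$converged)
}

#' Per-sample zFPKM fit parameters
#'
#' @param x A [zfpkm_transform()] result.
#' @param ... Ignored.
#' @return Tibble with `sample_id`, `mu_peak`, `sigma`, `bandwidth`.
#' @export
tidy.zfpkm_matrix <- function(x, ...) x$fits

#' One-row summary of a zFPKM matrix
#'
#' @param x A [zfpkm_transform()] result.
#' @param ... Ignored.
#' @return Tibble with gene/sample counts, cutoff and the overall expressed
#'   fraction.
#' @export
glance.zfpkm_matrix <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$z), n_samples = ncol(x$z), cutoff = x$cutoff,
    prop_expressed = mean(x$z >= x$cutoff)
  )
}

#' One-row summary of a P_ST scan
#'
#' @param x A `pst_scan` tibble.
#' @param ... Ignored.
#' @return Tibble with the organ, gene count, DE counts and median P_ST.
#' @export
glance.pst_scan <- function(x, ...) {
  tibble::tibble(
    organ = attr(x, "organ"), n_genes = nrow(x),
    n_de = sum(x$de), prop_de = mean(x$de),
    median_pst = median(x$pst, na.rm = TRUE),
    m = x$m[1]
  )
}
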
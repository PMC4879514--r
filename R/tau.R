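#' Organ-specificity index tau for one gene
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over the organ mean expression
#' vector: 0 for uniform expression over all N organs, 1 for single-organ
#' expression. Inputs must be non-negative; an all-zero vector gives `NA`.
#'
#' @param organ_means Non-negative numeric vector of per-organ mean
#'   expression (N >= 2).
#' @return tau in `[0, 1]` (or `NA` for an all-zero vector).
#' @examples
#' tau(c(1, 1, 1, 1))  # 0
#' tau(c(5, 0, 0, 0))  # 1
#' tau(c(4, 2, 0, 0))  # 2.5/3
#' @export
tau <- function(organ_means) {
  assert_that(length(organ_means) >= 2, "tau needs at least two organs.")
  if (any(organ_means < 0 | is.na(organ_means))) {
    abort("Organ means must be non-negative and non-missing.")
  }
  mx <- max(organ_means)
  if (mx == 0) return(NA_real_)
  sum(1 - organ_means / mx) / (length(organ_means) - 1)
}

#' Per-gene, per-species organ specificity
#'
#' Computes organ mean expression per gene within each species (means over
#' individuals), then tau per gene and species, plus expression breadth
#' `1 - tau`. By default means are taken on the linear FPKM-like scale
#' (`2^zFPKM`, sentinels giving 0), since tau assumes non-negative
#' intensities; `scale = "zfpkm"` instead uses zFPKM values floored at 0.
#'
#' @param z A [zfpkm_transform()] result.
#' @param scale `"linear"` (default) or `"zfpkm"`.
#' @param organs Organs to include (default: all with samples).
#' @return Tibble with `gene_id`, `species`, `tau`, `breadth`, `n_organs`,
#'   `max_organ` (the organ with highest mean expression).
#' @export
tau_table <- function(z, scale = c("linear", "zfpkm"), organs = NULL) {
  stopifnot(inherits(z, "zfpkm_matrix"))
  scale <- match.arg(scale)
  meta <- z$samples
  if (is.null(organs)) organs <- sort(unique(meta$organ))
  keep_organs <- organs[organs %in% meta$organ]
  if (length(keep_organs) < length(organs)) {
    warn(paste0("Organ(s) without samples dropped: ",
                paste(setdiff(organs, keep_organs), collapse = ", ")))
  }
  assert_that(length(keep_organs) >= 2, "tau needs >= 2 organs with samples.")
  vals <- if (scale == "linear") 2^z$z else pmax(z$z, 0)
  vals[!is.finite(vals)] <- 0
  purrr::map_dfr(sort(unique(meta$species)), function(sp) {
    means <- sapply(keep_organs, function(o) {
      cols <- meta$species == sp & meta$organ == o
      if (!any(cols)) return(rep(NA_real_, nrow(vals)))
      rowMeans(vals[, cols, drop = FALSE])
    })
    tau_v <- apply(means, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) NA_real_ else tau(x)
    })
    tibble::tibble(
      gene_id = rownames(vals), species = sp, tau = unname(tau_v),
      breadth = 1 - unname(tau_v), n_organs = length(keep_organs),
      max_organ = unname(keep_organs[apply(means, 1, which.max)])
    )
  })
}
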
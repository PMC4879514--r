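#' Genes expressed exclusively in one species
#'
#' A gene is unique to species S when at least `min_individuals` distinct
#' individuals of S have an expressed call in at least one organ, while the
#' other species shows zero expressed calls over all organs, individuals and
#' samples. Counting individuals (not samples) guards against single-library
#' artefacts; requiring complete absence in the other species makes the call
#' a presence/absence difference rather than a quantitative one.
#'
#' @param calls Logical genes x samples matrix from [call_expressed()].
#' @param meta Sample metadata (`sample_id`, `individual_id`, `species`,
#'   `organ`), matched to the matrix columns by `sample_id`.
#' @param min_individuals Minimum expressing individuals in the unique
#'   species (default 5).
#' @param same_organ If `TRUE`, the expressing individuals must share at
#'   least one organ; default `FALSE` (any organ counts).
#' @return Tibble with `gene_id`, `present_in`, `n_individuals_expressing`,
#'   `organs_expressing` (list-column).
#' @export
species_unique_genes <- function(calls, meta, min_individuals = 5,
                                 same_organ = FALSE) {
  meta <- tibble::as_tibble(meta)
  meta <- meta[match(colnames(calls), meta$sample_id), , drop = FALSE]
  species <- sort(unique(meta$species))
  assert_that(length(species) == 2, "Exactly two species required.")
  res <- purrr::map_dfr(1:2, function(i) {
    this <- meta$species == species[i]
    other_expressed <- rowSums(calls[, !this, drop = FALSE]) > 0
    m <- calls[, this, drop = FALSE]
    inds <- meta$individual_id[this]
    organs <- meta$organ[this]
    n_ind <- apply(m, 1, function(row) length(unique(inds[row])))
    if (same_organ) {
      max_per_organ <- apply(m, 1, function(row) {
        if (!any(row)) return(0L)
        max(tapply(inds[row], organs[row],
                   function(x) length(unique(x))))
      })
      enough <- max_per_organ >= min_individuals
    } else {
      enough <- n_ind >= min_individuals
    }
    flag <- enough & !other_expressed
    tibble::tibble(
      gene_id = rownames(calls)[flag],
      present_in = species[i],
      n_individuals_expressing = unname(n_ind[flag]),
      organs_expressing = purrr::map(which(flag), function(g) {
        sort(unique(organs[calls[g, this]]))
      })
    )
  })
  res
}

#' Overlap of expressed gene sets between species, per organ
#'
#' Counts, per organ, the genes expressed (in at least one individual) in
#' both species, in one only, or in neither.
#'
#' @inheritParams species_unique_genes
#' @return Tibble with `organ`, `both`, one column per species, `neither`.
#' @export
expressed_overlap <- function(calls, meta) {
  meta <- tibble::as_tibble(meta)
  meta <- meta[match(colnames(calls), meta$sample_id), , drop = FALSE]
  species <- sort(unique(meta$species))
  purrr::map_dfr(sort(unique(meta$organ)), function(o) {
    in_sp <- sapply(species, function(s) {
      cols <- meta$organ == o & meta$species == s
      if (!any(cols)) return(rep(NA, nrow(calls)))
      rowSums(calls[, cols, drop = FALSE]) > 0
    })
    out <- tibble::tibble(
      organ = o,
      both = sum(in_sp[, 1] & in_sp[, 2], na.rm = TRUE),
      neither = sum(!in_sp[, 1] & !in_sp[, 2], na.rm = TRUE)
    )
    out[[paste0("only_", species[1])]] <-
      sum(in_sp[, 1] & !in_sp[, 2], na.rm = TRUE)
    out[[paste0("only_", species[2])]] <-
      sum(!in_sp[, 1] & in_sp[, 2], na.rm = TRUE)
    out
  })
}

#' Screen coverage for fixed deletions
#'
#' Finds maximal runs of at least `min_region_windows` consecutive windows
#' with depth exactly zero in every individual of one species and positive
#' depth in every individual of the other — the signature of a deletion
#' fixed in one species. Windows with zero depth in all individuals of both
#' species are assembly gaps, not deletion evidence; they are excluded and
#' terminate runs, as do windows with missing depth for any individual.
#'
#' @param cov A [coverage_study()].
#' @param min_region_windows Minimum run length in windows (default 5, i.e.
#'   a 1-kb minimum callable deletion at 200-bp windows).
#' @return Tibble with `scaffold`, `start`, `end` (0-based half-open),
#'   `species_deleted`, `n_windows`, `n_zero_individuals`,
#'   `n_nonzero_other`, `exons_overlapped`, `coding_exons_overlapped`.
#' @export
deletion_screen <- function(cov, min_region_windows = 5) {
  stopifnot(inherits(cov, "coverage_study"))
  species <- sort(unique(cov$individual_species))
  assert_that(length(species) == 2, "Exactly two species required.")
  depth <- cov$depth
  complete <- colSums(is.na(depth)) == 0
  gap <- complete & colSums(depth > 0, na.rm = TRUE) == 0
  purrr::map_dfr(1:2, function(i) {
    del_rows <- cov$individual_species == species[i]
    all_zero <- complete &
      colSums(depth[del_rows, , drop = FALSE] > 0) == 0
    all_present <- complete &
      colSums(depth[!del_rows, , drop = FALSE] == 0) == 0
    evidence <- all_zero & all_present & !gap
    r <- rle(evidence)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    runs <- which(r$values & r$lengths >= min_region_windows)
    purrr::map_dfr(runs, function(j) {
      w0 <- starts_idx[j]
      w1 <- ends_idx[j]
      start <- cov$windows$start[w0]
      end <- cov$windows$end[w1]
      exons <- cov$gene_model
      n_ex <- 0L
      n_cod <- 0L
      if (!is.null(exons)) {
        hit <- exons$end > start & exons$start < end
        n_ex <- sum(hit)
        if ("coding" %in% names(exons)) n_cod <- sum(hit & exons$coding)
      }
      tibble::tibble(
        scaffold = cov$scaffold, start = start, end = end,
        species_deleted = species[i], n_windows = w1 - w0 + 1L,
        n_zero_individuals = sum(del_rows),
        n_nonzero_other = sum(!del_rows),
        exons_overlapped = n_ex, coding_exons_overlapped = n_cod
      )
    })
  })
}
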
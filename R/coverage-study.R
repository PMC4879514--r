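#' Build a coverage study from a depth matrix
#'
#' A coverage study holds per-individual read depth in uniform windows along
#' one scaffold, together with the species of each individual and (optionally)
#' a gene exon model. It feeds the fixed-deletion screen. All coordinates are
#' 0-based half-open (BED convention).
#'
#' @param depth Numeric matrix, individuals in rows (rownames = individual
#'   ids), windows in columns. `NA` marks windows without data (gaps are not
#'   zero depth).
#' @param windows Data frame with `start`, `end` per window (0-based
#'   half-open), same order as the matrix columns.
#' @param individual_species Named character vector or data frame
#'   (`individual_id`, `species`) giving each individual's species.
#' @param scaffold Scaffold label.
#' @param gene_model Optional data frame of exons: `start`, `end`, `coding`
#'   (logical), non-overlapping and sorted.
#' @return An object of class `coverage_study`.
#' @export
coverage_study <- function(depth, windows, individual_species,
                           scaffold = "scaffold_1", gene_model = NULL) {
  if (!is.matrix(depth) || is.null(rownames(depth))) {
    abort("`depth` must be a matrix with individual ids as rownames.")
  }
  if (any(depth < 0, na.rm = TRUE)) abort("Depths must be non-negative.")
  windows <- tibble::as_tibble(windows)
  assert_that(all(c("start", "end") %in% names(windows)),
              "`windows` needs `start` and `end` columns.")
  assert_that(nrow(windows) == ncol(depth),
              "One window row per depth column required.")
  sizes <- unique(windows$end - windows$start)
  if (length(sizes) != 1 || sizes <= 0) {
    abort("Windows must have one uniform positive size.")
  }
  ord <- order(windows$start)
  windows <- windows[ord, , drop = FALSE]
  depth <- depth[, ord, drop = FALSE]
  if (is.data.frame(individual_species)) {
    individual_species <- setNames(as.character(individual_species$species),
                                   individual_species$individual_id)
  }
  missing_sp <- setdiff(rownames(depth), names(individual_species))
  if (length(missing_sp) > 0) {
    abort(paste0("No species assignment for individual(s): ",
                 paste(missing_sp, collapse = ", ")))
  }
  if (!is.null(gene_model)) {
    gene_model <- tibble::as_tibble(gene_model)
    assert_that(all(c("start", "end") %in% names(gene_model)),
                "`gene_model` needs `start` and `end` columns.")
    gene_model <- gene_model[order(gene_model$start), , drop = FALSE]
    assert_that(all(gene_model$end > gene_model$start),
                "Exons must satisfy end > start.")
    if (nrow(gene_model) > 1) {
      assert_that(all(gene_model$start[-1] >=
                        gene_model$end[-nrow(gene_model)]),
                  "Exons must be non-overlapping.")
    }
  }
  structure(
    list(depth = depth, windows = windows,
         individual_species = individual_species[rownames(depth)],
         scaffold = scaffold, window_size = sizes, gene_model = gene_model),
    class = "coverage_study"
  )
}

#' @export
print.coverage_study <- function(x, ...) {
  cat("<coverage_study> ", x$scaffold, ": ", nrow(x$depth),
      " individuals x ", ncol(x$depth), " windows of ", x$window_size,
      " bp\n", sep = "")
  invisible(x)
}

#' Read windowed coverage from a BED-like TSV
#'
#' Rows are `(scaffold, start, end, individual, depth)` with a uniform window
#' size; coordinates 0-based half-open. Windows absent for an individual are
#' filled as missing (`NA`), not zero — missing data is not evidence of a
#' deletion.
#'
#' @param bed_like_path Path to the 5-column TSV (no header).
#' @param species_map Data frame with `individual_id`, `species`.
#' @param gene_model Optional exon table, see [coverage_study()].
#' @return A [coverage_study()].
#' @export
read_coverage <- function(bed_like_path, species_map, gene_model = NULL) {
  bed <- readr::read_tsv(
    bed_like_path,
    col_names = c("scaffold", "start", "end", "individual", "depth"),
    col_types = "ciicd", progress = FALSE
  )
  scaffolds <- unique(bed$scaffold)
  assert_that(length(scaffolds) == 1,
              "Coverage file must describe a single scaffold.")
  sizes <- unique(bed$end - bed$start)
  if (length(sizes) != 1) abort("Inconsistent window sizes in coverage file.")
  unknown <- setdiff(unique(bed$individual), species_map$individual_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown individual(s) in coverage file: ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(bed[c("individual", "start")])) {
    abort("Duplicated (individual, window) rows in coverage file.")
  }
  starts <- sort(unique(bed$start))
  individuals <- unique(bed$individual)
  depth <- matrix(NA_real_, nrow = length(individuals),
                  ncol = length(starts),
                  dimnames = list(individuals, NULL))
  depth[cbind(match(bed$individual, individuals),
              match(bed$start, starts))] <- bed$depth
  coverage_study(
    depth,
    tibble::tibble(start = starts, end = starts + sizes),
    species_map, scaffold = scaffolds, gene_model = gene_model
  )
}

#' Write a coverage study to a BED-like TSV
#'
#' Missing windows are omitted from the file (they are re-read as missing).
#'
#' @param cov A [coverage_study()].
#' @param path Output path.
#' @export
write_coverage <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_study"))
  long <- tidyr::expand_grid(
    individual = rownames(cov$depth),
    window = seq_len(ncol(cov$depth))
  )
  long$depth <- cov$depth[cbind(match(long$individual, rownames(cov$depth)),
                                long$window)]
  long <- long[!is.na(long$depth), , drop = FALSE]
  out <- tibble::tibble(
    scaffold = cov$scaffold,
    start = cov$windows$start[long$window],
    end = cov$windows$end[long$window],
    individual = long$individual,
    depth = long$depth
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(cov)
}
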
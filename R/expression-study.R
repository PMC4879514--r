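#' Build an expression study from an FPKM matrix and sample metadata
#'
#' An expression study bundles a genes x samples FPKM matrix with a sample
#' metadata table (individual, species, organ, sex). It is the universal input
#' of the pipeline: normalization, divergence scans, specificity and
#' ordination all start from it.
#'
#' @param fpkm Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids). All values must be non-negative FPKM.
#' @param samples Data frame with one row per sample and columns `sample_id`,
#'   `individual_id`, `species`, `organ`, `sex` (sex in `"F"`, `"M"`,
#'   `"unknown"`). Order need not match the matrix; samples are reconciled by
#'   id.
#' @return An object of class `expression_study`: a list with elements
#'   `fpkm` (matrix), `samples` (tibble, in matrix column order) and
#'   `genes` (character vector).
#' @examples
#' fpkm <- matrix(c(1, 0, 5, 2, 3, 1, 4, 8), nrow = 2,
#'                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
#' meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
#'                    individual_id = c("i1", "i2", "i1", "i2"),
#'                    species = c("A", "A", "B", "B"),
#'                    organ = "liver", sex = c("F", "M", "F", "M"))
#' expression_study(fpkm, meta)
#' @export
expression_study <- function(fpkm, samples) {
  if (!is.matrix(fpkm) || !is.numeric(fpkm)) {
    abort("`fpkm` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm))) {
    abort("`fpkm` must carry gene ids as rownames and sample ids as colnames.")
  }
  samples <- tibble::as_tibble(samples)
  required <- c("sample_id", "individual_id", "species", "organ", "sex")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- dplyr::mutate(samples, dplyr::across(dplyr::all_of(required),
                                                  as.character))
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    abort(paste0("Duplicated sample id(s): ", paste(dup, collapse = ", ")))
  }
  extra <- setdiff(colnames(fpkm), samples$sample_id)
  absent <- setdiff(samples$sample_id, colnames(fpkm))
  if (length(extra) > 0 || length(absent) > 0) {
    abort(paste0(
      "Matrix and metadata sample ids disagree.",
      if (length(extra)) paste0(" In matrix only: ",
                                paste(extra, collapse = ", "), ".") else "",
      if (length(absent)) paste0(" In metadata only: ",
                                 paste(absent, collapse = ", "), ".") else ""
    ))
  }
  if (anyDuplicated(rownames(fpkm))) {
    abort("Duplicated gene ids in the FPKM matrix.")
  }
  if (anyNA(fpkm)) abort("FPKM matrix contains missing values.")
  if (any(fpkm < 0)) {
    bad <- rownames(fpkm)[which(rowSums(fpkm < 0) > 0)]
    abort(paste0("Negative FPKM values for gene(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad_sex <- setdiff(unique(samples$sex), c("F", "M", "unknown"))
  if (length(bad_sex) > 0) {
    abort(paste0("Sex labels must be F, M or unknown; found: ",
                 paste(bad_sex, collapse = ", ")))
  }
  io <- paste(samples$individual_id, samples$organ, sep = "\r")
  if (anyDuplicated(io)) {
    dup <- samples$sample_id[duplicated(io) | duplicated(io, fromLast = TRUE)]
    abort(paste0("Each (individual, organ) pair may appear once; offending ",
                 "samples: ", paste(dup, collapse = ", ")))
  }
  samples <- samples[match(colnames(fpkm), samples$sample_id), , drop = FALSE]
  structure(
    list(fpkm = fpkm, samples = samples, genes = rownames(fpkm)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", nrow(x$fpkm), " genes x ", ncol(x$fpkm),
      " samples\n", sep = "")
  cat("  species: ", paste(sort(unique(x$samples$species)), collapse = ", "),
      "\n", sep = "")
  cat("  organs:  ", paste(sort(unique(x$samples$organ)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$fpkm)

#' Read an expression study from TSV files
#'
#' The matrix file is tab-delimited with a `gene_id` column followed by one
#' column per sample; the metadata file has one row per sample with columns
#' `sample_id`, `individual_id`, `species`, `organ`, `sex`.
#'
#' @param matrix_path Path to the FPKM matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An [expression_study()].
#' @seealso [write_expression_study()]
#' @export
read_expression_study <- function(matrix_path, metadata_path) {
  mat_df <- readr::read_tsv(matrix_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene_id" %in% names(mat_df)) {
    abort("Matrix TSV must have a `gene_id` first column.")
  }
  fpkm <- as.matrix(mat_df[setdiff(names(mat_df), "gene_id")])
  rownames(fpkm) <- mat_df$gene_id
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  expression_study(fpkm, meta)
}

#' Write an expression study to TSV files
#'
#' @param study An [expression_study()].
#' @inheritParams read_expression_study
#' @return Invisibly, `study`.
#' @export
write_expression_study <- function(study, matrix_path, metadata_path) {
  stopifnot(inherits(study, "expression_study"))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = study$genes),
                          tibble::as_tibble(study$fpkm))
  readr::write_tsv(out, matrix_path, progress = FALSE)
  readr::write_tsv(study$samples, metadata_path, progress = FALSE)
  invisible(study)
}

#' Subset an expression study by organ
#'
#' @param study An [expression_study()].
#' @param organ Organ label to keep.
#' @return An [expression_study()] restricted to the organ's samples.
#' @export
filter_organ <- function(study, organ) {
  keep <- study$samples$organ == organ
  if (!any(keep)) abort(paste0("No samples for organ `", organ, "`."))
  expression_study(study$fpkm[, keep, drop = FALSE],
                   study$samples[keep, , drop = FALSE])
}

#' Read a per-gene covariate table from TSV
#'
#' Columns: `gene_id`, `fst_upstream`, `dn`, `ds`, `interactions_metabolic`,
#' `interactions_complex`, `interactions_signalling`, `gene_length`, `gc`,
#' `chromosome`, `start`, `end`. Missing values are encoded as `.` or empty
#' and are kept as explicit `NA`, never zero. Coordinates are 0-based
#' half-open.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per gene.
#' @export
read_gene_covariates <- function(path) {
  cov <- readr::read_tsv(path, na = c("", ".", "NA"), col_types = readr::cols(
    gene_id = readr::col_character(),
    chromosome = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_gene_covariates(cov)
}

validate_gene_covariates <- function(cov) {
  cov <- tibble::as_tibble(cov)
  if (!"gene_id" %in% names(cov)) abort("Covariate table needs `gene_id`.")
  if (anyDuplicated(cov$gene_id)) abort("Duplicated gene ids in covariates.")
  if ("fst_upstream" %in% names(cov)) {
    bad <- !is.na(cov$fst_upstream) &
      (cov$fst_upstream < 0 | cov$fst_upstream > 1)
    if (any(bad)) abort("fst_upstream must lie in [0, 1].")
  }
  if (all(c("start", "end") %in% names(cov))) {
    bad <- !is.na(cov$start) & !is.na(cov$end) & cov$end <= cov$start
    if (any(bad)) abort("Gene coordinates must satisfy end > start.")
  }
  cov
}

#' Write a per-gene covariate table to TSV
#'
#' @param covariates Tibble as returned by [simulate_covariates()] or
#'   [read_gene_covariates()].
#' @param path Output path; missing values are written as `.`.
#' @export
write_gene_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, na = ".", progress = FALSE)
  invisible(covariates)
}
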
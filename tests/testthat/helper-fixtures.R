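# small in-code fixtures shared across test files

make_tiny_study <- function() {
  fpkm <- matrix(
    c(1, 0, 5, 2,
      3, 1, 4, 8,
      0.5, 0.7, 0.9, 1.1),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4"))
  )
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    individual_id = c("i1", "i2", "i3", "i4"),
    species = c("A", "A", "B", "B"),
    organ = "liver",
    sex = c("F", "M", "F", "M")
  )
  expression_study(fpkm, meta)
}

# a hand-built zfpkm_matrix for white-box unit tests of downstream stages
make_manual_z <- function(z, meta, cutoff = 0.125) {
  structure(
    list(z = z,
         fits = tibble::tibble(sample_id = colnames(z), mu_peak = 0,
                               sigma = 1, bandwidth = 1),
         cutoff = cutoff,
         samples = tibble::as_tibble(meta)),
    class = "zfpkm_matrix"
  )
}

# metadata for a one-organ, two-species design with one sample per individual
balanced_meta <- function(n_per_species, organ = "liver") {
  n <- 2 * n_per_species
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    individual_id = paste0("i", seq_len(n)),
    species = rep(c("A", "B"), each = n_per_species),
    organ = organ,
    sex = rep(rep(c("F", "M"), length.out = n_per_species), 2)
  )
}
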
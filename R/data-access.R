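# Bundled plain-text data.

#' Published extreme-pool codon counts for Bombyx mori
#'
#' The pooled codon usage of the putatively highly and lowly expressed gene
#' sets (axis-1 ordination extremes) reported for the silkworm
#' transcriptome, as printed: per codon, the count and RSCU in each pool
#' and whether the codon was reported optimal. Shipped as the package's
#' worked-example input: recomputing pooled RSCU and the chi-squared
#' optimal-codon test from the `n_high`/`n_low` columns reproduces the
#' printed `rscu_high`/`rscu_low` values and optimal flags.
#'
#' @return A tibble with columns `amino_acid` (three-letter, `TER` for
#'   stop), `codon` (DNA), `codon_rna` (as printed), `rscu_high`, `n_high`,
#'   `rscu_low`, `n_low`, `optimal_reported`.
#' @examples
#' pools <- bmori_pool_counts()
#' ala <- pools[pools$amino_acid == "Ala", ]
#' rscu(stats::setNames(ala$n_high, ala$codon))
#' @export
bmori_pool_counts <- function() {
  path <- system.file("extdata", "bmori_extreme_pool_counts.tsv",
                      package = "codonscope", mustWork = TRUE)
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = "ccdidil")
  out$optimal_reported <- as.logical(out$optimal_reported)
  dplyr::mutate(out,
                codon_rna = .data$codon,
                codon = stringr::str_replace_all(.data$codon, "U", "T"),
                .after = "codon")
}
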
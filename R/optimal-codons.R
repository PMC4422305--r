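# Identification of translationally optimal codons: pooling of axis-1
# extreme gene sets and the per-codon 2x2 chi-squared contingency test.

#' Select the ordination-extreme gene pools
#'
#' Ranks genes by their coordinate on the first correspondence-analysis axis
#' and takes the two tails of size `ceiling(fraction * n)`. The tail whose
#' pooled mean ENc is lower is labelled `high` (putatively highly
#' expressed), the other `low`. Ties in the axis coordinate at the cutoff
#' are broken by gene id in lexicographic order, so pool membership is
#' deterministic.
#'
#' @param ordination A `codon_ca` object from [correspondence_analysis()]
#'   run on the gene RSCU matrix.
#' @param metrics Per-gene metrics tibble with `id` and `enc` columns.
#' @param fraction Tail fraction in `(0, 0.5]` (default 0.05).
#' @return A list with `high` and `low` (character vectors of gene ids) and
#'   `summary` (tibble: pool, n, mean_enc, mean_axis1).
#' @export
select_extreme_pools <- function(ordination, metrics, fraction = 0.05) {
  stopifnot(inherits(ordination, "codon_ca"), fraction > 0, fraction <= 0.5)
  ax1 <- ordination$row_coords[, 1]
  ids <- rownames(ordination$row_coords)
  n_tail <- ceiling(fraction * length(ids))
  if (n_tail < 1) stop("fraction too small: empty tail", call. = FALSE)
  bottom <- ids[order(ax1, ids)][seq_len(n_tail)]
  top <- ids[order(-ax1, ids)][seq_len(n_tail)]
  enc_by_id <- stats::setNames(metrics$enc, metrics$id)
  mean_enc <- function(g) mean(enc_by_id[g], na.rm = TRUE)
  if (mean_enc(top) <= mean_enc(bottom)) {
    high <- top; low <- bottom
  } else {
    high <- bottom; low <- top
  }
  summary <- tibble::tibble(
    pool = c("high", "low"),
    n = c(length(high), length(low)),
    mean_enc = c(mean_enc(high), mean_enc(low)),
    mean_axis1 = c(mean(ax1[high]), mean(ax1[low]))
  )
  list(high = high, low = low, summary = summary)
}

#' Chi-squared identification of optimal codons
#'
#' For each sense codon c in a synonymous family A, a 2x2 contingency table
#' is formed — counts of c versus the other synonyms of A, in the high- and
#' low-expression pools — and tested with Pearson's chi-squared (no
#' continuity correction by default). A codon is flagged optimal iff
#' `p < alpha` *and* its relative synonymous frequency is higher in the
#' high pool. Met and Trp (single-codon families) are never optimal; stop
#' codons are excluded from testing unless `include_stops = TRUE`. Codons
#' of a family absent from either pool are reported untestable.
#'
#' @param high,low Codon counts of the pooled high- and low-expression gene
#'   sets: tibbles with `codon`/`count` columns or named numeric vectors.
#' @param alpha Significance level (default 0.01).
#' @param correct Apply Yates continuity correction? Default `FALSE`.
#' @param include_stops Also test stop codons? Default `FALSE`.
#' @return A tibble of class `optimal_codon_table` with one row per tested
#'   codon: `amino_acid`, `codon`, `rscu_high`, `n_high`, `rscu_low`,
#'   `n_low`, `chi2`, `p`, `testable`, `optimal`.
#' @export
chi2_optimal <- function(high, low, alpha = 0.01, correct = FALSE,
                         include_stops = FALSE) {
  hc <- as_codon_counts(high)
  lc <- as_codon_counts(low)
  if (sum(hc) == 0 || sum(lc) == 0) {
    stop("both pools must contain codons", call. = FALSE)
  }
  tab <- dplyr::inner_join(
    dplyr::rename(rscu(hc, include_stops = include_stops),
                  rscu_high = "rscu", n_high = "count"),
    dplyr::rename(rscu(lc, include_stops = include_stops),
                  rscu_low = "rscu", n_low = "count"),
    by = c("amino_acid", "codon")
  )
  fam_high <- as.numeric(tapply(tab$n_high, tab$amino_acid, sum)[tab$amino_acid])
  fam_low <- as.numeric(tapply(tab$n_low, tab$amino_acid, sum)[tab$amino_acid])
  k <- unname(AA_DEGENERACY[tab$amino_acid])
  k[is.na(k)] <- 3L  # stop codons, when included, form their own 3-family
  res <- purrr::pmap(
    list(tab$n_high, tab$n_low, fam_high, fam_low, k),
    function(nh, nl, fh, fl, deg) {
      if (deg < 2 || fh == 0 || fl == 0 || (fh - nh) + (fl - nl) == 0) {
        return(list(chi2 = NA_real_, p = NA_real_, testable = FALSE))
      }
      m <- matrix(c(nh, fh - nh, nl, fl - nl), nrow = 2, byrow = TRUE)
      ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
      list(chi2 = unname(ct$statistic), p = ct$p.value, testable = TRUE)
    })
  tab$chi2 <- purrr::map_dbl(res, "chi2")
  tab$p <- purrr::map_dbl(res, "p")
  tab$testable <- purrr::map_lgl(res, "testable")
  tab$optimal <- tab$testable & !is.na(tab$p) & tab$p < alpha &
    (tab$n_high / fam_high) > (tab$n_low / fam_low) &
    !tab$amino_acid %in% c("M", "W", "*")
  out <- dplyr::select(tab, "amino_acid", "codon", "rscu_high", "n_high",
                       "rscu_low", "n_low", "chi2", "p", "testable",
                       "optimal")
  class(out) <- c("optimal_codon_table", class(out))
  out
}

#' Plot optimal-codon RSCU contrast
#'
#' RSCU in the high-expression pool against RSCU in the low pool, optimal
#' codons highlighted; the diagonal marks equal usage.
#'
#' @param object An `optimal_codon_table` from [chi2_optimal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimal_codon_table <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$testable)
  ggplot2::ggplot(d, ggplot2::aes(.data$rscu_low, .data$rscu_high,
                                  colour = .data$optimal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "RSCU (low pool)", y = "RSCU (high pool)",
                  colour = "Optimal") +
    ggplot2::theme_minimal()
}
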
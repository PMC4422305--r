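# Correspondence analysis of codon usage: RSCU matrix and amino-acid usage
# matrix construction, classical CA via SVD of standardized residuals, and
# the GC-content gene classification used to colour ordination plots.

#' Genes x synonymous-codon RSCU matrix
#'
#' Builds the 59-column RSCU matrix that correspondence analysis of codon
#' usage operates on: the 61 sense codons minus the single-codon Met and Trp
#' families, so that variation caused by unequal amino-acid usage is
#' removed. Columns are in a fixed order (amino acid alphabetical, codon
#' alphabetical within family; see [SYNONYMOUS_CODONS] via `colnames`).
#' Undefined RSCU values — families absent from a gene — are set to 0 so the
#' gene set stays identical across analysis stages.
#'
#' @param seqs Tibble of QC-passed sequences (`id`, `seq`).
#' @return A numeric matrix, genes x 59 codons, rownames = gene ids.
#' @export
build_rscu_matrix <- function(seqs) {
  if (nrow(seqs) == 0) stop("no genes to build an RSCU matrix from",
                            call. = FALSE)
  m <- codon_count_matrix(seqs)
  aa <- GENETIC_CODE_DNA[SYNONYMOUS_CODONS]
  out <- matrix(0, nrow(m), length(SYNONYMOUS_CODONS),
                dimnames = list(rownames(m), SYNONYMOUS_CODONS))
  for (a in unique(aa)) {
    cods <- SYNONYMOUS_CODONS[aa == a]
    sub <- m[, cods, drop = FALSE]
    tot <- rowSums(sub)
    nz <- tot > 0
    out[nz, cods] <- length(cods) * sub[nz, , drop = FALSE] / tot[nz]
  }
  out
}

#' Genes x amino-acid usage matrix
#'
#' Per-gene relative amino-acid frequencies of the conceptual translation
#' (stop codons excluded); rows sum to 1. Used for correspondence analysis
#' of amino-acid usage.
#'
#' @inheritParams build_rscu_matrix
#' @return A numeric matrix, genes x 20 amino acids (single-letter codes,
#'   alphabetical).
#' @export
build_aa_matrix <- function(seqs) {
  if (nrow(seqs) == 0) stop("no genes to build an amino-acid matrix from",
                            call. = FALSE)
  m <- codon_count_matrix(seqs)
  aa <- GENETIC_CODE_DNA[SENSE_CODONS]
  aas <- sort(unique(aa))
  out <- vapply(aas, function(a) {
    rowSums(m[, SENSE_CODONS[aa == a], drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), aas))
  out / rowSums(out)
}

#' Correspondence analysis of a usage matrix
#'
#' Classical correspondence analysis of a non-negative table (RSCU values or
#' amino-acid frequencies): with P the table divided by its grand total, row
#' masses r and column masses c, the standardized residuals
#' `S = D_r^(-1/2) (P - r c') D_c^(-1/2)` are decomposed by SVD; principal
#' coordinates are the mass-scaled singular vectors times the singular
#' values, and the inertia fraction of axis i is `sigma_i^2 / sum(sigma^2)`.
#' Total inertia equals the table's chi-squared statistic divided by its
#' grand total.
#'
#' All-zero rows or columns are dropped with a warning. Because CA axis
#' signs are arbitrary, each axis is oriented so that the column with the
#' largest absolute coordinate on it is positive, making runs reproducible.
#'
#' @param x Non-negative numeric matrix with row and column names, e.g. from
#'   [build_rscu_matrix()] or [build_aa_matrix()].
#' @param n_axes Number of axes to retain (default 20, truncated to the
#'   number of non-trivial dimensions).
#' @return An object of class `codon_ca`: a list with `row_coords` and
#'   `col_coords` (principal-coordinate matrices), `sv` (singular values),
#'   `inertia` (tibble with `axis`, `eigenvalue`, `fraction`, `cumulative`),
#'   `total_inertia`, and `dropped` (names of removed rows/columns).
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
correspondence_analysis <- function(x, n_axes = 20) {
  stopifnot(is.matrix(x), n_axes >= 1)
  if (any(x < 0)) stop("usage matrix must be non-negative", call. = FALSE)
  dropped <- c(rownames(x)[rowSums(x) == 0], colnames(x)[colSums(x) == 0])
  if (length(dropped) > 0) {
    warning("dropping all-zero rows/columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  }
  total <- sum(x)
  if (total <= 0) stop("usage matrix has zero grand total", call. = FALSE)
  p <- x / total
  r <- rowSums(p)
  cm <- colSums(p)
  s <- (p - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  dec <- svd(s)
  keep <- which(dec$d > 1e-12)
  k <- min(n_axes, length(keep), min(dim(x)) - 1L)
  k <- max(k, 1L)
  sv <- dec$d[seq_len(k)]
  row_coords <- (dec$u[, seq_len(k), drop = FALSE] / sqrt(r)) %*% diag(sv, k)
  col_coords <- (dec$v[, seq_len(k), drop = FALSE] / sqrt(cm)) %*% diag(sv, k)
  # orient each axis: largest-|loading| column positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(col_coords[, j]))
    if (col_coords[lead, j] < 0) {
      col_coords[, j] <- -col_coords[, j]
      row_coords[, j] <- -row_coords[, j]
    }
  }
  dimnames(row_coords) <- list(rownames(x), paste0("axis", seq_len(k)))
  dimnames(col_coords) <- list(colnames(x), paste0("axis", seq_len(k)))
  ev_all <- dec$d[dec$d > 1e-12]^2
  total_inertia <- sum(ev_all)
  inertia <- tibble::tibble(
    axis = seq_len(k),
    eigenvalue = sv^2,
    fraction = if (total_inertia > 0) sv^2 / total_inertia else rep(0, k),
    cumulative = cumsum(if (total_inertia > 0) sv^2 / total_inertia
                        else rep(0, k))
  )
  structure(
    list(row_coords = row_coords, col_coords = col_coords, sv = sv,
         inertia = inertia, total_inertia = total_inertia, dropped = dropped),
    class = "codon_ca"
  )
}

#' @export
print.codon_ca <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns,", length(x$sv), "axes retained\n")
  cat("Total inertia:", signif(x$total_inertia, 6), "\n")
  f <- x$inertia$fraction[seq_len(min(4, nrow(x$inertia)))]
  cat("Axis inertia fractions:",
      paste(sprintf("%.2f%%", 100 * f), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a correspondence analysis
#'
#' @param x A `codon_ca` object.
#' @param matrix One of `"rows"` (gene coordinates), `"cols"` (codon or
#'   amino-acid coordinates) or `"inertia"` (per-axis inertia table).
#' @param ... Unused.
#' @return A tibble. For coordinates, one row per gene/column with `id` and
#'   `axis1..axisK`; for `"inertia"`, the per-axis eigenvalue and fraction.
#' @export
tidy.codon_ca <- function(x, matrix = c("rows", "cols", "inertia"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "inertia") return(x$inertia)
  m <- if (matrix == "rows") x$row_coords else x$col_coords
  dplyr::bind_cols(tibble::tibble(id = rownames(m)),
                   tibble::as_tibble(m))
}

#' @rdname tidy.codon_ca
#' @export
glance.codon_ca <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$row_coords),
    n_cols = nrow(x$col_coords),
    n_axes = length(x$sv),
    total_inertia = x$total_inertia,
    axis1_fraction = x$inertia$fraction[1],
    axis2_fraction = if (nrow(x$inertia) >= 2) x$inertia$fraction[2]
                     else NA_real_
  )
}

#' Classify genes into low/mid/high GC categories
#'
#' Half-open intervals: `low` for GC < breaks[1], `mid` for
#' breaks[1] <= GC < breaks[2], `high` for GC >= breaks[2]. The defaults
#' (45% and 60%) are the conventional cut points for colouring codon-usage
#' ordination plots.
#'
#' @param gc Numeric vector of GC fractions in `[0, 1]`.
#' @param breaks Two cut points, default `c(0.45, 0.60)`.
#' @return A factor with levels `low`, `mid`, `high`.
#' @export
classify_gc <- function(gc, breaks = c(0.45, 0.60)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  cut(gc, breaks = c(-Inf, breaks, Inf), labels = c("low", "mid", "high"),
      right = FALSE)
}

#' Plot a correspondence analysis
#'
#' Scatter of the first two principal axes. For gene (row) coordinates a
#' `colour_by` vector (e.g. the GC class from [classify_gc()]) can be
#' supplied; column plots are coloured by the codon's third base when the
#' columns are codons.
#'
#' @param object A `codon_ca` object.
#' @param matrix `"rows"` or `"cols"`.
#' @param colour_by Optional vector (recycled against the plotted rows) used
#'   as the colour aesthetic.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_ca <- function(object, matrix = c("rows", "cols"),
                              colour_by = NULL, ...) {
  matrix <- match.arg(matrix)
  d <- tidy.codon_ca(object, matrix = matrix)
  if (ncol(d) < 3) stop("need at least two axes to plot", call. = FALSE)
  if (is.null(colour_by) && matrix == "cols" &&
      all(d$id %in% CODONS)) {
    colour_by <- substring(d$id, 3, 3)
  }
  lab <- function(i) sprintf("Axis %d (%.2f%% of inertia)", i,
                             100 * object$inertia$fraction[i])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$axis1, .data$axis2))
  if (!is.null(colour_by)) {
    d$colour_by <- colour_by
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$axis1, .data$axis2,
                                         colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}
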
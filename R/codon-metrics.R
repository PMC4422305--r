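# Per-gene and pooled codon-usage indices: codon counts, RSCU, GC
# partitions, silent-site base composition, Wright's ENc and its
# GC3s-expected value, CAI, GRAVY and aromaticity.

#' Per-gene codon count matrix
#'
#' Counts in-frame triplets from position 1 for every sequence. The terminal
#' stop codon, when present, is excluded from counting (it is still part of
#' `length_nt`). In-frame internal stop codons, which QC-passed sequences do
#' not contain, would be counted as-is.
#'
#' @param seqs Tibble with `id` and `seq` columns; every sequence length must
#'   be a multiple of 3.
#' @param drop_terminal_stop Drop the final codon when it is a stop codon
#'   (default `TRUE`).
#' @return An integer matrix, genes in rows (named by `id`), the 64 codons in
#'   columns in [CODONS] order.
#' @export
codon_count_matrix <- function(seqs, drop_terminal_stop = TRUE) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  bad <- nchar(seqs$seq) %% 3L != 0L
  if (any(bad)) {
    stop("sequence length not a multiple of 3 for: ",
         paste(utils::head(seqs$id[bad], 5), collapse = ", "), call. = FALSE)
  }
  m <- t(vapply(seqs$seq, function(s) {
    cod <- codon_split(s)
    k <- length(cod)
    if (drop_terminal_stop && k > 0 && cod[k] %in% STOP_CODONS) {
      cod <- cod[-k]
    }
    tabulate(factor(cod, levels = CODONS), nbins = length(CODONS))
  }, integer(length(CODONS)), USE.NAMES = FALSE))
  dimnames(m) <- list(seqs$id, CODONS)
  m
}

#' Count codons in a gene or pooled gene set
#'
#' Pooled counting over one or more coding sequences; pooling simply sums the
#' per-gene counts. The terminal stop codon of each gene is excluded.
#'
#' @inheritParams codon_count_matrix
#' @return A tibble with columns `amino_acid`, `codon`, `count`, in
#'   [CODONS] order, one row per codon (64 rows). The total number of
#'   counted codons is `sum(.$count)`.
#' @examples
#' count_codons(tibble::tibble(id = "g", seq = "ATGAAATAA"))
#' @export
count_codons <- function(seqs, drop_terminal_stop = TRUE) {
  m <- codon_count_matrix(seqs, drop_terminal_stop = drop_terminal_stop)
  tibble::tibble(
    amino_acid = unname(GENETIC_CODE_DNA[CODONS]),
    codon = CODONS,
    count = as.integer(colSums(m))
  )
}

#' Relative synonymous codon usage
#'
#' For a codon `c` in a `k`-fold synonymous family with family total `T`,
#' RSCU(c) = k * count(c) / T: the ratio of observed to expected frequency
#' under uniform synonymous usage. Within every observed family the RSCU
#' values sum to the family's degeneracy. Families with `T = 0` yield `NA`.
#' Met and Trp (single-codon families) have RSCU 1 when present. Stop codons
#' are excluded by default but computed the same way over the three stop
#' codons when `include_stops = TRUE`.
#'
#' @param counts Codon counts: a tibble with `codon` and `count` columns (as
#'   from [count_codons()]) or a named numeric vector.
#' @param include_stops Also report stop-codon RSCU? Default `FALSE`.
#' @return A tibble with columns `amino_acid`, `codon`, `count`, `rscu`.
#' @examples
#' rscu(c(GCT = 288, GCC = 818, GCA = 133, GCG = 575))
#' @export
rscu <- function(counts, include_stops = FALSE) {
  cnt <- as_codon_counts(counts)
  tab <- codon_table(include_stops = include_stops)
  tab$count <- unname(cnt[tab$codon])
  dplyr::mutate(
    dplyr::group_by(tab, .data$amino_acid),
    family_total = sum(.data$count),
    rscu = ifelse(.data$family_total > 0,
                  dplyr::n() * .data$count / .data$family_total, NA_real_)
  ) |>
    dplyr::ungroup() |>
    dplyr::select("amino_acid", "codon", "count", "rscu")
}

#' GC content by codon position
#'
#' Fractions of G or C at each codon position over all counted codons,
#' their mean, and GC12 (the mean of GC1 and GC2 used by the neutrality
#' plot).
#'
#' @inheritParams rscu
#' @return A one-row tibble with `gc`, `gc1`, `gc2`, `gc3`, `gc12` (fractions
#'   in `[0, 1]`).
#' @export
gc_partitions <- function(counts) {
  cnt <- as_codon_counts(counts)
  n <- sum(cnt)
  if (n == 0) stop("empty codon count table: GC content undefined",
                   call. = FALSE)
  gcp <- vapply(BASE_AT_POS, function(ind) {
    sum(cnt * (ind[, "G"] + ind[, "C"])) / n
  }, numeric(1))
  tibble::tibble(gc = mean(gcp), gc1 = gcp[1], gc2 = gcp[2], gc3 = gcp[3],
                 gc12 = (gcp[1] + gcp[2]) / 2)
}

#' Base composition at synonymous third positions
#'
#' Computed over codons that belong to synonymous families only (Met, Trp
#' and stops excluded). Two denominators are available:
#'
#' * `"simple"` (default): `x3s` is the fraction of synonymous-family codons
#'   carrying base x at position 3, so `a3s + t3s + c3s + g3s = 1`.
#' * `"codonw"`: per-base opportunity denominator in the style of codonW —
#'   for base x, only codons of families in which some synonym ends in x are
#'   counted in the denominator; the four values then need not sum to 1.
#'
#' `gc3s` is always the simple G+C fraction at synonymous third positions
#' (the quantity the expected-ENc curve is parameterised by).
#'
#' @inheritParams rscu
#' @param method `"simple"` or `"codonw"` (see Details).
#' @return A one-row tibble with `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`.
#' @export
silent_composition <- function(counts, method = c("simple", "codonw")) {
  method <- match.arg(method)
  cnt <- as_codon_counts(counts)[SYNONYMOUS_CODONS]
  n_syn <- sum(cnt)
  if (n_syn == 0) {
    stop("no synonymous-family codons: silent composition undefined",
         call. = FALSE)
  }
  third <- substring(SYNONYMOUS_CODONS, 3, 3)
  by_base <- vapply(c("A", "T", "C", "G"),
                    function(b) sum(cnt[third == b]), numeric(1))
  gc3s <- unname(by_base["C"] + by_base["G"]) / n_syn
  if (method == "simple") {
    comp <- by_base / n_syn
  } else {
    aa <- GENETIC_CODE_DNA[SYNONYMOUS_CODONS]
    comp <- vapply(c("A", "T", "C", "G"), function(b) {
      fams <- unique(aa[third == b])
      denom <- sum(cnt[aa %in% fams])
      if (denom == 0) NA_real_ else unname(by_base[b]) / denom
    }, numeric(1))
  }
  tibble::tibble(gc3s = gc3s, a3s = comp[["A"]], t3s = comp[["T"]],
                 c3s = comp[["C"]], g3s = comp[["G"]])
}

#' Effective number of codons (Wright's ENc)
#'
#' Wright's estimator of how far a gene departs from uniform synonymous
#' usage: 20 means one codon per amino acid (extreme bias), 61 means no
#' bias. For each amino acid with degeneracy k > 1 and n >= 2 observed
#' codons, the codon homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1); F
#' values are averaged within degeneracy classes (2-, 3-, 4-, 6-fold) and
#' ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61.
#'
#' Conventions follow codonW: F values of exactly 0 are excluded from their
#' class average; if the single 3-fold family (Ile) is unusable its class
#' average is imputed as (F2 + F4) / 2; if any other class average is
#' missing or 0 the estimator is undefined and `NA` is returned.
#'
#' @inheritParams rscu
#' @return A single numeric value in `[20, 61]`, or `NA` when the estimator
#'   is undefined for the input.
#' @references Wright F (1990) The 'effective number of codons' used in a
#'   gene. Gene 87:23-29.
#' @export
enc <- function(counts) {
  cnt <- as_codon_counts(counts)
  aa <- GENETIC_CODE_DNA[SYNONYMOUS_CODONS]
  f_by_aa <- vapply(unique(aa), function(a) {
    x <- cnt[SYNONYMOUS_CODONS[aa == a]]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  deg <- AA_DEGENERACY[unique(aa)]
  class_mean <- vapply(c(2, 3, 4, 6), function(k) {
    f <- f_by_aa[deg == k]
    f <- f[!is.na(f) & f > 0]  # codonW: F == 0 excluded from the average
    if (length(f) == 0) NA_real_ else mean(f)
  }, numeric(1))
  names(class_mean) <- c("F2", "F3", "F4", "F6")
  if (is.na(class_mean["F3"])) {
    if (is.na(class_mean["F2"]) || is.na(class_mean["F4"])) return(NA_real_)
    class_mean["F3"] <- (class_mean["F2"] + class_mean["F4"]) / 2
  }
  if (anyNA(class_mean)) return(NA_real_)
  out <- 2 + 9 / class_mean["F2"] + 1 / class_mean["F3"] +
    5 / class_mean["F4"] + 3 / class_mean["F6"]
  unname(min(out, 61))
}

#' Expected ENc under G+C mutation bias alone
#'
#' The expected effective number of codons for a gene whose codon choice is
#' constrained only by a G+C bias at synonymous third positions:
#' `ENc = 2 + S + 29 / (S^2 + (1 - S)^2)` with S = GC3s. Genes falling well
#' below this curve are candidates for forces beyond mutation bias.
#'
#' @param gc3s Numeric vector of GC3s values in `[0, 1]`.
#' @return Expected ENc, same length as `gc3s`.
#' @export
expected_enc <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    stop("gc3s must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative adaptiveness weights for the codon adaptation index
#'
#' Pools the codon counts of a reference set of highly expressed genes
#' (classically, ribosomal-protein genes) and derives Sharp & Li relative
#' adaptiveness values: within each synonymous family,
#' `w(c) = RSCU(c) / max RSCU`, so the most used synonym has weight 1.
#' Codons unobserved in the reference receive the floor weight (default
#' 0.01) to keep `log(w)` finite; a family entirely absent from the
#' reference gets the floor for all its codons, with a warning. Met, Trp
#' and stop codons carry no weight (they are excluded from CAI).
#'
#' @param reference Reference sequences (tibble with `id`, `seq`) or a codon
#'   count input accepted by [rscu()].
#' @param floor Weight assigned to reference-absent codons (default 0.01).
#' @return A tibble with columns `amino_acid`, `codon`, `w`, attribute
#'   `source_ids` carrying the reference gene ids when sequences were given.
#' @export
cai_weights <- function(reference, floor = 0.01) {
  source_ids <- character()
  if (is.data.frame(reference) && "seq" %in% names(reference)) {
    source_ids <- reference$id
    counts <- count_codons(reference)
  } else {
    counts <- reference
  }
  r <- rscu(counts, include_stops = FALSE)
  r <- dplyr::filter(r, !.data$codon %in% c("ATG", "TGG"))
  out <- dplyr::mutate(
    dplyr::group_by(r, .data$amino_acid),
    w = ifelse(is.na(.data$rscu) | .data$rscu == 0, floor,
               .data$rscu / max(.data$rscu))
  ) |>
    dplyr::ungroup() |>
    dplyr::select("amino_acid", "codon", "w")
  absent <- unique(r$amino_acid[is.na(r$rscu)])
  if (length(absent) > 0) {
    warning("amino-acid families absent from CAI reference (floored): ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  attr(out, "source_ids") <- source_ids
  out
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness values of a gene's codons,
#' excluding Met, Trp and stop codons:
#' `CAI = exp(sum(n_c * log(w_c)) / sum(n_c))`. Values near 1 indicate codon
#' usage matching the highly expressed reference set.
#'
#' @inheritParams rscu
#' @param weights A weight table from [cai_weights()].
#' @return A single numeric value in `(0, 1]`, or `NA` when the gene has no
#'   eligible codons.
#' @references Sharp PM, Li WH (1987) The codon adaptation index. Nucleic
#'   Acids Res 15:1281-1295.
#' @export
cai <- function(counts, weights) {
  cnt <- as_codon_counts(counts)[weights$codon]
  n <- sum(cnt)
  if (n == 0) return(NA_real_)
  exp(sum(cnt * log(weights$w)) / n)
}

# amino-acid counts from a codon-count vector, stops dropped
aa_counts_from_codons <- function(cnt) {
  aa <- GENETIC_CODE_DNA[SENSE_CODONS]
  vapply(split(cnt[SENSE_CODONS], aa), sum, numeric(1))
}

#' General average hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy of the conceptual translation (stop codons
#' excluded). Negative values indicate hydrophilic products.
#'
#' @inheritParams rscu
#' @return A single numeric value.
#' @export
gravy <- function(counts) {
  aa <- aa_counts_from_codons(as_codon_counts(counts))
  n <- sum(aa)
  if (n == 0) stop("no sense codons: GRAVY undefined", call. = FALSE)
  sum(aa * KD_HYDROPATHY[names(aa)]) / n
}

#' Aromaticity of the translated product
#'
#' Fraction of residues in the conceptual translation that are aromatic
#' (Phe, Tyr, Trp).
#'
#' @inheritParams rscu
#' @return A single numeric value in `[0, 1]`.
#' @export
aromo <- function(counts) {
  aa <- aa_counts_from_codons(as_codon_counts(counts))
  n <- sum(aa)
  if (n == 0) stop("no sense codons: aromaticity undefined", call. = FALSE)
  sum(aa[names(aa) %in% AROMATIC_AA]) / n
}

#' Per-gene codon-usage metrics table
#'
#' The package's main per-gene driver: computes every index for each
#' QC-passed sequence — length, codon total, GC partitions, silent-site base
#' composition, ENc, expected ENc, CAI (when a reference is supplied), GRAVY
#' and aromaticity — in one tidy table, one row per gene.
#'
#' @param seqs Tibble of QC-passed sequences (`id`, `seq`).
#' @param reference Optional CAI reference: sequences tibble, count input, or
#'   a precomputed weight table from [cai_weights()]. When `NULL`, the `cai`
#'   column is `NA`.
#' @param silent_method Denominator convention for [silent_composition()].
#' @return A tibble with columns `id`, `length_nt`, `n_codons`, `gc`, `gc1`,
#'   `gc2`, `gc3`, `gc12`, `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`, `enc`,
#'   `enc_expected`, `cai`, `gravy`, `aromo`.
#' @export
codon_usage_metrics <- function(seqs, reference = NULL,
                                silent_method = c("simple", "codonw")) {
  silent_method <- match.arg(silent_method)
  m <- codon_count_matrix(seqs)
  w <- NULL
  if (!is.null(reference)) {
    w <- if (is.data.frame(reference) && "w" %in% names(reference)) {
      reference
    } else {
      cai_weights(reference)
    }
  }
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    cnt <- m[i, ]
    sil <- tryCatch(
      silent_composition(cnt, method = silent_method),
      error = function(e) tibble::tibble(gc3s = NA_real_, a3s = NA_real_,
                                         t3s = NA_real_, c3s = NA_real_,
                                         g3s = NA_real_))
    dplyr::bind_cols(
      tibble::tibble(
        id = rownames(m)[i],
        length_nt = nchar(seqs$seq[i]),
        n_codons = sum(cnt)
      ),
      gc_partitions(cnt),
      sil,
      tibble::tibble(
        enc = enc(cnt),
        enc_expected = expected_enc(sil$gc3s),
        cai = if (is.null(w)) NA_real_ else cai(cnt, w),
        gravy = gravy(cnt),
        aromo = aromo(cnt)
      )
    )
  })
  dplyr::bind_rows(rows)
}
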
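# Seeded simulator of coding-sequence sets with controlled codon-usage
# structure: per-amino-acid codon sampling distributions (optionally
# parameterised by a GC3 target), gene lengths, and an expression-class
# structure in which a "highly expressed" subset is enriched for a planted
# optimal-codon set. Every pipeline stage can be exercised on this output
# without real data.

#' Uniform within-family codon preferences
#'
#' Every synonym of each amino acid equally likely — the "absence of bias"
#' limit under which Wright's ENc tends to 61 for long genes.
#'
#' @return A tibble with `amino_acid`, `codon`, `pref`; preferences sum to 1
#'   within each family (Met and Trp have pref 1).
#' @export
uniform_prefs <- function() {
  tab <- codon_table(include_stops = FALSE)
  dplyr::mutate(dplyr::group_by(tab, .data$amino_acid),
                pref = 1 / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("amino_acid", "codon", "pref")
}

#' GC3-targeted codon preferences
#'
#' Within each synonymous family, G/C-ending codons share total weight
#' `gc3_target` evenly and A/T-ending codons share `1 - gc3_target`;
#' families with only one third-base class renormalise to that class. This
#' is the mutation-only model: genes sampled from these preferences track
#' the expected-ENc curve.
#'
#' @param gc3_target Target G+C fraction at synonymous third positions, in
#'   `[0, 1]`.
#' @return A tibble with `amino_acid`, `codon`, `pref`.
#' @export
gc3_targeted_prefs <- function(gc3_target) {
  stopifnot(gc3_target >= 0, gc3_target <= 1)
  tab <- codon_table(include_stops = FALSE)
  tab$gc_end <- tab$third_base %in% c("G", "C")
  out <- dplyr::group_by(tab, .data$amino_acid) |>
    dplyr::mutate(
      n_gc = sum(.data$gc_end), n_at = dplyr::n() - sum(.data$gc_end),
      pref = dplyr::case_when(
        n_gc == 0 ~ 1 / n_at,
        n_at == 0 ~ 1 / n_gc,
        gc_end ~ gc3_target / n_gc,
        TRUE ~ (1 - gc3_target) / n_at
      )
    ) |>
    dplyr::ungroup()
  # degenerate targets (0 or 1) can zero a whole family side; renormalise
  out <- dplyr::group_by(out, .data$amino_acid) |>
    dplyr::mutate(pref = if (sum(.data$pref) > 0) .data$pref / sum(.data$pref)
                  else 1 / dplyr::n()) |>
    dplyr::ungroup()
  dplyr::select(out, "amino_acid", "codon", "pref")
}

#' Default planted optimal-codon set
#'
#' One G/C-ending codon per degenerate amino-acid family (the C-ending
#' codon where one exists, otherwise the G-ending one): 18 codons, all
#' ending in G or C, mirroring the optimal-codon structure reported for
#' GC-selected transcriptomes.
#'
#' @return Character vector of 18 codons (DNA alphabet).
#' @export
default_planted_optimal <- function() {
  tab <- dplyr::filter(codon_table(include_stops = FALSE),
                       .data$degeneracy > 1)
  picks <- dplyr::group_by(tab, .data$amino_acid) |>
    dplyr::summarise(codon = {
      third <- substring(.data$codon, 3, 3)
      if (any(third == "C")) .data$codon[third == "C"][1]
      else .data$codon[third == "G"][1]
    }, .groups = "drop")
  sort(picks$codon)
}

# validate a preference tibble and return a list of per-family probability
# vectors (named by codon)
prefs_as_list <- function(prefs) {
  stopifnot(is.data.frame(prefs),
            all(c("amino_acid", "codon", "pref") %in% names(prefs)))
  if (any(prefs$pref < 0)) stop("negative codon preference", call. = FALSE)
  by_fam <- split(stats::setNames(prefs$pref, prefs$codon), prefs$amino_acid)
  bad <- names(by_fam)[vapply(by_fam, sum, numeric(1)) <= 0]
  if (length(bad) > 0) {
    stop("empty codon preference for family: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lapply(by_fam, function(x) x / sum(x))
}

#' Simulate a set of coding sequences with controlled codon usage
#'
#' Each simulated gene is `ATG` + sampled codons + one stop codon, so every
#' gene passes [qc_filter()] by construction (no internal stops, valid start
#' and stop, length a multiple of 3 and at least `3 * min(length_range)`).
#' Amino acids are drawn from `aa_weights`; codons within each family from
#' `codon_prefs` (or from [gc3_targeted_prefs()] when `gc3_target` is
#' given — `gc3_target` may be a single value or per-gene vector). A
#' fraction of genes (`high_expr_fraction`) forms a highly expressed class
#' whose family preferences up-weight the `planted_optimal` codons by
#' `enrichment`.
#'
#' Reproducibility: a single integer `seed` drives the whole simulation;
#' per-gene substreams are derived from it by counter, so increasing
#' `n_genes` extends a run without reshuffling earlier genes.
#'
#' @param n_genes Number of genes.
#' @param length_range Inclusive range of gene lengths in codons (start and
#'   stop included); default `c(100, 600)` emulates a CDS set filtered at
#'   300 nt with a mean around 350 codons.
#' @param aa_weights Optional named numeric vector of amino-acid sampling
#'   weights (single-letter codes). Default: weight 1 for the 18 degenerate
#'   amino acids and 0.2 for Met and Trp, so every ENc degeneracy class is
#'   populated.
#' @param codon_prefs Preference tibble (`amino_acid`, `codon`, `pref`) as
#'   from [uniform_prefs()] or [gc3_targeted_prefs()]. Default uniform.
#' @param gc3_target Optional GC3 target (scalar or length `n_genes`)
#'   overriding `codon_prefs` per gene.
#' @param high_expr_fraction Fraction of genes in the highly expressed
#'   class (default 0).
#' @param planted_optimal Codons up-weighted in the highly expressed class;
#'   default [default_planted_optimal()].
#' @param enrichment Multiplicative up-weighting factor (default 3).
#' @param seed Integer seed (required for reproducibility; default 1).
#' @return A list with `sequences` (tibble `id`, `seq`, `length_nt`) and
#'   `truth` (tibble `id`, `class` ("high"/"background"), `n_codons`,
#'   `gc3_target`), plus attributes `planted_optimal` and `enrichment`.
#' @export
simulate_cds <- function(n_genes, length_range = c(100, 600),
                         aa_weights = NULL, codon_prefs = NULL,
                         gc3_target = NULL, high_expr_fraction = 0,
                         planted_optimal = default_planted_optimal(),
                         enrichment = 3, seed = 1) {
  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 4, length_range[1] <= length_range[2],
            high_expr_fraction >= 0, high_expr_fraction <= 1,
            enrichment > 0)
  if (is.null(aa_weights)) {
    aa <- names(AA_DEGENERACY)
    aa_weights <- stats::setNames(ifelse(AA_DEGENERACY[aa] > 1, 1, 0.2), aa)
  }
  aa_weights <- aa_weights / sum(aa_weights)
  base_prefs <- if (!is.null(codon_prefs)) prefs_as_list(codon_prefs)
                else prefs_as_list(uniform_prefs())
  gc3_per_gene <- if (is.null(gc3_target)) rep(NA_real_, n_genes)
                  else rep_len(gc3_target, n_genes)
  planted_optimal <- toupper(stringr::str_replace_all(planted_optimal, "U", "T"))

  enrich <- function(pl) {
    lapply(pl, function(p) {
      up <- names(p) %in% planted_optimal
      p[up] <- p[up] * enrichment
      p / sum(p)
    })
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)
  n_high <- round(high_expr_fraction * n_genes)
  classes <- rep("background", n_genes)
  if (n_high > 0) classes[seq_len(n_high)] <- "high"

  width <- max(4, nchar(n_genes))
  ids <- sprintf(paste0("gene%0", width, "d"), seq_len(n_genes))
  seqs <- character(n_genes)
  n_codons <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    set.seed(gene_seeds[i])
    pl <- if (!is.na(gc3_per_gene[i])) {
      prefs_as_list(gc3_targeted_prefs(gc3_per_gene[i]))
    } else {
      base_prefs
    }
    if (classes[i] == "high") pl <- enrich(pl)
    len <- if (length_range[1] == length_range[2]) length_range[1] else
      sample(length_range[1]:length_range[2], 1)
    n_body <- len - 2L
    aa_seq <- sample(names(aa_weights), n_body, replace = TRUE,
                     prob = aa_weights)
    codons <- character(n_body)
    for (a in unique(aa_seq)) {
      idx <- which(aa_seq == a)
      p <- pl[[a]]
      codons[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    stop_codon <- sample(STOP_CODONS, 1)
    seqs[i] <- paste0("ATG", paste(codons, collapse = ""), stop_codon)
    n_codons[i] <- len
  }
  list(
    sequences = tibble::tibble(id = ids, seq = seqs, length_nt = nchar(seqs)),
    truth = structure(
      tibble::tibble(id = ids, class = classes, n_codons = n_codons,
                     gc3_target = gc3_per_gene),
      planted_optimal = planted_optimal, enrichment = enrichment)
  )
}
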
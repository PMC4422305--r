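# Genetic-code machinery shared across the package. All codons are keyed as
# DNA (T alphabet); RNA (U) input is normalised on read and only re-emitted
# as RNA in human-facing reports. Standard code (NCBI table 1) only:
# Leu/Ser/Arg are 6-fold families, Ile the sole 3-fold family.

GENETIC_CODE_DNA <- Biostrings::GENETIC_CODE

#' The 64 codons in the package's canonical order
#'
#' Order follows the standard genetic-code table layout used by
#' [Biostrings::GENETIC_CODE] (TTT, TTC, TTA, TTG, CTT, ...). All codon-count
#' vectors and matrices produced by codonscope use this order.
#' @export
CODONS <- names(GENETIC_CODE_DNA)

#' @rdname CODONS
#' @export
STOP_CODONS <- CODONS[GENETIC_CODE_DNA == "*"]

SENSE_CODONS <- CODONS[GENETIC_CODE_DNA != "*"]

# degeneracy (number of synonyms) per amino acid, from the code itself
AA_DEGENERACY <- table(GENETIC_CODE_DNA[GENETIC_CODE_DNA != "*"])
AA_DEGENERACY <- stats::setNames(as.integer(AA_DEGENERACY), names(AA_DEGENERACY))

# the 59 synonymous sense codons: 61 sense minus the unique Met (ATG) and
# Trp (TGG) codons; fixed column order for the RSCU matrix is amino acid
# (single-letter, alphabetical) then codon alphabetical within family
SYNONYMOUS_CODONS <- {
  cod <- SENSE_CODONS[AA_DEGENERACY[GENETIC_CODE_DNA[SENSE_CODONS]] > 1L]
  aa <- GENETIC_CODE_DNA[cod]
  cod[order(aa, cod)]
}

# Kyte-Doolittle hydropathy scale (canonical constants)
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AROMATIC_AA <- c("F", "Y", "W")

# 0/1 indicator matrices: is base b at codon position p, for fast GC sums
.codon_base_indicator <- function(position) {
  base <- substring(CODONS, position, position)
  out <- vapply(c("A", "C", "G", "T"), function(b) as.numeric(base == b),
                numeric(length(CODONS)))
  rownames(out) <- CODONS
  out
}
BASE_AT_POS <- lapply(1:3, .codon_base_indicator)

#' Codon reference table
#'
#' One row per codon of the standard genetic code, with the encoded amino
#' acid (single-letter, `*` for stop), its degeneracy (number of synonyms),
#' and the third-position base. This is the lookup table the rest of the
#' package joins against.
#'
#' @param include_stops Keep the three stop codons? Default `TRUE`.
#' @return A tibble with columns `codon`, `codon_rna`, `amino_acid`,
#'   `degeneracy`, `third_base`.
#' @examples
#' codon_table()
#' @export
codon_table <- function(include_stops = TRUE) {
  out <- tibble::tibble(
    codon = CODONS,
    codon_rna = stringr::str_replace_all(CODONS, "T", "U"),
    amino_acid = unname(GENETIC_CODE_DNA[CODONS]),
    degeneracy = ifelse(amino_acid == "*", NA_integer_,
                        AA_DEGENERACY[amino_acid]),
    third_base = substring(CODONS, 3, 3)
  )
  if (!include_stops) out <- dplyr::filter(out, .data$amino_acid != "*")
  out
}

# normalise assorted codon-count inputs (named vector, tibble with
# codon/count columns) to a full named 64-vector in CODONS order
as_codon_counts <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("codon", "count") %in% names(x)))
    x <- stats::setNames(x$count, toupper(stringr::str_replace_all(x$codon, "U", "T")))
  }
  if (is.null(names(x))) {
    stop("codon counts must be named by codon", call. = FALSE)
  }
  names(x) <- toupper(stringr::str_replace_all(names(x), "U", "T"))
  bad <- setdiff(names(x), CODONS)
  if (length(bad) > 0) {
    stop("unknown codons in count input: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(numeric(length(CODONS)), CODONS)
  out[names(x)] <- out[names(x)] + as.numeric(x)
  if (any(out < 0)) stop("negative codon counts", call. = FALSE)
  out
}
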
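# Cross-species codon-preference comparison against Kazusa-format codon
# usage tables: parsing, per-1000 frequency ratios, and indicative codons.

#' Parse a Kazusa-format codon usage table
#'
#' Reads the standard Codon Usage Database layout, i.e. repeated fields of
#' the form `UUU 17.6(714298)` — triplet, frequency per thousand codons,
#' and raw count in parentheses — in any line arrangement. All 64 codons
#' must be present; the RNA alphabet is normalised to DNA internally.
#'
#' @param x Path to a Kazusa-format file, or the table text itself.
#' @param organism Optional organism label stored on the result.
#' @return A tibble of class `kazusa_table` with columns `codon` (DNA),
#'   `codon_rna`, `freq_per_1000`, `count`, 64 rows in [CODONS] order.
#' @export
parse_kazusa <- function(x, organism = NA_character_) {
  txt <- if (length(x) == 1 && !grepl("[(\n]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  pat <- "([ACGTUacgtu]{3})\\s+([0-9]+\\.?[0-9]*)\\s*\\(\\s*([0-9]+)\\s*\\)"
  m <- stringr::str_match_all(txt, pat)[[1]]
  # reject lines with non-matching residue that look like entries
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  bad <- which(grepl("\\(", lines) &
                 !grepl(pat, lines) & nzchar(trimws(lines)))
  if (length(bad) > 0) {
    stop("malformed codon usage line ", bad[1], ": ",
         trimws(lines[bad[1]]), call. = FALSE)
  }
  cod <- toupper(stringr::str_replace_all(m[, 2], "U|u", "T"))
  if (anyDuplicated(cod)) {
    stop("duplicated codons in usage table: ",
         paste(unique(cod[duplicated(cod)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(CODONS, cod)
  if (length(missing) > 0) {
    stop("codon usage table is missing codons: ",
         paste(stringr::str_replace_all(missing, "T", "U"), collapse = ", "),
         call. = FALSE)
  }
  ord <- match(CODONS, cod)
  out <- tibble::tibble(
    codon = CODONS,
    codon_rna = stringr::str_replace_all(CODONS, "T", "U"),
    freq_per_1000 = as.numeric(m[ord, 3]),
    count = as.integer(m[ord, 4])
  )
  total <- sum(out$freq_per_1000)
  if (abs(total - 1000) > 1) {
    warning(sprintf("frequencies sum to %.2f, not 1000 +/- 1", total),
            call. = FALSE)
  }
  attr(out, "organism") <- organism
  class(out) <- c("kazusa_table", class(out))
  out
}

#' Codon frequency ratios against a reference organism
#'
#' Converts the pooled codon counts of the study organism to per-1000
#' frequencies (stop codons included in the normalisation, matching the
#' Kazusa convention) and divides by the reference per-1000 frequencies.
#' With `method = "family"`, within-family relative frequencies are
#' compared instead. A zero reference frequency gives an `NA` ratio rather
#' than an infinity.
#'
#' @param own Pooled codon counts of the organism under study (tibble with
#'   `codon`/`count` or named vector).
#' @param ref A `kazusa_table` from [parse_kazusa()].
#' @param method `"per1000"` (default) or `"family"`.
#' @return A tibble with `codon`, `codon_rna`, `own_freq`, `ref_freq`,
#'   `ratio`, 64 rows.
#' @export
frequency_ratio <- function(own, ref, method = c("per1000", "family")) {
  method <- match.arg(method)
  cnt <- as_codon_counts(own)
  if (sum(cnt) == 0) stop("own codon pool is empty", call. = FALSE)
  stopifnot(is.data.frame(ref), all(c("codon", "freq_per_1000") %in% names(ref)))
  if (method == "per1000") {
    own_freq <- 1000 * cnt / sum(cnt)
    ref_freq <- stats::setNames(ref$freq_per_1000, ref$codon)[CODONS]
  } else {
    aa <- GENETIC_CODE_DNA[CODONS]
    fam_own <- tapply(cnt, aa, sum)[aa]
    own_freq <- ifelse(fam_own > 0, cnt / fam_own, NA_real_)
    refc <- stats::setNames(ref$freq_per_1000, ref$codon)[CODONS]
    fam_ref <- tapply(refc, aa, sum)[aa]
    ref_freq <- ifelse(fam_ref > 0, refc / fam_ref, NA_real_)
  }
  tibble::tibble(
    codon = CODONS,
    codon_rna = stringr::str_replace_all(CODONS, "T", "U"),
    own_freq = unname(own_freq),
    ref_freq = unname(ref_freq),
    ratio = ifelse(!is.na(ref_freq) & ref_freq > 0, own_freq / ref_freq,
                   NA_real_)
  )
}

#' Indicative codons between two organisms
#'
#' Codons whose frequency ratio exceeds `hi` or falls below `lo` (strict
#' inequalities; a ratio of exactly 2 is not indicative). Undefined ratios
#' are excluded.
#'
#' @param ratios Tibble from [frequency_ratio()] (columns `codon`, `ratio`),
#'   or a named numeric vector of ratios.
#' @param hi,lo Thresholds (defaults 2 and 0.5).
#' @return Character vector of indicative codons (DNA alphabet).
#' @export
indicative_codons <- function(ratios, hi = 2.0, lo = 0.5) {
  if (is.data.frame(ratios)) {
    r <- stats::setNames(ratios$ratio, ratios$codon)
  } else {
    r <- ratios
  }
  names(which(!is.na(r) & (r > hi | r < lo)))
}

#' Full codon-preference comparison table
#'
#' Convenience wrapper combining [frequency_ratio()] and
#' [indicative_codons()] into one report table.
#'
#' @inheritParams frequency_ratio
#' @inheritParams indicative_codons
#' @return The [frequency_ratio()] tibble with an added logical
#'   `indicative` column.
#' @export
compare_usage <- function(own, ref, method = c("per1000", "family"),
                          hi = 2.0, lo = 0.5) {
  fr <- frequency_ratio(own, ref, method = method)
  fr$indicative <- fr$codon %in% indicative_codons(fr, hi = hi, lo = lo)
  fr
}
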
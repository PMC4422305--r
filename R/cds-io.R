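# CDS input and quality control.

QC_REASONS <- c("AMBIGUOUS_BASE", "GAP", "NOT_MULTIPLE_OF_3", "NO_START",
                "NO_STOP", "INTERNAL_STOP", "TOO_SHORT", "BLACKLISTED")

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a tibble
#' of coding sequences. Sequences are uppercased and the RNA alphabet is
#' normalised to DNA (U becomes T). Record order is preserved; the record id
#' is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length_nt`.
#' @seealso [qc_filter()] for the quality filters applied before analysis.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("FASTA file contains no records: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), seq = character(),
                          length_nt = integer()))
  }
  ids <- stringr::str_extract(names(set), "^\\S+")
  seqs <- toupper(as.character(set))
  seqs <- stringr::str_replace_all(seqs, "U", "T")
  tibble::tibble(id = unname(ids), seq = unname(seqs),
                 length_nt = nchar(seqs))
}

# split a (multiple-of-3) sequence into consecutive triplets
codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

qc_reasons_one <- function(seq, min_length_nt) {
  reasons <- character()
  if (stringr::str_detect(seq, "-")) reasons <- c(reasons, "GAP")
  if (stringr::str_detect(gsub("-", "", seq), "[^ACGT]")) {
    reasons <- c(reasons, "AMBIGUOUS_BASE")
  }
  n <- nchar(seq)
  if (n %% 3L != 0L) reasons <- c(reasons, "NOT_MULTIPLE_OF_3")
  if (substring(seq, 1, 3) != "ATG") reasons <- c(reasons, "NO_START")
  n_full <- n %/% 3L
  if (n_full >= 1L) {
    codons <- substring(seq, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
    terminal_ok <- n %% 3L == 0L && codons[n_full] %in% STOP_CODONS
    if (!terminal_ok) reasons <- c(reasons, "NO_STOP")
    internal <- if (n %% 3L == 0L) codons[-n_full] else codons
    if (length(internal) > 0 && any(internal %in% STOP_CODONS)) {
      reasons <- c(reasons, "INTERNAL_STOP")
    }
  } else {
    reasons <- c(reasons, "NO_STOP")
  }
  if (n < min_length_nt) reasons <- c(reasons, "TOO_SHORT")
  reasons
}

#' Quality-filter coding sequences
#'
#' Applies the CDS quality filters used throughout the package: a sequence
#' passes iff it contains only A/C/G/T (no ambiguity codes, no gaps), its
#' length is a multiple of 3, it begins with ATG, ends with a stop codon
#' (TAA/TAG/TGA), contains no in-frame internal stop codon, and is at least
#' `min_length_nt` nucleotides long (stop codon included, GenBank CDS
#' convention). All failure reasons are enumerated per sequence, never
#' short-circuited, so a report row states everything wrong with a record.
#'
#' Ids listed in `blacklist` (e.g. mitochondrial genes) are rejected with
#' reason `BLACKLISTED` regardless of sequence content.
#'
#' @param seqs A tibble as returned by [read_cds_fasta()] (columns `id`,
#'   `seq`; `length_nt` recomputed if absent).
#' @param min_length_nt Minimum length in nucleotides (default 300).
#' @param blacklist Optional character vector of ids to exclude.
#' @return A list with elements `passed` (tibble of sequences that passed,
#'   same columns as the input) and `report` (tibble with `id`, `passed`,
#'   `reasons`; `reasons` is a comma-separated string, empty when passed).
#' @examples
#' seqs <- tibble::tibble(id = "g1", seq = strrep("ATGAAATAA", 1))
#' qc_filter(seqs, min_length_nt = 9)$report
#' @export
qc_filter <- function(seqs, min_length_nt = 300, blacklist = NULL) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  reasons <- purrr::map(seqs$seq, qc_reasons_one, min_length_nt = min_length_nt)
  if (!is.null(blacklist)) {
    reasons <- purrr::map2(reasons, seqs$id %in% blacklist,
                           ~ if (.y) c(.x, "BLACKLISTED") else .x)
  }
  ok <- lengths(reasons) == 0L
  report <- tibble::tibble(
    id = seqs$id,
    passed = ok,
    reasons = purrr::map_chr(reasons, paste, collapse = ",")
  )
  passed <- dplyr::mutate(seqs[ok, , drop = FALSE], length_nt = nchar(seq))
  list(passed = passed, report = report)
}

#' Write simulated or filtered sequences as FASTA
#'
#' Plain unwrapped FASTA writer; output is byte-stable for a given input,
#' which the simulator's determinism guarantee relies on.
#'
#' @param seqs Tibble with `id` and `seq` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path, sep = "\n")
  invisible(path)
}
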
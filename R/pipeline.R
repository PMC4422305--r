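# End-to-end orchestration: QC -> per-gene indices -> correspondence
# analysis -> selection diagnostics -> optimal codons -> species
# comparison, with every report table written as TSV and a machine-readable
# run summary.

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), NA, formatC(x, digits = digits, format = "f"))
}

write_report_tsv <- function(x, path, digits = 4) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], fmt_num, digits = digits)
  readr::write_tsv(x, path, na = "")
  path
}

#' Run the full codon-usage-bias analysis
#'
#' Executes the whole pipeline on a CDS FASTA file: quality filtering,
#' per-gene codon-usage indices (with CAI when a highly expressed reference
#' set is supplied), correspondence analysis of the RSCU matrix,
#' mutation-versus-selection diagnostics (ENc-GC3s plot data, ENc deviation
#' distribution, neutrality regression, GC histogram, Spearman correlation
#' matrix), chi-squared optimal-codon identification from the axis-1
#' extreme pools, and optional comparison against Kazusa-format codon usage
#' tables of other organisms. All report tables are written as TSV (floats
#' to 4 decimals) plus a JSON run summary; the run is deterministic for a
#' given configuration.
#'
#' If any stage fails the run aborts with the stage name and cause, and
#' partially written outputs are removed.
#'
#' @param input_fasta Path to the CDS FASTA file.
#' @param output_dir Output directory (created if needed).
#' @param reference_fasta Optional FASTA of highly expressed genes
#'   (classically ribosomal proteins) for CAI; when omitted the CAI column
#'   is empty and a warning is logged.
#' @param blacklist Optional path to a file of ids to exclude (one per
#'   line), or a character vector of ids.
#' @param comparison_tables Named character vector (or list) of paths to
#'   Kazusa-format codon usage tables; names become organism labels.
#' @param extreme_fraction Tail fraction for the optimal-codon pools
#'   (default 0.05).
#' @param alpha Optimal-codon significance level (default 0.01).
#' @param min_length_nt QC length threshold (default 300).
#' @param n_axes Correspondence-analysis axes to retain (default 20).
#' @param silent_method Silent-site composition convention, see
#'   [silent_composition()].
#' @param verbose Log stage progress via [message()]? Default `TRUE`.
#' @return A list of class `codon_run`: gene counts per stage, the file
#'   manifest, headline statistics (neutrality slope, axis-1 inertia,
#'   number of optimal codons, mean ENc), and the echoed configuration.
#' @export
run_codon_analysis <- function(input_fasta, output_dir,
                               reference_fasta = NULL, blacklist = NULL,
                               comparison_tables = character(),
                               extreme_fraction = 0.05, alpha = 0.01,
                               min_length_nt = 300, n_axes = 20,
                               silent_method = c("simple", "codonw"),
                               verbose = TRUE) {
  silent_method <- match.arg(silent_method)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  say <- function(...) if (verbose) message(...)
  emit <- function(x, name, digits = 4) {
    path <- file.path(output_dir, name)
    write_report_tsv(x, path, digits = digits)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "cds_io"
    if (is.character(blacklist) && length(blacklist) == 1 &&
        file.exists(blacklist)) {
      blacklist <- readLines(blacklist, warn = FALSE)
    }
    seqs <- read_cds_fasta(input_fasta)
    qc <- qc_filter(seqs, min_length_nt = min_length_nt,
                    blacklist = blacklist)
    say(sprintf("QC: %d of %d sequences passed", nrow(qc$passed),
                nrow(seqs)))
    emit(qc$report, "qc_report.tsv")
    if (nrow(qc$passed) < 3) {
      stop("fewer than 3 sequences passed QC", call. = FALSE)
    }

    stage <- "codon_metrics"
    weights <- NULL
    if (!is.null(reference_fasta)) {
      ref <- read_cds_fasta(reference_fasta)
      ref_qc <- qc_filter(ref, min_length_nt = min_length_nt)
      weights <- cai_weights(ref_qc$passed)
      say(sprintf("CAI reference: %d genes", nrow(ref_qc$passed)))
    } else {
      warning("no CAI reference supplied; cai column left empty",
              call. = FALSE)
    }
    metrics <- codon_usage_metrics(qc$passed, reference = weights,
                                   silent_method = silent_method)
    emit(metrics, "gene_metrics.tsv")
    pooled <- count_codons(qc$passed)
    emit(rscu(pooled, include_stops = TRUE), "codon_usage.tsv")

    stage <- "multivariate"
    rm_mat <- build_rscu_matrix(qc$passed)
    ca <- correspondence_analysis(rm_mat, n_axes = n_axes)
    gene_coords <- tidy.codon_ca(ca, "rows")
    gene_coords$gc_class <- as.character(
      classify_gc(metrics$gc[match(gene_coords$id, metrics$id)]))
    emit(gene_coords, "coa_genes.tsv")
    codon_coords <- tidy.codon_ca(ca, "cols")
    codon_coords <- dplyr::mutate(codon_coords,
                                  third_base = substring(.data$id, 3, 3),
                                  .after = "id")
    emit(codon_coords, "coa_codons.tsv")
    emit(tidy.codon_ca(ca, "inertia"), "coa_inertia.tsv", digits = 6)
    say(sprintf("COA: axis 1 explains %.2f%% of inertia",
                100 * ca$inertia$fraction[1]))

    stage <- "selection_diagnostics"
    ep <- enc_plot_data(metrics)
    emit(ep$points, "enc_plot.tsv")
    emit(ep$curve, "enc_curve.tsv")
    dev <- enc_deviation(metrics)
    emit(bin_histogram(dev$deviation, 0.05), "enc_deviation.tsv")
    emit(gc_histogram(metrics), "gc_histogram.tsv")
    nf <- neutrality_fit(metrics)
    emit(glance.neutrality_fit(nf), "neutrality.tsv", digits = 6)
    say(sprintf("Neutrality: slope %.4f (mutation %.2f%%)", nf$slope,
                nf$mutation_pct))
    corr_vars <- c("length_nt", "gc", "gc1", "gc2", "gc3", "gc3s", "a3s",
                   "t3s", "c3s", "g3s", "gravy", "aromo", "enc", "cai")
    corr_data <- dplyr::left_join(
      metrics,
      gene_coords[, c("id", "axis1",
                      if ("axis2" %in% names(gene_coords)) "axis2")],
      by = "id")
    corr_vars <- c(corr_vars, intersect(c("axis1", "axis2"),
                                        names(corr_data)))
    corr_vars <- corr_vars[vapply(corr_data[corr_vars],
                                  function(v) any(!is.na(v)), logical(1))]
    cm <- spearman_matrix(corr_data, corr_vars)
    emit(tidy.correlation_matrix(cm), "correlations.tsv")

    stage <- "optimal_codons"
    pools <- select_extreme_pools(ca, metrics, fraction = extreme_fraction)
    counts_m <- codon_count_matrix(qc$passed)
    opt <- chi2_optimal(colSums(counts_m[pools$high, , drop = FALSE]),
                        colSums(counts_m[pools$low, , drop = FALSE]),
                        alpha = alpha)
    opt_out <- dplyr::mutate(tibble::as_tibble(opt),
                             star = ifelse(.data$optimal, "*", ""))
    emit(opt_out, "optimal_codons.tsv")
    emit(pools$summary, "extreme_pools.tsv")
    say(sprintf("Optimal codons: %d flagged at p < %g", sum(opt$optimal),
                alpha))

    stage <- "species_comparison"
    comparisons <- character()
    tabs <- as.list(comparison_tables)
    if (length(tabs) > 0 && is.null(names(tabs))) {
      names(tabs) <- tools::file_path_sans_ext(basename(unlist(tabs)))
    }
    for (org in names(tabs)) {
      ref_tab <- parse_kazusa(tabs[[org]], organism = org)
      cmp <- compare_usage(pooled, ref_tab)
      emit(cmp, paste0("comparison_", org, ".tsv"))
      comparisons[org] <- sum(cmp$indicative)
    }

    stage <- "summary"
    summary <- list(
      config = list(
        input_fasta = input_fasta, reference_fasta = reference_fasta,
        extreme_fraction = extreme_fraction, alpha = alpha,
        min_length_nt = min_length_nt, n_axes = n_axes,
        silent_method = silent_method
      ),
      n_input = nrow(seqs), n_passed = nrow(qc$passed),
      n_codons = sum(pooled$count),
      mean_enc = mean(metrics$enc, na.rm = TRUE),
      axis1_inertia_fraction = ca$inertia$fraction[1],
      neutrality_slope = nf$slope,
      neutrality_mutation_pct = nf$mutation_pct,
      n_optimal_codons = sum(opt$optimal),
      indicative_codons = as.list(comparisons),
      files = basename(written)
    )
    json_path <- file.path(output_dir, "run_summary.json")
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, json_path)
    summary$files <- basename(written)
    structure(summary, class = "codon_run")
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' @export
print.codon_run <- function(x, ...) {
  cat("codonscope run:", x$n_passed, "of", x$n_input, "sequences analysed (",
      x$n_codons, "codons )\n")
  cat(sprintf("  axis-1 inertia: %.2f%%\n", 100 * x$axis1_inertia_fraction))
  cat(sprintf("  neutrality slope: %.4f (mutation %.2f%%)\n",
              x$neutrality_slope, x$neutrality_mutation_pct))
  cat(sprintf("  optimal codons: %d\n", x$n_optimal_codons))
  cat("  files:", length(x$files), "written\n")
  invisible(x)
}
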
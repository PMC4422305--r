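# Mutation-versus-selection diagnostics: ENc-GC3s plot data, the
# (ENCexp - ENCobs)/ENCexp deviation distribution, the neutrality
# regression of GC12 on GC3, GC histograms, and Spearman correlation
# matrices with significance stars.

#' ENc-GC3s plot data
#'
#' One point per gene with defined ENc and GC3s, plus the expected-ENc
#' reference curve sampled uniformly on `[0, 1]`. Genes lying on or near the
#' curve are compatible with codon choice constrained only by G+C mutation
#' bias; genes well below it suggest additional forces such as selection.
#'
#' @param metrics Per-gene metrics tibble from [codon_usage_metrics()]
#'   (columns `id`, `gc3s`, `enc`).
#' @param curve_points Number of points at which to sample the curve.
#' @return A list with `points` (tibble `id`, `gc3s`, `enc`) and `curve`
#'   (tibble `gc3s`, `enc_expected`). Genes lacking a defined ENc are
#'   omitted from `points` and counted in a message.
#' @export
enc_plot_data <- function(metrics, curve_points = 101) {
  ok <- !is.na(metrics$enc) & !is.na(metrics$gc3s)
  if (any(!ok)) {
    message(sum(!ok), " gene(s) without defined ENc/GC3s omitted from ENc plot")
  }
  s <- seq(0, 1, length.out = curve_points)
  list(
    points = dplyr::select(metrics[ok, , drop = FALSE], "id", "gc3s", "enc"),
    curve = tibble::tibble(gc3s = s, enc_expected = expected_enc(s))
  )
}

#' Plot ENc against GC3s with the mutation-only expectation curve
#'
#' @inheritParams enc_plot_data
#' @param colour_by Optional per-gene vector for the colour aesthetic (e.g.
#'   a highly-expressed flag).
#' @return A ggplot object.
#' @export
plot_enc_gc3s <- function(metrics, colour_by = NULL, curve_points = 101) {
  d <- enc_plot_data(metrics, curve_points)
  p <- ggplot2::ggplot(d$points, ggplot2::aes(.data$gc3s, .data$enc))
  if (!is.null(colour_by)) {
    d$points$colour_by <- colour_by[!is.na(metrics$enc) & !is.na(metrics$gc3s)]
    p <- ggplot2::ggplot(d$points,
                         ggplot2::aes(.data$gc3s, .data$enc,
                                      colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = d$curve,
                       ggplot2::aes(.data$gc3s, .data$enc_expected),
                       colour = "red", inherit.aes = FALSE) +
    ggplot2::labs(x = "GC3s", y = "ENc") +
    ggplot2::ylim(0, 61) +
    ggplot2::theme_minimal()
}

#' Relative ENc deviation from the mutation-only expectation
#'
#' For each gene, `(ENc_expected - ENc_observed) / ENc_expected` with the
#' expectation taken at the gene's GC3s. Positive values mean the observed
#' ENc falls below the curve (more bias than mutation alone predicts).
#'
#' @inheritParams enc_plot_data
#' @return A tibble with `id`, `gc3s`, `enc`, `enc_expected`, `deviation`,
#'   restricted to genes where both quantities are defined.
#' @export
enc_deviation <- function(metrics) {
  ok <- !is.na(metrics$enc) & !is.na(metrics$gc3s)
  d <- metrics[ok, , drop = FALSE]
  ee <- expected_enc(d$gc3s)
  tibble::tibble(id = d$id, gc3s = d$gc3s, enc = d$enc, enc_expected = ee,
                 deviation = (ee - d$enc) / ee)
}

#' Bin values into a fixed-width histogram
#'
#' Closed-left bins (`[start, end)`) of width `bin_width` spanning the data
#' (or `range` when given); the bin counts always sum to the number of
#' finite input values.
#'
#' @param values Numeric vector.
#' @param bin_width Bin width (default 0.05).
#' @param range Optional `c(lo, hi)` to fix the binned span; values outside
#'   are clamped into the terminal bins.
#' @return A tibble with `bin_start`, `bin_end`, `count`.
#' @export
bin_histogram <- function(values, bin_width = 0.05, range = NULL) {
  v <- values[is.finite(values)]
  if (is.null(range)) {
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling((max(v) + 1e-12) / bin_width) * bin_width
  } else {
    lo <- range[1]; hi <- range[2]
  }
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  idx <- pmin(pmax(findInterval(v, edges, left.open = FALSE), 1L),
              length(edges) - 1L)
  tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    count = tabulate(idx, nbins = length(edges) - 1L)
  )
}

#' GC-content histogram of a gene set
#'
#' @inheritParams enc_plot_data
#' @param bin_width Bin width on the GC fraction scale (default 0.05, i.e.
#'   5 percentage points).
#' @return A tibble with `bin_start`, `bin_end`, `count` over `[0, 1]`.
#' @export
gc_histogram <- function(metrics, bin_width = 0.05) {
  bin_histogram(metrics$gc, bin_width = bin_width, range = c(0, 1))
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean G+C at codon positions 1 and 2) on
#' GC3. Under complete neutrality — composition at all positions driven by
#' the same directional mutation pressure — the slope is 1; under complete
#' selective constraint at positions 1-2 the slope is 0. The slope times
#' 100 is conventionally read as the percentage contribution of mutation
#' pressure, and its complement as that of other forces such as selection.
#'
#' @param metrics Tibble with columns `gc12` and `gc3` (e.g. from
#'   [codon_usage_metrics()]); at least 3 complete rows required.
#' @return An object of class `neutrality_fit` wrapping the [stats::lm()]
#'   fit, with fields `slope`, `intercept`, `r2`, `pearson_r`, `p_value`,
#'   `mutation_pct`, `other_pct`, `n`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
neutrality_fit <- function(metrics) {
  d <- metrics[stats::complete.cases(metrics[, c("gc12", "gc3")]), ,
               drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 genes with GC12 and GC3",
                        call. = FALSE)
  if (stats::sd(d$gc3) == 0) {
    stop("GC3 has zero variance: neutrality slope undefined", call. = FALSE)
  }
  fit <- stats::lm(gc12 ~ gc3, data = d)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  structure(
    list(
      fit = fit, data = tibble::as_tibble(d[, c("gc3", "gc12")]),
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r2 = sm$r.squared,
      pearson_r = sign(slope) * sqrt(sm$r.squared),
      p_value = sm$coefficients[2, 4],
      mutation_pct = 100 * slope,
      other_pct = 100 * (1 - slope),
      n = nrow(d)
    ),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality plot regression (n = %d)\nGC12 = %.4f + %.4f * GC3\nR2 = %.4f, p = %.3g\nMutation pressure %.2f%% vs other forces %.2f%%\n",
    x$n, x$intercept, x$slope, x$r2, x$p_value, x$mutation_pct, x$other_pct))
  invisible(x)
}

#' Tidy/glance a neutrality regression
#'
#' @param x A `neutrality_fit` object.
#' @param ... Unused.
#' @return `tidy()`: per-term coefficient table. `glance()`: one row with
#'   `slope`, `intercept`, `r2`, `pearson_r`, `p_value`, `mutation_pct`,
#'   `other_pct`, `n`.
#' @export
tidy.neutrality_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "gc3"),
    estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )
}

#' @rdname tidy.neutrality_fit
#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 pearson_r = x$pearson_r, p_value = x$p_value,
                 mutation_pct = x$mutation_pct, other_pct = x$other_pct,
                 n = x$n)
}

#' @export
autoplot.neutrality_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$gc3, .data$gc12)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "blue") +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(
      x = "GC3", y = "GC12",
      subtitle = sprintf("slope = %.4f (R2 = %.4f): mutation %.2f%%, other %.2f%%",
                         object$slope, object$r2, object$mutation_pct,
                         object$other_pct)) +
    ggplot2::theme_minimal()
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations (mid-rank ties) with two-tailed p-values,
#' using pairwise-complete observations. Constant variables yield `NA`
#' correlations for their pairs, with a warning. No multiple-testing
#' correction is applied; the conventional star notation (`**` p < 0.01,
#' `*` p < 0.05) is available from [tidy()].
#'
#' @param data A data frame of numeric variables.
#' @param variables Character vector of column names to correlate (default:
#'   all numeric columns).
#' @return An object of class `correlation_matrix` with `rho`, `p` and `n`
#'   matrices and a `variables` vector. Supports [tidy()].
#' @export
spearman_matrix <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(all(variables %in% names(data)))
  k <- length(variables)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1
  diag(p) <- 0
  constant <- character()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j >= i) next
      x <- data[[variables[i]]]
      y <- data[[variables[j]]]
      ok <- stats::complete.cases(x, y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        constant <- union(constant, variables[c(i, j)])
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(n) <- vapply(variables, function(v) sum(!is.na(data[[v]])), numeric(1))
  if (length(constant) > 0 && any(is.na(rho[lower.tri(rho)]))) {
    warning("correlation undefined for pairs involving constant or ",
            "too-sparse variables", call. = FALSE)
  }
  structure(list(variables = variables, rho = rho, p = p, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman correlation matrix over", length(x$variables),
      "variables\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Tidy a correlation matrix
#'
#' @param x A `correlation_matrix` object.
#' @param ... Unused.
#' @return A tibble in long form: `var1`, `var2`, `rho`, `p`, `n`, `stars`
#'   (`**` p < 0.01, `*` p < 0.05, empty otherwise), one row per unordered
#'   variable pair.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  idx <- which(lower.tri(x$rho), arr.ind = TRUE)
  p <- x$p[idx]
  tibble::tibble(
    var1 = x$variables[idx[, 1]],
    var2 = x$variables[idx[, 2]],
    rho = x$rho[idx],
    p = p,
    n = x$n[idx],
    stars = dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**",
                             p < 0.05 ~ "*", TRUE ~ "")
  )
}

#' Plot the ENc deviation distribution
#'
#' Frequency distribution of `(ENc_expected - ENc_observed) / ENc_expected`.
#'
#' @param deviations Tibble from [enc_deviation()].
#' @param bin_width Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_enc_deviation <- function(deviations, bin_width = 0.05) {
  h <- bin_histogram(deviations$deviation, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.95, fill = "steelblue") +
    ggplot2::labs(x = "(ENc expected - ENc observed) / ENc expected",
                  y = "Number of genes") +
    ggplot2::theme_minimal()
}
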
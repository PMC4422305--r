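test_that("RSCU matrix has 59 fixed-order columns with zeros for absent families", {
  sim <- simulate_cds(3, length_range = c(100, 120), seed = 8)
  m <- build_rscu_matrix(sim$sequences)
  expect_equal(dim(m), c(3L, 59L))
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% colnames(m)))
  expect_equal(colnames(m), colnames(build_rscu_matrix(sim$sequences)))

  lys_gene <- make_gene(rep(c("AAA", "AAG"), 50))
  row <- build_rscu_matrix(lys_gene)[1, ]
  expect_true(all(row[setdiff(names(row), c("AAA", "AAG"))] == 0))
  expect_equal(unname(row[c("AAA", "AAG")]), c(1, 1))

  expect_error(build_rscu_matrix(tibble::tibble(id = character(),
                                                seq = character())),
               "no genes")
})

test_that("amino-acid usage matrix rows are simplex frequencies", {
  sim <- simulate_cds(5, length_range = c(100, 150), seed = 9)
  m <- build_aa_matrix(sim$sequences)
  expect_equal(dim(m), c(5L, 20L))
  expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)

  lys_gene <- make_gene(rep("AAA", 60))
  row <- build_aa_matrix(lys_gene)[1, ]
  # the ATG start contributes one Met residue alongside the Lys body
  expect_equal(unname(row["K"]), 60 / 61, tolerance = 1e-12)
  expect_equal(sum(row > 0), 2L)
})

test_that("CA eigenvalues match a brute-force eigendecomposition oracle", {
  withr::local_seed(110)
  for (rep in 1:5) {
    x <- matrix(rpois(12, 8) + 1, 3, 4,
                dimnames = list(paste0("r", 1:3), paste0("c", 1:4)))
    ca <- correspondence_analysis(x, n_axes = 10)
    expect_equal(ca$sv^2, oracle_ca_eigenvalues(x), tolerance = 1e-8)
    # total inertia equals the chi-squared statistic over the grand total
    chi2 <- suppressWarnings(stats::chisq.test(x)$statistic)
    expect_equal(ca$total_inertia, unname(chi2) / sum(x), tolerance = 1e-8)
    expect_equal(sum(ca$inertia$fraction), 1, tolerance = 1e-8)
    expect_true(all(diff(ca$inertia$fraction) <= 1e-12))
  }
})

test_that("CA satisfies the row-column transition formulas", {
  withr::local_seed(111)
  x <- matrix(rpois(40, 10) + 1, 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  ca <- correspondence_analysis(x, n_axes = 4)
  p <- x / sum(x)
  r <- rowSums(p)
  k <- length(ca$sv)
  # row principal coords = row profiles times column standard coords
  col_std <- ca$col_coords %*% diag(1 / ca$sv, k)
  expect_equal(unname((p / r) %*% col_std),
               unname(ca$row_coords), tolerance = 1e-8)
})

test_that("identical rows give zero inertia and zero coordinates", {
  x <- matrix(rep(c(2, 3, 5), each = 4), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  ca <- correspondence_analysis(x)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_equal(max(abs(ca$row_coords)), 0, tolerance = 1e-7)
})

test_that("CA result is invariant to row permutation", {
  withr::local_seed(112)
  x <- matrix(rpois(60, 6) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  ca1 <- correspondence_analysis(x, n_axes = 4)
  perm <- sample(nrow(x))
  ca2 <- correspondence_analysis(x[perm, ], n_axes = 4)
  expect_equal(ca1$inertia, ca2$inertia, tolerance = 1e-10)
  expect_equal(ca1$row_coords[rownames(x), ],
               ca2$row_coords[rownames(x), ], tolerance = 1e-8)
  expect_equal(ca1$col_coords, ca2$col_coords, tolerance = 1e-8)
})

test_that("CA axis-1 inertia agrees with an independent implementation", {
  withr::local_seed(113)
  x <- matrix(rpois(80, 12) + 1, 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:10)))
  ca <- correspondence_analysis(x, n_axes = 4)
  ref <- MASS::corresp(x, nf = 4)
  expect_equal(ca$sv[1:4], ref$cor[1:4], tolerance = 1e-8)
})

test_that("opposite GC3-extreme gene groups separate in sign on axis 1", {
  at_rich <- simulate_cds(15, length_range = c(150, 200), gc3_target = 0.15,
                          seed = 21)$sequences
  gc_rich <- simulate_cds(15, length_range = c(150, 200), gc3_target = 0.85,
                          seed = 22)$sequences
  gc_rich$id <- paste0("gc_", gc_rich$id)
  ca <- correspondence_analysis(build_rscu_matrix(
    dplyr::bind_rows(at_rich, gc_rich)))
  ax1 <- ca$row_coords[, 1]
  s_at <- sign(ax1[at_rich$id])
  s_gc <- sign(ax1[gc_rich$id])
  expect_true(all(s_at == s_at[1]))
  expect_true(all(s_gc == s_gc[1]))
  expect_true(s_at[1] != s_gc[1])
})

test_that("GC classification uses half-open intervals at the printed cuts", {
  got <- classify_gc(c(0.44, 0.45, 0.599, 0.60, 0.30, 0.95))
  expect_equal(as.character(got),
               c("low", "mid", "mid", "high", "low", "high"))
})

test_that("CA tidiers and plot return the advertised shapes", {
  sim <- simulate_cds(10, length_range = c(100, 150), seed = 23)
  ca <- correspondence_analysis(build_rscu_matrix(sim$sequences), n_axes = 3)
  rows <- tidy(ca, "rows")
  cols <- tidy(ca, "cols")
  expect_equal(nrow(rows), 10)
  expect_equal(nrow(cols), sum(colSums(build_rscu_matrix(sim$sequences)) > 0))
  expect_named(glance(ca),
               c("n_rows", "n_cols", "n_axes", "total_inertia",
                 "axis1_fraction", "axis2_fraction"))
  p <- autoplot(ca, colour_by = classify_gc(runif(10, 0.3, 0.7)))
  expect_s3_class(p, "ggplot")
})
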
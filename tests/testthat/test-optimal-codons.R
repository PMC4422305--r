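test_that("extreme pools have ceiling(fraction * n) genes, high = lower ENc", {
  sim <- simulate_cds(100, length_range = c(100, 150),
                      high_expr_fraction = 0.1, enrichment = 4, seed = 40)
  m <- codon_usage_metrics(sim$sequences)
  ca <- correspondence_analysis(build_rscu_matrix(sim$sequences))
  pools <- select_extreme_pools(ca, m, fraction = 0.05)
  expect_length(pools$high, 5)
  expect_length(pools$low, 5)
  expect_length(intersect(pools$high, pools$low), 0)
  s <- pools$summary
  expect_lte(s$mean_enc[s$pool == "high"], s$mean_enc[s$pool == "low"])
})

test_that("pool membership is deterministic under coordinate ties", {
  coords <- matrix(c(rep(0.5, 3), -1, -2, 1, 2, rep(0, 3)), ncol = 1)
  rownames(coords) <- c("b", "a", "c", "lo1", "lo2", "hi1", "hi2",
                        "z1", "z2", "z3")
  ca <- structure(list(row_coords = coords), class = "codon_ca")
  m <- tibble::tibble(id = rownames(coords), enc = rep(50, 10))
  p1 <- select_extreme_pools(ca, m, fraction = 0.3)
  p2 <- select_extreme_pools(ca, m, fraction = 0.3)
  expect_equal(p1$high, p2$high)
  # tied coordinates at each cutoff resolve lexicographically: of the three
  # genes tied at 0.5, "a" joins the top tail; of the zeros, "z1" the bottom
  expect_setequal(p1$high, c("hi1", "hi2", "a"))
  expect_setequal(p1$low, c("lo1", "lo2", "z1"))
})

test_that("planted high-expression genes dominate the recovered high pool", {
  sim <- simulate_cds(200, length_range = c(120, 200),
                      high_expr_fraction = 0.1, enrichment = 3, seed = 41)
  m <- codon_usage_metrics(sim$sequences)
  ca <- correspondence_analysis(build_rscu_matrix(sim$sequences))
  pools <- select_extreme_pools(ca, m, fraction = 0.05)
  truly_high <- sim$truth$id[sim$truth$class == "high"]
  expect_gte(mean(pools$high %in% truly_high), 0.8)
})

test_that("chi-squared flags printed Ser and Gly optimal codons exactly", {
  p <- bmori_pool_counts()
  opt <- chi2_optimal(stats::setNames(p$n_high, p$codon),
                      stats::setNames(p$n_low, p$codon))
  ser <- opt$codon[opt$amino_acid == "S" & opt$optimal]
  gly <- opt$codon[opt$amino_acid == "G" & opt$optimal]
  expect_setequal(ser, c("TCC", "TCG", "AGC"))
  expect_setequal(gly, c("GGC", "GGG"))
})

test_that("full printed pool table reproduces every reported optimal flag", {
  p <- bmori_pool_counts()
  opt <- chi2_optimal(stats::setNames(p$n_high, p$codon),
                      stats::setNames(p$n_low, p$codon))
  merged <- dplyr::inner_join(opt, p[, c("codon", "optimal_reported")],
                              by = "codon")
  expect_equal(merged$optimal, merged$optimal_reported)
  expect_equal(sum(opt$optimal), 27)
  expect_true(all(substring(opt$codon[opt$optimal], 3, 3) %in% c("G", "C")))
  # reported per-pool RSCU is recovered to the printed 2-decimal precision
  # (|diff| <= 0.005 admits the half-up/half-even tie at CGG low, 0.225)
  expect_true(all(abs(merged$rscu_high -
                        p$rscu_high[match(merged$codon, p$codon)]) <=
                    0.005 + 1e-9))
  expect_true(all(abs(merged$rscu_low -
                        p$rscu_low[match(merged$codon, p$codon)]) <=
                    0.005 + 1e-9))
})

test_that("identical pools yield chi2 = 0, p = 1 and no optimal codons", {
  cnt <- c(GCT = 50, GCC = 80, GCA = 20, GCG = 30, AAA = 40, AAG = 60)
  opt <- chi2_optimal(cnt, cnt)
  testable <- opt[opt$testable, ]
  expect_equal(testable$chi2, rep(0, nrow(testable)))
  expect_equal(testable$p, rep(1, nrow(testable)))
  expect_false(any(opt$optimal))
})

test_that("at most k - 1 codons per family can be optimal", {
  p <- bmori_pool_counts()
  opt <- chi2_optimal(stats::setNames(p$n_high, p$codon),
                      stats::setNames(p$n_low, p$codon))
  per_family <- tapply(opt$optimal, opt$amino_acid, sum)
  deg <- tapply(opt$codon, opt$amino_acid, length)
  expect_true(all(per_family <= deg[names(per_family)] - 1))
})

test_that("effect direction is scale invariant, significance is not", {
  hi <- c(GCT = 6, GCC = 14, GCA = 5, GCG = 5)
  lo <- c(GCT = 12, GCC = 8, GCA = 5, GCG = 5)
  small <- chi2_optimal(hi, lo, alpha = 0.01)
  big <- chi2_optimal(10 * hi, 10 * lo, alpha = 0.01)
  dir_small <- small$n_high / sum(hi) > small$n_low / sum(lo)
  dir_big <- big$n_high / sum(10 * hi) > big$n_low / sum(10 * lo)
  expect_equal(dir_small, dir_big)
  expect_true(all(big$chi2[big$testable] >= small$chi2[small$testable]))
  expect_gte(sum(big$optimal), sum(small$optimal))
})

test_that("untestable families and never-optimal Met/Trp are handled", {
  hi <- c(GCC = 30, GCT = 10, ATG = 20, TGG = 5)
  lo <- c(GCC = 10, GCT = 30, ATG = 15, TGG = 5, AAA = 12)
  opt <- chi2_optimal(hi, lo)
  expect_false(opt$optimal[opt$codon == "ATG"])
  expect_false(opt$optimal[opt$codon == "TGG"])
  # Lys absent from the high pool: untestable, never optimal
  expect_false(opt$testable[opt$codon == "AAA"])
  expect_false(opt$optimal[opt$codon == "AAA"])
  expect_true(opt$optimal[opt$codon == "GCC"])
})
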
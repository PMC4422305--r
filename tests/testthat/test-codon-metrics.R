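test_that("codon counting excludes the terminal stop and pools additively", {
  g <- tibble::tibble(id = "g1", seq = "ATGAAATAA")
  cnt <- count_codons(g)
  expect_equal(sum(cnt$count), 2)
  expect_equal(cnt$count[cnt$codon == "ATG"], 1L)
  expect_equal(cnt$count[cnt$codon == "AAA"], 1L)
  expect_equal(cnt$count[cnt$codon == "TAA"], 0L)

  two <- dplyr::bind_rows(g, dplyr::mutate(g, id = "g2"))
  expect_equal(count_codons(two)$count, 2L * cnt$count)

  expect_error(count_codons(tibble::tibble(id = "x", seq = "ATGA")),
               "multiple of 3")
})

test_that("RSCU matches brute-force enumeration and conserves family sums", {
  withr::local_seed(101)
  for (rep in 1:5) {
    cnt <- random_codon_counts(50)
    got <- rscu(cnt)
    expected <- oracle_rscu(counts_to_codon_strings(cnt))
    obs <- stats::setNames(got$rscu, got$codon)[names(expected)]
    expect_equal(unname(obs), unname(expected), tolerance = 1e-12)
    sums <- tapply(got$rscu, got$amino_acid, sum)
    deg <- tapply(got$count, got$amino_acid, length)
    present <- !is.na(sums)
    expect_equal(unname(sums[present]), unname(deg[present]),
                 tolerance = 1e-12)
  }
})

test_that("RSCU handles uniform usage, absent families, and stop request", {
  got <- rscu(c(GCT = 5, GCC = 5, GCA = 5, GCG = 5))
  expect_equal(got$rscu[got$amino_acid == "A"], rep(1, 4))
  expect_true(all(is.na(got$rscu[got$amino_acid == "K"])))
  with_stops <- rscu(c(TAA = 2, TGA = 1, TAG = 0), include_stops = TRUE)
  expect_equal(with_stops$rscu[with_stops$codon == "TAA"], 2)
})

test_that("GC partitions match hand counts and brute-force enumeration", {
  two_codon <- gc_partitions(c(ATG = 1, AAA = 1))
  expect_equal(two_codon$gc1, 0)
  expect_equal(two_codon$gc2, 0)
  expect_equal(two_codon$gc3, 0.5)
  expect_equal(two_codon$gc12, 0)

  all_gcg <- gc_partitions(c(GCG = 10))
  expect_equal(unlist(all_gcg), c(gc = 1, gc1 = 1, gc2 = 1, gc3 = 1, gc12 = 1))

  withr::local_seed(102)
  cnt <- random_codon_counts(50)
  got <- unlist(gc_partitions(cnt))
  expect_equal(unname(got),
               unname(oracle_gc_positions(counts_to_codon_strings(cnt))),
               tolerance = 1e-12)
  expect_error(gc_partitions(c(AAA = 0)), "empty")
})

test_that("silent composition excludes Met/Trp/stops and sums to one", {
  lys_only <- silent_composition(c(AAA = 5))
  expect_equal(lys_only$a3s, 1)
  expect_equal(lys_only$gc3s, 0)
  expect_error(silent_composition(c(ATG = 7)), "undefined")
  mixed <- silent_composition(c(GCC = 1, GCA = 1))
  expect_equal(mixed$c3s, 0.5)
  expect_equal(mixed$a3s, 0.5)
  expect_equal(mixed$gc3s, 0.5)

  withr::local_seed(103)
  for (rep in 1:5) {
    cnt <- random_codon_counts(50)
    got <- silent_composition(cnt)
    expect_equal(got$a3s + got$t3s + got$c3s + got$g3s, 1, tolerance = 1e-12)
    expect_equal(unlist(got),
                 oracle_silent(counts_to_codon_strings(cnt)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("codonW-style silent denominators differ but stay in [0, 1]", {
  cnt <- c(GCC = 3, GCA = 1, AAA = 2, AAG = 2)
  simple <- silent_composition(cnt, method = "simple")
  cw <- silent_composition(cnt, method = "codonw")
  expect_equal(simple$gc3s, cw$gc3s)  # gc3s definition is shared
  vals <- unlist(cw[c("a3s", "t3s", "c3s", "g3s")])
  expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
})

test_that("ENc hits Wright's analytic limits and handles F = 0", {
  # one codon per amino acid, n = 2 each: every family monomorphic
  tab <- codon_table(include_stops = FALSE)
  mono <- stats::setNames(rep(0, 64), CODONS)
  for (a in unique(tab$amino_acid)) {
    mono[tab$codon[tab$amino_acid == a][1]] <- 2
  }
  expect_equal(enc(mono), 20)

  # uniform synonymous usage at large n approaches 61
  unif <- stats::setNames(rep(0, 64), CODONS)
  for (a in unique(tab$amino_acid)) {
    fam <- tab$codon[tab$amino_acid == a]
    unif[fam] <- 600 / length(fam)
  }
  expect_equal(enc(unif), 61, tolerance = 1e-6)

  # a 2-fold family with n = 2 split 1/1 has F = 0 and is excluded from its
  # class average; with no other usable 2-fold family ENc is undefined
  expect_true(is.na(enc(c(AAA = 1, AAG = 1))))

  expect_true(is.na(enc(c(ATG = 10))))
})

test_that("ENc stays within [20, 61] on random and simulated genes", {
  withr::local_seed(104)
  for (rep in 1:10) {
    cnt <- random_codon_counts(sample(60:300, 1))
    e <- enc(cnt)
    if (!is.na(e)) expect_true(e >= 20 && e <= 61)
  }
  sim <- simulate_cds(20, length_range = c(500, 600), seed = 5)
  m <- codon_usage_metrics(qc_filter(sim$sequences)$passed)
  expect_true(all(m$enc >= 20 & m$enc <= 61))
  expect_gt(mean(m$enc), 59)
  expect_lte(mean(m$enc), 61)
})

test_that("expected ENc follows the analytic curve on a grid", {
  s <- seq(0, 1, by = 0.1)
  oracle <- vapply(s, function(S) 2 + S + 29 / (S^2 + (1 - S)^2), numeric(1))
  expect_equal(expected_enc(s), oracle)
  expect_error(expected_enc(1.2), "0, 1")
})

test_that("CAI weights derive from reference RSCU with a floor", {
  equal_ref <- c(GCT = 5, GCC = 5, GCA = 5, GCG = 5)
  w <- suppressWarnings(cai_weights(equal_ref))
  expect_equal(w$w[w$amino_acid == "A"], rep(1, 4))

  skew <- suppressWarnings(cai_weights(c(AAA = 9, AAG = 1)))
  expect_equal(skew$w[skew$codon == "AAA"], 1)
  expect_equal(skew$w[skew$codon == "AAG"], 1 / 9, tolerance = 1e-12)

  floored <- suppressWarnings(cai_weights(c(AAA = 10, AAG = 0)))
  expect_equal(floored$w[floored$codon == "AAG"], 0.01)
  expect_false(any(c("ATG", "TGG") %in% floored$codon))
})

test_that("CAI is the geometric mean of weights, bounded by one", {
  w <- suppressWarnings(cai_weights(c(AAA = 9, GCC = 9, GCT = 3)))
  only_max <- c(AAA = 4, GCC = 2)
  expect_equal(cai(only_max, w), 1)

  # two codons with w = 1 and w = 0.25: geometric mean 0.5
  w2 <- suppressWarnings(cai_weights(c(GCC = 8, GCT = 2)))
  expect_equal(w2$w[w2$codon == "GCT"], 0.25)
  expect_equal(cai(c(GCC = 1, GCT = 1), w2), 0.5)

  expect_equal(cai(c(GCC = 2, GCT = 2), w2), cai(c(GCC = 1, GCT = 1), w2))

  withr::local_seed(105)
  for (rep in 1:5) {
    cnt <- random_codon_counts(40)
    expect_lte(cai(cnt, w2), 1)
  }
})

test_that("GRAVY and aromaticity match the hydropathy scale", {
  expect_equal(gravy(c(CGT = 10)), -4.5)   # poly-Arg
  expect_equal(gravy(c(ATT = 10)), 4.5)    # poly-Ile
  expect_equal(gravy(c(CGT = 5, ATT = 5)), 0)
  expect_equal(aromo(c(TTT = 10)), 1)      # poly-Phe
  expect_equal(aromo(c(AAA = 10)), 0)      # poly-Lys
  expect_equal(aromo(c(TGG = 1, AAA = 9)), 0.1)
})

test_that("hydropathy constants agree with the published aaindex scale", {
  data("aaindex", package = "seqinr", envir = environment())
  kd <- aaindex[["KYTJ820101"]]$I
  three <- sapply(names(kd), function(n) {
    paste0(toupper(substring(n, 1, 1)), substring(n, 2))
  })
  one <- seqinr::a(three)
  expect_equal(unname(kd[match(names(codonscope:::KD_HYDROPATHY), one)]),
               unname(codonscope:::KD_HYDROPATHY))
})

test_that("per-gene metrics table carries every index consistently", {
  sim <- simulate_cds(8, length_range = c(100, 200), seed = 6)
  ref <- simulate_cds(4, length_range = c(100, 150),
                      gc3_target = 0.8, seed = 7)
  m <- codon_usage_metrics(sim$sequences, reference = ref$sequences)
  expect_equal(nrow(m), 8)
  expect_true(all(!is.na(m$cai) & m$cai > 0 & m$cai <= 1))
  expect_equal(m$gc12, (m$gc1 + m$gc2) / 2)
  expect_equal(m$enc_expected, expected_enc(m$gc3s))
  expect_equal(m$n_codons, m$length_nt / 3 - 1)
  no_ref <- codon_usage_metrics(sim$sequences)
  expect_true(all(is.na(no_ref$cai)))
})
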
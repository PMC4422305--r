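# Brute-force oracles and small fixture builders. Every oracle works by
# direct enumeration over codon strings or explicit formulas, independent of
# the implementation paths it checks.

# expand a named codon-count vector into the flat vector of codon strings
counts_to_codon_strings <- function(cnt) {
  rep(names(cnt), times = cnt)
}

# brute-force RSCU by enumeration over codon strings
oracle_rscu <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  out <- list()
  for (a in unique(aa[aa != "*"])) {
    fam <- names(code)[code == a]
    obs <- table(factor(codons[aa == a], levels = fam))
    out[fam] <- as.list(length(fam) * as.numeric(obs) / sum(obs))
  }
  unlist(out)
}

# brute-force GC by position, counting characters one by one
oracle_gc_positions <- function(codons) {
  chars <- do.call(rbind, strsplit(codons, ""))
  gcp <- colMeans(chars == "G" | chars == "C")
  c(gc = mean(gcp), gc1 = gcp[[1]], gc2 = gcp[[2]], gc3 = gcp[[3]],
    gc12 = (gcp[[1]] + gcp[[2]]) / 2)
}

# brute-force silent-site composition (simple definition)
oracle_silent <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  deg <- table(code[code != "*"])
  syn <- codons[code[codons] != "*" & deg[code[codons]] > 1]
  third <- substring(syn, 3, 3)
  c(gc3s = mean(third %in% c("G", "C")),
    a3s = mean(third == "A"), t3s = mean(third == "T"),
    c3s = mean(third == "C"), g3s = mean(third == "G"))
}

# brute-force Spearman rho via explicit Pearson-on-midranks formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force CA eigenvalues: eigendecomposition of S'S for the
# standardized-residual matrix built from first principles
oracle_ca_eigenvalues <- function(x) {
  p <- x / sum(x)
  r <- rowSums(p); cm <- colSums(p)
  e <- outer(r, cm)
  s <- (p - e) / sqrt(e)
  ev <- eigen(crossprod(s), symmetric = TRUE)$values
  ev[ev > 1e-12]
}

# random codon-count table over a subset of codons
random_codon_counts <- function(n_codons = 50, include_stops = FALSE) {
  pool <- names(Biostrings::GENETIC_CODE)
  if (!include_stops) pool <- pool[Biostrings::GENETIC_CODE != "*"]
  cod <- sample(pool, n_codons, replace = TRUE)
  tab <- table(cod)
  stats::setNames(as.numeric(tab), names(tab))
}

# write a tibble of sequences to a temporary FASTA, wrapped or not
write_temp_fasta <- function(seqs, wrap = FALSE) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(seq_len(nrow(seqs)), function(i) {
    body <- seqs$seq[i]
    if (wrap) body <- gsub("(.{60})", "\\1\n", body)
    c(paste0(">", seqs$id[i]), strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, path)
  path
}

# render a codon-count vector as Kazusa-format text (4 entries per line)
kazusa_text <- function(cnt) {
  cnt <- cnt[names(Biostrings::GENETIC_CODE)]
  names(cnt) <- names(Biostrings::GENETIC_CODE)
  cnt[is.na(cnt)] <- 0
  freq <- round(1000 * cnt / sum(cnt), 1)
  fields <- sprintf("%s %.1f(%d)", gsub("T", "U", names(cnt)), freq, cnt)
  paste(vapply(split(fields, ceiling(seq_along(fields) / 4)),
               paste, character(1), collapse = "  "),
        collapse = "\n")
}

# a QC-clean hand-built gene: ATG + body codons + TAA
make_gene <- function(body_codons, id = "g1") {
  tibble::tibble(id = id,
                 seq = paste0("ATG", paste(body_codons, collapse = ""), "TAA"))
}
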
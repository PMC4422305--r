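---
title: "Analysing codon usage bias with codonscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing codon usage bias with codonscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscope)
```

## The problem

Synonymous codons are not used uniformly. In a genome the balance between
directional mutation pressure (which drags all positions toward a
nucleotide composition) and natural selection (which favours codons matched
to the tRNA pool, especially in highly expressed genes) leaves a
quantifiable signature in coding sequences. codonscope implements the
classical codonW-style workflow for dissecting that signature in a set of
coding DNA sequences (CDSs), as applied to transcriptome-scale gene sets
such as the silkworm *Bombyx mori* RefSeq collection: per-gene indices,
ordination of codon usage, mutation-versus-selection diagnostics,
identification of translationally optimal codons, and comparison of codon
preferences against other organisms.

Everything operates on tidy tables: sequences in, tibbles out, so stages
chain with the pipe and feed straight into dplyr/ggplot2.

## Input and quality control

`read_cds_fasta()` reads multi-record FASTA (uppercased, U normalised to
T). `qc_filter()` applies the filters conventional for codon-usage work: no
ambiguity codes or gaps, length a multiple of 3, a correct ATG start and
stop codon, no internal in-frame stop, and a minimum length. Every failure
reason is enumerated per sequence rather than short-circuited, so one QC
report row tells the whole story.

Two boundary conventions are deliberate package choices, exposed as
parameters rather than hard-coded:

* the length filter is `length_nt >= 300` (the threshold is the
  `min_length_nt` argument), with the stop codon counted in the length —
  the GenBank CDS convention;
* the terminal stop codon is excluded from all downstream codon counting,
  so a 300 nt gene contributes 99 codons.

Known contaminant ids (e.g. mitochondrial genes in a nuclear analysis) are
excluded by an explicit id blacklist, not by sequence inspection, and are
reported with their own `BLACKLISTED` reason code so the QC report still
covers every input exactly once.

## Per-gene indices

`codon_usage_metrics()` computes, per gene:

* **GC, GC1, GC2, GC3, GC12** — G+C fractions over counted codons, by
  position; GC12 is the mean of GC1 and GC2.
* **GC3s, A3s/T3s/C3s/G3s** — composition at *synonymous* third positions,
  i.e. over codons of multi-codon families only (Met, Trp, stops
  excluded). The default (`method = "simple"`) divides by the number of
  synonymous-family codons, so the four base fractions sum to 1. A
  codonW-style per-base-opportunity denominator is available with
  `method = "codonw"`; the two differ because not every family can use
  every base at position 3. GC3s itself is always the simple G+C fraction
  at synonymous third positions.
* **RSCU** — for codon $c$ in a $k$-fold family with total $T$:
  $\mathrm{RSCU}(c) = k\,n_c/T$. Family values sum to $k$; absent families
  give `NA` (and 0 in the ordination matrix, see below).
* **ENc** — Wright's effective number of codons. For each amino acid with
  degeneracy $k>1$ and $n \ge 2$ counted codons, the homozygosity is
  $F = (n\sum_i p_i^2 - 1)/(n-1)$; class averages $\bar F_k$ over
  $k \in \{2,3,4,6\}$ give
  $\mathrm{ENc} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
  capped at 61. Conventions (below) follow codonW so that results are
  reproducible against the field's reference implementation.
* **CAI** — the codon adaptation index: the geometric mean of relative
  adaptiveness values $w_c$ over the gene's codons (Met, Trp, stops
  excluded), where $w_c = \mathrm{RSCU}(c)/\max_{c' \in \text{family}}
  \mathrm{RSCU}(c')$ is derived by `cai_weights()` from a pooled reference
  set of highly expressed genes, classically ribosomal proteins.
* **GRAVY** and **Aromo** — mean Kyte–Doolittle hydropathy and the
  fraction of aromatic residues (Phe/Tyr/Trp) of the conceptual
  translation; both are covariates of codon usage trends, not codon
  statistics themselves.

### ENc numerical conventions

Three degenerate situations need fixed rules:

1. An amino acid with $n < 2$ counted codons carries no information about
   homozygosity and is skipped.
2. $F = 0$ (e.g. a two-fold family observed once with each codon) would
   make a class average blow up; such $F$ values are excluded from their
   class average, with the class's contributing count reduced accordingly.
3. The 3-fold class contains only Ile. When it is missing or excluded, its
   class average is imputed as $(\bar F_2 + \bar F_4)/2$; when any *other*
   class average is missing, ENc is reported `NA` for that gene.

These are the codonW conventions; they matter only for short or highly
biased genes, but they make results bit-for-bit reproducible.

### CAI floor

Codons absent from the reference pool would have $w = 0$ and an undefined
$\log w$. They receive a configurable floor, default $w = 0.01$. A family
entirely absent from the reference gets the floor for all its codons and a
warning.

## The expected-ENc curve and deviation statistic

If codon choice is constrained only by a G+C bias at silent sites, the
expected ENc at $S = \mathrm{GC3s}$ is

$$\mathrm{ENc}_{\exp} = 2 + S + \frac{29}{S^2 + (1-S)^2},$$

a curve with maximum 61 near $S = 0.5$ and values 31 and 32 at the
composition extremes. `enc_plot_data()` pairs each gene with this curve;
`enc_deviation()` computes the relative shortfall
$(\mathrm{ENc}_{\exp} - \mathrm{ENc}_{\mathrm{obs}})/\mathrm{ENc}_{\exp}$,
whose frequency distribution peaks near zero when mutation bias alone is
at work and shifts positive when genes are more biased than their GC3s
predicts.

## Correspondence analysis

`build_rscu_matrix()` assembles the genes × 59 matrix of RSCU values (61
sense codons minus the single-codon Met and Trp families, removing
amino-acid-composition variation). `correspondence_analysis()` then runs
classical CA: with $P$ the matrix over its grand total, row masses $r$ and
column masses $c$, the standardized residuals
$S = D_r^{-1/2}(P - rc^{\mathsf T})D_c^{-1/2}$ are decomposed by SVD;
principal coordinates are mass-scaled singular vectors times singular
values, axis $i$ explains $\sigma_i^2/\sum_j \sigma_j^2$ of the total
inertia, and the total inertia equals the table's chi-squared statistic
over its grand total. The same machinery applies to the genes × 20
amino-acid frequency matrix from `build_aa_matrix()`.

Numerical choices:

* CA signs are arbitrary, so each axis is oriented to make the column
  (codon) with the largest absolute coordinate positive — runs and
  plots are reproducible without changing any distance.
* Genes with absent families contribute 0 in those columns instead of
  being dropped, keeping the gene set identical across pipeline stages.
  All-zero rows or columns (which CA cannot weight) are dropped with a
  warning.
* 20 axes are retained by default, enough to draw the usual relative/
  cumulative inertia profile.

`classify_gc()` provides the conventional low / mid / high GC colouring
(half-open intervals at 45% and 60%) for `autoplot()` of the ordination.

## Neutrality regression

`neutrality_fit()` regresses GC12 on GC3 by ordinary least squares. Under
complete neutrality the same mutational pressure drives all positions and
the slope is 1; under complete selective constraint at positions 1–2 the
slope is 0. The slope × 100 is conventionally reported as the mutation
pressure percentage and its complement attributed to other forces,
principally selection. OLS (not major-axis) regression is used because
that percentage reading presumes the regression of GC12 *on* GC3.
`spearman_matrix()` complements this with the usual rank-correlation table
between indices and ordination axes (mid-rank ties, pairwise-complete,
two-tailed p, no multiple-testing correction — correlation reports in
this field conventionally print raw p with `**`/`*` stars).

## Optimal codons

`select_extreme_pools()` ranks genes by CA axis 1 and takes the two tails
of size `ceiling(fraction * n)` (default fraction 0.05; coordinate ties at
a cutoff are broken lexicographically by gene id so pools are
deterministic). The tail with the lower pooled mean ENc — the more biased,
putatively highly expressed side — is labelled `high`. `chi2_optimal()`
then tests each sense codon with a 2×2 Pearson chi-squared (codon versus
its other synonyms × high versus low pool), without continuity correction
by default (a Yates flag exists), and flags a codon optimal iff $p <
\alpha$ (default 0.01) **and** its relative synonymous frequency is higher
in the high pool. The per-codon directional test is what lets a codon with
RSCU below 1 in both pools still be optimal when its relative use rises
significantly in the high pool. Stop codons are excluded from testing by
default; Met and Trp are never optimal. No multiple-testing correction is
applied, matching the conventional fixed-$\alpha$ rule for this test.

The pool fraction deliberately remains a user-facing parameter: published
analyses vary between percentage-of-genes and fixed-count conventions for
the ordination extremes, and the choice changes the pooled counts.

## Species comparison

`parse_kazusa()` reads the Codon Usage Database text layout
(`UUU 17.6(714298)` fields); all 64 codons are required and frequencies
must sum to 1000 ± 1. `frequency_ratio()` converts the study organism's
pooled counts to per-1000 frequencies — stop codons included in the
normalisation, matching the Kazusa convention (a ~0.3% effect on ratios) —
and divides by the reference. A within-family relative-frequency mode
(`method = "family"`) is available because both conventions appear in the
literature. `indicative_codons()` flags ratios strictly above 2 or
strictly below 0.5; the strictness means a ratio of exactly 2 is not
indicative, and the thresholds are symmetric (a table and its reciprocal
select the same codons).

## The synthetic-data generator

`simulate_cds()` is the statistical stand-in for a real CDS collection:
every pipeline stage is exercised against it, and its defaults define the
package's validation conditions.

* **Structure**: each gene is ATG + sampled codons + one stop, so
  simulated genes pass QC by construction.
* **Lengths**: uniform over 100–600 codons by default — a set filtered at
  300 nt with a mean around 350 codons, the shape of a typical curated CDS
  collection.
* **Amino-acid composition**: uniform over the 18 degenerate amino acids
  with Met and Trp down-weighted to 0.2, guaranteeing every ENc degeneracy
  class is populated in genes of realistic length.
* **Codon preferences**: uniform within family by default (the no-bias
  limit: mean ENc of long genes lands in [59, 61]);
  `gc3_targeted_prefs(S)` splits each family's probability mass between
  G/C-ending and A/T-ending codons to hit a GC3s target — a mutation-only
  model whose genes track the expected-ENc curve within ±2 units.
* **Expression classes**: a `high_expr_fraction` (0.1 in the validation
  runs) of genes sample codons with a planted optimal set up-weighted by
  an `enrichment` factor (3 in the validation runs). The default planted
  set is one G/C-ending codon per degenerate family (18 codons),
  mirroring the G/C-ending optimal-codon structure reported for
  GC-selected transcriptomes. At enrichment 1 the classes are
  statistically indistinguishable, which calibrates the false-positive
  rate of the optimal-codon test at ~α.
* **Reproducibility**: one integer seed; per-gene substreams are derived
  by counter, so extending `n_genes` leaves earlier genes unchanged and
  the emitted FASTA is byte-identical across runs.

What the simulator does **not** emulate: real amino-acid composition (and
hence realistic GRAVY/Aromo distributions), correlation between expression
class and GC content or length, isochore structure, or any phylogenetic
signal. Passing the validation suite therefore demonstrates that the
*estimators and the pipeline logic* behave correctly under controlled
codon-sampling models — not that any biological conclusion about a real
genome is reproduced. Runs on real data are supported (the QC funnel,
indices and reports all scale) but are outside the test suite.

## Validation problem sizes

The test suite and the acceptance script use: published pooled high/low
codon counts (≈34,000 codons) for the RSCU and optimal-codon oracles;
30 genes of 500–600 codons for the no-bias ENc limit; 5 random 6×8 tables
for the CA eigen-oracle; n = 1000 points per slope for neutrality
recovery (slopes 0.15/0.5/1.0 recovered within ±0.05); and 1000 simulated
genes (10% highly expressed, enrichment 3) for end-to-end planted-optimal
recovery, where sensitivity is ≥ 90%. These sizes were chosen so each
check is statistically decisive while the whole suite stays fast enough to
run on every change.

## Known limitations

* Standard genetic code only; no alternative codes, no tRNA adaptation
  index, no codon-pair statistics.
* The codonW-style silent-composition denominator implemented behind
  `method = "codonw"` follows the per-base-opportunity idea; other
  implementations differ in how they treat the Ser/Leu/Arg split
  families, so cross-tool comparisons of A3s–G3s should use
  `method = "simple"`.
* ENc is undefined (NA) for genes too short or too skewed to populate the
  degeneracy classes; downstream functions drop and count such genes
  rather than imputing.
* Correspondence analysis treats the RSCU matrix as a contingency-like
  table (the classical codonW choice). Row masses are then driven by RSCU
  totals, not by gene length; this matches the reference workflow but is
  a modelling convention, not a statistical necessity.
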
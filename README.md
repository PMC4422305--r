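# codonscope

Codon usage bias analysis for coding sequences, in tidyverse style.

Synonymous codons are used unevenly, and the pattern of that unevenness
records which forces — directional mutation pressure, natural selection
for translational efficiency, nucleotide composition, expression level —
shaped a gene set. codonscope implements the classical codonW-style
workflow for dissecting codon usage in a collection of coding DNA
sequences (CDSs), of the kind applied to transcriptome-scale gene sets
such as the silkworm (*Bombyx mori*) RefSeq collection:

* **QC** of CDS FASTA input (start/stop/internal-stop/ambiguity/length
  filters, every failure reason enumerated);
* **per-gene indices**: GC, GC1–GC3, GC12, GC3s, silent-site base
  composition (A3s/T3s/C3s/G3s), RSCU, Wright's effective number of
  codons (ENc), the codon adaptation index (CAI) against a highly
  expressed reference set, GRAVY and aromaticity;
* **correspondence analysis** of the genes × 59 RSCU matrix (and of
  amino-acid usage), with per-axis inertia fractions;
* **mutation-vs-selection diagnostics**: ENc–GC3s plot with the expected
  curve `ENc = 2 + S + 29/(S² + (1−S)²)` (S = GC3s), the
  `(ENCexp − ENCobs)/ENCexp` deviation distribution, the neutrality
  regression of GC12 on GC3 (slope × 100 read as the mutation-pressure
  percentage), and Spearman correlation matrices;
* **optimal codons**: pooled codon usage of the axis-1 extreme gene
  tails compared codon-by-codon with a 2×2 Pearson chi-squared test
  (optimal iff p < 0.01 and relatively more frequent in the
  low-ENc/"highly expressed" pool);
* **species comparison** against Kazusa-format codon usage tables
  (indicative codons: per-1000 frequency ratio > 2 or < 0.5);
* a **seeded CDS simulator** with controllable codon preferences, GC3
  targets and a planted optimal-codon set, used to validate every stage.

All user-facing functions take a data frame first and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

The package ships the published pooled codon counts of the ordination
extreme gene pools for *B. mori* (`bmori_pool_counts()`). Re-running the
optimal-codon test on the serine family:

```r
library(codonscope)
pools <- bmori_pool_counts()
opt <- chi2_optimal(setNames(pools$n_high, pools$codon),
                    setNames(pools$n_low, pools$codon))
dplyr::filter(opt, amino_acid == "S")
#> # A tibble: 6 × 10
#>   codon rscu_high n_high rscu_low n_low        p optimal
#>   <chr>     <dbl>  <dbl>    <dbl> <dbl>    <dbl> <lgl>
#> 1 TCT       0.713    153    1.49    233 1.33e-15 FALSE
#> 2 TCC       1.71     366    0.442    69 4.24e-35 TRUE
#> 3 TCA       0.420     90    1.77    276 2.88e-45 FALSE
#> 4 TCG       1.56     335    0.340    53 8.37e-36 TRUE
#> 5 AGT       0.336     72    1.40    219 1.07e-34 FALSE
#> 6 AGC       1.26     271    0.551    86 5.27e-14 TRUE
```

Three serine codons (UCC, UCG, AGC — all G/C-ending) are significantly
over-used in the highly expressed pool: they are the optimal codons for
Ser. Over the whole table the test flags 27 optimal codons, every one
ending in G or C.

On simulated data, end to end:

```r
sim     <- simulate_cds(200, high_expr_fraction = 0.1, enrichment = 3, seed = 1)
passed  <- qc_filter(sim$sequences, min_length_nt = 300)$passed
metrics <- codon_usage_metrics(passed)
metrics[1:3, c("id", "n_codons", "gc", "gc3s", "enc", "gravy", "aromo")]
#> # A tibble: 3 × 7
#>   id       n_codons    gc  gc3s   enc  gravy aromo
#> 1 gene0001      278 0.537 0.731  49.7 -0.438 0.140
#> 2 gene0002      274 0.555 0.716  46.1 -0.740 0.113
#> 3 gene0003      577 0.541 0.719  47.7 -0.654 0.116

ca <- correspondence_analysis(build_rscu_matrix(passed))
ca
#> Correspondence analysis: 200 rows x 59 columns, 20 axes retained
#> Total inertia: 0.244622
#> Axis inertia fractions: 12.16%, 6.15%, 5.57%, 4.79%

neutrality_fit(metrics)
#> Neutrality plot regression (n = 200)
#> GC12 = 0.4346 + 0.0267 * GC3
#> R2 = 0.0074, p = 0.227
#> Mutation pressure 2.67% vs other forces 97.33%
```

The per-gene metrics feed `select_extreme_pools()` + `chi2_optimal()` for
optimal-codon discovery, `plot_enc_gc3s()` / `plot_enc_deviation()` /
`autoplot()` for the standard figures, and `compare_usage()` with a
`parse_kazusa()` table for cross-species comparison. `run_codon_analysis()`
orchestrates all stages on a FASTA file and writes every report table as
TSV plus a JSON run summary (a thin CLI wrapper lives in
`inst/scripts/cub.R`).

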
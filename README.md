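# cardioburden

Family- and cohort-based analysis of rare, damaging variants in a candidate
cardiac gene, built around the alpha-myosin heavy chain gene *MYH6* and
hypoplastic left heart syndrome (HLHS). The package is for genetics groups
who need the complete analytic chain from a multigenerational pedigree to a
case-control burden statement, an outcome comparison, and tissue-level
expression follow-up — with every statistical primitive testable, and a
synthetic-data generator standing in for protected patient data.

The pipeline has four analytic stages plus simulation:

1. **Pedigree segregation filtering** — keep variants whose alternate allele
   is shared by all affected relatives (two sibs and a distant relative in
   the template family) and confirmed absent in the unaffected mother, then
   reduce to genes and rank by cardiac expression.
2. **Carrier-collapsing burden test** — classify variants as rare
   (population frequency ≤ 0.5% or novel) and damaging (protein-truncating
   or in-frame indel; missense with PolyPhen-2 ≥ 0.5 or SIFT ≤ 0.05),
   collapse to a per-subject carrier indicator, and test the 2×2 table

   |         | carrier | non-carrier |
   |---------|---------|-------------|
   | case    | a       | b           |
   | control | c       | d           |

   with a from-scratch two-sided Fisher exact test
   (p = Σ Pr(table) over tables with the observed margins whose probability
   ≤ that of the observed table, computed in log space), the sample odds
   ratio (ad)/(bc) with Woolf interval, and the carrier-fraction enrichment
   100·(a/(a+b))/(c/(c+d)).
3. **Transplant-free survival** — Kaplan-Meier product-limit curves
   S(t_j) = Π (1 − d_i/n_i) per genotype group and the Gehan-Breslow
   (generalized Wilcoxon) test, the weighted log-rank with weight n_j (total
   at risk), U = Σ_j n_j (d_1j − d_j n_1j / n_j) referred through U²/Var to
   a 1-df chi-square.
4. **Matched-pair expression** — TPM normalization, fold changes as
   geometric means of per-pair MUT/WT ratios with a paired t-test on log₂
   ratios (BH-corrected across genes), and Western blot densitometry via a
   pair-blocked linear model on log(band/GAPDH), reported as a percent
   increase with a delta-method SE.

All functions take data frames and return tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

The package ships a transcription of the study's 21-row *MYH6* variant
table. `table1_report()` parses, annotates and summarizes it, and tests
carrier enrichment against the reconstructed reference cohort (31 of 1,063
controls, the integer consistent with a 2.9% control carrier frequency):

```r
library(cardioburden)
table1_report()
#> Variant table summary
#>   records: 21 (19 distinct variants, 10 novel)
#>   distinct carrier subjects: 20 (10.5% of cases)
#>   distinct variants by domain: head 7, neck 1, tail 11
#>   enrichment vs controls: 361%
#>   Fisher exact p = 1.64e-05; sample OR 3.92 (95% CI 2.18-7.03)
```

Reading: 190 sequenced cases yielded 21 qualifying variant observations (19
distinct variants, 10 of them novel) in 20 subjects — a 10.5% carrier rate
against 2.9% in controls, a 361% enrichment unlikely under no association
(exact p ≈ 1.6 × 10⁻⁵), with carriers having about 3.9 times the odds of
being a case.

The outcome and expression stages run identically on synthetic cohorts:

```r
sim <- simulate_survival(seed = 1)          # 10 carriers vs 62 wild type
survival_report(sim$records)
#> Transplant-free survival report
#>   eligible subjects (age >= 6 yr): MUT n=10, WT n=62
#>   median follow-up: 14.70 yr
#> Gehan-Breslow (generalized Wilcoxon) two-group test
#>   groups: MUT (n=10) vs WT (n=62)
#>   chi-square = 29.6 (1 df), p = 5.316e-08

se <- simulate_expression(seed = 1, n_genes = 200)   # MYH7 planted at 3.46x
paired_de_test(se$expr, se$pairs, "MYH7")
#> Paired test for MYH7: fold change 3.81 (MUT/WT), t = 18.5, p = 3.31e-07 (8 pairs)

densitometry_model(simulate_densitometry(seed = 1)$records)  # +62% planted
#> Densitometry (pair-blocked): +73.6% (SE 15.9%), p = 6.77e-07 over 4 pairs
```

The segregation filter closes its own loop: `simulate_pedigree_vcf()` plants
a dominant variant in the affected family members among hundreds of
background variants, and `segregation_filter()` recovers it; the expected
background leakage is computed exactly by enumerating all genotype
configurations of the family (`segregation_pass_probability()`).

See the methods vignette (`vignettes/cardioburden-methods.Rmd`) for the
models, assumptions, defaults and limitations.

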
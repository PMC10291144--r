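# xreact

Off-target cross-reactivity risk screening for T-cell epitopes.

Engineered T-cells directed against a tumor peptide can recognize
unrelated self-peptides displayed by healthy tissue — the mechanism behind
several fatal immunotherapy trials, most famously a MAGEA3-specific T-cell
(`EVDPIGHLY`, HLA-A\*01:01) that cross-reacted with a TITIN-derived
cardiac peptide (`ESDPIVAQY`). xreact screens HLA class I immunopeptidomes
(experimentally eluted 9-mer ligands) for self-peptides biochemically
similar to a query and ranks them for off-target risk, for immunologists
and computational biologists selecting targets for T-cell therapies or
peptide vaccines.

## Method

Amino acids are embedded in a PCA-reduced coordinate space built from the
AAIndex collection of biochemical property scales (scales z-scored over the
20 residues; component scores retained up to a 95% cumulative-variance
target; 531 complete scales give K = 14 components). A peptide's
**biochemical profile** is the 9 × K matrix of its residues' coordinates,
and two peptides are compared with the **relatedness score**, a
length-normalized position-weighted squared Euclidean distance

    RdS(a, b; w) = (1/L) Σᵢ wᵢ Σₖ (aᵢₖ − bᵢₖ)² ,  L = 9,

where low scores mean biochemically similar peptides. The weight vector
`w` is uniform for peptide-centered screening, or a **contact map** —
per-position TCR contact counts from a crystal structure or simulation,
with pseudo-count 0.5 at uncontacted positions — for TCR-centered
screening. Significance comes from a Monte-Carlo null: relatedness scores
of random peptide pairs drawn from the pooled database, fitted with a
Gaussian, giving each candidate a lower-tail p-value (screening threshold
p ≤ 0.01). Hits are annotated with tissue-specificity classes from pTPM
expression data and with externally predicted HLA binding (strong binder:
IC50 ≤ 50 nM) and immunogenicity (immunogenic: score > 0.65).

The score's functional form and absolute scale are fixed by a documented
calibration against published worked values (see the vignette in
`vignettes/off-target-screening.Rmd`); everything downstream — bins,
thresholds, null parameters — lives on that published scale.

## Worked example

```r
library(xreact)
library(tibble)

pm <- default_property_matrix()          # calibrated AAIndex-PCA space
relatedness("EVDPIGHLY", "ESDPIVAQY", matrix = pm)
#> [1] 15.77415

# published full-scale null; or fit your own with sample_rds_pairs()
null <- null_distribution(mu = 32.77, sigma = 6.05, n_pairs = 5e6)

# synthetic HLA-A*01:01 universe with the TITIN peptide spiked in
db <- synth_peptidome(n = 5000, seed = 7)
u  <- as_peptide_db(rbind(as_tibble(db)[, 1:3],
                          tibble(peptide = "ESDPIVAQY",
                                 allele = "HLA-A*01:01",
                                 source = "validated")))

res <- cross_screen("EVDPIGHLY", u, weights = cm_custom(), null = null)
res
#> <screen_result> query EVDPIGHLY vs 5001 peptides (HLA-A*01:01), weights: CM-custom
#> # A tibble: 5,001 × 7
#>   peptide   gene  source      rds  rank percentile_rank  p_value
#> 1 ETDPVCQSY <NA>  synthetic  10.3     1           100.0 0.000101
#> 2 ESDPIVAQY <NA>  validated  11.3     2           100.0 0.000188
#> 3 ELEPVHHKY <NA>  synthetic  12.1     3            99.9 0.000309
#> ...

rank_of("ESDPIVAQY", res)
#> [1] 2
classify_significance(11.3, null)
#> [1] "significant"
```

The TITIN peptide scores RdS 15.8 against the MAGEA3 query (inside the
14–16 bin where validated cross-reactive pairs concentrate), and under the
TCR-centered contact map it surfaces at rank 2 of 5,001 with p ≈ 2e-4 —
the kind of candidate that would be flagged for experimental validation.
`annotate_screen()` and `prioritize()` then attach expression,
binding, and immunogenicity evidence per candidate.

A thin command-line front end over the same functions lives at
`inst/scripts/xreact-cli.R` (subcommands `build-matrix`, `null-fit`,
`screen`, `contacts-weights`, `db-summary`, `synth-peptidome`).

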
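---
title: "Biochemical relatedness screening for T-cell off-target risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biochemical relatedness screening for T-cell off-target risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xreact)
```

## The problem

Therapeutic T-cells engineered against a tumor-associated peptide can
cross-react with unrelated self-peptides displayed by healthy tissue. The
canonical cautionary example is a MAGEA3-specific T-cell (cognate peptide
`EVDPIGHLY`, HLA-A\*01:01) that also recognized a TITIN-derived cardiac
peptide (`ESDPIVAQY`), with lethal consequences. xreact screens an
immunopeptidome — the set of peptides experimentally observed to be
displayed by a given HLA allele — for self-peptides biochemically similar
to a query, and attaches statistical and functional evidence so that a
handful of candidates can be prioritized for experimental validation.

Restricting the search universe to eluted-ligand data (instead of scanning
the whole proteome through an HLA-binding predictor) removes one layer of
prediction error: every candidate reported has been observed on the cell
surface.

## The descriptor space

Amino acids are embedded in a low-dimensional biochemical coordinate
system derived from the AAIndex collection of property scales:

1. Scales with a missing value for any residue are dropped (no
   imputation). Constant scales, for which standardization is undefined,
   are also dropped and counted separately; the packaged AAIndex release
   9.1 contains none.
2. Each remaining scale is z-scored across the 20 amino acids.
3. Treating amino acids as observations and scales as variables, the 20
   observations are projected onto principal components; the smallest K
   whose cumulative explained variance reaches the `variance_target`
   (default 0.95) is retained, taking the component that crosses the
   target (ceiling rule).
4. The 20 x K component *scores* are the residue coordinates. Because
   scores preserve the Euclidean geometry of the standardized scale
   space, every downstream quantity is invariant to the sign ambiguity
   and to any orthogonal rotation of the components — a property the test
   suite asserts directly.

On the packaged AAIndex copy (544 scales, 531 complete), K = 14
components reach the 95% target; the 12-component figure sometimes quoted
for this kind of reduction is not reproduced by this release under any
convention we tested, so the dimensionality should be read as a function
of the scale set, not a constant of the method. `build_property_matrix()`
exposes `variance_target` for users who want a different cut.

A peptide is encoded as its **biochemical profile**: the 9 x K matrix of
its residues' coordinates (`encode_peptide()`), a pure lookup with no
further scaling.

## The relatedness score and its calibration

Two profiles are compared with a length-normalized, position-weighted
**squared** Euclidean distance,

$$\mathrm{RdS}(a, b; w) \;=\; \frac{1}{L}\sum_{i=1}^{L} w_i
  \sum_{k=1}^{K} (a_{ik} - b_{ik})^2 , \qquad L = 9,$$

low values meaning biochemically similar peptides. Identical sequences
score exactly 0; the score is symmetric; raising the weight of a position
where the residues differ strictly raises the score; and scaling all
weights by $c$ scales the score by $c$.

Two conventions are not determined by first principles and were fixed by
a calibration step against published worked values for three reference
pairs (`EVDPIGHLY`/`EVDPIGHVY` = 1.35, `EVDPIGHLY`/`EVAPAGASY` = 12.95,
and the MAGEA3–TITIN pair inside the 14–16 score bin):

* **Functional form.** Candidate square-root forms
  ($\sqrt{\sum_i w_i d_i^2}/L$, $\sum_i \sqrt{w_i}\,d_i/L$,
  $\sqrt{\sum_i w_i d_i^2/L}$) are ruled out by a scale-free argument:
  the *ratio* of the two printed reference values (12.95/1.35 = 9.59)
  cannot be matched by any of them under any global rescaling of the
  coordinates (they give 3.1–6.2), while the squared form gives 9.8.
  Ratios, not absolute values, identify the form, because a single
  multiplicative constant is absorbed by the scale calibration below.
* **Absolute scale.** PCA fixes geometry up to the preprocessing of the
  source scales. A single multiplicative constant is fitted by least
  squares on the two reference pairs whose sequences are printed in full
  (`calibrate_rds_scale()`), rescaling the coordinates once and recording
  the constant in the matrix metadata. After calibration the two anchored
  pairs reproduce at 1.324 and 12.953, and the *unanchored* MAGEA3–TITIN
  pair lands at 15.77, inside its expected bin. As an independent
  corroboration, the mean relatedness over all unordered residue pairs in
  the calibrated space is 32.7 — in close agreement with the published
  full-scale Monte-Carlo null mean of 32.77, which the calibration never
  targeted.

The residual ~2% misfit on the anchored pairs reflects differences
between AAIndex snapshots and scale filters, and is the tolerance used by
the acceptance tests for these quantities.

`blosum_score()` provides the ungapped substitution-matrix baseline
(BLOSUM matrices packaged with Biostrings) used only for rank
comparisons, never for p-values.

## Weights: uniform and contact maps

The weight vector $w$ encodes TCR recognition hotspots. With
$w = (1, \ldots, 1)$ the score is the peptide-centered protocol. A
**contact map** turns a residue-contact table from a TCR–peptide
structure (GetContacts-style TSV; nine interaction types `hbbb`, `hbsb`,
`hbss`, `sb`, `pc`, `ps`, `ts`, `hp`, `vdw`) into per-position weights:
raw per-position contact counts, with a pseudo-count (default 0.5)
substituted at positions without TCR contacts. Counts are used raw rather
than normalized to frequencies — the only reading consistent with the
reference penalty vector for the A3A TCR crystal structure,
$(3.0, 0.5, 0.5, 4.0, 2.0, 0.5, 1.0, 1.0, 0.5)$, which
`build_contact_weights()` reproduces bit-exactly from its per-position
counts. Knowledge-based overrides (`apply_weight_overrides()`) yield
customized maps, e.g. raising the HLA-A\*01 anchor positions 3 and 9 to
2.0 (`cm_custom()`).

Multi-frame (molecular-dynamics) tables are aggregated by counting a
(position, type, partner-residue) contact once per frame and summing
across frames; `per_frame_dedup = FALSE` counts every row instead. The
4.0 Å hydrogen-bond threshold used for curated TCR contact data is an
upstream GetContacts setting, expected to be applied before export.
Structure preparation, simulation, and energy analysis are out of scope:
this package consumes contact tables, not structures.

```{r contact-map}
cm_crystal()
cm_custom()
```

## The Monte-Carlo null and p-values

Significance is judged against the score distribution of unrelated
peptide pairs. `sample_rds_pairs()` draws both ends of each pair
independently and uniformly (with replacement) from the pooled,
allele-agnostic database and scores them; `fit_null()` fits a Gaussian by
moments. The full-scale reference analysis used 5 million pairs; the test
suite works at $10^4$–$2\times10^5$ pairs, where moment estimates carry
standard errors $\sigma/\sqrt{n}$ and $\sigma/\sqrt{2n}$ that the
parameter-recovery tests respect (3 SE bands).

P-values are the lower-tail normal CDF $\Phi((s-\mu)/\sigma)$; the
standard screening threshold is $p \le 0.01$. Normality is monitored with
a Shapiro–Wilk statistic on a fixed-seed subsample of at most 5,000
scores — at Monte-Carlo sample sizes the test rejects for deviations far
too small to matter for tail thresholds, so it is stored as a diagnostic
and never used as a gate. One published worked example
(pair score 21.36 under the full-scale null) is consistent with this
rule to the printed precision ($\Phi = 0.0297 \approx 2.96\times10^{-2}$);
another printed value ($1.03\times10^{-2}$ for a pair scoring 1.35) is
not consistent with any lower-tail Gaussian reading
($\Phi \approx 10^{-7}$) and we implement the consistent rule rather than
reverse-engineering an undocumented variant.

`bin_summary()` partitions scores into left-closed width-2 bins from 0
("0-2", "2-4", ...) with per-bin pair fractions, validated-case counts,
and mean p-values — the tabular form of the usual enrichment figure.

## Screening and reports

`cross_screen()` ranks one allele's peptide set by ascending RdS, with
ties broken lexicographically by sequence so ranks are reproducible
across platforms. The query is deliberately *not* removed from the
universe: self and paralog recoveries are informative positive controls.
Percentile ranks are $(1 - \mathrm{rank}/N) \times 100$. The vectorized
scorer is a 20 x 20 squared-distance lookup; an independent brute-force
path (re-encode, re-score, re-sort) is kept in the test suite and must
agree row for row on universes of 2,000 peptides.

`substitution_profile()` and `protocol_comparison()` are pure projections
of screen results (per-position residue frequencies of the top k;
per-target ranks, top-k overlaps and validated-case recovery across
weighting protocols). `annotate_screen()` attaches per-gene
tissue-specificity classes computed from a pTPM expression table with the
five-way Human Protein Atlas-style rules (fold 5, minimum 1 pTPM, group
size at most 7 — all configurable), plus predicted IC50 and
immunogenicity values consumed from external predictor output;
`prioritize()` flags strong binders (IC50 $\le$ 50 nM, inclusive),
immunogenic candidates (score $> 0.65$, strict), and their conjunction as
high-risk. Annotation is left-join only: rows never disappear, missing
evidence is marked `NA`.

## What the synthetic generator does and does not emulate

All tests run without downloads on synthetic fixtures:

* `synth_property_table()` — random Gaussian scales with controllable
  missingness, for the parser/filter/PCA plumbing.
* `synth_peptidome()` — motif-constrained unique 9-mers; the default
  motif fixes acidic residues at position 3 and tyrosine at position 9,
  mimicking HLA-A\*01:01 anchors so that fixtures structurally resemble
  the MAGEA3 screening scenario. `synth_multi_allele_db()` pools five
  anchor presets to emulate an allele-diverse database for the
  allele-agnostic null.
* `spike_offtargets()` — variants at an exact Hamming distance from a
  query, the synthetic stand-in for experimentally determined
  cross-reactive sets.

Beyond anchor constraints the generator samples residues uniformly, so it
does not reproduce the amino-acid composition, source biases, length
spectrum, or gene structure of real immunopeptidomes. Consequently the
synthetic Monte-Carlo null is close to, but not identical with, the
published full-scale parameters (anchored positions contribute no
variance), and full-database quantities — a specific off-target's rank
among ~36,000 real peptides, locus proportions, top-50 recovery of
validated cases — are not reproducible at desk scale. Those analyses are
provided in `inst/scripts/fullscale_integration.R` for users who hold the
full data; the qualitative core of the claim (an off-target deviating
only at low-weight positions climbs the ranking monotonically from
uniform to crystal-derived to customized contact maps) *is* asserted in
CI on a constructed scenario verified against brute force.

## Numerical choices and degenerate inputs

* Non-9-mer or non-canonical peptides are hard errors naming the
  offending position — silent coercion would corrupt screens.
* Tie-break: stable sort by (RdS, sequence); the documented alternative
  of counting ties jointly would change published-style rank statements
  by at most the tie-group size.
* Cumulative-variance ties use the ceiling rule (retain the crossing
  component).
* Weights must be strictly positive; a zero weight would silently blind
  the score to a position, so the pseudo-count path is the only sanctioned
  way to down-weight.
* `fit_null()` refuses zero-variance samples; `classify_specificity()`
  refuses single-tissue records (fold contrasts undefined).
* All generators take explicit seeds, use a private RNG scope, and
  restore the caller's RNG state.

Problem sizes in the shipped tests — 2,000-peptide oracle universes,
$10^5$-pair null fits, 20-trial invariant sweeps — were chosen as the
smallest sizes at which the corresponding standard errors make the
assertions meaningful.

## Known limitations

* 9-mer class I peptides only; no gapped comparison, no class II.
* One allele per screen; cross-allele search is intentionally excluded.
* The Gaussian null is a single pooled distribution, not allele-specific.
* The absolute relatedness scale depends on the AAIndex snapshot through
  the calibration constant; scores from matrices built with different
  snapshots should not be mixed (the `matrix_id` check enforces this for
  profiles).
* Binding affinity and immunogenicity values are consumed, not computed;
  their biases propagate into the risk flags.
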
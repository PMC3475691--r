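---
title: "Methods: reporter-ion quantification, pathway enrichment, literature LSI and longitudinal plasma statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-ion quantification, pathway enrichment, literature LSI and longitudinal plasma statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoproteo)
```

hypoproteo implements, as one tested pipeline, the computational analysis
scheme used in hypothalamic proteomics studies of the transgenic Huntington's
disease (tgHD) rat: 4-plex isobaric reporter-ion protein quantification with
fold-change differential calling, hypergeometric gene-set enrichment ranked
by a hybrid score, latent-semantic-indexing (LSI) correlation of
differential proteins against literature interrogation terms, and a
two-track statistics scheme for longitudinal plasma analyte panels. A
synthetic-data module generates every input with known ground truth, so each
stage can be exercised and scored at desk scale without any external data.

## Reporter-ion quantification

The labelling design places three pooled transgenic samples on reporter
channels 114, 115 and 116 and one pooled wild-type sample on channel 117,
the reference. Quantification proceeds per peptide-spectrum match (PSM) and
rolls up to proteins:

1. **Isotope-overlap correction.** Isobaric labels carry isotope impurities,
   so a fraction of each channel's true signal appears in neighbouring
   channels. Writing the observed intensities as $y = M x$, where
   $M_{ij}$ is the fraction of channel $j$'s signal observed in channel $i$,
   the true signal is recovered by solving the linear system; any negative
   component (possible at low counts) is clamped to zero. Impurity values
   are lot-specific vendor data; the packaged default puts 94% of signal
   on-diagonal, 2% on each $\pm 1$ neighbour and 1% on the $-2$ neighbour,
   truncated at the matrix edge, and is fully configurable. Matrices with
   reciprocal condition number below $10^{-12}$ are rejected rather than
   solved.
2. **Saturation filtering.** Reporter peaks at or above 1500 counts are in
   the detector's saturated regime and no longer measure abundance
   linearly. Because a ratio needs both of its channels, the whole spectrum
   is dropped when *any* channel reaches the threshold; the boundary value
   itself is excluded (qualifying intensities are strictly below the
   threshold). The threshold is configurable.
3. **Peptide gates and ratios.** Spectra below 95% identification
   confidence are excluded from quantification entirely, not merely from
   the peptide count. Spectra with a zero reference intensity are excluded
   with a recorded reason (a ratio would be undefined); this is data
   triage, not an error. Each surviving spectrum yields three ratios,
   channel/reference.
4. **Protein roll-up.** Proteins require an unused ProtScore of at least
   2.0 (the vendor identification score counting only peptide evidence not
   better explained by a higher-ranking protein) and at least two
   qualifying peptides. Per-channel means over peptides are averaged across
   the three test channels into one mean ratio. The mean is arithmetic — a
   deliberate match to how such ratios are conventionally averaged in this
   workflow — with a log-space geometric mean available as an option.
5. **Differential calling.** A protein is called up-regulated when its mean
   ratio is $\geq 1.2$ and down-regulated when $\leq 0.8$ (both inclusive).
   These fixed fold-change cutoffs stand where replicate-based testing is
   impossible in a pooled 4-plex design. On top of the cutoffs, a
   *channel-consistency gate* requires all three per-channel means on the
   same side of unity before a call is made — a reproducibility surrogate
   for manual cross-experiment validation, and configurable off. The
   reported signed expression equals the mean ratio, negated for
   down-regulated proteins so the sign encodes direction.

Every exclusion is accounted: the input protein count always equals the
score-gate exclusions plus peptide-gate exclusions plus up, down and
unchanged calls, and the pipeline report asserts this identity.

## Pathway enrichment with the hybrid score

Given a query of $n$ differential proteins inside a background of $N$
annotated symbols, a gene set with $K$ members and overlap $O$ is scored by

* the expectation $E = nK/N$ and enrichment ratio $R = O/E$ ($R = 0$ for an
  empty overlap),
* the upper-tail hypergeometric probability $p = P(X \geq O)$, $X \sim$
  Hypergeometric$(N, K, n)$ (enrichment only; depletion is out of scope),
* and the hybrid score $R \cdot (-\log_{10} p)$, which balances enrichment
  strength against significance and is the ranking statistic.

A set is reported significant only when $O \geq 2$, $p < 0.05$ (strict) and
$R > 1$. No multiple-testing correction is applied by default — the raw-p
gate is the scheme this package reproduces — but a Benjamini–Hochberg option
exists. The background defaults to the union of all set members; an explicit
background file overrides it. Query symbols outside the background are
dropped and counted, since $E$ is undefined for them. Symbol matching is
case-insensitive after trimming, with no alias resolution (no external
database is consulted). The same engine serves KEGG-style pathway sets and
GO-style category sets alike; any GMT file is accepted.

The up- and down-regulated protein sets are enriched separately in the
pipeline (they partition the differential list); a combined run is possible
by passing the union explicitly.

## Literature LSI

Gene–literature association is scored in a latent semantic space built from
a gene-tagged abstract corpus:

* **Tokenization** is frozen with the package (lower-case, split on
  non-alphanumerics, drop tokens shorter than 2 and a packaged stop-word
  list), because scores depend on the exact rules.
* **Weighting** is log-entropy — local $\log_2(1+tf)$, global
  $g_i = 1 + \sum_j p_{ij}\log_2 p_{ij} / \log_2 n$ — the scheme standard in
  literature-LSI systems; TF-IDF is available as an option. A term confined
  to one document gets full weight; a term spread uniformly gets zero.
* **Decomposition** is a rank-$k$ truncated SVD. $k$ defaults to 10 at desk
  scale, matched to the synthetic corpus's small number of latent topics;
  real corpora warrant larger $k$. Singular-vector signs are fixed
  deterministically (largest-magnitude term component positive) so results
  are identical across runs and platforms.
* **Genes and queries** are folded in as pseudo-documents: a gene is the sum
  of its linked abstracts' weighted term columns, projected as
  $\hat v = \Sigma^{-1} U^\top x$; a query term is weighted the same way. A
  centroid-of-documents gene representation is available as an option.
  Similarity is the cosine taken on the $\Sigma$-scaled coordinates, which
  at full rank reproduces the cosines of the original weighted columns
  exactly.
* **Scores** lie in $[-1, 1]$: positive values grade association strength,
  0 is neutral, and negative values grade a strengthening lack of
  association. Genes scoring strictly above 0.1 are reported significant
  and labelled with their regulation direction from the quantification
  stage (up conventionally rendered red, down green). A gene with no linked
  abstract, or a term with no in-vocabulary token, yields a *missing* score
  — preserved as `NA` through every writer, never conflated with 0.

The default interrogation terms are Huntingtin, Chorea, Diabetes and
Insulin.

## Longitudinal plasma statistics

The analyte panel is long-format: subject, genotype (tgHD/WT), age group
(3, 9, 12 months), analyte, value. Per analyte the scheme runs:

1. genotype contrasts (tgHD vs WT) at each age — 3 tests;
2. within-genotype longitudinal contrasts against the 3-month baseline
   (9 vs 3, 12 vs 3 for each genotype) — 4 tests;
3. one two-way ANOVA with genotype and age as crossed factors, including
   their interaction.

The t-test is the classical pooled-variance Student form (that is what the
name denotes; Welch is an option) and two-sided — at these group sizes
(n = 5 per cell) reported borderline "trend" p-values are only coherent
two-sided. Significance is $p < 0.05$, strict. No correction is applied
across analytes by default, mirroring the scheme's per-analyte reporting.
The ANOVA uses sequential sums of squares; with balanced cells this equals
the other SS types, so no further choice is exposed. Degenerate inputs are
defined: identical constant groups give $t = 0, p = 1$; constant groups
with different means raise an error; an all-constant ANOVA reports zero SS
and $F = 0$ for every effect. Comparisons whose groups are missing are
skipped with a warning while the rest of the panel proceeds.

## The synthetic-data module

Each generator is a pure function of its configuration and seed
(byte-identical reruns), with per-entity random sub-streams so adding
proteins, documents or analytes never reshuffles existing ones.

* `simulate_psm_experiment()` emulates the pooled 4-plex experiment: 200
  proteins, 10% planted 1.5-fold up and 10% 0.67-fold down, peptide counts
  $1 + \mathrm{Poisson}(3)$, lognormal reference intensities (median 300
  counts, sdlog 0.5), multiplicative lognormal channel noise at 10% CV,
  impurity mixing by the default matrix, 5% of spectra pushed past the
  1500-count saturation threshold, and 10% of proteins drawn below the
  ProtScore gate. Lognormal noise was chosen because reporter intensities
  are non-negative and its CV parameterization makes the recovery
  thresholds meaningful.
* `simulate_annotations()` plants one enriched gene set by composing the
  query largely from that set's members.
* `simulate_corpus()` plants gene–term associations (probability 0.8 of
  linkage to a topic document versus 0.05 background) over 300 bag-of-words
  abstracts with a Zipf-like filler vocabulary.
* `simulate_plasma_panel()` draws Gaussian cell values (n = 5 per
  genotype-by-age cell) around configured means; the defaults emulate the
  hormone patterns of the modelled disease study — reduced insulin and
  leptin in young transgenic animals, age-dependent insulin decline, and a
  flat analyte for calibration.

What the generators do *not* emulate: real spectral peak shapes, the
instrument's absolute intensity distribution, real identification-score
distributions, actual biomedical vocabulary and abstract structure, or
assay-specific measurement error. Passing the recovery and calibration
tests therefore demonstrates that the *analysis rules* behave as specified
under controlled conditions, not that any given real experiment would reach
a particular sensitivity.

## Numerical and design choices

* Strict-versus-inclusive boundaries follow the scheme's definitions
  exactly: ratio cutoffs inclusive ($\geq 1.2$, $\leq 0.8$), saturation
  exclusive (1500 itself is dropped), enrichment gate strict ($p < 0.05$),
  LSI threshold strict ($> 0.1$), significance strict ($p < 0.05$).
* Output ordering is deterministic: quantification tables sort by
  $|$signed expression$|$ descending with accession as tie-break;
  enrichment tables by hybrid score with set id as tie-break.
* Negative corrected intensities are clamped to zero; near-singular
  impurity matrices are rejected.
* The test suite and acceptance script run at desk scale — 200-protein
  experiments, 300-document corpora, 2000 simulated null panels — sizes
  chosen so the full suite runs in about a minute while keeping Monte Carlo
  error well inside the asserted bands.

## Known limitations

* ProtScores are inputs: spectrum-to-peptide identification is upstream of
  this package, and the generators fabricate scores rather than model them.
* The enrichment stage reproduces the analysis scheme's raw-p gates;
  users screening many gene-set collections should enable the BH option.
* LSI internals of commercial literature-indexing systems (weighting,
  dimensionality, gene-document construction) are proprietary; the choices
  here are reasonable, config-exposed defaults, not claims about any
  particular product, and published scores from such systems are not
  expected to be numerically reproduced.
* With n = 5 per cell the t-tests have limited power for small effects;
  the panel scheme reports raw per-analyte results by design.
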
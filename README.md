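# hypoproteo

Quantitative proteomics and metabolic-panel analysis for studies of
hypothalamic dysfunction in the transgenic Huntington's disease (tgHD) rat —
or any comparable 4-plex isobaric design. The package implements, as one
reproducible pipeline with a fully synthetic test bed:

1. **Reporter-ion quantification** — 4-plex isobaric (iTRAQ-style) PSM
   tables with three transgenic channels (114/115/116) against a wild-type
   reference (117): isotope-impurity correction by solving the mixing
   system, exclusion of detector-saturated spectra (any channel ≥ 1500
   counts), peptide confidence gating (≥ 95%), protein roll-up (unused
   ProtScore ≥ 2.0, ≥ 2 peptides), and differential calling at mean ratio
   ≥ 1.2 (up) / ≤ 0.8 (down) with a channel-consistency gate; down calls
   carry a negated signed expression.
2. **Pathway enrichment** — for each gene set, the enrichment ratio
   `R = O/E` with `E = nK/N`, the upper-tail hypergeometric probability
   `p = P(X ≥ O)`, and the hybrid ranking score `R · (−log10 p)`; sets are
   significant when `O ≥ 2`, `p < 0.05` and `R > 1`. Up- and down-regulated
   sets are analysed separately.
3. **Literature LSI** — a log-entropy-weighted term-document matrix over a
   gene-tagged abstract corpus, truncated SVD (default rank 10), gene
   pseudo-documents folded in as `Σ⁻¹Uᵀx`, and cosine correlation against
   interrogation terms (defaults: Huntingtin, Chorea, Diabetes, Insulin);
   genes scoring > 0.1 are reported with their regulation direction.
4. **Longitudinal plasma statistics** — per analyte: pooled-variance
   Student's t-tests for tgHD vs WT at each age and for each genotype
   against its 3-month baseline, plus a genotype × age two-way ANOVA
   (sequential SS, balanced n = 5 cells).
5. **Synthetic data** — seeded generators for all of the above with planted
   fold changes, enriched sets, gene–term associations and hormone effects,
   so every stage is scored against known ground truth.

## Worked example

The `analysis/` scripts run the whole study on synthetic inputs; each is a
thin driver over exported functions. From the repository root:

```sh
Rscript analysis/01_simulate.R     # generate inputs with ground truth
Rscript analysis/02_quantify.R     # reporter-ion quantification
Rscript analysis/03_enrichment.R   # hybrid-score pathway enrichment
Rscript analysis/04_literature_lsi.R
Rscript analysis/05_plasma_stats.R
Rscript analysis/06_full_pipeline.R  # same stages from one config
```

`02_quantify.R` prints:

```
Quantified 792 spectra over 200 proteins:
  47 spectra saturated, 39 excluded (confidence / zero reference)
  20 proteins below the ProtScore gate, 15 below the peptide gate
  calls: 16 up, 19 down, 130 unchanged
Against planted truth: sensitivity 1.000, FDP 0.000 (35 called, 35 planted)
```

i.e. every protein planted at 1.5-fold up or 0.67-fold down (and passing
the identification gates) is recovered with the correct direction, and no
unchanged protein is miscalled. `03_enrichment.R` then finds the planted
gene set at the top of both directions:

```
up set (16 proteins): 1/20 sets pass the gates; top set SET001 (O=7, E=1.28, R=5.47, p=3.91e-05, hybrid=24.10) <- planted set
down set (19 proteins): 1/20 sets pass the gates; top set SET001 (O=5, E=1.52, R=3.29, p=1.01e-02, hybrid=6.57) <- planted set
```

and `05_plasma_stats.R` recovers the planted hormone pattern (reduced
insulin in 3- and 12-month transgenics, reduced leptin at 3 months, an
age-dependent insulin decline), e.g.:

```
8 of 21 t-tests significant at p < 0.05:
  insulin  tgHD vs WT at 3m   p = 0.0001
  insulin  tgHD vs WT at 12m  p = 0.0008
  ...
ANOVA insulin  genotype p = 2.912e-06, age p = 0.0003672, interaction p = 0.05412
```

The same can be done programmatically:

```r
library(hypoproteo)
bundle <- simulate_input_bundle(tempfile(), seed = 1)
cfg <- pipeline_config(inputs = bundle$paths, out_dir = tempfile())
res <- run_all(cfg)
head(res$quant)       # called proteins, signed expression
res$enrichment_up     # ranked gene sets with hybrid scores
res$report            # per-stage exclusion accounting
```

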
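# glycardio

Analysis of N-glycomics data from cardiac tissue and isolated
cardiomyocytes measured by negative-mode porous graphitized carbon
LC-MS/MS. The package is aimed at glycomics researchers comparing disease
and control cohorts at the composition, structure, and class level — for
example, profiling how cardiac N-glycosylation (paucimannose, high
mannose, hybrid, and complex classes) shifts after a viral infection,
independent of age, sex, and comorbidities.

## What it does

* **Composition algebra and masses** — parse/format compositions over
  Hex (H), HexNAc (N), Fuc (F), NeuAc (S); monoisotopic neutral masses of
  reduced (alditol) glycans and deprotonated m/z values, all from one
  mass table. For a composition with counts $n_r$ over residues $r$:

  $M = \sum_r n_r m_r + m_{\mathrm{H_2O}} + m_{\mathrm{2H}}$, and
  $m/z = (M - z\,m_p)/z$ for $[M - z\mathrm{H}]^{z-}$ ions.

* **Class taxonomy** — paucimannose / oligomannose / processed at the
  composition level; paucimannose, high-mannose, hybrid, bisecting, and
  complex-mono/bi/tri/tetra (plus core-fucose, LacNAc, LacdiNAc,
  sialylation motifs) at the structure level, on rooted residue trees
  with a documented bracket grammar.

* **Composition graphs** — library relatedness graphs where adjacent
  nodes differ by one monosaccharide; library set comparison (shared /
  exclusive structures); GraphML and TSV export.

* **Fragment annotation** — theoretical B/C/Y/Z ions for every
  glycosidic cleavage plus the negative-mode diagnostic ions (D, D−18,
  D−221, E, optional 0,2A) that localize the 6-arm, detect bisecting
  GlcNAc, and evidence tri-antennary branching; ppm-tolerance peak
  matching and topology read-out; MGF I/O.

* **Quantification and differential abundance** — relative abundance
  (percent of total per sample), median normalization, log2; per-glycan
  linear models with empirical-Bayes moderated t statistics
  ($\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, $d_0 + d$ df),
  covariate-adjusted models for confounder control, Benjamini–Hochberg
  FDR, and composition-level differentials.

* **Glycogene pathway profiling** — filter differential-expression gene
  tables (|log2FC| > 1, FDR < 0.05) against a 19-category
  glycosylation-pathway reference and compute per-cell-type pathway
  percentage contributions.

* **Synthetic data** — biosynthetically coherent glycan libraries,
  two-group cohorts with planted effects, confounders, and 10% technical
  CV, toy MS/MS spectra, and DE gene tables, with ground truth emitted
  for every dataset.

## Worked example

```r
library(glycardio)

# printed m/z of the doubly deprotonated reduced core-fucosylated Man6
round(glycan_mz("H6N2F1", charge = 2), 4)
#> [1] 771.2726

# synthetic cohort: 60-glycan tissue library, 16 vs 18 samples,
# paucimannose planted one log2 unit down in the positive group
lib    <- generate_library(60, profile = "tissue", seed = 42)
cohort <- generate_cohort(lib, effects = list(paucimannose = -1), seed = 43)

fit <- glycan_diffab(cohort$areas, cohort$metadata,
                     classes = setNames(lib$fine_class, lib$glycan_id))
fit
#> Differential glycan abundance (moderated t)
#>   60 glycans, 34 samples, design: (Intercept) + grouppositive
#>   significant: 38 at p<0.05, 28 at q<0.05

head(summary(fit)[, c("glycan_id", "class", "log2fc", "t", "p", "q")], 5)
#>     glycan_id        class     log2fc         t            p            q
#> 1   G003_H1N2 paucimannose -0.9868041 -18.56027 6.736010e-77 4.041606e-75
#> 2 G005_H3N2F1 paucimannose -0.9749161 -18.33668 4.217890e-75 1.265367e-73
#> 3   G001_H3N2 paucimannose -0.9184285 -17.27423 7.354401e-67 1.470880e-65
#> 4 G006_H4N2F1 paucimannose -0.8725500 -16.41133 1.586948e-60 2.380423e-59
#> 5   G004_H4N2 paucimannose -0.8716710 -16.39480 2.083355e-60 2.500026e-59

build_composition_graph(lib$composition)
#> <composition graph> 50 nodes, 74 edges
```

The top of the results table is exactly the planted signal: every
paucimannose glycan is recovered near its true log2 fold change of −1
(the small attenuation is the compositional-closure effect discussed in
the methods vignette), with BH q-values far below 0.05. The composition
graph is connected — every composition reaches the H3N2 trimannosyl core
through single-residue steps — as expected for a biosynthetically complete
library. `plot(fit)` draws the volcano plot.

End-to-end runs with provenance (`config.json` with seed and config
hash, byte-identical reruns) are available through `simulate_dataset()`,
`run_diff()`, `run_annotate()`, and `run_glycogenes()`.

## Documentation

The methods vignette (`vignettes/cardiac-nglycomics-methods.Rmd`)
describes the models, the diagnostic-ion rules, the moderation machinery,
the synthetic-data generative model and its limits, and every numerical
design choice.
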
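---
title: "Methods: cardiac N-glycomics with glycardio"
author: "glycardio authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac N-glycomics with glycardio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycardio)
```

# Scope and model

glycardio analyses released, reduced (alditol) N-glycans measured by
negative-mode PGC-LC-MS/MS, the workflow used for profiling human cardiac
tissue and isolated cardiomyocytes. The package covers the computational
stages downstream of peak integration: composition algebra and mass
calculation, class taxonomy, composition-graph comparison of glycan
libraries, diagnostic-ion structural annotation of MS/MS spectra,
relative-abundance quantification, differential abundance with and without
confounder adjustment, and glycogene pathway profiling of published
differential-expression tables. Raw-data peak picking, chromatographic
alignment, and transcriptome preprocessing are out of scope; the package
consumes exported peak areas, peak lists, and gene-level DE tables.

# Composition algebra and masses

A composition is a count vector over hexose (H), HexNAc (N),
deoxyhexose/fucose (F), and NeuAc (S). All mass arithmetic flows from a
single monoisotopic table (`mass_table()`): Hex 162.052824, HexNAc
203.079373, dHex 146.057909, NeuAc 291.095417 Da, water 18.010565, proton
1.007276, and the +2H alditol delta 2.015650. The neutral mass is the
residue sum plus one water, plus the reduction delta for alditols;
deprotonated ions follow $m/z = (M - z\,m_p)/z$. For example, the reduced
core-fucosylated Man6 glycan H6N2F1 gives an (M−2H)²⁻ ion at

```{r}
glycan_mz("H6N2F1", charge = 2, reduced = TRUE)
```

which rounds to the nominal m/z 771 used to report that structure.

# Class taxonomy

Composition-level classes follow the biosynthetic reading of HexNAc2
compositions: 1–4 hexoses (no sialic acid) are paucimannose, 5–12 are
oligomannose, and HexNAc ≥ 3 means Golgi-processed (hybrid/complex).
Two bounds are deliberate design choices exposed as parameters:

* `pauci_max_hex = 4`: Man4 glycans are counted as paucimannose (some
  literature caps the class at Man3); the bound is configurable.
* `oligo_max_hex = 12`: admits glucosylated precursors (Man9Glc1–3);
  nothing above Hex12 is classified.

Sialylated HexNAc2 compositions return `"unclassified"` rather than a
guess. Structure-level classification counts antennae as HexNAc-initiated
branches on the two core arm mannoses. A bisecting GlcNAc pre-empts the
antenna-count classes (the pie-chart vocabulary treats "bisecting" as its
own class; the taxonomy is silent on precedence, so bisecting wins by
design here). The hybrid rule requires one arm to carry *only mannose and
at least one extra mannose* while the other carries an antenna; without
the extra-mannose requirement every mono-antennary complex glycan with a
bare second arm would be called hybrid, which contradicts the
complex-mono class. Fucosylated oligomannose (e.g. Man6Fuc) stays in the
oligomannose class, mirroring how core-fucosylated high mannose is
reported.

# Composition graphs

Libraries are compared on a relatedness graph whose nodes are unique
observed compositions and whose edges join compositions differing by
exactly one monosaccharide (Manhattan distance 1 over H/N/F/S). Only
observed compositions become nodes by default; `virtual_nodes = TRUE`
inserts unobserved one-step intermediates, flagged as `"virtual"`, for
gap inspection. Edges are computed from a Manhattan distance matrix and
verified in the test suite against an independent all-pairs double loop
up to 200 nodes.

# Fragment annotation

For every glycosidic cleavage the package emits B/C/Y/Z ions: B is the
non-reducing residue-mass sum, C = B + water, Y is the reducing-side sum
plus water (plus the alditol delta), Z = Y − water. These definitions
satisfy the conservation identities B + Y = M and C + Z = M for the
neutral precursor mass M, which the acceptance suite asserts for every
cleavage of a 50-structure synthetic library.

Diagnostic ions implement the negative-mode topology evidence rules:

* **D** — double-cleavage B-type fragment retaining the 6-arm subtree,
  the β-mannose, and (when present) the bisecting GlcNAc;
* **D−18** — water loss from D;
* **D−221** — loss of the bisecting HexNAc + water (221.0899 Da), emitted
  only for bisected structures;
* **E** — emitted for ≥3 antennae. Its exact residue content is not
  standardized across instruments and collision regimes, so it is a rule
  table entry: the default keeps the 3-arm subtree plus the β-mannose
  with zero mass offset, and both the subtree selector and the offset are
  configurable (`diagnostic_rules()`).
* an optional single 0,2A cross-ring rule on the reducing-end HexNAc
  (default offset C₂H₄O₂ = 60.0211 Da), disabled by default; full A/X
  enumeration is out of scope.

Whether the D fragment keeps mannose extensions of the 6-arm in hybrid
structures also varies by convention; `d_retains_extended_6arm` selects
the variant (default keeps them). Peak matching is greedy
nearest-neighbour within a ppm tolerance (default 20 ppm for MS/MS; the
15 ppm figure used during peak integration applies to MS1), each peak
annotated by at most one ion, ties broken by smaller ppm error then by
ion-kind priority. Topology evidence reads out matched ions directly: the
D family fixes the 6-arm content (and, by complement, the 3-arm), D−221
evidences bisection, E evidences tri-antennary branching; every flag
cites its supporting peaks.

# Quantification

Relative abundance is peak area over total area × 100 per sample.
Statistical preprocessing follows relative abundance → median scaling →
log2. The scaling is performed on the log scale (subtracting the
per-sample median log2 value), which is identical to dividing by the
sample median for an odd number of glycans and keeps the median log value
exactly zero for even counts. Zeros are handled by a policy chosen before
the log: half-minimum imputation per glycan (default; preserves the
matrix for linear models), dropping to missing, or a pseudocount. Whether
the original analysis took medians before or after the log is
indistinguishable for location-shift comparisons, since group contrasts
are invariant to per-sample monotone rescaling; the stated order is
followed. Control-standard stability is summarized as %CV (sd/mean) per
analyte with a 10% flagging threshold.

# Differential abundance

Each glycan is fit with the same linear model: intercept + group
indicator (+ optional covariates), via a shared QR decomposition. In the
two-group case the group coefficient is exactly the difference of group
means of the log2 values, i.e. a log2 fold change. The univariate
analysis (default) applies empirical-Bayes variance moderation: the
per-glycan residual variances are modelled as scaled-F draws around a
prior variance $s_0^2$ with prior degrees of freedom $d_0$, estimated by
matching the first two moments of $\log s^2$ (digamma/trigamma
inversion); posterior variances are the precision-weighted average
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ and moderated t statistics use $d_0 + d$
degrees of freedom. Degenerate cases are handled explicitly: non-positive
moment estimates give $d_0 = \infty$ (all posterior variances equal
$s_0^2$), and a forced $d_0 = 0$ reproduces ordinary t statistics
exactly. With identical observed variances the estimator returns
$d_0 = \infty$ and the moderated t differs from the ordinary t only by a
constant small-sample bias-correction factor
$\exp((\psi(d/2)-\log(d/2))/2)$, under 2% at the default cohort size —
the test suite pins this down, and cross-checks the whole moderation
path against an independent reference implementation.

The covariate-adjusted model (age, sex, and binary comorbidity
indicators encoded as separate 0/1 columns — the encoding is a design
choice, exposed through `design_from_metadata()`) uses plain OLS t by
default, with moderation available by flag. Significance is reported at
both conventions, raw p < 0.05 and BH q < 0.05, in every results table.
BH adjustment is the standard step-up, validated in the tests against a
brute-force implementation of the definition. Composition-level
differentials aggregate isomer abundances within composition per sample
and compare group means on the log2 scale, with an `unchanged` band of
|log2FC| < 0.1 by default.

# Synthetic data: what it emulates and what it does not

`generate_library()` draws structures from a curated biosynthetic
candidate table in which every composition names a prerequisite differing
by one residue, so each library connects to the H3N2 trimannosyl core in
the composition graph — emulating the observed completeness of cardiac
glycan repertoires. Class quotas beyond the curated compositions are
filled with structural isomers (arm-swapped trees stamped with an isomer
tag on the reducing end, standing in for linkage/retention-resolved
isomerism). `generate_cohort()` plants:

* baseline abundances: class shares follow the reported tissue
  (complex-bi-dominated) or cardiomyocyte (high-mannose-dominated)
  profiles, split within class by log-normal weights (sd 0.5 on the
  natural-log scale) and normalized so the class shares are exact;
* group effects: multiplicative $2^\Delta$ on glycans selected by id,
  fine class, or coarse class (default scenario: paucimannose down,
  $\Delta = -1$);
* covariates: age (group means 63/66, sd 10), sex, and comorbidity flags
  with group-dependent prevalences mirroring the cohort table (16
  negative / 18 positive samples); covariate effects on selected glycans
  model confounding;
* technical noise: multiplicative log-normal with CV 10%, the stated
  run-to-run stability of the method.

The generator does not emulate biological between-subject variance beyond
the covariate structure, chromatographic peak shapes, isotope envelopes,
missingness mechanisms, or instrument drift — so passing tests demonstrate
the correctness of the statistical machinery under the declared model,
not performance on real cohorts, where between-subject variability will
widen all intervals.

One consequence of compositional closure is worth stating explicitly:
relative abundances sum to 100 per sample, so a one-sided planted change
in ~12% of glycans shifts every other glycan's relative abundance and
drags the per-sample median with it. The per-glycan estimator applied to
log2 abundances recovers a planted $\Delta = -1$ with |bias| < 0.01, while
the full pipeline estimate (relative abundance + median normalization) is
attenuated to about −0.87 under the default tissue profile. Both levels
are asserted in the acceptance tests at their own tolerances. With mixed
up/down effects, as real cohorts show, the attenuation largely cancels.

# Glycogene pathway profiling

DE gene tables (gene, cell type, region, log2FC, adjusted p) are filtered
at |log2FC| strictly greater than 1 and FDR strictly below 0.05, then
joined to a gene → pathway reference spanning 19 glycosylation-related
categories. Pathway contributions are percentages of the filtered genes
per (cell type, region) stratum; because the source wording is ambiguous
between counting genes and weighting by effect size, both weightings are
implemented (`gene-count` default, `abs-log2fc` optional). The shipped
reference is a synthetic stand-in — ~230 well-known glycogene symbols
across the 19 categories, clearly labelled synthetic — and a loader
accepts full reference exports for real analyses.

# Numerical and reproducibility choices

* All randomness flows through a mandatory integer seed; generators are
  deterministic given the seed (base R RNG, fixed sampling order).
* Peak matching and all result tables are deterministic; ties in matching
  break by ppm error then ion-kind priority then m/z.
* Pipeline runs (`run_diff()`, `run_annotate()`, `run_glycogenes()`)
  serialize their resolved configuration with an FNV-1a hash and the seed;
  reruns with identical inputs are byte-identical.
* Test and acceptance problem sizes: libraries of 50–155 structures,
  cohorts of 16/18 samples, 100–200 simulation replicates for parameter
  recovery, 4 × 500 glycans for null error rates — sizes at which all
  Monte-Carlo margins in the tests are comfortably stable.

# Known limitations

* Linkage stereochemistry (α2-3 vs α2-6 NeuAc, arm assignments beyond
  diagnostic-ion evidence) is carried as annotation, never inferred.
* The E-ion and 0,2A defaults are documented conventions, not asserted
  instrument truths; override them per laboratory practice.
* The moderated model assumes independent glycans; co-regulated isomer
  families violate this mildly, which the composition-level aggregation
  partially addresses.
* Mixed-effects structure (e.g. anatomical region nested in donor) is not
  modelled.
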
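Package: glycardio
Title: Cardiac N-Glycomics: Composition Algebra, Fragment Annotation, and
    Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for LC-MS/MS N-glycomics of cardiac tissue and isolated
    cardiomyocytes. Provides glycan composition parsing and monoisotopic
    mass/m-z computation for reduced (alditol) N-glycans, a glycan class
    taxonomy at composition and structure level, composition-relatedness
    graphs for comparing glycan libraries, theoretical fragment generation
    and diagnostic-ion (B/C/Y/Z, D, D-18, D-221, E) annotation of
    negative-mode MS/MS spectra, relative-abundance quantification with
    median normalization, univariate empirical-Bayes moderated-t and
    covariate-adjusted differential abundance with Benjamini-Hochberg FDR,
    glycogene pathway profiling from differential-expression tables, and a
    synthetic-data module that generates biosynthetically coherent glycan
    libraries, abundance cohorts with planted effects and confounders, toy
    spectra, and gene tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
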
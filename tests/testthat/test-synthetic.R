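test_that("library generation is deterministic and respects the class mix", {
  lib1 <- generate_library(50, seed = 1)
  lib2 <- generate_library(50, seed = 1)
  expect_identical(lib1, lib2)
  expect_false(identical(lib1, generate_library(50, seed = 2)))
  expect_equal(nrow(lib1), 50)
  expect_error(generate_library(50), "seed")
  expect_error(generate_library(3, seed = 1), "at least 5")
  expect_error(generate_library(50, class_mix = c(paucimannose = 0.6),
                                seed = 1), "sum to 1")
  # pure paucimannose mix stays within HexNAc2, Hex <= 4
  p <- generate_library(12, class_mix = c(paucimannose = 1), seed = 3)
  cm <- t(vapply(p$composition,
                 function(s) unclass(parse_composition(s)), integer(4)))
  expect_true(all(cm[, "hexnac"] == 2 & cm[, "hex"] <= 4))
  # a mix demanding long biosynthetic chains errors when n is too small
  expect_error(generate_library(5, class_mix = c("complex-tetra" = 1),
                                seed = 4), "infeasible")
})

test_that("every library composition connects to the H3N2 core", {
  for (seed in c(5, 6)) {
    lib <- generate_library(50, seed = seed)
    g <- build_composition_graph(lib$composition)
    expect_true("H3N2" %in% g$nodes$composition)
    expect_equal(graph_summary(g)$n_components, 1L)
  }
  cm <- generate_library(60, profile = "cardiomyocyte", seed = 7)
  expect_equal(graph_summary(build_composition_graph(cm$composition))$n_components,
               1L)
})

test_that("library structures are internally consistent", {
  lib <- generate_library(40, seed = 8)
  for (i in seq_len(nrow(lib))) {
    s <- parse_structure(lib$structure[i])
    expect_identical(s$composition, lib$composition[i],
                     label = lib$glycan_id[i])
    expect_identical(classify_structure(s)$fine, lib$fine_class[i],
                     label = lib$glycan_id[i])
    expect_equal(lib$theoretical_mz[i],
                 glycan_mz(lib$composition[i], charge = lib$charge[i]),
                 tolerance = 1e-9)
  }
})

test_that("cohorts are deterministic with planted effects and metadata shapes", {
  lib <- generate_library(30, seed = 9)
  c1 <- generate_cohort(lib, effects = list(paucimannose = -1), seed = 10)
  c2 <- generate_cohort(lib, effects = list(paucimannose = -1), seed = 10)
  expect_identical(c1, c2)
  expect_error(generate_cohort(lib, effects = list(paucimannose = -1)),
               "seed")
  expect_equal(dim(c1$areas), c(30, 34))
  expect_equal(as.vector(table(c1$metadata$group)), c(16, 18))
  expect_true(all(c("hypertension", "cardiovascular_disease") %in%
                    names(c1$metadata)))
  # ground truth marks exactly the targeted glycans
  tg <- c1$truth$per_glycan
  expect_identical(tg$glycan_id[tg$true_log2fc == -1],
                   lib$glycan_id[lib$fine_class == "paucimannose"])
  expect_error(generate_cohort(lib, effects = list(nosuchclass = -1),
                               seed = 1), "matches no glycan")
})

test_that("a null cohort has near-zero group differences", {
  lib <- generate_library(40, seed = 11)
  ch <- generate_cohort(lib, seed = 12)
  lfc <- rowMeans(log2(ch$areas[, ch$metadata$group == "positive"])) -
    rowMeans(log2(ch$areas[, ch$metadata$group == "negative"]))
  # technical CV 10% at n=16/18: SE of each difference is ~0.05 log2
  expect_lt(max(abs(lfc)), 0.25)
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("spectra reproduce theoretical ions under zero jitter and respect seeds", {
  lib <- generate_library(30, seed = 13)
  s <- parse_structure(lib$structure[which(lib$fine_class == "complex-bi")[1]])
  sp0 <- generate_spectrum(s, jitter_ppm = 0, n_noise = 0, seed = 14)
  ions <- rbind(enumerate_glycosidic_fragments(s, max_charge = 1),
                diagnostic_ions(s))
  expect_setequal(round(sp0$mz, 6), unique(round(ions$mz, 6)))
  expect_identical(generate_spectrum(s, seed = 15),
                   generate_spectrum(s, seed = 15))
  # 5 ppm jitter keeps every true peak within 15 ppm of theory (3 sigma)
  deviations <- unlist(lapply(1:20, function(i) {
    sp <- generate_spectrum(s, jitter_ppm = 5, n_noise = 0, seed = 100 + i)
    truth <- attr(sp, "truth")
    abs(sp$mz - truth$theoretical_mz) / truth$theoretical_mz * 1e6
  }))
  # ~3 sigma: at most a fraction of a percent of peaks exceed 15 ppm
  expect_lt(mean(deviations > 15), 0.015)
  expect_lt(stats::median(deviations), 5)
})

test_that("DE gene tables plant the requested significant rows", {
  ref <- glycogene_reference()
  de0 <- generate_de_gene_table(ref, n_sig = 0, cell_types = "cm",
                                regions = "LV", seed = 16)
  expect_equal(nrow(filter_significant(de0)), 0L)
  de1 <- generate_de_gene_table(ref, pathway_sig = c("Sialylation" = 10),
                                n_per_stratum = 10, cell_types = "cm",
                                regions = "LV", seed = 17)
  pc <- pathway_contribution(filter_significant(de1), ref)
  expect_equal(pc$percent, 100)
  expect_identical(generate_de_gene_table(ref, seed = 18),
                   generate_de_gene_table(ref, seed = 18))
  expect_error(generate_de_gene_table(ref), "seed")
})
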
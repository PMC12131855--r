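test_that("composition parsing, formatting and round trips are canonical", {
  expect_equal(unclass(parse_composition("H5N4F1S2")),
               c(hex = 5L, hexnac = 4L, fuc = 1L, neuac = 2L),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_composition("H3N2")),
               c(hex = 3L, hexnac = 2L, fuc = 0L, neuac = 0L),
               ignore_attr = TRUE)
  expect_identical(format_composition(parse_composition("H7N6F1S1")),
                   "H7N6F1S1")
  # order-insensitive, A accepted as NeuAc alias, S canonical on output
  expect_identical(format_composition(parse_composition("N2H3")), "H3N2")
  expect_identical(format_composition(parse_composition("H5N4A2")), "H5N4S2")
  # round trip over random compositions
  for (s in random_comps(50, seed = 11)) {
    expect_identical(format_composition(parse_composition(s)), s)
  }
})

test_that("malformed composition strings raise named parse errors", {
  expect_error(parse_composition("H5X2"), "X2")
  expect_error(parse_composition("H2H3"), "repeated")
  expect_error(parse_composition("H5N4S1A1"), "repeated")
  expect_error(parse_composition("H-1N2"), "malformed")
  expect_error(parse_composition("5H"), "malformed")
  expect_error(glycan_composition(hex = -1), "non-negative")
  expect_error(glycan_composition(hex = 1.5), "non-negative")
})

test_that("neutral masses match residue-mass arithmetic", {
  # 6 Hex + 2 HexNAc + 1 dHex + water + alditol delta
  expect_equal(neutral_mass("H6N2F1", reduced = TRUE), 1544.5598,
               tolerance = 1e-7)
  expect_equal(neutral_mass("H2N2", reduced = TRUE), 750.2906,
               tolerance = 1e-7)
  expect_equal(neutral_mass("", reduced = FALSE), 18.010565)
})

test_that("mass additivity holds under glycosidic condensation", {
  set.seed(21)
  for (i in 1:25) {
    a <- glycan_composition(sample(0:6, 1), sample(0:5, 1),
                            sample(0:2, 1), sample(0:3, 1))
    b <- glycan_composition(sample(0:6, 1), sample(0:5, 1),
                            sample(0:2, 1), sample(0:3, 1))
    ab <- glycan_composition(a[["hex"]] + b[["hex"]],
                             a[["hexnac"]] + b[["hexnac"]],
                             a[["fuc"]] + b[["fuc"]],
                             a[["neuac"]] + b[["neuac"]])
    expect_equal(neutral_mass(ab, reduced = FALSE),
                 neutral_mass(a, reduced = FALSE) +
                   neutral_mass(b, reduced = FALSE) - mass_table()$water)
  }
})

test_that("deprotonated m/z follows (M - zH)/z and the algebraic identity", {
  expect_equal(glycan_mz("H6N2F1", charge = 2, reduced = TRUE), 771.2726,
               tolerance = 1e-6)
  expect_identical(round(glycan_mz("H6N2F1", charge = 2)), 771)
  expect_equal(glycan_mz("H2N2", charge = 1, reduced = TRUE), 749.2833,
               tolerance = 1e-6)
  expect_error(glycan_mz("H3N2", charge = 0), "positive integer")
  # mz * z + z * proton recovers the neutral mass for every charge
  proton <- mass_table()$proton
  for (s in random_comps(20, seed = 31)) {
    for (z in 1:3) {
      expect_equal(glycan_mz(s, charge = z) * z + z * proton,
                   neutral_mass(s))
    }
  }
})

test_that("composition classification follows the paucimannose/oligomannose/processed rules", {
  expect_identical(unname(classify_composition("H4N2F1")), "paucimannose")
  expect_identical(unname(classify_composition("H10N2")), "oligomannose")
  expect_identical(unname(classify_composition("H5N4F1S2")), "processed")
  # sialylated HexNAc2 and sub-core compositions refuse classification
  expect_identical(unname(classify_composition("H5N2S1")), "unclassified")
  expect_identical(unname(classify_composition("H3N1")), "unclassified")
  # configurable paucimannose bound
  expect_identical(unname(classify_composition("H4N2", pauci_max_hex = 3)),
                   "oligomannose")
  # partition: every composition maps to exactly one of the four labels
  cls <- classify_composition(random_comps(200, seed = 41))
  expect_true(all(cls %in% c("paucimannose", "oligomannose", "processed",
                             "unclassified")))
})

test_that("composition property buckets split by fucose/sialic acid with a HexNAc2 bucket", {
  expect_identical(unname(composition_property("H7N6F1S1")), "fuco-sialylated")
  expect_identical(unname(composition_property("H6N4F1")), "fuco")
  expect_identical(unname(composition_property("H5N2")),
                   "oligomannose/paucimannose")
  expect_identical(unname(composition_property("H5N4S1")), "sialylated")
  expect_identical(unname(composition_property("H5N4")), "neutral")
})

test_that("class distribution averages per-sample class sums and totals 100", {
  rel <- relative_abundance(matrix(c(25, 25, 50, 10, 40, 50), 3, 2,
                                   dimnames = list(c("g1", "g2", "g3"),
                                                   c("s1", "s2"))))
  one_class <- class_distribution(rel, c(g1 = "high-mannose",
                                         g2 = "high-mannose",
                                         g3 = "high-mannose"))
  expect_equal(unname(one_class), 100)
  two <- class_distribution(
    relative_abundance(matrix(c(5, 5), 2, 1,
                              dimnames = list(c("g1", "g2"), "s1"))),
    c(g1 = "paucimannose", g2 = "complex-bi"))
  expect_equal(unname(two), c(50, 50))
  expect_equal(sum(class_distribution(rel, c(g1 = "a", g2 = "b", g3 = "c"))),
               100)
  expect_error(class_distribution(rel, c(g1 = "a", g2 = "b")), "g3")
})

test_that("class distribution recovers generator abundance shares", {
  lib <- generate_library(60, profile = "cardiomyocyte", seed = 5)
  cohort <- generate_cohort(lib, abundance_profile = "cardiomyocyte",
                            seed = 6)
  rel <- relative_abundance(cohort$areas)
  got <- class_distribution(rel, stats::setNames(lib$fine_class,
                                                 lib$glycan_id))
  want <- 100 * class_abundance_profile("cardiomyocyte")
  # generator plants exact class shares; only the technical CV perturbs them
  expect_equal(got[["high-mannose"]], want[["high-mannose"]], tolerance = 0.02)
  expect_equal(got[["paucimannose"]], want[["paucimannose"]], tolerance = 0.05)
})
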
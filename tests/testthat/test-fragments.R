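test_that("glycosidic fragments follow the B/C/Y/Z mass rules", {
  s <- parse_structure(SIAL_BI_STR)
  frags <- enumerate_glycosidic_fragments(s, max_charge = 1)
  # terminal NeuAc cleavage: B at the bare residue mass, [B-H]- at 290.0881
  b_neuac <- frags[frags$kind == "B" & frags$residues == "S1", ]
  expect_equal(b_neuac$neutral, 291.095417)
  expect_equal(b_neuac$mz, 290.088141, tolerance = 1e-6)
  # C = B + water for every cleavage
  expect_equal(frags$neutral[frags$kind == "C"],
               frags$neutral[frags$kind == "B"] + mass_table()$water)
  # reduced Man3 core has 4 edges, so 4 ions of each kind per charge
  man3 <- enumerate_glycosidic_fragments(parse_structure(MAN3_STR),
                                         max_charge = 1)
  expect_equal(unname(table(man3$kind)[c("B", "C", "Y", "Z")]),
               rep(4L, 4), ignore_attr = TRUE)
})

test_that("complementary fragments conserve the precursor mass", {
  lib <- generate_library(50, seed = 14)
  for (i in seq_len(nrow(lib))) {
    s <- parse_structure(lib$structure[i])
    M <- neutral_mass(s$composition, reduced = TRUE)
    fr <- enumerate_glycosidic_fragments(s, max_charge = 1)
    b <- fr[fr$kind == "B", ]; y <- fr[fr$kind == "Y", ]
    cc <- fr[fr$kind == "C", ]; z <- fr[fr$kind == "Z", ]
    expect_equal(b$neutral + y$neutral[match(b$edge, y$edge)],
                 rep(M, nrow(b)), tolerance = 1e-9, label = lib$glycan_id[i])
    expect_equal(cc$neutral + z$neutral[match(cc$edge, z$edge)],
                 rep(M, nrow(cc)), tolerance = 1e-9)
  }
})

test_that("ion m/z values recompute from residue multiset and kind deltas", {
  s <- parse_structure(BIANT_STR)
  fr <- rbind(enumerate_glycosidic_fragments(s, max_charge = 2),
              diagnostic_ions(s))
  mt <- mass_table()
  for (k in seq_len(nrow(fr))) {
    counts <- unclass(parse_composition(fr$residues[k]))
    base <- sum(counts * mt$residues)
    delta <- switch(fr$kind[k],
                    B = 0, C = mt$water, D = 0, "D-18" = -mt$water,
                    Y = mt$water + mt$reduction, Z = mt$reduction,
                    NA_real_)
    if (is.na(delta)) next
    expect_equal(fr$neutral[k], base + delta, tolerance = 1e-9)
    expect_equal(fr$mz[k],
                 (fr$neutral[k] - fr$charge[k] * mt$proton) / fr$charge[k])
  }
})

test_that("diagnostic D-family ions encode 6-arm content and bisecting GlcNAc", {
  d <- diagnostic_ions(parse_structure(BIANT_STR))
  # D = beta-Man + 6-arm Man + GlcNAc + Gal
  expect_equal(d$neutral[d$kind == "D"], 689.2378, tolerance = 1e-4)
  expect_equal(d$mz[d$kind == "D"], 688.2306, tolerance = 1e-4)
  expect_equal(d$neutral[d$kind == "D-18"],
               d$neutral[d$kind == "D"] - mass_table()$water)
  expect_false("D-221" %in% d$kind)
  # bisected: D retains the bisecting GlcNAc and emits its 221.0899 loss
  db <- diagnostic_ions(parse_structure(BIANT_BIS_STR))
  expect_true("D-221" %in% db$kind)
  expect_equal(db$neutral[db$kind == "D"] - db$neutral[db$kind == "D-221"],
               221.089938, tolerance = 1e-6)
  # Man3: D contains the 6-arm Man + beta-Man only
  dm <- diagnostic_ions(parse_structure(MAN3_STR))
  expect_equal(dm$neutral[dm$kind == "D"], 324.1056, tolerance = 1e-4)
  expect_equal(dm$mz[dm$kind == "D"], 323.0984, tolerance = 1e-4)
  # no core: error
  expect_error(diagnostic_ions(parse_structure("GlcNAc(GlcNAc)")), "core")
  # E ion appears for tri-antennary structures only
  tri <- paste0("GlcNAc(GlcNAc(Man(Man[6](GlcNAc(Gal)))",
                "(Man[3](GlcNAc(Gal))(GlcNAc(Gal)))))")
  expect_true("E" %in% diagnostic_ions(parse_structure(tri))$kind)
  expect_false("E" %in% d$kind)
})

test_that("peak matching is greedy, tolerance-bounded and deterministic", {
  s <- parse_structure(BIANT_STR)
  ions <- rbind(enumerate_glycosidic_fragments(s, max_charge = 1),
                diagnostic_ions(s))
  empty <- glycan_spectrum(numeric(0), numeric(0))
  expect_equal(nrow(match_peaks(empty, ions)), 0L)
  # self-match with zero jitter annotates every peak
  sp0 <- generate_spectrum(s, jitter_ppm = 0, n_noise = 0, seed = 2)
  ann0 <- match_peaks(sp0, ions, tol_ppm = 20)
  expect_equal(nrow(ann0), length(sp0$mz))
  expect_true(all(abs(ann0$ppm_error) < 1e-6))
  # jittered peaks within tolerance are matched; noise stays unmatched
  sp <- generate_spectrum(s, jitter_ppm = 5, n_noise = 10, seed = 3)
  truth <- attr(sp, "truth")
  ann <- match_peaks(sp, ions, tol_ppm = 20)
  true_peaks <- truth$peak[truth$kind != "noise"]
  expect_true(all(true_peaks %in% ann$peak))
  noise_matched <- intersect(truth$peak[truth$kind == "noise"], ann$peak)
  expect_lt(length(noise_matched), 3)
  expect_identical(match_peaks(sp, ions, tol_ppm = 20), ann)
})

test_that("topology evidence reads out matched diagnostic ions", {
  ann <- data.frame(peak = 1:2, kind = c("D", "D-18"))
  topo <- infer_topology(ann)
  expect_true(topo$six_arm_confirmed$flag)
  expect_equal(topo$six_arm_confirmed$peaks, 1:2)
  expect_false(topo$bisecting_present$flag)
  expect_true(infer_topology(
    data.frame(peak = 5, kind = "D-221"))$bisecting_present$flag)
  none <- infer_topology(data.frame(peak = integer(0), kind = character(0)))
  expect_false(any(none$six_arm_confirmed$flag, none$bisecting_present$flag,
                   none$tri_antennary_present$flag))
})

test_that("MGF files round-trip spectra", {
  s <- parse_structure(BIANT_STR)
  sp <- generate_spectrum(s, seed = 4)
  sp$title <- "demo"
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(sp), path)
  back <- read_mgf(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$mz, sp$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$precursor_mz, sp$precursor_mz, tolerance = 1e-6)
  expect_identical(back[[1]]$precursor_charge, sp$precursor_charge)
  expect_identical(back[[1]]$title, "demo")
  expect_error(read_mgf(withr::local_tempfile(lines = "BEGIN IONS")),
               "malformed")
})
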
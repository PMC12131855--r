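#' @name synthetic-data
#' @title Synthetic glycomics data generators
#' @description Generators for glycan libraries, abundance cohorts with
#'   planted effects and confounders, toy MS/MS spectra, and DE-gene
#'   tables, so every pipeline stage can be exercised without raw data.
#'   All generators are deterministic under a fixed seed and emit ground
#'   truth sufficient to score sensitivity, FDR, and bias.
NULL

.GLYCAN_CLASSES <- c("paucimannose", "high-mannose", "hybrid", "complex-mono",
                     "complex-bi", "bisecting", "complex-tri", "complex-tetra")

# library-count mixes (fraction of structures per class)
.LIBRARY_MIX <- list(
  tissue = c("paucimannose" = 0.12, "high-mannose" = 0.20, "hybrid" = 0.10,
             "complex-mono" = 0.08, "complex-bi" = 0.28, "bisecting" = 0.10,
             "complex-tri" = 0.08, "complex-tetra" = 0.04),
  cardiomyocyte = c("paucimannose" = 0.16, "high-mannose" = 0.30,
                    "hybrid" = 0.12, "complex-mono" = 0.10,
                    "complex-bi" = 0.22, "bisecting" = 0.06,
                    "complex-tri" = 0.04, "complex-tetra" = 0))

#' Class abundance profiles
#'
#' Default per-class shares of total glycan abundance used by
#' [generate_cohort()], emulating the distinct profiles of whole cardiac
#' tissue (complex-biantennary-dominated) and isolated cardiomyocytes
#' (high-mannose-dominated).
#'
#' @param profile `"tissue"` or `"cardiomyocyte"`.
#' @return Named numeric vector of class shares summing to 1.
#' @export
class_abundance_profile <- function(profile = c("tissue", "cardiomyocyte")) {
  profile <- match.arg(profile)
  p <- switch(profile,
    tissue = c("complex-bi" = 46, "high-mannose" = 32, "paucimannose" = 6.7,
               "bisecting" = 5.3, "hybrid" = 4.6, "complex-tri" = 3.3,
               "complex-mono" = 2, "complex-tetra" = 0.2),
    cardiomyocyte = c("high-mannose" = 72, "paucimannose" = 11,
                      "complex-bi" = 8.2, "hybrid" = 6, "complex-mono" = 2.5,
                      "bisecting" = 1, "complex-tri" = 0.6,
                      "complex-tetra" = 0))
  p / sum(p)
}

# curated biosynthetic candidate table: each row is a composition with the
# branch parameters needed to build a concrete tree, plus a prerequisite
# composition that differs by exactly one residue (anchoring every
# candidate to the H3N2 core through single-step intermediates)
.candidate_table <- function() {
  cand <- function(comp, class, arms = 2L, man6 = 0L, man3 = 0L,
                   ant6 = 0L, ant3 = 0L, gal = 0L, gdn = 0L, bis = 0L,
                   cf = 0L, tfuc = 0L, sia = 0L, prereq = NA_character_) {
    data.frame(comp = comp, class = class, arms = arms, man6 = man6,
               man3 = man3, ant6 = ant6, ant3 = ant3, gal = gal, gdn = gdn,
               bis = bis, cf = cf, tfuc = tfuc, sia = sia, prereq = prereq,
               stringsAsFactors = FALSE)
  }
  rbind(
    # paucimannose (trimmed core, +/- core fucose)
    cand("H3N2", "paucimannose"),
    cand("H2N2", "paucimannose", arms = 1L, prereq = "H3N2"),
    cand("H1N2", "paucimannose", arms = 0L, prereq = "H2N2"),
    cand("H4N2", "paucimannose", man6 = 1L, prereq = "H3N2"),
    cand("H3N2F1", "paucimannose", cf = 1L, prereq = "H3N2"),
    cand("H4N2F1", "paucimannose", man6 = 1L, cf = 1L, prereq = "H4N2"),
    cand("H2N2F1", "paucimannose", arms = 1L, cf = 1L, prereq = "H2N2"),
    # high-mannose ladder (+/- core fucose)
    cand("H5N2", "high-mannose", man6 = 2L, prereq = "H4N2"),
    cand("H6N2", "high-mannose", man6 = 2L, man3 = 1L, prereq = "H5N2"),
    cand("H7N2", "high-mannose", man6 = 3L, man3 = 1L, prereq = "H6N2"),
    cand("H8N2", "high-mannose", man6 = 3L, man3 = 2L, prereq = "H7N2"),
    cand("H9N2", "high-mannose", man6 = 4L, man3 = 2L, prereq = "H8N2"),
    cand("H10N2", "high-mannose", man6 = 4L, man3 = 3L, prereq = "H9N2"),
    cand("H5N2F1", "high-mannose", man6 = 2L, cf = 1L, prereq = "H5N2"),
    cand("H6N2F1", "high-mannose", man6 = 2L, man3 = 1L, cf = 1L,
         prereq = "H6N2"),
    # hybrid: 6-arm mannose extension + GlcNAc antenna on the 3-arm
    cand("H5N3", "hybrid", man6 = 2L, ant3 = 1L, prereq = "H5N2"),
    cand("H6N3", "hybrid", man6 = 2L, ant3 = 1L, gal = 1L, prereq = "H5N3"),
    cand("H5N3F1", "hybrid", man6 = 2L, ant3 = 1L, cf = 1L, prereq = "H5N3"),
    cand("H6N3S1", "hybrid", man6 = 2L, ant3 = 1L, gal = 1L, sia = 1L,
         prereq = "H6N3"),
    cand("H6N3F1S1", "hybrid", man6 = 2L, ant3 = 1L, gal = 1L, cf = 1L,
         sia = 1L, prereq = "H6N3S1"),
    # complex-mono
    cand("H3N3", "complex-mono", ant3 = 1L, prereq = "H3N2"),
    cand("H4N3", "complex-mono", ant3 = 1L, gal = 1L, prereq = "H3N3"),
    cand("H4N3F1", "complex-mono", ant3 = 1L, gal = 1L, cf = 1L,
         prereq = "H4N3"),
    cand("H4N3S1", "complex-mono", ant3 = 1L, gal = 1L, sia = 1L,
         prereq = "H4N3"),
    # complex-bi (incl. LacdiNAc variants)
    cand("H3N4", "complex-bi", ant6 = 1L, ant3 = 1L, prereq = "H3N3"),
    cand("H4N4", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 1L,
         prereq = "H3N4"),
    cand("H5N4", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L,
         prereq = "H4N4"),
    cand("H5N4F1", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, cf = 1L,
         prereq = "H5N4"),
    cand("H5N4F2", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, cf = 1L,
         tfuc = 1L, prereq = "H5N4F1"),
    cand("H5N4S1", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, sia = 1L,
         prereq = "H5N4"),
    cand("H5N4F1S1", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, cf = 1L,
         sia = 1L, prereq = "H5N4F1"),
    cand("H5N4S2", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, sia = 2L,
         prereq = "H5N4S1"),
    cand("H5N4F1S2", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, cf = 1L,
         sia = 2L, prereq = "H5N4F1S1"),
    cand("H4N4S1", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 1L, sia = 1L,
         prereq = "H4N4"),
    cand("H4N4F1S1", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 1L, cf = 1L,
         sia = 1L, prereq = "H4N4S1"),
    cand("H6N4F1", "complex-bi", ant6 = 1L, ant3 = 1L, gal = 2L, man6 = 1L,
         cf = 1L, prereq = "H5N4F1"),
    cand("H3N5", "complex-bi", ant6 = 1L, ant3 = 1L, gdn = 1L,
         prereq = "H3N4"),
    cand("H3N5F1", "complex-bi", ant6 = 1L, ant3 = 1L, gdn = 1L, cf = 1L,
         prereq = "H3N5"),
    cand("H3N5F1S1", "complex-bi", ant6 = 1L, ant3 = 1L, gdn = 1L, cf = 1L,
         sia = 1L, prereq = "H3N5F1"),
    cand("H3N6", "complex-bi", ant6 = 1L, ant3 = 1L, gdn = 2L,
         prereq = "H3N5"),
    cand("H3N6F1", "complex-bi", ant6 = 1L, ant3 = 1L, gdn = 2L, cf = 1L,
         prereq = "H3N6"),
    cand("H3N6F1S1", "complex-bi", ant6 = 1L, ant3 = 1L, gdn = 2L, cf = 1L,
         sia = 1L, prereq = "H3N6F1"),
    # bisecting (biantennary + bisecting GlcNAc)
    cand("H5N5", "bisecting", ant6 = 1L, ant3 = 1L, gal = 2L, bis = 1L,
         prereq = "H5N4"),
    cand("H5N5F1", "bisecting", ant6 = 1L, ant3 = 1L, gal = 2L, bis = 1L,
         cf = 1L, prereq = "H5N5"),
    cand("H5N5S1", "bisecting", ant6 = 1L, ant3 = 1L, gal = 2L, bis = 1L,
         sia = 1L, prereq = "H5N5"),
    # complex-tri
    cand("H6N5", "complex-tri", ant6 = 1L, ant3 = 2L, gal = 3L,
         prereq = "H5N5"),
    cand("H6N5F1", "complex-tri", ant6 = 1L, ant3 = 2L, gal = 3L, cf = 1L,
         prereq = "H6N5"),
    cand("H6N5S1", "complex-tri", ant6 = 1L, ant3 = 2L, gal = 3L, sia = 1L,
         prereq = "H6N5"),
    cand("H6N5F1S1", "complex-tri", ant6 = 1L, ant3 = 2L, gal = 3L, cf = 1L,
         sia = 1L, prereq = "H6N5F1"),
    # complex-tetra
    cand("H6N6", "complex-tetra", ant6 = 2L, ant3 = 2L, gal = 3L,
         prereq = "H6N5"),
    cand("H7N6", "complex-tetra", ant6 = 2L, ant3 = 2L, gal = 4L,
         prereq = "H6N6"),
    cand("H7N6F1", "complex-tetra", ant6 = 2L, ant3 = 2L, gal = 4L, cf = 1L,
         prereq = "H7N6"),
    cand("H7N6F1S1", "complex-tetra", ant6 = 2L, ant3 = 2L, gal = 4L,
         cf = 1L, sia = 1L, prereq = "H7N6F1"))
}

# build a concrete tree from a candidate row; `variant` > 0 generates a
# structural isomer: odd variants swap the arm assignment where both arms
# exist, and every variant is stamped with an isomer annotation tag on the
# reducing end (standing in for the linkage/retention-resolved isomerism
# that distinguishes co-compositional structures in real libraries)
.build_candidate <- function(row, variant = 0L) {
  swap_arms <- variant %% 2L == 1L
  man6 <- row$man6; man3 <- row$man3; ant6 <- row$ant6; ant3 <- row$ant3
  if (swap_arms && row$arms == 2L) {
    tmp <- man6; man6 <- man3; man3 <- tmp
    tmp <- ant6; ant6 <- ant3; ant3 <- tmp
  }
  rows <- list(); nid <- 0L
  add <- function(parent, residue, tag = "") {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(node = nid, parent = parent, residue = residue,
                               tag = tag, stringsAsFactors = FALSE)
    nid
  }
  root <- add(0L, "GlcNAc",
              if (variant > 0L) paste0("iso", variant) else "")
  if (row$cf) add(root, "Fuc", "cf")
  g2 <- add(root, "GlcNAc")
  bman <- add(g2, "Man")
  if (row$bis) add(bman, "GlcNAc", "bis")
  caps <- c(rep("Gal", row$gal), rep("GalNAc", row$gdn))
  sia_left <- row$sia
  tfuc_left <- row$tfuc
  cap_i <- 0L
  grow_arm <- function(tag, n_man, n_ant) {
    if (row$arms == 0L) return(invisible(NULL))
    if (tag == "3" && row$arms < 2L) return(invisible(NULL))
    arm <- add(bman, "Man", tag)
    tip <- arm
    for (i in seq_len(n_man)) tip <- add(tip, "Man")
    for (i in seq_len(n_ant)) {
      ant <- add(arm, "GlcNAc")
      if (tfuc_left > 0L) { add(ant, "Fuc"); tfuc_left <<- tfuc_left - 1L }
      cap_i <<- cap_i + 1L
      if (cap_i <= length(caps)) {
        cap <- add(ant, caps[cap_i])
        if (sia_left > 0L) { add(cap, "NeuAc"); sia_left <<- sia_left - 1L }
      }
    }
  }
  grow_arm("6", man6, ant6)
  grow_arm("3", man3, ant3)
  s <- glycan_structure(do.call(rbind, rows), reduced = TRUE)
  if (s$composition != format_composition(parse_composition(row$comp))) {
    stop("internal: built structure ", s$composition,
         " does not match candidate composition ", row$comp)
  }
  s
}

#' Generate a biosynthetically coherent glycan library
#'
#' Draws `n` structures according to a class mix, always including the
#' single-residue biosynthetic intermediates each structure needs, so that
#' every composition connects to the H3N2 trimannosyl core in the
#' composition graph through members of the library. When the class quota
#' exceeds the curated composition repertoire, additional structural
#' isomers (arm-swapped trees sharing a composition) are emitted.
#'
#' @param n Number of structures (>= 5).
#' @param class_mix Named proportions over the eight fine classes, summing
#'   to 1; default is the mix for the chosen `profile`.
#' @param profile `"tissue"` (default) or `"cardiomyocyte"`; sets the
#'   default `class_mix`.
#' @param seed Integer seed (mandatory).
#' @return A glycan library data.frame (see [read_glycan_library()]).
#' @examples
#' lib <- generate_library(30, seed = 7)
#' table(lib$fine_class)
#' @export
generate_library <- function(n, class_mix = NULL,
                             profile = c("tissue", "cardiomyocyte"), seed) {
  if (missing(seed)) stop("`seed` is mandatory for every stochastic call")
  profile <- match.arg(profile)
  if (n < 5L) stop("n must be at least 5")
  if (is.null(class_mix)) class_mix <- .LIBRARY_MIX[[profile]]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix proportions must sum to 1")
  unknown <- setdiff(names(class_mix), .GLYCAN_CLASSES)
  if (length(unknown)) stop("unknown class(es) in class_mix: ",
                            paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  tab <- .candidate_table()
  mix <- stats::setNames(numeric(length(.GLYCAN_CLASSES)), .GLYCAN_CLASSES)
  mix[names(class_mix)] <- class_mix
  quota <- round(mix * n)
  # make quotas sum to n, adjusting the largest class
  delta <- n - sum(quota)
  if (delta != 0) {
    big <- names(which.max(quota))
    quota[big] <- quota[big] + delta
  }
  count <- stats::setNames(integer(length(.GLYCAN_CLASSES)), .GLYCAN_CLASSES)
  selected <- character(0)          # candidate comps, in inclusion order
  add_cand <- function(comp) {
    if (comp %in% selected) return(invisible(NULL))
    row <- tab[tab$comp == comp, ]
    if (!nrow(row)) stop("internal: unknown candidate ", comp)
    if (!is.na(row$prereq)) add_cand(row$prereq)
    selected <<- c(selected, comp)
    count[row$class] <<- count[row$class] + 1L
  }
  for (cls in .GLYCAN_CLASSES) {
    if (quota[cls] <= 0) next
    cands <- tab$comp[tab$class == cls]
    if (!length(cands)) stop("no candidates available for class ", cls)
    for (comp in cands) {
      if (count[cls] >= quota[cls]) break
      add_cand(comp)
    }
  }
  if (length(selected) > n) {
    stop("infeasible class mix: the ", length(selected),
         " biosynthetic intermediates required exceed n = ", n,
         "; increase n or simplify the mix")
  }
  # fill remaining slots with structural isomers of already-selected
  # candidates, favouring classes still under quota
  entries <- data.frame(comp = selected, variant = 0L,
                        stringsAsFactors = FALSE)
  while (nrow(entries) < n) {
    deficit <- quota - count
    cls <- if (any(deficit > 0)) names(which.max(deficit)) else
      names(which.max(quota))
    pool <- selected[tab$class[match(selected, tab$comp)] == cls]
    if (!length(pool)) pool <- selected
    comp <- sample(pool, 1L)
    cls <- tab$class[tab$comp == comp]
    v <- max(entries$variant[entries$comp == comp]) + 1L
    entries <- rbind(entries, data.frame(comp = comp, variant = v,
                                         stringsAsFactors = FALSE))
    count[cls] <- count[cls] + 1L
  }
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    row <- tab[tab$comp == entries$comp[i], ]
    s <- .build_candidate(row, variant = entries$variant[i])
    mass <- neutral_mass(s$composition, reduced = TRUE)
    z <- if (mass > 1200) 2L else 1L
    data.frame(
      glycan_id = sprintf("G%03d_%s%s", i, row$comp,
                          if (entries$variant[i] > 0)
                            paste0("_iso", entries$variant[i]) else ""),
      composition = s$composition,
      fine_class = row$class,
      structure = format_structure(s),
      theoretical_mz = glycan_mz(s$composition, charge = z, reduced = TRUE),
      charge = z,
      rrt = round(stats::runif(1, 0.3, 2.5), 3),
      glytoucan_id = sprintf("G%05dSY", i),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# resolve a per-glycan effect vector from a selector -> log2FC spec
.resolve_effects <- function(spec, library) {
  delta <- stats::setNames(numeric(nrow(library)), library$glycan_id)
  if (is.null(spec) || !length(spec)) return(delta)
  spec <- unlist(spec)
  coarse <- classify_composition(library$composition)
  for (sel in names(spec)) {
    hit <- if (sel %in% library$glycan_id) {
      library$glycan_id == sel
    } else if (sel %in% library$fine_class) {
      library$fine_class == sel
    } else if (sel %in% c("paucimannose", "oligomannose", "processed")) {
      unname(coarse) == sel
    } else {
      rep(FALSE, nrow(library))
    }
    if (!any(hit)) stop("effect selector '", sel, "' matches no glycan")
    delta[hit] <- delta[hit] + spec[[sel]]
  }
  delta
}

#' Generate a cohort of peak areas with planted effects and confounders
#'
#' Baseline areas are log-normal with class-dependent means calibrated to
#' a class-abundance profile; the disease group multiplies selected
#' glycans by `2^delta`; covariates (age, sex, comorbidity flags) are
#' drawn with group-dependent distributions and can carry their own
#' multiplicative effects on selected glycans (confounding); technical
#' noise is multiplicative log-normal with the stated CV. Ground truth is
#' returned alongside the data.
#'
#' @param library A [generate_library()] table.
#' @param effects Named list/vector: selector (glycan id, fine class, or
#'   coarse class) -> planted log2 fold change (positive vs negative).
#' @param covariate_effects Named list: covariate (`"age"` per decade,
#'   `"sexM"`, or a comorbidity flag name) -> either a scalar log2 effect
#'   applied to all glycans or a named selector vector like `effects`.
#' @param n_negative,n_positive Group sizes (default 16 and 18).
#' @param cv Technical coefficient of variation (default 0.10).
#' @param abundance_profile Profile name or named class-share vector for
#'   [class_abundance_profile()].
#' @param age_mean Named vector of group mean ages (default 63/66).
#' @param age_sd Age standard deviation (default 10).
#' @param male_prob Named vector of P(male) per group (default 10/16 and
#'   13/18).
#' @param comorbidity_prev Named list: flag -> c(negative, positive)
#'   prevalence. Defaults follow common cardiac comorbidities.
#' @param total_area Mean total peak area per sample (arbitrary units).
#' @param seed Integer seed (mandatory).
#' @return List with `areas` (matrix glycans x samples), `metadata`
#'   (data.frame), and `truth` (list: `per_glycan` data.frame with
#'   `true_log2fc` and class; `covariate_effects` matrix; parameters).
#' @export
generate_cohort <- function(library, effects = list(),
                            covariate_effects = list(),
                            n_negative = 16L, n_positive = 18L, cv = 0.10,
                            abundance_profile = "tissue",
                            age_mean = c(negative = 63, positive = 66),
                            age_sd = 10,
                            male_prob = c(negative = 10 / 16,
                                          positive = 13 / 18),
                            comorbidity_prev = list(
                              hypertension = c(negative = 9 / 16,
                                               positive = 12 / 18),
                              cardiovascular_disease = c(negative = 9 / 16,
                                                         positive = 4 / 18),
                              type2_diabetes = c(negative = 3 / 16,
                                                 positive = 6 / 18),
                              copd = c(negative = 4 / 16,
                                       positive = 3 / 18)),
                            total_area = 1e6, seed) {
  if (missing(seed)) stop("`seed` is mandatory for every stochastic call")
  stopifnot(cv > 0, n_negative >= 2L, n_positive >= 2L)
  set.seed(as.integer(seed))
  shares <- if (is.character(abundance_profile)) {
    class_abundance_profile(abundance_profile)
  } else abundance_profile / sum(abundance_profile)
  n_samp <- n_negative + n_positive
  group <- factor(rep(c("negative", "positive"), c(n_negative, n_positive)),
                  levels = c("negative", "positive"))
  metadata <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group = group,
    age = round(stats::rnorm(n_samp, mean = age_mean[as.character(group)],
                             sd = age_sd)),
    sex = ifelse(stats::runif(n_samp) <
                   male_prob[as.character(group)], "M", "F"),
    stringsAsFactors = FALSE)
  for (flag in names(comorbidity_prev)) {
    metadata[[flag]] <- as.integer(
      stats::runif(n_samp) < comorbidity_prev[[flag]][as.character(group)])
  }
  # baseline shares: class share split within class by log-normal weights
  g_ids <- library$glycan_id
  base <- stats::setNames(numeric(length(g_ids)), g_ids)
  for (cls in unique(library$fine_class)) {
    in_cls <- library$fine_class == cls
    share <- if (cls %in% names(shares)) shares[[cls]] else 0.01
    w <- exp(stats::rnorm(sum(in_cls), sd = 0.5))
    base[in_cls] <- share * w / sum(w)
  }
  base <- base / sum(base) * total_area
  delta <- .resolve_effects(effects, library)
  # per-covariate, per-glycan log2 effect matrix
  covs <- names(covariate_effects)
  cov_fx <- matrix(0, nrow = length(g_ids), ncol = length(covs),
                   dimnames = list(g_ids, covs))
  for (cn in covs) {
    v <- covariate_effects[[cn]]
    cov_fx[, cn] <- if (is.null(names(v)) && length(v) == 1L) {
      rep(as.numeric(v), length(g_ids))
    } else .resolve_effects(v, library)
  }
  # covariate design values per sample
  cov_x <- matrix(0, nrow = n_samp, ncol = length(covs),
                  dimnames = list(metadata$sample_id, covs))
  for (cn in covs) {
    cov_x[, cn] <- switch(cn,
      age = (metadata$age - mean(metadata$age)) / 10,
      sexM = as.integer(metadata$sex == "M"),
      {
        if (!cn %in% names(metadata)) {
          stop("covariate effect '", cn, "' has no matching metadata column")
        }
        metadata[[cn]]
      })
  }
  sdlog2 <- sqrt(log1p(cv^2)) / log(2)
  pos <- as.integer(group == "positive")
  log2area <- outer(log2(base), rep(0, n_samp), "+") +
    outer(delta, pos) +
    cov_fx %*% t(cov_x) +
    matrix(stats::rnorm(length(g_ids) * n_samp, sd = sdlog2),
           nrow = length(g_ids))
  areas <- 2^log2area
  dimnames(areas) <- list(g_ids, metadata$sample_id)
  truth <- list(
    per_glycan = data.frame(glycan_id = g_ids,
                            fine_class = library$fine_class,
                            composition = library$composition,
                            true_log2fc = unname(delta),
                            stringsAsFactors = FALSE),
    covariate_effects = cov_fx,
    params = list(cv = cv, n_negative = n_negative, n_positive = n_positive,
                  seed = seed))
  list(areas = areas, metadata = metadata, truth = truth)
}

#' Generate a toy MS/MS spectrum from a structure
#'
#' Theoretical B/C/Y/Z and diagnostic ions with Gaussian ppm jitter plus
#' uniform random noise peaks; the ground-truth annotation map is attached
#' as attribute `"truth"`.
#'
#' @param structure A [glycan_structure] (or serialized structure string).
#' @param jitter_ppm Gaussian m/z jitter in ppm (>= 0; default 5).
#' @param n_noise Number of uniform noise peaks (default 10).
#' @param seed Integer seed (mandatory).
#' @param precursor_charge Charge of the precursor (default 2).
#' @param max_fragment_charge Highest fragment charge enumerated
#'   (default 1).
#' @return A [glycan_spectrum]; `attr(, "truth")` is a data.frame mapping
#'   peak index to the generating ion kind (`"noise"` for noise peaks).
#' @export
generate_spectrum <- function(structure, jitter_ppm = 5, n_noise = 10, seed,
                              precursor_charge = 2L,
                              max_fragment_charge = 1L) {
  if (missing(seed)) stop("`seed` is mandatory for every stochastic call")
  stopifnot(jitter_ppm >= 0, n_noise >= 0)
  if (is.character(structure)) structure <- parse_structure(structure)
  set.seed(as.integer(seed))
  ions <- enumerate_glycosidic_fragments(structure,
                                         max_charge = max_fragment_charge)
  core <- .find_core(structure$nodes)
  if (!is.na(core$bman)) {
    ions <- rbind(ions, diagnostic_ions(structure,
                                        max_charge = max_fragment_charge))
  }
  ions <- ions[!duplicated(round(ions$mz, 6)), , drop = FALSE]
  mz_true <- ions$mz * (1 + stats::rnorm(nrow(ions), sd = jitter_ppm) / 1e6)
  int_true <- 100 * exp(stats::rnorm(nrow(ions), sd = 0.5))
  prec_mz <- glycan_mz(structure$composition, charge = precursor_charge,
                       reduced = structure$reduced)
  kinds <- ions$kind
  if (n_noise > 0) {
    mz_noise <- stats::runif(n_noise, min = 150, max = max(prec_mz, 500))
    int_noise <- stats::runif(n_noise, 1, 20)
    mz_all <- c(mz_true, mz_noise)
    int_all <- c(int_true, int_noise)
    kinds <- c(kinds, rep("noise", n_noise))
  } else {
    mz_all <- mz_true; int_all <- int_true
  }
  o <- order(mz_all)
  sp <- glycan_spectrum(mz_all[o], int_all[o], precursor_mz = prec_mz,
                        precursor_charge = precursor_charge,
                        title = structure$id)
  attr(sp, "truth") <- data.frame(peak = seq_along(o), kind = kinds[o],
                                  theoretical_mz = c(ions$mz,
                                                     rep(NA, length(kinds) - nrow(ions)))[o],
                                  stringsAsFactors = FALSE)
  sp
}

#' Generate a differential-expression glycogene table
#'
#' Samples genes from a glycogene reference per (cell type, region)
#' stratum and plants a chosen number of significant genes (|log2FC| > 1,
#' adjusted p < 0.05), optionally concentrated in specific pathways.
#' Ground truth is attached as attribute `"truth"`.
#'
#' @param ref Reference from [glycogene_reference()].
#' @param n_per_stratum Genes sampled per stratum (default 60).
#' @param n_sig Number of significant genes per stratum (default 12);
#'   ignored when `pathway_sig` is given.
#' @param pathway_sig Optional named vector pathway -> number of planted
#'   significant genes per stratum.
#' @param cell_types,regions Stratum labels.
#' @param seed Integer seed (mandatory).
#' @return DE gene table (`gene`, `cell_type`, `region`, `log2fc`,
#'   `padj`); `attr(, "truth")` marks the planted significant rows.
#' @export
generate_de_gene_table <- function(ref, n_per_stratum = 60L, n_sig = 12L,
                                   pathway_sig = NULL,
                                   cell_types = c("cardiomyocyte",
                                                  "endothelial",
                                                  "fibroblast"),
                                   regions = c("LV", "RV"), seed) {
  if (missing(seed)) stop("`seed` is mandatory for every stochastic call")
  set.seed(as.integer(seed))
  out <- list()
  for (ct in cell_types) for (rg in regions) {
    if (!is.null(pathway_sig)) {
      sig_genes <- character(0)
      for (pw in names(pathway_sig)) {
        pool <- ref$gene[ref$pathway == pw]
        k <- pathway_sig[[pw]]
        if (k > length(pool)) {
          stop("pathway '", pw, "' has only ", length(pool), " genes")
        }
        sig_genes <- c(sig_genes, sample(pool, k))
      }
      rest <- setdiff(ref$gene, sig_genes)
      n_rest <- max(0L, n_per_stratum - length(sig_genes))
      genes <- c(sig_genes, sample(rest, min(n_rest, length(rest))))
      is_sig <- genes %in% sig_genes
    } else {
      genes <- sample(ref$gene, min(n_per_stratum, nrow(ref)))
      is_sig <- seq_along(genes) <= n_sig
    }
    n <- length(genes)
    lfc <- numeric(n); padj <- numeric(n)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    lfc[is_sig] <- sgn[is_sig] * stats::runif(sum(is_sig), 1.2, 3)
    padj[is_sig] <- stats::runif(sum(is_sig), 0, 0.04)
    lfc[!is_sig] <- stats::runif(sum(!is_sig), -0.95, 0.95)
    padj[!is_sig] <- stats::runif(sum(!is_sig), 0.06, 1)
    out[[length(out) + 1L]] <- data.frame(
      gene = genes, cell_type = ct, region = rg, log2fc = lfc, padj = padj,
      planted_sig = is_sig, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  truth <- tab[tab$planted_sig, c("gene", "cell_type", "region", "log2fc")]
  tab$planted_sig <- NULL
  rownames(tab) <- NULL
  attr(tab, "truth") <- truth
  tab
}
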
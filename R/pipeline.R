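#' Run configuration
#'
#' Validated configuration for pipeline runs. Unknown keys are rejected;
#' the resolved configuration (with its FNV-1a hash and the seed) is
#' serialized alongside every run's outputs so that reruns are
#' reproducible and byte-identical.
#'
#' @param ... Named settings overriding the defaults: `lfc_threshold`,
#'   `p_threshold`, `q_threshold`, `zero_policy`, `tol_ppm`, `moderate`,
#'   `covariates`, `weighting`, `seed`.
#' @return A named list of settings (class `glycardio_config`).
#' @export
run_config <- function(...) {
  defaults <- list(lfc_threshold = 1, p_threshold = 0.05, q_threshold = 0.05,
                   zero_policy = "halfmin", tol_ppm = 20, moderate = TRUE,
                   covariates = character(0), weighting = "gene-count",
                   seed = 1L)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(user)] <- user
  class(defaults) <- "glycardio_config"
  defaults
}

# FNV-1a 32-bit hash of the serialized config (provenance stamp)
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[order(names(config))]),
                           collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to keep exact doubles
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.write_provenance <- function(config, out_dir) {
  prov <- unclass(config)
  prov$covariates <- as.list(prov$covariates)
  prov$config_hash <- .config_hash(config)
  jsonlite::write_json(prov, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Write a complete synthetic demo dataset
#'
#' Generates a glycan library, a two-group cohort with a planted
#' paucimannose decrease and confounded comorbidity structure, MS/MS
#' spectra for the first few structures, and a DE glycogene table, in the
#' CSV/MGF schemas the pipeline reads.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_glycans Library size (default 60).
#' @param seed Integer seed.
#' @return Invisibly, the list of written file paths.
#' @export
simulate_dataset <- function(out_dir, n_glycans = 60L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(n_glycans, seed = seed)
  cohort <- generate_cohort(lib, effects = list(paucimannose = -1),
                            covariate_effects = list(
                              hypertension = c(paucimannose = -0.3)),
                            seed = seed + 1L)
  spectra <- lapply(utils::head(which(lib$fine_class != "paucimannose"), 5),
                    function(i) {
                      sp <- generate_spectrum(parse_structure(
                        lib$structure[i], id = lib$glycan_id[i]),
                        seed = seed + 10L + i)
                      sp$title <- lib$glycan_id[i]
                      sp
                    })
  de <- generate_de_gene_table(glycogene_reference(), seed = seed + 2L)
  paths <- list(
    library = file.path(out_dir, "library.csv"),
    areas = file.path(out_dir, "areas.csv"),
    metadata = file.path(out_dir, "metadata.csv"),
    spectra = file.path(out_dir, "spectra.mgf"),
    de_genes = file.path(out_dir, "de_genes.csv"),
    truth = file.path(out_dir, "truth.csv"))
  write_glycan_library(lib, paths$library)
  write_peak_areas(cohort$areas, paths$areas)
  utils::write.csv(cohort$metadata, paths$metadata, row.names = FALSE,
                   quote = FALSE)
  write_mgf(spectra, paths$spectra)
  utils::write.csv(de, paths$de_genes, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth$per_glycan, paths$truth, row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' Annotate MS/MS spectra against a glycan library
#'
#' For each spectrum, the library structure whose theoretical precursor
#' m/z is nearest within tolerance is selected; its theoretical
#' glycosidic and diagnostic ions are matched to the peaks and the
#' topology evidence is read out. Writes `annotations.tsv`,
#' `topology.tsv`, and `config.json` to `out_dir`.
#'
#' @param spectra_file MGF path.
#' @param library_file Glycan library CSV path.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly, the annotations data.frame.
#' @export
run_annotate <- function(spectra_file, library_file, out_dir,
                         config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- read_mgf(spectra_file)
  lib <- read_glycan_library(library_file)
  ann_all <- list(); topo_all <- list()
  for (sp in spectra) {
    ppm <- abs(sp$precursor_mz - lib$theoretical_mz) / lib$theoretical_mz * 1e6
    ok <- which(lib$charge == sp$precursor_charge & ppm <= config$tol_ppm)
    if (!length(ok)) ok <- which.min(ppm)
    hit <- ok[which.min(ppm[ok])]
    s <- parse_structure(lib$structure[hit], id = lib$glycan_id[hit])
    ions <- enumerate_glycosidic_fragments(s, max_charge = 1L)
    if (!is.na(.find_core(s$nodes)$bman)) {
      ions <- rbind(ions, diagnostic_ions(s))
    }
    ann <- match_peaks(sp, ions, tol_ppm = config$tol_ppm)
    if (nrow(ann)) {
      ann <- cbind(spectrum = sp$title %||% "", glycan_id = lib$glycan_id[hit],
                   ann)
      ann_all[[length(ann_all) + 1L]] <- ann
    }
    topo <- infer_topology(ann[, setdiff(names(ann),
                                         c("spectrum", "glycan_id")),
                               drop = FALSE])
    topo_all[[length(topo_all) + 1L]] <- data.frame(
      spectrum = sp$title %||% "", glycan_id = lib$glycan_id[hit],
      six_arm_confirmed = topo$six_arm_confirmed$flag,
      three_arm_confirmed = topo$three_arm_confirmed$flag,
      bisecting_present = topo$bisecting_present$flag,
      tri_antennary_present = topo$tri_antennary_present$flag,
      stringsAsFactors = FALSE)
  }
  ann <- if (length(ann_all)) do.call(rbind, ann_all) else
    data.frame(spectrum = character(0), glycan_id = character(0))
  write_tsv_canonical(ann, file.path(out_dir, "annotations.tsv"))
  write_tsv_canonical(do.call(rbind, topo_all) %||%
                        data.frame(spectrum = character(0)),
                      file.path(out_dir, "topology.tsv"))
  .write_provenance(config, out_dir)
  invisible(ann)
}

#' End-to-end differential abundance run
#'
#' Reads peak areas, metadata, and the glycan library; runs the
#' univariate (moderated) and covariate-adjusted differential analyses,
#' the composition-level differential, the class distribution, and the
#' composition-graph summary; writes `results_univariate.tsv`,
#' `results_adjusted.tsv` (when covariates are configured),
#' `composition_differential.tsv`, `class_distribution.tsv`,
#' `graph_nodes.tsv`, `graph_edges.tsv`, and `config.json`. Reruns with
#' the same inputs and configuration are byte-identical.
#'
#' @param areas_file,metadata_file,library_file Input CSV paths.
#' @param out_dir Output directory.
#' @param config A [run_config()]; `covariates` selects the adjusted
#'   model's covariate columns.
#' @return Invisibly, a list with the univariate and adjusted
#'   [glycan_diffab] fits.
#' @export
run_diff <- function(areas_file, metadata_file, library_file, out_dir,
                     config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  areas <- read_peak_areas(areas_file)
  md <- read_sample_metadata(metadata_file)
  lib <- read_glycan_library(library_file)
  classes <- stats::setNames(lib$fine_class, lib$glycan_id)
  uni <- glycan_diffab(areas, md, moderate = config$moderate,
                       zero_policy = config$zero_policy, classes = classes)
  write_tsv_canonical(uni$table, file.path(out_dir, "results_univariate.tsv"))
  adj <- NULL
  if (length(config$covariates)) {
    adj <- glycan_diffab(areas, md, covariates = config$covariates,
                         moderate = FALSE, zero_policy = config$zero_policy,
                         classes = classes)
    write_tsv_canonical(adj$table, file.path(out_dir, "results_adjusted.tsv"))
  }
  rel <- relative_abundance(areas)
  comp_map <- stats::setNames(lib$composition, lib$glycan_id)
  cdiff <- composition_differential(rel, comp_map, md$group)
  write_tsv_canonical(cdiff, file.path(out_dir, "composition_differential.tsv"))
  cdist <- class_distribution(rel, classes)
  write_tsv_canonical(data.frame(class = names(cdist),
                                 percent = unname(cdist),
                                 stringsAsFactors = FALSE),
                      file.path(out_dir, "class_distribution.tsv"))
  g <- build_composition_graph(lib$composition)
  write_composition_graph(g, file.path(out_dir, "graph_nodes.tsv"), "nodes")
  write_composition_graph(g, file.path(out_dir, "graph_edges.tsv"), "edges")
  gs <- graph_summary(g)
  write_tsv_canonical(data.frame(metric = c("nodes", "edges", "components"),
                                 value = c(gs$n_nodes, gs$n_edges,
                                           gs$n_components)),
                      file.path(out_dir, "graph_summary.tsv"))
  .write_provenance(config, out_dir)
  invisible(list(univariate = uni, adjusted = adj))
}

#' Glycogene pathway-contribution run
#'
#' Filters a DE glycogene table and writes the per-stratum pathway
#' percentage contributions plus the long-format radial heat-map table.
#' An unmapped-gene fraction above 50% is an error unless
#' `allow_unmapped = TRUE`.
#'
#' @param de_file DE gene table CSV.
#' @param reference_file Optional glycogene reference CSV (default: the
#'   shipped synthetic reference).
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param allow_unmapped Tolerate >50% unmapped genes (default `FALSE`).
#' @return Invisibly, the contributions data.frame.
#' @export
run_glycogenes <- function(de_file, reference_file = NULL, out_dir,
                           config = run_config(), allow_unmapped = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  de <- utils::read.csv(de_file, stringsAsFactors = FALSE)
  .check_de_table(de)
  ref <- glycogene_reference(reference_file)
  filt <- filter_significant(de, lfc_threshold = config$lfc_threshold,
                             fdr_threshold = config$q_threshold)
  unmapped_frac <- if (nrow(filt)) {
    mean(!unique(filt$gene) %in% ref$gene)
  } else 0
  if (unmapped_frac > 0.5 && !allow_unmapped) {
    stop("more than 50% of filtered genes are absent from the reference (",
         round(100 * unmapped_frac), "%); pass allow_unmapped = TRUE to override")
  }
  contrib <- pathway_contribution(filt, ref, weighting = config$weighting)
  write_tsv_canonical(contrib, file.path(out_dir, "pathway_contributions.tsv"))
  if (nrow(filt) && any(filt$gene %in% ref$gene)) {
    write_tsv_canonical(radial_heatmap_table(filt, ref),
                        file.path(out_dir, "radial_heatmap.tsv"))
  }
  .write_provenance(config, out_dir)
  invisible(contrib)
}
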
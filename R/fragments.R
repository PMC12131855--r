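#' MS/MS spectra
#'
#' A `glycan_spectrum` holds a precursor m/z and charge and a peak list
#' sorted by m/z with non-negative intensities.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (positive integer; the ions are
#'   deprotonated, the sign is implicit).
#' @param title Optional scan title.
#' @return An object of class `glycan_spectrum`.
#' @export
glycan_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                            precursor_charge = NA_integer_, title = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 title = title),
            class = "glycan_spectrum")
}

#' @export
print.glycan_spectrum <- function(x, ...) {
  cat("<spectrum", if (!is.null(x$title)) paste0(" ", x$title), "> ",
      length(x$mz), " peaks, precursor m/z ",
      formatC(x$precursor_mz, digits = 4, format = "f"),
      " (", x$precursor_charge, "-)\n", sep = "")
  invisible(x)
}

#' Read and write Mascot Generic Format peak lists
#'
#' Minimal MGF support: `BEGIN IONS`/`END IONS` blocks with `TITLE`,
#' `PEPMASS`, `CHARGE` headers and two-column peak lines.
#'
#' @param path File path.
#' @return `read_mgf()` returns a list of [glycan_spectrum] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF file: unbalanced BEGIN/END IONS in ", path)
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    meta <- block[hdr]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), meta, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    title <- get("TITLE")
    pepmass <- suppressWarnings(as.numeric(strsplit(get("PEPMASS"), " ")[[1]][1]))
    charge <- get("CHARGE")
    z <- if (is.na(charge)) NA_integer_ else
      as.integer(gsub("[^0-9]", "", charge))
    peaks <- block[!hdr & nzchar(trimws(block))]
    pm <- do.call(rbind, lapply(strsplit(trimws(peaks), "[ \t]+"), function(p) {
      v <- suppressWarnings(as.numeric(p[1:2]))
      if (anyNA(v)) stop("malformed MGF peak line: \"", paste(p, collapse = " "), "\"")
      v
    }))
    if (is.null(pm)) pm <- matrix(numeric(0), 0, 2)
    glycan_spectrum(pm[, 1], pm[, 2], precursor_mz = pepmass,
                    precursor_charge = z,
                    title = if (is.na(title)) NULL else title)
  })
}

#' @rdname read_mgf
#' @param spectra A list of [glycan_spectrum] objects (or one spectrum).
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "glycan_spectrum")) spectra <- list(spectra)
  out <- unlist(lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    c("BEGIN IONS",
      paste0("TITLE=", if (is.null(sp$title)) paste0("spectrum_", i) else sp$title),
      paste0("PEPMASS=", formatC(sp$precursor_mz, digits = 6, format = "f")),
      paste0("CHARGE=", sp$precursor_charge, "-"),
      sprintf("%.6f %.4f", sp$mz, sp$intensity),
      "END IONS", "")
  }))
  writeLines(out, path)
  invisible(path)
}

# residue multiset of a node set as a composition string
.residues_string <- function(nodes, ids) {
  cls <- .RESIDUE_CLASS[nodes$residue[nodes$node %in% ids]]
  counts <- table(factor(cls, levels = c("hex", "hexnac", "fuc", "neuac")))
  format_composition(glycan_composition(counts[["hex"]], counts[["hexnac"]],
                                        counts[["fuc"]], counts[["neuac"]]))
}

.residue_mass_sum <- function(nodes, ids) {
  sum(.MASS$residues[.RESIDUE_CLASS[nodes$residue[nodes$node %in% ids]]])
}

.ion_row <- function(kind, neutral, charge, residues, edge = NA_integer_) {
  data.frame(kind = kind, neutral = neutral, charge = charge,
             mz = .mz_from_neutral(neutral, charge),
             residues = residues, edge = edge, stringsAsFactors = FALSE)
}

#' Theoretical glycosidic fragments (B/C/Y/Z)
#'
#' For every single glycosidic cleavage of the tree: the non-reducing
#' fragment has neutral mass B = sum of its residue masses and C = B +
#' water; the reducing fragment has Y = sum of retained residues + water
#' (+ the alditol delta when the reducing end is reduced) and Z = Y -
#' water. Each fragment is emitted at charges `1..max_charge` as a
#' deprotonated ion.
#'
#' @param s A [glycan_structure].
#' @param max_charge Highest charge state to emit (default 2).
#' @return A data.frame of ions: `kind`, `neutral`, `charge`, `mz`,
#'   `residues` (composition string of the fragment), `edge` (child node id
#'   of the cleaved bond).
#' @export
enumerate_glycosidic_fragments <- function(s, max_charge = 2L) {
  stopifnot(inherits(s, "glycan_structure"), max_charge >= 1L)
  nodes <- s$nodes
  all_ids <- nodes$node
  red <- if (s$reduced) .MASS$reduction else 0
  rows <- list()
  for (child in nodes$node[nodes$parent != 0L]) {
    sub <- .subtree_nodes(nodes, child)
    b_res <- .residue_mass_sum(nodes, sub)
    y_ids <- setdiff(all_ids, sub)
    y_res <- .residue_mass_sum(nodes, y_ids)
    b_str <- .residues_string(nodes, sub)
    y_str <- .residues_string(nodes, y_ids)
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <- rbind(
        .ion_row("B", b_res, z, b_str, child),
        .ion_row("C", b_res + .MASS$water, z, b_str, child),
        .ion_row("Y", y_res + .MASS$water + red, z, y_str, child),
        .ion_row("Z", y_res + red, z, y_str, child))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnostic-ion rule set
#'
#' Configurable rules for the topology-diagnostic ions of negative-mode
#' CID: the D ion (double-cleavage B-type fragment retaining the 6-arm
#' subtree, the beta-mannose, and - when present - the bisecting GlcNAc),
#' its satellites D-18 (water loss) and D-221 (loss of the bisecting
#' HexNAc + water, emitted only for bisected structures), the E ion
#' (default: the 3-arm counterpart of D, emitted for >= 3 antennae), and a
#' single 0,2A cross-ring rule on the reducing-end HexNAc.
#'
#' @param e_selector Subtree kept by the E ion, `"3-arm"` (default) or
#'   `"6-arm"`.
#' @param e_offset Mass offset in Da added to the E-ion neutral (default 0).
#' @param d_retains_extended_6arm Keep mannose extensions of the 6-arm in
#'   the D fragment (default `TRUE`).
#' @param a02_offset Offset added to the non-reducing residue sum for the
#'   0,2A cross-ring fragment at the reducing-end HexNAc (default C2H4O2 =
#'   60.02113 Da).
#' @param enable_a02 Emit the 0,2A ion (default `FALSE`).
#' @return A list of rule settings for [diagnostic_ions()].
#' @export
diagnostic_rules <- function(e_selector = c("3-arm", "6-arm"),
                             e_offset = 0,
                             d_retains_extended_6arm = TRUE,
                             a02_offset = 60.021130,
                             enable_a02 = FALSE) {
  list(e_selector = match.arg(e_selector), e_offset = e_offset,
       d_retains_extended_6arm = d_retains_extended_6arm,
       a02_offset = a02_offset, enable_a02 = enable_a02)
}

#' Diagnostic ions for arm topology, bisecting GlcNAc, and branching
#'
#' @param s A [glycan_structure] carrying the canonical chitobiose +
#'   beta-mannose core (error otherwise).
#' @param rules A [diagnostic_rules()] list.
#' @param max_charge Highest charge state (default 1; D-family ions are
#'   typically singly charged).
#' @return A data.frame like [enumerate_glycosidic_fragments()].
#' @examples
#' s <- parse_structure(paste0("GlcNAc(GlcNAc(Man",
#'   "(Man[6](GlcNAc(Gal)))(Man[3](GlcNAc(Gal))))"))
#' diagnostic_ions(s)
#' @export
diagnostic_ions <- function(s, rules = diagnostic_rules(), max_charge = 1L) {
  stopifnot(inherits(s, "glycan_structure"))
  nodes <- s$nodes
  core <- .find_core(nodes)
  if (is.na(core$bman)) {
    stop("structure lacks the canonical chitobiose + beta-mannose core; ",
         "diagnostic D ions are undefined")
  }
  d_ids <- core$bman
  if (!is.na(core$arm6)) {
    arm6_sub <- .subtree_nodes(nodes, core$arm6)
    if (!rules$d_retains_extended_6arm) {
      # drop pure-mannose extensions beyond the 6-arm core mannose
      keep <- core$arm6
      kids <- nodes$node[nodes$parent == core$arm6 &
                           .RESIDUE_CLASS[nodes$residue] != "hex"]
      for (k in kids) keep <- c(keep, .subtree_nodes(nodes, k))
      arm6_sub <- intersect(arm6_sub, keep)
    }
    d_ids <- c(d_ids, arm6_sub)
  }
  if (!is.na(core$bis)) d_ids <- c(d_ids, .subtree_nodes(nodes, core$bis))
  d_neutral <- .residue_mass_sum(nodes, d_ids)
  d_str <- .residues_string(nodes, d_ids)
  rows <- list()
  for (z in seq_len(max_charge)) {
    rows[[length(rows) + 1L]] <- .ion_row("D", d_neutral, z, d_str)
    rows[[length(rows) + 1L]] <- .ion_row("D-18", d_neutral - .MASS$water, z, d_str)
    if (!is.na(core$bis)) {
      rows[[length(rows) + 1L]] <-
        .ion_row("D-221", d_neutral - (.MASS$residues[["hexnac"]] + .MASS$water),
                 z, d_str)
    }
  }
  cl <- classify_structure(s)
  if (cl$n_antennae >= 3L) {
    arm_id <- if (rules$e_selector == "3-arm") core$arm3 else core$arm6
    if (!is.na(arm_id)) {
      e_ids <- c(core$bman, .subtree_nodes(nodes, arm_id))
      e_neutral <- .residue_mass_sum(nodes, e_ids) + rules$e_offset
      for (z in seq_len(max_charge)) {
        rows[[length(rows) + 1L]] <-
          .ion_row("E", e_neutral, z, .residues_string(nodes, e_ids))
      }
    }
  }
  if (isTRUE(rules$enable_a02)) {
    non_root <- setdiff(nodes$node, core$root)
    a_neutral <- .residue_mass_sum(nodes, non_root) + rules$a02_offset
    rows[[length(rows) + 1L]] <-
      .ion_row("0,2A-core", a_neutral, 1L, .residues_string(nodes, non_root))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.ION_PRIORITY <- c("B", "C", "Y", "Z", "D", "D-18", "D-221", "E", "0,2A-core")

#' Match spectrum peaks to theoretical ions
#'
#' Greedy nearest matching: each peak is annotated by at most one ion, the
#' one with the smallest absolute ppm error within `tol_ppm`; ties are
#' broken by ion-kind priority (B, C, Y, Z, D, D-18, D-221, E, 0,2A-core).
#' Matching is deterministic for fixed inputs.
#'
#' @param spec A [glycan_spectrum].
#' @param theoretical Ion table from [enumerate_glycosidic_fragments()]
#'   and/or [diagnostic_ions()].
#' @param tol_ppm Match tolerance in ppm (default 20; must be > 0).
#' @return A data.frame of annotations: `peak`, `mz`, `intensity`, `kind`,
#'   `ion_mz`, `charge`, `ppm_error`, `residues`.
#' @export
match_peaks <- function(spec, theoretical, tol_ppm = 20) {
  stopifnot(inherits(spec, "glycan_spectrum"), tol_ppm > 0)
  empty <- data.frame(peak = integer(0), mz = numeric(0),
                      intensity = numeric(0), kind = character(0),
                      ion_mz = numeric(0), charge = integer(0),
                      ppm_error = numeric(0), residues = character(0),
                      stringsAsFactors = FALSE)
  if (length(spec$mz) == 0L || is.null(theoretical) || nrow(theoretical) == 0L) {
    return(empty)
  }
  prio <- match(theoretical$kind, .ION_PRIORITY)
  prio[is.na(prio)] <- length(.ION_PRIORITY) + 1L
  rows <- lapply(seq_along(spec$mz), function(i) {
    ppm <- (spec$mz[i] - theoretical$mz) / theoretical$mz * 1e6
    ok <- which(abs(ppm) <= tol_ppm)
    if (!length(ok)) return(NULL)
    ord <- ok[order(abs(ppm[ok]), prio[ok], theoretical$mz[ok])]
    j <- ord[1]
    data.frame(peak = i, mz = spec$mz[i], intensity = spec$intensity[i],
               kind = theoretical$kind[j], ion_mz = theoretical$mz[j],
               charge = theoretical$charge[j], ppm_error = ppm[j],
               residues = theoretical$residues[j], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Topology evidence from matched diagnostic ions
#'
#' Reads out the structural evidence the diagnostic ions encode: a matched
#' D or D-18 ion fixes the content of the 6-arm (and, by complement, the
#' 3-arm); a matched D-221 evidences a bisecting GlcNAc; a matched E ion
#' evidences tri-antennary branching. Every set flag cites the supporting
#' peak indices.
#'
#' @param annotations Output of [match_peaks()].
#' @return A list of flags `six_arm_confirmed`, `three_arm_confirmed`,
#'   `bisecting_present`, `tri_antennary_present`, each a list with
#'   `flag` (logical) and `peaks` (supporting peak indices).
#' @export
infer_topology <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  pick <- function(kinds) {
    idx <- annotations$peak[annotations$kind %in% kinds]
    list(flag = length(idx) > 0L, peaks = idx)
  }
  d_family <- pick(c("D", "D-18"))
  list(six_arm_confirmed = d_family,
       three_arm_confirmed = d_family,
       bisecting_present = pick("D-221"),
       tri_antennary_present = pick("E"))
}
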
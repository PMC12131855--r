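#' Glycan compositions
#'
#' An N-glycan composition is a count vector over four monosaccharide
#' classes: hexose (H), N-acetylhexosamine (N), deoxyhexose/fucose (F), and
#' N-acetylneuraminic acid (S). Compositions are written as strings like
#' `"H5N4F1S2"`; zero counts are omitted on output and letters may appear in
#' any order on input. `"A"` is accepted as an input alias for NeuAc
#' (`"S"` is canonical).
#'
#' @param hex,hexnac,fuc,neuac Non-negative integer counts.
#' @return An object of class `glycan_composition`: a named integer vector
#'   with elements `hex`, `hexnac`, `fuc`, `neuac`.
#' @examples
#' glycan_composition(hex = 5, hexnac = 4, fuc = 1, neuac = 2)
#' parse_composition("H5N4F1S2")
#' format_composition(parse_composition("N2H3"))  # canonical order
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, fuc = 0L, neuac = 0L) {
  counts <- c(hex = hex, hexnac = hexnac, fuc = fuc, neuac = neuac)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("composition counts must be non-negative integers")
  }
  structure(as.integer(counts),
            names = c("hex", "hexnac", "fuc", "neuac"),
            class = "glycan_composition")
}

.COMP_LETTER <- c(H = "hex", N = "hexnac", F = "fuc", S = "neuac", A = "neuac")

#' @rdname glycan_composition
#' @param text A composition string, e.g. `"H5N4F1S2"`.
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single composition string")
  }
  s <- gsub("[[:space:]]", "", text)
  counts <- c(hex = 0L, hexnac = 0L, fuc = 0L, neuac = 0L)
  if (!nzchar(s)) {
    return(do.call(glycan_composition, as.list(counts)))
  }
  m <- gregexpr("[A-Za-z][0-9]+", s)[[1]]
  tokens <- regmatches(s, gregexpr("[A-Za-z][0-9]+", s))[[1]]
  covered <- if (m[1] == -1) 0L else sum(attr(m, "match.length"))
  if (covered != nchar(s)) {
    # find the part not matched by letter+digits tokens
    bad <- s
    if (m[1] != -1) {
      keep <- rep(TRUE, nchar(s))
      for (i in seq_along(m)) {
        keep[seq(m[i], length.out = attr(m, "match.length")[i])] <- FALSE
      }
      bad <- paste(strsplit(s, "")[[1]][keep], collapse = "")
    }
    stop("malformed composition token(s) in \"", text, "\": \"", bad, "\"")
  }
  seen <- character(0)
  for (tok in tokens) {
    letter <- toupper(substr(tok, 1, 1))
    if (!letter %in% names(.COMP_LETTER)) {
      stop("unknown monosaccharide letter in token \"", tok,
           "\" (expected one of H, N, F, S/A)")
    }
    slot <- .COMP_LETTER[[letter]]
    if (slot %in% seen) {
      stop("repeated monosaccharide letter in token \"", tok, "\"")
    }
    seen <- c(seen, slot)
    counts[[slot]] <- as.integer(substr(tok, 2, nchar(tok)))
  }
  do.call(glycan_composition, as.list(counts))
}

#' @rdname glycan_composition
#' @param comp A `glycan_composition` (or string coercible to one).
#' @export
format_composition <- function(comp) {
  comp <- as_glycan_composition(comp)
  letters <- c(hex = "H", hexnac = "N", fuc = "F", neuac = "S")
  n <- unclass(comp)
  keep <- n > 0
  paste0(letters[keep], n[keep], collapse = "")
}

#' @rdname glycan_composition
#' @param x Object to coerce: a composition string or `glycan_composition`.
#' @export
as_glycan_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format_composition(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) format_composition(x)

# counts matrix (rows = compositions) from a character vector; internal
.composition_matrix <- function(texts) {
  out <- t(vapply(texts, function(s) unclass(parse_composition(s)),
                  integer(4)))
  colnames(out) <- c("hex", "hexnac", "fuc", "neuac")
  rownames(out) <- texts
  out
}

#' Coarse glycan class from composition
#'
#' HexNAc2 compositions without sialic acid are the unprocessed arm of the
#' biosynthetic pathway: 1-4 hexoses are paucimannose (truncated) and 5+ are
#' oligomannose (high-mannose) structures. Compositions with three or more
#' HexNAc have entered Golgi processing (`"processed"`: hybrid/complex).
#' Anything outside those rules (HexNAc < 2, sialylated HexNAc2, hexose
#' above `oligo_max_hex`) returns the `"unclassified"` sentinel rather than
#' a guess.
#'
#' @param comp Composition string(s) or a single `glycan_composition`.
#' @param pauci_max_hex Upper hexose bound for paucimannose (default 4,
#'   which keeps Man4 in the paucimannose class).
#' @param oligo_max_hex Upper hexose bound for oligomannose (default 12,
#'   admitting glucosylated precursors).
#' @return Character vector over
#'   `{"paucimannose","oligomannose","processed","unclassified"}`.
#' @examples
#' classify_composition(c("H4N2F1", "H10N2", "H5N4F1S2"))
#' @export
classify_composition <- function(comp, pauci_max_hex = 4L, oligo_max_hex = 12L) {
  if (inherits(comp, "glycan_composition")) comp <- format_composition(comp)
  vapply(comp, function(s) {
    x <- unclass(parse_composition(s))
    if (x[["hexnac"]] < 2L) return("unclassified")
    if (x[["hexnac"]] >= 3L) return("processed")
    # hexnac == 2
    if (x[["neuac"]] > 0L) return("unclassified")
    h <- x[["hex"]]
    if (h >= 1L && h <= pauci_max_hex) return("paucimannose")
    if (h > pauci_max_hex && h <= oligo_max_hex) return("oligomannose")
    "unclassified"
  }, character(1), USE.NAMES = !inherits(comp, "glycan_composition"))
}

#' Composition property category
#'
#' The property buckets used for summarizing inferred composition
#' distributions: HexNAc2 compositions form a single
#' oligomannose/paucimannose bucket; the rest split by presence of fucose
#' and sialic acid.
#'
#' @inheritParams classify_composition
#' @return Character vector over `{"neutral","fuco","sialylated",
#'   "fuco-sialylated","oligomannose/paucimannose"}`.
#' @examples
#' composition_property(c("H7N6F1S1", "H6N4F1", "H5N2"))
#' @export
composition_property <- function(comp) {
  if (inherits(comp, "glycan_composition")) comp <- format_composition(comp)
  vapply(comp, function(s) {
    x <- unclass(parse_composition(s))
    if (x[["hexnac"]] == 2L) return("oligomannose/paucimannose")
    if (x[["fuc"]] > 0L && x[["neuac"]] > 0L) return("fuco-sialylated")
    if (x[["fuc"]] > 0L) return("fuco")
    if (x[["neuac"]] > 0L) return("sialylated")
    "neutral"
  }, character(1), USE.NAMES = !inherits(comp, "glycan_composition"))
}

#' Class distribution from relative abundances
#'
#' Per-class percentage of the glycome: within each sample the relative
#' abundances of glycans sharing a class are summed (columns already sum to
#' 100), then averaged over samples.
#'
#' @param rel Relative-abundance matrix (glycans x samples, percent), as
#'   produced by [relative_abundance()].
#' @param classes Named character vector mapping every glycan id (rowname of
#'   `rel`) to a class label.
#' @return Named numeric vector of mean percentages per class (sums to 100).
#' @examples
#' rel <- relative_abundance(matrix(c(2, 2), 2, 1,
#'   dimnames = list(c("g1", "g2"), "s1")))
#' class_distribution(rel, c(g1 = "high-mannose", g2 = "paucimannose"))
#' @export
class_distribution <- function(rel, classes) {
  stopifnot(is.matrix(rel), !is.null(rownames(rel)))
  missing <- setdiff(rownames(rel), names(classes))
  if (length(missing)) {
    stop("no class mapping for glycan(s): ", paste(missing, collapse = ", "))
  }
  cls <- classes[rownames(rel)]
  per_sample <- rowsum(rel, group = cls)   # classes x samples
  out <- rowMeans(per_sample, na.rm = TRUE)
  sort(out, decreasing = TRUE)
}
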
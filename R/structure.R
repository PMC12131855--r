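#' Glycan structures as rooted residue trees
#'
#' A `glycan_structure` is a rooted tree of monosaccharide residues. The
#' root is the reducing-end HexNAc (an alditol for reduced glycans);
#' branches carry arm tags. Recognized residue codes are `Man`, `Gal`,
#' `Glc` (hexoses), `GlcNAc`, `GalNAc` (HexNAcs), `Fuc`, and `NeuAc`.
#' Recognized tags: `6` (6-arm core mannose), `3` (3-arm core mannose),
#' `bis` (bisecting GlcNAc on the beta-mannose), `cf` (core fucose on the
#' reducing-end GlcNAc), and `a1`-`a4` (antenna index, informational).
#'
#' The serialization grammar is nested parentheses: a node is a residue
#' code, an optional bracketed tag, then one parenthesized child per
#' branch, e.g. the reduced Man3 core is
#' `"GlcNAc(GlcNAc(Man(Man[6])(Man[3])))"`.
#'
#' @param nodes A data.frame with columns `node` (integer id), `parent`
#'   (integer id, 0 for the root), `residue` (code), `tag` (tag string,
#'   `""` for none).
#' @param id Optional structure identifier.
#' @param reduced Logical; reducing-end alditol (default `TRUE`).
#' @return An object of class `glycan_structure` with fields `id`, `nodes`,
#'   `reduced`, and `composition` (canonical composition string).
#' @examples
#' s <- parse_structure("GlcNAc(Fuc[cf])(GlcNAc(Man(Man[6])(Man[3])))")
#' s$composition
#' classify_structure(s)$fine
#' @export
glycan_structure <- function(nodes, id = NULL, reduced = TRUE) {
  stopifnot(is.data.frame(nodes),
            all(c("node", "parent", "residue", "tag") %in% names(nodes)))
  nodes$node <- as.integer(nodes$node)
  nodes$parent <- as.integer(nodes$parent)
  nodes$residue <- as.character(nodes$residue)
  nodes$tag <- as.character(nodes$tag)
  if (anyDuplicated(nodes$node)) stop("duplicate node ids")
  roots <- nodes$node[nodes$parent == 0L]
  if (length(roots) != 1L) stop("structure must have exactly one root")
  if (!all(nodes$parent %in% c(0L, nodes$node))) stop("parent id not in tree")
  unknown <- setdiff(nodes$residue, names(.RESIDUE_CLASS))
  if (length(unknown)) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  }
  if (.RESIDUE_CLASS[[nodes$residue[nodes$node == roots]]] != "hexnac") {
    stop("root must be the reducing-end HexNAc")
  }
  if (sum(nodes$tag == "bis") > 1L) stop("at most one bisecting node allowed")
  cf <- nodes[nodes$tag == "cf", , drop = FALSE]
  if (nrow(cf) > 1L) stop("at most one core-fucose node allowed")
  if (nrow(cf) == 1L &&
      (cf$residue != "Fuc" || cf$parent != roots)) {
    stop("core-fucose tag must mark a Fuc attached to the root")
  }
  # reachability check (no orphan cycles)
  reach <- roots
  repeat {
    nxt <- nodes$node[nodes$parent %in% reach & !nodes$node %in% reach]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (length(reach) != nrow(nodes)) stop("tree contains unreachable nodes")
  comp_counts <- table(factor(.RESIDUE_CLASS[nodes$residue],
                              levels = c("hex", "hexnac", "fuc", "neuac")))
  comp <- glycan_composition(hex = comp_counts[["hex"]],
                             hexnac = comp_counts[["hexnac"]],
                             fuc = comp_counts[["fuc"]],
                             neuac = comp_counts[["neuac"]])
  structure(list(id = id, nodes = nodes, reduced = isTRUE(reduced),
                 composition = format_composition(comp)),
            class = "glycan_structure")
}

.RESIDUE_CLASS <- c(Man = "hex", Gal = "hex", Glc = "hex",
                    GlcNAc = "hexnac", GalNAc = "hexnac",
                    Fuc = "fuc", NeuAc = "neuac")

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan structure", if (!is.null(x$id)) paste0(" ", x$id), "> ",
      x$composition, if (x$reduced) " (reduced)", "\n", sep = "")
  cat("  ", format_structure(x), "\n", sep = "")
  invisible(x)
}

#' @rdname glycan_structure
#' @param text Serialized structure string.
#' @export
parse_structure <- function(text, id = NULL, reduced = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  rows <- list()
  next_id <- 0L
  parse_node <- function(parent) {
    m <- regexpr("^[A-Za-z]+", substr(s, pos, n))
    if (m == -1L) stop("expected residue code at position ", pos, " in \"", s, "\"")
    name <- regmatches(substr(s, pos, n), m)
    pos <<- pos + nchar(name)
    tag <- ""
    if (peek() == "[") {
      close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
      if (close == -1L) stop("unclosed tag bracket at position ", pos)
      tag <- substr(s, pos + 1L, pos + close - 2L)
      pos <<- pos + close
    }
    next_id <<- next_id + 1L
    me <- next_id
    rows[[me]] <<- data.frame(node = me, parent = parent, residue = name,
                              tag = tag, stringsAsFactors = FALSE)
    while (peek() == "(") {
      pos <<- pos + 1L
      parse_node(me)
      if (peek() != ")") stop("expected ')' at position ", pos, " in \"", s, "\"")
      pos <<- pos + 1L
    }
    me
  }
  parse_node(0L)
  if (pos <= n) stop("trailing characters after structure: \"",
                     substr(s, pos, n), "\"")
  glycan_structure(do.call(rbind, rows), id = id, reduced = reduced)
}

#' @rdname glycan_structure
#' @param s A `glycan_structure`.
#' @export
format_structure <- function(s) {
  stopifnot(inherits(s, "glycan_structure"))
  nodes <- s$nodes
  fmt <- function(id) {
    row <- nodes[nodes$node == id, ]
    kids <- nodes$node[nodes$parent == id]
    paste0(row$residue,
           if (nzchar(row$tag)) paste0("[", row$tag, "]") else "",
           paste0(vapply(kids, function(k) paste0("(", fmt(k), ")"),
                         character(1)), collapse = ""))
  }
  fmt(nodes$node[nodes$parent == 0L])
}

# descendants of `id` including itself
.subtree_nodes <- function(nodes, id) {
  out <- id
  repeat {
    nxt <- nodes$node[nodes$parent %in% out & !nodes$node %in% out]
    if (!length(nxt)) break
    out <- c(out, nxt)
  }
  out
}

# locate the chitobiose + trimannosyl core; returns list of node ids
# (some possibly NA when the structure is trimmed below the full core)
.find_core <- function(nodes) {
  root <- nodes$node[nodes$parent == 0L]
  kids_of <- function(id) nodes[nodes$parent == id, , drop = FALSE]
  k <- kids_of(root)
  glcnac2 <- k$node[.RESIDUE_CLASS[k$residue] == "hexnac"]
  glcnac2 <- if (length(glcnac2)) glcnac2[1] else NA_integer_
  bman <- NA_integer_; arm6 <- NA_integer_; arm3 <- NA_integer_
  bis <- NA_integer_
  if (!is.na(glcnac2)) {
    k2 <- kids_of(glcnac2)
    bman_cand <- k2$node[.RESIDUE_CLASS[k2$residue] == "hex"]
    bman <- if (length(bman_cand)) bman_cand[1] else NA_integer_
  }
  if (!is.na(bman)) {
    k3 <- kids_of(bman)
    bis_cand <- k3$node[k3$tag == "bis"]
    bis <- if (length(bis_cand)) bis_cand[1] else NA_integer_
    hex_kids <- k3[.RESIDUE_CLASS[k3$residue] == "hex", , drop = FALSE]
    a6 <- hex_kids$node[hex_kids$tag == "6"]
    a3 <- hex_kids$node[hex_kids$tag == "3"]
    untagged <- hex_kids$node[!hex_kids$tag %in% c("6", "3")]
    if (!length(a6) && length(untagged)) { a6 <- untagged[1]; untagged <- untagged[-1] }
    if (!length(a3) && length(untagged)) a3 <- untagged[1]
    arm6 <- if (length(a6)) a6[1] else NA_integer_
    arm3 <- if (length(a3)) a3[1] else NA_integer_
  }
  list(root = root, glcnac2 = glcnac2, bman = bman,
       arm6 = arm6, arm3 = arm3, bis = bis)
}

#' Fine glycan class and motif flags from a structure
#'
#' Assigns exactly one fine class per structure. Antennae are the
#' HexNAc-initiated branches on the two core arm mannoses (the bisecting
#' GlcNAc is excluded). HexNAc2 structures without antennae are
#' paucimannose (<= `pauci_max_hex` hexoses) or high-mannose; a bisecting
#' GlcNAc pre-empts the antenna-count classes; a structure with one
#' mannose-extended arm and at least one antenna on the other is hybrid;
#' otherwise the class is complex-mono/bi/tri/tetra by antenna count.
#' Motif flags report core/terminal fucosylation, LacNAc (Gal-GlcNAc),
#' LacdiNAc (GalNAc-GlcNAc), and sialylation.
#'
#' @param s A [glycan_structure].
#' @param pauci_max_hex Paucimannose hexose bound (default 4).
#' @return A list with elements `coarse`, `fine`, `motifs` (character
#'   vector), and `n_antennae`.
#' @examples
#' classify_structure(parse_structure("GlcNAc(GlcNAc(Man(Man[6])(Man[3])))"))
#' @export
classify_structure <- function(s, pauci_max_hex = 4L) {
  stopifnot(inherits(s, "glycan_structure"))
  nodes <- s$nodes
  comp <- unclass(parse_composition(s$composition))
  core <- .find_core(nodes)
  antennae <- integer(0)
  arm_pure_extended <- c(`6` = FALSE, `3` = FALSE)
  arm_has_antenna <- c(`6` = FALSE, `3` = FALSE)
  for (arm in c("6", "3")) {
    arm_id <- if (arm == "6") core$arm6 else core$arm3
    if (is.na(arm_id)) next
    sub <- setdiff(.subtree_nodes(nodes, arm_id), arm_id)
    kids <- nodes[nodes$parent == arm_id, , drop = FALSE]
    ant <- kids$node[.RESIDUE_CLASS[kids$residue] == "hexnac" & kids$tag != "bis"]
    antennae <- c(antennae, ant)
    arm_has_antenna[[arm]] <- length(ant) > 0
    sub_res <- nodes$residue[nodes$node %in% sub]
    arm_pure_extended[[arm]] <-
      length(sub) >= 1L && all(.RESIDUE_CLASS[sub_res] == "hex")
  }
  n_ant <- length(antennae)
  has_bis <- !is.na(core$bis)
  fine <- NULL
  if (n_ant == 0L && !has_bis && comp[["hexnac"]] == 2L) {
    fine <- if (comp[["hex"]] <= pauci_max_hex) "paucimannose" else "high-mannose"
  } else if (has_bis) {
    fine <- "bisecting"
  } else if (n_ant >= 1L &&
             ((arm_pure_extended[["6"]] && arm_has_antenna[["3"]]) ||
              (arm_pure_extended[["3"]] && arm_has_antenna[["6"]]))) {
    fine <- "hybrid"
  } else if (n_ant >= 1L && n_ant <= 4L) {
    fine <- c("complex-mono", "complex-bi", "complex-tri", "complex-tetra")[n_ant]
  } else if (n_ant > 4L) {
    stop("antenna count ", n_ant, " outside the class vocabulary (max 4)")
  } else {
    stop("cannot classify structure ", s$composition,
         ": HexNAc residues outside core/antenna positions")
  }
  coarse <- switch(fine,
                   "paucimannose" = "paucimannose",
                   "high-mannose" = "oligomannose",
                   "processed")
  motifs <- character(0)
  root <- core$root
  fuc_nodes <- nodes[nodes$residue == "Fuc", , drop = FALSE]
  if (any(fuc_nodes$parent == root)) motifs <- c(motifs, "core-fucose")
  if (any(fuc_nodes$parent != root)) motifs <- c(motifs, "terminal-fucose")
  hexnac_parents <- nodes$node[nodes$residue == "GlcNAc"]
  if (any(nodes$residue == "Gal" & nodes$parent %in% hexnac_parents)) {
    motifs <- c(motifs, "LacNAc")
  }
  if (any(nodes$residue == "GalNAc" & nodes$parent %in% hexnac_parents)) {
    motifs <- c(motifs, "LacdiNAc")
  }
  if (any(nodes$residue == "NeuAc")) motifs <- c(motifs, "sialylated")
  list(coarse = coarse, fine = fine, motifs = motifs, n_antennae = n_ant)
}
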
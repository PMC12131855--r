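#' Composition relatedness graph
#'
#' Builds the graph of observed N-glycan compositions in which two nodes
#' are adjacent iff their compositions differ by exactly one monosaccharide
#' residue (Manhattan distance 1 over the H/N/F/S counts). Only observed
#' compositions become nodes; inferred intermediates are not added unless
#' `virtual_nodes = TRUE`, in which case missing single-step intermediates
#' between observed nodes are inserted (flagged `membership = "virtual"`).
#'
#' @param compositions Character vector of composition strings (duplicates
#'   are collapsed; multiplicity is recorded).
#' @param memberships Optional named character vector mapping compositions
#'   to a library membership label (e.g. `"A-only"`, `"B-only"`, `"both"`).
#' @param provenance Optional character vector of library names.
#' @param virtual_nodes Insert unobserved one-step intermediates (default
#'   `FALSE`).
#' @return An object of class `composition_graph`: list with `nodes`
#'   (data.frame: composition, hex..neuac, multiplicity, membership,
#'   property) and `edges` (data.frame: from, to).
#' @examples
#' g <- build_composition_graph(c("H7N6F1S1", "H7N6F1"))
#' g$edges
#' @export
build_composition_graph <- function(compositions, memberships = NULL,
                                    provenance = NULL, virtual_nodes = FALSE) {
  if (length(compositions) == 0L) {
    return(structure(list(
      nodes = data.frame(composition = character(0), hex = integer(0),
                         hexnac = integer(0), fuc = integer(0),
                         neuac = integer(0), multiplicity = integer(0),
                         membership = character(0), property = character(0)),
      edges = data.frame(from = character(0), to = character(0)),
      provenance = provenance), class = "composition_graph"))
  }
  canon <- vapply(compositions, function(s)
    format_composition(parse_composition(s)), character(1), USE.NAMES = FALSE)
  mult <- table(canon)
  uniq <- names(mult)
  M <- .composition_matrix(uniq)
  if (virtual_nodes) {
    repeat {
      D <- as.matrix(stats::dist(M, method = "manhattan"))
      added <- FALSE
      idx <- which(D == 2, arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      for (k in seq_len(nrow(idx))) {
        a <- M[idx[k, 1], ]; b <- M[idx[k, 2], ]
        d <- b - a
        # midpoint: half-step for a single letter changed by 2, or one of
        # the two letters for two single-residue steps
        step <- if (sum(d != 0) == 1) d %/% 2L else {
          s0 <- d; s0[which(s0 != 0)[2]] <- 0L; s0
        }
        mid <- a + step
        mid_s <- format_composition(do.call(glycan_composition,
                                            as.list(mid)))
        if (!mid_s %in% rownames(M)) {
          M <- rbind(M, mid)
          rownames(M)[nrow(M)] <- mid_s
          added <- TRUE
        }
      }
      if (!added) break
    }
    uniq <- rownames(M)
  }
  D <- as.matrix(stats::dist(M, method = "manhattan"))
  pairs <- which(D == 1, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  edges <- data.frame(from = uniq[pairs[, 1]], to = uniq[pairs[, 2]],
                      stringsAsFactors = FALSE)
  member <- rep("observed", length(uniq))
  names(member) <- uniq
  if (!is.null(memberships)) {
    canon_names <- vapply(names(memberships), function(s)
      format_composition(parse_composition(s)), character(1))
    member[canon_names] <- unname(memberships)
  }
  member[!uniq %in% names(mult)] <- "virtual"
  nodes <- data.frame(
    composition = uniq,
    hex = M[, "hex"], hexnac = M[, "hexnac"],
    fuc = M[, "fuc"], neuac = M[, "neuac"],
    multiplicity = as.integer(mult[uniq]),
    membership = unname(member[uniq]),
    property = unname(composition_property(uniq)),
    stringsAsFactors = FALSE, row.names = NULL)
  nodes$multiplicity[is.na(nodes$multiplicity)] <- 0L
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "composition_graph")
}

#' @export
print.composition_graph <- function(x, ...) {
  cat("<composition graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Summary counts for a composition graph
#'
#' @param g A [build_composition_graph()] result.
#' @return A list with `n_nodes`, `n_edges`, `n_components`,
#'   `nodes_by_membership`, and `nodes_by_property`.
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "composition_graph"))
  n_comp <- if (nrow(g$nodes) == 0L) 0L else {
    ig <- igraph::graph_from_data_frame(
      g$edges, directed = FALSE,
      vertices = g$nodes[, "composition", drop = FALSE])
    igraph::count_components(ig)
  }
  list(n_nodes = nrow(g$nodes),
       n_edges = nrow(g$edges),
       n_components = n_comp,
       nodes_by_membership = if (nrow(g$nodes)) table(g$nodes$membership) else table(character(0)),
       nodes_by_property = if (nrow(g$nodes)) table(g$nodes$property) else table(character(0)))
}

#' Compare two glycan libraries
#'
#' Exact set partition of two libraries into shared, A-only, and B-only
#' entries. At `level = "structure"` identity is the (composition,
#' structure serialization) pair; at `level = "composition"` identity is
#' the canonical composition string (deduplicated within each library).
#'
#' @param libA,libB Library data.frames with at least a `composition`
#'   column (and `structure` for structure-level comparison) as read by
#'   [read_glycan_library()].
#' @param level `"structure"` or `"composition"`.
#' @return A list with character vectors `shared`, `A_only`, `B_only` and
#'   the `level` used.
#' @export
compare_libraries <- function(libA, libB,
                              level = c("structure", "composition")) {
  level <- match.arg(level)
  key <- function(lib, name) {
    stopifnot(is.data.frame(lib), "composition" %in% names(lib))
    comp <- vapply(lib$composition, function(s)
      format_composition(parse_composition(s)), character(1), USE.NAMES = FALSE)
    if (level == "structure") {
      if (!"structure" %in% names(lib)) {
        stop("library ", name, " lacks a 'structure' column for structure-level comparison")
      }
      k <- paste(comp, lib$structure, sep = "|")
      if (anyDuplicated(k)) {
        stop("duplicate structure ids in library ", name, ": ",
             paste(unique(k[duplicated(k)]), collapse = ", "))
      }
      k
    } else {
      unique(comp)
    }
  }
  a <- key(libA, "A"); b <- key(libB, "B")
  list(shared = sort(intersect(a, b)),
       A_only = sort(setdiff(a, b)),
       B_only = sort(setdiff(b, a)),
       level = level)
}

#' Export a composition graph
#'
#' Writes GraphML (via igraph) or tab-separated edge-list / node-attribute
#' files.
#'
#' @param g A composition graph.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"edges"`, `"nodes"`.
#' @return `path`, invisibly.
#' @export
write_composition_graph <- function(g, path,
                                    format = c("graphml", "edges", "nodes")) {
  stopifnot(inherits(g, "composition_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes)
    igraph::write_graph(ig, path, format = "graphml")
  } else if (format == "edges") {
    write_tsv_canonical(g$edges, path)
  } else {
    write_tsv_canonical(g$nodes, path)
  }
  invisible(path)
}
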
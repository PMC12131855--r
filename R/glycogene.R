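#' Glycogene pathway reference
#'
#' Loads a gene -> glycosylation-pathway reference table (columns `gene`,
#' `pathway`; one pathway per gene). By default the synthetic reference
#' shipped with the package is used: a curated stand-in covering 19
#' glycosylation-related pathway categories with ~230 well-known glycogene
#' symbols, intended for testing and demonstration. For real analyses,
#' pass the path to a full reference export (e.g. a GlycoMaple download
#' reformatted to the two-column schema).
#'
#' @param path Optional CSV path; default uses the shipped synthetic
#'   reference.
#' @return data.frame with columns `gene`, `pathway`; attributes `source`
#'   and `n_genes`.
#' @export
glycogene_reference <- function(path = NULL) {
  src <- if (is.null(path)) {
    system.file("extdata", "glycogene_reference_synthetic.csv",
                package = "glycardio", mustWork = TRUE)
  } else path
  ref <- utils::read.csv(src, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(ref))) {
    stop("glycogene reference must have columns 'gene' and 'pathway'")
  }
  if (anyDuplicated(ref$gene)) {
    stop("each gene must map to exactly one pathway; duplicates: ",
         paste(unique(ref$gene[duplicated(ref$gene)]), collapse = ", "))
  }
  attr(ref, "source") <- if (is.null(path)) "synthetic" else path
  attr(ref, "n_genes") <- nrow(ref)
  ref
}

.check_de_table <- function(table) {
  required <- c("gene", "cell_type", "region", "log2fc", "padj")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("DE gene table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.na(table$padj) & (table$padj < 0 | table$padj > 1))) {
    stop("adjusted p-values must lie in [0, 1]")
  }
  invisible(table)
}

#' Filter differentially expressed glycogenes
#'
#' Retains rows with `|log2FC|` strictly greater than `lfc_threshold` and
#' adjusted p strictly below `fdr_threshold` (defaults 1 and 0.05: log2FC
#' greater than +1 or less than -1 at FDR < 0.05). Idempotent.
#'
#' @param table DE gene table with columns `gene`, `cell_type`, `region`,
#'   `log2fc`, `padj`.
#' @param lfc_threshold Absolute log2FC threshold (default 1).
#' @param fdr_threshold Adjusted-p threshold (default 0.05).
#' @return The filtered table.
#' @export
filter_significant <- function(table, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(lfc_threshold > 0, fdr_threshold > 0)
  .check_de_table(table)
  keep <- !is.na(table$log2fc) & !is.na(table$padj) &
    abs(table$log2fc) > lfc_threshold & table$padj < fdr_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway percentage contributions
#'
#' For each (cell type, region) stratum, the percentage contribution of
#' each glycosylation pathway among the filtered differentially expressed
#' glycogenes: pathway weight / total weight x 100, where the weight is
#' either the gene count (default) or the summed |log2FC|. Genes absent
#' from the reference are reported and dropped with a warning.
#'
#' @param filtered Output of [filter_significant()].
#' @param ref Reference from [glycogene_reference()].
#' @param weighting `"gene-count"` (default) or `"abs-log2fc"`.
#' @return data.frame: `cell_type`, `region`, `pathway`, `weight`,
#'   `percent`; percentages sum to 100 within each non-empty stratum.
#' @export
pathway_contribution <- function(filtered, ref,
                                 weighting = c("gene-count", "abs-log2fc")) {
  weighting <- match.arg(weighting)
  .check_de_table(filtered)
  if (nrow(filtered) == 0L) {
    warning("empty filtered table; no contributions to compute")
    return(data.frame(cell_type = character(0), region = character(0),
                      pathway = character(0), weight = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  unmapped <- setdiff(unique(filtered$gene), ref$gene)
  if (length(unmapped)) {
    warning(length(unmapped), " gene(s) not in the glycogene reference, dropped: ",
            paste(utils::head(unmapped, 10), collapse = ", "),
            if (length(unmapped) > 10) ", ...")
    filtered <- filtered[!filtered$gene %in% unmapped, , drop = FALSE]
  }
  if (nrow(filtered) == 0L) {
    warning("no mapped genes left after dropping unmapped genes")
    return(data.frame(cell_type = character(0), region = character(0),
                      pathway = character(0), weight = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  filtered$pathway <- ref$pathway[match(filtered$gene, ref$gene)]
  filtered$weight <- if (weighting == "gene-count") 1 else abs(filtered$log2fc)
  agg <- stats::aggregate(weight ~ cell_type + region + pathway,
                          data = filtered, FUN = sum)
  tot <- stats::aggregate(weight ~ cell_type + region, data = agg, FUN = sum)
  names(tot)[3] <- "total"
  out <- merge(agg, tot, by = c("cell_type", "region"))
  out$percent <- 100 * out$weight / out$total
  out$total <- NULL
  out <- out[order(out$cell_type, out$region, -out$percent, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Long-format table for radial heat maps
#'
#' One row per filtered gene with its pathway and the pathway's percentage
#' contribution within the gene's (cell type, region) stratum; suitable
#' for radial heat-map plotting.
#'
#' @inheritParams pathway_contribution
#' @return data.frame: `cell_type`, `region`, `pathway`, `gene`, `log2fc`,
#'   `pathway_percent`.
#' @export
radial_heatmap_table <- function(filtered, ref) {
  .check_de_table(filtered)
  if (nrow(filtered) == 0L) stop("filtered table is empty")
  contrib <- pathway_contribution(filtered, ref, weighting = "gene-count")
  mapped <- filtered[filtered$gene %in% ref$gene, , drop = FALSE]
  mapped$pathway <- ref$pathway[match(mapped$gene, ref$gene)]
  out <- merge(mapped[, c("cell_type", "region", "pathway", "gene", "log2fc")],
               contrib[, c("cell_type", "region", "pathway", "percent")],
               by = c("cell_type", "region", "pathway"))
  names(out)[names(out) == "percent"] <- "pathway_percent"
  out <- out[order(out$cell_type, out$region, out$pathway, out$gene), ]
  rownames(out) <- NULL
  out
}
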
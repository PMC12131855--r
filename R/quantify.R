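#' Relative abundance from peak areas
#'
#' Converts a glycans x samples peak-area matrix to percent of total glycan
#' signal per sample: `area / column total * 100`. Missing areas are
#' ignored in the totals and propagated.
#'
#' @param areas Numeric matrix (glycans x samples) of non-negative peak
#'   areas; rownames are glycan ids, colnames sample ids.
#' @return Matrix of the same shape in percent; each sample column sums to
#'   100 over non-missing entries.
#' @examples
#' relative_abundance(matrix(c(2, 3, 5), 3, 1,
#'   dimnames = list(paste0("g", 1:3), "s1")))
#' @export
relative_abundance <- function(areas) {
  stopifnot(is.matrix(areas), is.numeric(areas))
  if (any(areas < 0, na.rm = TRUE)) stop("peak areas must be non-negative")
  totals <- colSums(areas, na.rm = TRUE)
  bad <- which(totals <= 0)
  if (length(bad)) {
    stop("sample(s) with zero total area: ",
         paste(colnames(areas)[bad] %||% bad, collapse = ", "))
  }
  sweep(areas, 2, totals, "/") * 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median normalization and log2 transform
#'
#' Per sample, relative abundances are scaled by the sample median and
#' log2-transformed, so each sample's median log value is exactly 0. (The
#' scaling divisor is the sample median for an odd number of glycans and
#' the geometric mean of the two central values for an even number, which
#' keeps the zero-median property exact.) Zeros are handled by a policy applied before the
#' log: `"halfmin"` (default) imputes half of the glycan's smallest
#' positive value across samples, `"drop"` sets zeros to `NA`, and
#' `"pseudocount"` adds `epsilon` to every value.
#'
#' @param rel Relative-abundance matrix from [relative_abundance()].
#' @param zero_policy `"halfmin"`, `"drop"`, or `"pseudocount"`.
#' @param epsilon Pseudocount for `zero_policy = "pseudocount"`.
#' @return Matrix of log2 values with per-sample median 0.
#' @examples
#' m <- matrix(c(1, 4, 16), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
#' median_normalize_log(m)
#' @export
median_normalize_log <- function(rel, zero_policy = c("halfmin", "drop", "pseudocount"),
                                 epsilon = 1e-3) {
  stopifnot(is.matrix(rel), is.numeric(rel))
  zero_policy <- match.arg(zero_policy)
  x <- rel
  if (zero_policy == "pseudocount") {
    x <- x + epsilon
  } else if (zero_policy == "drop") {
    x[x == 0] <- NA_real_
  } else {
    for (g in seq_len(nrow(x))) {
      zero <- !is.na(x[g, ]) & x[g, ] == 0
      if (any(zero)) {
        pos <- x[g, !is.na(x[g, ]) & x[g, ] > 0]
        if (!length(pos)) {
          x[g, zero] <- NA_real_
        } else {
          x[g, zero] <- min(pos) / 2
        }
      }
    }
  }
  n_ok <- colSums(!is.na(x))
  if (any(n_ok < 3)) {
    stop("sample(s) with fewer than 3 non-missing values: ",
         paste(colnames(x)[n_ok < 3] %||% which(n_ok < 3), collapse = ", "))
  }
  # normalize on the log scale: subtracting the per-sample median of the
  # log2 values equals dividing by the sample median for odd counts and
  # guarantees an exactly-zero median log value for even counts as well
  lx <- log2(x)
  med <- apply(lx, 2, stats::median, na.rm = TRUE)
  sweep(lx, 2, med, "-")
}

#' Percent coefficient of variation of control analytes
#'
#' Quality control for run stability: %CV (`100 * sd / mean`) of replicate
#' peak areas per control analyte (e.g. dextran DP3-DP10 internal
#' standards), with a flag for analytes exceeding the acceptance
#' threshold.
#'
#' @param control_areas Numeric matrix (analytes x replicates) or a vector
#'   of replicates for a single analyte. At least 2 replicates.
#' @param threshold %CV threshold for flagging (default 10).
#' @return data.frame with `analyte`, `mean`, `sd`, `cv` (percent),
#'   `flagged`.
#' @examples
#' qc_cv(rbind(DP3 = c(10, 10, 10), DP4 = c(9, 11)))
#' @export
qc_cv <- function(control_areas, threshold = 10) {
  if (is.vector(control_areas)) {
    control_areas <- matrix(control_areas, nrow = 1,
                            dimnames = list("control", NULL))
  }
  stopifnot(is.matrix(control_areas))
  if (ncol(control_areas) < 2L) stop("at least 2 replicates required")
  mu <- rowMeans(control_areas, na.rm = TRUE)
  if (any(mu == 0)) {
    stop("zero mean for analyte(s): ",
         paste(rownames(control_areas)[mu == 0], collapse = ", "))
  }
  sdv <- apply(control_areas, 1, stats::sd, na.rm = TRUE)
  cv <- 100 * sdv / mu
  data.frame(analyte = rownames(control_areas) %||% seq_along(mu),
             mean = mu, sd = sdv, cv = cv, flagged = cv >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
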
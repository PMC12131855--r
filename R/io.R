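#' Read and write glycan library tables
#'
#' The library CSV schema mirrors a curated glycan summary table: columns
#' `glycan_id`, `composition`, `fine_class`, `structure` (bracket
#' serialization, see [parse_structure()]), `theoretical_mz`, `charge`,
#' `rrt` (relative retention time), `glytoucan_id`. Compositions are
#' canonicalized on read.
#'
#' @param path CSV file path.
#' @return A data.frame with the schema above.
#' @export
read_glycan_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("glycan_id", "composition", "fine_class", "structure",
                "theoretical_mz", "charge")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    stop("glycan library ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(lib$glycan_id)) {
    stop("duplicate glycan_id values in ", path)
  }
  lib$composition <- vapply(lib$composition, function(s)
    format_composition(parse_composition(s)), character(1), USE.NAMES = FALSE)
  lib
}

#' @rdname read_glycan_library
#' @param lib Library data.frame.
#' @export
write_glycan_library <- function(lib, path) {
  utils::write.csv(lib, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak-area matrix
#'
#' Wide CSV with a `glycan_id` first column and one column per sample, or
#' long CSV with columns `glycan_id`, `sample_id`, `area`.
#'
#' @param path CSV path.
#' @return Numeric matrix glycans x samples.
#' @export
read_peak_areas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("glycan_id", "sample_id", "area") %in% names(df))) {
    wide <- stats::reshape(df[, c("glycan_id", "sample_id", "area")],
                           idvar = "glycan_id", timevar = "sample_id",
                           direction = "wide")
    names(wide) <- sub("^area\\.", "", names(wide))
    df <- wide
  }
  if (names(df)[1] != "glycan_id") {
    stop("peak-area file ", path,
         " must have 'glycan_id' as its first column (wide) or ",
         "glycan_id/sample_id/area columns (long)")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$glycan_id
  m
}

#' @rdname read_peak_areas
#' @param areas Matrix glycans x samples.
#' @export
write_peak_areas <- function(areas, path) {
  df <- data.frame(glycan_id = rownames(areas), areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Required columns: `sample_id` (unique) and `group` (values `negative` /
#' `positive`). Optional: `age` (years), `sex` (`M`/`F`), `region`, and any
#' number of binary comorbidity flag columns.
#'
#' @param path CSV path.
#' @return A data.frame, `group` as a factor with levels negative,
#'   positive.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "group"), names(md))
  if (length(missing)) {
    stop("metadata ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id values in ", path)
  if (any(is.na(md$group))) stop("metadata has missing group values")
  bad <- setdiff(unique(md$group), c("negative", "positive"))
  if (length(bad)) {
    stop("group values must be 'negative'/'positive'; found: ",
         paste(bad, collapse = ", "))
  }
  md$group <- factor(md$group, levels = c("negative", "positive"))
  md
}

#' Canonical TSV writer
#'
#' Tab-separated, UTF-8, header row, `"."` for missing values, no quoting,
#' Unix line endings; used for all pipeline outputs so that reruns are
#' byte-identical and diff-able.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv_canonical <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 6, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
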
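#' Design matrix from sample metadata
#'
#' Builds the samples x predictors matrix for differential abundance: an
#' intercept, the group indicator (positive vs negative), and any
#' requested covariate columns (numeric covariates enter as-is; factors
#' and characters are dummy-coded; logical comorbidity flags become 0/1
#' indicators). Errors on rank deficiency, naming the collinear columns.
#'
#' @param metadata Data.frame with `sample_id`, `group` (factor
#'   negative/positive) and covariate columns.
#' @param covariates Character vector of metadata column names to adjust
#'   for (default none: univariate design).
#' @return Numeric design matrix with rownames = sample ids; the group
#'   contrast column is named `"grouppositive"`.
#' @export
design_from_metadata <- function(metadata, covariates = NULL) {
  stopifnot(is.data.frame(metadata), all(c("sample_id", "group") %in% names(metadata)))
  md <- metadata
  md$group <- factor(md$group, levels = c("negative", "positive"))
  missing <- setdiff(covariates, names(md))
  if (length(missing)) {
    stop("covariate column(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  form <- stats::as.formula(paste(
    "~ group", if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else ""))
  X <- stats::model.matrix(form, data = md)
  rownames(X) <- md$sample_id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  X
}

#' Per-glycan ordinary least squares
#'
#' Fits the same linear model to every glycan (row of `Y`) by QR
#' decomposition of the shared design, and extracts the group contrast:
#' coefficient (log2 fold change positive vs negative), unscaled standard
#' deviation, residual variance s^2 and residual degrees of freedom. In
#' the two-group design without covariates the coefficient is exactly the
#' difference of group means.
#'
#' @param Y Numeric matrix glycans x samples of log2 values (no missing
#'   values; impute or drop upstream).
#' @param design Design matrix from [design_from_metadata()].
#' @param coef Name of the contrast column (default `"grouppositive"`).
#' @return Object of class `glycan_lmfit`: list with `coefficients`, `se`,
#'   `sigma2`, `df_residual`, `stdev_unscaled`, `residuals`, `fitted`,
#'   `coef_name`, `design`.
#' @export
fit_glycan_lm <- function(Y, design, coef = "grouppositive") {
  stopifnot(is.matrix(Y), is.matrix(design), ncol(Y) == nrow(design))
  if (anyNA(Y)) {
    stop("Y contains missing values; apply a zero/missing policy first")
  }
  if (!coef %in% colnames(design)) {
    stop("contrast column '", coef, "' not found in design")
  }
  n <- nrow(design); p <- ncol(design)
  if (n <= p) stop("need more samples (", n, ") than predictors (", p, ")")
  qrX <- qr(design)
  if (qrX$rank < p) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  tY <- t(Y)
  beta <- qr.coef(qrX, tY)            # p x glycans
  res <- qr.resid(qrX, tY)            # samples x glycans
  fitted <- tY - res
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(design), colnames(design))
  unscaled <- sqrt(XtXinv[coef, coef])
  structure(list(
    coefficients = stats::setNames(beta[coef, ], rownames(Y)),
    se = stats::setNames(sqrt(sigma2) * unscaled, rownames(Y)),
    sigma2 = stats::setNames(sigma2, rownames(Y)),
    df_residual = df,
    stdev_unscaled = unscaled,
    residuals = t(res),
    fitted = t(fitted),
    coef_name = coef,
    design = design), class = "glycan_lmfit")
}

# Newton inversion of the trigamma function
.trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks the per-glycan residual variances toward a common prior by
#' matching the first two moments of log s^2 to a scaled F distribution
#' (digamma/trigamma inversion), yielding prior degrees of freedom d0 and
#' prior variance s0^2. Posterior variances are the precision-weighted
#' average `(d0 s0^2 + d s^2) / (d0 + d)`; moderated t statistics use the
#' posterior variance and d0 + d degrees of freedom. An infinite d0
#' (observed variances consistent with a single value) sets every
#' posterior variance to s0^2; `df_prior = 0` can be forced to recover
#' ordinary t statistics.
#'
#' @param fit A [fit_glycan_lm()] result (needs >= 2 glycans with finite
#'   positive variances; >= 10 recommended for stable hyperparameters).
#' @param df_prior Optional forced prior df (`0` disables shrinkage,
#'   `Inf` shrinks completely).
#' @return Object of class `glycan_ebayes`: `df_prior`, `var_prior`,
#'   `var_post`, `t`, `df_total`, `p`, plus the fit's coefficients.
#' @export
moderate_ebayes <- function(fit, df_prior = NULL) {
  stopifnot(inherits(fit, "glycan_lmfit"))
  s2 <- fit$sigma2
  if (length(s2) < 2L) stop("need at least 2 glycans for moderation")
  if (any(!is.finite(s2))) stop("non-finite residual variances")
  d <- fit$df_residual
  if (is.null(df_prior)) {
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    d0 <- df_prior
    s02 <- if (is.finite(d0) && d0 == 0) NA_real_ else {
      z <- log(pmax(s2, 1e-300))
      exp(mean(z - digamma(d / 2) + log(d / 2)))
    }
  }
  var_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  names(var_post) <- names(s2)
  tmod <- fit$coefficients / (sqrt(var_post) * fit$stdev_unscaled)
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  structure(list(df_prior = d0, var_prior = s02, var_post = var_post,
                 t = tmod, df_total = df_total, p = p,
                 coefficients = fit$coefficients, se_post = sqrt(var_post) * fit$stdev_unscaled,
                 fit = fit), class = "glycan_ebayes")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_i = min over {j : p_j >= p_i} of m p_j /
#' rank_j`, capped at 1 and order-preserving; delegated to
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Volcano-ready differential table
#'
#' Deterministic per-glycan results sorted by p-value with significance
#' flags at both conventions: raw `p < p_threshold` (univariate reporting)
#' and BH `q < q_threshold` (covariate-adjusted reporting).
#'
#' @param moderated A [moderate_ebayes()] result (or `glycan_lmfit` for
#'   unmoderated ordinary t).
#' @param classes Optional named character vector glycan id -> class.
#' @param p_threshold,q_threshold Significance thresholds (default 0.05).
#' @return data.frame: `glycan_id`, `class`, `log2fc`, `t`, `p`, `q`,
#'   `sig_p`, `sig_q`, sorted by `p`.
#' @export
differential_table <- function(moderated, classes = NULL,
                               p_threshold = 0.05, q_threshold = 0.05) {
  if (inherits(moderated, "glycan_lmfit")) {
    moderated <- moderate_ebayes(moderated, df_prior = 0)
  }
  stopifnot(inherits(moderated, "glycan_ebayes"))
  ids <- names(moderated$coefficients)
  q <- adjust_bh(moderated$p)
  out <- data.frame(
    glycan_id = ids,
    class = if (is.null(classes)) NA_character_ else unname(classes[ids]),
    log2fc = unname(moderated$coefficients),
    t = unname(moderated$t),
    p = unname(moderated$p),
    q = unname(q),
    stringsAsFactors = FALSE)
  out$sig_p <- out$p < p_threshold
  out$sig_q <- out$q < q_threshold
  out <- out[order(out$p, out$glycan_id), ]
  rownames(out) <- NULL
  out
}

#' Composition-level differential abundance
#'
#' Aggregates structure-level relative abundances to compositions (summing
#' isomers within each sample), then compares group means on the log2
#' scale. The sign of the mean log2 ratio labels each composition
#' increased/decreased; compositions with `|log2FC| < tol` are labeled
#' unchanged. Zero group means are handled by half-minimum substitution
#' over the composition's per-sample sums.
#'
#' @param rel Relative-abundance matrix (structures x samples).
#' @param comp_map Named character vector structure id -> composition.
#' @param groups Factor/character of sample groups (negative/positive),
#'   aligned with columns of `rel`.
#' @param tol Unchanged band on |log2FC| (default 0.1).
#' @return data.frame: `composition`, `mean_negative`, `mean_positive`,
#'   `log2fc`, `direction`.
#' @export
composition_differential <- function(rel, comp_map, groups, tol = 0.1) {
  stopifnot(is.matrix(rel), length(groups) == ncol(rel))
  groups <- factor(groups, levels = c("negative", "positive"))
  missing <- setdiff(rownames(rel), names(comp_map))
  if (length(missing)) {
    stop("no composition mapping for structure(s): ",
         paste(missing, collapse = ", "))
  }
  comp <- vapply(unname(comp_map[rownames(rel)]), function(s)
    format_composition(parse_composition(s)), character(1), USE.NAMES = FALSE)
  by_comp <- rowsum(rel, group = comp)
  fix_zero <- function(v) {
    pos <- v[v > 0 & !is.na(v)]
    if (length(pos)) v[!is.na(v) & v == 0] <- min(pos) / 2
    v
  }
  by_comp <- t(apply(by_comp, 1, fix_zero))
  mu_neg <- rowMeans(by_comp[, groups == "negative", drop = FALSE], na.rm = TRUE)
  mu_pos <- rowMeans(by_comp[, groups == "positive", drop = FALSE], na.rm = TRUE)
  lfc <- log2(mu_pos / mu_neg)
  direction <- ifelse(abs(lfc) < tol, "unchanged",
                      ifelse(lfc > 0, "increased", "decreased"))
  out <- data.frame(composition = rownames(by_comp),
                    mean_negative = unname(mu_neg),
                    mean_positive = unname(mu_pos),
                    log2fc = unname(lfc),
                    direction = unname(direction),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Differential glycan abundance
#'
#' The package's central model fit. Peak areas are converted to relative
#' abundances (percent of total per sample), median-normalized and
#' log2-transformed, and each glycan is fit with the same linear model:
#' intercept + group indicator + optional covariates (age, sex,
#' comorbidity flags). The group coefficient is the log2 fold change
#' (positive vs negative). With `moderate = TRUE` (default, intended for
#' the univariate analysis) variances are shrunk by empirical Bayes and
#' moderated t statistics are reported; with `moderate = FALSE` plain OLS
#' t statistics are used (default choice for the covariate-adjusted
#' model). BH q-values are always reported alongside raw p-values.
#'
#' @param areas Numeric matrix glycans x samples; interpretation set by
#'   `input`.
#' @param metadata Sample metadata (see [read_sample_metadata()]); rows
#'   are matched to `colnames(areas)` by `sample_id`.
#' @param covariates Character vector of metadata columns to adjust for.
#' @param moderate Use empirical-Bayes moderated t (default `TRUE`).
#' @param zero_policy Passed to [median_normalize_log()].
#' @param input `"areas"` (raw peak areas, default), `"relative"`
#'   (already percent), or `"log2"` (already normalized log2 values).
#' @param classes Optional named vector glycan id -> class label carried
#'   into the results table.
#' @return Object of class `glycan_diffab` with the results `table`
#'   (see [differential_table()]), the `fit`, the moderation `eb`, the
#'   `design`, and the normalized log matrix `logY`. Methods: `print`,
#'   `summary`, `coef`, `plot` (volcano), `residuals`, `fitted`.
#' @examples
#' set.seed(1)
#' lib <- generate_library(20, seed = 1)
#' cohort <- generate_cohort(lib, effects = list(paucimannose = -1), seed = 2)
#' fit <- glycan_diffab(cohort$areas, cohort$metadata)
#' head(summary(fit))
#' @export
glycan_diffab <- function(areas, metadata, covariates = NULL, moderate = TRUE,
                          zero_policy = "halfmin",
                          input = c("areas", "relative", "log2"),
                          classes = NULL) {
  input <- match.arg(input)
  stopifnot(is.matrix(areas), is.data.frame(metadata))
  samp <- colnames(areas)
  extra <- setdiff(samp, metadata$sample_id)
  miss <- setdiff(metadata$sample_id, samp)
  if (length(extra) || length(miss)) {
    stop("sample mismatch between areas and metadata;",
         if (length(extra)) paste0(" missing from metadata: ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0(" missing from areas: ",
                                  paste(miss, collapse = ", ")))
  }
  metadata <- metadata[match(samp, metadata$sample_id), , drop = FALSE]
  logY <- switch(input,
    areas = median_normalize_log(relative_abundance(areas), zero_policy),
    relative = median_normalize_log(areas, zero_policy),
    log2 = areas)
  if (anyNA(logY)) {
    bad <- rownames(logY)[rowSums(is.na(logY)) > 0]
    warning("dropping ", length(bad), " glycan(s) with missing values: ",
            paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ...")
    logY <- logY[!rownames(logY) %in% bad, , drop = FALSE]
  }
  design <- design_from_metadata(metadata, covariates)
  fit <- fit_glycan_lm(logY, design)
  eb <- moderate_ebayes(fit, df_prior = if (moderate) NULL else 0)
  tab <- differential_table(eb, classes = classes)
  structure(list(table = tab, fit = fit, eb = eb, design = design,
                 logY = logY, moderate = moderate, covariates = covariates,
                 call = match.call()),
            class = "glycan_diffab")
}

#' @export
print.glycan_diffab <- function(x, ...) {
  cat("Differential glycan abundance (",
      if (x$moderate) "moderated t" else "ordinary t", ")\n", sep = "")
  cat("  ", nrow(x$table), " glycans, ", nrow(x$design), " samples, ",
      "design: ", paste(colnames(x$design), collapse = " + "), "\n", sep = "")
  if (is.finite(x$eb$df_prior)) {
    cat("  prior df ", formatC(x$eb$df_prior, digits = 3, format = "g"),
        ", prior variance ", formatC(x$eb$var_prior, digits = 3, format = "g"),
        "\n", sep = "")
  }
  cat("  significant: ", sum(x$table$sig_p), " at p<0.05, ",
      sum(x$table$sig_q), " at q<0.05\n", sep = "")
  invisible(x)
}

#' @export
summary.glycan_diffab <- function(object, ...) object$table

#' @export
coef.glycan_diffab <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$glycan_id)
}

#' @export
residuals.glycan_diffab <- function(object, ...) object$fit$residuals

#' @export
fitted.glycan_diffab <- function(object, ...) object$fit$fitted

#' Volcano plot of a differential-abundance fit
#'
#' @param x A [glycan_diffab()] object.
#' @param q_threshold Highlight glycans with `q` below this (default 0.05).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glycan_diffab <- function(x, q_threshold = 0.05, ...) {
  tab <- x$table
  col <- ifelse(tab$q < q_threshold,
                ifelse(tab$log2fc > 0, "firebrick", "steelblue"), "grey60")
  graphics::plot(tab$log2fc, -log10(tab$p), pch = 19, col = col,
                 xlab = "log2 fold change (positive vs negative)",
                 ylab = "-log10 p", ...)
  graphics::abline(h = -log10(0.05), lty = 2, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey40")
  invisible(x)
}
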
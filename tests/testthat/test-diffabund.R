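make_md <- function(n_neg = 6, n_pos = 6, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%02d", seq_len(n_neg + n_pos)),
             group = rep(c("negative", "positive"), c(n_neg, n_pos)),
             age = round(rnorm(n_neg + n_pos, 65, 8)),
             sex = sample(c("M", "F"), n_neg + n_pos, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("the group coefficient is the difference of group means", {
  md <- make_md()
  X <- design_from_metadata(md)
  Y <- matrix(rep(c(3, 5), each = 6), 1, 12,
              dimnames = list("g1", md$sample_id))
  Y <- rbind(Y, g2 = rnorm(12))
  fit <- fit_glycan_lm(Y, X)
  expect_equal(unname(fit$coefficients["g1"]), 2)
  expect_equal(unname(fit$coefficients["g2"]),
               mean(Y["g2", 7:12]) - mean(Y["g2", 1:6]))
  expect_equal(fit$df_residual, 10)
})

test_that("a covariate orthogonal to group leaves the group coefficient unchanged", {
  md <- make_md()
  # balanced covariate, orthogonal to the group indicator
  md$balanced <- rep(c(-1, 1), 6)
  set.seed(2)
  Y <- matrix(rnorm(60), 5, 12,
              dimnames = list(paste0("g", 1:5), md$sample_id))
  f0 <- fit_glycan_lm(Y, design_from_metadata(md))
  f1 <- fit_glycan_lm(Y, design_from_metadata(md, "balanced"))
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  md <- make_md()
  md$dup <- as.integer(md$group == "positive")
  expect_error(design_from_metadata(md, "dup"), "dup")
  expect_error(design_from_metadata(md, "nope"), "nope")
})

test_that("empirical-Bayes moderation matches limma on random data", {
  skip_if_not_installed("limma")
  set.seed(3)
  md <- make_md(8, 8)
  X <- design_from_metadata(md)
  Y <- matrix(rnorm(16 * 80, sd = rep(sqrt(1 / rgamma(80, 4, 4)), each = 16)),
              80, 16, byrow = FALSE,
              dimnames = list(paste0("g", 1:80), md$sample_id))
  fit <- fit_glycan_lm(Y, X)
  eb <- moderate_ebayes(fit)
  lfit <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(unname(eb$df_prior), unname(lfit$df.prior), tolerance = 1e-6)
  expect_equal(unname(eb$var_prior), unname(lfit$s2.prior), tolerance = 1e-6)
  expect_equal(unname(eb$var_post), unname(lfit$s2.post), tolerance = 1e-8)
  expect_equal(unname(eb$t), unname(lfit$t[, "grouppositive"]),
               tolerance = 1e-8)
  expect_equal(unname(eb$p), unname(lfit$p.value[, "grouppositive"]),
               tolerance = 1e-8)
})

test_that("moderated t collapses to ordinary t in the stated limits", {
  md <- make_md()
  X <- design_from_metadata(md)
  set.seed(4)
  Y <- matrix(rnorm(120), 10, 12,
              dimnames = list(paste0("g", 1:10), md$sample_id))
  fit <- fit_glycan_lm(Y, X)
  t_ord <- fit$coefficients / fit$se
  # forced d0 = 0: no shrinkage
  eb0 <- moderate_ebayes(fit, df_prior = 0)
  expect_equal(eb0$t, t_ord, tolerance = 1e-12)
  # equal variances: the prior df estimate diverges, every posterior
  # variance collapses to the common prior variance (no differential
  # shrinkage), and the moderated t differs from the ordinary t only by
  # the constant small-sample log-variance bias correction
  Yc <- matrix(rnorm(120), 10, 12,
               dimnames = list(paste0("g", 1:10), md$sample_id))
  # force identical residual variance across glycans by rescaling rows
  fitc <- fit_glycan_lm(Yc / sqrt(fit_glycan_lm(Yc, X)$sigma2), X)
  ebc <- moderate_ebayes(fitc)
  expect_true(is.infinite(ebc$df_prior))
  expect_equal(unname(ebc$var_post), rep(unname(ebc$var_prior), 10))
  ratio <- ebc$t / (fitc$coefficients / fitc$se)
  expect_lt(stats::sd(ratio), 1e-10)           # same t up to a constant
  d <- fitc$df_residual
  expect_equal(unname(ratio[1]),
               exp((digamma(d / 2) - log(d / 2)) / 2), tolerance = 1e-10)
  # d0 = Inf: every posterior variance equals the prior variance
  ebi <- moderate_ebayes(fit, df_prior = Inf)
  expect_equal(unname(ebi$var_post), rep(unname(ebi$var_prior), 10))
  expect_error(moderate_ebayes(fit_glycan_lm(Y[1, , drop = FALSE], X)),
               "at least 2")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.42), 0.42)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- adjust_bh(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  }
})

test_that("differential tables sort by p and flag both conventions", {
  md <- make_md()
  set.seed(6)
  Y <- matrix(rnorm(120), 10, 12,
              dimnames = list(paste0("g", 1:10), md$sample_id))
  Y[1, md$group == "positive"] <- Y[1, md$group == "positive"] + 10
  eb <- moderate_ebayes(fit_glycan_lm(Y, design_from_metadata(md)))
  tab <- differential_table(eb, classes = c(g1 = "paucimannose"))
  expect_identical(tab$glycan_id[1], "g1")
  expect_identical(tab$class[1], "paucimannose")
  expect_false(is.unsorted(tab$p))
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(tab$sig_p[1] && tab$sig_q[1])
  # q threshold of 0 flags nothing
  tab0 <- differential_table(eb, q_threshold = 0)
  expect_equal(sum(tab0$sig_q), 0)
})

test_that("composition-level differential aggregates isomers before comparing", {
  groups <- rep(c("negative", "positive"), each = 4)
  # two isomers of one composition moving +1 and -1 in equal abundance
  rel <- rbind(iso1 = c(rep(20, 4), rep(40, 4)),
               iso2 = c(rep(40, 4), rep(20, 4)),
               other = rep(40, 8))
  colnames(rel) <- paste0("s", 1:8)
  cd <- composition_differential(rel, c(iso1 = "H5N2", iso2 = "H5N2",
                                        other = "H3N2"), groups)
  expect_identical(cd$direction[cd$composition == "H5N2"], "unchanged")
  expect_equal(cd$log2fc[cd$composition == "H5N2"], 0)
  # single-isomer composition inherits the structure fold change
  rel2 <- rbind(a = c(rep(25, 4), rep(50, 4)), b = c(rep(75, 4), rep(50, 4)))
  colnames(rel2) <- paste0("s", 1:8)
  cd2 <- composition_differential(rel2, c(a = "H4N2", b = "H3N2"), groups)
  expect_equal(cd2$log2fc[cd2$composition == "H4N2"], 1)
  expect_identical(cd2$direction[cd2$composition == "H4N2"], "increased")
  expect_error(composition_differential(rel2, c(a = "H4N2"), groups), "b")
})

test_that("planted paucimannose decreases label the right compositions", {
  lib <- generate_library(40, seed = 15)
  ch <- generate_cohort(lib, effects = list(paucimannose = -1), seed = 16)
  rel <- relative_abundance(ch$areas)
  cd <- composition_differential(
    rel, stats::setNames(lib$composition, lib$glycan_id), ch$metadata$group)
  pauci_comps <- unique(lib$composition[lib$fine_class == "paucimannose"])
  expect_true(all(cd$direction[cd$composition %in% pauci_comps] ==
                    "decreased"))
})

test_that("the estimator recovers a planted effect without material bias", {
  lib <- generate_library(60, seed = 17)
  ests <- vapply(1:30, function(i) {
    ch <- generate_cohort(lib, effects = list(paucimannose = -1),
                          seed = 300 + i)
    pm <- ch$truth$per_glycan$glycan_id[ch$truth$per_glycan$true_log2fc != 0]
    fit <- fit_glycan_lm(log2(ch$areas),
                         design_from_metadata(ch$metadata))
    mean(fit$coefficients[pm])
  }, numeric(1))
  expect_lt(abs(mean(ests) + 1), 0.1)
})

test_that("null data yield uniform p-values and nominal error rates", {
  lib <- generate_library(80, seed = 18)
  ch <- generate_cohort(lib, seed = 19)
  fit <- glycan_diffab(ch$areas, ch$metadata)
  tab <- summary(fit)
  expect_lt(mean(tab$sig_p), 0.15)
  ks <- stats::ks.test(tab$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("glycan_diffab methods expose the fit", {
  lib <- generate_library(30, seed = 20)
  ch <- generate_cohort(lib, effects = list(paucimannose = -1), seed = 21)
  fit <- glycan_diffab(ch$areas, ch$metadata,
                       classes = stats::setNames(lib$fine_class,
                                                 lib$glycan_id))
  expect_s3_class(fit, "glycan_diffab")
  expect_named(coef(fit))
  expect_equal(dim(residuals(fit)), dim(fit$logY))
  expect_equal(fitted(fit) + residuals(fit), fit$logY, tolerance = 1e-10)
  expect_output(print(fit), "Differential glycan abundance")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # sample mismatch is reported
  md_bad <- ch$metadata[-1, ]
  expect_error(glycan_diffab(ch$areas, md_bad), "mismatch")
})
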
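#' Mixed-model test of larval-density effects with Tukey letters
#'
#' Fits a linear mixed model on the `log(x + 1)`-transformed response with
#' larval density as a fixed factor and block as a random intercept
#' (maximum likelihood), then summarises all pairwise density contrasts with
#' Tukey's HSD as a compact letter display. If the random-effect fit is
#' singular or fails, a fixed-block linear model is used instead (with a
#' warning).
#'
#' @param response per-sample emission rates (one compound group or total).
#' @param density larval-density treatment (coerced to factor).
#' @param block randomized block identifier (coerced to factor).
#' @param transform apply the natural-log `log(x + 1)` transform (default
#'   `TRUE`, the convention for right-skewed emission data).
#' @return A `density_fit` list: `model`, `overall_p` (F-test for density),
#'   `means` (per-density means of the transformed response), `letters`
#'   (compact letter display, ordered by group mean), `fixed_block_fallback`.
#' @export
fit_density_effect <- function(response, density, block, transform = TRUE) {
  density <- factor(density)
  block <- factor(block)
  stopifnot(length(response) == length(density),
            length(response) == length(block))
  reps <- table(density)
  if (any(reps < 2L)) {
    integrity_error(sprintf("density level(s) with fewer than 2 replicates: %s",
                            paste(names(reps)[reps < 2L], collapse = ", ")))
  }
  y <- if (transform) log1p(response) else response
  means <- tapply(y, density, mean)

  if (stats::var(y) < .Machine$double.eps) {
    # constant response: nothing to test, one letter group
    letters <- stats::setNames(rep("a", nlevels(density)), levels(density))
    return(structure(list(model = NULL, overall_p = NA_real_, means = means,
                          letters = letters[order(means)],
                          fixed_block_fallback = FALSE),
                     class = "density_fit"))
  }

  dat <- data.frame(y = y, density = density, block = block)
  fallback <- FALSE
  fit <- tryCatch(
    nlme::lme(y ~ density, random = ~ 1 | block, data = dat, method = "ML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular mixed-model fit; falling back to a fixed-block model")
    fallback <- TRUE
    fit <- stats::lm(y ~ density + block, data = dat)
    overall_p <- stats::anova(fit)["density", "Pr(>F)"]
  } else {
    overall_p <- stats::anova(fit)["density", "p-value"]
  }
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(density = "Tukey"))
  cld <- multcomp::cld(glht_fit, level = 0.05)
  letters <- cld$mcletters$Letters[levels(density)]
  structure(list(model = fit, overall_p = unname(overall_p), means = means,
                 letters = letters[order(means[names(letters)])],
                 tukey = summary(glht_fit),
                 fixed_block_fallback = fallback),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat("Larval-density effect (log(x+1) LMM",
      if (x$fixed_block_fallback) ", fixed-block fallback" else "", ")\n",
      sep = "")
  cat("  overall F-test p =", format(x$overall_p, digits = 3), "\n")
  cat("  Tukey letters:\n")
  print(x$letters)
  invisible(x)
}

#' Damage dose-response regression
#'
#' Ordinary least-squares regression of an emission rate on the percentage of
#' leaf area eaten.
#'
#' @param rates per-sample emission rates (response).
#' @param percent_eaten per-sample percentage of leaf area eaten (predictor).
#' @return A `damage_regression` list: `slope` (rate change per % eaten),
#'   `slope_se`, `intercept`, `r_squared`, `p_value`, `n`, `conf_int`
#'   (95% CI for the slope), `model`.
#' @export
regress_on_damage <- function(rates, percent_eaten) {
  keep <- is.finite(rates) & is.finite(percent_eaten)
  rates <- rates[keep]; percent_eaten <- percent_eaten[keep]
  n <- length(rates)
  if (n < 3L) integrity_error("damage regression needs at least 3 observations")
  if (stats::var(percent_eaten) < .Machine$double.eps) {
    integrity_error("percent_eaten has zero variance")
  }
  fit <- stats::lm(rates ~ percent_eaten)
  s <- summary(fit)
  ci <- stats::confint(fit, "percent_eaten", level = 0.95)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 slope_se = s$coefficients["percent_eaten", "Std. Error"],
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared,
                 p_value = s$coefficients["percent_eaten", "Pr(>|t|)"],
                 n = n,
                 conf_int = c(lower = ci[1L], upper = ci[2L]),
                 model = fit),
            class = "damage_regression")
}

#' @export
print.damage_regression <- function(x, ...) {
  cat(sprintf(
    "Damage regression: slope %.3g +/- %.3g ng cm-2 h-1 per %% eaten (r2 = %.2f, p = %.3g, n = %d)\n",
    x$slope, x$slope_se, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Covariate screen for enclosure conditions
#'
#' Multiple regression of an emission rate on arbitrary covariates (e.g.
#' enclosure temperature and relative humidity). Advisory: reports per-term
#' coefficients and p-values; never gates the pipeline.
#'
#' @param rates per-sample emission rates.
#' @param covariates data.frame of numeric covariates.
#' @return data.frame with one row per covariate: estimate, se, t, p_value.
#' @export
screen_covariates <- function(rates, covariates) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(rates))
  dat <- data.frame(.y = rates, covariates, check.names = TRUE)
  fit <- stats::lm(.y ~ ., data = dat)
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  data.frame(term = rownames(co), estimate = co[, 1L], se = co[, 2L],
             t = co[, 3L], p_value = co[, 4L], row.names = NULL)
}

#' Compositional proportions of compound-group totals
#'
#' Converts per-sample group totals to relative proportions (rows sum to 1,
#' fixed class order).
#'
#' @param class_totals output of [aggregate_groups()] (or any data.frame with
#'   `sample_id` and the six group columns).
#' @return data.frame of proportions with the same `sample_id` column.
#' @export
blend_proportions <- function(class_totals) {
  m <- as.matrix(class_totals[, BVOC_CLASSES, drop = FALSE])
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    integrity_error(sprintf("sample(s) with zero total emission: %s",
                            paste(class_totals$sample_id[tot <= 0],
                                  collapse = ", ")))
  }
  out <- m / tot
  data.frame(sample_id = class_totals$sample_id, out,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' PCA of blend composition
#'
#' Principal component analysis of a samples x variables matrix after
#' zero-centering and scaling to unit variance. Zero-variance variables are
#' dropped with a warning. Component signs follow a deterministic convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix or data.frame (non-numeric columns such as
#'   `sample_id` are ignored).
#' @return A `bvoc_pca` list: `scores`, `loadings`, `variance_explained`
#'   (fractions summing to 1, descending).
#' @export
pca_composition <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1L))])
  if (nrow(x) < 2L || ncol(x) < 2L) {
    integrity_error("PCA needs at least 2 samples and 2 variables")
  }
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping zero-variance variable(s): %s",
                    paste(colnames(x)[v == 0], collapse = ", ")))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2L) integrity_error("fewer than 2 variable columns remain")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, "*")
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "bvoc_pca")
}

#' @export
print.bvoc_pca <- function(x, ...) {
  ve <- round(100 * x$variance_explained, 1)
  cat("Blend-composition PCA:", nrow(x$scores), "samples,",
      ncol(x$loadings), "components\n")
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' Residual diagnostics: normality and variance homogeneity
#'
#' Shapiro-Wilk normality test on the residuals and Levene's test of variance
#' homogeneity across groups. Advisory only; returns `NA` on degenerate input
#' (fewer than 3 residuals, or any group with fewer than 3 observations for
#' Levene).
#'
#' @param residuals numeric residual vector.
#' @param groups grouping factor of the same length.
#' @return data.frame with columns `test`, `statistic`, `p_value`.
#' @export
check_assumptions <- function(residuals, groups) {
  groups <- factor(groups)
  stopifnot(length(residuals) == length(groups))
  n <- length(residuals)
  sw <- if (n >= 3L && n <= 5000L && stats::var(residuals) > 0) {
    t <- stats::shapiro.test(residuals)
    c(t$statistic, t$p.value)
  } else c(NA_real_, NA_real_)
  lv <- if (all(table(groups) >= 3L) && nlevels(groups) >= 2L &&
            stats::var(residuals) > 0) {
    t <- car::leveneTest(residuals ~ groups)
    c(t[1L, "F value"], t[1L, "Pr(>F)"])
  } else c(NA_real_, NA_real_)
  data.frame(test = c("shapiro_wilk", "levene"),
             statistic = c(sw[1L], lv[1L]),
             p_value = c(sw[2L], lv[2L]))
}
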
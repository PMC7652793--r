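#' Classify samples into low and high herbivory
#'
#' Labels a sample `"low"` when its percentage of leaf area eaten is at or
#' below the threshold (ties go to `"low"`) and `"high"` otherwise. The 4%
#' default separates background-level from elevated feeding damage.
#'
#' @param pct percentage of leaf area eaten per sample.
#' @param threshold classification cut, % leaf area eaten (default 4).
#' @return factor with levels `low`, `high`.
#' @export
classify_damage <- function(pct, threshold = 4) {
  if (any(!is.finite(pct))) integrity_error("percent eaten must be finite")
  if (any(pct < 0)) integrity_error("percent eaten cannot be negative")
  factor(ifelse(pct <= threshold, "low", "high"), levels = c("low", "high"))
}

#' Random-forest discrimination of damage groups from blend composition
#'
#' Trains a random forest on per-compound proportional emissions to separate
#' low- from high-herbivory samples, reporting out-of-bag error, per-class
#' errors and variable importance (mean decrease in Gini impurity).
#'
#' @param proportions samples x compounds matrix of per-compound proportions
#'   of the total blend.
#' @param labels factor of damage groups (see [classify_damage()]).
#' @param n_tree number of bootstrap trees (default 100000).
#' @param m_try predictors sampled per split (default: `randomForest`'s
#'   `sqrt(p)` heuristic).
#' @return An `rf_blend` list: `oob_error`, `class_errors`, `importance`
#'   (sorted decreasing), `confusion`, `forest`.
#' @export
rf_discriminate <- function(proportions, labels, n_tree = 100000,
                            m_try = NULL) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    integrity_error("random-forest discrimination needs two classes")
  }
  if (any(table(labels) < 2L)) {
    integrity_error("each class needs at least 2 samples")
  }
  x <- as.matrix(proportions)
  if (is.null(m_try)) m_try <- max(1L, floor(sqrt(ncol(x))))
  fit <- randomForest::randomForest(x = x, y = labels, ntree = n_tree,
                                    mtry = min(m_try, ncol(x)),
                                    importance = TRUE)
  conf <- fit$confusion
  class_errors <- conf[, "class.error"]
  oob <- 1 - sum(diag(conf[, colnames(conf) != "class.error", drop = FALSE])) /
    length(labels)
  imp <- fit$importance[, "MeanDecreaseGini"]
  structure(list(oob_error = oob, class_errors = class_errors,
                 importance = sort(imp, decreasing = TRUE),
                 confusion = conf, forest = fit),
            class = "rf_blend")
}

#' @export
print.rf_blend <- function(x, ...) {
  cat(sprintf("Random-forest blend discrimination: OOB error %.1f%%\n",
              100 * x$oob_error))
  cat(sprintf("  class errors: %s\n",
              paste(sprintf("%s %.1f%%", names(x$class_errors),
                            100 * x$class_errors), collapse = ", ")))
  cat("  top compounds:", paste(utils::head(names(x$importance), 3L),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise Pearson correlation structure of compound emissions
#'
#' Computes the compound x compound Pearson correlation matrix of absolute
#' emission rates within one sample group, together with two-sided p-values
#' from the standard t-transform of r on n - 2 degrees of freedom. Compounds
#' with zero variance within the group are dropped with a message.
#'
#' @param emissions samples x compounds emission matrix for one group.
#' @return A `cor_structure` list: `R` (correlations), `P` (p-values), `n`
#'   (samples), `p` (compounds retained), `dropped` (compound ids).
#' @export
correlation_structure <- function(emissions) {
  emissions <- as.matrix(emissions)
  n <- nrow(emissions)
  if (n < 3L) integrity_error("correlation structure needs at least 3 samples")
  v <- apply(emissions, 2L, stats::var)
  dropped <- colnames(emissions)[v == 0]
  if (length(dropped) > 0L) {
    message("dropping zero-variance compound(s): ",
            paste(dropped, collapse = ", "))
    emissions <- emissions[, v > 0, drop = FALSE]
  }
  p <- ncol(emissions)
  if (p < 2L) integrity_error("fewer than 2 compounds vary within the group")
  R <- stats::cor(emissions)
  r <- R
  diag(r) <- 0
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  P[abs(r) >= 1 - 1e-12 & row(P) != col(P)] <- 0
  diag(P) <- NA_real_
  structure(list(R = R, P = P, n = n, p = p, dropped = dropped),
            class = "cor_structure")
}

#' Phenotypic integration index (eigenvalue variance)
#'
#' The variance of the eigenvalues of a compound correlation matrix measures
#' how tightly intercorrelated the emission blend is. Because the eigenvalues
#' of a p x p correlation matrix always average 1, the index is
#' `sum((lambda - 1)^2) / (p - 1)`. It is 0 for an identity matrix and
#' attains its maximum, p (the number of substances), when all correlations
#' are +/-1.
#'
#' @param R correlation matrix (symmetric, unit diagonal), or a
#'   `cor_structure` from [correlation_structure()].
#' @return `int_raw`, the integration index, with the eigenvalue spectrum as
#'   attribute `eigenvalues`.
#' @export
integration_index <- function(R) {
  if (inherits(R, "cor_structure")) R <- R$R
  R <- as.matrix(R)
  p <- ncol(R)
  if (p < 2L) integrity_error("integration index needs at least 2 compounds")
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) {
    integrity_error("correlation matrix must be symmetric")
  }
  if (any(abs(diag(R) - 1) > 1e-8)) {
    integrity_error("correlation matrix must have a unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * p) {
    integrity_error("correlation matrix is not positive semi-definite")
  }
  structure(sum((ev - 1)^2) / (p - 1), eigenvalues = ev)
}

#' Relative phenotypic integration (% of maximum)
#'
#' Standardises a raw integration index for sample size and dimensionality:
#' the expected eigenvalue variance under random covariation,
#' `(p - 1) / n`, is subtracted and the result divided by the potential
#' maximum, p (the number of substances), then expressed as a percentage.
#' Slightly negative values are legal for near-independent data.
#'
#' @param int_raw raw integration index from [integration_index()].
#' @param p number of substances in the correlation matrix.
#' @param n number of samples the matrix was estimated from.
#' @return Relative integration, percent of maximum.
#' @export
relative_integration <- function(int_raw, p, n) {
  if (p < 2L) integrity_error("relative integration needs p >= 2")
  if (n <= 0L) integrity_error("relative integration needs n > 0")
  100 * (as.numeric(int_raw) - (p - 1) / n) / p
}

#' Connectance of the compound correlation network
#'
#' The fraction of all possible compound pairs whose pairwise correlation is
#' significant at `alpha` (raw p-values, no multiplicity correction).
#'
#' @param P p-value matrix from [correlation_structure()], or a
#'   `cor_structure`.
#' @param alpha significance threshold (default 0.05).
#' @return Fraction in `[0, 1]`.
#' @export
connectance <- function(P, alpha = 0.05) {
  if (inherits(P, "cor_structure")) P <- P$P
  P <- as.matrix(P)
  p <- ncol(P)
  if (p < 2L) integrity_error("connectance needs at least 2 compounds")
  pv <- P[upper.tri(P)]
  sum(pv < alpha) / (p * (p - 1) / 2)
}

#' Full integration profile of one sample group
#'
#' Convenience wrapper running [correlation_structure()],
#' [integration_index()], [relative_integration()] and [connectance()] on one
#' herbivory group's emission matrix.
#'
#' @param emissions samples x compounds absolute emission rates for the group.
#' @param group group label (e.g. `"low"` or `"high"`), stored in the result.
#' @param alpha significance threshold for connectance.
#' @return A `pi_result` list: `group`, `n`, `p`, `eigenvalues`, `int_raw`,
#'   `int_expected_random`, `int_relative`, `connectance`.
#' @export
integrate_group <- function(emissions, group = NA_character_, alpha = 0.05) {
  cs <- correlation_structure(emissions)
  int_raw <- integration_index(cs$R)
  structure(list(group = group, n = cs$n, p = cs$p,
                 eigenvalues = attr(int_raw, "eigenvalues"),
                 int_raw = as.numeric(int_raw),
                 int_expected_random = (cs$p - 1) / cs$n,
                 int_relative = relative_integration(int_raw, cs$p, cs$n),
                 connectance = connectance(cs$P, alpha),
                 dropped = cs$dropped),
            class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("Phenotypic integration [%s]: n = %d, p = %d\n",
              x$group, x$n, x$p))
  cat(sprintf("  int_raw = %.3f (random expectation %.3f)\n",
              x$int_raw, x$int_expected_random))
  cat(sprintf("  relative integration = %.1f%% of maximum\n", x$int_relative))
  cat(sprintf("  connectance = %.2f\n", x$connectance))
  invisible(x)
}

#' Compare phenotypic integration between herbivory groups
#'
#' Given per-experiment relative-integration values for the low and high
#' herbivory groups, reports group means with standard errors and a two-group
#' linear-model F test (1 and 2(k - 1) degrees of freedom for k experiments).
#'
#' @param pi_low relative PI per experiment, low-herbivory group.
#' @param pi_high relative PI per experiment, high-herbivory group.
#' @return A `pi_comparison` list: `mean_low`, `se_low`, `mean_high`,
#'   `se_high`, `f_value`, `df`, `p_value`, `k`.
#' @export
compare_pi <- function(pi_low, pi_high) {
  k <- length(pi_low)
  if (length(pi_high) != k) {
    integrity_error("groups must cover the same number of experiments")
  }
  if (k < 2L) integrity_error("PI comparison needs at least 2 experiments")
  grp <- factor(rep(c("low", "high"), each = k), levels = c("low", "high"))
  fit <- stats::lm(c(pi_low, pi_high) ~ grp)
  an <- stats::anova(fit)
  structure(list(mean_low = mean(pi_low),
                 se_low = stats::sd(pi_low) / sqrt(k),
                 mean_high = mean(pi_high),
                 se_high = stats::sd(pi_high) / sqrt(k),
                 f_value = an["grp", "F value"],
                 df = c(1L, 2L * (k - 1L)),
                 p_value = an["grp", "Pr(>F)"],
                 k = k),
            class = "pi_comparison")
}

#' @export
print.pi_comparison <- function(x, ...) {
  cat(sprintf("PI comparison over %d experiments\n", x$k))
  cat(sprintf("  low:  %.2f +/- %.2f\n", x$mean_low, x$se_low))
  cat(sprintf("  high: %.2f +/- %.2f\n", x$mean_high, x$se_high))
  cat(sprintf("  F(%d,%d) = %.2f, p = %.3g\n",
              x$df[1L], x$df[2L], x$f_value, x$p_value))
  invisible(x)
}
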
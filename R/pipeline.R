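PIPELINE_STAGES <- c("preprocess", "emission", "stats", "integration")

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    bvoc_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)),
              "bvoc_stage_error")
  })
}

#' Run the full herbivory-BVOC analysis pipeline
#'
#' Executes preprocess (blank subtraction, compound filtering, proxy
#' quantification), emission (leaf-area imputation, emission rates, group
#' totals), stats (density mixed models with Tukey letters, damage
#' regressions, proportions, PCA, diagnostics) and integration (damage
#' classification, random-forest discrimination, per-group phenotypic
#' integration and connectance) for every experiment in the input, and writes
#' all result tables plus a machine-readable run log.
#'
#' @param config named list (or path to a YAML/JSON file read with
#'   [read_config()]) with elements:
#'   * `simulate`: list of [synthetic_truth()] arguments (or a list of such
#'     lists for several experiments), or
#'   * `inputs`: named paths `peaks`, `samples`, `leaves`, `compounds`;
#'   * `outdir`: output directory;
#'   * optional `stages` (subset of preprocess/emission/stats/integration),
#'     `presence_frac` (0.30), `mf_min` (800), `response_factors` (all 1),
#'     `damage_threshold` (4), `alpha` (0.05), `rf_ntree` (100000),
#'     `rf_mtry`.
#' @param seed integer seed for every source of randomness; overrides
#'   `config$seed`.
#' @return Invisibly, a list with per-experiment results (`experiments`),
#'   the cross-experiment PI comparison when >= 2 experiments are present
#'   (`pi_comparison`), and the run log (`log`).
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  if (is.null(config$outdir)) config_error("config must name an outdir")
  stages <- config$stages %||% PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0L) {
    config_error(sprintf("unknown stage name(s): %s (known: %s)",
                         paste(unknown, collapse = ", "),
                         paste(PIPELINE_STAGES, collapse = ", ")))
  }
  seed <- seed %||% config$seed %||% 1L
  set.seed(seed)
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  meta <- list(seed = seed, config = hash,
               package = as.character(utils::packageVersion("herbivoc")))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  presence_frac <- config$presence_frac %||% 0.30
  mf_min <- config$mf_min %||% 800
  threshold <- config$damage_threshold %||% 4
  alpha <- config$alpha %||% 0.05
  rf_ntree <- config$rf_ntree %||% 100000
  rf_mtry <- config$rf_mtry

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    specs <- config$simulate
    if (isTRUE(specs)) specs <- list(list())
    if (!is.null(names(specs)) || length(specs) == 0L) specs <- list(specs)
    datasets <- lapply(specs, function(s) {
      truth <- do.call(synthetic_truth, as.list(s))
      sim <- simulate_experiment(truth, seed = NULL)  # seeded at top level
      write_bvoc_tables(sim$data,
                        file.path(outdir, "simulated", truth$experiment),
                        meta = meta)
      sim$data
    })
  } else if (!is.null(config$inputs)) {
    datasets <- list(read_bvoc_tables(config$inputs))
  } else {
    config_error("config must provide either 'simulate' parameters or 'inputs' paths")
  }

  # split by experiment; each experiment is analysed independently
  experiments <- list()
  for (d in datasets) {
    for (exp_name in unique(d$samples$experiment)) {
      keep <- d$samples$experiment == exp_name
      sub <- bvoc_dataset(
        peak_table(unclass(d$peaks)[rownames(d$peaks) %in%
                                      d$samples$sample_id[keep], ,
                                    drop = FALSE],
                   blank_subtracted = is_blank_subtracted(d$peaks)),
        d$samples[keep, ],
        d$leaves[d$leaves$branch_id %in% d$samples$branch_id[keep], ],
        d$compounds)
      experiments[[exp_name]] <- sub
    }
  }

  results <- lapply(names(experiments), function(exp_name) {
    analyse_experiment(experiments[[exp_name]], exp_name, stages,
                       presence_frac = presence_frac, mf_min = mf_min,
                       response_factors = config$response_factors,
                       threshold = threshold, alpha = alpha,
                       rf_ntree = rf_ntree, rf_mtry = rf_mtry,
                       outdir = outdir, meta = meta)
  })
  names(results) <- names(experiments)

  pi_cmp <- NULL
  if ("integration" %in% stages) {
    pis <- lapply(results, function(r) r$integration$relative)
    ok <- !vapply(pis, is.null, logical(1L))
    if (sum(ok) >= 2L) {
      pi_cmp <- compare_pi(
        vapply(pis[ok], function(x) x[["low"]], numeric(1L)),
        vapply(pis[ok], function(x) x[["high"]], numeric(1L)))
      write_csv_with_meta(
        data.frame(group = c("low", "high"),
                   mean_pi = c(pi_cmp$mean_low, pi_cmp$mean_high),
                   se_pi = c(pi_cmp$se_low, pi_cmp$se_high),
                   f_value = pi_cmp$f_value, p_value = pi_cmp$p_value),
        file.path(outdir, "pi_comparison.csv"), meta)
    }
  }

  log <- c(meta, list(
    stages = stages,
    experiments = names(experiments),
    parameters = list(presence_frac = presence_frac, mf_min = mf_min,
                      damage_threshold = threshold, alpha = alpha,
                      rf_ntree = rf_ntree),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(experiments = results, pi_comparison = pi_cmp, log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyse_experiment <- function(data, exp_name, stages, presence_frac, mf_min,
                               response_factors, threshold, alpha,
                               rf_ntree, rf_mtry, outdir, meta) {
  out <- list()
  exp_dir <- file.path(outdir, exp_name)
  dir.create(exp_dir, showWarnings = FALSE, recursive = TRUE)

  # --- preprocess -------------------------------------------------------
  peaks <- data$peaks
  if ("preprocess" %in% stages) {
    run_stage("preprocess", {
      is_blank <- data$samples$sample_type[match(rownames(peaks),
                                                 data$samples$sample_id)] ==
        "blank"
      if (!is_blank_subtracted(peaks)) {
        peaks <- subtract_blanks(
          peak_table(unclass(peaks)[!is_blank, , drop = FALSE]),
          unclass(data$peaks)[is_blank, , drop = FALSE])
      } else {
        peaks <- peak_table(unclass(peaks)[!is_blank, , drop = FALSE],
                            blank_subtracted = TRUE)
      }
      filt <- filter_compounds(peaks, data$compounds,
                               presence_frac = presence_frac, mf_min = mf_min)
      peaks <- filt$peaks
      if (!is.null(response_factors)) {
        peaks <- quantify_compounds(peaks, data$compounds,
                                    unlist(response_factors))
      }
      out$exclusions <- filt$exclusions
      write_csv_with_meta(filt$exclusions,
                          file.path(exp_dir, "excluded_compounds.csv"), meta)
    })
  }

  # --- emission ---------------------------------------------------------
  branch <- data$samples[data$samples$sample_type == "branch", ]
  leaves <- data$leaves
  emissions <- class_totals <- NULL
  if ("emission" %in% stages) {
    run_stage("emission", {
      dens_by_branch <- branch$larval_density[match(leaves$branch_id,
                                                    branch$branch_id)]
      leaves <- impute_leaf_area(leaves, dens_by_branch)
      d2 <- bvoc_dataset(peaks, data$samples, leaves, data$compounds)
      emissions <- build_emission_matrix(d2)
      class_totals <- aggregate_groups(emissions, data$compounds)
      write_csv_with_meta(
        data.frame(sample_id = rownames(emissions), emissions,
                   check.names = FALSE),
        file.path(exp_dir, "emission_rates.csv"), meta)
      write_csv_with_meta(class_totals,
                          file.path(exp_dir, "class_totals.csv"), meta)
      out$emissions <- emissions
      out$class_totals <- class_totals
    })
  }
  if (is.null(emissions)) return(out)

  idx <- match(rownames(emissions), branch$sample_id)
  density <- branch$larval_density[idx]
  block <- branch$block_id[idx]
  pct <- leaves$percent_eaten[match(branch$branch_id[idx], leaves$branch_id)]
  present_classes <- BVOC_CLASSES[colSums(
    as.matrix(class_totals[, BVOC_CLASSES])) > 0]

  # --- stats ------------------------------------------------------------
  if ("stats" %in% stages) {
    run_stage("stats", {
      fits <- lapply(c(present_classes, total = "total"), function(g) {
        fit_density_effect(class_totals[[g]], density, block)
      })
      names(fits) <- c(present_classes, "total")
      tukey <- do.call(rbind, lapply(names(fits), function(g) {
        data.frame(group = g, density = names(fits[[g]]$letters),
                   letter = unname(fits[[g]]$letters),
                   overall_p = fits[[g]]$overall_p)
      }))
      regs <- lapply(c(present_classes, total = "total"), function(g) {
        regress_on_damage(class_totals[[g]], pct)
      })
      names(regs) <- c(present_classes, "total")
      reg_tab <- do.call(rbind, lapply(names(regs), function(g) {
        r <- regs[[g]]
        data.frame(experiment = exp_name, group = g, slope = r$slope,
                   se = r$slope_se, r_squared = r$r_squared,
                   p_value = r$p_value, n = r$n)
      }))
      props <- blend_proportions(class_totals)
      pca <- pca_composition(class_totals[, present_classes])
      diag_tab <- if (!is.null(fits$total$model)) {
        check_assumptions(stats::residuals(fits$total$model), factor(density))
      } else NULL
      covars <- screen_covariates(
        class_totals$total,
        data$samples[match(rownames(emissions), data$samples$sample_id),
                     c("temperature", "rh")])

      write_csv_with_meta(tukey, file.path(exp_dir, "tukey_letters.csv"), meta)
      write_csv_with_meta(reg_tab,
                          file.path(exp_dir, "damage_regressions.csv"), meta)
      write_csv_with_meta(props, file.path(exp_dir, "proportions.csv"), meta)
      write_csv_with_meta(
        data.frame(sample_id = class_totals$sample_id,
                   pca$scores, check.names = FALSE),
        file.path(exp_dir, "pca_scores.csv"), meta)
      out$density_fits <- fits
      out$regressions <- regs
      out$proportions <- props
      out$pca <- pca
      out$diagnostics <- diag_tab
      out$covariate_screen <- covars
    })
  }

  # --- integration ------------------------------------------------------
  if ("integration" %in% stages) {
    run_stage("integration", {
      labels <- classify_damage(pct, threshold)
      per_compound_props <- emissions / pmax(rowSums(emissions),
                                             .Machine$double.eps)
      rf <- if (all(table(labels) >= 2L)) {
        rf_discriminate(per_compound_props, labels, n_tree = rf_ntree,
                        m_try = rf_mtry)
      } else NULL
      pis <- lapply(c("low", "high"), function(g) {
        rows <- labels == g
        if (sum(rows) < 3L) return(NULL)
        integrate_group(emissions[rows, , drop = FALSE], group = g,
                        alpha = alpha)
      })
      names(pis) <- c("low", "high")
      ok <- !vapply(pis, is.null, logical(1L))
      tab <- do.call(rbind, lapply(pis[ok], function(x) {
        data.frame(experiment = exp_name, group = x$group, n = x$n, p = x$p,
                   int_raw = x$int_raw,
                   int_expected_random = x$int_expected_random,
                   int_relative = x$int_relative,
                   connectance = x$connectance,
                   mean_leaf_area_eaten = mean(pct[labels == x$group]),
                   mean_total_emission =
                     mean(class_totals$total[labels == x$group]))
      }))
      write_csv_with_meta(tab, file.path(exp_dir, "integration.csv"), meta)
      if (!is.null(rf)) {
        write_csv_with_meta(
          data.frame(compound_id = names(rf$importance),
                     importance = unname(rf$importance)),
          file.path(exp_dir, "rf_importance.csv"), meta)
      }
      out$labels <- labels
      out$rf <- rf
      out$integration <- list(
        results = pis,
        relative = if (all(ok)) c(low = pis$low$int_relative,
                                  high = pis$high$int_relative) else NULL,
        table = tab)
    })
  }
  out
}
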
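# Synthetic branch-enclosure experiments.
#
# One experiment = a randomized complete block design of larval-density
# treatments on birch branches. Per-compound emission rates follow
#   ER_i = basal_i + induction_i * percent_eaten + sd_i * e_i,  floored at 0,
# where e is a single-latent-factor Gaussian (e_i = lambda f + sqrt(1-l^2) z_i)
# whose loading depends on the branch's damage group: low-damage branches get
# a strong common factor (tightly intercorrelated constitutive blend),
# high-damage branches a weak one. Cartridge masses are back-computed by
# inverting the emission-rate equation, and a constant blank contamination is
# added to every cartridge.

default_compound_catalog <- function() {
  data.frame(
    compound_id = c("linalool", "e_beta_ocimene", "alpha_pinene", "limonene",
                    "camphene",
                    "dmnt",
                    "z_beta_farnesene", "e_beta_caryophyllene",
                    "alpha_humulene", "germacrene_d",
                    "e_2_hexenal", "z_3_hexenol", "z_3_hexenyl_acetate",
                    "hexanal",
                    "toluene", "benzaldehyde", "methyl_salicylate",
                    "nonanal", "decanal", "octanal", "heptanal",
                    "6_methyl_5_hepten_2_one", "2_ethyl_hexanol"),
    name = c("linalool", "(E)-beta-ocimene", "alpha-pinene", "limonene",
             "camphene",
             "(E)-4,8-dimethylnona-1,3,7-triene",
             "(Z)-beta-farnesene", "(E)-beta-caryophyllene",
             "alpha-humulene", "germacrene D",
             "(E)-2-hexenal", "(Z)-3-hexenol", "(Z)-3-hexenyl acetate",
             "hexanal",
             "toluene", "benzaldehyde", "methyl salicylate",
             "nonanal", "decanal", "octanal", "heptanal",
             "6-methyl-5-hepten-2-one", "2-ethylhexanol"),
    compound_class = rep(c("MT", "HT_DMNT", "SQT", "GLV", "BENZENOID",
                           "OTHER"),
                         times = c(5L, 1L, 4L, 4L, 3L, 6L)),
    stringsAsFactors = FALSE)
}

#' Generating parameters for a synthetic enclosure experiment
#'
#' Defaults emulate a Subarctic birch larval-density manipulation: 5 density
#' levels x 4 replicate blocks, leaf areas uniform in the 150-253 cm^2 range,
#' leaf-area loss increasing with density up to ~10%, class-specific
#' induction (GLV, DMNT and MT most responsive), and a damage-group-dependent
#' latent-factor correlation structure (strong common factor under low
#' damage, weak under high).
#'
#' @param experiment experiment label.
#' @param density_levels larvae per branch.
#' @param replicates blocks (one branch per density per block).
#' @param leaf_area_range original leaf area bounds, cm^2.
#' @param damage_slope mean % leaf area eaten per larva.
#' @param damage_background mean % eaten on control branches.
#' @param damage_noise sd of % eaten: `base + prop * mean`.
#' @param damage_max upper clip for % eaten.
#' @param class_basal constitutive class-total emission rates, ng cm^-2 h^-1.
#' @param class_induction class-total induction, ng cm^-2 h^-1 per % eaten.
#' @param dominant_share share of a class's basal/induction carried by its
#'   first (most abundant) compound.
#' @param noise_cv per-compound noise sd as a fraction of its basal rate.
#' @param loading_low,loading_high latent-factor loading for low-/high-damage
#'   branches (squared loading = pairwise noise correlation).
#' @param group_threshold % eaten separating the two covariance regimes.
#' @param blank_level constant blank contamination, ng per cartridge.
#' @param n_blanks blank cartridges per experiment.
#' @param inflow_rate,cartridge_flow,duration enclosure sampling settings
#'   (mL min^-1, mL min^-1, min).
#' @param seed RNG seed recorded with the truth (used by
#'   [simulate_experiment()] when set).
#' @return A `synthetic_truth` list, including the derived per-compound
#'   `catalog` (basal, induction, noise sd per compound).
#' @export
synthetic_truth <- function(experiment = "Abisko1",
                            density_levels = c(0, 5, 15, 30, 50),
                            replicates = 4,
                            leaf_area_range = c(150, 253),
                            damage_slope = 0.18,
                            damage_background = 0.1,
                            damage_noise = c(base = 0.3, prop = 0.25),
                            damage_max = 15,
                            class_basal = c(MT = 0.01, HT_DMNT = 0.01,
                                            SQT = 0.03, GLV = 0.1,
                                            BENZENOID = 0.2, OTHER = 0.6),
                            class_induction = c(MT = 0.035, HT_DMNT = 0.114,
                                                SQT = 0.006, GLV = 0.4,
                                                BENZENOID = 0.002,
                                                OTHER = 0.06),
                            dominant_share = 0.6,
                            noise_cv = 0.8,
                            loading_low = 0.85,
                            loading_high = 0.1,
                            group_threshold = 4,
                            blank_level = 0.5,
                            n_blanks = 3,
                            inflow_rate = 300,
                            cartridge_flow = 200,
                            duration = 15,
                            seed = NULL) {
  stopifnot(replicates >= 1, all(density_levels >= 0),
            noise_cv >= 0, blank_level >= 0,
            abs(loading_low) <= 1, abs(loading_high) <= 1)
  if (!setequal(names(class_basal), BVOC_CLASSES) ||
      !setequal(names(class_induction), BVOC_CLASSES)) {
    config_error("class_basal and class_induction must cover all six classes")
  }
  catalog <- default_compound_catalog()
  # split class totals: dominant compound gets dominant_share, rest equal
  share <- unlist(lapply(split(catalog$compound_id, catalog$compound_class),
                         function(ids) {
                           k <- length(ids)
                           if (k == 1L) return(stats::setNames(1, ids))
                           stats::setNames(c(dominant_share,
                                             rep((1 - dominant_share) / (k - 1),
                                                 k - 1L)), ids)
                         }))
  names(share) <- sub("^[A-Z_]+\\.", "", names(share))
  catalog$basal <- class_basal[catalog$compound_class] *
    share[catalog$compound_id]
  catalog$induction <- class_induction[catalog$compound_class] *
    share[catalog$compound_id]
  catalog$noise_sd <- noise_cv * catalog$basal
  # High-damage branches respond idiosyncratically: their noise tracks the
  # induced emission level of each compound (basal + induction at the typical
  # high-group damage) rather than the constitutive level. The resulting sd
  # vector is rescaled so the blend-level noise variance,
  # Var(total noise) = lambda^2 (sum s)^2 + (1 - lambda^2) sum s^2,
  # is identical in both regimes: herbivory reallocates blend variability
  # from a coordinated common factor to compound-specific induction without
  # changing its overall magnitude.
  blend_var <- function(l, s) l^2 * sum(s)^2 + (1 - l^2) * sum(s^2)
  exp_eaten <- damage_background + damage_slope * density_levels
  damage_ref_high <- if (any(exp_eaten > group_threshold)) {
    mean(exp_eaten[exp_eaten > group_threshold])
  } else group_threshold
  d_high <- noise_cv * (catalog$basal + catalog$induction * damage_ref_high)
  bv_high <- blend_var(loading_high, d_high)
  catalog$noise_sd_high <- if (bv_high > 0) {
    d_high * sqrt(blend_var(loading_low, catalog$noise_sd) / bv_high)
  } else d_high
  structure(list(experiment = experiment,
                 density_levels = density_levels,
                 replicates = replicates,
                 leaf_area_range = leaf_area_range,
                 damage_slope = damage_slope,
                 damage_background = damage_background,
                 damage_noise = damage_noise,
                 damage_max = damage_max,
                 class_basal = class_basal,
                 class_induction = class_induction,
                 total_induction = sum(class_induction),
                 catalog = catalog,
                 noise_cv = noise_cv,
                 loading_low = loading_low,
                 loading_high = loading_high,
                 group_threshold = group_threshold,
                 blank_level = blank_level,
                 n_blanks = n_blanks,
                 inflow_rate = inflow_rate,
                 cartridge_flow = cartridge_flow,
                 duration = duration,
                 seed = seed),
            class = "synthetic_truth")
}

#' Presets for the three field experiments
#'
#' Density levels, replication, leaf-area ranges, and damage intensity of the
#' two Abisko and the Tromso larval-density experiments.
#'
#' @param experiment one of `"Abisko1"`, `"Abisko2"`, `"Tromso"`.
#' @param ... overrides passed to [synthetic_truth()].
#' @return A `synthetic_truth`.
#' @export
study_truth <- function(experiment = c("Abisko1", "Abisko2", "Tromso"), ...) {
  experiment <- match.arg(experiment)
  preset <- switch(experiment,
    Abisko1 = list(density_levels = c(0, 5, 15, 30, 50), replicates = 4,
                   leaf_area_range = c(150, 253), damage_slope = 0.15),
    Abisko2 = list(density_levels = c(0, 5, 15, 30, 50), replicates = 4,
                   leaf_area_range = c(256, 522), damage_slope = 0.20),
    Tromso  = list(density_levels = c(0, 5, 15, 30), replicates = 5,
                   leaf_area_range = c(135, 337), damage_slope = 0.30))
  args <- utils::modifyList(c(list(experiment = experiment), preset),
                            list(...))
  do.call(synthetic_truth, args)
}

#' Simulate one branch-enclosure experiment
#'
#' Draws leaf areas, feeding damage, per-compound emission rates (latent
#' factor noise, floored at zero), then back-computes the cartridge masses by
#' inverting the emission-rate equation and adds blank contamination, so the
#' full preprocessing + emission pipeline can be exercised end to end.
#'
#' @param truth a [synthetic_truth()].
#' @param seed RNG seed; defaults to `truth$seed`. `NULL` leaves the RNG
#'   state untouched.
#' @return A `bvoc_simulation` list: `data` (a [bvoc_dataset()] of cartridge
#'   masses), `emissions` (true emission-rate matrix, branch x compound),
#'   `groups` (damage-group factor per branch), `truth`.
#' @export
simulate_experiment <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  cat_tab <- truth$catalog
  p <- nrow(cat_tab)
  dens <- rep(truth$density_levels, times = truth$replicates)
  block <- rep(seq_len(truth$replicates), each = length(truth$density_levels))
  n <- length(dens)
  ids <- sprintf("%s_s%02d", truth$experiment, seq_len(n))
  branch_ids <- sprintf("%s_br%02d", truth$experiment, seq_len(n))

  la0 <- stats::runif(n, truth$leaf_area_range[1L], truth$leaf_area_range[2L])
  eaten_mean <- truth$damage_background + truth$damage_slope * dens
  sd_eaten <- truth$damage_noise[["base"]] +
    truth$damage_noise[["prop"]] * eaten_mean
  pct <- pmin(pmax(stats::rnorm(n, eaten_mean, sd_eaten), 0), truth$damage_max)
  eaten_area <- pct / 100 * la0
  la_remaining <- la0 - eaten_area

  groups <- classify_damage(pct, truth$group_threshold)
  lambda <- ifelse(groups == "low", truth$loading_low, truth$loading_high)

  f <- stats::rnorm(n)
  z <- matrix(stats::rnorm(n * p), n, p)
  e <- lambda * f + sqrt(1 - lambda^2) * z
  sd_mat <- matrix(cat_tab$noise_sd, n, p, byrow = TRUE)
  sd_mat[groups == "high", ] <- matrix(cat_tab$noise_sd_high,
                                       sum(groups == "high"), p, byrow = TRUE)
  mu <- outer(pct, cat_tab$induction) +
    matrix(cat_tab$basal, n, p, byrow = TRUE)
  er <- pmax(mu + sd_mat * e, 0)
  colnames(er) <- cat_tab$compound_id
  rownames(er) <- ids

  masses <- mass_from_rate(er, truth$cartridge_flow, truth$duration,
                           truth$inflow_rate, la_remaining) +
    truth$blank_level

  blank_ids <- sprintf("%s_blank%d", truth$experiment,
                       seq_len(truth$n_blanks))
  blank_m <- matrix(truth$blank_level, truth$n_blanks, p,
                    dimnames = list(blank_ids, cat_tab$compound_id))
  peaks <- peak_table(rbind(masses, blank_m), blank_subtracted = FALSE)

  samples <- data.frame(
    sample_id = c(ids, blank_ids),
    experiment = truth$experiment,
    block_id = c(sprintf("B%d", block), rep("blank", truth$n_blanks)),
    branch_id = c(branch_ids, blank_ids),
    sample_type = c(rep("branch", n), rep("blank", truth$n_blanks)),
    larval_density = c(dens, rep(NA_real_, truth$n_blanks)),
    inflow_rate = truth$inflow_rate,
    cartridge_flow = truth$cartridge_flow,
    duration = truth$duration,
    temperature = round(stats::rnorm(n + truth$n_blanks, 18, 3), 1),
    rh = round(stats::runif(n + truth$n_blanks, 40, 75), 1),
    par = round(stats::runif(n + truth$n_blanks, 200, 1200)),
    stringsAsFactors = FALSE)

  leaves <- data.frame(
    branch_id = branch_ids,
    leaf_area_total = la_remaining,
    leaf_area_eaten = eaten_area,
    percent_eaten = pct,
    imputed = FALSE,
    fresh_mass = round(la_remaining * 0.02, 3),
    dry_mass = round(la_remaining * 0.008, 3),
    stringsAsFactors = FALSE)

  compounds <- data.frame(
    compound_id = cat_tab$compound_id,
    name = cat_tab$name,
    compound_class = cat_tab$compound_class,
    match_factor = rep_len(c(905L, 862L, 934L, 881L, 918L), p),
    id_basis = ifelse(cat_tab$compound_id %in%
                        c("linalool", "alpha_pinene",
                          "e_beta_caryophyllene", "e_2_hexenal",
                          "hexanal", "toluene", "dmnt"),
                      "pure_standard", "library_tentative"),
    proxy_standard = unname(default_proxies()[cat_tab$compound_class]),
    stringsAsFactors = FALSE)

  structure(list(data = bvoc_dataset(peaks, samples, leaves, compounds),
                 emissions = er,
                 groups = groups,
                 truth = truth),
            class = "bvoc_simulation")
}

#' @export
print.bvoc_simulation <- function(x, ...) {
  cat("Synthetic enclosure experiment", x$truth$experiment, "\n")
  print(x$data)
  cat("  damage groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                        table(x$groups)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Integration index of the generating correlation structure
#'
#' Closed-form eigenvalue-variance index of the noise correlation matrix the
#' generator uses for a damage group. With a single latent factor of loading
#' `lambda` on all p compounds, pairwise correlations are `lambda^2` and the
#' index is `p * lambda^4` (the equicorrelated closed form `p * r^2`).
#'
#' @param truth a [synthetic_truth()].
#' @param group `"low"` or `"high"`.
#' @return Expected `int_raw`; the generating correlation matrix is attached
#'   as attribute `R_true`.
#' @export
theoretical_integration <- function(truth, group = c("low", "high")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  group <- match.arg(group)
  lambda <- if (group == "low") truth$loading_low else truth$loading_high
  p <- nrow(truth$catalog)
  r <- lambda^2
  R_true <- matrix(r, p, p)
  diag(R_true) <- 1
  ev <- eigen(R_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) config_error("loadings do not define a valid correlation matrix")
  structure(p * r^2, R_true = R_true)
}
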
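#' Leaf-area-normalised emission rate
#'
#' Converts a cartridge mass to an emission rate via the enclosure mass
#' balance `ER = (C_out - C_in) * Q / LA`, with `C_in = 0` for filtered inlet
#' air. `C_out` is the compound concentration in the sampled air: the
#' cartridge mass divided by the air volume pulled through the cartridge
#' (`cartridge_flow * duration`). `Q` is the enclosure inflow rate converted
#' to L h^-1.
#'
#' @param mass collected mass, ng per cartridge (scalar or vector).
#' @param cartridge_flow flow through the adsorbent cartridge, mL min^-1.
#' @param duration sampling time, min.
#' @param inflow enclosure inflow rate Q, mL min^-1.
#' @param leaf_area branch leaf area LA, cm^2.
#' @return Emission rate, ng cm^-2 leaf area h^-1.
#' @examples
#' emission_rate(90, cartridge_flow = 200, duration = 15,
#'               inflow = 300, leaf_area = 200)  # 2.7
#' @export
emission_rate <- function(mass, cartridge_flow, duration, inflow, leaf_area) {
  if (any(leaf_area <= 0)) integrity_error("leaf_area must be positive")
  if (any(duration <= 0)) integrity_error("duration must be positive")
  if (any(cartridge_flow <= 0) || any(inflow <= 0)) {
    integrity_error("flows must be positive")
  }
  sampled_volume_l <- cartridge_flow * duration / 1000   # L through cartridge
  c_out <- mass / sampled_volume_l                        # ng L^-1
  q_l_per_h <- inflow * 60 / 1000                         # L h^-1
  c_out * q_l_per_h / leaf_area
}

# inverse of emission_rate(): cartridge mass implied by an emission rate
mass_from_rate <- function(rate, cartridge_flow, duration, inflow, leaf_area) {
  rate * leaf_area * (cartridge_flow * duration / 1000) / (inflow * 60 / 1000)
}

#' Impute missing leaf areas by treatment mean
#'
#' Branches whose leaf scans failed get the mean measured leaf area of their
#' treatment group; imputed records are flagged.
#'
#' @param leaves leaf record table (`leaf_area_total` may contain `NA`).
#' @param treatment vector of treatment labels, one per leaf record.
#' @return Leaf table with `leaf_area_total` complete and `imputed` flags set.
#' @export
impute_leaf_area <- function(leaves, treatment) {
  stopifnot(length(treatment) == nrow(leaves))
  if (!"imputed" %in% names(leaves)) leaves$imputed <- FALSE
  missing <- is.na(leaves$leaf_area_total)
  if (!any(missing)) return(leaves)
  means <- tapply(leaves$leaf_area_total, treatment, mean, na.rm = TRUE)
  if (any(!is.finite(means[unique(as.character(treatment[missing]))]))) {
    integrity_error("a treatment group has no measured leaf areas to impute from")
  }
  leaves$leaf_area_total[missing] <- means[as.character(treatment[missing])]
  leaves$imputed[missing] <- TRUE
  fill <- missing & !is.na(leaves$leaf_area_eaten)
  leaves$percent_eaten[fill] <- percent_eaten(leaves$leaf_area_total[fill],
                                              leaves$leaf_area_eaten[fill])
  validate_leaves(leaves)
}

#' Build the emission-rate matrix for a dataset
#'
#' Applies [emission_rate()] row-wise using each branch sample's flows,
#' duration, and its branch's leaf area. Blank samples are excluded.
#'
#' @param data a [bvoc_dataset()] whose peaks are blank-subtracted.
#' @return Numeric matrix, branch samples x compounds, ng cm^-2 h^-1.
#' @export
build_emission_matrix <- function(data) {
  stopifnot(inherits(data, "bvoc_dataset"))
  if (!is_blank_subtracted(data$peaks)) {
    warning("building emission matrix from peaks without blank subtraction")
  }
  branch <- data$samples[data$samples$sample_type == "branch", ]
  branch <- branch[branch$sample_id %in% rownames(data$peaks), ]
  la <- data$leaves$leaf_area_total[match(branch$branch_id,
                                          data$leaves$branch_id)]
  if (anyNA(la)) integrity_error("missing leaf area for a branch sample")
  m <- unclass(data$peaks)[branch$sample_id, , drop = FALSE]
  out <- m * emission_rate(1, branch$cartridge_flow, branch$duration,
                           branch$inflow_rate, la)
  rownames(out) <- branch$sample_id
  out
}

#' Aggregate compound emission rates into group totals
#'
#' Sums per-sample emission rates within each compound group (MT, HT_DMNT,
#' SQT, GLV, BENZENOID, OTHER) and appends the grand total. Group totals sum
#' exactly to the grand total.
#'
#' @param emissions samples x compounds emission matrix.
#' @param compounds compound descriptor table covering every column.
#' @return data.frame with `sample_id`, one column per group, and `total`.
#' @export
aggregate_groups <- function(emissions, compounds) {
  compounds <- validate_compounds(compounds)
  cls <- compounds$compound_class[match(colnames(emissions),
                                        compounds$compound_id)]
  if (anyNA(cls)) {
    integrity_error(sprintf(
      "unclassified compound(s): %s",
      paste(colnames(emissions)[is.na(cls)], collapse = ", ")))
  }
  out <- sapply(BVOC_CLASSES, function(k) {
    rowSums(emissions[, cls == k, drop = FALSE])
  })
  if (nrow(emissions) == 1L) out <- matrix(out, nrow = 1L,
                                           dimnames = list(NULL, BVOC_CLASSES))
  df <- data.frame(sample_id = rownames(emissions), out,
                   total = rowSums(emissions), check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
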
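#' @keywords internal
"_PACKAGE"

#' Recognised BVOC compound groups
#'
#' Monoterpenes (MT), the homoterpene DMNT (HT_DMNT), sesquiterpenes (SQT),
#' green leaf volatiles (GLV), benzenoids, and a residual class for compounds
#' outside those groups.
#'
#' @export
BVOC_CLASSES <- c("MT", "HT_DMNT", "SQT", "GLV", "BENZENOID", "OTHER")

# classed conditions so callers can distinguish schema from integrity problems
bvoc_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "bvoc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

schema_error    <- function(msg) bvoc_stop(msg, "bvoc_schema_error")
integrity_error <- function(msg) bvoc_stop(msg, "bvoc_integrity_error")
config_error    <- function(msg) bvoc_stop(msg, "bvoc_config_error")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    schema_error(sprintf("%s table is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Construct a peak table
#'
#' A peak table holds collected compound masses (ng per cartridge) as a
#' numeric matrix with sample ids as row names and compound ids as column
#' names. The `blank_subtracted` attribute records whether blank levels have
#' already been removed.
#'
#' @param values numeric matrix, samples x compounds, with dimnames.
#' @param blank_subtracted logical flag.
#' @return A `peak_table` object (numeric matrix subclass).
#' @export
peak_table <- function(values, blank_subtracted = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    schema_error("peak table values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    schema_error("peak table needs sample ids as rownames and compound ids as colnames")
  }
  if (anyDuplicated(rownames(values)) > 0L) {
    integrity_error("duplicate sample_id in peak table")
  }
  if (anyDuplicated(colnames(values)) > 0L) {
    integrity_error("duplicate compound_id in peak table")
  }
  if (any(!is.finite(values))) {
    integrity_error("peak table contains non-finite values")
  }
  if (isTRUE(blank_subtracted) && any(values < 0)) {
    integrity_error("blank-subtracted peak table contains negative values")
  }
  structure(values,
            blank_subtracted = isTRUE(blank_subtracted),
            class = c("peak_table", class(values)))
}

is_blank_subtracted <- function(peaks) isTRUE(attr(peaks, "blank_subtracted"))

#' Validate a compound descriptor table
#'
#' Required columns: `compound_id`, `name`, `compound_class` (one of
#' [BVOC_CLASSES]), `match_factor` (0-1000), `id_basis`
#' (`"pure_standard"` or `"library_tentative"`), `proxy_standard`.
#'
#' @param df data.frame of compound descriptors.
#' @return The validated data.frame, invisibly classed.
#' @export
validate_compounds <- function(df) {
  require_columns(df, c("compound_id", "name", "compound_class",
                        "match_factor", "id_basis", "proxy_standard"),
                  "compound")
  if (anyDuplicated(df$compound_id) > 0L) {
    integrity_error("duplicate compound_id in compound table")
  }
  bad_class <- setdiff(unique(df$compound_class), BVOC_CLASSES)
  if (length(bad_class) > 0L) {
    integrity_error(sprintf("unknown compound_class: %s",
                            paste(bad_class, collapse = ", ")))
  }
  if (any(df$match_factor < 0 | df$match_factor > 1000, na.rm = TRUE)) {
    integrity_error("match_factor must lie in [0, 1000]")
  }
  bad_basis <- setdiff(unique(df$id_basis), c("pure_standard", "library_tentative"))
  if (length(bad_basis) > 0L) {
    integrity_error(sprintf("unknown id_basis: %s", paste(bad_basis, collapse = ", ")))
  }
  tentative <- df$id_basis == "library_tentative"
  if (any(tentative & (is.na(df$proxy_standard) | !nzchar(df$proxy_standard)))) {
    integrity_error("library-tentative compounds must name a proxy_standard")
  }
  df
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `experiment`, `block_id`, `branch_id`,
#' `sample_type` (`"branch"` or `"blank"`), `larval_density`, `inflow_rate`,
#' `cartridge_flow`, `duration` (all flows in mL min^-1, duration in min).
#' Optional: `temperature`, `rh`, `par`.
#'
#' @param df data.frame of sample records.
#' @return The validated data.frame.
#' @export
validate_samples <- function(df) {
  require_columns(df, c("sample_id", "experiment", "block_id", "branch_id",
                        "sample_type", "larval_density", "inflow_rate",
                        "cartridge_flow", "duration"),
                  "sample")
  if (anyDuplicated(df$sample_id) > 0L) {
    integrity_error("duplicate sample_id in sample table")
  }
  bad_type <- setdiff(unique(df$sample_type), c("branch", "blank"))
  if (length(bad_type) > 0L) {
    integrity_error(sprintf("unknown sample_type: %s", paste(bad_type, collapse = ", ")))
  }
  if (any(df$duration <= 0, na.rm = TRUE)) {
    integrity_error("sampling duration must be positive")
  }
  if (any(df$cartridge_flow > df$inflow_rate, na.rm = TRUE)) {
    integrity_error("cartridge_flow cannot exceed inflow_rate")
  }
  branch <- df$sample_type == "branch"
  if (any(branch & (is.na(df$larval_density) | df$larval_density < 0))) {
    integrity_error("branch samples need a non-negative larval_density")
  }
  df
}

#' Validate a leaf record table
#'
#' Required columns: `branch_id`, `leaf_area_total` (measured remaining leaf
#' area, cm^2, used as LA in the emission-rate equation), `leaf_area_eaten`
#' (cm^2). Optional: `percent_eaten`, `imputed`, `fresh_mass`, `dry_mass`.
#' `percent_eaten` is expressed relative to the reconstructed original leaf
#' area (remaining + eaten); missing values are filled in.
#'
#' @param df data.frame of leaf records.
#' @return The validated data.frame with `percent_eaten` populated.
#' @export
validate_leaves <- function(df) {
  require_columns(df, c("branch_id", "leaf_area_total", "leaf_area_eaten"),
                  "leaf")
  if (anyDuplicated(df$branch_id) > 0L) {
    integrity_error("duplicate branch_id in leaf table")
  }
  present <- !is.na(df$leaf_area_total)
  if (any(present & df$leaf_area_total <= 0)) {
    integrity_error("leaf_area_total must be positive")
  }
  if (any(df$leaf_area_eaten < 0, na.rm = TRUE)) {
    integrity_error("leaf_area_eaten cannot be negative")
  }
  if (any(df$leaf_area_eaten > df$leaf_area_total, na.rm = TRUE)) {
    integrity_error("leaf_area_eaten cannot exceed leaf_area_total")
  }
  if (!"imputed" %in% names(df)) df$imputed <- FALSE
  if (!"percent_eaten" %in% names(df)) df$percent_eaten <- NA_real_
  fill <- is.na(df$percent_eaten)
  df$percent_eaten[fill] <- percent_eaten(df$leaf_area_total[fill],
                                          df$leaf_area_eaten[fill])
  if (all(c("fresh_mass", "dry_mass") %in% names(df))) {
    both <- !is.na(df$fresh_mass) & !is.na(df$dry_mass)
    if (any(both & df$dry_mass > df$fresh_mass)) {
      integrity_error("dry_mass cannot exceed fresh_mass")
    }
  }
  df
}

#' Percentage of leaf area eaten
#'
#' Computed relative to the reconstructed original leaf area, i.e. the
#' measured remaining area plus the eaten area.
#'
#' @param remaining measured remaining leaf area, cm^2.
#' @param eaten eaten leaf area, cm^2.
#' @return percentage in `[0, 100)`.
#' @export
percent_eaten <- function(remaining, eaten) {
  100 * eaten / (remaining + eaten)
}

#' Bundle the four input tables into one dataset object
#'
#' Cross-checks referential integrity: every peak-table row must have a
#' sample record, every branch sample a leaf record, and every peak-table
#' column a compound descriptor.
#'
#' @param peaks a [peak_table()].
#' @param samples sample metadata (see [validate_samples()]).
#' @param leaves leaf records (see [validate_leaves()]).
#' @param compounds compound descriptors (see [validate_compounds()]).
#' @return A `bvoc_dataset` list.
#' @export
bvoc_dataset <- function(peaks, samples, leaves, compounds) {
  samples   <- validate_samples(samples)
  leaves    <- validate_leaves(leaves)
  compounds <- validate_compounds(compounds)
  if (!inherits(peaks, "peak_table")) {
    peaks <- peak_table(as.matrix(peaks), blank_subtracted = FALSE)
  }
  orphan_samples <- setdiff(rownames(peaks), samples$sample_id)
  if (length(orphan_samples) > 0L) {
    integrity_error(sprintf(
      "peak table rows without sample metadata: %s",
      paste(orphan_samples, collapse = ", ")))
  }
  orphan_compounds <- setdiff(colnames(peaks), compounds$compound_id)
  if (length(orphan_compounds) > 0L) {
    integrity_error(sprintf(
      "peak table columns without compound descriptors: %s",
      paste(orphan_compounds, collapse = ", ")))
  }
  branch_ids <- samples$branch_id[samples$sample_type == "branch" &
                                    samples$sample_id %in% rownames(peaks)]
  missing_leaf <- setdiff(branch_ids, leaves$branch_id)
  if (length(missing_leaf) > 0L) {
    integrity_error(sprintf(
      "branch samples without leaf records: %s",
      paste(missing_leaf, collapse = ", ")))
  }
  structure(list(peaks = peaks, samples = samples,
                 leaves = leaves, compounds = compounds),
            class = "bvoc_dataset")
}

#' @export
print.bvoc_dataset <- function(x, ...) {
  n_branch <- sum(x$samples$sample_type == "branch")
  n_blank  <- sum(x$samples$sample_type == "blank")
  cat("BVOC dataset:", nrow(x$peaks), "cartridges x",
      ncol(x$peaks), "compounds\n")
  cat("  samples:", n_branch, "branch,", n_blank, "blank;",
      "experiments:", paste(unique(x$samples$experiment), collapse = ", "), "\n")
  cat("  blank subtracted:", is_blank_subtracted(x$peaks), "\n")
  invisible(x)
}
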
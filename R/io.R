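# CSV dialect: comma-separated, UTF-8, mandatory header, '.' decimal.
# Lines starting with '#' carry run metadata (config hash, seed) and are
# skipped on read.

read_bvoc_csv <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("input file not found: %s", path))
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read the four pipeline input tables
#'
#' @param paths named character vector or list with elements `peaks`,
#'   `samples`, `leaves`, `compounds`, each a CSV path. The peaks file is
#'   wide: a `sample_id` column followed by one numeric column per compound.
#' @param blank_subtracted whether the peak values already had blanks removed.
#' @return A [bvoc_dataset()].
#' @export
read_bvoc_tables <- function(paths, blank_subtracted = FALSE) {
  needed <- c("peaks", "samples", "leaves", "compounds")
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0L) {
    config_error(sprintf("paths must name files for: %s",
                         paste(missing, collapse = ", ")))
  }
  peaks_df  <- read_bvoc_csv(paths[["peaks"]])
  samples   <- read_bvoc_csv(paths[["samples"]])
  leaves    <- read_bvoc_csv(paths[["leaves"]])
  compounds <- read_bvoc_csv(paths[["compounds"]])
  if ("proxy_standard" %in% names(compounds)) {
    # empty proxy fields (pure standards) round-trip as NA in CSV
    compounds$proxy_standard <- as.character(compounds$proxy_standard)
    compounds$proxy_standard[is.na(compounds$proxy_standard)] <- ""
  }

  require_columns(peaks_df, "sample_id", "peak")
  ids <- peaks_df$sample_id
  m <- as.matrix(peaks_df[setdiff(names(peaks_df), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  peaks <- peak_table(m, blank_subtracted = blank_subtracted)
  bvoc_dataset(peaks, samples, leaves, compounds)
}

write_csv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (nm in names(meta)) {
      writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

peaks_to_df <- function(peaks) {
  data.frame(sample_id = rownames(peaks),
             as.data.frame(unclass(peaks)[, , drop = FALSE],
                           check.names = FALSE),
             check.names = FALSE)
}

#' Write a dataset back to CSV files
#'
#' Inverse of [read_bvoc_tables()] (round-trip identity on valid data).
#' Optional metadata (e.g. seed and config hash) is written as `#`-prefixed
#' header lines on every file.
#'
#' @param data a [bvoc_dataset()].
#' @param dir output directory (created if needed).
#' @param meta optional named list written as comment headers.
#' @return Named character vector of the paths written.
#' @export
write_bvoc_tables <- function(data, dir, meta = NULL) {
  stopifnot(inherits(data, "bvoc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             samples = file.path(dir, "samples.csv"),
             leaves = file.path(dir, "leaves.csv"),
             compounds = file.path(dir, "compounds.csv"))
  write_csv_with_meta(peaks_to_df(data$peaks), paths[["peaks"]], meta)
  write_csv_with_meta(data$samples, paths[["samples"]], meta)
  write_csv_with_meta(data$leaves, paths[["leaves"]], meta)
  write_csv_with_meta(data$compounds, paths[["compounds"]], meta)
  paths
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, decided by file extension.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    config_error(sprintf("unsupported config format: .%s (use YAML or JSON)", ext))
  }
}

# Stable fingerprint of a configuration: md5 of its canonical JSON form.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
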
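#' Subtract mean blank levels from sample peaks
#'
#' Blank cartridges capture compounds contributed by the sampling materials
#' and analysis system. Their per-compound mean is removed from every sample
#' and the result floored at zero. Compounds seen only in blanks are ignored
#' with a warning.
#'
#' @param peaks [peak_table()] of branch samples (ng per cartridge).
#' @param blanks [peak_table()] (or matrix) of blank cartridges sharing the
#'   sample columns.
#' @return A blank-subtracted [peak_table()].
#' @export
subtract_blanks <- function(peaks, blanks) {
  if (nrow(blanks) == 0L) schema_error("no blank samples supplied")
  extra <- setdiff(colnames(blanks), colnames(peaks))
  if (length(extra) > 0L) {
    warning(sprintf("compound(s) present only in blanks ignored: %s",
                    paste(extra, collapse = ", ")))
  }
  blank_mean <- rep(0, ncol(peaks))
  names(blank_mean) <- colnames(peaks)
  shared <- intersect(colnames(peaks), colnames(blanks))
  blank_mean[shared] <- colMeans(blanks[, shared, drop = FALSE])
  out <- sweep(unclass(peaks), 2L, blank_mean, "-")
  out[out < 0] <- 0
  peak_table(out, blank_subtracted = TRUE)
}

#' Filter compounds by presence and identification confidence
#'
#' A compound is retained when it is present (value > 0 after blank
#' subtraction) in at least `presence_frac` of the experiment's samples AND
#' either its library match factor exceeds `mf_min` (strict) or it was
#' identified against a pure standard (which bypasses the match-factor gate).
#'
#' @param peaks blank-subtracted [peak_table()] for one experiment.
#' @param compounds compound descriptor table.
#' @param presence_frac minimum attained presence fraction (default 0.30).
#' @param mf_min match-factor threshold, exceeded strictly (default 800).
#' @return list with `peaks` (filtered table) and `exclusions` (data.frame
#'   `compound_id`, `reason` in `{"presence", "match_factor"}`).
#' @export
filter_compounds <- function(peaks, compounds, presence_frac = 0.30,
                             mf_min = 800) {
  if (nrow(peaks) == 0L || ncol(peaks) == 0L) {
    schema_error("cannot filter an empty peak table")
  }
  compounds <- validate_compounds(compounds)
  desc <- compounds[match(colnames(peaks), compounds$compound_id), ]
  if (anyNA(desc$compound_id)) {
    integrity_error("peak table contains compounds without descriptors")
  }
  presence <- colMeans(unclass(peaks) > 0)
  ok_presence <- presence >= presence_frac
  ok_mf <- desc$id_basis == "pure_standard" | desc$match_factor > mf_min
  keep <- ok_presence & ok_mf
  # presence is the primary exclusion reason; MF only reported for compounds
  # that met the presence rule
  reason <- ifelse(!ok_presence, "presence", "match_factor")
  exclusions <- data.frame(compound_id = colnames(peaks)[!keep],
                           reason = unname(reason[!keep]),
                           row.names = NULL,
                           stringsAsFactors = FALSE)
  list(peaks = peak_table(unclass(peaks)[, keep, drop = FALSE],
                          blank_subtracted = is_blank_subtracted(peaks)),
       exclusions = exclusions)
}

#' Default proxy standards per compound group
#'
#' Compounds lacking their own pure standard are quantified against a class
#' proxy: alpha-pinene for monoterpenes and DMNT, (E)-beta-caryophyllene for
#' sesquiterpenes, hexanal for green leaf volatiles, toluene for benzenoids
#' and other compounds.
#'
#' @return Named character vector, class -> proxy id.
#' @export
default_proxies <- function() {
  c(MT = "alpha_pinene", HT_DMNT = "alpha_pinene",
    SQT = "e_beta_caryophyllene", GLV = "hexanal",
    BENZENOID = "toluene", OTHER = "toluene")
}

#' Quantify peak responses against proxy standards
#'
#' Rescales each compound column by the response factor (ng per response
#' unit) of its proxy standard. Quantification is linear and class-consistent.
#'
#' @param peaks [peak_table()] of instrument responses.
#' @param compounds compound descriptor table (`proxy_standard` column names
#'   each compound's proxy).
#' @param response_factors named numeric vector, proxy id -> ng per unit.
#' @return A [peak_table()] in ng per cartridge.
#' @export
quantify_compounds <- function(peaks, compounds, response_factors) {
  compounds <- validate_compounds(compounds)
  desc <- compounds[match(colnames(peaks), compounds$compound_id), ]
  if (anyNA(desc$compound_id)) {
    integrity_error("peak table contains compounds without descriptors")
  }
  proxy <- ifelse(desc$id_basis == "pure_standard" &
                    (is.na(desc$proxy_standard) | !nzchar(desc$proxy_standard)),
                  desc$compound_id, desc$proxy_standard)
  unknown <- setdiff(proxy, names(response_factors))
  if (length(unknown) > 0L) {
    first <- colnames(peaks)[match(unknown[1L], proxy)]
    config_error(sprintf(
      "no response factor for proxy '%s' (compound '%s')", unknown[1L], first))
  }
  f <- response_factors[proxy]
  out <- sweep(unclass(peaks), 2L, f, "*")
  peak_table(out, blank_subtracted = is_blank_subtracted(peaks))
}
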
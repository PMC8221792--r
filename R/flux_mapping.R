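#' Map genome-scale fluxes onto a 13C reaction namespace
#'
#' A coarse 13C flux-analysis model rarely maps one-to-one onto a
#' genome-scale model: one 13C reaction may correspond to several
#' genome-scale reactions (their fluxes are summed or subtracted depending
#' on direction), equivalent reactions in several compartments are summed,
#' and lumped steps are compared against the net flux of their
#' constituents. All three cases reduce to a signed many-to-one sum, which
#' is what the mapping table encodes.
#'
#' @param v a `flux_vector`.
#' @param table mapping data.frame with columns `c13_id`, `gsmm_id`, `sign`
#'   (see [read_mapping_table()]).
#' @return named numeric vector of mapped fluxes, one per `c13_id`.
#' @export
map_fluxes <- function(v, table) {
  stopifnot(inherits(v, "flux_vector"))
  missing <- setdiff(table$gsmm_id, names(v$fluxes))
  if (length(missing))
    stop("mapping entry references unknown reaction '", missing[1], "'")
  contrib <- table$sign * v$fluxes[table$gsmm_id]
  out <- tapply(contrib, table$c13_id, sum)
  stats::setNames(as.numeric(out), names(out))[unique(table$c13_id)]
}

#' Drop near-zero experimental fluxes
#'
#' Removes 13C entries whose flux magnitude is below a fraction of the
#' dataset's maximum absolute flux (`|v_i| / max|v| < threshold`). Small
#' fluxes carry huge relative errors while their absolute deviations are
#' negligible, which distorts median-relative-error profiles; the 1%
#' default reproduces the standard filter used for mATP estimation.
#'
#' @param data a `c13_dataset`.
#' @param threshold fraction of the maximum absolute flux (default 0.01).
#' @return the filtered `c13_dataset` (subset of input rows).
#' @export
filter_small_fluxes <- function(data, threshold = 0.01) {
  stopifnot(inherits(data, "c13_dataset"))
  vmax <- max(abs(data$fluxes$value))
  if (vmax == 0) {
    warning("all experimental fluxes are zero; empty dataset returned")
    data$fluxes <- data$fluxes[0, , drop = FALSE]
    return(data)
  }
  keep <- abs(data$fluxes$value) / vmax >= threshold
  data$fluxes <- data$fluxes[keep, , drop = FALSE]
  data
}
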
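#' Extracellular exchange-rate dataset
#'
#' Measured uptake/secretion rates for one cultivation, with the sign
#' convention uptake < 0 < secretion, plus growth rate and (for producer
#' cell lines) productivity and product amino-acid composition.
#'
#' @param dataset_id identifier.
#' @param rates data.frame with columns `metabolite` (compartment-free id),
#'   `value`, `sd` (both mmol gDW^-1 h^-1) and logical `is_aa`.
#' @param growth_rate,growth_sd growth rate (h^-1).
#' @param productivity,productivity_sd product secretion (mmol gDW^-1 h^-1);
#'   0 for non-producers.
#' @param product_aa_composition named mole-fraction vector (sums to 1) when
#'   `productivity > 0`.
#' @param dry_mass cell dry mass in pg; the CHO average 264 pg by default.
#' @return object of class `exchange_dataset`.
#' @export
exchange_dataset <- function(dataset_id, rates, growth_rate, growth_sd = 0,
                             productivity = 0, productivity_sd = 0,
                             product_aa_composition = NULL,
                             dry_mass = 264) {
  stopifnot(is.data.frame(rates),
            all(c("metabolite", "value", "sd") %in% names(rates)))
  if (is.null(rates$is_aa)) {
    aa <- c(paste0(c("ala", "arg", "asn", "asp", "cys", "gln", "glu",
                     "his", "ile", "leu", "lys", "met", "phe", "pro",
                     "ser", "thr", "trp", "tyr", "val"), "__L"), "gly")
    rates$is_aa <- rates$metabolite %in% aa
  }
  if (any(rates$sd < 0)) stop("negative SD in exchange rates")
  if (productivity > 0) {
    if (is.null(product_aa_composition) ||
        abs(sum(product_aa_composition) - 1) > 1e-6)
      stop("producer datasets need an amino-acid composition summing to 1")
  }
  structure(list(dataset_id = dataset_id, rates = rates,
                 growth_rate = growth_rate, growth_sd = growth_sd,
                 productivity = productivity,
                 productivity_sd = productivity_sd,
                 product_aa_composition = product_aa_composition,
                 dry_mass = dry_mass),
            class = "exchange_dataset")
}

#' @export
print.exchange_dataset <- function(x, ...) {
  cat("<exchange_dataset> ", x$dataset_id, ": ", nrow(x$rates),
      " rates, growth ", signif(x$growth_rate, 3), " h^-1",
      if (x$productivity > 0) " (producer)", "\n", sep = "")
  invisible(x)
}

#' Intracellular 13C flux dataset
#'
#' Fluxes in the coarse reaction namespace of a 13C flux-analysis model,
#' with confidence intervals, each tagged with a central-carbon subsystem,
#' plus the companion extracellular dataset.
#'
#' @param dataset_id identifier.
#' @param fluxes data.frame with columns `c13_id`, `value`, `ci_low`,
#'   `ci_high`, `subsystem`.
#' @param exchange the companion [exchange_dataset()].
#' @return object of class `c13_dataset`.
#' @export
c13_dataset <- function(dataset_id, fluxes, exchange) {
  stopifnot(all(c("c13_id", "value", "ci_low", "ci_high", "subsystem")
                %in% names(fluxes)))
  bad <- fluxes$ci_low > fluxes$value | fluxes$value > fluxes$ci_high
  if (any(bad, na.rm = TRUE))
    stop("confidence interval does not bracket the value for ",
         fluxes$c13_id[which(bad)[1]])
  structure(list(dataset_id = dataset_id, fluxes = fluxes,
                 exchange = exchange),
            class = "c13_dataset")
}

#' @export
print.c13_dataset <- function(x, ...) {
  cat("<c13_dataset> ", x$dataset_id, ": ", nrow(x$fluxes),
      " fluxes in ", length(unique(x$fluxes$subsystem)),
      " subsystems\n", sep = "")
  invisible(x)
}

#' Read / write a 13C-to-GSMM mapping table
#'
#' Three-column tab-separated format (`c13_id`, `gsmm_id`, `sign`), several
#' rows per 13C reaction: a +1/-1 signed, many-to-one correspondence that
#' expresses compartment sums, lumped-step net fluxes and multi-reaction
#' sums with one mechanism.
#'
#' @param path file path.
#' @return data.frame with columns `c13_id`, `gsmm_id`, `sign`.
#' @export
read_mapping_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("c13_id", "gsmm_id", "sign") %in% names(tab)))
    stop("mapping table needs columns c13_id, gsmm_id, sign")
  if (!all(tab$sign %in% c(-1, 1)))
    stop("mapping signs must be +1 or -1")
  tab
}

#' @rdname read_mapping_table
#' @param table mapping data.frame.
#' @export
write_mapping_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
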
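#' Minimal essential amino-acid uptakes sustaining measured growth
#'
#' With growth rate (and productivity, for producers) fixed to the
#' experimental values and all other exchanges unconstrained, the uptake
#' of each essential amino acid is minimized in magnitude one at a time.
#' Because uptake is negative, minimizing the magnitude means maximizing
#' the exchange flux towards zero with secretion disallowed.
#'
#' @param model a `metabolic_model`.
#' @param data an [exchange_dataset()] (only growth and productivity are
#'   used).
#' @param essential_ids compartment-free amino-acid ids; defaults to the
#'   model's `essential_aas`.
#' @param biomass_id biomass variant.
#' @return named vector of minimal uptake rates (non-positive).
#' @export
minimal_essential_uptakes <- function(model, data, essential_ids = NULL,
                                      biomass_id = NULL) {
  essential_ids <- essential_ids %||% model$essential_aas
  if (is.null(essential_ids)) stop("no essential amino acids declared")
  biomass_id <- biomass_id %||% model$objective$reaction
  m <- select_biomass(model, biomass_id)
  if (data$productivity > 0) {
    m <- add_product_synthesis_reaction(m, data$product_aa_composition)
    m <- fix_flux(m, "EX_product_e", data$productivity)
  }
  m <- fix_flux(m, biomass_id, data$growth_rate)
  if (fba(m, m$maintenance_id, "max")$status != "optimal")
    stop("experimental growth rate infeasible even with all uptakes ",
         "free: model/data inconsistency")
  out <- vapply(essential_ids, function(aa) {
    ex <- find_exchange(m, aa, required = TRUE)
    sol <- fba(set_bounds(m, ex, -1000, 0), ex, "max")
    if (sol$status != "optimal")
      stop("minimization of ", aa, " uptake ", sol$status)
    sol$objective_value
  }, 0)
  pmin(out, 0)
}

#' Reconcile measured and minimal required uptakes
#'
#' Where the measured uptake magnitude is below the model's minimum
#' requirement for the measured growth rate, the computed minimal uptake
#' replaces it (and the adjustment is logged); otherwise the measurement
#' stands. Applicable to essential amino acids and to conditionally
#' limiting ones such as tyrosine or cysteine.
#'
#' @param measured,minimal named vectors of uptake rates (negative), with
#'   shared names.
#' @return list with `uptakes` (named vector) and `adjustments`
#'   (data.frame `metabolite`, `measured`, `adjusted`; zero rows when
#'   nothing changed).
#' @export
reconcile_uptakes <- function(measured, minimal) {
  keys <- names(minimal)
  stopifnot(!is.null(keys), all(keys %in% names(measured)))
  out <- measured[keys]
  adj <- abs(out) < abs(minimal[keys])
  log <- data.frame(metabolite = keys[adj],
                    measured = unname(out[adj]),
                    adjusted = unname(minimal[keys][adj]))
  out[adj] <- minimal[keys][adj]
  list(uptakes = out, adjustments = log)
}

#' Parsimonious FBA with an uptake objective function
#'
#' Implements the two-step uptake-objective protocol: nonessential
#' uptakes, secretions, growth and productivity are fixed to the
#' experimental values; essential amino-acid uptakes are fixed to the
#' reconciled (measured or minimal required) values; the chosen
#' nonessential objective metabolite is left free and its uptake magnitude
#' is minimized by parsimonious FBA.
#'
#' @param model a `metabolic_model`.
#' @param data an [exchange_dataset()].
#' @param objective_metabolite compartment-free id of the nonessential
#'   metabolite whose uptake is minimized (e.g. `"glc__D"`).
#' @param essential_ids essential amino acids; defaults to the model's
#'   `essential_aas`.
#' @param biomass_id biomass variant.
#' @param matp optional maintenance-ATP value fixed during the simulation.
#' @return object of class `uof_result`: `objective_metabolite`,
#'   `minimal_uptake`, `measured_uptake`, `fluxes` (a `flux_vector`), and
#'   `adjusted_constraints` (the reconciliation log).
#' @export
uof_pfba <- function(model, data, objective_metabolite,
                     essential_ids = NULL, biomass_id = NULL,
                     matp = NULL) {
  essential_ids <- essential_ids %||% model$essential_aas
  if (objective_metabolite %in% essential_ids)
    stop("'", objective_metabolite, "' is essential; the uptake objective ",
         "applies to nonessential metabolites")
  biomass_id <- biomass_id %||% model$objective$reaction
  minimal <- minimal_essential_uptakes(model, data, essential_ids,
                                       biomass_id)
  measured <- stats::setNames(data$rates$value, data$rates$metabolite)
  present <- intersect(names(minimal), names(measured))
  rec <- reconcile_uptakes(measured[present], minimal[present])

  m <- prepare_condition(model, data, biomass_id, policy = "point")
  m <- fix_flux(m, biomass_id, data$growth_rate)
  for (aa in names(rec$uptakes))
    m <- fix_flux(m, find_exchange(m, aa, required = TRUE),
                  rec$uptakes[[aa]])
  if (!is.null(matp)) m <- fix_flux(m, m$maintenance_id, matp)
  obj_ex <- find_exchange(m, objective_metabolite, required = TRUE)
  m <- set_bounds(m, obj_ex, -1000, 0)
  sol <- pfba(m, obj_ex, "max")
  if (sol$status != "optimal") {
    blocker <- diagnose_infeasibility(m, obj_ex, measured, essential_ids)
    stop("uptake-objective simulation ", sol$status,
         "; relaxation probe implicates: ", blocker)
  }
  structure(list(objective_metabolite = objective_metabolite,
                 minimal_uptake = sol$objective_value,
                 measured_uptake = unname(measured[objective_metabolite]),
                 fluxes = sol,
                 adjusted_constraints = rec$adjustments),
            class = "uof_result")
}

#' @export
print.uof_result <- function(x, ...) {
  cat("<uof_result> min ", x$objective_metabolite, " uptake ",
      signif(x$minimal_uptake, 4),
      if (!is.na(x$measured_uptake))
        paste0(" (measured ", signif(x$measured_uptake, 4), ")"),
      ", ", nrow(x$adjusted_constraints), " adjusted constraints\n",
      sep = "")
  invisible(x)
}

# serial relaxation probe: free one constraint family at a time (secretions,
# then nonessential uptakes, then growth) and report the first that restores
# feasibility
diagnose_infeasibility <- function(m, obj_ex, measured, essential_ids) {
  families <- list(
    secretions = names(measured)[measured > 0],
    nonessential_uptakes =
      setdiff(names(measured)[measured < 0], essential_ids),
    growth = character(0))
  probe <- m
  for (fam in names(families)) {
    if (fam == "growth") {
      probe <- set_bounds(probe, probe$objective$reaction, 0, 1000)
    } else {
      for (met in families[[fam]]) {
        ex <- find_exchange(probe, met)
        if (!is.na(ex) && ex != obj_ex)
          probe <- set_bounds(probe, ex, -1000, 1000)
      }
    }
    if (fba(probe, obj_ex, "max")$status == "optimal") return(fam)
  }
  "no single constraint family"
}
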
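#' Flux balance analysis
#'
#' Solves `max (or min) v_obj` subject to `S v = 0` and the model's flux
#' bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id; defaults to the model objective.
#' @param direction `"max"` or `"min"`; defaults to the model objective.
#' @return a `flux_vector`: list with `fluxes` (named vector,
#'   mmol gDW^-1 h^-1), `objective_value`, `status` ("optimal",
#'   "infeasible" or "unbounded").
#' @export
fba <- function(model, objective = NULL, direction = NULL) {
  objective <- objective %||% model$objective$reaction
  direction <- direction %||% model$objective$direction
  S <- stoichiometric_matrix(model)
  rxn <- model$reactions
  obj <- as.numeric(rxn$id == objective)
  if (!any(obj > 0)) stop("unknown objective reaction '", objective, "'")
  sol <- solve_lp(obj, S, rep(0, nrow(S)), rxn$lower_bound,
                  rxn$upper_bound, maximize = direction == "max")
  flux_vector(stats::setNames(sol$x, rxn$id), sol$objective, sol$status)
}

flux_vector <- function(fluxes, objective_value, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> status ", x$status, ", objective ",
      signif(x$objective_value, 6), ", ", length(x$fluxes),
      " reactions\n", sep = "")
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Stage 1 optimizes the objective by [fba()]; stage 2 fixes the objective
#' flux at its optimum, splits every reaction into two irreversible
#' directions and minimizes the total absolute flux. The returned vector
#' attains the stage-1 optimum with minimal `sum(|v|)` (stored in attribute
#' `total_flux`).
#'
#' @inheritParams fba
#' @return a `flux_vector` with attribute `total_flux`.
#' @export
pfba <- function(model, objective = NULL, direction = NULL) {
  objective <- objective %||% model$objective$reaction
  direction <- direction %||% model$objective$direction
  stage1 <- fba(model, objective, direction)
  if (stage1$status != "optimal") return(stage1)
  S <- stoichiometric_matrix(model)
  rxn <- model$reactions
  n <- nrow(rxn)
  ub_pos <- pmax(rxn$upper_bound, 0)
  ub_neg <- pmax(-rxn$lower_bound, 0)
  lb_pos <- pmax(rxn$lower_bound, 0)
  lb_neg <- pmax(-rxn$upper_bound, 0)
  A <- cbind(S, -S)
  cfix <- as.numeric(rxn$id == objective)
  A <- rbind(A, c(cfix, -cfix))
  b <- c(rep(0, nrow(S)), stage1$objective_value)
  sol <- solve_lp(rep(1, 2 * n), A, b,
                  lb = c(lb_pos, lb_neg), ub = c(ub_pos, ub_neg),
                  maximize = FALSE)
  if (sol$status != "optimal")
    stop("pFBA stage 2 ", sol$status,
         " at fixed optimum: numerical tolerance problem")
  v <- sol$x[1:n] - sol$x[n + 1:n]
  out <- flux_vector(stats::setNames(v, rxn$id),
                     stage1$objective_value, "optimal")
  attr(out, "total_flux") <- sol$objective
  out
}

#' Maximize ATP hydrolysis
#'
#' Parsimonious FBA with the model's maintenance reaction as the maximized
#' objective; used after constraining exchange rates and growth to measured
#' values to quantify total energy production.
#'
#' @param model a `metabolic_model` with constraints already applied.
#' @return a `flux_vector`.
#' @export
maximize_atp_hydrolysis <- function(model) {
  pfba(model, objective = model$maintenance_id, direction = "max")
}

#' Total nucleoside-triphosphate production of a flux distribution
#'
#' Sums the positive NTP-producing contributions `max(s_nr * v_r, 0)` over
#' all reactions and all NTP species (ATP, GTP, CTP, UTP, TTP, ITP and
#' their deoxy forms, matched by metabolite id). Stoichiometries of the
#' same NTP in different compartments are netted within a reaction first,
#' so transporters do not count as producers, and reactions that merely
#' interconvert NTPs (nucleoside-diphosphate and adenylate kinases) are
#' excluded so transferred phosphate is not double-counted.
#'
#' @param v a `flux_vector` with optimal status.
#' @param model the model `v` was computed on.
#' @param exclude reaction ids excluded as NTP interconversions.
#' @return total NTP production flux (mmol gDW^-1 h^-1).
#' @export
total_ntp_production <- function(v, model,
                                 exclude = c("NDPK_m", "NDPK_c", "ADK")) {
  stopifnot(inherits(v, "flux_vector"))
  if (v$status != "optimal") stop("flux vector is not optimal")
  ntp_re <- "^d?[agcuti]tp_"
  ntp <- model$metabolites$id[grepl(ntp_re, model$metabolites$id)]
  if (!length(ntp)) return(0)
  base <- sub("_[a-z]+$", "", ntp)
  total <- 0
  for (rid in setdiff(model$reactions$id, exclude)) {
    st <- model$stoichiometry[[rid]]
    hit <- intersect(names(st), ntp)
    if (length(hit)) {
      net <- tapply(st[hit], base[match(hit, ntp)], sum)
      total <- total + sum(pmax(net * v$fluxes[[rid]], 0))
    }
  }
  total
}

#' Measure the operational P/O ratio of a model
#'
#' Independent oracle for the respiratory stoichiometry: closes every
#' exchange except oxygen, water, protons, CO2 and phosphate, disables
#' growth, injects a fixed mitochondrial NADH-regenerating flux (the
#' chemical proton of the donor oxidation included, as for any
#' dehydrogenase) and maximizes ATP hydrolysis by FBA. The returned
#' objective equals the moles of ATP made per mole NADH oxidized.
#'
#' @param model a `metabolic_model` with the proton-explicit respiratory
#'   chain.
#' @param nadh_flux size of the NADH-regenerating flux (default 1).
#' @return measured P/O ratio for NADH.
#' @export
measure_po_ratio <- function(model, nadh_flux = 1) {
  keep <- paste0("EX_", c("o2", "h2o", "h", "co2", "pi"), "_e")
  for (exr in model$reactions$id[model$reactions$is_exchange])
    if (!exr %in% keep) model <- fix_flux(model, exr, 0)
  for (b in model$biomass_ids) model <- fix_flux(model, b, 0)
  model <- set_bounds(model, model$maintenance_id, 0, 1000)
  model <- add_reaction(model, "NADH_SRC", "NADH regeneration probe",
                        c(nad_m = -1, nadh_m = 1, h_m = 1),
                        nadh_flux, nadh_flux, pseudo = TRUE)
  sol <- fba(model, objective = model$maintenance_id, direction = "max")
  if (sol$status != "optimal") stop("P/O measurement ", sol$status)
  sol$objective_value / nadh_flux
}
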
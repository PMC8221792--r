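#' Construct a metabolic model
#'
#' Container for a compartmentalized stoichiometric network: metabolite and
#' reaction tables, per-reaction stoichiometry, flux bounds, named biomass
#' and maintenance reactions and an objective. Fluxes are in
#' mmol gDW^-1 h^-1 throughout; exchange fluxes are negative for uptake and
#' positive for secretion.
#'
#' @param id model identifier.
#' @param compartments named character vector, id -> name.
#' @param metabolites data.frame with columns id, name, compartment, formula,
#'   charge.
#' @param reactions data.frame with columns id, name, lower_bound,
#'   upper_bound, subsystem, is_exchange.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (by metabolite id); negative coefficients are consumed.
#' @param biomass_ids character vector of biomass reaction ids.
#' @param maintenance_id id of the ATP-hydrolysis maintenance reaction.
#' @param objective list with `reaction` and `direction` ("max"/"min").
#' @param pseudo_ids reactions exempt from elemental balance (demands, sinks).
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            stoichiometry, biomass_ids, maintenance_id,
                            objective = list(reaction = biomass_ids[1],
                                             direction = "max"),
                            pseudo_ids = character(0)) {
  m <- structure(list(id = id, compartments = compartments,
                      metabolites = metabolites, reactions = reactions,
                      stoichiometry = stoichiometry,
                      biomass_ids = biomass_ids,
                      maintenance_id = maintenance_id,
                      objective = objective, pseudo_ids = pseudo_ids),
                 class = "metabolic_model")
  validate_model(m)
  m
}

validate_model <- function(model) {
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids")
  if (!all(met$compartment %in% names(model$compartments)))
    stop("metabolite in undeclared compartment")
  if (!setequal(names(model$stoichiometry), rxn$id))
    stop("stoichiometry list does not match reaction table")
  for (id in rxn$id) {
    unknown <- setdiff(names(model$stoichiometry[[id]]), met$id)
    if (length(unknown))
      stop("reaction '", id, "' references unknown metabolite '",
           unknown[1], "'")
  }
  if (any(rxn$lower_bound > rxn$upper_bound))
    stop("lower bound above upper bound")
  if (!model$maintenance_id %in% rxn$id)
    stop("maintenance reaction '", model$maintenance_id,
         "' missing from model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      " in ", length(x$compartments), " compartments\n",
      "  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchanges)\n",
      "  objective:   ", x$objective$direction, " ", x$objective$reaction,
      "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (id in model$reactions$id) {
    st <- model$stoichiometry[[id]]
    S[names(st), id] <- st
  }
  S
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param rxn_id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn_id, lower = NULL, upper = NULL) {
  i <- match(rxn_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction '", rxn_id, "'")
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i])
    stop("lower bound above upper bound for '", rxn_id, "'")
  model
}

#' Fix a reaction flux to a single value
#' @rdname set_bounds
#' @param value flux value applied to both bounds.
#' @export
fix_flux <- function(model, rxn_id, value) {
  set_bounds(model, rxn_id, lower = value, upper = value)
}

#' Find the exchange reaction for a metabolite
#'
#' Matches on the extracellular species `<met_id>_e`.
#'
#' @param model a `metabolic_model`.
#' @param met_id compartment-free metabolite id (e.g. `"glc__D"`).
#' @param required error (rather than `NA`) when absent.
#' @return exchange reaction id or `NA_character_`.
#' @export
find_exchange <- function(model, met_id, required = FALSE) {
  target <- paste0(met_id, "_e")
  ex <- model$reactions$id[model$reactions$is_exchange]
  for (id in ex) {
    if (identical(names(model$stoichiometry[[id]]), target)) return(id)
  }
  if (required)
    stop("no exchange reaction for metabolite '", met_id, "'", call. = FALSE)
  NA_character_
}

add_metabolite <- function(model, id, name, compartment, formula, charge) {
  if (id %in% model$metabolites$id) return(model)
  model$metabolites <- rbind(model$metabolites,
    data.frame(id = id, name = name, compartment = compartment,
               formula = formula, charge = charge))
  model
}

add_reaction <- function(model, id, name, stoich, lower, upper,
                         subsystem = "", is_exchange = FALSE,
                         pseudo = FALSE) {
  if (id %in% model$reactions$id) stop("reaction '", id, "' already exists")
  model$reactions <- rbind(model$reactions,
    data.frame(id = id, name = name, lower_bound = lower, upper_bound = upper,
               subsystem = subsystem, is_exchange = is_exchange))
  model$stoichiometry[[id]] <- stoich
  if (pseudo) model$pseudo_ids <- union(model$pseudo_ids, id)
  model
}

drop_reaction <- function(model, id) {
  keep <- model$reactions$id != id
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry[[id]] <- NULL
  model$pseudo_ids <- setdiff(model$pseudo_ids, id)
  model
}

#' Select the active biomass reaction
#'
#' Fixes all other biomass variants to zero flux so that simulations use one
#' biomass equation at a time.
#'
#' @param model a `metabolic_model`.
#' @param biomass_id one of `model$biomass_ids`.
#' @return model with the chosen variant open and the others closed.
#' @export
select_biomass <- function(model, biomass_id) {
  if (!biomass_id %in% model$biomass_ids)
    stop("'", biomass_id, "' is not a biomass reaction of this model")
  for (b in setdiff(model$biomass_ids, biomass_id))
    model <- fix_flux(model, b, 0)
  model <- set_bounds(model, biomass_id, lower = 0, upper = 1000)
  model$objective <- list(reaction = biomass_id, direction = "max")
  model
}

#' Add a recombinant-product synthesis reaction
#'
#' Builds a protein-product reaction from an amino-acid composition. Per mole
#' of polymerized amino acid the reaction hydrolyses 2 GTP and 1.306 ATP to
#' 2 GDP, 1 AMP and 0.306 ADP (translation plus amino-acid activation
#' bookkeeping: ATP -> AMP for charging and a fractional ATP -> ADP share for
#' auxiliary steps). Phosphate and water closure species are added explicitly
#' so that the energetic part of the reaction is element- and charge-closed:
#' per mole AA, 2.306 Pi, 1 PPi and 3.306 H+ are released, 3.306 H2O are
#' hydrolysed and 1 H2O is returned by peptide-bond formation. One unit of
#' product is
#' produced and exported through an added exchange reaction; the product
#' species is a polymer pseudo-metabolite (formula left empty).
#'
#' @param model a `metabolic_model`.
#' @param composition named numeric vector, amino-acid id (compartment-free,
#'   e.g. `"ala__L"`) -> mole fraction; must sum to 1.
#' @param product_id id for the product metabolite (default `"product"`).
#' @param chain_length number of residues per mole of product; coefficients
#'   scale linearly (default 1, i.e. the reaction is written per mole AA).
#' @return model with the synthesis reaction `PROD_<product_id>` and exchange
#'   `EX_<product_id>_e` added.
#' @export
add_product_synthesis_reaction <- function(model, composition,
                                           product_id = "product",
                                           chain_length = 1) {
  if (abs(sum(composition) - 1) > 1e-6)
    stop("amino-acid mole fractions must sum to 1")
  aa_c <- paste0(names(composition), "_c")
  missing <- setdiff(aa_c, model$metabolites$id)
  if (length(missing))
    stop("unknown amino acid in composition: ", missing[1])
  L <- chain_length
  met_e <- paste0(product_id, "_e")
  model <- add_metabolite(model, met_e, product_id, "e", "", 0)
  # water: 2 (GTP hydrolysis) + 1 (ATP -> AMP + PPi) + 0.306 (ATP -> ADP)
  # consumed, 1 released by peptide-bond formation => net -2.306 per mole AA
  st <- c(
    stats::setNames(-composition * L, aa_c),
    gtp_c = -2 * L, atp_c = -1.306 * L, h2o_c = -2.306 * L,
    gdp_c = 2 * L, amp_c = 1 * L, adp_c = 0.306 * L,
    pi_c = 2.306 * L, ppi_c = 1 * L, h_c = 3.306 * L
  )
  st[met_e] <- 1
  need_ppi <- !"ppi_c" %in% model$metabolites$id
  if (need_ppi)
    model <- add_metabolite(model, "ppi_c", "diphosphate", "c", "HP2O7", -3)
  rid <- paste0("PROD_", product_id)
  model <- add_reaction(model, rid, paste0(product_id, " synthesis"),
                        st, 0, 1000, subsystem = "Product synthesis",
                        pseudo = TRUE)
  if (need_ppi) {
    # inorganic pyrophosphatase so the charging by-product is recyclable
    model <- add_reaction(model, "PPA",
                          "inorganic diphosphatase",
                          c(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1),
                          0, 1000, subsystem = "Energy metabolism")
  }
  add_reaction(model, paste0("EX_", product_id, "_e"),
               paste0(product_id, " exchange"),
               stats::setNames(-1, met_e), 0, 1000,
               is_exchange = TRUE)
}

#' Apply measured exchange rates as flux constraints
#'
#' Sets exchange-reaction bounds from an [exchange_dataset()]. Under the
#' `"point"` policy both bounds are fixed to the measured value; under
#' `"interval"` they are set to value +/- SD. Oxygen is never constrained.
#' If tryptophan has an exchange reaction in the model but no measured rate,
#' its uptake bound is set to the smallest-magnitude measured amino-acid
#' uptake (tryptophan being the least abundant amino acid in biomass).
#'
#' @param model a `metabolic_model`.
#' @param data an [exchange_dataset()].
#' @param policy `"point"` or `"interval"`.
#' @param growth constrain the active biomass reaction to the dataset growth
#'   rate under the same policy (used by the chemostat energy analysis).
#' @param trp_id compartment-free tryptophan id.
#' @param oxygen_id compartment-free oxygen id.
#' @return constrained model.
#' @export
apply_exchange_constraints <- function(model, data,
                                       policy = c("point", "interval"),
                                       growth = FALSE,
                                       trp_id = "trp__L",
                                       oxygen_id = "o2") {
  policy <- match.arg(policy)
  stopifnot(inherits(data, "exchange_dataset"))
  rates <- data$rates
  rates <- rates[rates$metabolite != oxygen_id, , drop = FALSE]
  for (i in seq_len(nrow(rates))) {
    ex <- find_exchange(model, rates$metabolite[i])
    if (is.na(ex))
      stop("no exchange reaction for measured metabolite '",
           rates$metabolite[i], "'", call. = FALSE)
    v <- rates$value[i]; s <- rates$sd[i]
    if (policy == "point") model <- set_bounds(model, ex, v, v)
    else model <- set_bounds(model, ex, v - s, v + s)
  }
  trp_ex <- find_exchange(model, trp_id)
  if (!is.na(trp_ex) && !trp_id %in% rates$metabolite) {
    aa <- rates[rates$is_aa & rates$value < 0, , drop = FALSE]
    if (nrow(aa)) {
      v <- -min(abs(aa$value))
      model <- set_bounds(model, trp_ex, v, 0)
    }
  }
  if (growth) {
    bid <- model$objective$reaction
    mu <- data$growth_rate; s <- data$growth_sd
    if (policy == "point") model <- fix_flux(model, bid, mu)
    else model <- set_bounds(model, bid, max(mu - s, 0), mu + s)
  }
  model
}

#' Reconfigure the P/O ratio of the electron transport chain
#'
#' The bundled models use an explicit proton-translocation formulation:
#' the NADH-oxidizing respiratory lump pumps `4 * po_nadh` protons out of
#' the matrix and the ATP synthase uses 4 protons per ATP (one of them
#' consumed chemically; the phosphate carrier returns one proton per Pi), so
#' the ATP yield per NADH equals `po_nadh` as an emergent network property.
#' The FADH2 branch is rescaled proportionally (factor 0.6).
#'
#' @param model a `metabolic_model` with reactions `ETC_NADH` and
#'   `ETC_FADH2` in the proton-explicit form.
#' @param po_nadh target P/O ratio for NADH; values outside `[2, 3]` are
#'   allowed but flagged with a warning.
#' @return model with rescaled proton-pumping stoichiometry.
#' @export
set_po_ratio <- function(model, po_nadh) {
  if (po_nadh < 2 || po_nadh > 3)
    warning("P/O ratio ", po_nadh, " outside the usual range [2, 3]")
  if (!all(c("ETC_NADH", "ETC_FADH2") %in% model$reactions$id))
    stop("model lacks the proton-explicit respiratory lumps")
  n_pump <- 4 * po_nadh
  model$stoichiometry[["ETC_NADH"]][c("h_m", "h_i")] <- c(-(1 + n_pump), n_pump)
  f_pump <- 0.6 * n_pump
  model$stoichiometry[["ETC_FADH2"]][c("h_m", "h_i")] <- c(-f_pump, f_pump)
  model$po_nadh <- po_nadh
  model
}
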
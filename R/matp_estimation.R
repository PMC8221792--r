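#' Prepare a model for simulation of one dataset
#'
#' Selects the biomass variant, adds a product-synthesis reaction for
#' producer datasets (fixing the product exchange to the measured
#' productivity) and applies the exchange-rate constraints.
#'
#' @param model a `metabolic_model`.
#' @param data an [exchange_dataset()].
#' @param biomass_id biomass variant (default: the model objective).
#' @param policy constraint policy, see [apply_exchange_constraints()].
#' @param growth also constrain growth.
#' @return constrained model.
#' @export
prepare_condition <- function(model, data, biomass_id = NULL,
                              policy = "point", growth = FALSE) {
  biomass_id <- biomass_id %||% model$objective$reaction
  model <- select_biomass(model, biomass_id)
  if (data$productivity > 0) {
    model <- add_product_synthesis_reaction(model,
                                            data$product_aa_composition)
    ex <- "EX_product_e"
    if (policy == "point")
      model <- fix_flux(model, ex, data$productivity)
    else
      model <- set_bounds(model, ex,
                          max(data$productivity - data$productivity_sd, 0),
                          data$productivity + data$productivity_sd)
  }
  apply_exchange_constraints(model, data, policy, growth = growth)
}

#' Predict fluxes at a given maintenance-ATP value
#'
#' Applies the dataset's exchange rates (point policy), fixes the
#' maintenance reaction to `matp` and runs parsimonious FBA maximizing
#' growth.
#'
#' @param model a `metabolic_model`.
#' @param data an [exchange_dataset()].
#' @param matp maintenance-ATP flux (mmol gDW^-1 h^-1), fixed as an
#'   equality.
#' @param biomass_id biomass variant.
#' @return a `flux_vector` (non-optimal status propagated).
#' @export
predict_with_matp <- function(model, data, matp, biomass_id = NULL) {
  stopifnot(matp >= 0)
  m <- prepare_condition(model, data, biomass_id)
  m <- fix_flux(m, m$maintenance_id, matp)
  pfba(m)
}

#' Estimate maintenance ATP for one 13C dataset
#'
#' Grid search: for every candidate mATP value the maintenance reaction is
#' fixed, growth is maximized by parsimonious FBA, predicted fluxes are
#' mapped onto the 13C namespace and scored by the median relative error
#' over the filtered experimental fluxes. The feasible grid value with the
#' smallest median error is the estimate; ties break toward the smaller
#' (more parsimonious) energy demand. Feasibility of a fixed maintenance
#' value is an interval property of the LP, so the feasible range is
#' bracketed with two FBA calls before scanning.
#'
#' @param model a `metabolic_model`.
#' @param data a `c13_dataset` (its `exchange` member supplies the
#'   constraints).
#' @param table mapping table (see [read_mapping_table()]).
#' @param grid candidate mATP values, mmol gDW^-1 h^-1 (default 0-40 by
#'   0.25).
#' @param biomass_id biomass variant.
#' @param threshold small-flux filter threshold (see
#'   [filter_small_fluxes()]).
#' @return object of class `maintenance_estimate`: data.frame `profile`
#'   (`matp`, `feasible`, `median_re`, `growth`), `optimum`, `optimum_re`,
#'   `dataset_id`.
#' @export
estimate_matp <- function(model, data, table, grid = seq(0, 40, 0.25),
                          biomass_id = NULL, threshold = 0.01) {
  stopifnot(inherits(data, "c13_dataset"), !is.unsorted(grid))
  base <- prepare_condition(model, data$exchange, biomass_id)
  filt <- filter_small_fluxes(data, threshold)
  ve <- stats::setNames(filt$fluxes$value, filt$fluxes$c13_id)
  unmapped <- setdiff(names(ve), table$c13_id)
  if (length(unmapped)) {
    warning("unmapped 13C reactions excluded from scoring: ",
            paste(unmapped, collapse = ", "))
    ve <- ve[setdiff(names(ve), unmapped)]
  }
  mid <- base$maintenance_id
  lo <- fba(base, mid, "min"); hi <- fba(base, mid, "max")
  feasible <- if (lo$status == "optimal" && hi$status == "optimal")
    grid >= lo$objective_value - 1e-6 & grid <= hi$objective_value + 1e-6
  else rep(FALSE, length(grid))
  prof <- data.frame(matp = grid, feasible = feasible,
                     median_re = NA_real_, growth = NA_real_)
  for (i in which(feasible)) {
    sol <- pfba(fix_flux(base, mid, grid[i]))
    if (sol$status != "optimal") { prof$feasible[i] <- FALSE; next }
    mapped <- map_fluxes(sol, table)
    prof$median_re[i] <- relative_errors(mapped, ve)$median
    prof$growth[i] <- sol$objective_value
  }
  ok <- which(prof$feasible & !is.na(prof$median_re))
  if (!length(ok))
    stop("no feasible grid point for dataset ", data$dataset_id)
  best <- ok[which.min(prof$median_re[ok])]  # which.min: first = smallest mATP
  structure(list(profile = prof, optimum = prof$matp[best],
                 optimum_re = prof$median_re[best],
                 dataset_id = data$dataset_id),
            class = "maintenance_estimate")
}

#' @export
print.maintenance_estimate <- function(x, ...) {
  cat("<maintenance_estimate> ",
      if (!is.null(x$dataset_id)) paste0(x$dataset_id, ": "),
      "mATP = ", x$optimum, " mmol/gDW/h (median RE ",
      signif(x$optimum_re, 3), ", ", sum(x$profile$feasible),
      "/", nrow(x$profile), " grid points feasible)\n", sep = "")
  invisible(x)
}

#' Joint maintenance-ATP estimate across datasets
#'
#' For each grid value the per-dataset median relative errors are summed
#' over the datasets with a feasible solution and divided by the number of
#' feasible datasets (larger mATP values are feasible for fewer datasets);
#' the grid value minimizing this score is the joint estimate.
#'
#' @param model a `metabolic_model`.
#' @param datasets list of `c13_dataset` objects.
#' @param tables one mapping table shared by all datasets, or a list
#'   parallel to `datasets`.
#' @inheritParams estimate_matp
#' @return a `maintenance_estimate`; its `profile` carries `n_feasible`
#'   and the combined `median_re` score.
#' @export
estimate_matp_joint <- function(model, datasets, tables,
                                grid = seq(0, 40, 0.25),
                                biomass_id = NULL, threshold = 0.01) {
  stopifnot(length(datasets) >= 1)
  if (is.data.frame(tables)) tables <- rep(list(tables), length(datasets))
  singles <- Map(function(d, tb)
    estimate_matp(model, d, tb, grid, biomass_id, threshold),
    datasets, tables)
  res <- sapply(singles, function(s)
    ifelse(s$profile$feasible, s$profile$median_re, NA_real_))
  n_feas <- rowSums(!is.na(res))
  score <- ifelse(n_feas > 0, rowSums(res, na.rm = TRUE) / n_feas, NA_real_)
  prof <- data.frame(matp = grid, feasible = n_feas > 0,
                     median_re = score, n_feasible = n_feas)
  ok <- which(prof$feasible)
  if (!length(ok)) stop("no grid point feasible for any dataset")
  best <- ok[which.min(prof$median_re[ok])]
  structure(list(profile = prof, optimum = prof$matp[best],
                 optimum_re = prof$median_re[best],
                 dataset_id = "joint", singles = singles),
            class = "maintenance_estimate")
}
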
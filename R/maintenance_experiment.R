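#' Convert steady-state rates to an exchange dataset
#'
#' Oxygen and CO2 are excluded by default: they are not used as
#' constraints for the energy analysis (oxygen is never constrained; the
#' off-gas CO2 rate only enters the carbon recovery).
#'
#' @param rates a [steady_state_rates()].
#' @param exclude metabolites not carried over.
#' @param dry_mass pg per cell.
#' @return an [exchange_dataset()].
#' @export
rates_to_exchange_dataset <- function(rates, exclude = c("o2", "co2"),
                                      dry_mass = 264) {
  q <- rates$q[!rates$q$metabolite %in% exclude, , drop = FALSE]
  exchange_dataset(dataset_id = rates$dataset_id,
                   rates = data.frame(metabolite = q$metabolite,
                                      value = q$value, sd = q$sd),
                   growth_rate = rates$mu, growth_sd = rates$mu_sd,
                   dry_mass = dry_mass)
}

#' Total energy production at one steady state
#'
#' Applies the measured exchange rates and growth as interval constraints
#' (value +/- SD), reconciles essential amino-acid uptakes against the
#' minimal requirement for the measured growth, maximizes ATP hydrolysis
#' by parsimonious FBA and sums the total NTP production. If the
#' constraint set is infeasible, the lower bounds of secretion rates are
#' relaxed stepwise (default 5% steps up to a 40% cap, upper bounds kept
#' at the experimental values) and every relaxation is logged.
#'
#' @param model a `metabolic_model`.
#' @param data an [exchange_dataset()] (e.g. from
#'   [rates_to_exchange_dataset()]).
#' @param biomass_id biomass variant.
#' @param relax_step,relax_max secretion-relaxation step and cap
#'   (fractions).
#' @return list of class `atp_curve_point`: `mu` (realized growth),
#'   `atp_total`, `dataset_id`, `relaxations` (data.frame `metabolite`,
#'   `percent`), or `NULL` (with a warning) if infeasible after maximal
#'   relaxation.
#' @export
atp_curve_point <- function(model, data, biomass_id = NULL,
                            relax_step = 0.05, relax_max = 0.40) {
  biomass_id <- biomass_id %||% model$objective$reaction
  base <- prepare_condition(model, data, biomass_id,
                            policy = "interval", growth = TRUE)
  # essential amino acids: if the permitted uptake cannot sustain the
  # measured growth, fix the uptake to the computed minimal requirement
  # (these amino acids only feed biomass, not the ATP balance)
  if (!is.null(model$essential_aas)) {
    minimal <- minimal_essential_uptakes(model, data,
                                         biomass_id = biomass_id)
    for (aa in names(minimal)) {
      ex <- find_exchange(base, aa)
      if (is.na(ex)) next
      i <- match(ex, base$reactions$id)
      if (base$reactions$lower_bound[i] > minimal[[aa]])
        base <- fix_flux(base, ex, minimal[[aa]])
    }
  }
  secretions <- data$rates[data$rates$value > 0, , drop = FALSE]
  for (k in seq(0, relax_max + 1e-12, by = relax_step)) {
    m <- base
    if (k > 0) {
      for (j in seq_len(nrow(secretions))) {
        ex <- find_exchange(m, secretions$metabolite[j], required = TRUE)
        lb0 <- secretions$value[j] - secretions$sd[j]
        m <- set_bounds(m, ex, lower = lb0 * (1 - k))
      }
    }
    sol <- maximize_atp_hydrolysis(m)
    if (sol$status == "optimal") {
      relaxations <- if (k > 0)
        data.frame(metabolite = secretions$metabolite,
                   percent = 100 * k)
      else data.frame(metabolite = character(0), percent = numeric(0))
      return(structure(list(mu = sol$fluxes[[biomass_id]],
                            atp_total = total_ntp_production(sol, m),
                            dataset_id = data$dataset_id,
                            relaxations = relaxations),
                       class = "atp_curve_point"))
    }
  }
  warning("steady state ", data$dataset_id,
          " infeasible after maximal secretion relaxation; point excluded")
  NULL
}

#' Fit maintenance energy and maximal ATP yield
#'
#' Ordinary least squares of total ATP production against growth rate
#' over a set of steady states. The intercept is the non-growth-associated
#' maintenance (mATP); the maximal biomass yield per ATP is the reciprocal
#' slope, `Y_ATP^max = 1000 / slope` g/mol (slope in mmol ATP per gDW).
#'
#' @param points list of [atp_curve_point()] results (`NULL` entries are
#'   dropped).
#' @return object of class `maintenance_fit`: `matp`, `matp_se`,
#'   `matp_ci95`, `yatp_max`, `yatp_max_se`, `slope`, `slope_se`,
#'   `r_squared`, `n`.
#' @export
fit_maintenance <- function(points) {
  points <- Filter(Negate(is.null), points)
  mu <- vapply(points, `[[`, 0, "mu")
  atp <- vapply(points, `[[`, 0, "atp_total")
  if (length(mu) < 3 || length(unique(round(mu, 12))) < 2)
    stop("need at least 3 points spanning more than one growth rate")
  fit <- stats::lm(atp ~ mu)
  # noiseless synthetic curves are exactly collinear; the perfect-fit
  # warning from summary.lm is expected there
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["mu", "Estimate"]; slope_se <- cf["mu", "Std. Error"]
  if (slope <= 0) stop("non-positive ATP-vs-growth slope; fit invalid")
  structure(list(
    matp = cf["(Intercept)", "Estimate"],
    matp_se = cf["(Intercept)", "Std. Error"],
    matp_ci95 = as.numeric(
      suppressWarnings(stats::confint(fit, "(Intercept)", 0.95))),
    slope = slope, slope_se = slope_se,
    yatp_max = 1000 / slope,
    yatp_max_se = 1000 * slope_se / slope^2,
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n = length(mu), fit = fit),
    class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat("<maintenance_fit> mATP = ", signif(x$matp, 3), " +/- ",
      signif(x$matp_se, 2), " mmol/gDW/h, Y_ATP^max = ",
      signif(x$yatp_max, 3), " +/- ", signif(x$yatp_max_se, 2),
      " g/mol (R^2 ", signif(x$r_squared, 3), ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Maintenance fit across a sweep of P/O ratios
#'
#' Repeats the full ATP-curve construction and fit for each P/O value.
#'
#' @param model a `metabolic_model` (proton-explicit respiratory chain).
#' @param datasets list of [exchange_dataset()] objects (one per steady
#'   state).
#' @param po_values P/O ratios to evaluate, typically within `[2, 3]`.
#' @param ... passed to [atp_curve_point()].
#' @return named list of `maintenance_fit` objects (names = P/O values).
#' @export
po_sensitivity <- function(model, datasets, po_values, ...) {
  out <- lapply(po_values, function(po) {
    m <- set_po_ratio(model, po)
    fit_maintenance(lapply(datasets, function(d)
      atp_curve_point(m, d, ...)))
  })
  names(out) <- as.character(po_values)
  out
}
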
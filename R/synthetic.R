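#' Ground truth for synthetic datasets
#'
#' @param true_matp non-growth-associated maintenance, mmol gDW^-1 h^-1.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (0 = noiseless).
#' @param seed integer seed; recorded in every generated output.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_matp = 6, noise_cv = 0.1, seed = 1L) {
  stopifnot(true_matp >= 0, noise_cv >= 0)
  structure(list(true_matp = true_matp, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# multiplicative noise factor, truncated at 3 sigma to avoid sign flips
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  1 + cv * pmax(pmin(stats::rnorm(n), 3), -3)
}

#' Generate a synthetic 13C flux dataset with known ground truth
#'
#' Fixes the maintenance reaction to the true mATP, samples a feasible
#' nutrient environment (uptake bounds for glucose, glutamine and the
#' essential amino acids), runs parsimonious FBA maximizing growth and
#' treats the resulting fluxes as the ground truth. Intracellular fluxes
#' are aggregated into a coarse 13C namespace through a mapping table that
#' exercises all three mapping rules (multi-reaction sums, compartment
#' merges, signed net fluxes); observed fluxes and exchange rates are then
#' perturbed multiplicatively (`Normal(1, noise_cv)`, truncated at 3
#' sigma) and confidence intervals set to `+/- 1.96 * noise_cv * |value|`.
#' Ammonium, CO2 and oxygen are left unmeasured, as typical for the
#' literature datasets this emulates.
#'
#' @param model the toy model (see [build_toy_model()]).
#' @param truth a [synthetic_truth()].
#' @param dataset_id identifier stamped on the outputs.
#' @param max_tries resampling attempts for infeasible environments.
#' @param trp_measured include tryptophan among the measured exchange
#'   rates (default `TRUE`); set `FALSE` to emulate datasets where it is
#'   missing and the smallest-amino-acid fallback rule applies.
#' @return list with `exchange` ([exchange_dataset()]), `c13`
#'   (`c13_dataset`), `mapping` (table) and `true_growth`.
#' @export
simulate_c13_dataset <- function(model, truth, dataset_id = "synth1",
                                 max_tries = 10L, trp_measured = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  table <- toy_mapping_table()
  for (try in seq_len(max_tries)) {
    # scarce glucose, generous amino acids: growth must be energy-limited
    # at the true mATP (surplus amino acids are catabolized), so that the
    # predicted fluxes respond to the maintenance constraint on both sides
    # of the truth, as they do for the literature datasets this emulates
    env <- list(
      glc__D = -stats::runif(1, 0.12, 0.20),
      gln__L = -stats::runif(1, 0.06, 0.10),
      his__L = -stats::runif(1, 0.010, 0.015),
      lys__L = -stats::runif(1, 0.018, 0.028),
      thr__L = -stats::runif(1, 0.015, 0.025),
      trp__L = -stats::runif(1, 0.002, 0.004))
    m <- model
    for (met in names(env))
      m <- set_bounds(m, find_exchange(m, met, required = TRUE),
                      env[[met]], 0)
    for (met in c("ala__L", "ser__L", "gly"))
      m <- set_bounds(m, find_exchange(m, met, required = TRUE),
                      -0.02, 1000)
    m <- fix_flux(m, m$maintenance_id, truth$true_matp)
    sol <- pfba(m)
    responsive <- FALSE
    if (sol$status == "optimal" && sol$objective_value > 1e-6) {
      probe <- fix_flux(m, m$maintenance_id,
                        max(truth$true_matp - 0.5, 0))
      s2 <- fba(probe)
      responsive <- s2$status == "optimal" &&
        s2$objective_value > sol$objective_value + 1e-5
    }
    if (responsive) break
    if (try == max_tries)
      stop("could not sample a feasible, energy-limited environment")
  }
  true_mapped <- map_fluxes(sol, table)
  cv <- truth$noise_cv
  obs <- true_mapped * noise_factor(length(true_mapped), cv)
  half <- 1.96 * cv * abs(obs)
  measured <- c("glc__D", "lac__L", "gln__L", "ala__L", "ser__L", "gly",
                "his__L", "lys__L", "thr__L",
                if (trp_measured) "trp__L")
  ex_true <- vapply(measured, function(met)
    sol$fluxes[[find_exchange(model, met, required = TRUE)]], 0)
  ex_obs <- ex_true * noise_factor(length(ex_true), cv)
  growth_obs <- sol$objective_value * noise_factor(1, cv)
  exch <- exchange_dataset(
    dataset_id = dataset_id,
    rates = data.frame(metabolite = measured, value = unname(ex_obs),
                       sd = cv * abs(unname(ex_obs)),
                       is_aa = measured != "glc__D" & measured != "lac__L"),
    growth_rate = growth_obs, growth_sd = cv * abs(growth_obs))
  subsys <- stats::setNames(table$subsystem, table$c13_id)
  c13 <- c13_dataset(
    dataset_id = dataset_id,
    fluxes = data.frame(c13_id = names(obs), value = unname(obs),
                        ci_low = unname(obs - half),
                        ci_high = unname(obs + half),
                        subsystem = unname(subsys[names(obs)])),
    exchange = exch)
  list(exchange = exch, c13 = c13,
       mapping = table[, c("c13_id", "gsmm_id", "sign")],
       true_growth = sol$objective_value, truth = truth)
}

#' Mapping table between the toy model and its 13C namespace
#'
#' Covers all three mapping rules: plain one-to-one entries, a
#' multi-reaction sum (`TCA_FULL`), a compartment merge of the two alanine
#' transaminase isoforms (`ALATA_TOTAL`), and a signed net flux
#' (`PPP_NET`, oxidative branch minus the non-oxidative return).
#'
#' @return data.frame with columns `c13_id`, `gsmm_id`, `sign`,
#'   `subsystem`.
#' @export
toy_mapping_table <- function() {
  e <- function(c13, gsmm, sign, sub)
    data.frame(c13_id = c13, gsmm_id = gsmm, sign = sign, subsystem = sub)
  rbind(
    e("GLYC_13", "GLYC", 1, "Glycolysis"),
    e("PPP_OX", "PPP", 1, "PPP"),
    e("PPP_NET", "PPP", 1, "PPP"),
    e("PPP_NET", "PPPNOX", -1, "PPP"),
    e("LDH_NET", "LDH", 1, "Pyr metabolism"),
    e("PYR_MITO", "PYRtm", 1, "Pyr metabolism"),
    e("PDH_13", "PDH", 1, "Pyr metabolism"),
    e("CS_TCA", "TCA", 1, "TCA"),
    e("AKG_OX", "AKGOX", 1, "TCA"),
    e("TCA_FULL", "TCA", 1, "TCA"),
    e("TCA_FULL", "AKGOX", 1, "TCA"),
    e("GLS_13", "GLS", 1, "AA metabolism"),
    e("GDH_NET", "GDH", 1, "AA metabolism"),
    e("ALATA_TOTAL", "ALATA", 1, "AA metabolism"),
    e("ALATA_TOTAL", "ALATA_m", 1, "AA metabolism"),
    e("SERD_NET", "SERD", 1, "AA metabolism"),
    e("GLYS_13", "GLYS", 1, "AA metabolism"),
    e("GLYCL_13", "GLYCL", 1, "AA metabolism"),
    e("HISDEG_13", "HISDEG", 1, "AA metabolism"),
    e("LYSDEG_13", "LYSDEG", 1, "AA metabolism"),
    e("THRDEG_13", "THRDEG", 1, "AA metabolism"))
}

#' Simulate a chemostat run with known ground truth
#'
#' For each dilution rate the steady state consistent with the model at
#' the true maintenance is solved (growth fixed to `D * Nt/Nv`,
#' maintenance fixed, uptakes bounded by feed availability, glucose uptake
#' minimized by parsimonious FBA); bioreactor concentrations follow from
#' the mass balance `Cout = Cin + q X / D`. Each record carries a
#' feed-mass series implying the exact dilution rate and noisy
#' steady-state sample series; it is carbon-balanced by construction. CO2
#' is included among the recorded rates (off-gas measurement) so that
#' carbon recovery closes exactly in the noiseless case.
#'
#' @param model the toy model.
#' @param truth a [synthetic_truth()].
#' @param dilution_rates vector of dilution rates (h^-1).
#' @param feed named vector of feed concentrations (mM) for consumables.
#' @param viability viable cell fraction Nv/Nt (default 0.95).
#' @param viable_density viable cells per mL at steady state.
#' @param volume working volume, mL (default 270).
#' @param dry_mass pg per cell (default 264).
#' @param n_samples steady-state samples per record.
#' @return list of `chemostat_record` objects (one per dilution rate),
#'   each with attribute `true_rates` (the exact exchange fluxes).
#' @export
simulate_chemostat <- function(model, truth, dilution_rates,
                               feed = c(glc__D = 30, gln__L = 6,
                                        his__L = 1, lys__L = 2,
                                        thr__L = 1.5, trp__L = 0.4),
                               viability = 0.95, viable_density = 5.5e6,
                               volume = 270, dry_mass = 264,
                               n_samples = 5L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed + 1000L)
  X <- viable_density * 1e3 * dry_mass * 1e-12   # gDW per L
  measured <- c("glc__D", "lac__L", "gln__L", "nh4", "co2",
                "ala__L", "ser__L", "gly",
                "his__L", "lys__L", "thr__L", "trp__L")
  cv <- truth$noise_cv
  lapply(seq_along(dilution_rates), function(k) {
    D <- dilution_rates[k]
    mu <- D / viability
    m <- model
    for (met in names(feed)) {
      avail <- -feed[[met]] * D / X
      m <- set_bounds(m, find_exchange(m, met, required = TRUE), avail, 0)
    }
    for (met in c("ala__L", "ser__L", "gly"))
      m <- set_bounds(m, find_exchange(m, met, required = TRUE), 0, 1000)
    m <- fix_flux(m, m$objective$reaction, mu)
    m <- fix_flux(m, m$maintenance_id, truth$true_matp)
    sol <- pfba(m, find_exchange(m, "glc__D"), "max")
    if (sol$status != "optimal")
      stop("dilution rate ", D, " h^-1 is not sustainable with this feed ",
           "(washout or maintenance not payable)")
    q <- vapply(measured, function(met)
      sol$fluxes[[find_exchange(model, met, required = TRUE)]], 0)
    cin <- vapply(measured, function(met)
      if (met %in% names(feed)) feed[[met]] else 0, 0)
    cout <- pmax(cin + q * X / D, 0)  # clamp tiny negative round-off
    times <- seq(0, by = 12, length.out = n_samples)
    conc <- vapply(seq_along(measured), function(j)
      cout[j] * noise_factor(n_samples, cv), numeric(n_samples))
    colnames(conc) <- measured
    feed_mass <- D * volume * times * noise_factor(n_samples, cv / 10)
    nv_series <- viable_density * noise_factor(n_samples, cv)
    via_series <- pmin(viability * noise_factor(n_samples, cv / 5), 0.999)
    rec <- chemostat_record(
      dataset_id = sprintf("DR%02d", k),
      times = times, feed_mass = feed_mass, volume = volume,
      viable_density = nv_series,
      total_density = nv_series / via_series,
      concentrations = conc,
      feed_concentrations = stats::setNames(cin, measured),
      dry_mass = dry_mass)
    attr(rec, "true_rates") <- list(D = D, mu = mu, q = q, X = X)
    rec
  })
}
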
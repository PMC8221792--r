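#' Build the bundled central-carbon toy model
#'
#' Deterministically constructs a compartmentalized (extracellular/cytosol/
#' mitochondria) stoichiometric model of CHO-like central carbon metabolism,
#' sized so that every analysis in the package can be exercised with exact
#' linear-programming oracles: lumped glycolysis, an oxidative
#' pentose-phosphate branch, lactate dehydrogenase, pyruvate and TCA lumps
#' producing NADH/FADH2/GTP, glutaminolysis, degradation routes for all
#' consumable amino acids, a proton-explicit respiratory chain with ATP
#' synthase (P/O emerges from proton stoichiometry; see [set_po_ratio()]),
#' a proton leak, two biomass variants differing in protein content
#' (56% vs 70%), and an ATP-hydrolysis maintenance reaction `DM_atp_c`.
#' All internal reactions are elementally and charge balanced
#' (see [check_mass_balance()]).
#'
#' @param po_nadh P/O ratio realized for NADH (default 2.5).
#' @param gam growth-associated energy demand, mmol ATP per gDW embedded
#'   in both biomass reactions. The default 173 makes the model's total
#'   ATP cost of growth (GAM plus precursor-synthesis ATP) about
#'   175 mmol gDW^-1, i.e. a maximal biomass yield per ATP near the
#'   5.7 g/mol reported for CHO.
#' @param protein_fraction 0.56 or 0.70; selects which biomass variant is
#'   the default objective (both are always present).
#' @param essential_aas amino acids with uptake-only metabolism; the model
#'   provides no synthesis route for these.
#' @return a `metabolic_model` with extra fields `essential_aas` and
#'   `po_nadh`.
#' @export
build_toy_model <- function(po_nadh = 2.5, gam = 173,
                            protein_fraction = 0.56,
                            essential_aas = c("his__L", "lys__L", "thr__L")) {
  stopifnot(protein_fraction %in% c(0.56, 0.70))

  forms <- list(
    glc__D = c("C6H12O6", 0),  pyr = c("C3H3O3", -1),
    lac__L = c("C3H5O3", -1),  akg = c("C5H4O5", -2),
    atp = c("C10H12N5O13P3", -4), adp = c("C10H12N5O10P2", -3),
    amp = c("C10H12N5O7P", -2),
    gtp = c("C10H12N5O14P3", -4), gdp = c("C10H12N5O11P2", -3),
    pi = c("HPO4", -2), h2o = c("H2O", 0), h = c("H", 1),
    o2 = c("O2", 0), co2 = c("CO2", 0), nh4 = c("NH4", 1),
    nad = c("C21H26N7O14P2", -1), nadh = c("C21H27N7O14P2", -2),
    nadp = c("C21H25N7O17P3", -3), nadph = c("C21H26N7O17P3", -4),
    fad = c("C27H31N9O15P2", -2), fadh2 = c("C27H33N9O15P2", -2),
    coa = c("C21H32N7O16P3S", -4), accoa = c("C23H34N7O17P3S", -4),
    rib__D = c("C5H10O5", 0),
    glu__L = c("C5H8NO4", -1), gln__L = c("C5H10N2O3", 0),
    ala__L = c("C3H7NO2", 0), ser__L = c("C3H7NO3", 0),
    gly = c("C2H5NO2", 0),
    his__L = c("C6H9N3O2", 0), lys__L = c("C6H15N2O2", 1),
    thr__L = c("C4H9NO3", 0), trp__L = c("C11H12N2O2", 0))

  where <- list(
    e = c("glc__D", "lac__L", "gln__L", "ala__L", "ser__L", "gly",
          "his__L", "lys__L", "thr__L", "trp__L",
          "nh4", "o2", "co2", "h2o", "h", "pi"),
    c = c("glc__D", "pyr", "lac__L", "akg", "atp", "adp", "amp",
          "gtp", "gdp", "pi", "h2o", "h", "o2", "co2", "nh4",
          "nad", "nadh", "nadp", "nadph", "rib__D",
          "glu__L", "gln__L", "ala__L", "ser__L", "gly",
          "his__L", "lys__L", "thr__L", "trp__L"),
    m = c("pyr", "akg", "atp", "adp", "gtp", "gdp", "pi", "h2o", "h",
          "o2", "co2", "nad", "nadh", "fad", "fadh2", "coa", "accoa",
          "ala__L", "glu__L"),
    i = "h")
  mets <- do.call(rbind, lapply(names(where), function(cp) {
    data.frame(id = paste0(where[[cp]], "_", cp),
               name = where[[cp]], compartment = cp,
               formula = vapply(where[[cp]], function(m) forms[[m]][1], ""),
               charge = as.numeric(
                 vapply(where[[cp]], function(m) forms[[m]][2], "")))
  }))

  rxns <- list()
  rx <- function(id, name, st, lb = 0, ub = 1000, sub = "Transport",
                 ex = FALSE, pseudo = FALSE) {
    rxns[[id]] <<- list(id = id, name = name, st = st, lb = lb, ub = ub,
                        sub = sub, ex = ex, pseudo = pseudo)
  }
  ex <- function(met, lb = -1000, ub = 1000)
    rx(paste0("EX_", met, "_e"), paste0(met, " exchange"),
       stats::setNames(-1, paste0(met, "_e")), lb, ub,
       sub = "Exchange", ex = TRUE)
  tr <- function(id, met, from, to, lb = 0, ub = 1000)
    rx(id, paste0(met, " transport ", from, "->", to),
       stats::setNames(c(-1, 1), paste0(met, c(paste0("_", from),
                                               paste0("_", to)))), lb, ub)

  # waste products are secretion-only by default (absent from fresh medium)
  for (m in where$e) ex(m, lb = if (m %in% c("lac__L", "nh4")) 0 else -1000)

  tr("GLCt",  "glc__D", "e", "c")
  tr("LACt",  "lac__L", "c", "e", lb = -1000)
  tr("GLNt",  "gln__L", "e", "c")
  tr("ALAt",  "ala__L", "c", "e", lb = -1000)
  tr("SERt",  "ser__L", "c", "e", lb = -1000)
  tr("GLYt",  "gly",    "c", "e", lb = -1000)
  tr("HISt",  "his__L", "e", "c")
  tr("LYSt",  "lys__L", "e", "c")
  tr("THRt",  "thr__L", "e", "c")
  tr("TRPt",  "trp__L", "e", "c")
  tr("NH4t",  "nh4",    "c", "e", lb = -1000)
  tr("O2t",   "o2",     "e", "c", lb = -1000)
  tr("O2tm",  "o2",     "c", "m", lb = -1000)
  tr("CO2tm", "co2",    "m", "c", lb = -1000)
  tr("CO2t",  "co2",    "c", "e", lb = -1000)
  tr("H2Ot",  "h2o",    "e", "c", lb = -1000)
  tr("H2Otm", "h2o",    "c", "m", lb = -1000)
  tr("Ht",    "h",      "c", "e", lb = -1000)
  tr("PIt",   "pi",     "e", "c", lb = -1000)
  tr("PYRtm", "pyr",    "c", "m")
  tr("AKGtm", "akg",    "c", "m", lb = -1000)
  rx("PIt2m", "phosphate carrier (H+ symport)",
     c(pi_c = -1, h_c = -1, pi_m = 1, h_m = 1))
  rx("ATPtm", "adenine nucleotide translocase",
     c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1))
  rx("NADHtm", "NADH shuttle (malate-aspartate lump)",
     c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1))
  tr("Hmt", "h", "m", "c", lb = -1000)
  rx("Hleak", "proton leak (intermembrane to matrix)",
     c(h_i = -1, h_m = 1), sub = "Oxidative phosphorylation")

  rx("GLYC", "glycolysis (lumped)",
     c(glc__D_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
       pyr_c = 2, atp_c = 2, nadh_c = 2, h2o_c = 2, h_c = 2),
     sub = "Glycolysis")
  rx("PPP", "oxidative pentose phosphate branch (lumped)",
     c(glc__D_c = -1, atp_c = -1, nadp_c = -2, h2o_c = -2,
       rib__D_c = 1, co2_c = 1, nadph_c = 2, adp_c = 1, pi_c = 1, h_c = 3),
     sub = "PPP")
  rx("PPPNOX", "non-oxidative PPP return (lumped, 6 P5 -> 5 P6)",
     c(rib__D_c = -1.2, glc__D_c = 1), sub = "PPP")
  rx("LDH", "lactate dehydrogenase",
     c(pyr_c = -1, nadh_c = -1, h_c = -1, lac__L_c = 1, nad_c = 1),
     lb = -1000, sub = "Pyr metabolism")
  rx("PDH", "pyruvate dehydrogenase",
     c(pyr_m = -1, coa_m = -1, nad_m = -1,
       accoa_m = 1, co2_m = 1, nadh_m = 1),
     sub = "Pyr metabolism")
  rx("TCA", "citrate cycle (lumped)",
     c(accoa_m = -1, nad_m = -3, fad_m = -1, gdp_m = -1, pi_m = -1,
       h2o_m = -2,
       coa_m = 1, co2_m = 2, nadh_m = 3, fadh2_m = 1, gtp_m = 1, h_m = 2),
     sub = "TCA")
  rx("AKGOX", "2-oxoglutarate oxidation to pyruvate (lumped)",
     c(akg_m = -1, nad_m = -2, fad_m = -1, gdp_m = -1, pi_m = -1,
       h2o_m = -1,
       pyr_m = 1, co2_m = 2, nadh_m = 2, fadh2_m = 1, gtp_m = 1),
     sub = "TCA")

  np <- 4 * po_nadh
  rx("ETC_NADH", "respiratory chain, NADH branch",
     c(nadh_m = -1, o2_m = -0.5, h_m = -(1 + np),
       nad_m = 1, h2o_m = 1, h_i = np),
     sub = "Oxidative phosphorylation")
  rx("ETC_FADH2", "respiratory chain, FADH2 branch",
     c(fadh2_m = -1, o2_m = -0.5, h_m = -0.6 * np,
       fad_m = 1, h2o_m = 1, h_i = 0.6 * np),
     sub = "Oxidative phosphorylation")
  rx("ATPS", "ATP synthase (4 H+ per ATP)",
     c(adp_m = -1, pi_m = -1, h_i = -4, atp_m = 1, h2o_m = 1, h_m = 3),
     lb = -1000, sub = "Oxidative phosphorylation")
  rx("NDPK_m", "nucleoside-diphosphate kinase, mitochondrial",
     c(gtp_m = -1, adp_m = -1, gdp_m = 1, atp_m = 1),
     lb = -1000, sub = "Energy metabolism")
  rx("NDPK_c", "nucleoside-diphosphate kinase, cytosolic",
     c(atp_c = -1, gdp_c = -1, adp_c = 1, gtp_c = 1),
     lb = -1000, sub = "Energy metabolism")
  rx("ADK", "adenylate kinase",
     c(amp_c = -1, atp_c = -1, adp_c = 2),
     lb = -1000, sub = "Energy metabolism")

  rx("GLS", "glutaminase",
     c(gln__L_c = -1, h2o_c = -1, glu__L_c = 1, nh4_c = 1),
     sub = "AA metabolism")
  rx("GLNS", "glutamine synthetase",
     c(glu__L_c = -1, nh4_c = -1, atp_c = -1,
       gln__L_c = 1, adp_c = 1, pi_c = 1, h_c = 1),
     sub = "AA metabolism")
  rx("GDH", "glutamate dehydrogenase",
     c(glu__L_c = -1, h2o_c = -1, nad_c = -1,
       akg_c = 1, nh4_c = 1, nadh_c = 1, h_c = 1),
     lb = -1000, sub = "AA metabolism")
  rx("ALATA", "alanine transaminase, cytosolic",
     c(pyr_c = -1, glu__L_c = -1, ala__L_c = 1, akg_c = 1),
     lb = -1000, sub = "AA metabolism")
  tr("ALAtm", "ala__L", "c", "m", lb = -1000)
  tr("GLUtm", "glu__L", "c", "m", lb = -1000)
  rx("ALATA_m", "alanine transaminase, mitochondrial",
     c(pyr_m = -1, glu__L_m = -1, ala__L_m = 1, akg_m = 1),
     lb = -1000, sub = "AA metabolism")
  rx("SERD", "serine ammonia-lyase (reversible lump)",
     c(ser__L_c = -1, pyr_c = 1, nh4_c = 1),
     lb = -1000, sub = "AA metabolism")
  rx("GLYS", "serine to glycine oxidation (lumped)",
     c(ser__L_c = -1, nad_c = -2, h2o_c = -1,
       gly_c = 1, co2_c = 1, nadh_c = 2, h_c = 2),
     sub = "AA metabolism")
  rx("GLYCL", "glycine cleavage (lumped oxidation)",
     c(gly_c = -1, h2o_c = -2, nad_c = -3,
       co2_c = 2, nh4_c = 1, nadh_c = 3, h_c = 2),
     sub = "AA metabolism")
  rx("HISDEG", "histidine degradation to glutamate (lumped)",
     c(his__L_c = -1, h2o_c = -4, nad_c = -1,
       glu__L_c = 1, nh4_c = 2, co2_c = 1, nadh_c = 1),
     sub = "AA metabolism")
  rx("LYSDEG", "lysine degradation to glutamate (lumped)",
     c(lys__L_c = -1, h2o_c = -4, nad_c = -5,
       glu__L_c = 1, nh4_c = 1, co2_c = 1, nadh_c = 5, h_c = 6),
     sub = "AA metabolism")
  rx("THRDEG", "threonine degradation to pyruvate (lumped)",
     c(thr__L_c = -1, h2o_c = -2, nad_c = -3,
       pyr_c = 1, nh4_c = 1, co2_c = 1, nadh_c = 3, h_c = 3),
     sub = "AA metabolism")
  rx("TRPDEG", "tryptophan degradation (lumped oxidation)",
     c(trp__L_c = -1, h2o_c = -20, nad_c = -23,
       nh4_c = 2, co2_c = 11, nadh_c = 23, h_c = 21),
     sub = "AA metabolism")

  rx("DM_atp_c", "non-growth-associated maintenance (ATP hydrolysis)",
     c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
     sub = "Maintenance", pseudo = TRUE)

  aa_frac <- c(ala__L = 0.22, ser__L = 0.14, gly = 0.18, glu__L = 0.10,
               gln__L = 0.08, his__L = 0.06, lys__L = 0.12, thr__L = 0.09,
               trp__L = 0.01)
  biomass <- function(frac, rib, nadph) {
    aa_total <- frac * 1000 / 110      # mean residue mass ~110 g/mol
    st <- stats::setNames(-aa_frac * aa_total, paste0(names(aa_frac), "_c"))
    c(st, rib__D_c = -rib, nadph_c = -nadph, nadp_c = nadph,
      atp_c = -gam, h2o_c = -gam, adp_c = gam, pi_c = gam, h_c = gam)
  }
  rx("BIOMASS_cho", "biomass, 56% protein",
     biomass(0.56, rib = 0.20, nadph = 4), sub = "Biomass", pseudo = TRUE)
  rx("BIOMASS_cho_producing", "biomass, 70% protein",
     biomass(0.70, rib = 0.12, nadph = 3), sub = "Biomass", pseudo = TRUE)

  rtab <- data.frame(
    id = vapply(rxns, `[[`, "", "id"),
    name = vapply(rxns, `[[`, "", "name"),
    lower_bound = vapply(rxns, `[[`, 0, "lb"),
    upper_bound = vapply(rxns, `[[`, 0, "ub"),
    subsystem = vapply(rxns, `[[`, "", "sub"),
    is_exchange = vapply(rxns, `[[`, FALSE, "ex"),
    row.names = NULL)
  model <- metabolic_model(
    id = "toy_cho",
    compartments = c(e = "extracellular", c = "cytosol",
                     m = "mitochondrial matrix",
                     i = "mitochondrial intermembrane space"),
    metabolites = mets,
    reactions = rtab,
    stoichiometry = lapply(rxns, `[[`, "st"),
    biomass_ids = c("BIOMASS_cho", "BIOMASS_cho_producing"),
    maintenance_id = "DM_atp_c",
    objective = list(
      reaction = if (protein_fraction == 0.56) "BIOMASS_cho"
                 else "BIOMASS_cho_producing",
      direction = "max"),
    pseudo_ids = names(rxns)[vapply(rxns, `[[`, FALSE, "pseudo")])
  model <- select_biomass(model, model$objective$reaction)
  model$essential_aas <- essential_aas
  model$po_nadh <- po_nadh
  bad <- check_mass_balance(model, tol = 1e-9)
  if (nrow(bad))
    stop("internal error: unbalanced toy reaction ", bad$reaction[1])
  model
}
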
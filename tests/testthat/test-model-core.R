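test_that("formula parsing and carbon counting follow the formulas", {
  expect_equal(carbon_count("C6H12O6"), 6)   # glucose
  expect_equal(carbon_count("C3H5O3"), 3)    # lactate
  expect_equal(carbon_count("NH4"), 0)       # ammonium
  expect_equal(unname(parse_formula("C10H12N5O13P3")["P"]), 3)
  expect_error(parse_formula("C6H12O6!"), "unparseable")
})

test_that("the toy model satisfies its structural invariants", {
  expect_s3_class(TOY, "metabolic_model")
  expect_true(all(c("e", "c", "m") %in% names(TOY$compartments)))
  expect_equal(nrow(check_mass_balance(TOY)), 0)
  expect_true(TOY$maintenance_id %in% TOY$reactions$id)
  ex <- TOY$reactions$id[TOY$reactions$is_exchange]
  for (id in ex)
    expect_length(TOY$stoichiometry[[id]], 1)
  # essential amino acids have no synthesis route: with their uptake closed
  # growth is impossible
  m <- TOY
  for (aa in TOY$essential_aas)
    m <- fix_flux(m, find_exchange(m, aa, required = TRUE), 0)
  expect_lt(fba(m)$objective_value, 1e-9)
})

test_that("model editing validates its inputs", {
  expect_error(set_bounds(TOY, "nonexistent", 0, 1), "unknown reaction")
  expect_error(set_bounds(TOY, "GLYC", 2, 1), "lower bound above")
  expect_error(select_biomass(TOY, "GLYC"), "not a biomass reaction")
  expect_equal(find_exchange(TOY, "glc__D"), "EX_glc__D_e")
  expect_true(is.na(find_exchange(TOY, "pyr")))
  expect_error(find_exchange(TOY, "pyr", required = TRUE), "no exchange")
})

test_that("JSON and SBML round trips preserve the network exactly", {
  for (ext in c("json", "xml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model(TOY, path)
    back <- read_model(path)
    S0 <- stoichiometric_matrix(TOY)
    S1 <- stoichiometric_matrix(back)[rownames(S0), colnames(S0)]
    expect_equal(S1, S0, info = ext)
    expect_equal(back$reactions$lower_bound, TOY$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, TOY$reactions$upper_bound)
    expect_equal(back$reactions$subsystem, TOY$reactions$subsystem)
    expect_equal(back$maintenance_id, TOY$maintenance_id)
    expect_setequal(back$biomass_ids, TOY$biomass_ids)
    unlink(path)
  }
})

test_that("the bundled model fixtures load and match the built model", {
  for (f in c("toy_cho.json", "toy_cho.xml")) {
    path <- system.file("extdata", f, package = "maintflux")
    m <- read_model(path)
    expect_true(all(c("e", "c", "m") %in% names(m$compartments)))
    S0 <- stoichiometric_matrix(TOY)
    expect_equal(stoichiometric_matrix(m)[rownames(S0), colnames(S0)], S0)
    expect_equal(sort(m$essential_aas), sort(TOY$essential_aas))
  }
  tab <- read_mapping_table(system.file("extdata", "c13_mapping.tsv",
                                        package = "maintflux"))
  expect_true(all(tab$gsmm_id %in% TOY$reactions$id))
})

test_that("malformed model files are rejected with informative errors", {
  path <- tempfile(fileext = ".json")
  raw <- jsonlite::fromJSON(write_model(TOY, path), simplifyVector = TRUE)
  raw$stoichiometry$GLYC$ghost_met <- 1
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "unknown metabolite")
  raw$stoichiometry$GLYC$ghost_met <- NULL
  raw$maintenance_id <- "not_there"
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "maintenance")
  unlink(path)
  expect_error(read_model("/nonexistent/model.json"), "not found")
})

test_that("product synthesis carries the translation energetics per mole AA", {
  comp <- c(ala__L = 0.5, gly = 0.3, ser__L = 0.2)
  m <- add_product_synthesis_reaction(TOY, comp, "mab")
  st <- m$stoichiometry[["PROD_mab"]]
  expect_equal(unname(-st["atp_c"]), 1.306)
  expect_equal(unname(-st["gtp_c"]), 2)
  expect_equal(unname(st["adp_c"]), 0.306)
  expect_equal(unname(st["amp_c"]), 1)
  expect_equal(unname(st["gdp_c"]), 2)
  expect_true("EX_mab_e" %in% m$reactions$id)
  # a 100-residue product scales linearly
  m2 <- add_product_synthesis_reaction(TOY, comp, "mab", chain_length = 100)
  st2 <- m2$stoichiometry[["PROD_mab"]]
  expect_equal(unname(-st2["gtp_c"]), 200)
  expect_equal(unname(-st2["atp_c"]), 130.6)
  # the energetic species (nucleotides, phosphates, water, protons) close
  # elementally up to exactly one water per peptide bond, which is credited
  # to the polymer: residual = +1 H2O per mole of amino acid
  aa <- paste0(names(comp), "_c")
  res <- partial_balance(m, "PROD_mab", drop_mets = c(aa, "mab_e"))
  expect_equal(res[["H"]], 2, tolerance = 1e-9)
  expect_equal(res[["O"]], 1, tolerance = 1e-9)
  for (el in c("C", "N", "P", "charge"))
    expect_equal(res[[el]], 0, tolerance = 1e-9, info = el)
})

test_that("product composition is validated", {
  expect_error(add_product_synthesis_reaction(TOY, c(ala__L = 0.7)),
               "sum to 1")
  expect_error(add_product_synthesis_reaction(TOY, c(selenocys = 1)),
               "unknown amino acid")
})

test_that("exchange constraints honor policy, tryptophan rule and oxygen", {
  rates <- data.frame(metabolite = c("glc__D", "lac__L", "ala__L", "o2"),
                      value = c(-0.42, 0.56, -0.003, -5),
                      sd = c(0.02, 0.03, 0.001, 1))
  d <- exchange_dataset("t", rates, growth_rate = 0.02)
  m <- apply_exchange_constraints(TOY, d, "point")
  i <- match("EX_glc__D_e", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -0.42)
  expect_equal(m$reactions$upper_bound[i], -0.42)
  # interval policy: value +/- sd
  m2 <- apply_exchange_constraints(TOY, d, "interval")
  i <- match("EX_glc__D_e", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], -0.44)
  expect_equal(m2$reactions$upper_bound[i], -0.40)
  # tryptophan missing: bound equals smallest measured AA uptake
  i <- match("EX_trp__L_e", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -0.003)
  expect_equal(m$reactions$upper_bound[i], 0)
  # oxygen never constrained
  i <- match("EX_o2_e", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -1000)
  # unmapped metabolite errors
  bad <- exchange_dataset("b", data.frame(metabolite = "unobtainium",
                                          value = -1, sd = 0),
                          growth_rate = 0.02)
  expect_error(apply_exchange_constraints(TOY, bad), "no exchange")
})
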
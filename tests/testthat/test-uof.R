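test_that("minimal essential uptakes equal growth times the biomass demand", {
  d <- exchange_dataset("m1", data.frame(metabolite = character(0),
                                         value = numeric(0),
                                         sd = numeric(0)),
                        growth_rate = 0.01)
  min_up <- minimal_essential_uptakes(TOY, d)
  st <- TOY$stoichiometry[["BIOMASS_cho"]]
  for (aa in names(min_up))
    expect_equal(unname(min_up[[aa]]),
                 0.01 * st[[paste0(aa, "_c")]], tolerance = 1e-6)
  # no growth, no demand
  d0 <- d; d0$growth_rate <- 0
  expect_true(all(abs(minimal_essential_uptakes(TOY, d0)) < 1e-9))
  # linear in growth
  d2 <- d; d2$growth_rate <- 0.02
  expect_equal(minimal_essential_uptakes(TOY, d2), 2 * min_up,
               tolerance = 1e-6)
})

test_that("reconciliation replaces insufficient measurements and logs them", {
  r <- reconcile_uptakes(c(his__L = -0.002), c(his__L = -0.003))
  expect_equal(unname(r$uptakes), -0.003)
  expect_equal(nrow(r$adjustments), 1)
  r2 <- reconcile_uptakes(c(his__L = -0.005), c(his__L = -0.003))
  expect_equal(unname(r2$uptakes), -0.005)
  expect_equal(nrow(r2$adjustments), 0)
  # boundary: equal magnitudes keep the measurement, no log entry
  r3 <- reconcile_uptakes(c(his__L = -0.003), c(his__L = -0.003))
  expect_equal(unname(r3$uptakes), -0.003)
  expect_equal(nrow(r3$adjustments), 0)
})

test_that("uptake-objective pFBA reproduces the energy closure of the network", {
  d <- SIM0$exchange
  res <- uof_pfba(TOY, d, "glc__D", matp = 6)
  # the generating environment is energy-limited, so the measured uptake is
  # exactly the minimum that sustains growth + maintenance
  expect_equal(res$minimal_uptake, res$measured_uptake, tolerance = 1e-6)
  # never exceeds any feasible measured magnitude
  expect_lte(abs(res$minimal_uptake), abs(res$measured_uptake) + 1e-9)
  # raising maintenance raises the requirement by matp / (ATP per glucose)
  res2 <- uof_pfba(TOY, d, "glc__D", matp = 7)
  expect_equal(res$minimal_uptake - res2$minimal_uptake, 1 / 32,
               tolerance = 1e-6)
  expect_error(uof_pfba(TOY, d, "his__L"), "essential")
})

test_that("uptake-objective and biomass-objective fluxes agree when growth is fixed", {
  d <- SIM0$exchange
  res <- uof_pfba(TOY, d, "glc__D", matp = 6)
  bof <- predict_with_matp(TOY, d, 6)
  mu <- map_fluxes(res$fluxes, SIM0$mapping)
  mb <- map_fluxes(bof, SIM0$mapping)
  keep <- abs(mb) > 1e-4
  re <- stats::median(abs(mu[keep] - mb[keep]) / abs(mb[keep]))
  expect_lt(re, 0.05)
})

test_that("infeasible uptake-objective runs name the blocking constraint family", {
  d <- SIM0$exchange
  # force an impossible secretion demand
  d$rates$value[d$rates$metabolite == "gly"] <- 5
  expect_error(uof_pfba(TOY, d, "glc__D"), "secretions")
})
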
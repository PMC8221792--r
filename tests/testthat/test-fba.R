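test_that("FBA respects bottlenecks and mass balance", {
  chain <- make_chain_model(cap = 5)
  sol <- fba(chain)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5)
  S <- stoichiometric_matrix(chain)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_error(fba(chain, "nope"), "unknown objective")
})

test_that("every optimal flux vector is mass-balanced within tolerance", {
  S <- stoichiometric_matrix(TOY)
  m <- set_bounds(TOY, "EX_glc__D_e", -0.3, 0)
  for (obj in c("BIOMASS_cho", "DM_atp_c")) {
    sol <- pfba(m, obj, "max")
    expect_equal(sol$status, "optimal")
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    bad <- sol$fluxes < TOY$reactions$lower_bound - 1e-6 |
      sol$fluxes > TOY$reactions$upper_bound + 1e-6
    expect_false(any(bad[!names(sol$fluxes) %in% "EX_glc__D_e"]))
  }
})

test_that("pFBA removes futile cycles and picks minimal total flux", {
  # chain with a parallel A_c <-> C_c <-> B_c detour and a reversible
  # futile pair
  chain <- make_chain_model(cap = 5)
  chain <- maintflux:::add_metabolite(chain, "C_c", "C", "c", "C", 0)
  chain <- maintflux:::add_reaction(chain, "AC", "A to C",
                                    c(A_c = -1, C_c = 1), -1000, 1000)
  chain <- maintflux:::add_reaction(chain, "CB", "C to B",
                                    c(C_c = -1, B_c = 1), -1000, 1000)
  sol <- pfba(chain)
  expect_equal(sol$objective_value, 5)
  # the 2-step detour carries nothing; the direct path everything
  expect_equal(unname(sol$fluxes[["AC"]]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[["AB"]]), 5, tolerance = 1e-9)
  expect_equal(attr(sol, "total_flux"), sum(abs(sol$fluxes)),
               tolerance = 1e-9)
})

test_that("pFBA attains the FBA optimum on random models and no vertex beats it", {
  for (seed in 1:25) {
    mod <- random_lp_model(seed)
    s1 <- fba(mod)
    s2 <- pfba(mod)
    expect_equal(s2$status, s1$status)
    if (s1$status != "optimal") next
    expect_equal(s2$objective_value, s1$objective_value, tolerance = 1e-7)
    V <- enum_vertices(stoichiometric_matrix(mod),
                       rep(0, nrow(mod$metabolites)),
                       mod$reactions$lower_bound,
                       mod$reactions$upper_bound)
    obj <- as.numeric(mod$reactions$id == mod$objective$reaction)
    opt_v <- V[abs(V %*% obj - s1$objective_value) < 1e-6, , drop = FALSE]
    if (nrow(opt_v))
      expect_gte(min(rowSums(abs(opt_v))), attr(s2, "total_flux") - 1e-6)
  }
})

test_that("NTP production sums producers, nets transport, excludes kinases", {
  v <- structure(
    list(fluxes = stats::setNames(numeric(nrow(TOY$reactions)),
                                  TOY$reactions$id),
         objective_value = 0, status = "optimal"),
    class = "flux_vector")
  v$fluxes[["ATPS"]] <- 10
  expect_equal(total_ntp_production(v, TOY), 10)
  v$fluxes[["TCA"]] <- 2
  expect_equal(total_ntp_production(v, TOY), 12)
  # adenine nucleotide translocase moves ATP but produces none
  v$fluxes[["ATPtm"]] <- 7
  expect_equal(total_ntp_production(v, TOY), 12)
  # kinases are interconversions, excluded by default
  v$fluxes[["NDPK_m"]] <- 3
  expect_equal(total_ntp_production(v, TOY), 12)
  expect_equal(total_ntp_production(v, TOY, exclude = character(0)), 15)
  # zero vector and permutation invariance
  v0 <- v; v0$fluxes[] <- 0
  expect_equal(total_ntp_production(v0, TOY), 0)
  perm <- sample(length(v$fluxes))
  vp <- v; vp$fluxes <- v$fluxes[perm]
  expect_equal(total_ntp_production(vp, TOY), total_ntp_production(v, TOY))
})

test_that("ATP-hydrolysis maximization reflects substrate availability", {
  m <- TOY
  keep <- paste0("EX_", c("o2", "co2", "h2o", "h", "pi"), "_e")
  for (exr in m$reactions$id[m$reactions$is_exchange])
    if (!exr %in% keep) m <- fix_flux(m, exr, 0)
  for (b in m$biomass_ids) m <- fix_flux(m, b, 0)
  m <- set_bounds(m, "DM_atp_c", 0, 1000)
  # no substrate: nothing to hydrolyse
  expect_equal(maximize_atp_hydrolysis(m)$objective_value, 0,
               tolerance = 1e-9)
  # one glucose: the hand-computed maximal yield of the network at P/O 2.5
  # (10 NADH * 2.5 + 2 FADH2 * 1.5 + 2 GTP + 2 substrate-level ATP)
  m1 <- fix_flux(m, "EX_glc__D_e", -1)
  m1 <- set_bounds(m1, "EX_lac__L_e", 0, 1000)
  expect_equal(maximize_atp_hydrolysis(m1)$objective_value, 32,
               tolerance = 1e-6)
  # relaxing the glucose bound never decreases the optimum
  m2 <- set_bounds(m1, "EX_glc__D_e", -2, -1)
  expect_gte(maximize_atp_hydrolysis(m2)$objective_value, 32 - 1e-9)
})
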
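test_that("the maintenance fit inverts exact collinear points", {
  pts <- Map(function(mu, atp)
    structure(list(mu = mu, atp_total = atp, dataset_id = "x",
                   relaxations = NULL), class = "atp_curve_point"),
    c(0.01, 0.02, 0.03), c(6.75, 8.50, 10.25))
  fit <- fit_maintenance(pts)
  expect_equal(fit$matp, 5, tolerance = 1e-9)
  expect_equal(fit$slope, 175, tolerance = 1e-9)
  expect_equal(fit$yatp_max, 1000 / 175, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # order invariance
  fit2 <- fit_maintenance(pts[c(3, 1, 2)])
  expect_equal(fit2$matp, fit$matp)
  # degenerate growth spread refused
  bad <- lapply(1:3, function(i)
    structure(list(mu = 0.02, atp_total = 8, dataset_id = "x",
                   relaxations = NULL), class = "atp_curve_point"))
  expect_error(fit_maintenance(bad), "more than one growth rate")
  expect_error(fit_maintenance(pts[1:2]), "at least 3")
})

test_that("the noiseless chemostat closed loop returns the generator truth", {
  truth <- synthetic_truth(true_matp = 4.3, noise_cv = 0, seed = 71)
  recs <- simulate_chemostat(TOY, truth, seq(0.016, 0.035, length.out = 6))
  pts <- lapply(recs, function(rec)
    atp_curve_point(TOY, rates_to_exchange_dataset(steady_state_rates(rec))))
  fit <- fit_maintenance(pts)
  expect_equal(fit$matp, 4.3, tolerance = 1e-6 * 4.3)
  # the ATP-vs-growth slope is set by the biomass energy demand; its
  # reciprocal is the maximal yield per ATP
  expect_equal(fit$yatp_max, 1000 / fit$slope)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # no relaxations needed on noiseless data
  expect_true(all(vapply(pts, function(p) nrow(p$relaxations) == 0, TRUE)))
})

test_that("infeasible secretion constraints are relaxed stepwise and logged", {
  truth <- synthetic_truth(4.3, 0, seed = 72)
  rec <- simulate_chemostat(TOY, truth, 0.025)[[1]]
  d <- rates_to_exchange_dataset(steady_state_rates(rec))
  # inflate the ammonium secretion beyond what the fixed nitrogen uptake
  # allows (the noiseless record determines it exactly)
  i <- which(d$rates$metabolite == "nh4")
  d$rates$value[i] <- d$rates$value[i] * 1.15
  pt <- atp_curve_point(TOY, d)
  expect_false(is.null(pt))
  expect_gt(nrow(pt$relaxations), 0)
  expect_lte(max(pt$relaxations$percent), 40)
  # far beyond the cap the point is excluded with a warning
  d$rates$value[i] <- d$rates$value[i] * 3
  expect_warning(pt2 <- atp_curve_point(TOY, d), "point excluded")
  expect_null(pt2)
})

test_that("the P/O sweep reduces to a single fit and shifts the intercept", {
  truth <- synthetic_truth(4.3, 0, seed = 73)
  recs <- simulate_chemostat(TOY, truth, seq(0.018, 0.032, length.out = 4))
  ds <- lapply(recs, function(rec)
    rates_to_exchange_dataset(steady_state_rates(rec)))
  sw <- po_sensitivity(TOY, ds, 2.5)
  ref <- fit_maintenance(lapply(ds, function(d) atp_curve_point(TOY, d)))
  expect_equal(sw[["2.5"]]$matp, ref$matp, tolerance = 1e-9)
  # truth generated at 2.5 is recovered at 2.5
  expect_equal(sw[["2.5"]]$matp, 4.3, tolerance = 1e-6)
  # evaluating the same data at other P/O values moves the estimate
  # monotonically (more ATP per substrate at higher P/O)
  sw3 <- po_sensitivity(TOY, ds, c(2.0, 2.5, 3.0))
  m <- vapply(sw3, `[[`, 0, "matp")
  expect_true(all(diff(m) > 0) || all(diff(m) < 0))
})
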
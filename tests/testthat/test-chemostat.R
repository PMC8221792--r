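mk_record <- function(feed_slope = 5.4, V = 270, n = 5,
                      conc = cbind(glc__D = rep(10, 5)),
                      cin = c(glc__D = 30), nv = 5.5e6, nt = NULL) {
  times <- seq(0, by = 12, length.out = n)
  chemostat_record("T1", times, feed_slope * times, V,
                   rep(nv, n), rep(nt %||% nv / 0.95, n),
                   conc, cin)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("dilution rate comes from the feed-mass slope over the volume", {
  r <- mk_record(feed_slope = 5.4, V = 270)
  d <- dilution_rate(r)
  expect_equal(d$D, 0.02, tolerance = 1e-12)
  expect_equal(d$F, 5.4, tolerance = 1e-12)
  # zero feed
  expect_equal(dilution_rate(mk_record(feed_slope = 0))$D, 0)
  # noisy series recovers the slope within the fit uncertainty
  set.seed(9)
  r2 <- mk_record(feed_slope = 5.4, n = 12)
  r2$feed_mass <- r2$feed_mass + rnorm(12, 0, 0.5)
  d2 <- dilution_rate(r2)
  expect_lt(abs(d2$D - 0.02), 3 * d2$sd + 1e-9)
  r1 <- mk_record(); r1$times <- r1$times[1]; r1$feed_mass <- r1$feed_mass[1]
  expect_error(dilution_rate(r1), "at least two")
})

test_that("growth rate scales the dilution rate by the viability ratio", {
  expect_equal(growth_rate(0.02, 100, 100)$mu, 0.02)
  expect_equal(growth_rate(0.020, 105, 100)$mu, 0.021)
  expect_equal(growth_rate(0.030, 110, 100)$mu, 0.033)
  expect_error(growth_rate(0.02, 1, 0), "positive")
  # mu >= D always, since Nt >= Nv
  set.seed(5)
  for (k in 1:20) {
    nv <- runif(1, 1, 10); nt <- nv * runif(1, 1, 1.2); d <- runif(1, 0, 0.05)
    expect_gte(growth_rate(d, nt, nv)$mu, d)
  }
})

test_that("exchange rates follow the concentration balance with uptake negative", {
  e <- exchange_rate(30, 10, 0.02, 1.5)
  expect_equal(e$q, -(20 * 0.02) / 1.5)  # magnitude 0.267, uptake negative
  expect_equal(exchange_rate(5, 5, 0.02, 1.5)$q, 0)
  expect_equal(exchange_rate(0, 40, 0.021, 1.5)$q, 0.56)
  expect_error(exchange_rate(-1, 5, 0.02, 1.5), "non-negative")
  expect_error(exchange_rate(1, 5, 0.02, 0), "positive")
  # linear in (Cout - Cin) and in D
  q1 <- exchange_rate(0, 10, 0.02, 1.5)$q
  expect_equal(exchange_rate(0, 20, 0.02, 1.5)$q, 2 * q1)
  expect_equal(exchange_rate(0, 10, 0.04, 1.5)$q, 2 * q1)
})

test_that("stability is judged by the slope confidence interval", {
  set.seed(11)
  t <- seq(0, 48, by = 6)
  flat <- stability_check(10 + rnorm(length(t), 0, 0.01), t)
  expect_true(flat$stable)
  trend <- stability_check(10 + 0.5 * t + rnorm(length(t), 0, 0.05), t)
  expect_false(trend$stable)
  expect_false(trend$insufficient_data)
  # two points: no confidence interval, flagged rather than silently stable
  two <- stability_check(c(10, 11), c(0, 12))
  expect_true(two$insufficient_data)
  expect_true(is.na(two$stable))
  # significant slope within instrument error is flagged as an override
  ovr <- stability_check(10 + 0.001 * t + rnorm(length(t), 0, 1e-5), t,
                         instrument_error = 0.2)
  expect_true(ovr$within_instrument_error)
})

test_that("steady-state rates and Monte-Carlo error propagation agree", {
  # Eq-5 form vs sampling oracle on the exchange-rate pipeline
  set.seed(13)
  nmc <- 1e5
  A <- rnorm(nmc, 20, 1); B <- rnorm(nmc, 0.02, 0.001)
  C <- rnorm(nmc, 1.5, 0.05)
  mc_sd <- stats::sd(A * B / C)
  an_sd <- propagate_sd("product_quotient", c(20, 0.02, 1.5),
                        c(1, 0.001, 0.05), result = 20 * 0.02 / 1.5)
  expect_equal(an_sd, mc_sd, tolerance = 0.05)
})

test_that("carbon recovery closes exactly on balanced synthetic steady states", {
  truth <- synthetic_truth(4.3, 0, seed = 61)
  recs <- simulate_chemostat(TOY, truth, c(0.018, 0.025, 0.032))
  for (rec in recs) {
    rts <- steady_state_rates(rec)
    expect_equal(carbon_recovery(rts, TOY), 1, tolerance = 1e-6)
    expect_gte(rts$mu, rts$D)
  }
  # hand-built: secretion carries half the uptake carbon, no growth
  fake <- list(mu = 0,
               q = data.frame(metabolite = c("glc__D", "lac__L"),
                              value = c(-1, 1), sd = 0))
  expect_equal(carbon_recovery(fake, TOY, mu = 0), 0.5)
  # under-measuring a secreted carbon species lowers recovery by exactly
  # that species' carbon share
  rts <- steady_state_rates(recs[[1]])
  i <- which(rts$q$metabolite == "co2")
  full <- carbon_recovery(rts, TOY)
  carbons <- vapply(rts$q$metabolite, function(met)
    carbon_count(TOY$metabolites[TOY$metabolites$id == paste0(met, "_e"), ]),
    0L)
  c_up <- sum(-rts$q$value[rts$q$value < 0] * carbons[rts$q$value < 0])
  share <- 0.1 * rts$q$value[i] * carbons[[i]] / c_up
  rts$q$value[i] <- 0.9 * rts$q$value[i]
  expect_equal(carbon_recovery(rts, TOY), full - share, tolerance = 1e-9)
  expect_lt(carbon_recovery(rts, TOY), full)
})
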
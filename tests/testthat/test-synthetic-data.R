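test_that("generators are deterministic under a fixed seed", {
  tr <- synthetic_truth(6, 0.1, seed = 41)
  a <- simulate_c13_dataset(TOY, tr, "d")
  b <- simulate_c13_dataset(TOY, tr, "d")
  expect_identical(a$c13$fluxes, b$c13$fluxes)
  expect_identical(a$exchange$rates, b$exchange$rates)
  ra <- simulate_chemostat(TOY, tr, c(0.02, 0.03))
  rb <- simulate_chemostat(TOY, tr, c(0.02, 0.03))
  expect_identical(ra[[1]]$concentrations, rb[[1]]$concentrations)
  # different seeds differ
  c2 <- simulate_c13_dataset(TOY, synthetic_truth(6, 0.1, seed = 42), "d")
  expect_false(identical(a$c13$fluxes$value, c2$c13$fluxes$value))
})

test_that("the generated mapping exercises all three mapping rules", {
  tab <- toy_mapping_table()
  terms <- split(tab, tab$c13_id)
  n_terms <- vapply(terms, nrow, 0L)
  expect_true(any(n_terms > 1))                     # multi-reaction sums
  expect_true(any(tab$sign == -1))                  # signed net flux
  # compartment merge: same enzyme in two compartments summed
  ala <- terms[["ALATA_TOTAL"]]
  expect_setequal(ala$gsmm_id, c("ALATA", "ALATA_m"))
  expect_true(all(ala$sign == 1))
  # every referenced reaction resolves in the model
  expect_true(all(tab$gsmm_id %in% TOY$reactions$id))
})

test_that("generated datasets satisfy their consumers' preconditions", {
  tr <- synthetic_truth(6, 0.1, seed = 43)
  sim <- simulate_c13_dataset(TOY, tr, "d43")
  expect_s3_class(sim$c13, "c13_dataset")
  f <- sim$c13$fluxes
  expect_true(all(f$ci_low <= f$value & f$value <= f$ci_high))
  expect_true(all(sim$exchange$rates$sd >= 0))
  # an estimation run accepts the dataset end to end
  est <- estimate_matp(TOY, sim$c13, sim$mapping, grid = seq(4, 8, 1))
  expect_s3_class(est, "maintenance_estimate")
})

test_that("multiplicative noise has the configured coefficient of variation", {
  set.seed(123)
  f <- maintflux:::noise_factor(20000, 0.1)
  expect_equal(stats::sd(f), 0.1, tolerance = 0.05)
  expect_equal(mean(f), 1, tolerance = 0.01)
  expect_true(all(f > 0.69 & f < 1.31))  # truncated at 3 sigma
  expect_equal(maintflux:::noise_factor(5, 0), rep(1, 5))
  # observed dispersion across seeded datasets matches, relative to the
  # stated confidence intervals (ci half-width = 1.96 * cv * |value|)
  tr <- synthetic_truth(6, 0.1, seed = 45)
  sim <- simulate_c13_dataset(TOY, tr, "cv")
  f <- sim$c13$fluxes
  expect_equal((f$ci_high - f$ci_low) / 2, 1.96 * 0.1 * abs(f$value),
               tolerance = 1e-9)
})

test_that("chemostat simulation spans the requested dilution range or fails at washout", {
  tr <- synthetic_truth(4.3, 0, seed = 44)
  dr <- seq(0.016, 0.035, length.out = 11)
  recs <- simulate_chemostat(TOY, tr, dr)
  expect_length(recs, 11)
  mus <- vapply(recs, function(r) steady_state_rates(r)$mu, 0)
  expect_equal(mus, dr / 0.95, tolerance = 1e-6)
  expect_true(all(vapply(recs, function(r)
    all(r$total_density >= r$viable_density), TRUE)))
  # at very low dilution the feed cannot pay the fixed maintenance
  expect_error(simulate_chemostat(TOY, tr, 5e-4), "not sustainable")
})
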
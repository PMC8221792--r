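test_that("relative errors follow the elementwise definition", {
  expect_equal(relative_errors(c(a = 1), c(a = 1))$median, 0)
  expect_equal(relative_errors(c(a = 2), c(a = 1))$median, 1)
  re <- relative_errors(c(a = 1, b = 2, d = 4), c(a = 1, b = 1, d = 2))
  expect_equal(unname(re$errors), c(0, 1, 1))
  expect_equal(re$median, 1)
  expect_equal(re$mean, 2 / 3)
  # scale invariance
  set.seed(1)
  vp <- stats::setNames(rnorm(10, 5), letters[1:10])
  ve <- stats::setNames(rnorm(10, 5), letters[1:10])
  expect_equal(relative_errors(3 * vp, 3 * ve)$errors,
               relative_errors(vp, ve)$errors)
  expect_error(relative_errors(c(a = 1), c(a = 0)), "zero experimental")
})

test_that("weighted fit handles weights, caps and degenerate widths", {
  x <- 1:10; y <- 2 * x + 1
  f <- weighted_fit(x, y, ci_widths = runif(10, 1, 2))
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # equal widths reproduce ordinary least squares exactly
  set.seed(2)
  y2 <- 2 * x + rnorm(10)
  f_eq <- weighted_fit(x, y2, rep(3.7, 10))
  f_ols <- stats::lm(y2 ~ x)
  expect_equal(f_eq$slope, unname(stats::coef(f_ols)[2]), tolerance = 1e-10)
  expect_equal(f_eq$intercept, unname(stats::coef(f_ols)[1]),
               tolerance = 1e-10)
  # a dominant weight pulls the fit onto that point
  x3 <- c(1, 2, 3, 10); y3 <- c(1, 2, 3, 50)
  w <- c(1, 1, 1, 1e-6)  # widths: last point gets a 10^6-fold weight
  f3 <- weighted_fit(x3, y3, w)
  expect_lt(abs(50 - (f3$intercept + 10 * f3$slope)), 0.1)
  # zero width capped, missing width gets the median weight
  f4 <- weighted_fit(x, y2, c(0, NA, runif(8, 1, 2)))
  expect_s3_class(f4, "regression_result")
})

test_that("the interaction test separates changed from unchanged slopes", {
  set.seed(7)
  n <- 200
  ve <- runif(n, 0, 10)
  # same slope in both groups: interaction rarely significant
  hits <- 0
  for (r in 1:40) {
    vp0 <- 0.8 * ve + rnorm(n, 0, 1)
    vp1 <- 0.8 * ve + rnorm(n, 0, 1)
    if (matp_effect_test(ve, vp0, vp1)$p_interaction < 0.05)
      hits <- hits + 1
  }
  expect_lte(hits, 6)   # ~2 expected at the nominal level
  # slopes 0.36 vs 0.98 with modest noise: overwhelmingly significant
  res <- matp_effect_test(ve, 0.36 * ve + rnorm(n, 0, 0.5),
                          0.98 * ve + rnorm(n, 0, 0.5))
  expect_lt(res$p_interaction, 1e-6)
  expect_equal(res$slope_without, 0.36, tolerance = 0.1)
  expect_equal(res$slope_with, 0.98, tolerance = 0.1)
  expect_gte(res$lr_chi2, 0)
  expect_lt(res$lr_p, 1e-6)
  # zero noise, different slopes: perfect separation
  res0 <- matp_effect_test(ve, 0.36 * ve, 0.98 * ve)
  expect_lt(res0$p_interaction, 1e-12)
})

test_that("subsystem report reduces to the overall row and splits cleanly", {
  set.seed(4)
  ve <- stats::setNames(runif(12, 1, 5), paste0("r", 1:12))
  vp <- ve * (1 + rnorm(12, 0, 0.1))
  subs_one <- stats::setNames(rep("Glycolysis", 12), names(ve))
  rep1 <- subsystem_report(vp, ve, subs_one)
  expect_equal(nrow(rep1), 2)
  expect_equal(rep1$median_re[1], rep1$median_re[2])
  expect_equal(rep1$r_squared[1], rep1$r_squared[2])
  # disjoint perfect vs bad predictions
  subs2 <- stats::setNames(rep(c("TCA", "PPP"), each = 6), names(ve))
  vp2 <- ve
  vp2[subs2 == "PPP"] <- ve[subs2 == "PPP"] * 3
  rep2 <- subsystem_report(vp2, ve, subs2)
  expect_equal(rep2$median_re[rep2$subsystem == "TCA"], 0)
  expect_equal(rep2$median_re[rep2$subsystem == "PPP"], 2)
  # small subsystems are omitted but reported
  subs3 <- subs2; subs3[1] <- "Tiny"
  rep3 <- subsystem_report(vp2, ve, subs3)
  expect_false("Tiny" %in% rep3$subsystem)
  expect_true("Tiny" %in% attr(rep3, "omitted"))
})

test_that("error propagation matches the closed forms", {
  expect_equal(propagate_sd("product_quotient", c(10, 5), c(1, 0.5),
                            result = 50),
               50 * sqrt(0.01 + 0.01))
  expect_equal(propagate_sd("sum_difference", c(3, 4), c(3, 4)), 5)
  expect_equal(propagate_sd("product_quotient", c(10, 5), c(0, 0),
                            result = 2), 0)
  expect_error(propagate_sd("product_quotient", c(0, 1), c(1, 1),
                            result = 0), "zero operand")
})
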
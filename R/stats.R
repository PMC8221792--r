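#' Relative errors between predicted and experimental fluxes
#'
#' Computes `|v_p - v_e| / |v_e|` per shared entry, plus mean and median.
#' Entries with a zero experimental flux must be filtered upstream (see
#' [filter_small_fluxes()]); reaching this function with one is an error.
#'
#' @param vp,ve named numeric vectors of predicted and experimental values;
#'   errors are computed over the names of `ve`.
#' @return list with `errors` (named vector), `mean`, `median`.
#' @export
relative_errors <- function(vp, ve) {
  keys <- names(ve)
  if (is.null(keys) || !all(keys %in% names(vp)))
    stop("vp must cover all names of ve")
  if (any(ve == 0))
    stop("zero experimental flux reached relative_errors; ",
         "filter small fluxes first")
  err <- abs(vp[keys] - ve[keys]) / abs(ve[keys])
  list(errors = err, mean = mean(err), median = stats::median(err))
}

#' Weighted linear fit of predicted vs experimental fluxes
#'
#' Weighted least squares with the inverse experimental confidence-interval
#' widths as weights. Zero widths get the largest finite weight in the
#' dataset and missing widths the median weight, so single points cannot
#' acquire infinite leverage.
#'
#' @param x experimental values (abscissa).
#' @param y predicted values.
#' @param ci_widths confidence-interval widths (`ci_high - ci_low`), same
#'   length; `NULL` for an unweighted fit.
#' @return list of class `regression_result`: `slope`, `intercept` (each
#'   with `*_se`), `r_squared`, `fit` (the `lm` object).
#' @export
weighted_fit <- function(x, y, ci_widths = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(ci_widths)) {
    w <- rep(1, length(x))
  } else {
    stopifnot(length(ci_widths) == length(x))
    w <- ifelse(is.na(ci_widths), NA, 1 / ci_widths)
    finite <- is.finite(w)
    if (!any(finite)) {
      if (all(is.na(w))) w <- rep(1, length(x))
      else stop("no usable confidence-interval widths for weighting")
    } else {
      w[!is.na(w) & !finite] <- max(w[finite])
      w[is.na(w)] <- stats::median(w[!is.na(w)])
    }
  }
  fit <- stats::lm(y ~ x, weights = w)
  # exact collinearity is routine for noiseless synthetic data
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  structure(list(slope = cf["x", "Estimate"],
                 slope_se = cf["x", "Std. Error"],
                 intercept = cf["(Intercept)", "Estimate"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 r_squared = sm$r.squared,
                 fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> slope ", signif(x$slope, 4), " +/- ",
      signif(x$slope_se, 3), ", intercept ", signif(x$intercept, 4),
      ", R^2 ", signif(x$r_squared, 3), "\n", sep = "")
  invisible(x)
}

#' Test whether a maintenance constraint changes the fit
#'
#' Stacks the predictions made without and with the maintenance-ATP
#' constraint over the same experimental fluxes, adds the constraint as a
#' categorical predictor `g` (0/1) with an interaction term
#' (`vp ~ ve * g`), and reports the p-value of the interaction coefficient
#' (does the constraint change the slope?) together with a likelihood-ratio
#' chi-squared comparison of the nested models without vs with the `g`
#' terms.
#'
#' @param ve experimental fluxes.
#' @param vp_without,vp_with predictions without / with the constraint.
#' @param weights optional per-point weights, recycled across both groups.
#' @return list with `p_interaction`, `slope_without`, `slope_with`,
#'   `lr_chi2`, `lr_df`, `lr_p`.
#' @export
matp_effect_test <- function(ve, vp_without, vp_with, weights = NULL) {
  stopifnot(length(ve) == length(vp_without),
            length(ve) == length(vp_with))
  df <- data.frame(ve = c(ve, ve), vp = c(vp_without, vp_with),
                   g = rep(c(0, 1), each = length(ve)))
  w <- if (is.null(weights)) NULL else rep(weights, 2)
  fit0 <- stats::lm(vp ~ ve, data = df, weights = w)
  fit1 <- stats::lm(vp ~ ve * g, data = df, weights = w)
  cf <- suppressWarnings(summary(fit1))$coefficients  # exact fits possible
  if (!"ve:g" %in% rownames(cf)) stop("degenerate stacked regression")
  lr <- as.numeric(2 * (stats::logLik(fit1) - stats::logLik(fit0)))
  lr <- max(lr, 0)
  list(p_interaction = cf["ve:g", "Pr(>|t|)"],
       slope_without = cf["ve", "Estimate"],
       slope_with = cf["ve", "Estimate"] + cf["ve:g", "Estimate"],
       lr_chi2 = lr, lr_df = 2L,
       lr_p = stats::pchisq(lr, 2L, lower.tail = FALSE))
}

#' Per-subsystem agreement report
#'
#' R-squared (weighted fit) and median relative error per central-carbon
#' subsystem plus an overall row, the standard layout for comparing flux
#' predictions with and without a maintenance constraint.
#'
#' @param vp,ve named predicted / experimental fluxes (shared names).
#' @param subsystems named character vector, entry id -> subsystem.
#' @param ci_widths optional named confidence-interval widths for the
#'   weighted fits.
#' @return data.frame with columns `subsystem`, `n`, `r_squared`,
#'   `median_re`; subsystems with fewer than 3 entries are omitted (noted
#'   in attribute `omitted`), the `"All"` row is always present.
#' @export
subsystem_report <- function(vp, ve, subsystems, ci_widths = NULL) {
  keys <- names(ve)
  stopifnot(!is.null(keys), all(keys %in% names(vp)),
            all(keys %in% names(subsystems)))
  cw <- if (is.null(ci_widths)) NULL else ci_widths[keys]
  one <- function(sel, label) {
    fit <- weighted_fit(ve[sel], vp[sel],
                        if (is.null(cw)) NULL else cw[sel])
    re <- relative_errors(vp[sel], ve[sel])
    data.frame(subsystem = label, n = length(sel),
               r_squared = fit$r_squared, median_re = re$median)
  }
  subs <- split(keys, subsystems[keys])
  enough <- vapply(subs, length, 0L) >= 3L
  rows <- lapply(names(subs)[enough], function(s) one(subs[[s]], s))
  out <- rbind(do.call(rbind, rows), one(keys, "All"))
  rownames(out) <- NULL
  attr(out, "omitted") <- names(subs)[!enough]
  out
}

#' Propagate standard deviations through products and sums
#'
#' For products/quotients (`C = A*B` or `A/B`) the relative variances add:
#' `sigma_C = |C| * sqrt((sigma_A/A)^2 + (sigma_B/B)^2)`. For sums and
#' differences the absolute variances add:
#' `sigma_C = sqrt(sigma_A^2 + sigma_B^2)`.
#'
#' @param op `"product_quotient"` or `"sum_difference"`.
#' @param values numeric vector of the operands (any length); for the
#'   product/quotient form also supply `result`, the computed value of C.
#' @param sds standard deviations of the operands.
#' @param result value of the combined quantity (product/quotient only).
#' @return the propagated standard deviation.
#' @export
propagate_sd <- function(op = c("product_quotient", "sum_difference"),
                         values, sds, result = NULL) {
  op <- match.arg(op)
  stopifnot(length(values) == length(sds), all(sds >= 0))
  if (op == "sum_difference") return(sqrt(sum(sds^2)))
  if (any(values == 0))
    stop("relative error propagation undefined for a zero operand; ",
         "use the sum_difference form on absolute errors instead")
  if (is.null(result)) stop("supply the computed result C for the ",
                            "product/quotient form")
  abs(result) * sqrt(sum((sds / values)^2))
}
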
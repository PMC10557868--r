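#' Fit a thermal-aggregation melt curve
#'
#' Least-squares fit of a descending logistic
#' f(T) = bottom + (top - bottom) / (1 + exp((T - Tagg)/slope))
#' to soluble-fraction data; Tagg is the aggregation midpoint.
#'
#' @param temperature_C Heating temperatures, deg C (>= 4 distinct values).
#' @param soluble_fraction Normalized soluble fractions (same length).
#' @param flat_tol Minimum observed range below which the data are declared
#'   flat (no transition) and the fit fails.
#' @return An object of class `melt_curve_fit` with `tagg`, `slope`, `top`,
#'   `bottom`, `chi2`.
#' @export
fit_melt_curve <- function(temperature_C, soluble_fraction, flat_tol = 0.05) {
  if (length(temperature_C) != length(soluble_fraction))
    stop_data("temperature and fraction vectors must have equal length")
  if (length(unique(temperature_C)) < 4)
    stop_data("at least 4 distinct temperatures are required")
  if (diff(range(soluble_fraction)) < flat_tol)
    stop_fit(sprintf(
      "no melt transition: observed range %.3g is below the flatness tolerance %.3g",
      diff(range(soluble_fraction)), flat_tol))
  x <- temperature_C; y <- soluble_fraction
  top0 <- max(y); bot0 <- min(y)
  # midpoint init from the mean fraction profile crossing half-height
  prof <- stats::aggregate(y, list(x), mean)
  mid <- (top0 + bot0) / 2
  cross <- which(diff(sign(prof$x - mid)) != 0)
  t0 <- if (length(cross)) prof$Group.1[cross[1]] else stats::median(x)
  resid_fn <- function(p)
    y - (p[4] + (p[3] - p[4]) / (1 + exp((x - p[1]) / p[2])))
  best <- NULL
  for (s0 in c(1, 2.5, 5)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(c(t0, s0, top0, bot0),
                         lower = c(min(x) - 20, 0.05, -Inf, -Inf),
                         upper = c(max(x) + 20, 50, Inf, Inf),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop_fit("melt-curve fit failed to converge")
  p <- best$fit$par
  structure(list(tagg = p[1], slope = p[2], top = p[3], bottom = p[4],
                 chi2 = best$ssr / max(length(y) - 4, 1), ssr = best$ssr,
                 temperature_C = x, soluble_fraction = y),
            class = "melt_curve_fit")
}

#' @export
coef.melt_curve_fit <- function(object, ...) {
  c(tagg = object$tagg, slope = object$slope, top = object$top,
    bottom = object$bottom)
}

#' @export
print.melt_curve_fit <- function(x, ...) {
  cat(sprintf("Melt-curve fit: Tagg = %.2f C (slope %.2f, top %.3g, bottom %.3g)\n",
              x$tagg, x$slope, x$top, x$bottom))
  invisible(x)
}

#' @export
predict.melt_curve_fit <- function(object, temperature_C = object$temperature_C,
                                   ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + exp((temperature_C - object$tagg) / object$slope))
}

#' @export
plot.melt_curve_fit <- function(x, ...) {
  plot(x$temperature_C, x$soluble_fraction, xlab = "temperature (C)",
       ylab = "soluble fraction", ...)
  tt <- seq(min(x$temperature_C), max(x$temperature_C), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(v = x$tagg, lty = 3)
  invisible(x)
}

#' Mean/SE melt-curve summary
#'
#' Replicate mean and standard error of the soluble fraction per temperature
#' and treatment arm (the plotting-level summary of a melt experiment,
#' without any curve fit).
#'
#' @param melt Long table with columns treatment, replicate, temperature_C,
#'   soluble_fraction.
#' @return data.frame: treatment, temperature_C, mean_fraction, se_fraction,
#'   n.
#' @export
melt_curve_summary <- function(melt) {
  agg <- stats::aggregate(soluble_fraction ~ treatment + temperature_C, melt,
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  out <- data.frame(treatment = agg$treatment,
                    temperature_C = agg$temperature_C,
                    mean_fraction = agg$soluble_fraction[, "mean"],
                    se_fraction = agg$soluble_fraction[, "se"],
                    n = agg$soluble_fraction[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$treatment, out$temperature_C), ]
}

#' Thermal-shift estimate with bootstrap confidence interval
#'
#' Delta Tagg = Tagg(treated) - Tagg(vehicle) from melt-curve fits on the
#' pooled replicates of each arm. The confidence interval combines a
#' stratified bootstrap SE (replicate bands resampled with replacement
#' within each temperature, fixed seed) with a Student-t quantile at
#' replicate-level degrees of freedom; at typical replicate counts (2-4 per
#' arm) plain percentile intervals are markedly anti-conservative.
#'
#' @param treated,vehicle Long melt tables (columns replicate, temperature_C,
#'   soluble_fraction) for the two arms.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return List with `delta_tagg`, `ci`, `tagg_treated`, `tagg_vehicle`,
#'   `n_boot_ok`.
#' @export
delta_tagg <- function(treated, vehicle, n_boot = 199, seed = 1L,
                       conf = 0.95) {
  fit_arm <- function(d) fit_melt_curve(d$temperature_C, d$soluble_fraction)
  ft <- fit_arm(treated); fv <- fit_arm(vehicle)
  est <- ft$tagg - fv$tagg
  resample <- function(d) {
    idx <- unlist(lapply(split(seq_len(nrow(d)), d$temperature_C),
                         function(i) sample(i, length(i), replace = TRUE)),
                  use.names = FALSE)
    d[idx, , drop = FALSE]
  }
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      tryCatch(fit_arm(resample(treated))$tagg - fit_arm(resample(vehicle))$tagg,
               error = function(e) NA_real_)
    }, 0)
  })
  ok <- boots[is.finite(boots)]
  df <- length(unique(treated$replicate)) +
    length(unique(vehicle$replicate)) - 2
  ci <- if (length(ok) >= 10 && df >= 1) {
    half <- stats::qt(1 - (1 - conf) / 2, df) * stats::sd(ok)
    c(est - half, est + half)
  } else c(NA_real_, NA_real_)
  list(delta_tagg = est, ci = ci, se_boot = stats::sd(ok), df = df,
       tagg_treated = ft$tagg, tagg_vehicle = fv$tagg,
       n_boot_ok = length(ok))
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of
#' response = bottom + (top - bottom) / (1 + (dose/IC50)^hill).
#' The IC50 is the inflection dose of the fitted curve (relative IC50).
#'
#' @param dose Doses, M (> 0, >= 4 distinct values).
#' @param response Responses (same length).
#' @param assay Optional assay label (e.g. "viability" or "reporter").
#' @return An object of class `dose_response_fit` with `ic50`, `hill`,
#'   `top`, `bottom`, `chi2`, `assay`.
#' @export
fit_4pl <- function(dose, response, assay = NA_character_) {
  if (length(dose) != length(response))
    stop_data("dose and response must have equal length")
  if (any(dose <= 0)) stop_domain("doses must be > 0")
  if (length(unique(dose)) < 4)
    stop_data("at least 4 distinct doses are required for a 4PL fit")
  ld <- log10(dose)
  top0 <- max(response); bot0 <- min(response)
  resid_fn <- function(p)
    response - (p[4] + (p[3] - p[4]) / (1 + (dose / 10^p[1])^p[2]))
  best <- NULL
  for (i0 in stats::quantile(ld, c(0.25, 0.5, 0.75))) for (h0 in c(0.7, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(c(i0, h0, top0, bot0),
                         lower = c(min(ld) - 2, 0.05, -Inf, -Inf),
                         upper = c(max(ld) + 2, 20, Inf, Inf),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop_fit("4PL dose-response fit failed to converge")
  p <- best$fit$par
  out <- structure(list(ic50 = 10^p[1], hill = p[2], top = p[3],
                        bottom = p[4],
                        chi2 = best$ssr / max(length(response) - 4, 1),
                        ssr = best$ssr, dose = dose, response = response,
                        assay = assay),
                   class = "dose_response_fit")
  if (out$top < out$bottom)
    warning("responses increase with dose; fitted top is below bottom")
  out
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lbl <- if (is.na(x$assay)) "" else sprintf(" [%s]", x$assay)
  cat(sprintf("4PL dose-response fit%s: IC50 = %.4g M, hill = %.3g, top = %.3g, bottom = %.3g\n",
              lbl, x$ic50, x$hill, x$top, x$bottom))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, dose = object$dose, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (dose / object$ic50)^object$hill)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$dose, x$response, log = "x", xlab = "dose (M)", ylab = "response",
       ...)
  dd <- 10^seq(log10(min(x$dose)) - 0.5, log10(max(x$dose)) + 0.5,
               length.out = 100)
  graphics::lines(dd, predict(x, dd))
  graphics::abline(v = x$ic50, lty = 3)
  invisible(x)
}

#' Viability/reporter selectivity index
#'
#' IC50(viability) / IC50(reporter). An index above 1 means the reporter is
#' inhibited at doses below those required to kill the cells (an on-target
#' transcriptional effect); an index near 1 means overlapping curves.
#'
#' @param viability_fit,reporter_fit `dose_response_fit` objects for the same
#'   cell line and compound.
#' @return Dimensionless selectivity index.
#' @export
selectivity_index <- function(viability_fit, reporter_fit) {
  stopifnot(inherits(viability_fit, "dose_response_fit"),
            inherits(reporter_fit, "dose_response_fit"))
  viability_fit$ic50 / reporter_fit$ic50
}

#' Compare group IC50s
#'
#' Percent difference between two groups of IC50s,
#' 100 (mean_b - mean_a) / mean_b with group a the lower-mean (sensitive)
#' group by convention, plus a two-sample Student t test. Whether the test
#' is run on IC50s or log10 IC50s is recorded in the output.
#'
#' @param group_a IC50s of the sensitive group (M), >= 2 values.
#' @param group_b IC50s of the comparison group (M), >= 2 values.
#' @param log_scale Run the t test on log10 IC50s (default FALSE).
#' @param var_equal Pooled-variance Student test (default TRUE).
#' @return List with `percent_difference`, `p_value`, `t`, group means, and
#'   metadata recording the formula and scale used.
#' @export
compare_group_ic50 <- function(group_a, group_b, log_scale = FALSE,
                               var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_data("at least 2 IC50s per group are required")
  ma <- mean(group_a); mb <- mean(group_b)
  pct <- 100 * (mb - ma) / mb
  xa <- if (log_scale) log10(group_a) else group_a
  xb <- if (log_scale) log10(group_b) else group_b
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    # degenerate groups: identical means are indistinguishable (t = 0, p = 1)
    tv <- if (mean(xa) == mean(xb)) 0 else sign(mean(xa) - mean(xb)) * Inf
    ht <- list(statistic = tv, p.value = if (tv == 0) 1 else 0)
  } else {
    ht <- stats::t.test(xa, xb, var.equal = var_equal)
  }
  list(percent_difference = pct, p_value = ht$p.value,
       t = unname(ht$statistic), mean_a = ma, mean_b = mb,
       formula = "100*(mean_b - mean_a)/mean_b",
       test_scale = if (log_scale) "log10(IC50)" else "IC50",
       method = if (var_equal) "Student" else "Welch")
}
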
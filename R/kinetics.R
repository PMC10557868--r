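#' Global 1:1 kinetic fit of a multi-concentration sensorgram series
#'
#' Fits a single set of rate constants (ka, kd) and one Rmax to the
#' association and dissociation phases of all cycles simultaneously by
#' Levenberg-Marquardt least squares on log-scaled parameters, with an
#' optional free per-cycle bulk refractive-index offset during the injection.
#' The fit is repeated from several log-spaced starting points and the best
#' sum of squared residuals is returned.
#'
#' @param series List of preprocessed `sensorgram` objects at three or more
#'   distinct analyte concentrations sharing one phase structure.
#' @param include_bulk_offset Float a per-cycle constant offset during the
#'   injection (default TRUE).
#' @param ka_bounds,kd_bounds Box constraints on the rate constants,
#'   1/(M*s) and 1/s.
#' @param rmax_upper Upper bound on Rmax, RU; defaults to 10 times the
#'   largest observed response.
#' @param n_starts Number of log-spaced multi-start initializations.
#' @return An object of class `spr_kinetic_fit` with components `params`
#'   (a [kinetic_params()] with reduced chi-square), `offsets`, `fitted`,
#'   `series`, `ssr`, `n_points` and `convergence`.
#' @export
fit_kinetics <- function(series, include_bulk_offset = TRUE,
                         ka_bounds = c(1e2, 1e9), kd_bounds = c(1e-6, 1),
                         rmax_upper = NULL, n_starts = 5) {
  if (!is.list(series) || !all(vapply(series, inherits, TRUE, "sensorgram")))
    stop_data("series must be a list of sensorgram objects")
  conc <- vapply(series, function(s) s$analyte_concentration, 0)
  if (any(is.na(conc)) || any(conc <= 0))
    stop_data("every cycle must declare a positive analyte concentration")
  if (length(unique(conc)) < 3)
    stop_data("at least 3 distinct concentrations are required for a global kinetic fit")
  is0 <- series[[1]]$inject_start; ie0 <- series[[1]]$inject_end
  for (s in series)
    if (s$inject_start != is0 || s$inject_end != ie0)
      stop_data("all cycles must share the same phase structure")
  n_cyc <- length(series)
  obs <- lapply(series, function(s) {
    sel <- s$time >= s$inject_start
    list(t = s$time[sel], y = s$response[sel],
         assoc = s$time[sel] <= s$inject_end)
  })
  ymax <- max(vapply(obs, function(o) max(abs(o$y)), 0), 1e-6)
  if (is.null(rmax_upper)) rmax_upper <- 10 * ymax

  model_traces <- function(ka, kd, Rmax, offsets) {
    lapply(seq_len(n_cyc), function(j) {
      o <- obs[[j]]
      kobs <- ka * conc[j] + kd
      Req <- ka * conc[j] * Rmax / kobs
      r <- numeric(length(o$t))
      ta <- o$t[o$assoc] - is0
      r[o$assoc] <- Req * (1 - exp(-kobs * ta)) + offsets[j]
      R0 <- Req * (1 - exp(-kobs * (ie0 - is0)))
      r[!o$assoc] <- R0 * exp(-kd * (o$t[!o$assoc] - ie0))
      r
    })
  }
  resid_fn <- function(p) {
    ka <- 10^p[1]; kd <- 10^p[2]; Rmax <- 10^p[3]
    offsets <- if (include_bulk_offset) p[-(1:3)] else rep(0, n_cyc)
    tr <- model_traces(ka, kd, Rmax, offsets)
    unlist(lapply(seq_len(n_cyc), function(j) obs[[j]]$y - tr[[j]]),
           use.names = FALSE)
  }
  lo <- c(log10(ka_bounds[1]), log10(kd_bounds[1]), -6)
  hi <- c(log10(ka_bounds[2]), log10(kd_bounds[2]), log10(rmax_upper))
  if (include_bulk_offset) {
    lo <- c(lo, rep(-ymax, n_cyc)); hi <- c(hi, rep(ymax, n_cyc))
  }
  ka0 <- 10^seq(log10(ka_bounds[1]) + 1, log10(ka_bounds[2]) - 1,
                length.out = n_starts)
  kd0 <- 10^seq(log10(kd_bounds[1]) + 1, log10(kd_bounds[2]) - 0.5,
                length.out = n_starts)
  best <- NULL
  trace <- data.frame(start = integer(), ssr = numeric(),
                      converged = logical())
  for (i in seq_len(n_starts)) {
    p0 <- c(log10(ka0[i]), log10(kd0[i]), log10(min(2 * ymax, rmax_upper)))
    if (include_bulk_offset) p0 <- c(p0, rep(0, n_cyc))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    trace <- rbind(trace, data.frame(start = i, ssr = ssr,
                                     converged = fit$info %in% 1:4))
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop_fit("global kinetic fit failed to converge from any starting point")
  p <- best$fit$par
  n_points <- sum(vapply(obs, function(o) length(o$y), 0L))
  n_free <- length(p)
  chi2 <- best$ssr / max(n_points - n_free, 1)
  params <- kinetic_params(10^p[1], 10^p[2], 10^p[3], chi2 = chi2)
  offsets <- if (include_bulk_offset) p[-(1:3)] else rep(0, n_cyc)
  fitted <- model_traces(params$ka, params$kd, params$Rmax, offsets)
  structure(list(params = params, offsets = offsets, series = series,
                 obs = obs, fitted = fitted, ssr = best$ssr,
                 n_points = n_points, convergence = trace,
                 concentrations = conc),
            class = "spr_kinetic_fit")
}

#' @export
equilibrium_kd.spr_kinetic_fit <- function(object) {
  equilibrium_kd(object$params)
}

#' @export
coef.spr_kinetic_fit <- function(object, ...) {
  p <- object$params
  c(ka = p$ka, kd = p$kd, KD = p$kd / p$ka, Rmax = p$Rmax)
}

#' @export
print.spr_kinetic_fit <- function(x, ...) {
  cat(sprintf("Global 1:1 kinetic fit (%d cycles, %d points)\n",
              length(x$series), x$n_points))
  print(x$params)
  invisible(x)
}

#' @export
summary.spr_kinetic_fit <- function(object, ...) {
  structure(list(coef = coef(object), chi2 = object$params$chi2,
                 ssr = object$ssr, n_points = object$n_points,
                 n_cycles = length(object$series),
                 concentrations = object$concentrations,
                 convergence = object$convergence),
            class = "summary.spr_kinetic_fit")
}

#' @export
print.summary.spr_kinetic_fit <- function(x, ...) {
  cat(sprintf("Global 1:1 kinetic fit: %d cycles, %d points\n",
              x$n_cycles, x$n_points))
  cat(sprintf("  concentrations (M): %s\n",
              paste(signif(sort(x$concentrations), 3), collapse = ", ")))
  print(signif(x$coef, 4))
  cat(sprintf("  SSR %.4g RU^2, reduced chi2 %.4g RU^2\n", x$ssr, x$chi2))
  cat(sprintf("  multi-start: %d/%d starts converged\n",
              sum(x$convergence$converged), nrow(x$convergence)))
  invisible(x)
}

#' @export
residuals.spr_kinetic_fit <- function(object, ...) {
  lapply(seq_along(object$obs),
         function(j) object$obs[[j]]$y - object$fitted[[j]])
}

#' @export
fitted.spr_kinetic_fit <- function(object, ...) object$fitted

#' @export
predict.spr_kinetic_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) return(object$fitted)
  simulate_cycle(schedule, object$params)
}

#' @export
plot.spr_kinetic_fit <- function(x, ...) {
  rng <- range(unlist(lapply(x$obs, `[[`, "y")))
  plot(NA, xlim = range(x$obs[[1]]$t), ylim = rng,
       xlab = "time (s)", ylab = "response (RU)",
       main = "Global 1:1 kinetic fit", ...)
  for (j in seq_along(x$obs)) {
    graphics::lines(x$obs[[j]]$t, x$obs[[j]]$y, col = "grey60")
    graphics::lines(x$obs[[j]]$t, x$fitted[[j]], col = "black")
  }
  invisible(x)
}

#' Steady-state (equilibrium) affinity fit
#'
#' Least-squares fit of the 1:1 binding isotherm Req = C Rmax / (C + KD) to
#' equilibrium report points, on log-scaled parameters with multi-start.
#'
#' @param C Analyte concentrations, M; at least 3 distinct values.
#' @param Req Equilibrium responses, RU (same length as `C`).
#' @return An object of class `spr_affinity_fit` with components `KD`,
#'   `Rmax`, `chi2`, `n_points`, `method`.
#' @export
fit_steady_state <- function(C, Req) {
  if (length(C) != length(Req)) stop_data("C and Req must have equal length")
  if (length(unique(C)) < 3)
    stop_data("at least 3 distinct concentrations are required for a steady-state fit")
  if (any(C <= 0)) stop_domain("concentrations must be > 0")
  if (diff(range(Req)) == 0)
    stop_fit("responses are all equal; the isotherm is degenerate")
  resid_fn <- function(p) Req - steady_state_response(C, 10^p[1], 10^p[2])
  rmax0 <- max(Req) * 1.5
  kd_starts <- 10^seq(log10(min(C)) - 1, log10(max(C)) + 1, length.out = 5)
  best <- NULL
  for (k0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(c(log10(k0), log10(max(rmax0, 1e-6))),
                         lower = c(-12, -6), upper = c(0, 9), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop_fit("steady-state affinity fit failed to converge")
  KD <- 10^best$fit$par[1]; Rmax <- 10^best$fit$par[2]
  if (max(C) < KD)
    warning("highest concentration is below the fitted KD; the plateau is poorly constrained")
  structure(list(KD = KD, Rmax = Rmax,
                 chi2 = best$ssr / max(length(C) - 2, 1),
                 ssr = best$ssr, n_points = length(C), C = C, Req = Req,
                 method = "steady_state"),
            class = "spr_affinity_fit")
}

#' @export
equilibrium_kd.spr_affinity_fit <- function(object) object$KD

#' @export
coef.spr_affinity_fit <- function(object, ...) {
  c(KD = object$KD, Rmax = object$Rmax)
}

#' @export
print.spr_affinity_fit <- function(x, ...) {
  cat(sprintf("Steady-state affinity fit (%d points)\n", x$n_points))
  cat(sprintf("  KD   = %.4g M\n  Rmax = %.4g RU\n  chi2 = %.4g RU^2\n",
              x$KD, x$Rmax, x$chi2))
  invisible(x)
}

#' @export
predict.spr_affinity_fit <- function(object, C = object$C, ...) {
  steady_state_response(C, object$KD, object$Rmax)
}

#' @export
plot.spr_affinity_fit <- function(x, ...) {
  plot(x$C, x$Req, log = "x", xlab = "concentration (M)",
       ylab = "Req (RU)", main = "Steady-state affinity", ...)
  cc <- 10^seq(log10(min(x$C)) - 0.5, log10(max(x$C)) + 0.5, length.out = 100)
  graphics::lines(cc, predict(x, cc))
  invisible(x)
}

#' Aggregate replicate affinity estimates
#'
#' Arithmetic mean and standard error of the mean of replicate KD estimates
#' of the same interaction.
#'
#' @param fits List of fitted objects with an [equilibrium_kd()] method, or a
#'   numeric vector of KDs (M). At least 2 replicates.
#' @return An object of class `replicate_summary` with `mean_KD`, `se_KD`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(fits) {
  kds <- if (is.numeric(fits)) fits
         else vapply(fits, equilibrium_kd, 0)
  if (length(kds) < 2)
    stop_data("at least 2 replicates are required for a replicate summary")
  structure(list(mean_KD = mean(kds),
                 se_KD = stats::sd(kds) / sqrt(length(kds)),
                 n_replicates = length(kds), KD = kds),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate KD: mean %.4g M (SE %.4g M, n = %d)\n",
              x$mean_KD, x$se_KD, x$n_replicates))
  invisible(x)
}
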